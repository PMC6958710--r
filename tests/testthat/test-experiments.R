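test_that("a single-replicate ensemble reduces to that trajectory's record", {
  p <- fig1_params()
  ens <- extinction_ensemble("EcoEvoPlus", p, uniform_init(20, 60),
                             n_reps = 1, seed = 9)
  sys <- build_model("EcoEvoPlus", 2, p)
  one <- simulate_ct(sys, uniform_init(20, 60), stop_condition(t_max = 1e6),
                     seed = child_seed(9, 1), record_grid = numeric(0))
  expect_equal(ens$times, one$record$time)
  expect_equal(ens$mean, one$record$time)
})

test_that("ensembles are reproducible replicate-by-replicate", {
  p <- model_params(w_H = 0.5, w_P = 1)
  a <- extinction_ensemble("dtEvo", p, uniform_init(6, 6), 50, seed = 4)
  b <- extinction_ensemble("dtEvo", p, uniform_init(6, 6), 50, seed = 4)
  expect_identical(a$times, b$times)
  df <- as.data.frame(a)
  expect_equal(nrow(df), 50)
  expect_equal(df$extinction_time, a$times)
  expect_true(all(c("extinct_species", "extinct_genotype", "censored",
                    "seed", "w_H", "w_P") %in% names(df)))
  expect_true(all(df$extinct_species[!df$censored] %in% c("host", "parasite")))
  expect_error(extinction_ensemble("EcoEvo", fig1_params(),
                                   population_state(c(5, 0), c(5, 5)),
                                   10, seed = 1), "present")
})

test_that("fully censored ensembles are flagged unusable for the mean", {
  p <- model_params(w_H = 0, w_P = 0)
  ens <- extinction_ensemble("dtEvoPlus", p, uniform_init(40, 40),
                             n_reps = 5, seed = 2,
                             stop = stop_condition(event_max = 3))
  expect_true(ens$unusable_for_mean)
  expect_equal(ens$censored_count, 5)
  expect_true(is.na(ens$mean))
})

test_that("sweep cells pair host birth rates with equilibrium parasite sizes", {
  cells <- fig3_sweep_spec(N_P = c(30, 60), models = c("EcoEvoPlus", "EcoEvo",
                                                       "EvoPlus"))
  get <- function(m, np) cells[[which(vapply(cells, function(c)
    c$model == m && c$target_NP == np, logical(1)))]]
  # P* algebra: doubling the birth rate doubles the equilibrium N_P, and the
  # EcoEvo cell needs exactly half the EcoEvoPlus birth rate (mu = 0)
  expect_equal(get("EcoEvoPlus", 30)$b_H, 0.24, tolerance = 1e-6)
  expect_equal(get("EcoEvo", 30)$b_H, 0.12, tolerance = 1e-6)
  expect_equal(get("EcoEvoPlus", 60)$b_H, 2 * get("EcoEvoPlus", 30)$b_H,
               tolerance = 1e-6)
  # realised equilibrium hits the target and the host size stays at 250
  pp <- get("EcoEvoPlus", 60)
  fp <- interior_fixed_point("EcoEvoPlus", pp$params, 2)
  expect_equal(sum(fp[3:4]), 60, tolerance = 1e-6)
  expect_equal(sum(fp[1:2]), 250, tolerance = 1e-6)
  # constant-size cells carry the configured N_P exactly
  expect_equal(sum(get("EvoPlus", 30)$init$P), 30)
})

test_that("infeasible sweep points are flagged rather than dropped", {
  cells <- fig3_sweep_spec(N_P = c(-10, 30), models = "EcoEvoPlus")
  sw <- population_size_sweep(cells, n_reps = 2, seed = 1,
                              stop = stop_condition(t_max = 1e4))
  expect_equal(nrow(sw), 2)
  expect_false(sw$feasible[sw$target_NP == -10])
  expect_true(is.na(sw$mean_time[sw$target_NP == -10]))
  expect_true(sw$feasible[sw$target_NP == 30])
})

test_that("diversity starts at n, never increases without mutation", {
  dv <- diversity_time_series(n = 10, params = diversity_params(10),
                              n_reps = 8, seed = 3,
                              t_grid = seq(0, 40, by = 0.5))
  expect_equal(dv$host_mean[1], 10)
  expect_equal(dv$parasite_mean[1], 10)
  expect_true(all(apply(dv$host_per_rep, 1, function(x) all(diff(x) <= 0))))
  expect_true(all(apply(dv$parasite_per_rep, 1,
                        function(x) all(diff(x) <= 0))))
  expect_true(all(dv$host_mean >= 0 & dv$host_mean <= 10))
})

test_that("decay fitting recovers exact exponentials and rejects tiny windows", {
  t <- seq(0, 30, by = 0.5)
  exact <- data.frame(t = t, diversity = 20 * exp(-0.1 * t))
  fit <- fit_exponential_decay(exact)
  expect_equal(fit$rate, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  const <- data.frame(t = t, diversity = rep(5, length(t)))
  fitc <- fit_exponential_decay(const)
  expect_equal(fitc$rate, 0, tolerance = 1e-12)
  expect_error(fit_exponential_decay(data.frame(t = 1:2, diversity = c(3, 2))),
               "3 usable points")
})

test_that("the least-squares decay rate matches a direct-search refit", {
  dv <- diversity_time_series(n = 10, params = diversity_params(10),
                              n_reps = 10, seed = 8,
                              t_grid = seq(0, 40, by = 0.5))
  fit <- fit_exponential_decay(dv, "host")
  keep <- fit$t
  y <- fit$log_diversity
  sse <- function(par) sum((y - (par[1] - par[2] * keep))^2)
  direct <- optim(c(log(10), 0.05), sse, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$rate, direct$par[2], tolerance = 1e-6)
  expect_equal(fit$intercept, direct$par[1], tolerance = 1e-6)
})

test_that("revivals require mutation", {
  res <- simulate_ct(build_model("EcoEvoPlus", 5, fig4_params()),
                     uniform_init(300, 900, 5),
                     stop_condition(t_max = 30,
                                    stop_on_genotype_loss = FALSE),
                     seed = 5, record_grid = numeric(0))
  expect_equal(nrow(res$revivals), 0)
  mr <- mutation_regime_run(seed = 5, t_max = 30)
  expect_true(is.data.frame(mr$revivals))
  expect_true(all(c("N_H", "N_P") %in% names(mr$mean_sizes)))
})

test_that("raising the time cap never shortens a recorded extinction time", {
  p <- fig1_params()
  short <- extinction_ensemble("EcoEvoPlus", p, uniform_init(50, 150),
                               n_reps = 30, seed = 13,
                               stop = stop_condition(t_max = 3))
  long <- extinction_ensemble("EcoEvoPlus", p, uniform_init(50, 150),
                              n_reps = 30, seed = 13,
                              stop = stop_condition(t_max = 1e6))
  done_early <- !short$censored
  expect_equal(short$times[done_early], long$times[done_early])
  expect_true(all(long$times >= short$times - 1e-12))
})
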