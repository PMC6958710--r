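A2 <- matching_matrix(2)

test_that("Moran step distribution matches hand-evaluated transition probabilities", {
  st <- population_state(c(5, 5), c(8, 2))
  tr <- dt_step_distribution("dtEvoPlus", st, A2, w_H = 0.5, w_P = 1)
  # f_H = (0.6, 0.9), mean 0.75: P(+1) = .25*.6/.75, P(-1) = .25*.9/.75
  expect_equal(unname(tr$host), c(0.2, 0.5, 0.3), tolerance = 1e-12)
})

test_that("pairwise-comparison step is neutral when payoffs tie", {
  st <- population_state(c(5, 5), c(8, 2))
  tr <- dt_step_distribution("dtEvo", st, A2, w_H = 0.5, w_P = 1)
  # equal host frequencies make the parasite payoffs equal: term = 1/2
  expect_equal(unname(tr$parasite), c(0.08, 0.84, 0.08), tolerance = 1e-12)
  # alpha == beta with w > 0 degenerates to the neutral term, no error
  trc <- dt_step_distribution("dtEvo", st, matching_matrix(2, 0.5, 0.5),
                              w_H = 1, w_P = 1)
  expect_equal(unname(trc$host), c(0.125, 0.75, 0.125), tolerance = 1e-12)
})

test_that("selection intensity shifts the pairwise-comparison term", {
  st <- population_state(c(4, 6), c(9, 1))
  for (w in c(0, 0.3, 1)) {
    tr <- dt_step_distribution("dtEvo", st, A2, w_H = w, w_P = 0)
    # host 1 faces 0.9 matched parasites: f1 - f2 = w*(0.2 - 1.8)... payoffs
    # pi_H = (0.1, 0.9), so the term is 0.5 + 0.5*w*(0.1 - 0.9)
    term <- 0.5 + 0.5 * w * (0.1 - 0.9)
    expect_equal(tr$host[["up"]], 0.24 * term, tolerance = 1e-12)
  }
})

test_that("boundary states are absorbing", {
  st <- population_state(c(0, 10), c(5, 5))
  tr <- dt_step_distribution("dtEvoPlus", st, A2, 0.5, 1)
  expect_equal(unname(tr$host), c(0, 1, 0))
  expect_error(dt_step_distribution("dtX", st, A2, 0, 0), "unknown")
})

test_that("discrete simulation conserves sizes and stops at the first loss", {
  init <- uniform_init(8, 8)
  res <- simulate_discrete("dtEvoPlus", init, A2, 0.5, 1, seed = 7)
  tr <- res$trajectory
  expect_true(all(tr$H1 + tr$H2 == 8))
  expect_true(all(tr$P1 + tr$P2 == 8))
  last <- tr[nrow(tr), ]
  expect_true(any(c(last$H1, last$H2, last$P1, last$P2) == 0))
  expect_false(res$record$censored)
  expect_equal(res$record$time, max(tr$step))
  # no zero before the final step (monotone boundary: loss ends the run)
  body <- tr[-nrow(tr), ]
  expect_true(all(body$H1 > 0 & body$H1 < 8 & body$P1 > 0 & body$P1 < 8))
})

test_that("discrete simulation is deterministic given a seed and censors at the cap", {
  init <- uniform_init(20, 20)
  a <- simulate_discrete("dtEvo", init, A2, 0.5, 1, seed = 42)
  b <- simulate_discrete("dtEvo", init, A2, 0.5, 1, seed = 42)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$record$time, b$record$time)
  cens <- simulate_discrete("dtEvoPlus", init, A2, 0, 0, seed = 1,
                            max_steps = 5)
  expect_true(cens$record$censored || cens$record$time <= 5)
  already <- simulate_discrete("dtEvoPlus",
                               population_state(c(0, 8), c(4, 4)),
                               A2, 0.5, 1, seed = 1)
  expect_equal(already$record$time, 0)
  expect_equal(already$record$species, "host")
  expect_equal(already$record$genotype, 1L)
})

test_that("sparse first-passage times match dense brute-force enumeration", {
  for (cfg in list(list(m = "dtEvoPlus", w = c(0, 0), N = c(2, 2)),
                   list(m = "dtEvoPlus", w = c(0.5, 1), N = c(4, 3)),
                   list(m = "dtEvo", w = c(0.5, 1), N = c(3, 5)))) {
    exact <- exact_mean_extinction_time(cfg$m, A2, cfg$w[1], cfg$w[2],
                                        cfg$N[1], cfg$N[2])
    brute <- brute_force_dt_times(cfg$m, A2, cfg$w[1], cfg$w[2],
                                  cfg$N[1], cfg$N[2])
    expect_equal(unclass(exact), brute, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # neutral 3x3 chain from the central state, solvable by hand:
  # stay-interior probability 1/4 each step gives tau = 1/(3/4) = 4/3
  tau <- exact_mean_extinction_time("dtEvoPlus", A2, 0, 0, 2, 2)
  expect_equal(tau["1", "1"], 4 / 3, tolerance = 1e-12)
  tauE <- exact_mean_extinction_time("dtEvo", A2, 0, 0, 2, 2)
  expect_equal(tauE["1", "1"], 16 / 7, tolerance = 1e-12)
})

test_that("expected times are symmetric under genotype relabeling", {
  tau <- exact_mean_extinction_time("dtEvoPlus", A2, 0.5, 0.5, 6, 6)
  flipped <- tau[rev(seq_len(nrow(tau))), rev(seq_len(ncol(tau)))]
  expect_equal(unclass(tau), unclass(flipped), tolerance = 1e-9,
               ignore_attr = TRUE)
  df <- as.data.frame(tau)
  expect_equal(nrow(df), 49)
  expect_setequal(names(df), c("model", "N_H", "N_P", "w_H", "w_P",
                               "start_H1", "start_P1", "expected_time"))
})

test_that("the product transition kernel is stochastic at every state", {
  set.seed(77)
  for (k in 1:20) {
    st <- population_state(c(sample(0:6, 1), 6), c(sample(0:6, 1), 6))
    tr <- dt_step_distribution(sample(c("dtEvoPlus", "dtEvo"), 1), st, A2,
                               runif(1), runif(1))
    total <- sum(outer(tr$host, tr$parasite))
    expect_equal(total, 1, tolerance = 1e-10)
    expect_true(all(tr$host >= 0) && all(tr$parasite >= 0))
  }
})

test_that("Monte-Carlo means agree with the exact solver at N = 6", {
  p <- model_params(w_H = 0.5, w_P = 1)
  tau <- exact_mean_extinction_time("dtEvo", A2, 0.5, 1, 6, 6)
  ens <- extinction_ensemble("dtEvo", p, uniform_init(6, 6),
                             n_reps = 3000, seed = 11)
  expect_lt(abs(ens$mean - tau["3", "3"]) / ens$se, 3)
})

test_that("the Moran process outgrows the pairwise process in parasite size", {
  # increasing stabilisation by the attractive fixed point: exact times at
  # growing N_P with the host size of the population-size sweep (N_H = 250)
  ratio <- vapply(c(30, 100, 200), function(np) {
    tp <- exact_mean_extinction_time("dtEvoPlus", A2, 0.5, 1, 250, np)
    te <- exact_mean_extinction_time("dtEvo", A2, 0.5, 1, 250, np)
    tp["125", as.character(np / 2)] / te["125", as.character(np / 2)]
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[3], 1)  # ordering at the largest N_P tested
})

test_that("oversized state spaces are refused", {
  expect_error(exact_mean_extinction_time("dtEvo", A2, 0, 0, 600, 600),
               "state space")
})
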