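test_that("gillespie step inverts the exponential and categorical draws", {
  s <- gillespie_step(c(2), u_time = 0.5, u_reaction = 0.3)
  expect_equal(s$tau, log(2) / 2, tolerance = 1e-12)
  expect_equal(s$index, 1L)
  expect_equal(gillespie_step(c(0, 5), u_time = 0.5, u_reaction = 0.99)$index, 2L)
  expect_null(gillespie_step(c(0, 0)))
  expect_error(gillespie_step(c(-1, 2)), "non-negative")
  # rate-proportional selection: thirds within Monte-Carlo error
  set.seed(9)
  idx <- vapply(1:6000, function(i) gillespie_step(c(1, 1, 1))$index,
                integer(1))
  expect_true(all(abs(tabulate(idx, 3) / 6000 - 1 / 3) < 0.025))
})

test_that("a linear death chain is absorbed after the harmonic mean time", {
  # P = 3 individuals dying at per-capita rate 1: E[T] = 1 + 1/2 + 1/3
  p <- model_params(b_H = 0, d_P = 1, lam = 0)
  sys <- build_model("EcoEvo", 2, p)
  times <- vapply(1:2000, function(r) {
    res <- simulate_ct(sys, population_state(c(0, 0), c(3, 0)),
                       stop_condition(t_max = 1e4,
                                      stop_on_genotype_loss = FALSE),
                       seed = child_seed(31, r), record_grid = numeric(0))
    expect_true(res$absorbed)
    expect_equal(res$n_events, 3)
    res$final_state$t
  }, numeric(1))
  se <- sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - 11 / 6) / se, 3)
})

test_that("a birth-only population grows at the Yule rate", {
  p <- model_params(b_H = 1, d_P = 1, lam = 0)
  sys <- build_model("EcoEvo", 2, p)
  finals <- vapply(1:500, function(r) {
    res <- simulate_ct(sys, population_state(c(3, 3), c(1, 1)),
                       stop_condition(t_max = 1, n_max = 1e5,
                                      stop_on_genotype_loss = FALSE),
                       seed = child_seed(77, r), record_grid = numeric(0))
    sum(res$final_state$H)
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 6 * exp(1)) / se, 3)
})

test_that("constant-size models conserve both populations exactly", {
  sys <- build_model("Evo", 2, model_params(w_H = 0.5, w_P = 1))
  res <- simulate_ct(sys, uniform_init(50, 150),
                     stop_condition(t_max = 1e5), seed = 5,
                     record_grid = seq(0, 500, by = 0.5))
  tr <- res$trajectory
  expect_true(all(tr$H_1 + tr$H_2 == 50))
  expect_true(all(tr$P_1 + tr$P_2 == 150))
  expect_false(res$censored)
  expect_equal(res$record$time, res$final_state$t)
})

test_that("identical seeds reproduce trajectories bit-identically", {
  sys <- build_model("EcoEvoPlus", 2, fig1_params())
  a <- simulate_ct(sys, uniform_init(50, 150), stop_condition(t_max = 1e4),
                   seed = 12, record_grid = seq(0, 20, by = 0.1))
  b <- simulate_ct(sys, uniform_init(50, 150), stop_condition(t_max = 1e4),
                   seed = 12, record_grid = seq(0, 20, by = 0.1))
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$record$time, b$record$time)
})

test_that("an initially absent genotype is an immediate loss", {
  sys <- build_model("EcoEvoPlus", 2, fig1_params())
  res <- simulate_ct(sys, population_state(c(25, 0), c(75, 75)),
                     stop_condition(t_max = 100), seed = 3)
  expect_equal(res$record$time, 0)
  expect_equal(res$record$species, "host")
  expect_equal(res$record$genotype, 2L)
})

test_that("censoring at the time cap is reported, never dropped", {
  sys <- build_model("EvoPlus", 2, model_params(w_H = 0.5, w_P = 1))
  res <- simulate_ct(sys, uniform_init(100, 300),
                     stop_condition(t_max = 5), seed = 8)
  expect_true(res$censored)
  expect_true(res$record$censored)
  expect_equal(res$record$time, 5)
  # the unconstrained model stops at the total-population guard
  p <- model_params(b_H = 1, d_P = 1, lam = 0)
  res2 <- simulate_ct(build_model("EcoEvo", 2, p),
                      population_state(c(5, 5), c(1, 1)),
                      stop_condition(t_max = 1e4, n_max = 50,
                                     stop_on_genotype_loss = FALSE),
                      seed = 4, record_grid = numeric(0))
  expect_true(res2$censored)
})

test_that("the generic path agrees with the compiled path in distribution", {
  # same model run through R closures (non-native) and through the engine:
  # compare mean extinction times over seeded ensembles
  p <- fig1_params()
  native <- build_model("EcoEvoPlus", 2, p)
  generic <- native
  generic$native <- FALSE
  t_nat <- vapply(1:150, function(r) {
    simulate_ct(native, uniform_init(20, 60), stop_condition(t_max = 1e4),
                seed = child_seed(61, r), record_grid = numeric(0))$record$time
  }, numeric(1))
  t_gen <- vapply(1:150, function(r) {
    simulate_ct(generic, uniform_init(20, 60), stop_condition(t_max = 1e4),
                seed = child_seed(62, r), record_grid = numeric(0))$record$time
  }, numeric(1))
  pooled_se <- sqrt(var(t_nat) / 150 + var(t_gen) / 150)
  expect_lt(abs(mean(t_nat) - mean(t_gen)) / pooled_se, 3.5)
})

test_that("trajectories export to CSV and JSON-lines", {
  sys <- build_model("EcoEvoPlus", 2, fig1_params())
  res <- simulate_ct(sys, uniform_init(50, 150), stop_condition(t_max = 10),
                     seed = 2, record_grid = seq(0, 5, by = 1))
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(res$trajectory, csv, meta = list(seed = 2))
  back <- read.csv(csv)
  expect_equal(back$H_1, res$trajectory$H_1)
  expect_true(file.exists(paste0(csv, ".spec.json")))
  jl <- tempfile(fileext = ".jsonl")
  write_trajectory_jsonl(res$trajectory, jl)
  lines <- readLines(jl)
  expect_equal(length(lines), nrow(res$trajectory))
  row1 <- jsonlite::fromJSON(lines[1])
  expect_equal(row1$H_1 + row1$H_2, 50)
})

test_that("child seeds are valid 31-bit integers and order-independent", {
  s <- vapply(1:2000, child_seed, integer(1), master = 123)
  expect_true(all(s > 0 & s < 2^31))
  expect_equal(length(unique(s)), 2000)
  expect_identical(child_seed(123, 7), child_seed(123, 7))
  expect_false(child_seed(123, 7) == child_seed(124, 7))
})
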