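test_that("model construction yields the documented reaction sets", {
  p <- fig1_params()
  eep <- build_model("EcoEvoPlus", 2, p)
  expect_equal(length(eep$reactions), 10)  # 5 channel types x 2 genotypes
  expect_equal(length(build_model("EcoEvo", 2, p)$reactions), 8)
  expect_equal(length(build_model("Hybrid", 2, p)$reactions), 8)
  expect_equal(length(build_model("Evo", 2, model_params(w_H = 1, w_P = 1))$reactions), 4)
  # mutation adds two cyclic conversions per genotype and species
  em <- build_model("EcoEvoPlus", 5, fig4_params(), with_mutation = TRUE)
  expect_equal(length(em$reactions), 25 + 20)
  expect_error(build_model("Evo", 3, p), "two genotypes")
  expect_error(build_model("Evo", 2, p, with_mutation = TRUE), "mutation")
  expect_error(build_model("NoSuch", 2, p), "unknown")
  expect_error(build_model("EcoEvoPlus", 2, model_params(b_H = 1, d_P = 1,
                                                         lam = 0.1)),
               "comp_rate")
})

test_that("propensities follow the printed rate laws", {
  p <- fig1_params()
  sys <- build_model("EcoEvo", 2, p)
  a <- propensities(sys, population_state(c(25, 25), c(75, 75)))
  expect_equal(unname(a[c("matched_host_death_1", "matched_host_death_2")]),
               c(75, 75))                      # lam * H_i * P_i = 0.04*25*75
  expect_equal(unname(a[c("host_birth_1", "host_birth_2")]), c(150, 150))
  a0 <- propensities(sys, population_state(c(3, 4), c(0, 0)))
  expect_true(all(a0[grep("parasite|matched", names(a0))] == 0))
  expect_true(all(propensities(sys, population_state(c(0, 0), c(0, 0))) == 0))
  expect_error(propensities(sys, structure(list(H = c(-1, 2), P = c(1, 1)),
                                           class = "rq_state")), "corrupted")
})

test_that("Evo-type channel rates reproduce the discrete-time arithmetic", {
  sys <- build_model("EvoPlus", 2, model_params(w_H = 0.5, w_P = 1))
  a <- propensities(sys, population_state(c(5, 5), c(8, 2)))
  expect_equal(unname(a[c("host_1_replaces_2", "host_2_replaces_1")]),
               c(0.2, 0.3), tolerance = 1e-12)
  # boundary: no replacement once a genotype is gone
  ab <- propensities(sys, population_state(c(0, 10), c(8, 2)))
  expect_equal(unname(ab[1:2]), c(0, 0))
})

test_that("Hybrid birth and death rates balance at every state", {
  p <- model_params(w_H = 1, w_P = 1)
  sys <- build_model("Hybrid", 2, p)
  a <- propensities(sys, population_state(c(1, 1), c(1, 1)))
  expect_equal(unname(a[c("host_death_1", "host_death_2")]), c(0.5, 0.5))
  expect_equal(unname(a[c("host_birth_1", "host_birth_2")]), c(0.5, 0.5))
  set.seed(303)
  for (k in 1:8) {
    st <- rand_state(2)
    a <- propensities(sys, st)
    expect_equal(sum(a[grep("host_birth", names(a))]),
                 sum(a[grep("host_death", names(a))]), tolerance = 1e-12)
    expect_equal(sum(a[grep("parasite_birth", names(a))]),
                 sum(a[grep("parasite_death", names(a))]), tolerance = 1e-12)
  }
})

test_that("stoichiometry conserves population sizes where it must", {
  p <- fig1_params()
  for (m in c("Evo", "EvoPlus")) {
    sys <- build_model(m, 2, model_params(w_H = 0.5, w_P = 1))
    for (r in sys$reactions) {
      expect_equal(sum(r$delta_H), 0)
      expect_equal(sum(r$delta_P), 0)
    }
  }
  em <- build_model("EcoEvoPlus", 5, fig4_params(), with_mutation = TRUE)
  for (r in em$reactions[grep("mutation", vapply(em$reactions, `[[`,
                                                 character(1), "label"))]) {
    expect_equal(sum(r$delta_H) + sum(r$delta_P), 0)
  }
})

test_that("mean-field drift equals the deterministic right-hand side", {
  set.seed(404)
  p_eco <- fig1_params()
  p_game <- model_params(w_H = 0.5, w_P = 1)
  for (k in 1:6) {
    st <- rand_state(2)
    N_H <- sum(st$H); N_P <- sum(st$P)
    h <- st$H / N_H; p <- st$P / N_P

    for (m in c("EcoEvo", "EcoEvoPlus")) {
      drift <- mean_field_drift(build_model(m, 2, p_eco), st)
      rhs <- ode_rhs(m, c(st$H, st$P), p_eco, 2)
      expect_equal(c(drift$H, drift$P), rhs, tolerance = 1e-10)
    }
    # Hybrid: count drift is N times the replicator frequency drift
    drift <- mean_field_drift(build_model("Hybrid", 2, p_game), st)
    rhs <- ode_rhs("Hybrid", c(h, p), p_game, 2)
    expect_equal(drift$H / N_H, rhs[1:2], tolerance = 1e-10)
    expect_equal(drift$P / N_P, rhs[3:4], tolerance = 1e-10)
    # EvoPlus: rates are the Moran expressions, drift = adjusted replicator
    drift <- mean_field_drift(build_model("EvoPlus", 2, p_game), st)
    rhs <- ode_rhs("EvoPlus", c(h, p), p_game, 2)
    expect_equal(drift$H, rhs[1:2], tolerance = 1e-10)
    expect_equal(drift$P, rhs[3:4], tolerance = 1e-10)
    # Evo: pairwise-comparison normalisation rescales time by alpha - beta
    drift <- mean_field_drift(build_model("Evo", 2, p_game), st)
    rhs <- ode_rhs("Evo", c(h, p), p_game, 2)
    ab <- p_game$alpha - p_game$beta
    expect_equal(drift$H * ab, rhs[1:2], tolerance = 1e-10)
    expect_equal(drift$P * ab, rhs[3:4], tolerance = 1e-10)
  }
})

test_that("host-only EcoEvoPlus drift vanishes at the carrying capacity", {
  p <- fig1_params()  # K = 100
  sys <- build_model("EcoEvoPlus", 2, p)
  drift <- mean_field_drift(sys, population_state(c(50, 50), c(0, 0)))
  expect_equal(sum(drift$H), 0, tolerance = 1e-10)
  below <- mean_field_drift(sys, population_state(c(20, 20), c(0, 0)))
  expect_gt(sum(below$H), 0)
  above <- mean_field_drift(sys, population_state(c(80, 80), c(0, 0)))
  expect_lt(sum(above$H), 0)
})
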