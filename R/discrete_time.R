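#' @title Discrete-time Moran and pairwise-comparison processes
#' @description
#' The dtEvo+ process is a two-species Moran process: in each time step one
#' fitness-proportional birth and one uniformly random death occur within
#' each species, and both species are updated simultaneously from the
#' pre-step state. The dtEvo process replaces the normalisation by the
#' population mean fitness with a pairwise fitness comparison. Both keep
#' population sizes exactly constant and are restricted to two genotypes per
#' species, which makes the exact mean extinction time computable by
#' first-passage linear algebra.
#' @name discrete_time
NULL

dt_models <- c("dtEvoPlus", "dtEvo")

check_dt_model <- function(model) {
  if (!model %in% dt_models) {
    stop(sprintf("unknown discrete-time model '%s' (use %s)", model,
                 paste(dt_models, collapse = ", ")), call. = FALSE)
  }
  model
}

# One species' step triple (P(+1), P(0), P(-1)) for the genotype-1 count.
# `counts` are the focal species' counts, `f` its per-genotype fitnesses
# (already computed from the antagonist's pre-step frequencies).
dt_triple <- function(model, counts, f, alpha, beta) {
  N <- sum(counts)
  x1 <- counts[1] / N
  x2 <- counts[2] / N
  if (counts[1] == 0 || counts[2] == 0) {
    return(c(up = 0, stay = 1, down = 0))  # absorbing boundary
  }
  if (model == "dtEvoPlus") {
    fbar <- x1 * f[1] + x2 * f[2]
    up   <- x2 * x1 * f[1] / fbar
    down <- x1 * x2 * f[2] / fbar
  } else {
    # pairwise comparison: fitness difference scaled by the maximal payoff
    # difference alpha - beta; degenerate alpha == beta means no selection
    denom <- alpha - beta
    term <- if (denom <= 0 || f[1] == f[2]) 0.5 else
      0.5 + 0.5 * (f[1] - f[2]) / denom
    up   <- x1 * x2 * term
    down <- x1 * x2 * (1 - term)
  }
  c(up = up, stay = 1 - up - down, down = down)
}

#' Single-step transition distribution of a discrete-time process
#'
#' Returns, for each species, the probabilities that its genotype-1 count
#' changes by +1, 0 or -1 in one time step, evaluated at the current
#' (pre-step) state. Both species use the antagonist's pre-step frequencies,
#' so the simultaneous two-species update factorises into the product of the
#' two triples. Boundary states (a genotype at 0 or at the whole population)
#' are absorbing and yield the degenerate triple (0, 1, 0).
#'
#' @param model `"dtEvoPlus"` (Moran) or `"dtEvo"` (pairwise comparison).
#' @param state an [population_state()] with two genotypes per species.
#' @param A interaction matrix from [matching_matrix()] (2 x 2).
#' @param w_H,w_P selection intensities in `[0, 1]`.
#' @return list with elements `host` and `parasite`, each a named triple
#'   `(up, stay, down)` summing to 1.
#' @export
dt_step_distribution <- function(model, state, A, w_H, w_P) {
  check_dt_model(model)
  if (length(state$H) != 2L || nrow(A) != 2L) {
    stop("discrete-time processes support exactly two genotypes per species",
         call. = FALSE)
  }
  if (sum(state$H) < 1 || sum(state$P) < 1) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  alpha <- ma_alpha(A); beta <- ma_beta(A)
  h <- rel_freq(state$H)
  p <- rel_freq(state$P)
  f_H <- fitness_from_payoff(host_payoffs(p, A), w_H)
  f_P <- fitness_from_payoff(parasite_payoffs(h, A), w_P)
  list(host     = dt_triple(model, state$H, f_H, alpha, beta),
       parasite = dt_triple(model, state$P, f_P, alpha, beta))
}

#' Simulate a discrete-time process until the first genotype loss
#'
#' Each step draws one count change per species from
#' [dt_step_distribution()] evaluated at the pre-step state; both changes
#' are applied at once. Population sizes are exactly conserved. The run
#' stops at the first step after which any genotype count is 0 (extinction
#' time in steps) or when `max_steps` is reached (censored). When both
#' species lose a genotype in the same step the host is reported, by
#' convention.
#'
#' @param model `"dtEvoPlus"` or `"dtEvo"`.
#' @param init initial [population_state()] (two genotypes per species, all
#'   counts positive unless the state is already absorbed).
#' @param A 2 x 2 interaction matrix.
#' @param w_H,w_P selection intensities.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param max_steps cap on the number of steps.
#' @param record_stride record every k-th step in the trajectory (0 disables
#'   trajectory recording; the initial and final states are always kept).
#' @return list with `trajectory` (data.frame `step, H1, H2, P1, P2`) and
#'   `record` (an [extinction_record()], time in steps).
#' @export
simulate_discrete <- function(model, init, A, w_H, w_P, seed = NULL,
                              max_steps = 1e7, record_stride = 1) {
  check_dt_model(model)
  if (length(init$H) != 2L) {
    stop("discrete-time processes support exactly two genotypes per species",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate_dt(
    model_id = match(model, dt_models),
    H1 = init$H[1], N_H = sum(init$H), P1 = init$P[1], N_P = sum(init$P),
    w_H = w_H, w_P = w_P, alpha = ma_alpha(A), beta = ma_beta(A),
    max_steps = as.numeric(max_steps), record_stride = as.integer(record_stride))
  traj <- data.frame(step = res$rec_steps,
                     H1 = res$rec_H1, H2 = sum(init$H) - res$rec_H1,
                     P1 = res$rec_P1, P2 = sum(init$P) - res$rec_P1)
  record <- if (res$censored) {
    extinction_record(res$steps, censored = TRUE)
  } else {
    extinction_record(res$steps,
                      species = c("host", "parasite")[res$ext_species],
                      genotype = res$ext_genotype)
  }
  list(trajectory = traj, record = record)
}

#' Exact mean extinction times of a discrete-time process
#'
#' Builds the full one-step transition kernel over states `(H1, P1)` as the
#' product of the two per-species step triples, marks states with a genotype
#' at 0 or at the whole population as absorbing, and solves the first-passage
#' system `(I - Q) tau = 1` over the transient interior states with a sparse
#' LU factorisation. `tau[(H1, P1)]` is the expected number of steps until
#' the first genotype loss when starting from `(H1, P1)`; boundary starts
#' have `tau = 0`.
#'
#' Interior states are enumerated row-major in `(H1, P1)`:
#' `index = (H1 - 1) * (N_P - 1) + P1` for `H1 in 1..N_H-1`,
#' `P1 in 1..N_P-1`.
#'
#' @param model `"dtEvoPlus"` or `"dtEvo"`.
#' @param A 2 x 2 interaction matrix.
#' @param w_H,w_P selection intensities.
#' @param N_H,N_P population sizes (state space `(N_H+1) x (N_P+1)` must not
#'   exceed 2.5e5 states).
#' @return a `(N_H + 1) x (N_P + 1)` matrix of expected first-loss times,
#'   dimnames giving the starting `H1` and `P1`; class `rq_exact_dt` with
#'   the call's parameters attached for tidying via `as.data.frame()`.
#' @export
exact_mean_extinction_time <- function(model, A, w_H, w_P, N_H, N_P) {
  check_dt_model(model)
  n_states <- (N_H + 1) * (N_P + 1)
  if (n_states > 2.5e5) {
    stop(sprintf("state space too large for the sparse solve (%d > 250000)",
                 n_states), call. = FALSE)
  }
  if (N_H < 2 || N_P < 2) stop("need N_H >= 2 and N_P >= 2", call. = FALSE)
  alpha <- ma_alpha(A); beta <- ma_beta(A)

  nh <- N_H - 1L; np <- N_P - 1L          # interior grid dimensions
  H1 <- rep(seq_len(nh), each = np)       # row-major enumeration
  P1 <- rep(seq_len(np), times = nh)
  h1 <- H1 / N_H; p1 <- P1 / N_P
  S <- nh * np

  # vectorised per-species fitnesses at every interior state
  f_H1 <- 1 - w_H + w_H * ((alpha + beta) - (alpha * p1 + beta * (1 - p1)))
  f_H2 <- 1 - w_H + w_H * ((alpha + beta) - (alpha * (1 - p1) + beta * p1))
  f_P1 <- 1 - w_P + w_P * (alpha * h1 + beta * (1 - h1))
  f_P2 <- 1 - w_P + w_P * (alpha * (1 - h1) + beta * h1)

  triple <- function(x1, f1, f2) {
    x2 <- 1 - x1
    if (model == "dtEvoPlus") {
      fbar <- x1 * f1 + x2 * f2
      up   <- x1 * x2 * f1 / fbar
      down <- x1 * x2 * f2 / fbar
    } else {
      denom <- alpha - beta
      term <- if (denom <= 0) rep(0.5, length(x1)) else
        0.5 + 0.5 * (f1 - f2) / denom
      up   <- x1 * x2 * term
      down <- x1 * x2 * (1 - term)
    }
    list(up = up, stay = 1 - up - down, down = down)
  }
  th <- triple(h1, f_H1, f_H2)
  tp <- triple(p1, f_P1, f_P2)

  idx <- function(H, P) (H - 1L) * np + P
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dh in -1:1) {
    qh <- switch(as.character(dh), `-1` = th$down, `0` = th$stay, `1` = th$up)
    for (dp in -1:1) {
      qp <- switch(as.character(dp), `-1` = tp$down, `0` = tp$stay, `1` = tp$up)
      Hd <- H1 + dh; Pd <- P1 + dp
      keep <- Hd >= 1L & Hd <= nh & Pd >= 1L & Pd <= np
      ii <- c(ii, idx(H1, P1)[keep])
      jj <- c(jj, idx(Hd, Pd)[keep])
      xx <- c(xx, (qh * qp)[keep])
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(S, S))
  M <- Matrix::Diagonal(S) - Q
  tau <- tryCatch(as.numeric(Matrix::solve(M, rep(1, S))),
                  error = function(e) {
                    stop("first-passage system could not be solved: ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("first-passage solve produced non-finite or non-positive times",
         call. = FALSE)
  }

  out <- matrix(0, N_H + 1, N_P + 1,
                dimnames = list(H1 = 0:N_H, P1 = 0:N_P))
  out[cbind(H1 + 1L, P1 + 1L)] <- tau
  structure(out, class = c("rq_exact_dt", "matrix"),
            model = model, N_H = N_H, N_P = N_P,
            w_H = w_H, w_P = w_P, alpha = alpha, beta = beta)
}

#' Tidy table of exact mean extinction times
#'
#' @param x an object from [exact_mean_extinction_time()].
#' @param ... unused.
#' @return data.frame with columns `model, N_H, N_P, w_H, w_P, start_H1,
#'   start_P1, expected_time`, one row per starting state.
#' @export
as.data.frame.rq_exact_dt <- function(x, ...) {
  N_H <- attr(x, "N_H"); N_P <- attr(x, "N_P")
  grid <- expand.grid(start_H1 = 0:N_H, start_P1 = 0:N_P)
  data.frame(model = attr(x, "model"), N_H = N_H, N_P = N_P,
             w_H = attr(x, "w_H"), w_P = attr(x, "w_P"),
             start_H1 = grid$start_H1, start_P1 = grid$start_P1,
             expected_time = as.vector(unclass(x)[cbind(grid$start_H1 + 1L,
                                                        grid$start_P1 + 1L)]))
}
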