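#' @title Extinction-time experiments
#' @description
#' The computational experiments that compare the models: extinction-time
#' ensembles, the population-size sweep, multi-genotype diversity decay,
#' and the mutation-driven regime where negative frequency-dependent
#' selection and arms-race sweeps alternate.
#' @name experiments
NULL

#' Ensemble of extinction times
#'
#' Runs `n_reps` independent replicates of a model from the same initial
#' state and records the time until the first genotype loss in each.
#' Replicate `r` uses the child seed `child_seed(seed, r)`, so the ensemble
#' is reproducible replicate-by-replicate. The mean and median are computed
#' over uncensored replicates only; the censored count is reported
#' alongside.
#'
#' @param model any of the five continuous-time model names, or
#'   `"dtEvoPlus"` / `"dtEvo"` for the discrete-time processes (extinction
#'   time then counts steps).
#' @param params a [model_params()].
#' @param init initial [population_state()]; all genotypes present
#'   (typically [uniform_init()], the equal split used throughout).
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param stop an [stop_condition()]; for discrete-time models the
#'   `event_max` cap bounds the number of steps.
#' @return an object of class `rq_ensemble`.
#' @export
extinction_ensemble <- function(model, params, init, n_reps, seed,
                                stop = stop_condition(t_max = 1e6)) {
  stopifnot(n_reps >= 1, inherits(init, "rq_state"))
  if (any(init$H <= 0) || any(init$P <= 0)) {
    stop("all genotypes must be present initially", call. = FALSE)
  }
  n <- length(init$H)
  times <- numeric(n_reps)
  censored <- logical(n_reps)
  species <- character(n_reps)
  genotype <- integer(n_reps)

  grab <- function(r, rec) {
    times[r] <<- rec$time
    censored[r] <<- rec$censored
    species[r] <<- if (rec$censored) NA_character_ else rec$species
    genotype[r] <<- if (rec$censored) NA_integer_ else rec$genotype
  }
  if (model %in% dt_models) {
    A <- matching_matrix(2, params$alpha, params$beta)
    max_steps <- if (is.finite(stop$event_max)) stop$event_max else 1e8
    for (r in seq_len(n_reps)) {
      res <- simulate_discrete(model, init, A, params$w_H, params$w_P,
                               seed = child_seed(seed, r),
                               max_steps = max_steps, record_stride = 0)
      grab(r, res$record)
    }
  } else {
    system <- build_model(model, n, params)
    for (r in seq_len(n_reps)) {
      res <- simulate_ct(system, init, stop, seed = child_seed(seed, r),
                         record_grid = numeric(0))
      if (is.null(res$record)) stop("simulation ended without a record")  # nocov
      grab(r, res$record)
    }
  }

  ok <- !censored
  structure(list(
    model = model, params = params, init = init, n_reps = n_reps,
    seed = seed, times = times, censored = censored,
    species = species, genotype = genotype,
    mean = if (any(ok)) mean(times[ok]) else NA_real_,
    median = if (any(ok)) median(times[ok]) else NA_real_,
    se = if (sum(ok) > 1) stats::sd(times[ok]) / sqrt(sum(ok)) else NA_real_,
    hist = if (any(ok)) graphics::hist(times[ok], plot = FALSE) else NULL,
    censored_count = sum(censored),
    unusable_for_mean = !any(ok)), class = "rq_ensemble")
}

#' @exportS3Method base::print
print.rq_ensemble <- function(x, ...) {
  cat(sprintf("<rq_ensemble> %s: %d replicates, %d censored\n",
              x$model, x$n_reps, x$censored_count))
  if (x$unusable_for_mean) {
    cat("  all replicates censored: mean unusable\n")
  } else {
    cat(sprintf("  mean extinction time %.4g (se %.3g), median %.4g\n",
                x$mean, x$se, x$median))
  }
  invisible(x)
}

#' Tidy per-replicate table of an ensemble
#'
#' One row per replicate carrying the full parameter set, the replicate
#' seed, and the extinction record, so any row can be re-run on its own.
#'
#' @param x an `rq_ensemble`.
#' @param ... unused.
#' @return data.frame with one row per replicate.
#' @export
as.data.frame.rq_ensemble <- function(x, ...) {
  pars <- unclass(x$params)
  pars <- pars[!vapply(pars, is.na, logical(1))]
  cbind(data.frame(model = x$model, rep = seq_len(x$n_reps),
                   seed = vapply(seq_len(x$n_reps), child_seed, integer(1),
                                 master = x$seed)),
        as.data.frame(pars),
        data.frame(extinction_time = x$times, extinct_species = x$species,
                   extinct_genotype = x$genotype, censored = x$censored))
}

#' Sweep cells reproducing the population-size comparison
#'
#' Builds one cell per (model, target parasite population size). For the
#' constant-size models the target `N_P` is the configured size; for the
#' ecological models the host birth rate achieving the target equilibrium
#' size is found by inverting [interior_fixed_point()] (never assumed), with
#' `comp_rate = b_H / K` in EcoEvoPlus and `comp_rate = 0` in EcoEvo.
#' Simulations start at the (rounded) equilibrium with an equal genotype
#' split.
#'
#' @param N_P target total parasite population sizes (even numbers).
#' @param models subset of the model names to include; `"dtEvoPlus"` and
#'   `"dtEvo"` cells are computed exactly (first-passage solve) rather than
#'   simulated.
#' @param N_H host population size for the constant-size models (also the
#'   equilibrium host size of the ecological cells).
#' @param K carrying capacity for EcoEvoPlus.
#' @param lam0 base interaction rate (`lam = lam0 / K`).
#' @param d_P parasite death rate.
#' @param w_H,w_P selection intensities for the game-theory models.
#' @return list of cells for [population_size_sweep()].
#' @export
fig3_sweep_spec <- function(N_P = c(30, 60, 100),
                            models = c("EvoPlus", "Evo", "Hybrid",
                                       "EcoEvoPlus", "EcoEvo"),
                            N_H = 250, K = 500, lam0 = 4, d_P = 1,
                            w_H = 0.5, w_P = 1) {
  lam <- lam0 / K
  cells <- list()
  for (model in models) {
    for (np in N_P) {
      cell <- list(model = model, n = 2L, target_NP = np)
      if (model %in% c("EcoEvo", "EcoEvoPlus")) {
        target_b <- function(b) {
          pars <- model_params(b_H = b, d_P = d_P, lam = lam,
                               comp_rate = if (model == "EcoEvoPlus") b / K else 0)
          sum(interior_fixed_point(model, pars, 2)[3:4]) - np
        }
        cell <- tryCatch({
          b <- uniroot(target_b, c(1e-6, 1e3), tol = 1e-10)$root
          pars <- model_params(b_H = b, d_P = d_P, lam = lam,
                               comp_rate = if (model == "EcoEvoPlus") b / K else 0)
          fp <- interior_fixed_point(model, pars, 2)
          c(cell, list(params = pars, b_H = b,
                       init = population_state(round(fp[1:2]), round(fp[3:4])),
                       method = "simulate", feasible = TRUE))
        }, error = function(e) {
          c(cell, list(feasible = FALSE, reason = conditionMessage(e)))
        })
      } else {
        pars <- model_params(w_H = w_H, w_P = w_P)
        cell <- c(cell, list(
          params = pars, b_H = NA_real_,
          init = uniform_init(N_H, np, 2),
          method = if (model %in% dt_models) "exact" else "simulate",
          feasible = TRUE))
      }
      cells[[length(cells) + 1L]] <- cell
    }
  }
  cells
}

#' Mean extinction time across population sizes
#'
#' Runs every sweep cell: simulated cells get an [extinction_ensemble()]
#' with a cell-specific child seed; exact discrete-time cells get the
#' first-passage mean from the equal-split central start. Infeasible cells
#' (no positive equilibrium) are flagged, never dropped.
#'
#' @param cells list of cells from [fig3_sweep_spec()] (or hand-built).
#' @param n_reps replicates per simulated cell.
#' @param seed master seed.
#' @param stop an [stop_condition()] for the simulated cells.
#' @return data.frame with one row per cell: model, target_NP, b_H,
#'   mean_time, se, n_censored, method, feasible.
#' @export
population_size_sweep <- function(cells, n_reps = 100, seed = 1,
                                  stop = stop_condition(t_max = 1e6)) {
  rows <- lapply(seq_along(cells), function(k) {
    cell <- cells[[k]]
    base <- data.frame(model = cell$model, target_NP = cell$target_NP,
                       b_H = if (is.null(cell$b_H)) NA_real_ else cell$b_H,
                       mean_time = NA_real_, se = NA_real_,
                       n_reps = 0L, n_censored = 0L,
                       method = if (is.null(cell$method)) NA_character_
                                else cell$method,
                       feasible = isTRUE(cell$feasible))
    if (!isTRUE(cell$feasible)) return(base)
    if (cell$method == "exact") {
      A <- matching_matrix(2, cell$params$alpha, cell$params$beta)
      tau <- exact_mean_extinction_time(cell$model, A, cell$params$w_H,
                                        cell$params$w_P,
                                        N_H = sum(cell$init$H),
                                        N_P = sum(cell$init$P))
      base$mean_time <- tau[as.character(cell$init$H[1]),
                            as.character(cell$init$P[1])]
      base$se <- 0
      return(base)
    }
    ens <- extinction_ensemble(cell$model, cell$params, cell$init,
                               n_reps = n_reps,
                               seed = child_seed(seed, k), stop = stop)
    base$mean_time <- ens$mean
    base$se <- ens$se
    base$n_reps <- n_reps
    base$n_censored <- ens$censored_count
    base
  })
  do.call(rbind, rows)
}

#' Default many-genotype parameters for the diversity experiment
#'
#' Scaled from the two-genotype reference equilibrium (25 hosts and 75
#' parasites per genotype) to `n` genotypes: `b_H = 6`, `d_P = 1`,
#' `lam = 1/25` and `comp_rate` chosen so each genotype keeps those
#' per-genotype equilibrium abundances.
#'
#' @param n genotypes per species.
#' @return a [model_params()].
#' @export
diversity_params <- function(n = 20) {
  H_per <- 25; P_per <- 75; b_H <- 6; d_P <- 1
  lam <- d_P / H_per
  comp <- (b_H - lam * P_per) / (n * H_per)
  model_params(b_H = b_H, d_P = d_P, lam = lam, comp_rate = comp)
}

#' Mean genotype diversity over time
#'
#' Simulates `n_reps` replicates from a uniform initial distribution of `n`
#' genotypes and counts, on a fixed time grid and from event-exact states,
#' how many genotypes are still present in each species. Without mutation
#' every per-replicate series is non-increasing; the ensemble mean decays
#' exponentially during the loss phase.
#'
#' @param model model name (default the competition-regulated EcoEvoPlus).
#' @param n genotypes per species.
#' @param params a [model_params()] (default [diversity_params()]).
#' @param init initial state (default: the per-genotype equilibrium
#'   abundances of `params`).
#' @param n_reps replicates.
#' @param seed master seed.
#' @param t_grid recording grid.
#' @param with_mutation include genotype conversion.
#' @return an object of class `rq_diversity`: time grid, mean diversity per
#'   species, and the per-replicate series.
#' @export
diversity_time_series <- function(model = "EcoEvoPlus", n = 20,
                                  params = diversity_params(n), init = NULL,
                                  n_reps = 100, seed = 1,
                                  t_grid = seq(0, 150, by = 1),
                                  with_mutation = FALSE) {
  if (is.null(init)) {
    fp <- interior_fixed_point(model, params, n)
    init <- population_state(round(fp[seq_len(n)]), round(fp[n + seq_len(n)]))
  }
  system <- build_model(model, n, params, with_mutation = with_mutation)
  stop <- stop_condition(t_max = max(t_grid), stop_on_genotype_loss = FALSE)
  host <- matrix(NA_real_, n_reps, length(t_grid))
  para <- matrix(NA_real_, n_reps, length(t_grid))
  for (r in seq_len(n_reps)) {
    res <- simulate_ct(system, init, stop, seed = child_seed(seed, r),
                       record_grid = t_grid)
    tr <- res$trajectory
    m <- nrow(tr)
    Hc <- as.matrix(tr[, 1 + seq_len(n)])
    Pc <- as.matrix(tr[, 1 + n + seq_len(n)])
    host[r, seq_len(m)] <- rowSums(Hc > 0)
    para[r, seq_len(m)] <- rowSums(Pc > 0)
    if (m < length(t_grid)) {   # population died out: diversity stays put
      host[r, (m + 1):length(t_grid)] <- host[r, m]
      para[r, (m + 1):length(t_grid)] <- para[r, m]
    }
  }
  structure(list(t = t_grid, host_mean = colMeans(host),
                 parasite_mean = colMeans(para),
                 host_per_rep = host, parasite_per_rep = para,
                 model = model, n = n, n_reps = n_reps, params = params,
                 seed = seed), class = "rq_diversity")
}

#' @exportS3Method base::print
print.rq_diversity <- function(x, ...) {
  cat(sprintf(
    "<rq_diversity> %s, n = %d genotypes, %d replicates, t in [0, %g]\n",
    x$model, x$n, x$n_reps, max(x$t)))
  cat(sprintf("  mean diversity at end: host %.2f, parasite %.2f\n",
              tail(x$host_mean, 1), tail(x$parasite_mean, 1)))
  invisible(x)
}

#' Exponential decay rate of mean diversity
#'
#' Least-squares fit of `log(mean diversity)` on time. The default series
#' is the across-species mean (diversity treated as one statistic of the
#' standing variation; per-species fits are available). The default window
#' runs from `t = 0` to the first time the mean drops below 2 (the decay
#' phase; the terminal plateau near monomorphism is excluded).
#'
#' @param series an `rq_diversity`, or a data.frame with columns `t` and
#'   `diversity`.
#' @param species `"both"` (across-species mean), `"host"` or
#'   `"parasite"` (ignored for data.frame input).
#' @param window optional `c(t_min, t_max)` overriding the default.
#' @return list with `rate` (positive for decay), `intercept`,
#'   `r_squared`, `window`, and the fitted points.
#' @export
fit_exponential_decay <- function(series,
                                  species = c("both", "host", "parasite"),
                                  window = NULL) {
  if (is.data.frame(series)) {
    t <- series$t; d <- series$diversity
  } else {
    species <- match.arg(species)
    t <- series$t
    d <- switch(species,
                both = (series$host_mean + series$parasite_mean) / 2,
                host = series$host_mean,
                parasite = series$parasite_mean)
  }
  if (is.null(window)) {
    below <- which(d < 2)
    t_end <- if (length(below)) t[below[1]] else max(t)
    window <- c(0, t_end)
  }
  keep <- t >= window[1] & t <= window[2] & d > 1
  if (sum(keep) < 3) {
    stop("decay window contains fewer than 3 usable points", call. = FALSE)
  }
  y <- log(d[keep])
  fit <- lm(y ~ t[keep])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  list(rate = -unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, window = window,
       t = t[keep], log_diversity = y)
}

#' Long run with genotype conversion (mutation) enabled
#'
#' Simulates the competition-regulated ecological model with five genotypes
#' per species and cyclic neighbour conversion, logging every revival event
#' (a genotype count leaving zero). Revivals let oscillations re-emerge
#' after selective sweeps, mixing negative frequency-dependent selection
#' with arms-race dynamics.
#'
#' @param seed seed for the run.
#' @param params a [model_params()]; default: the five-genotype reference
#'   set (`b_H = 6`, `d_P = 1`, `K = 600`, `lam0 = 10`, `mut_H = 0.005`,
#'   `mut_P = 0.01`).
#' @param n genotypes per species.
#' @param init initial state (default: equal split of `N_H = 300`,
#'   `N_P = 900`, the deterministic equilibrium).
#' @param t_max run horizon.
#' @param record_dt trajectory recording interval.
#' @return list with `trajectory`, `revivals`, `mean_sizes` (time-averaged
#'   total abundances), `n_events`, and the resolved `params`.
#' @export
mutation_regime_run <- function(seed, params = NULL, n = 5, init = NULL,
                                t_max = 500, record_dt = 0.25) {
  if (is.null(params)) {
    params <- model_params(b_H = 6, d_P = 1, K = 600, lam0 = 10,
                           mut_H = 0.005, mut_P = 0.01)
  }
  if (is.null(init)) init <- uniform_init(300, 900, n)
  system <- build_model("EcoEvoPlus", n, params, with_mutation = TRUE)
  res <- simulate_ct(system, init,
                     stop_condition(t_max = t_max,
                                    stop_on_genotype_loss = FALSE),
                     seed = seed,
                     record_grid = seq(0, t_max, by = record_dt))
  tr <- res$trajectory
  N_H <- rowSums(tr[, 1 + seq_len(n), drop = FALSE])
  N_P <- rowSums(tr[, 1 + n + seq_len(n), drop = FALSE])
  list(trajectory = tr, revivals = res$revivals,
       mean_sizes = c(N_H = mean(N_H), N_P = mean(N_P)),
       n_events = res$n_events, params = params)
}
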