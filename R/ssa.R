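#' Stopping rules for a continuous-time simulation
#'
#' @param t_max simulated-time cap.
#' @param event_max cap on the number of reaction events.
#' @param n_max cap on the total population `N_H + N_P` (guards runaway
#'   growth in the unconstrained EcoEvo model).
#' @param stop_on_genotype_loss stop at the first genotype loss (default).
#'   At least one of the three caps must be finite.
#' @return an object of class `rq_stop`.
#' @export
stop_condition <- function(t_max = Inf, event_max = Inf, n_max = Inf,
                           stop_on_genotype_loss = TRUE) {
  if (!is.finite(t_max) && !is.finite(event_max) && !is.finite(n_max)) {
    stop("at least one stopping cap must be finite", call. = FALSE)
  }
  structure(list(t_max = t_max, event_max = event_max, n_max = n_max,
                 stop_on_genotype_loss = isTRUE(stop_on_genotype_loss)),
            class = "rq_stop")
}

#' One Gillespie step
#'
#' Draws an exponential waiting time with rate `sum(rates)` and a reaction
#' index with probability proportional to its rate (the direct method).
#' Deterministic uniforms can be injected for testing the inverse
#' transforms.
#'
#' @param rates non-negative rate vector.
#' @param u_time,u_reaction optional uniforms in (0, 1); drawn from the RNG
#'   when `NULL`.
#' @return `NULL` when all rates are zero (absorbing-state signal),
#'   otherwise a list with `tau` (waiting time) and `index` (1-based
#'   reaction index).
#' @export
gillespie_step <- function(rates, u_time = NULL, u_reaction = NULL) {
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  total <- sum(rates)
  if (total <= 0) return(NULL)
  if (is.null(u_time)) u_time <- runif(1)
  if (is.null(u_reaction)) u_reaction <- runif(1)
  tau <- -log(u_time) / total
  index <- findInterval(u_reaction * total, cumsum(rates),
                        left.open = TRUE) + 1L
  index <- min(index, length(rates))
  list(tau = tau, index = index)
}

#' Exact stochastic simulation of a reaction system
#'
#' Iterates Gillespie steps over the system's propensities. The run halts at
#' the first genotype loss (recording time, species and genotype index), at
#' an absorbing state where every rate is zero, or at a stopping cap
#' (censored). Built-in systems from [build_model()] run in compiled code;
#' custom systems use a generic R loop with the same semantics. The same
#' seed and inputs always reproduce the trajectory bit-identically.
#'
#' States are recorded on a fixed time grid (the event-exact state held at
#' each grid time), which bounds memory on long runs; extinction detection
#' always uses exact event states, never the grid.
#'
#' @param system an `rq_reaction_system`.
#' @param init initial [population_state()].
#' @param stop an [stop_condition()].
#' @param seed optional integer seed.
#' @param record_grid numeric vector of times at which to record the state
#'   (default: 201 points spanning `[0, t_max]` when `t_max` is finite,
#'   otherwise no recording).
#' @return list with `trajectory` (data.frame `t, H_1.., P_1..`), `record`
#'   (an [extinction_record()], or `NULL` if no genotype was ever lost),
#'   `revivals` (data.frame of events where a count left zero), `n_events`,
#'   `final_state`, `absorbed`, and `censored`.
#' @export
simulate_ct <- function(system, init, stop = stop_condition(t_max = 1000),
                        seed = NULL, record_grid = NULL) {
  stopifnot(inherits(system, "rq_reaction_system"), inherits(init, "rq_state"))
  if (length(init$H) != system$n) {
    stop("initial state dimension does not match the system", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_grid)) {
    record_grid <- if (is.finite(stop$t_max))
      seq(0, stop$t_max, length.out = 201) else numeric(0)
  }
  if (system$native) {
    p <- system$params
    res <- cpp_simulate_ct(
      model_id = match(system$model, ct_models),
      H0 = init$H, P0 = init$P,
      w_H = na0(p$w_H), w_P = na0(p$w_P),
      alpha = na0(p$alpha), beta = na0(p$beta),
      b_H = na0(p$b_H), d_P = na0(p$d_P), lam = na0(p$lam),
      comp_rate = na0(p$comp_rate),
      mut_H = na0(p$mut_H), mut_P = na0(p$mut_P),
      with_mutation = system$with_mutation,
      t_max = stop$t_max, event_max = stop$event_max, n_max = stop$n_max,
      stop_on_loss = stop$stop_on_genotype_loss,
      grid = as.numeric(record_grid))
    n_rec <- res$n_rec
    traj <- cbind(data.frame(t = res$rec_t[seq_len(n_rec)]),
                  mat_df(res$rec_H[seq_len(n_rec), , drop = FALSE], "H"),
                  mat_df(res$rec_P[seq_len(n_rec), , drop = FALSE], "P"))
    record <- if (res$ext_found) {
      extinction_record(res$ext_time,
                        species = c("host", "parasite")[res$ext_species],
                        genotype = res$ext_genotype)
    } else if (res$censored || res$absorbed) {
      extinction_record(res$t, censored = TRUE)
    } else NULL
    revivals <- data.frame(t = res$rev_t,
                           species = c("host", "parasite")[res$rev_species],
                           genotype = res$rev_genotype)
    return(list(trajectory = traj, record = record, revivals = revivals,
                n_events = res$n_events,
                final_state = population_state(res$H, res$P, res$t),
                absorbed = res$absorbed, censored = res$censored))
  }
  simulate_ct_generic(system, init, stop, record_grid)
}

na0 <- function(x) if (is.null(x) || is.na(x)) 0 else x

mat_df <- function(m, prefix) {
  colnames(m) <- paste0(prefix, "_", seq_len(ncol(m)))
  as.data.frame(m)
}

# Generic (closure-based) SSA loop for custom reaction systems.
simulate_ct_generic <- function(system, init, stop, record_grid) {
  n <- system$n
  state <- population_state(init$H, init$P, 0)
  deltas_H <- lapply(system$reactions, `[[`, "delta_H")
  deltas_P <- lapply(system$reactions, `[[`, "delta_P")

  grid <- as.numeric(record_grid)
  g <- 1L; G <- length(grid)
  rec_t <- numeric(G); rec_H <- matrix(0, G, n); rec_P <- matrix(0, G, n)
  record_upto <- function(limit) {
    while (g <= G && grid[g] <= limit) {
      rec_t[g] <<- grid[g]; rec_H[g, ] <<- state$H; rec_P[g, ] <<- state$P
      g <<- g + 1L
    }
  }

  ext <- NULL
  note_loss <- function(species, geno, when) {
    if (is.null(ext)) ext <<- extinction_record(when, species, geno)
  }
  for (i in seq_len(n)) if (state$H[i] <= 0) note_loss("host", i, 0)
  for (i in seq_len(n)) if (state$P[i] <= 0) note_loss("parasite", i, 0)

  revs <- list()
  n_events <- 0; censored <- FALSE; absorbed <- FALSE
  done <- stop$stop_on_genotype_loss && !is.null(ext)

  while (!done) {
    if (sum(state$H) + sum(state$P) > stop$n_max ||
        n_events >= stop$event_max) { censored <- TRUE; break }
    rates <- propensities(system, state)
    step <- gillespie_step(rates)
    if (is.null(step)) {                     # absorbing state
      absorbed <- TRUE
      record_upto(if (G) grid[G] else state$t)
      break
    }
    t_new <- state$t + step$tau
    if (t_new > stop$t_max) {
      record_upto(stop$t_max)
      state$t <- stop$t_max
      censored <- TRUE
      break
    }
    record_upto(t_new * (1 - 1e-15))
    r <- system$reactions[[step$index]]
    oldH <- state$H; oldP <- state$P
    state$H <- state$H + deltas_H[[step$index]]
    state$P <- state$P + deltas_P[[step$index]]
    state$t <- t_new
    n_events <- n_events + 1
    for (i in which(deltas_H[[step$index]] > 0)) {
      if (oldH[i] == 0) revs[[length(revs) + 1L]] <-
          data.frame(t = t_new, species = "host", genotype = i)
    }
    for (i in which(deltas_P[[step$index]] > 0)) {
      if (oldP[i] == 0) revs[[length(revs) + 1L]] <-
          data.frame(t = t_new, species = "parasite", genotype = i)
    }
    for (i in which(deltas_H[[step$index]] < 0)) {
      if (state$H[i] < 0) stop("internal error: negative host count")
      if (state$H[i] == 0) note_loss("host", i, t_new)
    }
    for (i in which(deltas_P[[step$index]] < 0)) {
      if (state$P[i] < 0) stop("internal error: negative parasite count")
      if (state$P[i] == 0) note_loss("parasite", i, t_new)
    }
    done <- stop$stop_on_genotype_loss && !is.null(ext)
    if (done) record_upto(t_new)
  }

  n_rec <- g - 1L
  traj <- cbind(data.frame(t = rec_t[seq_len(n_rec)]),
                mat_df(rec_H[seq_len(n_rec), , drop = FALSE], "H"),
                mat_df(rec_P[seq_len(n_rec), , drop = FALSE], "P"))
  if (is.null(ext) && (censored || absorbed)) {
    ext <- extinction_record(state$t, censored = TRUE)
  }
  revivals <- if (length(revs)) do.call(rbind, revs) else
    data.frame(t = numeric(0), species = character(0), genotype = integer(0))
  list(trajectory = traj, record = ext, revivals = revivals,
       n_events = n_events, final_state = state,
       absorbed = absorbed, censored = censored)
}

#' Derive a replicate seed from a master seed
#'
#' Replicate `r` of an experiment with master seed `m` always uses the same
#' child seed, independently of execution order, so ensembles are
#' reproducible replicate-by-replicate. Two rounds of the Lehmer
#' multiplicative congruence keep everything inside 31-bit integer range.
#'
#' @param master master seed (non-negative integer).
#' @param r replicate index (positive integer).
#' @return a positive integer seed below 2^31 - 1.
#' @export
child_seed <- function(master, r) {
  m <- 2147483647            # 2^31 - 1
  x <- (master %% m + r) %% m
  x <- (x * 48271 + 1) %% m  # products stay below 2^47 < 2^53
  x <- (x * 48271 + 1) %% m
  as.integer(x)
}

#' Write a trajectory to CSV
#'
#' @param trajectory data.frame from [simulate_ct()] or
#'   [simulate_discrete()].
#' @param path output file.
#' @param meta optional list serialised as a JSON sidecar `<path>.spec.json`
#'   so the result is re-runnable from its own metadata.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, meta = NULL) {
  write.csv(trajectory, path, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".spec.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Write a trajectory as a JSON-lines stream
#'
#' One compact JSON object per recorded state, suitable for streaming
#' consumers.
#'
#' @param trajectory data.frame from [simulate_ct()] or
#'   [simulate_discrete()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trajectory))) {
    writeLines(jsonlite::toJSON(as.list(trajectory[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
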