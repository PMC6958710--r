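#' @title Continuous-time model definitions as reaction systems
#' @description
#' Each continuous-time model is a list of reactions: an integer
#' stoichiometry on the host and parasite count vectors plus a
#' state-dependent propensity (a rate, not a probability). The reaction
#' order is fixed given `(model, n)` so seeded runs are reproducible.
#' @name reaction_systems
NULL

ct_models <- c("EcoEvo", "EcoEvoPlus", "Hybrid", "Evo", "EvoPlus")

#' A single reaction
#'
#' @param label human-readable name.
#' @param delta_H,delta_P integer stoichiometry vectors (entries in -1, 0, 1).
#' @param propensity function of an [population_state()] returning a
#'   non-negative rate; must be 0 whenever a consumed individual is absent.
#' @return an object of class `rq_reaction`.
#' @export
reaction <- function(label, delta_H, delta_P, propensity) {
  stopifnot(is.function(propensity),
            all(delta_H %in% -1:1), all(delta_P %in% -1:1))
  structure(list(label = label, delta_H = as.integer(delta_H),
                 delta_P = as.integer(delta_P), propensity = propensity),
            class = "rq_reaction")
}

#' A reaction system
#'
#' @param model model name (one of the five built-in names, or a custom
#'   label for user-assembled systems).
#' @param n number of genotypes per species.
#' @param reactions ordered list of [reaction()] objects.
#' @param params the [model_params()] the system was built with (optional
#'   for custom systems).
#' @param native whether the fast compiled simulation path applies (set by
#'   [build_model()]; custom systems use the generic R path).
#' @param with_mutation whether cyclic genotype-conversion channels are
#'   included.
#' @return an object of class `rq_reaction_system`.
#' @export
reaction_system <- function(model, n, reactions, params = NULL,
                            native = FALSE, with_mutation = FALSE) {
  stopifnot(length(reactions) >= 1L,
            all(vapply(reactions, inherits, logical(1), "rq_reaction")))
  structure(list(model = model, n = as.integer(n), reactions = reactions,
                 params = params, native = isTRUE(native),
                 with_mutation = isTRUE(with_mutation)),
            class = "rq_reaction_system")
}

#' @exportS3Method base::print
print.rq_reaction_system <- function(x, ...) {
  cat(sprintf("<rq_reaction_system> model = %s, n = %d, %d reactions%s\n",
              x$model, x$n, length(x$reactions),
              if (x$with_mutation) " (with mutation)" else ""))
  cat(paste0("  ", vapply(x$reactions, `[[`, character(1), "label"),
             collapse = "\n"), "\n", sep = "")
  invisible(x)
}

unit_vec <- function(n, i, sign = 1L) {
  v <- integer(n); v[i] <- sign; v
}

# Per-capita Hybrid rates: hosts die faster when matched parasites are
# common (raw matched load), parasites are born faster when matched hosts
# are common.
hybrid_rates <- function(H, P, alpha, beta, w_H, w_P) {
  N_H <- sum(H); N_P <- sum(P)
  d_H <- if (N_P > 0) 1 - w_H + w_H * (alpha * P + beta * (N_P - P)) / N_P
         else rep(1 - w_H, length(H))
  b_P <- if (N_H > 0) 1 - w_P + w_P * (alpha * H + beta * (N_H - H)) / N_H
         else rep(1 - w_P, length(P))
  list(d_H = d_H, b_P = b_P)
}

# Evo/EvoPlus replacement rates (n = 2): the dt transition expressions used
# directly as rates per unit time. Returns c(rate of 1 replacing 2,
# rate of 2 replacing 1) for one species.
evo_channel_rates <- function(model, counts, f, alpha, beta) {
  tr <- dt_triple(if (model == "EvoPlus") "dtEvoPlus" else "dtEvo",
                  counts, f, alpha, beta)
  c(tr[["up"]], tr[["down"]])
}

#' Build a continuous-time model as a reaction system
#'
#' The five models, in rate form (all propensities evaluated at the current
#' state; `i` runs over genotypes, `e_i` is a unit stoichiometry):
#'
#' * **EcoEvo** -- host birth `H_i -> H_i + 1` at `b_H * H_i`; parasite death
#'   `P_i -> P_i - 1` at `d_P * P_i`; a matching pair triggers, as two
#'   independent channels with the same rate constant, a host death at
#'   `lam * H_i * P_i` and a parasite birth at `lam * H_i * P_i`.
#'   Population sizes are unconstrained (individual-based Lotka-Volterra).
#' * **EcoEvoPlus** -- EcoEvo plus intraspecific host competition:
#'   `H_i -> H_i - 1` at `comp_rate * H_i * N_H` (logistic regulation with
#'   carrying capacity `K = b_H / comp_rate`).
#' * **Hybrid** -- game-driven per-capita host death
#'   `d_H,i = 1 - w_H + w_H (alpha P_i + beta (N_P - P_i)) / N_P` and
#'   parasite birth `b_P,i = 1 - w_P + w_P (alpha H_i + beta (N_H - H_i)) / N_H`;
#'   host births and parasite deaths are redistributed uniformly per capita
#'   so that the total birth rate equals the total death rate in each
#'   species at every state (population size constrained in expectation).
#' * **EvoPlus / Evo** (`n = 2` only) -- paired replacement within each
#'   species at the discrete-time Moran / pairwise-comparison transition
#'   expressions used as rates; population sizes exactly conserved.
#'
#' With `with_mutation = TRUE` (ecological and Hybrid models only), each
#' individual converts to either cyclic neighbour genotype at rate
#' `mut_H / 2` (hosts) or `mut_P / 2` (parasites); conversions change
#' genotype counts but not population sizes.
#'
#' @param name one of `"EcoEvo"`, `"EcoEvoPlus"`, `"Hybrid"`, `"Evo"`,
#'   `"EvoPlus"`.
#' @param n genotypes per species (`n = 2` required for Evo/EvoPlus).
#' @param params a [model_params()] carrying the rates the model needs.
#' @param with_mutation include cyclic genotype-conversion reactions.
#' @return an `rq_reaction_system`.
#' @export
build_model <- function(name, n, params, with_mutation = FALSE) {
  if (!name %in% ct_models) {
    stop(sprintf("unknown model '%s' (use %s)", name,
                 paste(ct_models, collapse = ", ")), call. = FALSE)
  }
  if (!inherits(params, "rq_params")) stop("`params` must be a model_params()",
                                           call. = FALSE)
  if (n < 2 || n != round(n)) stop("`n` must be an integer >= 2", call. = FALSE)
  n <- as.integer(n)
  if (name %in% c("Evo", "EvoPlus") && n != 2L) {
    stop(sprintf("model '%s' supports exactly two genotypes per species", name),
         call. = FALSE)
  }
  if (with_mutation && name %in% c("Evo", "EvoPlus")) {
    stop("mutation is not supported for the constant-size Evo/EvoPlus models",
         call. = FALSE)
  }
  alpha <- params$alpha; beta <- params$beta
  w_H <- params$w_H; w_P <- params$w_P
  reactions <- list()
  add <- function(r) reactions[[length(reactions) + 1L]] <<- r

  if (name %in% c("EcoEvo", "EcoEvoPlus")) {
    b_H <- params_field(params, "b_H", name)
    d_P <- params_field(params, "d_P", name)
    lam <- params_field(params, "lam", name)
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("host_birth_%d", k), unit_vec(n, k, 1L), integer(n),
                   function(s) b_H * s$H[k]))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("parasite_death_%d", k), integer(n), unit_vec(n, k, -1L),
                   function(s) d_P * s$P[k]))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("matched_host_death_%d", k), unit_vec(n, k, -1L),
                   integer(n), function(s) lam * s$H[k] * s$P[k]))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("matched_parasite_birth_%d", k), integer(n),
                   unit_vec(n, k, 1L), function(s) lam * s$H[k] * s$P[k]))
    })
    if (name == "EcoEvoPlus") {
      comp <- params$comp_rate
      if (is.na(comp) || comp <= 0) {
        stop("EcoEvoPlus requires a positive `comp_rate` (or `K`)", call. = FALSE)
      }
      for (i in seq_len(n)) local({
        k <- i
        add(reaction(sprintf("competition_death_%d", k), unit_vec(n, k, -1L),
                     integer(n), function(s) comp * s$H[k] * sum(s$H)))
      })
    }
  } else if (name == "Hybrid") {
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("host_death_%d", k), unit_vec(n, k, -1L), integer(n),
                   function(s) {
                     r <- hybrid_rates(s$H, s$P, alpha, beta, w_H, w_P)
                     s$H[k] * r$d_H[k]
                   }))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("parasite_birth_%d", k), integer(n), unit_vec(n, k, 1L),
                   function(s) {
                     r <- hybrid_rates(s$H, s$P, alpha, beta, w_H, w_P)
                     s$P[k] * r$b_P[k]
                   }))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("host_birth_%d", k), unit_vec(n, k, 1L), integer(n),
                   function(s) {
                     N_H <- sum(s$H)
                     if (N_H == 0) return(0)
                     r <- hybrid_rates(s$H, s$P, alpha, beta, w_H, w_P)
                     s$H[k] * sum(s$H * r$d_H) / N_H
                   }))
    })
    for (i in seq_len(n)) local({
      k <- i
      add(reaction(sprintf("parasite_death_%d", k), integer(n), unit_vec(n, k, -1L),
                   function(s) {
                     N_P <- sum(s$P)
                     if (N_P == 0) return(0)
                     r <- hybrid_rates(s$H, s$P, alpha, beta, w_H, w_P)
                     s$P[k] * sum(s$P * r$b_P) / N_P
                   }))
    })
  } else {  # Evo / EvoPlus, n = 2
    A <- matching_matrix(2, alpha, beta)
    host_rates <- function(s) {
      if (any(s$H == 0)) return(c(0, 0))
      f <- fitness_from_payoff(host_payoffs(rel_freq(s$P), A), w_H)
      evo_channel_rates(name, s$H, f, alpha, beta)
    }
    par_rates <- function(s) {
      if (any(s$P == 0)) return(c(0, 0))
      f <- fitness_from_payoff(parasite_payoffs(rel_freq(s$H), A), w_P)
      evo_channel_rates(name, s$P, f, alpha, beta)
    }
    add(reaction("host_1_replaces_2", c(1L, -1L), integer(2),
                 function(s) host_rates(s)[1]))
    add(reaction("host_2_replaces_1", c(-1L, 1L), integer(2),
                 function(s) host_rates(s)[2]))
    add(reaction("parasite_1_replaces_2", integer(2), c(1L, -1L),
                 function(s) par_rates(s)[1]))
    add(reaction("parasite_2_replaces_1", integer(2), c(-1L, 1L),
                 function(s) par_rates(s)[2]))
  }

  if (with_mutation) {
    mut_H <- params$mut_H; mut_P <- params$mut_P
    for (i in seq_len(n)) for (dir in c(1L, -1L)) local({
      k <- i; to <- ((i - 1L + dir) %% n) + 1L
      add(reaction(sprintf("host_mutation_%d_to_%d", k, to),
                   unit_vec(n, k, -1L) + unit_vec(n, to, 1L), integer(n),
                   function(s) mut_H / 2 * s$H[k]))
    })
    for (i in seq_len(n)) for (dir in c(1L, -1L)) local({
      k <- i; to <- ((i - 1L + dir) %% n) + 1L
      add(reaction(sprintf("parasite_mutation_%d_to_%d", k, to), integer(n),
                   unit_vec(n, k, -1L) + unit_vec(n, to, 1L),
                   function(s) mut_P / 2 * s$P[k]))
    })
  }

  reaction_system(name, n, reactions, params = params, native = TRUE,
                  with_mutation = with_mutation)
}

#' Evaluate all reaction propensities at a state
#'
#' @param system an `rq_reaction_system`.
#' @param state an [population_state()] of matching dimension.
#' @return named numeric vector of non-negative rates, in reaction order.
#' @export
propensities <- function(system, state) {
  if (length(state$H) != system$n || length(state$P) != system$n) {
    stop("state dimension does not match the reaction system", call. = FALSE)
  }
  if (any(state$H < 0) || any(state$P < 0)) {
    stop("corrupted state: negative genotype count", call. = FALSE)
  }
  rates <- vapply(system$reactions, function(r) r$propensity(state), numeric(1))
  names(rates) <- vapply(system$reactions, `[[`, character(1), "label")
  if (any(rates < 0) || any(!is.finite(rates))) {
    stop("propensity evaluation produced a negative or non-finite rate",
         call. = FALSE)
  }
  rates
}

#' Mean-field drift of a reaction system
#'
#' The expected instantaneous change of the count vectors,
#' `sum_r a_r(x) * Delta_r` -- the quantity whose large-population limit is
#' the model's deterministic right-hand side.
#'
#' @param system an `rq_reaction_system`.
#' @param state an [population_state()].
#' @return list with numeric vectors `H` and `P`.
#' @export
mean_field_drift <- function(system, state) {
  a <- propensities(system, state)
  dH <- numeric(system$n); dP <- numeric(system$n)
  for (j in seq_along(system$reactions)) {
    r <- system$reactions[[j]]
    dH <- dH + a[j] * r$delta_H
    dP <- dP + a[j] * r$delta_P
  }
  list(H = dH, P = dP)
}
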