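#' Model parameters for all host-parasite processes
#'
#' Collects every rate and intensity used by the five continuous-time models
#' and the two discrete-time processes. Derived quantities are resolved once,
#' here: the interaction rate may be given directly (`lam`) or as a base rate
#' scaled by the carrying capacity (`lam = lam0 / K`), and the intraspecific
#' host competition rate may be given directly (`comp_rate`) or derived from
#' the carrying capacity (`comp_rate = b_H / K`). Supplying redundant,
#' inconsistent values is an error rather than a silent override.
#'
#' @param w_H,w_P host and parasite selection intensities in `[0, 1]`
#'   (game-theory models only).
#' @param alpha,beta matching-allele fitness effects, `alpha >= beta`.
#' @param b_H host birth rate (per capita per unit time; ecological models).
#' @param d_P parasite death rate (per capita per unit time; default 1).
#' @param lam interaction rate: a matching host-parasite pair triggers a host
#'   death or a parasite birth at this rate (per pair per unit time).
#' @param lam0 base interaction rate; when given with `K`, `lam = lam0 / K`.
#' @param comp_rate intraspecific host competition rate (per host pair per
#'   unit time; the `+` in EcoEvo+). `comp_rate = 0` disables competition.
#' @param K host carrying capacity `b_H / comp_rate` (host population size
#'   reached in the absence of parasites).
#' @param mut_H,mut_P genotype conversion (mutation) rates per capita per
#'   unit time; each individual converts to either cyclic neighbour genotype
#'   at half this rate.
#' @return an object of class `rq_params` (a validated list).
#' @examples
#' model_params(w_H = 0.5, w_P = 1, b_H = 6, d_P = 1, K = 100, lam0 = 4)
#' @export
model_params <- function(w_H = 0, w_P = 0, alpha = 1, beta = 0,
                         b_H = NULL, d_P = 1, lam = NULL, lam0 = NULL,
                         comp_rate = NULL, K = NULL,
                         mut_H = 0, mut_P = 0) {
  num1 <- function(x, nm, lo = 0, hi = Inf) {
    if (is.null(x)) return(NA_real_)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("`%s` must be a single number in [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
    as.numeric(x)
  }
  w_H <- num1(w_H, "w_H", 0, 1); w_P <- num1(w_P, "w_P", 0, 1)
  alpha <- num1(alpha, "alpha", -Inf, Inf); beta <- num1(beta, "beta", -Inf, Inf)
  if (alpha < beta) stop("`alpha` must be >= `beta`", call. = FALSE)
  b_H <- num1(b_H, "b_H"); d_P <- num1(d_P, "d_P")
  lam <- num1(lam, "lam"); lam0 <- num1(lam0, "lam0")
  comp_rate <- num1(comp_rate, "comp_rate"); K <- num1(K, "K")
  mut_H <- num1(mut_H, "mut_H"); mut_P <- num1(mut_P, "mut_P")

  # resolve lam = lam0 / K
  if (!is.na(lam0) && !is.na(K)) {
    derived <- lam0 / K
    if (is.na(lam)) {
      lam <- derived
    } else if (abs(lam - derived) > 1e-9 * max(1, derived)) {
      stop(sprintf("inconsistent interaction rate: lam = %g but lam0/K = %g",
                   lam, derived), call. = FALSE)
    }
  } else if (!is.na(lam) && !is.na(K) && is.na(lam0)) {
    lam0 <- lam * K
  }

  # resolve comp_rate = b_H / K (only meaningful when competition is on)
  if (!is.na(K) && !is.na(b_H)) {
    derived <- b_H / K
    if (is.na(comp_rate)) {
      comp_rate <- derived
    } else if (comp_rate > 0 &&
               abs(comp_rate - derived) > 1e-9 * max(1, derived)) {
      stop(sprintf(
        "inconsistent competition rate: comp_rate = %g but b_H/K = %g",
        comp_rate, derived), call. = FALSE)
    }
  } else if (!is.na(comp_rate) && comp_rate > 0 && !is.na(b_H) && is.na(K)) {
    K <- b_H / comp_rate
  }
  if (is.na(comp_rate)) comp_rate <- 0

  structure(
    list(w_H = w_H, w_P = w_P, alpha = alpha, beta = beta,
         b_H = b_H, d_P = d_P, lam = lam, lam0 = lam0,
         comp_rate = comp_rate, K = K, mut_H = mut_H, mut_P = mut_P),
    class = "rq_params")
}

#' @exportS3Method base::print
print.rq_params <- function(x, ...) {
  cat("<rq_params>\n")
  vals <- unlist(x)
  shown <- vals[!is.na(vals)]
  cat(paste0("  ", names(shown), " = ", signif(shown, 6), collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

params_field <- function(params, nm, model) {
  v <- params[[nm]]
  if (is.null(v) || is.na(v)) {
    stop(sprintf("model '%s' requires parameter `%s`", model, nm),
         call. = FALSE)
  }
  v
}

#' Host and parasite population state
#'
#' Integer genotype abundance vectors for both species plus the current time
#' (steps for the discrete-time processes, continuous units otherwise).
#'
#' @param H,P non-negative integer genotype counts (equal length).
#' @param t current time (default 0).
#' @return an object of class `rq_state`.
#' @export
population_state <- function(H, P, t = 0) {
  H <- as.numeric(H); P <- as.numeric(P)
  if (length(H) != length(P)) {
    stop("host and parasite count vectors must have the same length",
         call. = FALSE)
  }
  if (any(H < 0) || any(P < 0) || any(H != round(H)) || any(P != round(P))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  structure(list(H = H, P = P, t = as.numeric(t)), class = "rq_state")
}

#' @exportS3Method base::print
print.rq_state <- function(x, ...) {
  cat(sprintf("<rq_state> t = %g\n  H = (%s)  N_H = %g\n  P = (%s)  N_P = %g\n",
              x$t, paste(x$H, collapse = ", "), sum(x$H),
              paste(x$P, collapse = ", "), sum(x$P)))
  invisible(x)
}

#' Equal-split initial state
#'
#' The standing genetic variation used throughout: every genotype starts at
#' `N_H / n` (hosts) and `N_P / n` (parasites). Totals must divide evenly.
#'
#' @param N_H,N_P total population sizes.
#' @param n number of genotypes per species.
#' @return an `rq_state`.
#' @export
uniform_init <- function(N_H, N_P, n = 2) {
  if (N_H %% n != 0 || N_P %% n != 0) {
    stop(sprintf("N_H and N_P must be divisible by n = %d for an equal split", n),
         call. = FALSE)
  }
  population_state(rep(N_H / n, n), rep(N_P / n, n))
}

#' Record of the first genotype loss
#'
#' @param time first-loss time (or the cap time when censored).
#' @param species `"host"`, `"parasite"`, or `NA` when censored.
#' @param genotype index of the lost genotype, or `NA` when censored.
#' @param censored `TRUE` when a stopping cap was reached before any loss.
#' @return an object of class `rq_extinction`.
#' @export
extinction_record <- function(time, species = NA_character_,
                              genotype = NA_integer_, censored = FALSE) {
  structure(list(time = as.numeric(time), species = species,
                 genotype = as.integer(genotype), censored = isTRUE(censored)),
            class = "rq_extinction")
}

#' @exportS3Method base::print
print.rq_extinction <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<rq_extinction> censored at t = %g (no genotype lost)\n", x$time))
  } else {
    cat(sprintf("<rq_extinction> %s genotype %d lost at t = %g\n",
                x$species, x$genotype, x$time))
  }
  invisible(x)
}
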