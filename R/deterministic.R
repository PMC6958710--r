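#' @title Deterministic limits of the stochastic models
#' @description
#' Large-population limits: the adjusted replicator dynamics (EvoPlus), the
#' replicator dynamics (Evo and Hybrid), and Lotka-Volterra dynamics with or
#' without logistic host competition (EcoEvoPlus / EcoEvo). Frequency models
#' evolve genotype frequencies `(h, p)`; ecological models evolve continuous
#' abundances `(H, P)`. The right-hand sides are written with the
#' selection-intensity-bearing fitness `f = 1 - w + w * pi`, matching the
#' rates of the stochastic processes.
#' @name deterministic
NULL

det_models <- c("Evo", "EvoPlus", "Hybrid", "EcoEvo", "EcoEvoPlus")

det_kind <- function(model) {
  model <- switch(model, dtEvo = "Evo", dtEvoPlus = "EvoPlus", model)
  if (!model %in% det_models) {
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  }
  list(model = model,
       kind = if (model %in% c("EcoEvo", "EcoEvoPlus")) "abundance"
              else "frequency")
}

#' Deterministic right-hand side
#'
#' For the frequency models the state is `y = c(h, p)` (each half summing
#' to 1); for the ecological models it is `y = c(H, P)` (non-negative
#' abundances). The derivatives:
#'
#' * Evo / Hybrid (replicator): `dh_i = h_i (f_H,i - fbar_H)`, and likewise
#'   for `p` with the parasite fitnesses.
#' * EvoPlus (adjusted replicator): the same selection terms divided by the
#'   mean fitness of the own species.
#' * EcoEvo(, Plus): `dH_i = H_i (b_H - comp_rate * N_H - lam * P_i)`,
#'   `dP_i = P_i (lam * H_i - d_P)`; `comp_rate = 0` recovers plain
#'   Lotka-Volterra.
#'
#' Frequency derivatives sum to zero within each species.
#'
#' @param model model name (dt names are mapped to their continuous
#'   counterparts).
#' @param y state vector of length `2 n`.
#' @param params a [model_params()].
#' @param n genotypes per species.
#' @return derivative vector of length `2 n`.
#' @export
ode_rhs <- function(model, y, params, n = 2) {
  mk <- det_kind(model)
  if (length(y) != 2 * n) stop("state must have length 2 * n", call. = FALSE)
  i1 <- seq_len(n); i2 <- n + i1
  if (mk$kind == "frequency") {
    h <- y[i1]; p <- y[i2]
    A <- matching_matrix(n, params$alpha, params$beta)
    f_H <- fitness_from_payoff((params$alpha + params$beta) - as.numeric(A %*% p),
                               params$w_H)
    f_P <- fitness_from_payoff(as.numeric(A %*% h), params$w_P)
    fbar_H <- sum(h * f_H); fbar_P <- sum(p * f_P)
    dh <- h * (f_H - fbar_H)
    dp <- p * (f_P - fbar_P)
    if (mk$model == "EvoPlus") {
      if (fbar_H <= 0 || fbar_P <= 0) {
        stop("mean fitness must be positive for the adjusted replicator",
             call. = FALSE)
      }
      dh <- dh / fbar_H; dp <- dp / fbar_P
    }
    c(dh, dp)
  } else {
    H <- y[i1]; P <- y[i2]
    b <- params_field(params, "b_H", mk$model)
    d <- params_field(params, "d_P", mk$model)
    lam <- params_field(params, "lam", mk$model)
    comp <- if (mk$model == "EcoEvoPlus") params$comp_rate else 0
    c(H * (b - comp * sum(H) - lam * P),
      P * (lam * H - d))
  }
}

#' Integrate a deterministic model
#'
#' Adaptive integration (lsoda) at the requested tolerances.
#'
#' @param model model name.
#' @param init initial state vector `c(h, p)` or `c(H, P)`.
#' @param params a [model_params()].
#' @param times output time grid.
#' @param n genotypes per species.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return data.frame with `time` and the state columns (`h_i, p_i` for
#'   frequency models, `H_i, P_i` for ecological models).
#' @export
integrate_ode <- function(model, init, params, times, n = 2,
                          rtol = 1e-10, atol = 1e-12) {
  mk <- det_kind(model)
  rhs <- function(t, y, parms) list(ode_rhs(mk$model, y, params, n))
  nm <- if (mk$kind == "frequency") c(paste0("h_", seq_len(n)),
                                      paste0("p_", seq_len(n)))
        else c(paste0("H_", seq_len(n)), paste0("P_", seq_len(n)))
  out <- deSolve::ode(y = setNames(as.numeric(init), nm), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed; last valid state attached",
         call. = FALSE)
  }
  as.data.frame(out)
}

#' Interior coexistence fixed point
#'
#' Frequency models: the uniform point `1/n` per genotype (symmetric
#' matching alleles). Ecological models: `H_i* = d_P / lam`,
#' `P_i* = (b_H - comp_rate * n * H_i*) / lam` per genotype.
#'
#' @param model model name.
#' @param params a [model_params()].
#' @param n genotypes per species.
#' @return state vector of length `2 n` at which [ode_rhs()] vanishes.
#' @export
interior_fixed_point <- function(model, params, n = 2) {
  mk <- det_kind(model)
  fp <- if (mk$kind == "frequency") {
    rep(1 / n, 2 * n)
  } else {
    b <- params_field(params, "b_H", mk$model)
    d <- params_field(params, "d_P", mk$model)
    lam <- params_field(params, "lam", mk$model)
    comp <- if (mk$model == "EcoEvoPlus") params$comp_rate else 0
    H_star <- d / lam
    P_star <- (b - comp * n * H_star) / lam
    if (H_star <= 0 || P_star <= 0) {
      stop(sprintf("no positive interior equilibrium (H* = %g, P* = %g)",
                   H_star, P_star), call. = FALSE)
    }
    c(rep(H_star, n), rep(P_star, n))
  }
  resid <- max(abs(ode_rhs(mk$model, fp, params, n)))
  if (resid > 1e-10 * max(1, max(abs(fp)))) {
    stop(sprintf("fixed-point residual %g exceeds tolerance", resid),
         call. = FALSE)
  }
  fp
}

# Reduced coordinates for frequency models: (h_1..h_{n-1}, p_1..p_{n-1})
# with the last frequency implied. Ecological models use all 2n coordinates.
reduce_rhs <- function(model, params, n) {
  mk <- det_kind(model)
  if (mk$kind == "frequency") {
    function(z) {
      h <- c(z[seq_len(n - 1)], 1 - sum(z[seq_len(n - 1)]))
      p <- c(z[n - 1 + seq_len(n - 1)], 1 - sum(z[n - 1 + seq_len(n - 1)]))
      d <- ode_rhs(mk$model, c(h, p), params, n)
      c(d[seq_len(n - 1)], d[n + seq_len(n - 1)])
    }
  } else {
    function(z) ode_rhs(mk$model, z, params, n)
  }
}

reduce_point <- function(model, fp, n) {
  mk <- det_kind(model)
  if (mk$kind == "frequency") c(fp[seq_len(n - 1)], fp[n + seq_len(n - 1)])
  else fp
}

#' Stability of the interior fixed point
#'
#' Classifies the interior coexistence point as attracting, neutral or
#' repelling. The Jacobian (in reduced coordinates for the frequency
#' models, so the simplex constraints contribute no spurious zero modes) is
#' examined first: a leading eigenvalue real part below `-tol` is
#' attracting, above `tol` repelling. When the linearisation is
#' center-like (leading real part within `tol` of zero -- the case for all
#' the two-population game models, whose host and parasite blocks only
#' couple off-diagonally), the classification falls back on a nonlinear
#' orbit probe: the trajectory from a perturbed start is integrated and the
#' radii at successive Poincare-section crossings are compared. Shrinking
#' radii mean nonlinear attraction (the adjusted replicator's damped
#' oscillations), constant radii mean genuine neutral cycles, growing radii
#' repulsion.
#'
#' @param model model name.
#' @param params a [model_params()].
#' @param n genotypes per species.
#' @param tol eigenvalue real-part tolerance (default 1e-8; the neutral
#'   cases have exactly zero real part analytically, so this is safe at
#'   double precision).
#' @param probe_crossings number of Poincare returns examined by the
#'   nonlinear probe.
#' @param probe_rel_tol relative radius change below which the probe calls
#'   the point neutral.
#' @return an object of class `rq_stability` with the fixed point, the
#'   eigenvalues, the classification, and the method that decided it.
#' @export
classify_fixed_point <- function(model, params, n = 2, tol = 1e-8,
                                 probe_crossings = 4, probe_rel_tol = 1e-3) {
  mk <- det_kind(model)
  fp <- interior_fixed_point(mk$model, params, n)
  f_red <- reduce_rhs(mk$model, params, n)
  z0 <- reduce_point(mk$model, fp, n)
  J <- pracma::jacobian(f_red, z0)
  ev <- eigen(J, only.values = TRUE)$values
  max_re <- max(Re(ev))
  scale_tol <- tol * max(1, max(Mod(ev)))

  if (max_re < -scale_tol) {
    cls <- "attracting"; method <- "jacobian"
  } else if (max_re > scale_tol) {
    cls <- "repelling"; method <- "jacobian"
  } else {
    probe <- orbit_probe(mk, params, n, fp, probe_crossings)
    method <- "orbit-probe"
    cls <- if (is.null(probe)) {
      "inconclusive"
    } else if (probe$ratio < 1 - probe_rel_tol) {
      "attracting"
    } else if (probe$ratio > 1 + probe_rel_tol) {
      "repelling"
    } else "neutral"
  }
  structure(list(model = mk$model, fixed_point = fp, eigenvalues = ev,
                 max_real_part = max_re, classification = cls,
                 method = method, tol = tol),
            class = "rq_stability")
}

#' @exportS3Method base::print
print.rq_stability <- function(x, ...) {
  cat(sprintf("<rq_stability> %s: %s (by %s)\n", x$model, x$classification,
              x$method))
  cat(sprintf("  max Re(eigenvalue) = %.3e\n", x$max_real_part))
  invisible(x)
}

# Integrate from a perturbed start and measure the radius (deviation of the
# second species' first coordinate from the fixed point) at successive
# upward crossings of the section y1 = fp1. Returns the last/first radius
# ratio per crossing interval, annualised over the crossings examined.
orbit_probe <- function(mk, params, n, fp, crossings) {
  i_sec <- 1L                       # section coordinate: h_1 or H_1
  i_rad <- n + 1L                   # radius coordinate: p_1 or P_1
  # perturb the genotype-difference (frequency) mode only: the total-size
  # mode of the competition models is linearly damped and would contaminate
  # the radius sequence with its fast transient
  y0 <- fp
  if (mk$kind == "frequency") {
    delta <- min(0.2, fp[1] / 2)
    y0[1] <- fp[1] + delta
    y0[2:n] <- (1 - y0[1]) / (n - 1)
  } else {
    delta <- 0.3 * fp[1]
    y0[1] <- fp[1] + delta
    y0[2:n] <- fp[2:n] - delta / (n - 1)
  }
  # crude period estimate from the linearisation frequency, then integrate
  f_red <- reduce_rhs(mk$model, params, n)
  J <- pracma::jacobian(f_red, reduce_point(mk$model, fp, n))
  omega <- max(abs(Im(eigen(J, only.values = TRUE)$values)))
  if (!is.finite(omega) || omega <= 0) return(NULL)
  horizon <- 2 * pi / omega * (crossings + 2)
  times <- seq(0, horizon, length.out = max(2000, 400 * (crossings + 2)))
  tr <- integrate_ode(mk$model, y0, params, times, n)
  y1 <- tr[[1 + i_sec]]; y2 <- tr[[1 + i_rad]]
  s <- y1 - fp[i_sec]
  up <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (length(up) < 2) return(NULL)
  up <- up[seq_len(min(length(up), crossings + 1))]
  # linear interpolation of the radius at each crossing
  radii <- vapply(up, function(k) {
    w <- s[k] / (s[k] - s[k + 1])
    abs((1 - w) * y2[k] + w * y2[k + 1] - fp[i_rad])
  }, numeric(1))
  list(radii = radii, ratio = radii[length(radii)] / radii[1])
}

#' First Poincare return of a deterministic orbit
#'
#' Integrates from `init` and reports the state and time of the first
#' return to the section where the first coordinate crosses its initial
#' value in the initial direction -- one full oscillation period. Used to
#' test orbit closure (neutral cycles return to the start; damped
#' oscillations return strictly inside).
#'
#' @param model model name.
#' @param init initial state vector.
#' @param params a [model_params()].
#' @param n genotypes per species.
#' @param t_max integration horizon to search for the return.
#' @return list with `period`, `state` at the return, and `distance` from
#'   the initial state, or `NULL` if no return is found before `t_max`.
#' @export
poincare_return <- function(model, init, params, n = 2, t_max = 200) {
  times <- seq(0, t_max, length.out = 20001)
  tr <- integrate_ode(model, init, params, times, n)
  y <- as.matrix(tr[, -1])
  # section: the first coordinate whose derivative is nonzero at the start
  # (a start at a turning point of coordinate 1 would never be detected)
  rhs0 <- ode_rhs(model, init, params, n)
  i_sec <- which(abs(rhs0) > 1e-12)[1]
  if (is.na(i_sec)) return(NULL)
  s <- y[, i_sec] - init[i_sec]
  d0 <- sign(rhs0[i_sec])
  cross <- if (d0 > 0) which(s[-length(s)] < 0 & s[-1] >= 0) else
    which(s[-length(s)] > 0 & s[-1] <= 0)
  cross <- cross[cross > 2]
  if (!length(cross)) return(NULL)
  k <- cross[1]
  w <- s[k] / (s[k] - s[k + 1])
  state <- (1 - w) * y[k, ] + w * y[k + 1, ]
  period <- (1 - w) * tr$time[k] + w * tr$time[k + 1]
  list(period = period, state = state,
       distance = sqrt(sum((state - init)^2)))
}
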