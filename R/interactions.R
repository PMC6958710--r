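#' Matching-allele interaction matrix
#'
#' Builds the n-by-n matching-allele payoff matrix with `alpha` on the
#' diagonal (a parasite genotype matching "its" host genotype) and `beta`
#' everywhere else. `alpha` is the fitness gain of a matching parasite and,
#' under the zero-sum convention, the fitness loss of the matched host;
#' `beta` is the corresponding effect for mismatching pairs.
#'
#' @param n number of genotypes per species (>= 2).
#' @param alpha fitness effect of a genotype match (default 1).
#' @param beta fitness effect of a mismatch (default 0). Must satisfy
#'   `alpha >= beta` so that the maximal payoff difference `alpha - beta`
#'   used to normalise the pairwise-comparison process is non-negative.
#' @return an `n x n` numeric matrix.
#' @examples
#' matching_matrix(2)          # diag(2)
#' matching_matrix(5, 1, 0)    # identity-patterned 5x5
#' @export
matching_matrix <- function(n, alpha = 1, beta = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (alpha < beta) {
    stop("`alpha` must be >= `beta` (matching cannot pay less than mismatching)",
         call. = FALSE)
  }
  A <- matrix(beta, n, n)
  diag(A) <- alpha
  A
}

ma_alpha <- function(A) A[1L, 1L]
ma_beta  <- function(A) if (ncol(A) > 1L) A[1L, 2L] else A[1L, 1L]

#' Relative genotype frequencies from integer counts
#'
#' Frequencies are always derived from counts, never stored independently.
#'
#' @param counts non-negative genotype counts with positive total.
#' @return numeric vector summing to 1.
#' @export
rel_freq <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- sum(counts)
  if (N <= 0) stop("total count must be positive", call. = FALSE)
  counts / N
}

check_freq <- function(x, n, what = "frequency vector") {
  if (length(x) != n) {
    stop(sprintf("%s has length %d, expected %d", what, length(x), n),
         call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12) || abs(sum(x) - 1) > 1e-12) {
    stop(sprintf("%s must lie in [0,1] and sum to 1 (tolerance 1e-12)", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Parasite payoffs against a host composition
#'
#' The payoff of parasite genotype i is the expected fitness effect of
#' attacking a host drawn from frequencies `h`:
#' `pi_P[i] = sum_j A[i, j] h[j]` (so `alpha * h_i + beta * (1 - h_i)` for
#' the matching-allele matrix). A common host genotype makes its matching
#' parasite profitable -- the engine of negative frequency-dependent
#' selection.
#'
#' @param h host genotype frequencies (sums to 1).
#' @param A interaction matrix from [matching_matrix()].
#' @return payoff vector, entries within `[min(alpha, beta), max(alpha, beta)]`.
#' @export
parasite_payoffs <- function(h, A) {
  check_freq(h, nrow(A), "host frequency vector")
  as.numeric(A %*% h)
}

#' Host payoffs against a parasite composition
#'
#' Hosts lose what matching parasites gain (zero-sum coupling). To keep
#' payoffs -- and hence fitnesses -- non-negative, the host payoff is the
#' complement `pi_H[i] = (alpha + beta) - sum_j A[i, j] p[j]`: a host
#' genotype targeted by common matching parasites has a low payoff. For the
#' canonical `alpha = 1, beta = 0, n = 2` case this reduces to
#' `pi_H[1] = p[2]`, the frequency of parasites that cannot infect host 1.
#'
#' @param p parasite genotype frequencies (sums to 1).
#' @param A interaction matrix from [matching_matrix()].
#' @return payoff vector.
#' @export
host_payoffs <- function(p, A) {
  check_freq(p, nrow(A), "parasite frequency vector")
  (ma_alpha(A) + ma_beta(A)) - as.numeric(A %*% p)
}

#' Fitness from payoff under a selection intensity
#'
#' `f = 1 - w + w * pi`: with `w = 0` selection is neutral (all fitnesses 1),
#' with `w = 1` fitness equals the game payoff.
#'
#' @param pi payoff vector.
#' @param w selection intensity in `[0, 1]`.
#' @return fitness vector.
#' @export
fitness_from_payoff <- function(pi, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("selection intensity `w` must be a single value in [0, 1]",
         call. = FALSE)
  }
  1 - w + w * pi
}
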