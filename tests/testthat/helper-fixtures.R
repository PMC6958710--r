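# Shared fixtures: the reference parameter sets and small helpers.

fig1_params <- function() {
  model_params(w_H = 0.5, w_P = 1, b_H = 6, d_P = 1, K = 100, lam0 = 4)
}

fig4_params <- function() {
  model_params(b_H = 6, d_P = 1, K = 600, lam0 = 10,
               mut_H = 0.005, mut_P = 0.01)
}

# random frequency vector of length n (uses the current RNG state)
rand_freq <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# random small integer population state
rand_state <- function(n, max_count = 40) {
  population_state(sample.int(max_count, n, replace = TRUE),
                   sample.int(max_count, n, replace = TRUE))
}

# Dense brute-force mean first-loss times for a discrete-time process over
# the FULL (N_H+1) x (N_P+1) state space, built state-by-state from
# dt_step_distribution (independent of the sparse solver's vectorised
# kernel and row-major indexing).
brute_force_dt_times <- function(model, A, w_H, w_P, N_H, N_P) {
  states <- expand.grid(H1 = 0:N_H, P1 = 0:N_P)
  S <- nrow(states)
  absorbing <- states$H1 %in% c(0, N_H) | states$P1 %in% c(0, N_P)
  K <- matrix(0, S, S)
  for (s in seq_len(S)) {
    if (absorbing[s]) { K[s, s] <- 1; next }
    st <- population_state(c(states$H1[s], N_H - states$H1[s]),
                           c(states$P1[s], N_P - states$P1[s]))
    tr <- dt_step_distribution(model, st, A, w_H, w_P)
    for (dh in -1:1) for (dp in -1:1) {
      pr <- tr$host[[c("down", "stay", "up")[dh + 2]]] *
        tr$parasite[[c("down", "stay", "up")[dp + 2]]]
      j <- which(states$H1 == states$H1[s] + dh &
                   states$P1 == states$P1[s] + dp)
      K[s, j] <- K[s, j] + pr
    }
  }
  Q <- K[!absorbing, !absorbing, drop = FALSE]
  tau <- rep(0, S)
  tau[!absorbing] <- solve(diag(sum(!absorbing)) - Q, rep(1, sum(!absorbing)))
  matrix(tau, N_H + 1, N_P + 1, dimnames = list(H1 = 0:N_H, P1 = 0:N_P))
}
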