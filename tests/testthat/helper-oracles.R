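# Independent oracles and small builders shared by the tests.

# brute-force occupancy propagation: plain repeated vector-matrix products,
# kept deliberately separate from the package's trace engine
brute_force_occupancy <- function(matrices, init) {
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]), function(i) matrices[, , i])
  }
  occ <- matrix(NA_real_, length(matrices) + 1, length(init))
  occ[1, ] <- init
  v <- init
  for (t in seq_along(matrices)) {
    v <- as.numeric(v %*% matrices[[t]])
    occ[t + 1, ] <- v
  }
  occ
}

# random row-stochastic matrix via normalized uniform rows
random_stochastic_matrix <- function(n = 6) {
  m <- matrix(stats::runif(n * n), n, n)
  m / rowSums(m)
}

# analytic half-cycle-corrected discounted life-years for a two-state
# {alive, dead} chain with constant death probability q over H cycles:
# sum_t [(s^(t-1) + s^t)/2] v^t with s = 1-q, v = 1/(1+r)
analytic_hcc_life_years <- function(q, r, horizon) {
  s <- 1 - q
  v <- 1 / (1 + r)
  sv <- s * v
  (1 + s) / 2 * v * if (abs(sv - 1) < 1e-15) horizon else
    (1 - sv^horizon) / (1 - sv)
}

# two-state {A, D} trace through the package engine
two_state_trace <- function(q, horizon, init = 1) {
  M <- matrix(c(1 - q, q, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "D"), c("A", "D")))
  markov_trace(rep(list(M), horizon), c(A = init, D = 0), absorbing = "D")
}

# a small random-but-valid configuration derived from the packaged default
random_valid_config <- function(seed, cfg = default_config()) {
  withr::with_seed(seed, {
    cfg$transitions$hd_pd <- stats::runif(1, 0, 0.05)
    cfg$transitions$hd_tx <- stats::runif(1, 0, 0.10)
    cfg$transitions$pd_hd <- stats::runif(1, 0, 0.10)
    cfg$transitions$pd_tx <- stats::runif(1, 0, 0.10)
    cfg$mortality$q0 <- stats::runif(1, 0.005, 0.05)
    cfg$mortality$growth <- stats::runif(1, 0, 0.06)
    occ <- stats::runif(5)
    occ <- occ / sum(occ)
    cfg$model$initial_occupancy <-
      as.list(c(stats::setNames(occ, rrt_alive_states()), D = 0))
  })
  cfg
}
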