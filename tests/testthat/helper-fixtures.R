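# shared fixture builders and brute-force oracles

tiny_snapshot <- function(mat, time = 0, species = NULL) {
  if (is.null(species)) species <- paste0("s", seq_len(ncol(mat)))
  snapshot(mat, time, species)
}

random_snapshot <- function(n_cells, species, time = 0, seed = 1,
                            lo = 10, hi = 500) {
  set.seed(seed)
  m <- matrix(runif(n_cells * length(species), lo, hi), n_cells)
  snapshot(m, time, species)
}

random_spd <- function(k, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(0.5, k)
}

# identity-covariance stand-in for compute_IM tests
identity_cov <- function(k) {
  list(subset = seq_len(k), mu = rep(0, k), J = diag(k), J_inv = diag(k),
       J_inv_sqrt = diag(k), ridge_used = 0)
}

# all permutations of 1..n as a matrix (rows = permutations)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(n, nrow(sub), n)
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# exhaustive minimum of E over all pairings, for small N
brute_force_min_E <- function(I1, I2) {
  P <- all_perms(length(I1))
  costs <- numeric(nrow(P))
  for (j in seq_len(ncol(P)))
    costs <- costs + (I1[j] - I2[P[, j]])^2
  min(costs)
}

# exhaustive linear assignment minimum for a square cost matrix
brute_force_lap <- function(C) {
  n <- nrow(C)
  P <- all_perms(n)
  costs <- numeric(nrow(P))
  for (i in seq_len(n))
    costs <- costs + C[i + n * (P[, i] - 1L)]
  min(costs)
}

# tracked linear test system shared by several files
linear_fixture <- function(n = 6, n_cells = 400, times = c(0, 5), seed = 42) {
  net <- make_linear_network(n, conservative = TRUE, seed = seed)
  sim <- generate_snapshot_series(net, n_cells = n_cells, times = times,
                                  seed = seed + 1)
  list(net = net, sim = sim,
       s1 = sim$series$snapshots[[1]], s2 = sim$series$snapshots[[2]])
}
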