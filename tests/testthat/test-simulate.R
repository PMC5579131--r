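test_that("conservative linear networks have zero column sums and are reproducible", {
  net <- make_linear_network(2, density = 1, conservative = TRUE, seed = 1)
  expect_equal(colSums(net$M), c(0, 0), tolerance = 1e-12)
  expect_true(all(net$M[row(net$M) != col(net$M)] >= 0))
  n14 <- make_linear_network(14, conservative = TRUE, seed = 3)
  expect_lt(max(abs(colSums(n14$M))), 1e-12)
  expect_identical(make_linear_network(14, seed = 3)$M, n14$M)
  open <- make_linear_network(5, conservative = FALSE, seed = 2)
  expect_true(all(colSums(open$M) < 0))
})

test_that("matrix-exponential propagation preserves totals and limits", {
  net <- make_linear_network(6, conservative = TRUE, seed = 8)
  set.seed(1); X <- matrix(runif(60, 50, 150), 10)
  expect_identical(propagate_linear(X, net, 0), X)
  X2 <- propagate_linear(X, net, 9)
  expect_equal(rowSums(X2), rowSums(X), tolerance = 1e-10)
  # two-state pure conversion decays to the absorbing species
  M <- matrix(c(-1, 1, 0, 0), 2)
  out <- propagate_linear(matrix(c(1, 0), 1), M, 60)
  expect_equal(as.numeric(out), c(0, 1), tolerance = 1e-12)
})

test_that("reaction networks validate stoichiometry and conservation claims", {
  expect_error(reaction_network("A", matrix(3, 1, 1), matrix(0, 1, 1), 1),
               "capped at 2")
  expect_error(reaction_network(c("A", "B"), matrix(c(1, 0), 1),
                                matrix(c(0, 0), 1), 1,
                                conservations = list(tot = c("A", "B"))),
               "violated")
  expect_error(reaction_network(c("A", "B"), matrix(c(1, 0), 1),
                                matrix(c(0, 1), 1), -1), "non-negative")
  net <- reaction_network(c("A", "B"), matrix(c(1, 0), 1),
                          matrix(c(0, 1), 1), 2,
                          conservations = list(tot = c("A", "B")))
  expect_s3_class(net, "reaction_network")
})

test_that("ODE trajectories agree with the matrix exponential for linear nets", {
  lm <- make_linear_network(5, conservative = TRUE, seed = 9)
  net <- as_reaction_network(lm)
  set.seed(2); x0 <- matrix(runif(25, 100, 300), 5)
  tr <- ode_trajectories(net, x0, times = c(0, 2, 5))
  expect_equal(tr[, , 1], x0, ignore_attr = TRUE)
  for (tt in c(2, 5)) {
    exact <- propagate_linear(x0, lm, tt)
    expect_equal(tr[, , as.character(tt)], exact, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # zero rates: constant trajectories
  frozen <- reaction_network(c("A", "B"), matrix(c(1, 0), 1),
                             matrix(c(0, 1), 1), 0)
  trf <- ode_trajectories(frozen, matrix(c(10, 20), 1), c(0, 10))
  expect_equal(trf[1, , 2], c(A = 10, B = 20))
})

test_that("declared conservation groups hold along ODE and SSA trajectories", {
  net <- build_ras_network("bistable", check = FALSE)
  x0 <- sample_initial_conditions(net$init_mean, net$init_cov, 20, seed = 3,
                                  integer = TRUE)
  tr <- ode_trajectories(net, x0, times = c(0, 50, 200))
  st <- ssa_trajectories(net, x0, times = c(0, 50, 200), seed = 4)
  for (grp in net$conservations) {
    gi <- match(grp, net$species)
    for (arr in list(tr, st)) {
      tot <- apply(arr[, gi, , drop = FALSE], c(1, 3), sum)
      expect_lt(max(abs(tot - tot[, 1]) / pmax(tot[, 1], 1)), 1e-6)
    }
  }
})

test_that("SSA reproduces the closed-form death process mean", {
  net <- reaction_network("A", matrix(1, 1, 1), matrix(0, 1, 1), rates = 0.2)
  x0 <- matrix(1000, 400, 1)
  tr <- ssa_trajectories(net, x0, times = c(0, 5), seed = 6)
  expected <- 1000 * exp(-0.2 * 5)
  sd_mean <- sqrt(1000 * exp(-1) * (1 - exp(-1)) / 400)
  expect_lt(abs(mean(tr[, 1, 2]) - expected), 3 * sd_mean)
  # empty reaction set stays frozen
  frozen <- reaction_network("A", matrix(0L, 0, 1), matrix(0L, 0, 1),
                             numeric(0))
  trf <- ssa_trajectories(frozen, matrix(5, 3, 1), c(0, 10), seed = 1)
  expect_equal(trf[, 1, 2], rep(5, 3))
})

test_that("SSA ensemble means track the ODE solution for linear kinetics", {
  lm <- make_linear_network(4, conservative = TRUE, seed = 5,
                            rate_range = c(0.05, 0.3))
  net <- as_reaction_network(lm)
  x0 <- matrix(rep(c(200, 150, 100, 50), each = 800), 800)
  tr <- ssa_trajectories(net, x0, times = c(0, 4), seed = 7)
  exact <- propagate_linear(x0[1, , drop = FALSE], lm, 4)
  for (j in 1:4) {
    se <- stats::sd(tr[, j, 2]) / sqrt(800)
    expect_lt(abs(mean(tr[, j, 2]) - exact[1, j]), 3 * se + 1e-9)
  }
})

test_that("initial ensembles honour mean, covariance, seed and clipping", {
  x <- sample_initial_conditions(c(10, 20), diag(0, 2), 50, seed = 1)
  expect_equal(unname(x), matrix(rep(c(10, 20), each = 50), 50),
               ignore_attr = TRUE)
  a <- sample_initial_conditions(c(100, 50), diag(c(25, 16)), 30, seed = 2)
  b <- sample_initial_conditions(c(100, 50), diag(c(25, 16)), 30, seed = 2)
  expect_identical(a, b)
  set.seed(3)
  big <- sample_initial_conditions(c(100, 200), diag(c(100, 400)), 2e4,
                                   seed = 4)
  expect_lt(max(abs(colMeans(big) - c(100, 200)) / c(10, 20) * sqrt(2e4)), 3)
  expect_warning(sample_initial_conditions(1, matrix(100), 200, seed = 5),
                 "clipped")
  i <- sample_initial_conditions(c(7.3, 2.9), diag(0, 2), 5, seed = 1,
                                 integer = TRUE)
  expect_true(all(i == round(i)))
})

test_that("tracked series carry identity ground truth; batch series are independent", {
  net <- make_linear_network(5, conservative = TRUE, seed = 11)
  tracked <- generate_snapshot_series(net, n_cells = 60, times = c(0, 2, 4),
                                      seed = 8)
  expect_identical(length(tracked$series), 3L)
  expect_identical(tracked$ground_truth[[1]]$partner_index, 1:60)
  expect_equal(tracked$ground_truth[[1]]$partner_abundances,
               tracked$series$snapshots[[2]]$abundances, ignore_attr = TRUE)

  batch <- generate_snapshot_series(net, n_cells = 60, times = c(0, 2),
                                    mode = "batch", seed = 8)
  expect_false(isTRUE(all.equal(batch$series$snapshots[[1]]$abundances,
                                tracked$series$snapshots[[1]]$abundances)))
  # ground truth for a batch interval is the forward-propagated t1 batch
  exact <- propagate_linear(batch$series$snapshots[[1]]$abundances, net, 2)
  expect_equal(batch$ground_truth[[1]]$partner_abundances, exact,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("measured-species projection drops snapshot columns but keeps full truth", {
  net <- build_ras_network("bistable", check = FALSE)
  rec <- c("RasGTP", "RasGDP", "SOS")
  sim <- generate_snapshot_series(net, n_cells = 15, times = c(0, 30),
                                  mode = "batch", method = "ssa",
                                  record = rec, seed = 2)
  expect_identical(sim$series$snapshots[[1]]$species, rec)
  expect_identical(ncol(sim$ground_truth[[1]]$partner_abundances), 14L)
})

test_that("simulate() dispatches on a network with its default ensemble", {
  net <- build_ras_network("bistable", check = FALSE)
  tr <- simulate(net, nsim = 5, seed = 1, times = c(0, 10), method = "ode")
  expect_identical(dim(tr), c(5L, 14L, 2L))
})
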