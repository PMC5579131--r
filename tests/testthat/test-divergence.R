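test_that("common histograms share a grid and normalise to 1", {
  h <- common_histograms(c(1, 2, 3), c(1, 2, 3), 1)
  expect_identical(h$p1, h$p2)
  expect_equal(sum(h$p1), 1, tolerance = 1e-12)
  hd <- common_histograms(c(0, 0), c(10, 10), 1)
  expect_equal(sum(hd$p1 * hd$p2), 0)    # disjoint support
  expect_error(common_histograms(0:1, c(0, 1e9), 1e-3), "larger bin width")
  expect_error(common_histograms(numeric(0), 1, 1), "non-empty")
  expect_error(common_histograms(1, 2, 0), "positive")
})

test_that("jsd matches hand-evaluated two-bin case and the analytic extremes", {
  # masses (1,0) vs (0.5,0.5): 0.5*ln(4/3) + 0.5*(0.5*ln(2/3)+0.5*ln 2)
  expected <- 0.5 * (log(1 / 0.75)) + 0.5 * (0.5 * log(0.5 / 0.75) +
                                               0.5 * log(0.5 / 0.25))
  got <- jsd(c(0.2, 0.2), c(0.2, 1.5), 1)   # two bins: (1,0) vs (.5,.5)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(expected, 0.2157, tolerance = 5e-4)
  a50 <- rnorm(50)
  expect_identical(jsd(a50, numeric(50), 1), jsd(numeric(50), a50, 1))
  expect_equal(jsd(c(0, 0), c(10, 10), 1), log(2))
  expect_equal(jsd(c(5, 6, 7), c(5, 6, 7), 1), 0)
})

test_that("jsd is bounded, symmetric and zero on identical samples (property)", {
  set.seed(101)
  for (i in 1:25) {
    a <- rnorm(200, sd = runif(1, 0.5, 5)) + runif(1, -10, 10)
    b <- rnorm(200, sd = runif(1, 0.5, 5)) + runif(1, -10, 10)
    w <- runif(1, 0.1, 3)
    d <- jsd(a, b, w)
    expect_gte(d, 0); expect_lte(d, log(2))
    expect_identical(d, jsd(b, a, w))
    expect_identical(jsd(a, a, w), 0)
  }
})

test_that("matched Gaussians diverge as the mean gap grows", {
  set.seed(55)
  a <- rnorm(1e4)
  base <- jsd(a, rnorm(1e4), 0.1)
  expect_lt(base, 0.01)
  gaps <- c(0.5, 1, 2, 4)
  ds <- vapply(gaps, function(g) jsd(a, rnorm(1e4) + g, 0.1), numeric(1))
  expect_true(all(diff(c(base, ds)) > 0))
})

test_that("I_T bin width is the subset cardinality", {
  expect_identical(bin_width_IT(1:3), 3L)
  expect_identical(bin_width_IT(5), 1L)
  expect_identical(bin_width_IT(1:14), 14L)
  expect_error(bin_width_IT(integer(0)), "non-empty")
})

test_that("I_M bin width propagates one-molecule uncertainty per cell", {
  # single species, both cells at 4, identity covariance: dI = 4/4 = 1
  s <- tiny_snapshot(matrix(c(4, 4), 2, 1), 0)
  cov1 <- identity_cov(1)
  im1 <- compute_IM(s, 1, cov = cov1)
  w <- bin_width_IM(s, s, cov1, cov1, 1, im1 = im1, im2 = im1)
  expect_equal(w, 1)

  # degenerate range: the floor applies
  expect_gt(w, 0)

  # brute-force re-evaluation on random data
  sa <- random_snapshot(100, letters[1:3], time = 0, seed = 2)
  sb <- random_snapshot(100, letters[1:3], time = 1, seed = 3)
  ca <- estimate_moments(sa); cb <- estimate_moments(sb)
  ia <- compute_IM(sa, cov = ca); ib <- compute_IM(sb, cov = cb)
  w <- bin_width_IM(sa, sb, ca, cb, 1:3)
  per_cell <- function(s, cm, iv) {
    vapply(seq_len(nrow(s$abundances)), function(a) {
      x <- s$abundances[a, ]
      abs(sum(cm$J_inv %*% x)) / iv$values[a]
    }, numeric(1))
  }
  brute <- min(c(per_cell(sa, ca, ia), per_cell(sb, cb, ib)))
  floorv <- diff(range(ia$values, ib$values)) / 1e5
  expect_equal(w, max(brute, floorv), tolerance = 1e-12)
})

test_that("species_jsd orders drifts and detects stasis", {
  s0 <- random_snapshot(2000, c("a", "b"), seed = 4, lo = 100, hi = 200)
  expect_identical(species_jsd(s0, s0, "a"), 0)
  shift_by <- function(d) snapshot(s0$abundances + d, 1, s0$species)
  expect_equal(species_jsd(s0, shift_by(1000), "a"), log(2))
  expect_lt(species_jsd(s0, shift_by(5), "b"),
            species_jsd(s0, shift_by(60), "b"))
})

test_that("steady_state_check flags a stationary regime and respects thresholds", {
  s0 <- random_snapshot(500, c("a", "b"), time = 0, seed = 6)
  s1 <- snapshot(s0$abundances[sample(500), ], 1, s0$species)
  ser <- snapshot_series(list(s0, s1))
  chk <- steady_state_check(ser, threshold = 0.05)
  expect_true(chk$stationary)
  # strongly relaxing kinetics: nothing flagged
  s2 <- snapshot(s0$abundances * 3 + 500, 1, s0$species)
  chk2 <- steady_state_check(snapshot_series(list(s0, s2)), threshold = 0.05)
  expect_false(any(chk2$flagged))
  chk3 <- steady_state_check(ser, threshold = 0)
  expect_false(any(chk3$flagged))
})
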