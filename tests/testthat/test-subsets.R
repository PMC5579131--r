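test_that("subset counting matches the closed form", {
  expect_identical(count_subsets(14), 16369L)
  expect_identical(count_subsets(4), 11L)
  expect_identical(count_subsets(2), 1L)
  expect_error(count_subsets(1), ">= 2")
})

test_that("enumeration is lexicographic within classes with stable addresses", {
  subs <- enumerate_subsets(3, 2, 3)
  expect_identical(subs[[1]], c(1L, 2L))
  expect_identical(subs[[2]], c(1L, 3L))
  expect_identical(subs[[3]], c(2L, 3L))
  expect_identical(subs[[4]], c(1L, 2L, 3L))
  expect_identical(attr(subs, "k"), c(2L, 2L, 2L, 3L))
  expect_identical(attr(subs, "m"), c(1L, 2L, 3L, 1L))

  k4 <- enumerate_subsets(14, 4, 4)
  expect_identical(length(k4), 1001L)

  for (n in c(4, 7, 10)) {
    e <- enumerate_subsets(n)
    expect_identical(length(e), count_subsets(n))
    expect_identical(as.vector(table(attr(e, "k"))),
                     as.integer(choose(n, 2:n)))
  }
  expect_error(enumerate_subsets(3, 1, 3), "k_min")
})

test_that("score_subset flags a conservation subset as invariant for I_T", {
  fx <- linear_fixture(n = 6, n_cells = 600, times = c(0, 4), seed = 3)
  ss <- score_subset(fx$s1, fx$s2, 1:6)
  expect_identical(ss$jsd_IT, 0)
  expect_identical(ss$jsd_IM, 0)
  expect_true(ss$slow_IT)      # member species do change
  expect_true(ss$slow_IM)
  expect_identical(ss$status_IT, "invariant")
  # partial subsets are not conserved here
  ss2 <- score_subset(fx$s1, fx$s2, 1:3)
  expect_gt(ss2$jsd_IT, 0)
})

test_that("score_subset is invariant to cell-row permutations", {
  fx <- linear_fixture(n = 5, n_cells = 300, times = c(0, 2), seed = 13)
  set.seed(1); p <- sample(300)
  s1p <- snapshot(fx$s1$abundances[p, ], fx$s1$time, fx$s1$species)
  a <- score_subset(fx$s1, fx$s2, c(1, 3, 5))
  b <- score_subset(s1p, fx$s2, c(1, 3, 5))
  expect_equal(a$jsd_IT, b$jsd_IT, tolerance = 1e-12)
  expect_equal(a$jsd_IM, b$jsd_IM, tolerance = 1e-12)
})

test_that("scan_subsets agrees with score_subset on every class", {
  fx <- linear_fixture(n = 5, n_cells = 400, times = c(0, 3), seed = 21)
  scan <- scan_subsets(fx$s1, fx$s2)
  for (i in sample(nrow(scan$table), 8)) {
    ss <- score_subset(fx$s1, fx$s2, scan$subsets[[i]])
    expect_equal(scan$table$jsd_IT[i], ss$jsd_IT, tolerance = 1e-12)
    expect_equal(scan$table$jsd_IM[i], ss$jsd_IM, tolerance = 1e-9)
    expect_equal(scan$table$jsd_species_min[i], min(ss$species_jsds),
                 tolerance = 1e-12)
  }
  expect_identical(nrow(scan$table), count_subsets(5))
})

test_that("rank_subsets picks per-class minima with lexicographic ties and order independence", {
  fx <- linear_fixture(n = 5, n_cells = 400, times = c(0, 3), seed = 21)
  scan <- scan_subsets(fx$s1, fx$s2)
  rk <- rank_subsets(scan, "IM")
  expect_identical(rk$k, 2:5)
  expect_identical(rk$n_subsets, as.integer(choose(5, 2:5)))
  # single-subset class (k = n) is trivially the winner
  expect_identical(rk$best_subset[rk$k == 5],
                   paste(fx$s1$species, collapse = "+"))
  # winner really is the class minimum
  for (k in 2:5) {
    cls <- scan$table[scan$table$k == k, ]
    expect_equal(rk$min_jsd[rk$k == k], min(cls$jsd_IM))
  }
  # full-set subset: both invariants exactly invariant
  expect_identical(rk$min_jsd[rk$k == 5], 0)
})

test_that("the scan warns when every species distribution is stationary", {
  s0 <- random_snapshot(400, letters[1:3], time = 0, seed = 2)
  s1 <- snapshot(s0$abundances[sample(400), ], 1, s0$species)
  expect_warning(scan_subsets(s0, s1), "stationary")
})

test_that("exhaustive enumeration refuses oversized panels", {
  s <- random_snapshot(30, paste0("s", 1:21), seed = 1)
  s2 <- snapshot(s$abundances, 1, s$species)
  expect_error(scan_subsets(s, s2), "capped at 20")
})
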