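mk_inv <- function(values, time = 0) {
  snapmatch:::new_invariant_values("IT", 1:2, time, values)
}

test_that("rank matching pairs equal ranks and recovers permutations", {
  m <- match_by_invariant(mk_inv(c(1, 3, 2)), mk_inv(c(30, 10, 20), 1))
  # value 1 <-> 10, 2 <-> 20, 3 <-> 30
  expect_identical(m$perm, c(2L, 1L, 3L))
  expect_equal(m$cost_E, (1 - 10)^2 + (3 - 30)^2 + (2 - 20)^2)

  set.seed(2)
  v <- runif(50)
  p <- sample(50)
  m2 <- match_by_invariant(mk_inv(v), mk_inv(v[p], 1))
  expect_equal(m2$cost_E, 0)
  expect_identical(v[1:50], v[p][m2$perm])

  expect_error(match_by_invariant(mk_inv(1:3), mk_inv(1:4, 1)),
               "downsample_to_match")
})

test_that("sort-based matching attains the exhaustive minimum of E", {
  set.seed(9)
  for (trial in 1:100) {
    n <- sample(2:8, 1)
    I1 <- runif(n, 0, 10); I2 <- runif(n, 0, 10)
    m <- match_by_invariant(mk_inv(I1), mk_inv(I2, 1))
    expect_equal(m$cost_E, brute_force_min_E(I1, I2), tolerance = 1e-12)
  }
})

test_that("tied invariant values pair in original-index order at unchanged cost", {
  m <- match_by_invariant(mk_inv(c(2, 2, 1)), mk_inv(c(2, 1, 2), 1))
  expect_identical(m$perm[3], 2L)          # unique low value
  expect_identical(m$perm[1:2], c(1L, 3L)) # ties keep original order
})

test_that("exact Euclidean assignment equals brute force on small clouds", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(2:7, 1)
    s1 <- tiny_snapshot(matrix(runif(n * 2, 0, 100), n), 0)
    s2 <- tiny_snapshot(matrix(runif(n * 2, 0, 100), n), 1)
    m <- match_euclidean(s1, s2, mode = "exact")
    C <- snapmatch:::sq_dist_matrix(s1$abundances, s2$abundances)
    expect_equal(m$cost_E, brute_force_lap(C), tolerance = 1e-9)
  }
})

test_that("identical point clouds match identically at zero cost", {
  s <- random_snapshot(40, c("a", "b"), seed = 7)
  s2 <- snapshot(s$abundances, 1, s$species)
  m <- match_euclidean(s, s2, mode = "exact")
  expect_identical(m$perm, 1:40)
  expect_equal(m$cost_E, 0)
})

test_that("in one dimension exact assignment reduces to rank matching", {
  set.seed(4)
  s1 <- tiny_snapshot(matrix(runif(30, 0, 100), 30, 1), 0)
  s2 <- tiny_snapshot(matrix(runif(30, 0, 100), 30, 1), 1)
  me <- match_euclidean(s1, s2, mode = "exact")
  mr <- match_by_invariant(compute_IT(s1, 1), compute_IT(s2, 1))
  expect_equal(me$cost_E, mr$cost_E, tolerance = 1e-9)
})

test_that("greedy Euclidean is a valid seeded bijection", {
  s1 <- random_snapshot(60, c("a", "b", "c"), seed = 11)
  s2 <- random_snapshot(60, c("a", "b", "c"), time = 1, seed = 12)
  g1 <- match_euclidean(s1, s2, mode = "greedy", seed = 5)
  g2 <- match_euclidean(s1, s2, mode = "greedy", seed = 5)
  expect_identical(g1$perm, g2$perm)
  expect_identical(sort(g1$perm), 1:60)
  ex <- match_euclidean(s1, s2, mode = "exact")
  expect_gte(g1$cost_E, ex$cost_E - 1e-9)
  expect_error(match_euclidean(s1, s2, mode = "exact", max_exact_n = 10),
               "refused")
})

test_that("random matching is uniform over permutations and reproducible", {
  expect_identical(match_random(1)$perm, 1L)
  expect_identical(match_random(20, seed = 3)$perm,
                   match_random(20, seed = 3)$perm)
  counts <- new.env()
  set.seed(0)
  draws <- vapply(1:6000, function(i)
    paste(match_random(3, seed = i)$perm, collapse = ""), character(1))
  tab <- table(draws)
  expect_identical(length(tab), 6L)
  # each of the 6 permutations within 3 sigma of 1000
  expect_true(all(abs(tab - 1000) < 3 * sqrt(6000 * (1 / 6) * (5 / 6))))
})

test_that("match_cells dispatches methods and carries invariant values", {
  fx <- linear_fixture(n = 4, n_cells = 80, times = c(0, 2), seed = 6)
  m <- match_cells(fx$s1, fx$s2, method = "IM")
  expect_identical(m$kind, "IM")
  expect_identical(sort(m$perm), 1:80)
  d <- matching_table(m)
  expect_identical(names(d), c("cell_id_t1", "cell_id_t2", "I_t1", "I_t2"))
  mr <- match_cells(fx$s1, fx$s2, method = "random")
  expect_identical(sort(mr$perm), 1:80)
})
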