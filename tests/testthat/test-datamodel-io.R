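test_that("snapshot construction validates its invariants", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("A", "B")))
  s <- snapshot(m, time = 0)
  expect_s3_class(s, "snapshot")
  expect_identical(s$species, c("A", "B"))
  expect_identical(s$cell_ids, c("1", "2", "3"))

  expect_error(snapshot(m, time = NA), "finite")
  expect_error(snapshot(m, 0, species = c("A", "A")), "unique")
  m2 <- m; m2[2, 1] <- -1
  expect_error(snapshot(m2, 0), "cell 2.*'A'")
  m3 <- m; m3[1, 2] <- NA
  expect_error(snapshot(m3, 0), "missing")
})

test_that("series requires shared species and increasing times", {
  a <- tiny_snapshot(matrix(1:4, 2), 0)
  b <- tiny_snapshot(matrix(1:4, 2), 1)
  expect_silent(snapshot_series(list(b, a)))  # sorted internally
  expect_identical(snapmatch:::series_times(snapshot_series(list(b, a))), c(0, 1))
  bad <- snapshot(matrix(1:4, 2), 1, species = c("x", "y"))
  expect_error(snapshot_series(list(a, bad)), "identical species")
  dup <- tiny_snapshot(matrix(1:4, 2), 0)
  expect_error(snapshot_series(list(a, dup)), "strictly increasing")
})

test_that("long CSV round-trips bit-for-bit, both dialects agree", {
  set.seed(3)
  snaps <- lapply(c(0, 7.5), function(tt)
    random_snapshot(20, c("A", "B", "C"), time = tt, seed = 10 + tt))
  ser <- snapshot_series(snaps)

  f <- tempfile(fileext = ".csv")
  write_snapshot_series(ser, f, "long_csv")
  back <- read_snapshot_series(f, "long_csv")
  expect_identical(length(back), 2L)
  for (i in 1:2) {
    expect_identical(unname(back$snapshots[[i]]$abundances),
                     unname(ser$snapshots[[i]]$abundances))
    expect_identical(back$snapshots[[i]]$time, ser$snapshots[[i]]$time)
  }

  d <- tempfile()
  write_snapshot_series(ser, d, "per_time_csv")
  back2 <- read_snapshot_series(d, "per_time_csv")
  for (i in 1:2)
    expect_identical(unname(back2$snapshots[[i]]$abundances),
                     unname(ser$snapshots[[i]]$abundances))
})

test_that("per-time reader rejects inconsistent species sets", {
  d <- tempfile(); dir.create(d)
  utils::write.csv(data.frame(cell_id = 1:2, A = c(1, 2), B = c(3, 4)),
                   file.path(d, "t0.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = 1:2, A = c(1, 2)),
                   file.path(d, "t1.csv"), row.names = FALSE)
  expect_error(read_snapshot_series(d, "per_time_csv"),
               "inconsistent species.*B")
})

test_that("long reader validates required columns and missing files", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = 0, A = 1), f, row.names = FALSE)
  expect_error(read_snapshot_series(f, "long_csv"), "cell_id")
  expect_error(read_snapshot_series(tempfile(), "long_csv"), "not found")
  expect_error(write_snapshot_series(
    structure(list(snapshots = list(), metadata = list()),
              class = "snapshot_series"), tempfile()), "empty")
})

test_that("strip_identities permutes rows but preserves per-time multisets", {
  fx <- linear_fixture(n = 4, n_cells = 50)
  anon <- strip_identities(fx$sim$series, seed = 9)
  for (i in 1:2) {
    orig <- fx$sim$series$snapshots[[i]]$abundances
    got <- anon$snapshots[[i]]$abundances
    p <- anon$metadata$anonymised_perms[[i]]
    expect_identical(unname(got), unname(orig[p, ]))
    # multiset equality via row sorting
    expect_equal(got[order(got[, 1], got[, 2]), ],
                 orig[order(orig[, 1], orig[, 2]), ],
                 ignore_attr = TRUE)
  }
  anon2 <- strip_identities(fx$sim$series, seed = 9)
  expect_identical(anon$metadata$anonymised_perms,
                   anon2$metadata$anonymised_perms)
  # single-cell series passes through with unchanged rows
  one <- snapshot_series(list(tiny_snapshot(matrix(1:2, 1), 0),
                              tiny_snapshot(matrix(3:4, 1), 1)))
  expect_identical(strip_identities(one, 1)$snapshots[[1]]$abundances[1, ],
                   one$snapshots[[1]]$abundances[1, ])
})

test_that("downsample_to_match subsamples reproducibly and validates", {
  fx <- linear_fixture(n = 3, n_cells = 40)
  d1 <- downsample_to_match(fx$sim$series, 25, seed = 4)
  d2 <- downsample_to_match(fx$sim$series, 25, seed = 4)
  expect_identical(d1$snapshots[[1]]$abundances, d2$snapshots[[1]]$abundances)
  expect_identical(nrow(d1$snapshots[[2]]$abundances), 25L)
  expect_error(downsample_to_match(fx$sim$series, 0), "positive")
  expect_error(downsample_to_match(fx$sim$series, 41), "exceeds")
})
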