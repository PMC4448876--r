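# Distances, PCoA, disparity curves ---------------------------------------

test_that("pairwise distances follow the rescaled Euclidean formula", {
  mk <- function(rows, ordered = FALSE) {
    m <- do.call(rbind, rows)
    rownames(m) <- paste0("t", seq_along(rows))
    character_matrix(m, ordered = ordered)
  }
  # identical rows -> 0
  cm <- mk(list(c("0", "1", "0", "1"), c("0", "1", "0", "1")))
  expect_equal(pairwise_distances(cm)$d[1, 2], 0)

  # 4 unordered characters, 2 mismatches -> sqrt(2)
  cm2 <- mk(list(c("0", "1", "0", "1"), c("1", "0", "0", "1")))
  expect_equal(pairwise_distances(cm2)$d[1, 2], sqrt(2))

  # 1 missing cell, 1 mismatch among the 3 shared -> sqrt(4/3)
  cm3 <- mk(list(c("0", "1", "0", "1"), c("1", "1", "0", NA)))
  expect_equal(pairwise_distances(cm3)$d[1, 2], sqrt(4 / 3))
  # raw pairwise-deletion variant: sqrt(1)
  expect_equal(pairwise_distances(cm3, rescale = "raw")$d[1, 2], 1)

  # ordered characters use |a - b|; polymorphisms take the min cross pair
  cm4 <- mk(list(c("0", "2"), c("2", "02")), ordered = TRUE)
  expect_equal(pairwise_distances(cm4)$d[1, 2], 2)  # sqrt(2^2 + 0)
  cm5 <- mk(list(c("02", "1"), c("1", "1")))
  expect_equal(pairwise_distances(cm5)$d[1, 2], sqrt(1))
})

test_that("with no missing data distances equal ordinary Euclidean
           distances on state vectors", {
  set.seed(211)
  X <- matrix(sample(0:3, 10 * 8, TRUE), 10, 8)
  m <- matrix(as.character(X), 10, 8,
              dimnames = list(paste0("t", 1:10), NULL))
  cm <- character_matrix(m, ordered = TRUE)
  got <- pairwise_distances(cm)$d
  want <- as.matrix(stats::dist(X))
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("incomparable pairs warn or fail depending on their share", {
  m <- rbind(t1 = c("0", NA), t2 = c(NA, "1"), t3 = c("0", "1"))
  expect_error(pairwise_distances(character_matrix(m)),
               "share no scored character")
  m2 <- rbind(t1 = c("0", NA), t2 = c(NA, "1"), t3 = c("0", "1"),
              t4 = c("1", "1"), t5 = c("0", "0"), t6 = c("1", "0"),
              t7 = c("0", "1"))
  expect_warning(dm <- pairwise_distances(character_matrix(m2),
                                          max_incomparable = 0.2),
                 "share no scored character")
  expect_true(is.na(dm$d["t1", "t2"]))
})

test_that("PCoA reconstructs distances and satisfies the variance
           identities", {
  # 3 collinear points, mutual distances 3, 2, 5: one positive axis
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["b", "c"] <- d["c", "b"] <- 2
  d["a", "c"] <- d["c", "a"] <- 5
  ord <- pcoa_ordination(d)
  expect_equal(ncol(ord$coordinates), 1L)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  # random planar points: two positive axes, distances reproduced
  set.seed(223)
  for (rep in 1:3) {
    P <- matrix(stats::rnorm(2 * 6), 6, 2)
    rownames(P) <- paste0("p", 1:6)
    d2 <- as.matrix(stats::dist(P))
    ord2 <- pcoa_ordination(d2)
    expect_equal(ncol(ord2$coordinates), 2L)
    expect_equal(unname(as.matrix(stats::dist(ord2$coordinates))),
                 unname(d2), tolerance = 1e-9)
    # axis variance identity: var(axis m) = lambda_m / (n - 1)
    expect_equal(apply(ord2$coordinates, 2, stats::var),
                 ord2$eigenvalues / (6 - 1), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # scores centred
    expect_equal(colMeans(ord2$coordinates), c(axis1 = 0, axis2 = 0),
                 tolerance = 1e-9)
  }

  expect_error(pcoa_ordination(matrix(0, 3, 3)), "degenerate")
})

test_that("PCoA agrees with ape's independent implementation", {
  set.seed(227)
  X <- matrix(sample(0:2, 12 * 9, TRUE), 12, 9)
  m <- matrix(as.character(X), 12, 9,
              dimnames = list(paste0("t", 1:12), NULL))
  m[sample(length(m), 15)] <- NA
  dm <- pairwise_distances(character_matrix(m))
  ord <- pcoa_ordination(dm)
  ref <- ape::pcoa(stats::as.dist(dm$d))
  npos <- ncol(ord$coordinates)
  expect_equal(ord$eigenvalues, ref$values$Eigenvalues[seq_len(npos)],
               tolerance = 1e-8)
  for (ax in seq_len(min(3, npos)))
    expect_equal(abs(ord$coordinates[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("sum of variances over all positive axes equals the eigenvalue
           total and is rotation invariant", {
  set.seed(229)
  X <- matrix(stats::rnorm(8 * 4), 8, 4)
  rownames(X) <- paste0("r", 1:8)
  ord <- pcoa_ordination(as.matrix(stats::dist(X)))
  sov <- sum(apply(ord$coordinates, 2, stats::var))
  expect_equal(sov, sum(ord$eigenvalues) / (8 - 1), tolerance = 1e-9)
  # rigid rotation of the retained coordinates leaves it unchanged
  k <- ncol(ord$coordinates)
  qr_ <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  expect_equal(sum(apply(ord$coordinates %*% qr_, 2, stats::var)), sov,
               tolerance = 1e-9)
})

simple_ord <- function(scores) {
  ids <- rownames(scores)
  structure(list(coordinates = scores,
                 eigenvalues = rep(1, ncol(scores)),
                 all_eigenvalues = rep(1, ncol(scores)),
                 percent_variance = rep(100 / ncol(scores), ncol(scores)),
                 ids = ids), class = "ordination")
}

simple_durations <- function(ids, start, end) {
  structure(data.frame(id = ids, node = seq_along(ids), start = start,
                       end = end, kind = "observed_tip",
                       stringsAsFactors = FALSE),
            class = c("lineage_durations", "data.frame"))
}

test_that("disparity per bin is the sum of member score variances", {
  sc <- matrix(c(0, 2), 2, 1, dimnames = list(c("x", "y"), "axis1"))
  ord <- simple_ord(sc)
  dur <- simple_durations(c("x", "y"), c(2, 2), c(0, 0))
  cur <- disparity_curve(ord, dur, time_bins(2, 0, 2), k_axes = 1,
                         n_boot = 50, seed = 1)
  expect_equal(cur$value[1], 2)   # var({0, 2}) = 2
  expect_equal(cur$n[1], 2L)

  # identical members: 0 with CI [0, 0]
  sc2 <- matrix(c(1, 1, 1), 3, 1,
                dimnames = list(c("x", "y", "z"), "axis1"))
  cur2 <- disparity_curve(simple_ord(sc2),
                          simple_durations(c("x", "y", "z"),
                                           rep(2, 3), rep(0, 3)),
                          time_bins(2, 0, 2), k_axes = 1, n_boot = 50,
                          seed = 1)
  expect_equal(c(cur2$value[1], cur2$lo[1], cur2$hi[1]), c(0, 0, 0))

  # bins with < 2 members undefined, not zero
  dur3 <- simple_durations(c("x", "y"), c(2, 1), c(1.2, 0))
  cur3 <- disparity_curve(ord, dur3, time_bins(2, 0, 1), k_axes = 1,
                          n_boot = 10, seed = 1)
  expect_false(cur3$defined[1])
  expect_true(is.na(cur3$value[1]))
})

test_that("adding a row at the bin centroid never increases disparity", {
  # (a duplicate of an extreme member CAN raise a sample variance, so the
  # meaningful no-inflation property is stated at the centroid)
  set.seed(233)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    sc <- matrix(stats::rnorm(n * 2), n, 2,
                 dimnames = list(paste0("t", 1:n), NULL))
    ctr <- rbind(sc, colMeans(sc))
    sov <- sum(apply(sc, 2, stats::var))
    sov_ctr <- sum(apply(ctr, 2, stats::var))
    expect_lte(sov_ctr, sov + 1e-12)
  }
})

test_that("rarefied curve equals the full value when the bin has exactly
           n_sub members, and is undefined below n_sub", {
  set.seed(239)
  sc <- matrix(stats::rnorm(8 * 2), 8, 2,
               dimnames = list(paste0("t", 1:8), NULL))
  ord <- simple_ord(sc)
  dur <- simple_durations(rownames(sc), rep(2, 8), rep(0, 8))
  full <- disparity_curve(ord, dur, time_bins(2, 0, 2), k_axes = 2,
                          n_boot = 20, seed = 5)
  rar <- rarefied_disparity_curve(ord, dur, time_bins(2, 0, 2), k_axes = 2,
                                  n_sub = 8, n_boot = 20, seed = 5)
  expect_equal(rar$value[1], full$value[1], tolerance = 1e-12)

  dur5 <- simple_durations(rownames(sc)[1:5], rep(2, 5), rep(0, 5))
  ord5 <- simple_ord(sc[1:5, ])
  rar5 <- rarefied_disparity_curve(ord5, dur5, time_bins(2, 0, 2),
                                   k_axes = 2, n_sub = 8, n_boot = 20,
                                   seed = 5)
  expect_false(rar5$defined[1])
})

test_that("bootstrap band width shrinks as bin membership grows", {
  # homogeneous members (alternating -1/+1 scores) so the only width
  # driver is the bin's sample size
  widths <- vapply(c(10, 100, 1000), function(n) {
    sc <- matrix(rep(c(-1, 1), n / 2), n, 1,
                 dimnames = list(paste0("t", 1:n), NULL))
    cur <- disparity_curve(simple_ord(sc),
                           simple_durations(rownames(sc), rep(2, n),
                                            rep(0, n)),
                           time_bins(2, 0, 2), k_axes = 1, n_boot = 300,
                           seed = 7)
    cur$hi[1] - cur$lo[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
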