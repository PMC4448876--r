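# Disparity: distances, ordination, per-bin sum of variances ---------------

#' Pairwise morphological distances
#'
#' Generalized Euclidean distance between rows of a discrete character
#' matrix. Per shared (both-scored) character the difference is
#' `|a - b|` for ordered characters and 0/1 for unordered ones;
#' polymorphic cells contribute the minimum difference over cross-set
#' state pairs. With `rescale = "wills"` (default) the squared distance is
#' rescaled by `C_total / |S_ij|` -- the total character count over the
#' number of shared scored characters -- so that incomplete rows are not
#' systematically drawn towards each other; `rescale = "raw"` uses plain
#' pairwise deletion.
#'
#' @param x an `augmented_sample` or a [character_matrix()].
#' @param rescale `"wills"` or `"raw"`.
#' @param max_incomparable hard-error threshold on the fraction of row
#'   pairs sharing no scored character (default 0.05).
#' @return a `dist_matrix`: list with `d` (symmetric matrix),
#'   `n_comparable` (shared scored characters per pair), `ids`,
#'   `incomparable` (2-column matrix of row pairs with no shared data).
#' @export
pairwise_distances <- function(x, rescale = c("wills", "raw"),
                               max_incomparable = 0.05) {
  rescale <- match.arg(rescale)
  cm <- if (inherits(x, "augmented_sample")) x$matrix else x
  stopifnot(inherits(cm, "char_matrix"))
  m <- cm$data
  nr <- nrow(m)
  if (nr < 2L) stop("need at least 2 rows for distances")
  nc <- ncol(m)
  obs <- !is_missing_cell(m)
  dim(obs) <- dim(m)
  ord <- cm$ordered

  ss <- matrix(0, nr, nr)       # rescaled squared differences
  shared <- matrix(0L, nr, nr)  # both-scored character counts
  for (i in seq_len(nr - 1L)) {
    for (jrow in (i + 1L):nr) {
      sh <- obs[i, ] & obs[jrow, ]
      nsh <- sum(sh)
      shared[i, jrow] <- shared[jrow, i] <- nsh
      if (nsh == 0L) next
      idx <- which(sh)
      a <- m[i, idx]; b <- m[jrow, idx]
      poly <- nchar(a) > 1L | nchar(b) > 1L
      dd <- numeric(nsh)
      simple <- which(!poly)
      if (length(simple)) {
        ai <- as.integer(a[simple]); bi <- as.integer(b[simple])
        o <- ord[idx[simple]]
        dd[simple] <- ifelse(o, abs(ai - bi), as.numeric(ai != bi))
      }
      for (q in which(poly)) {
        sa <- as.integer(strsplit(a[q], "")[[1L]])
        sb <- as.integer(strsplit(b[q], "")[[1L]])
        mn <- min(abs(outer(sa, sb, "-")))
        dd[q] <- if (ord[idx[q]]) mn else as.numeric(mn > 0)
      }
      ss[i, jrow] <- ss[jrow, i] <- sum(dd^2)
    }
  }
  fac <- if (rescale == "wills") nc / shared else 1
  d <- sqrt(ss * fac)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))

  incomp <- which(shared == 0L & upper.tri(shared), arr.ind = TRUE)
  if (nrow(incomp)) {
    frac <- nrow(incomp) / (nr * (nr - 1L) / 2)
    msg <- paste0(nrow(incomp), " row pairs share no scored character: ",
                  paste(utils::head(paste(rownames(m)[incomp[, 1L]],
                                          rownames(m)[incomp[, 2L]],
                                          sep = " ~ "), 5), collapse = "; "))
    if (frac > max_incomparable) stop(msg) else warning(msg)
    d[shared == 0L] <- NA
    diag(d) <- 0
  }
  structure(list(d = d, n_comparable = shared, ids = rownames(m),
                 incomparable = incomp),
            class = "dist_matrix")
}

#' Write a distance matrix as square TSV
#' @param x a `dist_matrix`.
#' @param path output file.
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(id = x$ids, formatC(x$d, digits = 10, format = "g"),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2` and
#' eigendecomposition. Axes with eigenvalues at or below
#' `tol * lambda_max` are dropped; negative eigenvalues are discarded and
#' percent variance is taken over the positive eigenvalues only (no
#' Cailliez/Lingoes correction). Coordinates are scaled so the sum of
#' squared scores on axis m equals its eigenvalue.
#'
#' @param dm a `dist_matrix` (must have no incomparable pairs) or a
#'   symmetric numeric matrix.
#' @param tol relative eigenvalue tolerance.
#' @return an `ordination`: `coordinates` (rows x positive axes),
#'   `eigenvalues` (positive, descending), `all_eigenvalues`,
#'   `percent_variance`, `ids`.
#' @export
pcoa_ordination <- function(dm, tol = 1e-8) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (anyNA(d)) stop("distance matrix has incomparable (NA) pairs")
  n <- nrow(d)
  # cmdscale warns when some eigenvalues are negative; that is the normal
  # situation for non-Euclidean character distances and handled below
  mds <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- mds$eig
  pos <- which(eig > tol * max(eig))
  if (!length(pos) || max(eig) <= 0) stop("degenerate distances")
  coords <- mds$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(pos))
  pct <- eig[pos] / sum(eig[eig > 0]) * 100
  structure(list(coordinates = coords, eigenvalues = eig[pos],
                 all_eigenvalues = eig, percent_variance = pct,
                 ids = rownames(d)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$coordinates), "rows,",
      ncol(x$coordinates), "positive axes\n")
  cat("  percent variance (first axes):",
      paste(sprintf("%.1f", utils::head(x$percent_variance, 6)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of axes reaching a cumulative-variance threshold
#' @param ord an `ordination`.
#' @param threshold cumulative fraction of positive-eigenvalue variance.
#' @return smallest axis count whose cumulative variance meets the
#'   threshold.
#' @export
axes_for_variance <- function(ord, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  cv <- cumsum(ord$percent_variance) / 100
  which(cv >= threshold - 1e-12)[1L]
}

disparity_bin_members <- function(ord, durations, bins) {
  dur <- durations[match(ord$ids, durations$id), ]
  if (anyNA(dur$start))
    stop("durations missing for rows: ",
         paste(ord$ids[is.na(dur$start)], collapse = ", "))
  lapply(seq_len(nrow(bins)), function(b)
    which(bin_overlap_members(dur$start, dur$end,
                              bins$older[b], bins$younger[b])))
}

sum_of_variances <- function(scores) sum(apply(scores, 2, stats::var))

#' Disparity-through-time curve
#'
#' Per time bin, the sum over the retained ordination axes of the sample
#' variance (n-1 denominator) of the scores of the lineages whose
#' duration overlaps the bin, with a percentile bootstrap confidence band
#' (members resampled with replacement within each bin). Bins with fewer
#' than 2 members are flagged undefined.
#'
#' @param ord an `ordination` of the (augmented) sample.
#' @param durations a [lineage_durations()] table covering the ordinated
#'   rows (use extensions for the disparity convention).
#' @param bins a [time_bins()] grid.
#' @param k_axes number of axes to sum over; if `NULL`, the smallest
#'   number reaching `variance_threshold` cumulative variance.
#' @param variance_threshold cumulative-variance target used when
#'   `k_axes` is `NULL` (default 0.95).
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci_level confidence level for the percentile band.
#' @param seed RNG seed (mandatory: bootstrap resampling must be
#'   reproducible).
#' @return a `bin_series` with metric `"disparity"`.
#' @export
disparity_curve <- function(ord, durations, bins = time_bins(),
                            k_axes = NULL, variance_threshold = 0.95,
                            n_boot = 1000, ci_level = 0.95, seed) {
  stopifnot(inherits(ord, "ordination"), n_boot >= 1)
  if (missing(seed)) stop("`seed` is required")
  if (is.null(k_axes)) k_axes <- axes_for_variance(ord, variance_threshold)
  if (k_axes > ncol(ord$coordinates))
    stop("k_axes exceeds the number of retained axes")
  sc <- ord$coordinates[, seq_len(k_axes), drop = FALSE]
  members <- disparity_bin_members(ord, durations, bins)
  if (!any(lengths(members) > 0L)) stop("no bin has any member lineage")

  set.seed(seed)
  nb <- nrow(bins)
  value <- lo <- hi <- rep(NA_real_, nb)
  nmem <- lengths(members)
  alpha <- (1 - ci_level) / 2
  for (b in seq_len(nb)) {
    idx <- members[[b]]
    if (length(idx) < 2L) next
    value[b] <- sum_of_variances(sc[idx, , drop = FALSE])
    bv <- boot_sov(sc, idx, n_boot, replace = TRUE, n_sub = length(idx))
    qs <- stats::quantile(bv, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    lo[b] <- qs[1L]; hi[b] <- qs[2L]
  }
  bin_series(data.frame(bin_older = bins$older, bin_younger = bins$younger,
                        n = nmem, value = value, lo = lo, hi = hi,
                        defined = !is.na(value)),
             metric = "disparity")
}

# n_boot sums-of-variances from resampled member rows
boot_sov <- function(sc, idx, n_boot, replace, n_sub) {
  m <- length(idx)
  k <- ncol(sc)
  out <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    pick <- idx[sample.int(m, n_sub, replace = replace)]
    x <- sc[pick, , drop = FALSE]
    out[r] <- sum(apply(x, 2, stats::var))
  }
  out
}

#' Rarefied disparity curve at fixed sample size
#'
#' Per bin with at least `n_sub` member lineages, draws `n_sub` members
#' without replacement `n_boot` times, computes the sum of variances per
#' draw, and reports the mean with a percentile band. Bins with fewer
#' than `n_sub` members are flagged undefined. This removes
#' sample-size differences between bins.
#'
#' @inheritParams disparity_curve
#' @param n_sub subsample size (default 8 lineages per bin).
#' @return a `bin_series` with metric `"disparity_rarefied"`.
#' @export
rarefied_disparity_curve <- function(ord, durations, bins = time_bins(),
                                     k_axes = NULL,
                                     variance_threshold = 0.95,
                                     n_sub = 8, n_boot = 1000,
                                     ci_level = 0.95, seed) {
  stopifnot(inherits(ord, "ordination"), n_sub >= 2, n_boot >= 1)
  if (missing(seed)) stop("`seed` is required")
  if (is.null(k_axes)) k_axes <- axes_for_variance(ord, variance_threshold)
  sc <- ord$coordinates[, seq_len(k_axes), drop = FALSE]
  members <- disparity_bin_members(ord, durations, bins)

  set.seed(seed)
  nb <- nrow(bins)
  value <- lo <- hi <- rep(NA_real_, nb)
  alpha <- (1 - ci_level) / 2
  for (b in seq_len(nb)) {
    idx <- members[[b]]
    if (length(idx) < n_sub) next
    bv <- boot_sov(sc, idx, n_boot, replace = FALSE, n_sub = n_sub)
    value[b] <- mean(bv)
    qs <- stats::quantile(bv, c(alpha, 1 - alpha), names = FALSE)
    lo[b] <- qs[1L]; hi[b] <- qs[2L]
  }
  bin_series(data.frame(bin_older = bins$older, bin_younger = bins$younger,
                        n = lengths(members), value = value, lo = lo,
                        hi = hi, defined = !is.na(value)),
             metric = "disparity_rarefied")
}

#' Occupied-morphospace proxy (per-axis score range product)
#'
#' Product of score ranges over the first `k` ordination axes for a
#' subset of rows; the convex-hull-volume proxy used to compare the
#' morphospace occupied with and without hypothetical ancestors.
#'
#' @param ord an `ordination`.
#' @param ids row ids to include (default all).
#' @param k number of axes (default 2).
#' @return the range product.
#' @export
range_product <- function(ord, ids = NULL, k = 2) {
  sc <- ord$coordinates[, seq_len(k), drop = FALSE]
  if (!is.null(ids)) sc <- sc[ord$ids %in% ids, , drop = FALSE]
  prod(apply(sc, 2, function(v) diff(range(v))))
}
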