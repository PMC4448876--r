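# Diversity (LTT) and evolutionary-rate curves -----------------------------

#' Lineage-through-time diversity curve
#'
#' In `"boundary"` mode (the default, the classic palaeo-LTT convention)
#' counts the lineages alive at each 1-Ma boundary age: a lineage with
#' duration `[start, end]` is alive at age `a` when `end < a <= start` --
#' it exists at the age it originates but not at the age it ends
#' (extinction or anagenetic replacement), except that lineages reaching
#' the present (`end == 0`) are only censored, not dead, and so count at
#' age 0. Because fossil lineages drop out
#' at the end of their (possibly extended) duration, the curve can
#' decline -- unlike extant-only LTT plots. In `"overlap"` mode counts
#' the lineages overlapping each bin with positive length.
#'
#' @param durations a [lineage_durations()] table, computed with
#'   `use_extensions = TRUE` for the diversity convention.
#' @param bins a [time_bins()] grid; boundary mode counts at its bin
#'   edges.
#' @param mode `"boundary"` or `"overlap"`.
#' @return a `bin_series` with metric `"diversity"`. In boundary mode the
#'   rows are boundary ages (`age` column; `bin_older == bin_younger`).
#' @export
ltt_curve <- function(durations, bins = time_bins(),
                      mode = c("boundary", "overlap")) {
  mode <- match.arg(mode)
  st <- durations$start
  en <- durations$end
  pos <- st - en > 1e-12
  if (mode == "boundary") {
    tol <- 1e-8
    ages <- unique(c(bins$older, bins$younger))
    counts <- vapply(ages, function(a)
      sum(pos & a <= st + tol &
            (a - en > tol | (a <= tol & en <= tol))), numeric(1))
    df <- data.frame(bin_older = ages, bin_younger = ages, age = ages,
                     n = counts, value = counts, lo = counts, hi = counts,
                     defined = TRUE)
  } else {
    counts <- vapply(seq_len(nrow(bins)), function(b)
      sum(bin_overlap_members(st, en, bins$older[b], bins$younger[b])),
      numeric(1))
    df <- data.frame(bin_older = bins$older, bin_younger = bins$younger,
                     n = counts, value = counts, lo = counts, hi = counts,
                     defined = TRUE)
  }
  bin_series(df, metric = "diversity")
}

#' Absolute per-branch evolutionary rates
#'
#' Converts per-branch relative clock rates (dimensionless multipliers,
#' as annotated on a dated consensus tree) into absolute rates in per
#' cent change per Ma: `absolute = relative * clock_rate * 100`. With the
#' overall median clock rate of 0.0018 changes per character per Ma, a
#' relative rate of 1 is 0.18 %/Ma.
#'
#' @param tree a [dated_tree()] whose branches are annotated with
#'   relative rates (or supply `rates`).
#' @param clock_rate overall median clock rate in expected changes per
#'   character per Ma (> 0).
#' @param rates optional numeric vector of per-branch relative rates
#'   overriding the tree's annotations.
#' @return a `branch_rates` data frame: the [branch_table()] plus
#'   `relative` and `absolute` (%/Ma) columns; `clock_rate` attribute.
#' @export
absolute_branch_rates <- function(tree, clock_rate, rates = NULL) {
  stopifnot(inherits(tree, "dated_tree"), clock_rate > 0)
  bt <- branch_table(tree)
  rel <- if (!is.null(rates)) rates else tree$rates
  if (is.null(rel)) stop("tree has no branch-rate annotations")
  stopifnot(length(rel) == nrow(bt))
  if (anyNA(rel))
    stop("unannotated branch(es): ",
         paste(bt$label[is.na(rel)], collapse = ", "))
  if (any(rel < 0)) stop("negative relative rate")
  bt$relative <- rel
  bt$absolute <- rel * clock_rate * 100
  structure(bt, class = c("branch_rates", "data.frame"),
            clock_rate = clock_rate)
}

#' Write a branch-rate table as TSV
#' @param x a `branch_rates` data frame.
#' @param path output file.
#' @export
write_branch_rates <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Lineage-averaged evolutionary-rate curve
#'
#' Per time bin, the unweighted mean of the absolute rates of the
#' branches whose time span overlaps the bin (rates mode: branch spans
#' are the raw dated-tree durations, never extended to younger referred
#' material), with a band of plus/minus one standard error of the mean.
#' Bins containing a single branch report SEM 0; empty bins are flagged
#' undefined.
#'
#' @param rates a `branch_rates` table from [absolute_branch_rates()].
#' @param bins a [time_bins()] grid.
#' @param mode `"overlap"` (branches overlapping the bin) or `"midpoint"`
#'   (branches spanning the bin midpoint age).
#' @param weight `"equal"` (per-lineage average, default) or
#'   `"duration"` (branch overlap-length weighted).
#' @return a `bin_series` with metric `"rate"` (value in %/Ma).
#' @export
binned_rate_curve <- function(rates, bins = time_bins(),
                              mode = c("overlap", "midpoint"),
                              weight = c("equal", "duration")) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  stopifnot(inherits(rates, "branch_rates"))
  nb <- nrow(bins)
  value <- lo <- hi <- rep(NA_real_, nb)
  nmem <- integer(nb)
  for (b in seq_len(nb)) {
    if (mode == "overlap") {
      memb <- which(bin_overlap_members(rates$parent_age, rates$child_age,
                                        bins$older[b], bins$younger[b]))
    } else {
      mid <- bins$mid[b]
      memb <- which(rates$child_age <= mid & mid <= rates$parent_age &
                      rates$parent_age - rates$child_age > 1e-12)
    }
    nmem[b] <- length(memb)
    if (!length(memb)) next
    r <- rates$absolute[memb]
    if (weight == "duration") {
      w <- pmin(rates$parent_age[memb], bins$older[b]) -
        pmax(rates$child_age[memb], bins$younger[b])
      w <- pmax(w, 0)
      value[b] <- sum(w * r) / sum(w)
      sem <- if (length(r) > 1L)
        sqrt(sum(w * (r - value[b])^2) / sum(w) / (length(r) - 1L)) else 0
    } else {
      value[b] <- mean(r)
      sem <- if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0
    }
    lo[b] <- value[b] - sem
    hi[b] <- value[b] + sem
  }
  bin_series(data.frame(bin_older = bins$older, bin_younger = bins$younger,
                        n = nmem, value = value, lo = lo, hi = hi,
                        defined = !is.na(value)),
             metric = "rate")
}
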