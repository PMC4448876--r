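# Time bins and per-bin curve containers ----------------------------------

#' Build a grid of half-open time bins
#'
#' Bins run from older to younger ages in Ma before present and are
#' half-open `[older, younger)` intervals, so a boundary age belongs to
#' the younger bin.
#'
#' @param oldest oldest bin edge (Ma), default 37 (the study window).
#' @param youngest youngest edge (Ma), default 0.
#' @param step bin width (Ma), default 1.
#' @return data frame with columns `older`, `younger`, `mid`.
#' @export
time_bins <- function(oldest = 37, youngest = 0, step = 1) {
  stopifnot(step > 0, oldest > youngest)
  edges <- seq(oldest, youngest, by = -step)
  if (edges[length(edges)] > youngest) edges <- c(edges, youngest)
  data.frame(older = edges[-length(edges)], younger = edges[-1L],
             mid = (edges[-length(edges)] + edges[-1L]) / 2)
}

# positive-length overlap of durations [start, end] with bin [older, younger)
bin_overlap_members <- function(start, end, older, younger, tol = 1e-12) {
  pmin(start, older) - pmax(end, younger) > tol
}

bin_series <- function(df, metric) {
  stopifnot(all(c("bin_older", "bin_younger", "n", "value", "lo", "hi",
                  "defined") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("bin_series", "data.frame"), metric = metric)
}

#' @export
print.bin_series <- function(x, ...) {
  cat("Bin series (", attr(x, "metric"), "): ", nrow(x), " bins, ",
      sum(x$defined), " defined\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Age of the peak of a curve
#'
#' The midpoint age of the oldest bin attaining the maximum defined value
#' (ties resolved towards the past: a curve that rises to a plateau is
#' said to peak where the plateau is first reached, matching how peak
#' ages of palaeodiversity curves are usually quoted).
#'
#' @param x a `bin_series`.
#' @return age in Ma, or NA if no bin is defined.
#' @export
peak_age <- function(x) {
  ok <- x$defined & !is.na(x$value)
  if (!any(ok)) return(NA_real_)
  v <- x$value[ok]
  mids <- if ("age" %in% names(x)) x$age[ok] else
    (x$bin_older[ok] + x$bin_younger[ok]) / 2
  o <- order(mids, decreasing = TRUE)  # oldest first
  mids[o][which.max(v[o])]
}

#' Write a bin series as TSV
#' @param x a `bin_series`.
#' @param path output file.
#' @export
write_bin_series <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bin series as plot-ready JSON
#' @param x a `bin_series`.
#' @param path output file.
#' @export
write_bin_series_json <- function(x, path) {
  jsonlite::write_json(list(metric = attr(x, "metric"),
                            bins = as.data.frame(x)),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
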