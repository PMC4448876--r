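# Stratigraphic ranges and lineage durations ------------------------------

#' Load a stratigraphic-range table
#'
#' CSV with header `taxon,oldest,youngest[,younger_material]`. Ages in Ma;
#' `oldest >= youngest >= 0`, and when present the age of younger referred
#' material must postdate (be less than or equal to) the youngest range
#' end.
#'
#' @param path CSV file.
#' @param tree optional [dated_tree()]; taxa absent from the tree trigger a
#'   warning listing their names.
#' @return a data frame of class `strat_records` with columns `taxon`,
#'   `oldest`, `youngest`, `younger_material` (NA when absent).
#' @export
load_strat_ranges <- function(path, tree = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("taxon", "oldest", "youngest")
  if (!all(need %in% names(df)))
    stop("stratigraphic table must have columns taxon,oldest,youngest")
  if (!"younger_material" %in% names(df)) df$younger_material <- NA_real_
  df <- df[, c(need, "younger_material")]
  df$oldest <- as.numeric(df$oldest)
  df$youngest <- as.numeric(df$youngest)
  df$younger_material <- as.numeric(df$younger_material)
  strat_records(df, tree = tree)
}

strat_records <- function(df, tree = NULL) {
  bad <- df$youngest > df$oldest | df$youngest < 0
  if (any(bad))
    stop("invalid stratigraphic range (youngest > oldest or negative) for: ",
         paste(df$taxon[bad], collapse = ", "))
  ym <- !is.na(df$younger_material)
  if (any(ym & df$younger_material > df$youngest))
    stop("younger material older than range end for: ",
         paste(df$taxon[ym & df$younger_material > df$youngest],
               collapse = ", "))
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon in stratigraphic table")
  if (!is.null(tree)) {
    unk <- setdiff(df$taxon, tree$phy$tip.label)
    if (length(unk))
      warning("stratigraphic records for taxa not in tree: ",
              paste(unk, collapse = ", "))
  }
  class(df) <- c("strat_records", "data.frame")
  df
}

#' Write a stratigraphic-range table
#' @param x a `strat_records` data frame.
#' @param path output CSV.
#' @export
write_strat_ranges <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Temporal durations of every lineage of a dated tree
#'
#' Each lineage is a row: observed tips span from the age of the node at
#' the origin of their terminal branch (i.e. including the ghost range
#' implied by the dated tree) down to the tip's age; with
#' `use_extensions = TRUE` (the diversity/disparity convention) a fossil
#' tip with younger referred material is extended down to that material's
#' age. Every internal node is a ghost lineage spanning its subtending
#' branch; the root, which has no subtending branch (any stem edge in the
#' input is ignored), gets a zero-length duration at the root age.
#'
#' @param tree a [dated_tree()].
#' @param strat optional `strat_records` supplying younger-material ages.
#' @param use_extensions logical; extend fossil tips to younger referred
#'   material (`TRUE` for diversity/disparity, `FALSE` for rates).
#' @param tol ages closer to 0 than `tol` count as extant (no extension).
#' @return data frame of class `lineage_durations`: `id`, `node`, `start`
#'   (older age), `end` (younger age), `kind` (`observed_tip`,
#'   `ghost_range_extension`, `ghost_lineage`).
#' @export
lineage_durations <- function(tree, strat = NULL, use_extensions = FALSE,
                              tol = 1e-8) {
  stopifnot(inherits(tree, "dated_tree"))
  bt <- branch_table(tree)
  phy <- tree$phy
  n <- length(phy$tip.label)
  root <- n + 1L

  tips <- bt[bt$is_tip, ]
  start <- tips$parent_age
  end <- tips$child_age
  kind <- rep("observed_tip", nrow(tips))
  if (use_extensions && !is.null(strat)) {
    i <- match(tips$label, strat$taxon)
    ym <- ifelse(is.na(i), NA_real_, strat$younger_material[i])
    ext <- !is.na(ym) & tips$child_age > tol
    if (any(ext & ym > tips$child_age + tol))
      stop("younger material older than tip age for: ",
           paste(tips$label[ext & ym > tips$child_age + tol], collapse = ", "))
    end[ext] <- pmin(ym[ext], end[ext])
    kind[ext] <- "ghost_range_extension"
  }
  tip_rows <- data.frame(id = tips$label, node = tips$child,
                         start = start, end = end, kind = kind,
                         stringsAsFactors = FALSE)

  ints <- bt[!bt$is_tip, ]
  int_rows <- data.frame(id = ints$label, node = ints$child,
                         start = ints$parent_age, end = ints$child_age,
                         kind = rep("ghost_lineage", nrow(ints)),
                         stringsAsFactors = FALSE)
  root_row <- data.frame(id = paste0("HA_", root), node = root,
                         start = tree$age[root], end = tree$age[root],
                         kind = "ghost_lineage", stringsAsFactors = FALSE)
  out <- rbind(tip_rows, int_rows, root_row)
  rownames(out) <- NULL
  class(out) <- c("lineage_durations", "data.frame")
  out
}

#' Write lineage durations as TSV
#' @param x a `lineage_durations` data frame.
#' @param path output file.
#' @export
write_durations <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
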