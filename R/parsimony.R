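# Parsimony ancestral states ----------------------------------------------
#
# Complete MPR (most-parsimonious-reconstruction) state sets for one
# discrete character on a rooted (possibly multifurcating) dated tree.
# Implemented as a min-cost dynamic programme over states with an outside
# (root-to-leaf) pass, so that for EVERY node -- tips included -- we get
# the set of states that occur in at least one reconstruction of minimal
# total cost. Unit cost for unordered characters reproduces
# Fitch/Hartigan sets; |a - b| cost for ordered characters reproduces the
# Farris interval method. Missing and inapplicable tips carry the full
# state set; polymorphic tips carry their state set (any member
# attainable at zero cost).

step_cost_matrix <- function(k, ordered) {
  if (ordered) abs(outer(0:(k - 1L), 0:(k - 1L), "-"))
  else 1 - diag(k)
}

#' MPR state sets and tree length for one character
#'
#' @param tree a [dated_tree()] (only the topology is used).
#' @param x a [character_matrix()] whose taxa include all tree tips.
#' @param char character id (column name) or index.
#' @return an `mpr_result`: `character`, `length` (minimum total cost),
#'   `nstates`, and `sets`, a list indexed by ape node number
#'   (tips `1..n`, then internal nodes) of integer state vectors.
#' @export
mpr_sets <- function(tree, x, char) {
  stopifnot(inherits(tree, "dated_tree"), inherits(x, "char_matrix"))
  j <- if (is.character(char)) match(char, colnames(x$data)) else char
  if (is.na(j) || j < 1L || j > ncol(x$data)) stop("unknown character: ", char)
  phy <- tree$phy
  tips <- phy$tip.label
  miss <- setdiff(tips, x$taxa)
  if (length(miss)) stop("tree tips absent from matrix: ",
                         paste(miss, collapse = ", "))
  k <- x$nstates[j]
  cells <- x$data[tips, j]
  allowed <- lapply(cells, cell_states, k = k)
  res <- mpr_engine(phy, allowed, step_cost_matrix(k, x$ordered[j]))
  structure(list(character = colnames(x$data)[j], length = res$length,
                 nstates = k, sets = res$sets),
            class = "mpr_result")
}

#' @export
print.mpr_result <- function(x, ...) {
  cat("MPR for character", x$character, "- minimum length", x$length, "\n")
  invisible(x)
}

# core DP; allowed = list of integer state vectors per tip (0-based),
# W = k x k step-cost matrix. Returns list(length, sets).
mpr_engine <- function(phy, allowed, W) {
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  k <- ncol(W)
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  ne <- nrow(edge)

  cost <- matrix(0, ntot, k)
  for (i in seq_len(n)) {
    row <- rep(Inf, k)
    row[allowed[[i]] + 1L] <- 0
    cost[i, ] <- row
  }
  M <- matrix(0, ne, k)  # M[e, t] = min_s (W[t, s] + cost_child[s])
  for (e in seq_len(ne)) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    cc <- cost[ch, ]
    for (t in seq_len(k)) M[e, t] <- min(W[t, ] + cc)
    cost[p, ] <- cost[p, ] + M[e, ]
  }
  root <- edge[ne, 1L]
  len <- min(cost[root, ])

  h <- matrix(0, ntot, k)
  for (e in rev(seq_len(ne))) {      # preorder
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    out_p <- h[p, ] + cost[p, ] - M[e, ]  # cost of everything outside ch,
    for (s in seq_len(k))                 # given parent state t
      h[ch, s] <- min(out_p + W[, s])
  }
  g <- cost + h
  tol <- 1e-9
  sets <- lapply(seq_len(ntot), function(v)
    which(g[v, ] <= len + tol) - 1L)
  list(length = len, sets = sets)
}

#' Build the phylogenetically adjusted (augmented) sample
#'
#' Applies the three phylogenetic corrections: (i) missing (and
#' inapplicable) tip scorings are replaced by the tip's parsimony state
#' when that is unambiguous (a singleton MPR set); (ii) every lineage
#' carries its dated-tree duration (ghost range for tips); (iii) every
#' internal node enters as a hypothetical ancestor (`HA_<node>`) scored
#' with its unambiguous MPR states, ambiguous cells being left missing.
#' Observed non-missing cells (including polymorphisms) are never
#' altered.
#'
#' @param tree a [dated_tree()].
#' @param x a [character_matrix()] covering the tree's tips.
#' @param durations a [lineage_durations()] table for `tree` (computed
#'   with `use_extensions = TRUE` for disparity/diversity work); must
#'   cover every tip and internal node.
#' @return an `augmented_sample`: list with `matrix` (a
#'   [character_matrix()] of tips then ancestors), `durations` (reordered
#'   to match the rows), `n_tips`, and `fill_counts` (cells filled in
#'   observed rows).
#' @export
build_augmented_sample <- function(tree, x, durations) {
  stopifnot(inherits(tree, "dated_tree"), inherits(x, "char_matrix"),
            inherits(durations, "lineage_durations"))
  phy <- tree$phy
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  if (!setequal(durations$node, seq_len(ntot)))
    stop("durations do not cover every branch of the tree")

  ids <- c(phy$tip.label, paste0("HA_", (n + 1L):ntot))
  nc <- ncol(x$data)
  aug <- matrix(NA_character_, ntot, nc,
                dimnames = list(ids, colnames(x$data)))
  aug[seq_len(n), ] <- x$data[phy$tip.label, ]

  filled <- 0L
  for (j in seq_len(nc)) {
    mpr <- mpr_sets(tree, x, j)
    single <- vapply(mpr$sets, function(s)
      if (length(s) == 1L) as.character(s) else NA_character_, character(1))
    # hypothetical ancestors
    aug[(n + 1L):ntot, j] <- single[(n + 1L):ntot]
    # fill missing tip cells
    fill <- which(is_missing_cell(aug[seq_len(n), j]) &
                    !is.na(single[seq_len(n)]))
    if (length(fill)) {
      aug[fill, j] <- single[fill]
      filled <- filled + length(fill)
    }
  }
  amat <- character_matrix(aug, ordered = x$ordered,
                           partition = x$partition, nstates = x$nstates)
  dur <- durations[match(ids, durations$id), ]
  rownames(dur) <- NULL
  structure(list(matrix = amat, durations = dur, n_tips = n,
                 fill_counts = filled),
            class = "augmented_sample")
}

#' @export
print.augmented_sample <- function(x, ...) {
  cat("Augmented sample:", x$n_tips, "observed taxa +",
      length(x$matrix$taxa) - x$n_tips, "hypothetical ancestors\n")
  cat("  tip cells filled with unambiguous ancestral states:",
      x$fill_counts, "\n")
  aud <- audit_matrix(x$matrix)
  cat(sprintf("  missing fraction (augmented): %.1f%%\n",
              100 * aud$missing_fraction))
  invisible(x)
}

#' Export an augmented sample
#'
#' Writes the augmented matrix as NEXUS (ancestor rows labelled
#' `HA_<node>`) or TSV, with the durations table as a TSV sidecar.
#'
#' @param x an `augmented_sample`.
#' @param path output matrix file (`.nex` or `.tsv` by `format`).
#' @param format `"nexus"` or `"tsv"`.
#' @export
write_augmented_sample <- function(x, path, format = c("nexus", "tsv")) {
  format <- match.arg(format)
  if (format == "nexus") write_character_matrix(x$matrix, path)
  else write_character_matrix_tsv(x$matrix, path)
  write_durations(x$durations, paste0(path, ".durations.tsv"))
  invisible(path)
}
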