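# Independent oracles used across tests ----------------------------------

# Exhaustive parsimony oracle: enumerate every assignment of states to
# internal nodes; tips contribute the minimum cost over their allowed
# states given the parent assignment. Independent of the package's DP.
brute_force_mpr <- function(phy, allowed, W) {
  n <- length(phy$tip.label)
  ni <- phy$Nnode
  k <- ncol(W)
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1L)), ni)))
  edge <- phy$edge
  total <- numeric(nrow(grid))
  tip_costs <- vector("list", n)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    pstate <- grid[, p - n]
    if (ch > n) {
      total <- total + W[cbind(pstate + 1L, grid[, ch - n] + 1L)]
    } else {
      costs <- vapply(allowed[[ch]], function(s) W[pstate + 1L, s + 1L],
                      numeric(nrow(grid)))
      if (is.null(dim(costs))) costs <- matrix(costs, nrow = 1L)
      tip_costs[[ch]] <- costs
      total <- total + apply(costs, 1L, min)
    }
  }
  len <- min(total)
  tol <- 1e-9
  sets <- vector("list", n + ni)
  for (v in (n + 1L):(n + ni))
    sets[[v]] <- sort(unique(grid[total <= len + tol, v - n]))
  for (tp in seq_len(n)) {
    costs <- tip_costs[[tp]]
    base <- total - apply(costs, 1L, min)
    best <- vapply(seq_len(ncol(costs)), function(i) min(base + costs[, i]),
                   numeric(1))
    sets[[tp]] <- sort(allowed[[tp]][best <= len + tol])
  }
  list(length = len, sets = sets)
}

# random parsimony instance; sometimes multifurcating
random_mpr_instance <- function(n_tips, k, p_missing = 0.15,
                                p_poly = 0.15, p_multi = 0.3) {
  phy <- ape::rtree(n_tips)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.5, 2)
  if (stats::runif(1) < p_multi && phy$Nnode > 2L) {
    internal <- which(phy$edge[, 2L] > n_tips)
    drop <- sample(internal, 1L)
    phy$edge.length[drop] <- 0
    phy <- ape::di2multi(phy, tol = 1e-8)
  }
  allowed <- lapply(seq_len(n_tips), function(i) {
    r <- stats::runif(1)
    if (r < p_missing) 0:(k - 1L)
    else if (r < p_missing + p_poly)
      sort(sample(0:(k - 1L), sample(2:k, 1L)))
    else sample(0:(k - 1L), 1L)
  })
  list(phy = phy, allowed = allowed)
}

# encode an allowed-state list as a one-character matrix for mpr_sets()
allowed_to_matrix <- function(phy, allowed, k, ordered) {
  cells <- vapply(allowed, function(s) {
    if (length(s) == k) NA_character_
    else paste(s, collapse = "")
  }, character(1))
  m <- matrix(cells, ncol = 1L, dimnames = list(phy$tip.label, "c1"))
  character_matrix(m, ordered = ordered, nstates = k)
}

# tiny deterministic dated tree used in several files
demo_tree <- function() {
  phy <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  dated_tree(phy)
}

tip_ages_of <- function(tr) {
  n <- length(tr$phy$tip.label)
  stats::setNames(tr$age[seq_len(n)], tr$phy$tip.label)
}

strat_records_for_test <- function(df) {
  if (!"younger_material" %in% names(df)) df$younger_material <- NA_real_
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  on.exit(unlink(f))
  load_strat_ranges(f)
}
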