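# Synthetic data: fossilized birth-death trees, relaxed-clock branch
# rates, Mk(+Gamma) discrete characters with recorded ground truth --------

#' Simulation configuration
#'
#' Defaults emulate the shape of a ~90-taxon, 272-character
#' total-evidence dataset spanning ~38 Ma: birth/death rates giving
#' marine-mammal-like species durations of 2-3 Ma with a modest extant
#' crown, a fossil-sampling rate recovering most extinct lineages, a
#' relaxed clock with independent gamma branch-rate multipliers, mostly
#' binary characters with ~25/272 ordered, gamma rate variation across
#' characters, and 43% missing data.
#'
#' @param lambda birth rate (events/lineage/Ma).
#' @param mu death rate.
#' @param psi fossil-sampling rate along extinct lineages.
#' @param origin_age origin of the process, Ma before present.
#' @param clock_mean overall clock rate, expected changes per character
#'   per Ma.
#' @param clock_sd spread of the clock rate (0 = fixed; if positive the
#'   realized clock is drawn from a truncated normal).
#' @param igr_var variance of the independent-gamma branch-rate
#'   multipliers (mean 1); 0 gives a strict clock.
#' @param n_characters number of discrete characters.
#' @param states_per_character a single state count applied to all
#'   characters, or `NULL` to draw 2/3/4 states per character with
#'   probabilities 0.65/0.25/0.10.
#' @param ordered_fraction fraction of characters treated as ordered
#'   transition series (only characters with >= 3 states are eligible).
#' @param gamma_shape shape of the gamma (mean 1) across-character rate
#'   factors; `Inf` disables rate variation across characters.
#' @param missing_fraction fraction of tip cells deleted.
#' @param missing_bias `"uniform"` deletion, or `"taxon"` for
#'   fragmentary-fossil emulation (per-taxon deletion propensities drawn
#'   from a beta distribution with the configured mean).
#' @param epoch_multipliers optional data frame `older, younger, mult`
#'   applying a multiplicative rate regime inside age windows (e.g. an
#'   early burst).
#' @param strat_window width (Ma) of the uniform stratigraphic-age
#'   window emitted around each fossil tip's true age.
#' @param min_tips,max_tips accepted sampled-tip range; draws outside it
#'   are rejected and redrawn. The default 70-115 keeps fixtures near the
#'   ~90-taxon shape being emulated.
#' @param seed RNG seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(lambda = 0.45, mu = 0.37, psi = 0.5,
                       origin_age = 38,
                       clock_mean = 0.01, clock_sd = 0,
                       igr_var = 0.1,
                       n_characters = 272, states_per_character = NULL,
                       ordered_fraction = 25 / 272,
                       gamma_shape = 0.5,
                       missing_fraction = 0.43,
                       missing_bias = c("uniform", "taxon"),
                       epoch_multipliers = NULL,
                       strat_window = 2,
                       min_tips = 70, max_tips = 115,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config")
  missing_bias <- match.arg(missing_bias)
  stopifnot(lambda > 0, mu >= 0, psi >= 0, origin_age > 0,
            clock_mean >= 0, clock_sd >= 0, igr_var >= 0,
            n_characters >= 1, ordered_fraction >= 0, ordered_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            gamma_shape > 0, strat_window >= 0, min_tips >= 2)
  if (!is.null(epoch_multipliers))
    stopifnot(is.data.frame(epoch_multipliers),
              all(c("older", "younger", "mult") %in%
                    names(epoch_multipliers)),
              all(epoch_multipliers$mult >= 0))
  structure(list(lambda = lambda, mu = mu, psi = psi,
                 origin_age = origin_age, clock_mean = clock_mean,
                 clock_sd = clock_sd, igr_var = igr_var,
                 n_characters = n_characters,
                 states_per_character = states_per_character,
                 ordered_fraction = ordered_fraction,
                 gamma_shape = gamma_shape,
                 missing_fraction = missing_fraction,
                 missing_bias = missing_bias,
                 epoch_multipliers = epoch_multipliers,
                 strat_window = strat_window,
                 min_tips = min_tips, max_tips = max_tips,
                 seed = as.integer(seed)),
            class = "sim_config")
}

epoch_mult_at <- function(age, epochs) {
  if (is.null(epochs)) return(rep(1, length(age)))
  out <- rep(1, length(age))
  for (i in seq_len(nrow(epochs))) {
    inside <- age <= epochs$older[i] & age > epochs$younger[i]
    out[inside] <- out[inside] * epochs$mult[i]
  }
  out
}

#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from a single lineage at the origin
#' age. Extant survivors become age-0 tips; extinct lineages are
#' retained as fossil tips when they carry at least one psi-sampling
#' event, dated to their oldest sample (later samples on the same
#' pendant lineage are recorded as younger referred material). Samples
#' on internal branches (would-be sampled ancestors) are dropped.
#' Rejected and redrawn until the sampled tip count lies in
#' `[min_tips, max_tips]`; 1000 consecutive rejections abort with an
#' error.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `tree` (a [dated_tree()], root at the MRCA of the
#'   sampled tips), `strat` (a `strat_records` table with uniform
#'   windows of width `strat_window` around true fossil ages), and
#'   `truth` (true tip ages, root and origin age, attempt count).
#' @export
simulate_fbd_tree <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  for (attempt in seq_len(1000L)) {
    sim <- fbd_forward_once(cfg)
    if (is.null(sim)) next
    ntips <- length(sim$tip_label)
    if (ntips >= cfg$min_tips && ntips <= cfg$max_tips) {
      tree <- dated_tree(sim$phy, anchor = sim$tip_age[which.min(sim$tip_age)])
      # anchor by explicit table for exactness
      tree$age <- sim$age
      tree$root_age <- sim$age[length(sim$tip_label) + 1L]
      strat <- make_strat(sim, cfg)
      truth <- list(tip_age = stats::setNames(sim$tip_age, sim$tip_label),
                    root_age = tree$root_age, origin_age = cfg$origin_age,
                    n_attempts = attempt)
      return(list(tree = tree, strat = strat, truth = truth))
    }
  }
  stop("1000 consecutive rejected draws; adjust lambda/mu/psi or the ",
       "accepted tip range")
}

# one forward draw; returns NULL if rejected (no/too many lineages)
fbd_forward_once <- function(cfg) {
  T <- cfg$origin_age
  lam <- cfg$lambda; mu <- cfg$mu; psi <- cfg$psi
  max_lin <- 20000L

  # grow flat lineage table
  n_alloc <- 256L
  start <- end <- numeric(n_alloc)
  fate <- character(n_alloc)           # "extant" | "extinct" | "split"
  child1 <- child2 <- integer(n_alloc)
  samples <- vector("list", n_alloc)
  n_lin <- 0L
  new_lineage <- function(t0) {
    n_lin <<- n_lin + 1L
    if (n_lin > length(start)) {
      grow <- function(v, fill) c(v, rep(fill, length(v)))
      start <<- grow(start, 0); end <<- grow(end, 0)
      fate <<- grow(fate, ""); child1 <<- grow(child1, 0L)
      child2 <<- grow(child2, 0L)
      length(samples) <<- 2L * length(samples)
    }
    start[n_lin] <<- t0
    n_lin
  }
  root_id <- new_lineage(0)
  stack <- root_id
  while (length(stack)) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (n_lin > max_lin) return(NULL)
    t0 <- start[id]
    wait <- if (lam + mu > 0) stats::rexp(1, lam + mu) else Inf
    t1 <- t0 + wait
    if (t1 >= T) {
      end[id] <- T; fate[id] <- "extant"
    } else {
      end[id] <- t1
      if (stats::runif(1) < lam / (lam + mu)) {
        fate[id] <- "split"
        c1 <- new_lineage(t1); c2 <- new_lineage(t1)
        child1[id] <- c1; child2[id] <- c2
        stack <- c(stack, c1, c2)
      } else fate[id] <- "extinct"
    }
    if (psi > 0 && fate[id] == "extinct") {
      ns <- stats::rpois(1, psi * (end[id] - t0))
      if (ns > 0) samples[[id]] <- sort(stats::runif(ns, t0, end[id]))
    }
  }

  retained <- logical(n_lin)
  # postorder over lineage ids (children have larger ids than parents)
  for (id in n_lin:1) {
    retained[id] <- fate[id] == "extant" || length(samples[[id]]) > 0 ||
      (fate[id] == "split" && (retained[child1[id]] || retained[child2[id]]))
  }
  if (!retained[root_id]) return(NULL)

  # build pruned node structure (suppress unary chains, drop internal
  # samples = no sampled ancestors)
  tip_label <- character(0); tip_age <- numeric(0); tip_ym <- numeric(0)
  n_ext <- 0L; n_fos <- 0L
  build <- function(id) {
    repeat {
      kids <- if (fate[id] == "split")
        Filter(function(k) retained[k], c(child1[id], child2[id]))
      else integer(0)
      if (length(kids) == 1L) { id <- kids[[1L]]; next }
      if (length(kids) == 2L)
        return(list(age = T - end[id],
                    children = list(build(kids[[1L]]), build(kids[[2L]]))))
      # leaf
      if (fate[id] == "extant") {
        n_ext <<- n_ext + 1L
        lab <- paste0("t", n_ext)
        tip_label <<- c(tip_label, lab); tip_age <<- c(tip_age, 0)
        tip_ym <<- c(tip_ym, NA_real_)
        return(list(age = 0, label = lab))
      }
      sm <- samples[[id]]
      n_fos <<- n_fos + 1L
      lab <- paste0("f", n_fos)
      age <- T - sm[1L]                       # oldest sample
      ym <- if (length(sm) > 1L) T - sm[length(sm)] else NA_real_
      tip_label <<- c(tip_label, lab); tip_age <<- c(tip_age, age)
      tip_ym <<- c(tip_ym, ym)
      return(list(age = age, label = lab))
    }
  }
  top <- build(root_id)
  if (length(tip_label) < 2L) return(NULL)

  # convert the nested structure to an ape phylo with exact ages
  n <- length(tip_label)
  edge <- matrix(0L, 0, 2); edge_len <- numeric(0)
  age_vec <- numeric(2L * n)               # upper bound
  next_internal <- n + 1L
  assign_ids <- function(node) {
    if (!is.null(node$label)) {
      i <- match(node$label, tip_label)
      age_vec[i] <<- node$age
      return(i)
    }
    my <- next_internal; next_internal <<- next_internal + 1L
    age_vec[my] <<- node$age
    for (ch in node$children) {
      ci <- assign_ids(ch)
      edge <<- rbind(edge, c(my, ci))
      edge_len <<- c(edge_len, node$age - age_vec[ci])
    }
    my
  }
  root_node <- assign_ids(top)
  nnode <- next_internal - 1L - n
  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = tip_label, Nnode = nnode),
                   class = "phylo", order = "cladewise")
  list(phy = phy, tip_label = tip_label, tip_age = tip_age, tip_ym = tip_ym,
       age = age_vec[seq_len(n + nnode)])
}

make_strat <- function(sim, cfg) {
  w <- cfg$strat_window
  fossil <- sim$tip_age > 1e-9
  oldest <- ifelse(fossil, sim$tip_age + w / 2, 0)
  youngest <- ifelse(fossil, pmax(sim$tip_age - w / 2, 0), 0)
  ym <- sim$tip_ym
  ym[!is.na(ym) & ym > youngest] <- NA    # keep ym strictly beyond range end
  strat_records(data.frame(taxon = sim$tip_label, oldest = oldest,
                           youngest = youngest, younger_material = ym,
                           stringsAsFactors = FALSE))
}

#' Simulate independent-gamma relaxed-clock branch rates
#'
#' One i.i.d. gamma multiplier (mean 1, variance `nu`) per branch;
#' `nu = 0` is the strict-clock limit (all multipliers exactly 1).
#'
#' @param tree a [dated_tree()].
#' @param nu variance of the multipliers.
#' @param seed optional RNG seed.
#' @return numeric vector, one multiplier per row of `tree$phy$edge`.
#' @export
simulate_branch_rates <- function(tree, nu, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"), nu >= 0)
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(tree$phy$edge)
  if (nu == 0) rep(1, ne)
  else stats::rgamma(ne, shape = 1 / nu, rate = 1 / nu)
}

#' Simulate discrete characters along a dated tree
#'
#' Per character: a gamma (mean 1) rate factor; a continuous-time
#' k-state Markov chain evolved along every branch with total change
#' rate `clock_mean x branch multiplier x character factor x epoch
#' multiplier(age)`. Unordered characters jump to a uniformly chosen
#' other state; ordered characters step to a neighbouring state
#' (reflecting at the ends). Cells are then deleted at the configured
#' missing fraction. The full change history, root states, pre-deletion
#' tip states and deletion mask are recorded; replaying the history from
#' the root states reproduces the emitted tip states exactly.
#'
#' @param tree a [dated_tree()].
#' @param multipliers per-branch rate multipliers
#'   (from [simulate_branch_rates()]).
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return list with `matrix` (a [character_matrix()] over the tree
#'   tips) and `truth` (`root_states`, `char_factors`, `nstates`,
#'   `ordered`, `history` data frame, `full_states` pre-deletion tip
#'   matrix, `mask` logical deletion matrix, `branch_mean_mult`
#'   duration-averaged epoch-x-branch multiplier per edge).
#' @export
simulate_characters <- function(tree, multipliers, cfg, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phy
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  ne <- nrow(phy$edge)
  stopifnot(length(multipliers) == ne)
  nc <- cfg$n_characters

  k_per <- if (!is.null(cfg$states_per_character))
    rep(as.integer(cfg$states_per_character), nc)
  else sample(2:4, nc, replace = TRUE, prob = c(0.65, 0.25, 0.10))
  if (any(k_per < 2L)) stop("characters need at least 2 states")

  eligible <- which(k_per >= 3L)
  n_ord <- min(length(eligible), round(cfg$ordered_fraction * nc))
  ordered <- rep(FALSE, nc)
  if (n_ord > 0)
    ordered[sample(eligible, n_ord)] <- TRUE

  clock <- if (cfg$clock_sd > 0) {
    cl <- -1
    while (cl <= 0) cl <- stats::rnorm(1, cfg$clock_mean, cfg$clock_sd)
    cl
  } else cfg$clock_mean

  char_factors <- if (is.finite(cfg$gamma_shape))
    stats::rgamma(nc, shape = cfg$gamma_shape, rate = cfg$gamma_shape)
  else rep(1, nc)

  # branch segments split at epoch boundaries (ages, older -> younger)
  epochs <- cfg$epoch_multipliers
  seg_of <- function(a0, a1) {
    cuts <- sort(unique(c(a0, a1,
                          if (!is.null(epochs))
                            c(epochs$older, epochs$younger))), decreasing = TRUE)
    cuts <- cuts[cuts <= a0 & cuts >= a1]
    if (cuts[1L] != a0) cuts <- c(a0, cuts)
    if (cuts[length(cuts)] != a1) cuts <- c(cuts, a1)
    cbind(older = cuts[-length(cuts)], younger = cuts[-1L])
  }
  edge_segments <- lapply(seq_len(ne), function(e) {
    a0 <- tree$age[phy$edge[e, 1L]]; a1 <- tree$age[phy$edge[e, 2L]]
    s <- seg_of(a0, a1)
    s <- s[s[, 1L] - s[, 2L] > 0, , drop = FALSE]
    s
  })
  branch_mean_mult <- vapply(seq_len(ne), function(e) {
    s <- edge_segments[[e]]
    if (!nrow(s)) return(multipliers[e])
    len <- s[, 1L] - s[, 2L]
    em <- epoch_mult_at((s[, 1L] + s[, 2L]) / 2, epochs)
    multipliers[e] * sum(len * em) / sum(len)
  }, numeric(1))

  po <- ape::reorder.phylo(phy, "postorder")
  pre_edges <- rev(seq_len(nrow(po$edge)))  # preorder over po$edge
  po_to_orig <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                      paste(phy$edge[, 1L], phy$edge[, 2L]))

  root_states <- integer(nc)
  full <- matrix(NA_integer_, n, nc)
  hist_by_char <- vector("list", nc)

  for (j in seq_len(nc)) {
    k <- k_per[j]
    s_root <- sample.int(k, 1L) - 1L
    root_states[j] <- s_root
    node_state <- integer(ntot)
    root_node <- po$edge[nrow(po$edge), 1L]
    node_state[root_node] <- s_root
    base <- clock * char_factors[j]
    h_edge <- integer(0); h_age <- numeric(0)
    h_from <- h_to <- integer(0)
    for (ei in pre_edges) {
      p <- po$edge[ei, 1L]; ch <- po$edge[ei, 2L]
      e_orig <- po_to_orig[ei]
      segs <- edge_segments[[e_orig]]
      s <- node_state[p]
      if (nrow(segs)) for (si in seq_len(nrow(segs))) {
        R <- base * multipliers[e_orig] *
          epoch_mult_at((segs[si, 1L] + segs[si, 2L]) / 2, epochs)
        if (R <= 0) next
        t <- segs[si, 1L]
        repeat {
          t <- t - stats::rexp(1, R)
          if (t <= segs[si, 2L]) break
          s_new <- jump_state(s, k, ordered[j])
          h_edge <- c(h_edge, e_orig); h_age <- c(h_age, t)
          h_from <- c(h_from, s); h_to <- c(h_to, s_new)
          s <- s_new
        }
      }
      node_state[ch] <- s
    }
    full[, j] <- node_state[seq_len(n)]
    if (length(h_edge))
      hist_by_char[[j]] <- data.frame(char = j, edge = h_edge, age = h_age,
                                      from = h_from, to = h_to)
  }
  history <- if (any(!vapply(hist_by_char, is.null, logical(1))))
    do.call(rbind, hist_by_char)
  else data.frame(char = integer(0), edge = integer(0), age = numeric(0),
                  from = integer(0), to = integer(0))

  mask <- matrix(FALSE, n, nc)
  if (cfg$missing_fraction > 0) {
    p <- if (cfg$missing_bias == "taxon") {
      f <- cfg$missing_fraction
      b <- 2 * (1 - f) / f
      stats::rbeta(n, 2, b)
    } else rep(cfg$missing_fraction, n)
    mask[] <- stats::runif(n * nc) < rep(p, nc)
  }

  m <- matrix(as.character(full), n, nc,
              dimnames = list(phy$tip.label, paste0("c", seq_len(nc))))
  m[mask] <- NA_character_
  cm <- character_matrix(m, ordered = ordered, nstates = k_per)
  rownames(history) <- NULL
  list(matrix = cm,
       truth = list(root_states = root_states, char_factors = char_factors,
                    nstates = k_per, ordered = ordered, history = history,
                    full_states = full, mask = mask,
                    branch_mean_mult = branch_mean_mult,
                    clock = clock))
}

jump_state <- function(s, k, ordered) {
  if (ordered) {
    if (s == 0L) 1L
    else if (s == k - 1L) k - 2L
    else s + sample(c(-1L, 1L), 1L)
  } else {
    others <- setdiff(0:(k - 1L), s)
    if (length(others) == 1L) others else sample(others, 1L)
  }
}

#' Generate a complete synthetic fixture on disk
#'
#' Draws a fossilized birth-death tree, branch-rate multipliers and a
#' character matrix under one configuration and writes five files to
#' `outdir`: `tree.nwk` (Newick with `[&rate=...]` branch comments),
#' `matrix.nex`, `strat.csv`, `truth.json` and `config.json`. Re-running
#' with the same configuration reproduces byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return (invisibly) list with the simulated objects and file paths.
#' @export
generate_fixture <- function(cfg, outdir, force = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fbd <- simulate_fbd_tree(cfg, seed = cfg$seed)
  rates <- simulate_branch_rates(fbd$tree, cfg$igr_var,
                                 seed = cfg$seed + 1L)
  chars <- simulate_characters(fbd$tree, rates, cfg, seed = cfg$seed + 2L)
  tree <- fbd$tree
  tree$rates <- rates

  paths <- list(tree = file.path(outdir, "tree.nwk"),
                matrix = file.path(outdir, "matrix.nex"),
                strat = file.path(outdir, "strat.csv"),
                truth = file.path(outdir, "truth.json"),
                config = file.path(outdir, "config.json"))
  write_dated_tree(tree, paths$tree, digits = 15)
  write_character_matrix(chars$matrix, paths$matrix)
  write_strat_ranges(fbd$strat, paths$strat)
  truth <- list(tree = fbd$truth,
                rates = rates,
                characters = chars$truth[c("root_states", "char_factors",
                                           "nstates", "ordered", "clock")],
                history = chars$truth$history,
                mask_cells = which(chars$truth$mask))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_out <- cfg
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(tree = tree, strat = fbd$strat, matrix = chars$matrix,
                 rates = rates, truth = chars$truth, fbd_truth = fbd$truth,
                 paths = paths))
}
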