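# Fossilized birth-death simulator, branch rates, characters ---------------

test_that("pure-birth tip counts match the exponential-growth expectation", {
  set.seed(401)
  cfg <- sim_config(lambda = 0.1, mu = 0, psi = 0, origin_age = 38,
                    min_tips = 2, max_tips = 100000, seed = 401)
  n_rep <- 400
  tips <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    fbd <- simulate_fbd_tree(cfg, seed = 401 + r)
    tips[r] <- length(fbd$tree$phy$tip.label)
  }
  expected <- exp(0.1 * 38)  # ~44.7
  expect_lt(abs(mean(tips) - expected) / expected, 0.15)
})

test_that("simulated trees are internally consistent and deterministic", {
  cfg <- sim_config(seed = 409, min_tips = 20, max_tips = 120)
  a <- simulate_fbd_tree(cfg)
  b <- simulate_fbd_tree(cfg)
  expect_identical(ape::write.tree(a$tree$phy), ape::write.tree(b$tree$phy))
  expect_identical(a$tree$age, b$tree$age)

  bt <- branch_table(a$tree)
  expect_true(all(bt$duration >= 0))
  expect_true(all(bt$parent_age >= bt$child_age))
  ta <- tip_ages_of(a$tree)
  expect_true(all(ta >= 0 & ta <= cfg$origin_age))
  # stratigraphic windows bracket the true fossil ages
  st <- a$strat
  fos <- st[st$oldest > 0, ]
  expect_true(all(fos$oldest >= ta[fos$taxon]))
  expect_true(all(fos$youngest <= ta[fos$taxon]))
})

test_that("igr branch-rate draws have mean 1, variance nu, and a strict
           clock limit", {
  cfg <- sim_config(seed = 419, min_tips = 20, max_tips = 120)
  fbd <- simulate_fbd_tree(cfg)
  expect_identical(simulate_branch_rates(fbd$tree, 0),
                   rep(1, nrow(fbd$tree$phy$edge)))
  set.seed(5)
  draws <- stats::rgamma(1e4, shape = 1 / 0.5, rate = 1 / 0.5)
  # large-sample moment check of the same generator settings
  r <- simulate_branch_rates(fbd$tree, 0.5, seed = 5)
  expect_identical(r, draws[seq_along(r)])
  se <- sqrt(0.5 / 1e4)
  expect_lt(abs(mean(draws) - 1), 3 * se)
  expect_identical(simulate_branch_rates(fbd$tree, 0.5, seed = 5),
                   simulate_branch_rates(fbd$tree, 0.5, seed = 5))
})

test_that("zero clock rate gives an invariant matrix equal to the root
           states", {
  cfg <- sim_config(seed = 421, clock_mean = 0, n_characters = 30,
                    missing_fraction = 0, min_tips = 10, max_tips = 60)
  fbd <- simulate_fbd_tree(cfg)
  sim <- simulate_characters(fbd$tree,
                             simulate_branch_rates(fbd$tree, 0.1), cfg)
  expect_equal(nrow(sim$truth$history), 0L)
  for (j in 1:30)
    expect_true(all(sim$matrix$data[, j] ==
                      as.character(sim$truth$root_states[j])))
  aud <- audit_matrix(sim$matrix)
  expect_equal(length(aud$invariant_characters), 30L)
})

test_that("at high rates unordered characters reach the uniform
           stationary distribution", {
  phy <- ape::read.tree(text = "(A:3,B:3);")
  tr <- dated_tree(phy)
  cfg <- sim_config(seed = 431, clock_mean = 5, n_characters = 4000,
                    states_per_character = 4, ordered_fraction = 0,
                    gamma_shape = Inf, missing_fraction = 0,
                    min_tips = 2, max_tips = 10)
  sim <- simulate_characters(tr, rep(1, 2), cfg, seed = 431)
  counts <- table(factor(sim$matrix$data, levels = as.character(0:3)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("realized change counts match the Poisson expectation", {
  set.seed(433)
  cfg <- sim_config(seed = 433, n_characters = 150, gamma_shape = Inf,
                    igr_var = 0, missing_fraction = 0,
                    states_per_character = 3,
                    min_tips = 30, max_tips = 120)
  fbd <- simulate_fbd_tree(cfg)
  mult <- simulate_branch_rates(fbd$tree, 0)
  sim <- simulate_characters(fbd$tree, mult, cfg)
  total_len <- sum(branch_table(fbd$tree)$duration)
  expected <- 150 * cfg$clock_mean * total_len
  observed <- nrow(sim$truth$history)
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1)
})

test_that("replaying the recorded change history reproduces the
           pre-deletion tip states", {
  cfg <- sim_config(seed = 439, n_characters = 60, min_tips = 15,
                    max_tips = 60)
  fbd <- simulate_fbd_tree(cfg)
  mult <- simulate_branch_rates(fbd$tree, cfg$igr_var, seed = 440)
  sim <- simulate_characters(fbd$tree, mult, cfg, seed = 441)
  phy <- fbd$tree$phy
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  h <- sim$truth$history
  for (j in seq_len(60)) {
    state <- integer(n + phy$Nnode)
    state[po$edge[nrow(po$edge), 1]] <- sim$truth$root_states[j]
    for (ei in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
      e_orig <- which(phy$edge[, 1] == p & phy$edge[, 2] == ch)
      s <- state[p]
      ev <- h[h$char == j & h$edge == e_orig, ]
      if (nrow(ev)) {
        ev <- ev[order(ev$age, decreasing = TRUE), ]
        # each recorded jump must chain from the current state
        expect_equal(ev$from[1], s)
        s <- ev$to[nrow(ev)]
      }
      state[ch] <- s
    }
    expect_identical(state[seq_len(n)], sim$truth$full_states[, j])
  }
})

test_that("fixtures are complete, readable and byte-identical across
           runs; deletion hits the configured fraction", {
  cfg <- sim_config(seed = 443, n_characters = 120, min_tips = 40,
                    max_tips = 110)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx <- generate_fixture(cfg, d1, force = TRUE)
  generate_fixture(cfg, d2, force = TRUE)
  files <- c("tree.nwk", "matrix.nex", "strat.csv", "truth.json",
             "config.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # refuse to clobber without force
  expect_error(generate_fixture(cfg, d1), "force")

  # read-back passes the io validations and matches the in-memory objects
  tr <- read_dated_tree(file.path(d1, "tree.nwk"),
                        anchor = tip_ages_of(fx$tree)[
                          which.min(tip_ages_of(fx$tree))])
  labs <- fx$tree$phy$tip.label
  expect_equal(tip_ages_of(tr)[labs], tip_ages_of(fx$tree)[labs],
               tolerance = 1e-9)
  cm <- read_character_matrix(file.path(d1, "matrix.nex"))
  expect_identical(cm$data, fx$matrix$data[cm$taxa, ])
  expect_identical(cm$ordered, fx$matrix$ordered)
  st <- load_strat_ranges(file.path(d1, "strat.csv"), tree = tr)
  expect_setequal(st$taxon, tr$phy$tip.label)

  aud <- audit_matrix(cm)
  expect_lt(abs(aud$missing_fraction - cfg$missing_fraction), 0.02)
})

test_that("epoch multipliers scale realized change counts inside their
           window", {
  set.seed(449)
  epochs <- data.frame(older = 38, younger = 28, mult = 5)
  cfg <- sim_config(seed = 449, n_characters = 150, gamma_shape = Inf,
                    igr_var = 0, missing_fraction = 0,
                    states_per_character = 4,
                    epoch_multipliers = epochs,
                    min_tips = 40, max_tips = 110)
  fbd <- simulate_fbd_tree(cfg)
  sim <- simulate_characters(fbd$tree, simulate_branch_rates(fbd$tree, 0),
                             cfg)
  h <- sim$truth$history
  early <- sum(h$age > 28)
  late <- sum(h$age <= 28)
  # expected change counts are rate x lineage-duration inside each window
  bt <- branch_table(fbd$tree)
  len_early <- sum(pmax(0, pmin(bt$parent_age, 38) -
                          pmax(bt$child_age, 28)))
  len_late <- sum(pmax(0, pmin(bt$parent_age, 28) - bt$child_age))
  exp_early <- 150 * cfg$clock_mean * 5 * len_early
  exp_late <- 150 * cfg$clock_mean * len_late
  expect_lt(abs(early - exp_early), 4 * sqrt(exp_early) + 1)
  expect_lt(abs(late - exp_late), 4 * sqrt(exp_late) + 1)
})
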