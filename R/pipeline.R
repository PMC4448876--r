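# Pipeline orchestration ---------------------------------------------------

#' Build a run configuration
#'
#' Exactly one of `inputs` (paths to a tree, matrix and optional
#' stratigraphic table on disk) or `simulation` (a [sim_config()]) must
#' be given.
#'
#' @param inputs list with `tree`, `matrix`, and optionally `strat`
#'   (file paths), plus optionally `anchor` (tip-age anchor for the
#'   tree).
#' @param simulation a [sim_config()].
#' @param bins list `oldest, youngest, step` (default 37/0/1).
#' @param disparity list of options: `k_axes` (NULL = by threshold),
#'   `variance_threshold` (0.95), `n_boot` (1000), `ci_level` (0.95),
#'   `n_sub` (8).
#' @param rates list of options: `clock_rate` (0.0018 changes per
#'   character per Ma unless the run is simulated, in which case the
#'   simulation's clock mean is used), `mode` (`"overlap"`).
#' @param seed RNG seed for every stochastic stage (mandatory).
#' @return a `run_config` list.
#' @export
run_config <- function(inputs = NULL, simulation = NULL,
                       bins = list(oldest = 37, youngest = 0, step = 1),
                       disparity = list(), rates = list(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (is.null(inputs) == is.null(simulation))
    stop("exactly one of `inputs` or `simulation` must be given")
  disp <- utils::modifyList(list(k_axes = NULL, variance_threshold = 0.95,
                                 n_boot = 1000, ci_level = 0.95, n_sub = 8),
                            disparity)
  rt <- utils::modifyList(list(clock_rate = NULL, mode = "overlap"), rates)
  stopifnot(bins$step > 0)
  structure(list(inputs = inputs, simulation = simulation, bins = bins,
                 disparity = disp, rates = rt, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file; keys as in [run_config()]; a `simulation`
#'   block is passed to [sim_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(js$simulation)) {
    sim_args <- js$simulation
    if (!is.null(sim_args$epoch_multipliers))
      sim_args$epoch_multipliers <-
        as.data.frame(sim_args$epoch_multipliers)
    if (is.null(sim_args$seed)) sim_args$seed <- js$seed
    sim <- do.call(sim_config, sim_args)
  }
  run_config(inputs = js$inputs, simulation = sim,
             bins = if (!is.null(js$bins)) js$bins else
               list(oldest = 37, youngest = 0, step = 1),
             disparity = if (!is.null(js$disparity)) js$disparity else
               list(),
             rates = if (!is.null(js$rates)) js$rates else list(),
             seed = js$seed)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate inputs; matrix audit; parsimony
#' ancestral states and the augmented sample; disparity (full and
#' rarefied curves); diversity (lineage-through-time); evolutionary
#' rates (absolute per-branch rates and the binned curve). Each stage
#' writes TSV/JSON outputs to `outdir`, and a `manifest.json` records
#' the configuration hash, seed, package version and per-stage row
#' counts. Identical configuration and seed give identical outputs.
#'
#' @param config a `run_config`, or path to a JSON configuration.
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("morphodyn")),
                   stages = list(), complete = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cat("seed: ", config$seed, "\n", sep = "", file = log_path)

  stage <- function(name, expr) {
    logf("stage: ", name)
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs --------------------------------------------------------------
  res <- stage("inputs", {
    if (!is.null(config$simulation)) {
      fx <- generate_fixture(config$simulation,
                             file.path(outdir, "simulated_inputs"),
                             force = TRUE)
      clock <- config$rates$clock_rate
      if (is.null(clock)) clock <- config$simulation$clock_mean
      list(tree = fx$tree, matrix = fx$matrix, strat = fx$strat,
           clock_rate = clock)
    } else {
      inp <- config$inputs
      anchor <- if (!is.null(inp$anchor)) inp$anchor else 0
      tr <- read_dated_tree(inp$tree, anchor = anchor)
      cm <- read_character_matrix(inp$matrix)
      st <- if (!is.null(inp$strat)) load_strat_ranges(inp$strat, tree = tr)
      else NULL
      clock <- config$rates$clock_rate
      if (is.null(clock)) clock <- 0.0018
      list(tree = tr, matrix = cm, strat = st, clock_rate = clock)
    }
  })
  manifest$stages$inputs <- list(
    status = "ok", n_tips = length(res$tree$phy$tip.label),
    n_taxa = length(res$matrix$taxa), n_characters = ncol(res$matrix$data))

  bins <- time_bins(config$bins$oldest, config$bins$youngest,
                    config$bins$step)

  # -- audit ---------------------------------------------------------------
  aud <- stage("audit", audit_matrix(res$matrix))
  jsonlite::write_json(unclass(aud), file.path(outdir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$audit <- list(status = "ok",
                                missing_fraction = aud$missing_fraction)

  # -- ancestral states ----------------------------------------------------
  asr <- stage("asr", {
    dur_ext <- lineage_durations(res$tree, res$strat, use_extensions = TRUE)
    aug <- build_augmented_sample(res$tree, res$matrix, dur_ext)
    write_augmented_sample(aug, file.path(outdir, "augmented_matrix.nex"))
    aug
  })
  manifest$stages$asr <- list(
    status = "ok", n_rows = length(asr$matrix$taxa),
    missing_fraction_augmented = audit_matrix(asr$matrix)$missing_fraction)

  # -- disparity -----------------------------------------------------------
  disp <- stage("disparity", {
    dm <- pairwise_distances(asr)
    write_dist_matrix(dm, file.path(outdir, "distances.tsv"))
    ord <- pcoa_ordination(dm)
    d <- config$disparity
    full <- disparity_curve(ord, asr$durations, bins, k_axes = d$k_axes,
                            variance_threshold = d$variance_threshold,
                            n_boot = d$n_boot, ci_level = d$ci_level,
                            seed = config$seed)
    rare <- rarefied_disparity_curve(ord, asr$durations, bins,
                                     k_axes = d$k_axes,
                                     variance_threshold =
                                       d$variance_threshold,
                                     n_sub = d$n_sub, n_boot = d$n_boot,
                                     ci_level = d$ci_level,
                                     seed = config$seed + 1L)
    write_bin_series(full, file.path(outdir, "disparity.tsv"))
    write_bin_series_json(full, file.path(outdir, "disparity.json"))
    write_bin_series(rare, file.path(outdir, "disparity_rarefied.tsv"))
    list(ordination = ord, full = full, rarefied = rare)
  })
  manifest$stages$disparity <- list(status = "ok",
                                    n_bins_defined = sum(disp$full$defined))

  # -- diversity -----------------------------------------------------------
  ltt <- stage("diversity", {
    dur_ext <- lineage_durations(res$tree, res$strat, use_extensions = TRUE)
    curve <- ltt_curve(dur_ext, bins)
    write_bin_series(curve, file.path(outdir, "diversity.tsv"))
    write_bin_series_json(curve, file.path(outdir, "diversity.json"))
    curve
  })
  manifest$stages$diversity <- list(status = "ok", n_bins = nrow(ltt))

  # -- rates ---------------------------------------------------------------
  ratec <- stage("rates", {
    br <- absolute_branch_rates(res$tree, res$clock_rate)
    write_branch_rates(br, file.path(outdir, "branch_rates.tsv"))
    curve <- binned_rate_curve(br, bins, mode = config$rates$mode)
    write_bin_series(curve, file.path(outdir, "rates.tsv"))
    write_bin_series_json(curve, file.path(outdir, "rates.json"))
    curve
  })
  manifest$stages$rates <- list(status = "ok",
                                n_bins_defined = sum(ratec$defined))

  manifest$complete <- TRUE
  manifest$curves <- c("diversity", "disparity", "rates")
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  cfg_plain <- strip_classes(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_file <- file.path(outdir, "config_used.json")
  writeLines(cfg_json, cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tree = res$tree, matrix = res$matrix, strat = res$strat,
                 audit = aud, augmented = asr, disparity = disp,
                 diversity = ltt, rates = ratec, manifest = manifest,
                 outdir = outdir))
}
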