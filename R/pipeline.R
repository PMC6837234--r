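#' Pipeline configuration
#'
#' A validated bag of paths, model settings and per-stage seeds consumed by
#' [run_stage()] and [run_all()].
#'
#' @param out_dir Output directory (created on demand).
#' @param wordlist,trees,frequencies,overrides Input paths; the first three
#'   default to the files the `simulate` stage writes under `out_dir/sim`.
#' @param tree_format `"newick"` or `"nexus"`.
#' @param theta Cognate clustering threshold (default 0.4).
#' @param linkage Linkage flavour for [flat_cluster()].
#' @param schedule A [chain_schedule()]; default [scaled_down_schedule()].
#'   Using the full-scale default schedule triggers a runtime warning.
#' @param n_chains Replicate chains per meaning (default 3).
#' @param prior,pi_mode,tree_mode Passed to [mcmc_rate()].
#' @param outcome Outcome transform for [fit_model()].
#' @param sim A [sim_config()] for the `simulate` stage.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, wordlist = NULL, trees = NULL,
                            frequencies = NULL, overrides = NULL,
                            tree_format = "newick", theta = 0.4,
                            linkage = "average",
                            schedule = scaled_down_schedule(),
                            n_chains = 3, prior = "uniform",
                            pi_mode = "empirical", tree_mode = "random",
                            outcome = "log", sim = sim_config(),
                            seed = 1L) {
  stopifnot(inherits(schedule, "chain_schedule"), inherits(sim, "sim_config"))
  cfg <- list(out_dir = out_dir, wordlist = wordlist, trees = trees,
              frequencies = frequencies, overrides = overrides,
              tree_format = tree_format, theta = theta, linkage = linkage,
              schedule = schedule, n_chains = n_chains, prior = prior,
              pi_mode = pi_mode, tree_mode = tree_mode, outcome = outcome,
              sim = sim, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tf <- tempfile()
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

## stable per-stage seed derived from the master seed (kept below 2^31)
stage_seed <- function(config, stage) {
  offs <- match(stage, c("simulate", "cognates", "rates", "freq", "regress"))
  (config$seed * 7L + offs * 1000003L) %% 2000000011L
}

log_stage <- function(config, stage, msg)
  message(sprintf("[%s] seed=%d %s", stage, stage_seed(config, stage), msg))

manifest_add <- function(config, stage, files, elapsed) {
  path <- file.path(config$out_dir, "manifest.json")
  entries <- if (file.exists(path)) jsonlite::read_json(path) else list()
  entries[[stage]] <- list(stage = stage, seed = stage_seed(config, stage),
                           config_md5 = config_hash(config),
                           files = as.list(unname(files)),
                           elapsed_s = round(elapsed, 3),
                           time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## write a data.frame atomically (temp file + rename)
write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

default_input <- function(config, field, fname) {
  config[[field]] %||% file.path(config$out_dir, "sim", fname)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic study), `cognates` (word list to
#' cognate classes and a character matrix), `rates` (character matrix +
#' trees to per-meaning replacement rates), `freq` (corpus counts to
#' clfpm), `regress` (rates + clfpm to the mixed-model fit). Outputs are
#' written atomically under `out_dir` and recorded in `manifest.json` with
#' the stage seed and config hash.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return The stage's main result, invisibly for file-producing stages.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "cognates", "rates", "freq", "regress")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; use one of: ",
         paste(stages, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(stage,
    simulate = stage_simulate(config),
    cognates = stage_cognates(config),
    rates = stage_rates(config),
    freq = stage_freq(config),
    regress = stage_regress(config))
  manifest_add(config, stage, attr(res, "files") %||% character(0),
               proc.time()[["elapsed"]] - t0)
  log_stage(config, stage, "done")
  invisible(res)
}

stage_simulate <- function(config) {
  study <- make_study_fixture(config$sim, seed = stage_seed(config, "simulate"),
                              dir = file.path(config$out_dir, "sim"))
  structure(study, files = study$files)
}

stage_cognates <- function(config) {
  wl_path <- default_input(config, "wordlist", "wordlist.csv")
  if (!file.exists(wl_path)) stop("cognates stage: missing input ", wl_path)
  wl <- read_wordlist(wl_path)
  ov <- if (!is.null(config$overrides)) read_overrides(config$overrides)
  parts <- code_all_cognates(wl, theta = config$theta,
                             linkage = config$linkage, overrides = ov)
  taxa <- sort(unique(wl$language))
  chars <- lapply(parts, build_character, taxa = taxa)
  class_csv <- file.path(config$out_dir, "cognate_classes.csv")
  write_atomic(do.call(rbind, parts), class_csv)
  nex <- file.path(config$out_dir, "characters.nex")
  write_character_matrix(chars, nex)
  structure(list(partitions = parts, characters = chars),
            files = c(class_csv, nex))
}

stage_rates <- function(config) {
  nex <- file.path(config$out_dir, "characters.nex")
  tr_path <- default_input(config, "trees", "trees.nwk")
  for (p in c(nex, tr_path))
    if (!file.exists(p)) stop("rates stage: missing input ", p)
  chars <- read_character_matrix(nex)
  trees <- read_tree_sample(tr_path, config$tree_format)
  base <- stage_seed(config, "rates")
  rows <- lapply(seq_along(chars), function(i) {
    chains <- lapply(seq_len(config$n_chains), function(j)
      mcmc_rate(chars[[i]], trees, schedule = config$schedule,
                prior = config$prior, pi_mode = config$pi_mode,
                tree_mode = config$tree_mode,
                seed = (base + i * 101L + j) %% 2000000011L))
    cbind(summarize_rates(chains),
          prior = chains[[1]]$prior,
          schedule = sprintf("%d/%d/%d", config$schedule$total,
                             config$schedule$burnin, config$schedule$thin),
          seed = base)
  })
  rates <- do.call(rbind, rows)
  rates$meaning <- names(chars)
  out <- file.path(config$out_dir, "rates.csv")
  write_atomic(rates, out)
  structure(rates, files = out)
}

stage_freq <- function(config) {
  fr_path <- default_input(config, "frequencies", "frequencies.csv")
  if (!file.exists(fr_path)) stop("freq stage: missing input ", fr_path)
  counts <- read_frequency_table(fr_path)
  clfpm <- exclude_kin_swadesh(aggregate_clfpm(counts))
  out <- file.path(config$out_dir, "clfpm.csv")
  write_atomic(clfpm, out)
  structure(clfpm, files = out)
}

stage_regress <- function(config) {
  rates_csv <- file.path(config$out_dir, "rates.csv")
  clfpm_csv <- file.path(config$out_dir, "clfpm.csv")
  for (p in c(rates_csv, clfpm_csv))
    if (!file.exists(p)) stop("regress stage: missing input ", p)
  rates <- utils::read.csv(rates_csv, stringsAsFactors = FALSE)
  clfpm <- utils::read.csv(clfpm_csv, stringsAsFactors = FALSE)
  flat <- rates$mean_rate <= 0  # invariant characters carry no rate signal
  if (any(flat)) {
    message("dropping ", sum(flat), " meaning(s) with zero estimated rate")
    rates <- rates[!flat, , drop = FALSE]
  }
  tab <- build_regression_table(rates, clfpm)
  fit <- select_random_effects(tab, outcome = config$outcome)
  co <- fit$coefficients
  summ <- data.frame(term = rownames(co), co, row.names = NULL)
  out <- file.path(config$out_dir, "fit_summary.csv")
  write_atomic(summ, out)
  rpt <- file.path(config$out_dir, "fit_report.txt")
  writeLines(c(utils::capture.output(print(fit)),
               "", "AIC comparison of random-effect structures:",
               utils::capture.output(print(fit$aic_table))), rpt)
  structure(fit, files = c(out, rpt))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order
#' (`simulate -> cognates -> rates -> freq -> regress`; `simulate` only
#' when no word-list input is configured). With `resume = TRUE`, stages
#' whose outputs already exist are skipped, so a run interrupted mid-way
#' reuses its completed stages.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip stages whose outputs exist (default FALSE).
#' @return The final `fit_result`.
#' @export
run_all <- function(config, resume = FALSE) {
  if (identical(unclass(config$schedule), unclass(chain_schedule())))
    warning("full-scale chain schedule configured: expect a very long run")
  stage_out <- list(
    simulate = file.path(config$out_dir, "sim", "wordlist.csv"),
    cognates = file.path(config$out_dir, "characters.nex"),
    rates = file.path(config$out_dir, "rates.csv"),
    freq = file.path(config$out_dir, "clfpm.csv"),
    regress = file.path(config$out_dir, "fit_summary.csv"))
  stages <- names(stage_out)
  if (!is.null(config$wordlist)) stages <- setdiff(stages, "simulate")
  res <- NULL
  for (s in stages) {
    if (resume && file.exists(stage_out[[s]])) {
      log_stage(config, s, "outputs present, skipped (resume)")
      next
    }
    res <- run_stage(s, config)
  }
  if (is.null(res) || !inherits(res, "fit_result"))
    res <- stage_regress(config)
  invisible(res)
}
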