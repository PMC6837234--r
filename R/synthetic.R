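#' Simulate a dated ultrametric language phylogeny
#'
#' Pure-birth (Yule) topology on `n` leaves, branch lengths rescaled so
#' every root-to-tip path equals `root_age` years.
#'
#' @param n Number of languages (>= 2).
#' @param root_age Root age in years (default 8,700, the depth assumed for
#'   the language family the package targets).
#' @param seed Optional integer seed.
#' @return A rooted ultrametric `phylo` with tips `lang_01`, `lang_02`, ...
#' @export
simulate_tree <- function(n, root_age = 8700, seed = NULL) {
  if (n < 2) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tree <- if (n == 2) {
    ape::read.tree(text = "(lang_01:1,lang_02:1);")
  } else {
    ape::rphylo(n, birth = 1, death = 0)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * root_age / depth
  tree$tip.label <- sprintf("lang_%02d", seq_len(n))
  tree
}

#' Emulate a posterior spread of trees by branch-length jitter
#'
#' Produces `m` copies of `tree` with each branch length multiplied by an
#' independent lognormal(0, `sd_log`) factor, mimicking the dating
#' uncertainty of a Bayesian posterior sample while keeping the topology
#' fixed.
#'
#' @param tree A `phylo` with branch lengths in years.
#' @param m Number of copies (>= 1).
#' @param sd_log Log-scale standard deviation of the noise (0 gives
#'   identical copies).
#' @param seed Optional integer seed.
#' @return A `tree_sample` of `m` trees.
#' @export
jitter_tree_sample <- function(tree, m, sd_log = 0.05, seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (sd_log < 0) stop("sd_log must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(m), function(i) {
    t2 <- tree
    t2$edge.length <- t2$edge.length *
      stats::rlnorm(length(t2$edge.length), 0, sd_log)
    t2
  })
  tree_sample(trees)
}

## preorder edge traversal with per-edge Poisson event placement; `on_event`
## and `on_drift` transform the inherited value along each edge
evolve_along_tree <- function(tree, event_rate_per_year, root_value,
                              on_event, on_interval = NULL) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  val <- vector("list", ntip + tree$Nnode)
  val[[ntip + 1L]] <- root_value
  n_events <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    v <- val[[pa]]
    k <- stats::rpois(1, event_rate_per_year * len)
    times <- sort(stats::runif(k, 0, len))
    prev <- 0
    for (tt in times) {
      if (!is.null(on_interval)) v <- on_interval(v, tt - prev)
      v <- on_event(v)
      prev <- tt
    }
    if (!is.null(on_interval)) v <- on_interval(v, len - prev)
    n_events <- n_events + k
    val[[ch]] <- v
  }
  list(tips = stats::setNames(val[seq_len(ntip)], tree$tip.label),
       n_events = n_events)
}

#' Simulate a multistate cognate character on a tree
#'
#' Replacement events are placed by a Poisson process along the branches,
#' with the event intensity matched so that the expected *observable*
#' replacement rate equals `R` per 10,000 years:
#' \describe{
#'   \item{infinite_alleles}{every event creates a brand-new class, so the
#'     event rate is `R` itself; the root is class 0. This mirrors how new
#'     cognate classes arise historically and is the default.}
#'   \item{f81}{events draw the new state from `pi` (possibly the current
#'     state), so the event rate is `R / (1 - sum(pi^2))`; the root state is
#'     drawn from `pi`. Under this mode the package's estimator is exactly
#'     well-specified.}
#' }
#'
#' @param tree Dated `phylo`, branch lengths in years.
#' @param R True global replacement rate per 10,000 years (> 0 allowed to
#'   be 0 for a constant character).
#' @param mode `"infinite_alleles"` or `"f81"`.
#' @param pi State frequencies for `f81` mode (default uniform over `k`).
#' @param k Number of states for `f81` mode (default 4).
#' @param seed Optional integer seed.
#' @param meaning Meaning label attached to the character.
#' @return A [multistate_character()] with attributes `n_events` (true
#'   event count) and `true_rate`.
#' @export
simulate_character <- function(tree, R, mode = c("infinite_alleles", "f81"),
                               pi = NULL, k = 4, seed = NULL,
                               meaning = NA_character_) {
  mode <- match.arg(mode)
  if (R < 0) stop("R must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "infinite_alleles") {
    counter <- new.env()
    counter$next_class <- 1L
    res <- evolve_along_tree(tree, R / 1e4, 0L, function(v) {
      cls <- counter$next_class
      counter$next_class <- cls + 1L
      cls
    })
  } else {
    if (is.null(pi)) pi <- rep(1 / k, k)
    check_pi(pi)
    lambda <- R / (1 - sum(pi^2)) / 1e4
    root <- sample.int(length(pi), 1, prob = pi) - 1L
    res <- evolve_along_tree(tree, lambda, root, function(v)
      sample.int(length(pi), 1, prob = pi) - 1L)
  }
  states <- unlist(res$tips)
  ch <- densify_states(multistate_character(states, meaning))
  attr(ch, "n_events") <- res$n_events
  attr(ch, "true_rate") <- R
  ch
}

#' Simulate word-form evolution on a tree
#'
#' Lexical replacement events (rate `R` per 10 kyr) replace the form with an
#' entirely new random one (length 4-8 over `alphabet`) and start a new true
#' cognate class; between events, each segment independently mutates at
#' `drift_prob` per 1,000 years, producing the gradual formal divergence
#' within a class that edit-distance clustering must tolerate.
#'
#' @param tree Dated `phylo`, branch lengths in years.
#' @param R True replacement rate per 10,000 years.
#' @param alphabet Character vector of at least 5 segment symbols.
#' @param drift_prob Per-segment substitution rate per 1,000 years
#'   (default 0.02).
#' @param seed Optional integer seed.
#' @param meaning Meaning label.
#' @return Data frame (`language`, `meaning`, `form`, `true_class`) with one
#'   row per tip.
#' @export
simulate_form_evolution <- function(tree, R, alphabet = letters[1:10],
                                    drift_prob = 0.02, seed = NULL,
                                    meaning = NA_character_) {
  if (length(alphabet) < 5) stop("alphabet must have at least 5 symbols")
  if (!is.null(seed)) set.seed(seed)
  new_form <- function() sample(alphabet, sample(4:8, 1), replace = TRUE)
  counter <- new.env(); counter$next_class <- 1L
  root <- list(form = new_form(), class = 0L)
  res <- evolve_along_tree(
    tree, R / 1e4, root,
    on_event = function(v) {
      cls <- counter$next_class; counter$next_class <- cls + 1L
      list(form = new_form(), class = cls)
    },
    on_interval = function(v, dt) {
      p <- 1 - exp(-drift_prob * dt / 1000)
      hit <- stats::runif(length(v$form)) < p
      if (any(hit)) v$form[hit] <- sample(alphabet, sum(hit), replace = TRUE)
      v
    })
  data.frame(language = names(res$tips), meaning = meaning,
             form = vapply(res$tips, function(v) paste(v$form, collapse = ""),
                           ""),
             true_class = vapply(res$tips, function(v) v$class, 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate corpus counts coupled to replacement rates
#'
#' Each meaning receives a latent log frequency per million,
#' `log fpm_m = a + b * log R*_m + Normal(0, sigma)`, shared across
#' languages; each corpus then contributes a Poisson count with mean
#' `fpm_m * corpus_size / 1e6` for every meaning the corpus's language has
#' a word for.
#'
#' @param truth Data frame with columns `meaning` and `rate` (true R* per
#'   10 kyr).
#' @param wordlist Word-form table supplying the word used per (language,
#'   meaning).
#' @param corpora Data frame describing the corpora: `corpus_id`,
#'   `language`, `corpus_type`, `corpus_size`.
#' @param a,b,sigma Coupling intercept, slope (default -0.58) and Gaussian
#'   noise sd on the log scale.
#' @param seed Optional integer seed.
#' @return List with `counts` (a corpus-counts table as read by
#'   [read_frequency_table()]) and `latent` (meaning, true latent fpm).
#' @export
simulate_frequencies <- function(truth, wordlist, corpora, a = log(50),
                                 b = -0.58, sigma = 0.5, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  lfpm <- a + b * log(truth$rate) + stats::rnorm(nrow(truth), 0, sigma)
  latent <- data.frame(meaning = truth$meaning, fpm = exp(lfpm),
                       stringsAsFactors = FALSE)
  rows <- merge(corpora, wordlist[c("language", "meaning", "form")],
                by = "language")
  rows <- merge(rows, latent, by = "meaning")
  rows$count <- stats::rpois(nrow(rows),
                             rows$fpm * rows$corpus_size / 1e6)
  counts <- data.frame(language = rows$language, word = rows$form,
                       meaning = rows$meaning, corpus_id = rows$corpus_id,
                       corpus_type = rows$corpus_type, count = rows$count,
                       corpus_size = rows$corpus_size,
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$corpus_id, counts$meaning), ]
  rownames(counts) <- NULL
  list(counts = counts, latent = latent)
}

#' Configuration for a synthetic study
#'
#' Defaults emulate the study design the package targets: 47 languages on
#' an 8,700-year phylogeny, a 1,000-tree posterior-like sample, 10 kinship
#' meanings with true replacement rates log-spaced over 0.5-8 per 10 kyr,
#' 190 core-vocabulary meanings with lognormal rates clipped to 0.1-10, and
#' 34 corpora across 21 languages in three register types with sizes of
#' 1e6-1e8 tokens. The frequency-rate coupling slope defaults to -0.58.
#'
#' @param n_languages,root_age,n_trees,sd_log Tree-sample settings.
#' @param kin_rates Named true rates for the ten kin types (per 10 kyr).
#' @param n_swadesh Number of open-class meanings.
#' @param swadesh_rate_meanlog,swadesh_rate_sdlog Lognormal parameters for
#'   open-class true rates.
#' @param coupling_a,coupling_b,coupling_sigma Frequency-rate coupling.
#' @param n_corpora,n_corpus_languages Corpus design.
#' @param corpus_size_range Token-count range (log-uniform).
#' @param alphabet,drift_prob Form-evolution settings.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_languages = 47, root_age = 8700, n_trees = 1000,
                       sd_log = 0.05,
                       kin_rates = stats::setNames(
                         exp(seq(log(0.5), log(8), length.out = 10)),
                         names(kin_types())),
                       n_swadesh = 190,
                       swadesh_rate_meanlog = log(3),
                       swadesh_rate_sdlog = 0.7,
                       coupling_a = log(50), coupling_b = -0.58,
                       coupling_sigma = 0.5,
                       n_corpora = 34, n_corpus_languages = 21,
                       corpus_size_range = c(1e6, 1e8),
                       alphabet = letters[1:10], drift_prob = 0.02) {
  cfg <- list(n_languages = n_languages, root_age = root_age,
              n_trees = n_trees, sd_log = sd_log, kin_rates = kin_rates,
              n_swadesh = n_swadesh,
              swadesh_rate_meanlog = swadesh_rate_meanlog,
              swadesh_rate_sdlog = swadesh_rate_sdlog,
              coupling_a = coupling_a, coupling_b = coupling_b,
              coupling_sigma = coupling_sigma, n_corpora = n_corpora,
              n_corpus_languages = n_corpus_languages,
              corpus_size_range = corpus_size_range, alphabet = alphabet,
              drift_prob = drift_prob)
  if (any(cfg$kin_rates <= 0)) stop("kin rates must be positive")
  if (n_languages < 2 || n_trees < 1 || n_corpora < 1)
    stop("invalid study dimensions")
  if (n_corpus_languages > n_languages)
    stop("more corpus languages than languages")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a full synthetic study
#'
#' Produces an end-to-end consistent bundle: a jittered tree sample, word
#' forms evolved per meaning (with true cognate classes), corpus counts
#' whose latent frequencies are log-linearly coupled to the true rates, and
#' a ground-truth table kept separate from the observables. With `dir` set,
#' all observables are written in the package's standard file formats plus
#' a manifest (file list, seed, config hash); ground truth goes to its own
#' clearly named files.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required: fixtures are reproducible by
#'   construction).
#' @param dir Optional output directory.
#' @return A `synthetic_study` list: `trees`, `wordlist`, `true_classes`,
#'   `counts`, `truth`, `corpora`, `config`, `seed`, and `files` when
#'   written.
#' @export
make_study_fixture <- function(config = sim_config(), seed, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  base_tree <- simulate_tree(config$n_languages, config$root_age)
  trees <- jitter_tree_sample(base_tree, config$n_trees, config$sd_log)

  swadesh <- sprintf("sw_%03d", seq_len(config$n_swadesh))
  sw_rates <- stats::rlnorm(config$n_swadesh, config$swadesh_rate_meanlog,
                            config$swadesh_rate_sdlog)
  sw_rates <- pmin(pmax(sw_rates, 0.1), 10)
  truth <- data.frame(
    meaning = c(names(config$kin_rates), swadesh),
    lexical_class = rep(c("kin", "swadesh"),
                        c(length(config$kin_rates), config$n_swadesh)),
    rate = c(unname(config$kin_rates), sw_rates),
    stringsAsFactors = FALSE)

  forms <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
    simulate_form_evolution(base_tree, truth$rate[i],
                            alphabet = config$alphabet,
                            drift_prob = config$drift_prob,
                            meaning = truth$meaning[i])))
  wordlist <- forms[c("language", "meaning", "form")]
  wordlist$transcription <- NA_character_
  wordlist$lexical_class <- truth$lexical_class[
    match(wordlist$meaning, truth$meaning)]
  ## identical independently replaced forms are possible in principle;
  ## disambiguate to keep (language, meaning, form) unique
  key <- paste(wordlist$language, wordlist$meaning, wordlist$form, sep = "\r")
  if (anyDuplicated(key)) wordlist <- wordlist[!duplicated(key), ]

  langs <- sort(unique(base_tree$tip.label))
  corp_langs <- langs[seq_len(config$n_corpus_languages)]
  corpora <- data.frame(
    corpus_id = sprintf("corpus_%02d", seq_len(config$n_corpora)),
    language = rep(corp_langs, length.out = config$n_corpora),
    corpus_type = rep(c("spoken", "written", "web"),
                      length.out = config$n_corpora),
    corpus_size = round(exp(stats::runif(config$n_corpora,
                                         log(config$corpus_size_range[1]),
                                         log(config$corpus_size_range[2])))),
    stringsAsFactors = FALSE)
  freq <- simulate_frequencies(truth, wordlist, corpora,
                               a = config$coupling_a, b = config$coupling_b,
                               sigma = config$coupling_sigma)

  study <- structure(
    list(trees = trees, wordlist = wordlist,
         true_classes = forms[c("language", "meaning", "form", "true_class")],
         counts = freq$counts,
         truth = merge(truth, freq$latent, by = "meaning", sort = FALSE),
         corpora = corpora, config = config, seed = seed),
    class = "synthetic_study")
  if (!is.null(dir)) study$files <- write_study(study, dir)
  study
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(wordlist = file.path(dir, "wordlist.csv"),
             trees = file.path(dir, "trees.nwk"),
             frequencies = file.path(dir, "frequencies.csv"),
             truth = file.path(dir, "TRUTH_rates_synthetic.csv"),
             true_classes = file.path(dir, "TRUTH_classes_synthetic.csv"))
  utils::write.csv(study$wordlist, paths["wordlist"], row.names = FALSE)
  ape::write.tree(study$trees$trees, paths["trees"])
  utils::write.csv(study$counts, paths["frequencies"], row.names = FALSE)
  utils::write.csv(study$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(study$true_classes, paths["true_classes"],
                   row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(study$config), auto_unbox = TRUE,
                               force = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(seed = study$seed,
                   config_md5 = unname(tools::md5sum(tf)),
                   files = as.list(paths))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  c(paths, manifest = file.path(dir, "manifest.json"))
}

#' Simulate a regression table with known fixed effects
#'
#' Generates the table [fit_model()] consumes, under the model it fits:
#' `log(rate) = b0 + b_freq * clfpm + b_class * [swadesh] +
#' b_int * clfpm * [swadesh] + u_language + noise`, with `u_language ~
#' Normal(0, re_sd)` and Gaussian noise. Used for estimator-recovery
#' studies.
#'
#' @param n_languages,n_kin,n_swadesh Table dimensions (rows =
#'   `n_languages * (n_kin + n_swadesh)`).
#' @param beta Fixed effects `c(intercept, freq, class, interaction)`;
#'   default intercept 0.5, slope -0.58, class 0.2, interaction 0.18.
#' @param re_sd By-language intercept standard deviation.
#' @param sigma Residual standard deviation.
#' @param seed Optional integer seed.
#' @return Regression table with an attribute `beta` recording the truth.
#' @export
simulate_regression_table <- function(n_languages = 20, n_kin = 10,
                                      n_swadesh = 90,
                                      beta = c(0.5, -0.58, 0.2, 0.18),
                                      re_sd = 0.3, sigma = 0.3,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  langs <- sprintf("lang_%02d", seq_len(n_languages))
  meanings <- c(sprintf("kin_%02d", seq_len(n_kin)),
                sprintf("sw_%03d", seq_len(n_swadesh)))
  cls <- rep(c("kin", "swadesh"), c(n_kin, n_swadesh))
  tab <- expand.grid(language = langs, meaning = meanings,
                     stringsAsFactors = FALSE)
  tab$lexical_class <- cls[match(tab$meaning, meanings)]
  tab$clfpm <- stats::rnorm(nrow(tab), 0, 1)
  u <- stats::setNames(stats::rnorm(n_languages, 0, re_sd), langs)
  sw <- as.numeric(tab$lexical_class == "swadesh")
  eta <- beta[1] + beta[2] * tab$clfpm + beta[3] * sw +
    beta[4] * tab$clfpm * sw + u[tab$language] +
    stats::rnorm(nrow(tab), 0, sigma)
  tab$mean_rate <- exp(eta)
  attr(tab, "beta") <- beta
  tab[c("language", "meaning", "lexical_class", "clfpm", "mean_rate")]
}
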