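## Internal time unit for inference is 10,000 years, so the sampled base
## rate is O(1) for realistic replacement rates; input branch lengths are in
## years and are rescaled on entry. Reported rates are per 10 kyr.
YEARS_PER_UNIT <- 1e4

#' Empirical state frequencies of a multistate character
#'
#' Relative frequencies of each observed state among the non-missing tips,
#' with no pseudocounts. These are the stationary frequencies of the
#' frequency-scaled replacement model.
#'
#' @param character A [multistate_character()].
#' @return Numeric vector `pi` of length k (k = number of observed states),
#'   summing to 1.
#' @export
empirical_frequencies <- function(character) {
  s <- character[!is.na(character)]
  if (!length(s)) stop("all tips missing: cannot compute state frequencies")
  as.numeric(table(factor(s, levels = sort(unique(s))))) / length(s)
}

check_pi <- function(pi) {
  if (any(pi <= 0)) stop("state frequencies must be positive")
  if (abs(sum(pi) - 1) > 1e-12) stop("state frequencies must sum to 1")
  pi
}

#' Build the frequency-scaled rate matrix
#'
#' Off-diagonal rates are `q_ij = mu * pi_j`; diagonals make rows sum to
#' zero. This is the k-state generalization of the F81 model: a single base
#' rate scaled by the target state's stationary frequency.
#'
#' @param pi Stationary state frequencies (positive, sum to 1).
#' @param mu Base rate, per unit branch length (years when branch lengths
#'   are in years).
#' @return `k x k` rate matrix Q.
#' @export
build_q <- function(pi, mu) {
  check_pi(pi)
  if (mu < 0) stop("mu must be non-negative")
  k <- length(pi)
  q <- mu * matrix(pi, k, k, byrow = TRUE)
  diag(q) <- -mu * (1 - pi)
  if (k == 1L) {
    q <- matrix(0, 1, 1)
    attr(q, "degenerate") <- TRUE
  }
  q
}

#' Global replacement rate from a rate matrix
#'
#' The stationary-frequency-weighted expected flux of the chain,
#' `R = -sum_i pi_i q_ii`; for [build_q()] this is
#' `mu * (1 - sum(pi^2))` -- the instantaneous rate at which the word in use
#' is replaced by a different one.
#'
#' @param q Rate matrix.
#' @param pi Stationary frequencies.
#' @return Scalar rate in the units of `q`.
#' @export
global_rate <- function(q, pi) {
  check_pi(pi)
  -sum(pi * diag(q))
}

#' Transition probabilities of the frequency-scaled model
#'
#' Closed form `p_ij(t) = pi_j + (delta_ij - pi_j) exp(-mu t)`, the matrix
#' exponential of [build_q()]'s Q.
#'
#' @param pi Stationary frequencies.
#' @param mu Base rate per unit branch length.
#' @param t Elapsed time (same unit), `>= 0`.
#' @return Row-stochastic `k x k` matrix.
#' @export
transition_matrix <- function(pi, mu, t) {
  check_pi(pi)
  if (t < 0) stop("t must be non-negative")
  k <- length(pi)
  e <- exp(-mu * t)
  p <- (1 - e) * matrix(pi, k, k, byrow = TRUE)
  diag(p) <- diag(p) + e
  p
}

#' Convert a per-year rate to per 10,000 years
#'
#' @param r_per_year Rate per year.
#' @return Rate per 10,000 years.
#' @export
scale_rate <- function(r_per_year) r_per_year * YEARS_PER_UNIT

## postorder edge encoding consumed by the C++ pruning kernel;
## branch lengths divided by `time_scale` on entry
prep_tree <- function(tree, time_scale = 1) {
  tree <- stats::reorder(tree, "postorder")
  list(parent = tree$edge[, 1] - 1L, child = tree$edge[, 2] - 1L,
       len = tree$edge.length / time_scale,
       ntip = length(tree$tip.label), nnode = tree$Nnode,
       tip.label = tree$tip.label)
}

## 0-based tip states in a tree's tip order (-1 = missing)
tip_states <- function(character, tip_labels) {
  s <- character[match(tip_labels, names(character))]
  s[is.na(s)] <- -1L
  as.integer(s)
}

## map observed states to 0..k-1 in sorted order (pi is indexed the same way)
densify_states <- function(character) {
  lev <- sort(unique(character[!is.na(character)]))
  st <- match(character, lev) - 1L
  multistate_character(stats::setNames(st, names(character)),
                       attr(character, "meaning"))
}

#' Pruning log-likelihood of a character on a tree
#'
#' Felsenstein's post-order pruning algorithm under the frequency-scaled
#' replacement model, combining the root partials with the stationary
#' frequencies `pi`. Missing tips contribute a partial-likelihood vector of
#' ones.
#'
#' @param tree Rooted `phylo`; branch lengths in the unit of `1/mu`.
#' @param character [multistate_character()] whose taxa are a subset of the
#'   tree's leaves; states must be `0..k-1` with `k = length(pi)`.
#' @param pi Stationary frequencies.
#' @param mu Base rate per unit branch length.
#' @return Log-likelihood (`-Inf` for impossible data).
#' @export
pruning_loglik <- function(tree, character, pi, mu) {
  check_pi(pi)
  if (mu < 0) stop("mu must be non-negative")
  extra <- setdiff(names(character), tree$tip.label)
  if (length(extra))
    stop("character taxa absent from tree: ", paste(extra, collapse = ", "))
  mx <- suppressWarnings(max(character, na.rm = TRUE))
  if (is.finite(mx) && mx >= length(pi))
    stop("character states exceed length(pi)")
  if (length(tree$tip.label) == 1L) {  # single leaf: likelihood is pi[state]
    s <- character[[tree$tip.label]]
    return(if (is.na(s)) 0 else log(pi[s + 1L]))
  }
  pt <- prep_tree(tree)
  .loglik_cpp(pt, tip_states(character, pt$tip.label), pi, mu)
}

#' MCMC chain schedule
#'
#' @param total Total iterations (default 10,010,000).
#' @param burnin Burn-in iterations discarded (default 10,000).
#' @param thin Sampling interval (default 1,000). `(total - burnin)` must be
#'   divisible by `thin`.
#' @return A `chain_schedule` with the derived number of retained draws.
#' @export
#' @examples
#' chain_schedule()$n_draws        # 10,000 retained samples
#' scaled_down_schedule()$n_draws  # 1,000, the desk-scale default
chain_schedule <- function(total = 10010000, burnin = 10000, thin = 1000) {
  if (burnin >= total) stop("burn-in must be smaller than total iterations")
  if (thin < 1) stop("thinning interval must be >= 1")
  if ((total - burnin) %% thin != 0)
    stop("(total - burnin) must be divisible by thin")
  structure(list(total = as.integer(total), burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 n_draws = as.integer((total - burnin) / thin)),
            class = "chain_schedule")
}

#' @rdname chain_schedule
#' @export
scaled_down_schedule <- function() chain_schedule(110000, 10000, 100)

prior_spec <- function(prior = c("uniform", "exponential"),
                       prior_par = NULL) {
  prior <- match.arg(prior)
  if (prior == "uniform")
    list(type = 0L, par = prior_par %||% 100, label = "uniform(0,100)")
  else
    list(type = 1L, par = prior_par %||% 1, label = "exponential(mean 1)")
}

## shared preprocessing for one character: per-tree pruning to the
## character's taxa, postorder encoding in 10-kyr units, tip states, pi
prep_one_char <- function(character, trees, pi_mode, drop_missing) {
  character <- densify_states(character)
  if (all(is.na(character))) stop("all-missing character")
  keep <- names(character)
  if (drop_missing) keep <- names(character)[!is.na(character)]
  if (length(keep) < 2) stop("fewer than 2 scorable taxa")
  pi <- switch(pi_mode,
    empirical = empirical_frequencies(character),
    uniform = {
      k <- length(unique(character[!is.na(character)]))
      rep(1 / k, k)
    })
  pre <- lapply(trees, function(tr) {
    extra <- setdiff(keep, tr$tip.label)
    if (length(extra))
      stop("character taxa absent from a tree: ",
           paste(extra, collapse = ", "))
    if (length(keep) < length(tr$tip.label)) tr <- prune_to_taxa(tr, keep)
    prep_tree(tr, time_scale = YEARS_PER_UNIT)
  })
  states <- lapply(pre, function(p) tip_states(character, p$tip.label))
  list(trees = pre, states = states, pi = pi,
       meaning = attr(character, "meaning"))
}

## preprocessing for one character or a list of replicate characters
## analysed jointly (log-likelihoods add; mu is shared)
prep_inference <- function(characters, trees, pi_mode, drop_missing) {
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)
  if (inherits(trees, "tree_sample")) trees <- trees$trees
  if (inherits(characters, "multistate_character"))
    characters <- list(characters)
  chars <- lapply(characters, prep_one_char, trees = trees,
                  pi_mode = pi_mode, drop_missing = drop_missing)
  ## observable-rate normalization R = mu * (1 - sum(pi^2)); for joint
  ## replicates (one process, several characters) use the mean factor
  c2 <- mean(vapply(chars, function(ch) 1 - sum(ch$pi^2), 1))
  list(chars = chars, ntree = length(trees), c2 = c2,
       meaning = chars[[1]]$meaning,
       pi = if (length(chars) == 1L) chars[[1]]$pi else
         lapply(chars, `[[`, "pi"))
}

#' Posterior sampling of the replacement rate
#'
#' Metropolis-Hastings sampling of the base rate `mu` (Gaussian random walk
#' on `log mu`, step size adapted toward 20-40% acceptance during burn-in
#' and frozen afterwards). Phylogenetic uncertainty is integrated over by
#' proposing, with probability 0.5 per iteration, to replace the current
#' tree with one drawn uniformly from the sample. Retained draws are
#' reported as the normalized global replacement rate `R` per 10,000 years
#' (see [global_rate()]).
#'
#' @param character A [multistate_character()], or a list of replicate
#'   characters for one meaning analysed jointly (their log-likelihoods
#'   add and the base rate is shared).
#' @param trees A `tree_sample`, `multiPhylo` or single `phylo`; branch
#'   lengths in years.
#' @param schedule A [chain_schedule()]; defaults to the desk-scale
#'   [scaled_down_schedule()].
#' @param prior Prior on the base rate in per-10-kyr units: `"uniform"`
#'   (0 to 100, default) or `"exponential"` (mean 1).
#' @param prior_par Upper bound (uniform) or mean (exponential); `NULL` for
#'   the defaults above.
#' @param seed Integer seed; the same (data, seed, schedule) reproduces the
#'   draw sequence exactly.
#' @param tree_mode `"random"` (uniform swap proposals, default),
#'   `"sequential"` (visit trees in order, a fixed share of iterations
#'   each) or `"fixed"` (first tree only; used by the oracle tests).
#' @param pi_mode `"empirical"` (stationary frequencies fixed at the
#'   observed tip frequencies, default) or `"uniform"` (equal-frequency Mk
#'   alternative).
#' @param drop_missing Prune each tree to the taxa with data (default TRUE,
#'   matching the study design); FALSE keeps missing tips with
#'   uninformative partials.
#' @param prior_only Force the likelihood to a constant so the chain
#'   samples the prior (validation mode).
#' @param init_mu,init_step Chain initialization.
#' @return A `rate_posterior`: list with `R` (draws per 10 kyr), `mu`
#'   (base-rate draws), `loglik`, `tree` (per-draw tree index), acceptance
#'   rate, final step size, `pi`, schedule, prior label, seed and meaning.
#' @export
mcmc_rate <- function(character, trees, schedule = scaled_down_schedule(),
                      prior = "uniform", prior_par = NULL, seed = NULL,
                      tree_mode = c("random", "sequential", "fixed"),
                      pi_mode = c("empirical", "uniform"),
                      drop_missing = TRUE, prior_only = FALSE,
                      init_mu = 1, init_step = 0.5) {
  tree_mode <- match.arg(tree_mode)
  pi_mode <- match.arg(pi_mode)
  stopifnot(inherits(schedule, "chain_schedule"))
  if (!is.null(seed)) set.seed(seed)
  inf <- prep_inference(character, trees, pi_mode, drop_missing)
  pr <- prior_spec(prior, prior_par)
  beta <- if (prior_only) 0 else 1
  if (tree_mode == "sequential" && inf$ntree > 1L) {
    res <- mcmc_sequential(inf, pr, schedule, beta, init_mu, init_step)
  } else {
    chars <- inf$chars; ntree <- inf$ntree
    if (tree_mode == "fixed") { chars <- take_tree(chars, 1L); ntree <- 1L }
    res <- .mcmc_cpp(chars, ntree, pr$type, pr$par,
                     schedule$total, schedule$burnin, schedule$thin,
                     init_mu, init_step, beta,
                     tree_moves = tree_mode == "random")
  }
  R <- res$mu * inf$c2
  structure(list(meaning = inf$meaning, R = R,
                 mu = res$mu, loglik = res$loglik, tree = res$tree,
                 acceptance = res$acceptance, step = res$step,
                 pi = inf$pi, schedule = schedule, prior = pr$label,
                 seed = seed),
            class = "rate_posterior")
}

## restrict preprocessed characters to a single tree index
take_tree <- function(chars, t) {
  lapply(chars, function(ch)
    list(trees = ch$trees[t], states = ch$states[t], pi = ch$pi))
}

## sequential visitation: trees in order, each holding the chain for an
## equal share of iterations; burn-in runs entirely on the first tree
mcmc_sequential <- function(inf, pr, schedule, beta, init_mu, init_step) {
  ntree <- inf$ntree
  post <- schedule$total - schedule$burnin
  per <- ceiling(post / ntree)
  per <- per + (schedule$thin - per %% schedule$thin) %% schedule$thin
  warm <- .mcmc_cpp(take_tree(inf$chars, 1L), 1L, pr$type, pr$par,
                    schedule$burnin + schedule$thin, schedule$burnin,
                    schedule$thin, init_mu, init_step, beta, FALSE)
  mu <- warm$mu[length(warm$mu)]; step <- warm$step
  draws <- list()
  for (t in seq_len(ntree)) {
    ch <- .mcmc_cpp(take_tree(inf$chars, t), 1L, pr$type, pr$par,
                    per, 0L, schedule$thin, mu, step, beta, FALSE)
    mu <- ch$mu[length(ch$mu)]
    draws[[t]] <- data.frame(mu = ch$mu, loglik = ch$loglik, tree = t)
  }
  d <- do.call(rbind, draws)
  d <- d[seq_len(min(nrow(d), schedule$n_draws)), , drop = FALSE]
  list(mu = d$mu, loglik = d$loglik, tree = d$tree,
       acceptance = warm$acceptance, step = step)
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat("Rate posterior", if (!is.na(x$meaning)) paste0("'", x$meaning, "'"),
      ":", length(x$R), "draws; mean R =", signif(mean(x$R), 4),
      "per 10 kyr; prior", x$prior, "\n")
  invisible(x)
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Samples the ladder of power posteriors `L^beta * prior` at powers set to
#' quantiles of Beta(0.3, 1), ascending from the prior to the posterior;
#' each stone's chain is warm-started from the previous stone. The log
#' marginal likelihood is the sum over stones of the log mean likelihood
#' ratio between adjacent powers.
#'
#' @inheritParams mcmc_rate
#' @param K Number of stones (default 100).
#' @param iters Retained iterations per stone (default 1,000).
#' @param burn_per_stone Discarded iterations at the start of each stone.
#' @return A `stepping_stone` result: `log_ml`, the powers `beta`, and
#'   per-stone terms.
#' @export
stepping_stone <- function(character, trees, prior = "uniform",
                           prior_par = NULL, K = 100, iters = 1000,
                           burn_per_stone = 200, seed = NULL,
                           pi_mode = c("empirical", "uniform"),
                           drop_missing = TRUE,
                           tree_mode = c("random", "fixed")) {
  pi_mode <- match.arg(pi_mode)
  tree_mode <- match.arg(tree_mode)
  if (!is.null(seed)) set.seed(seed)
  inf <- prep_inference(character, trees, pi_mode, drop_missing)
  chars <- inf$chars; ntree <- inf$ntree
  if (tree_mode == "fixed") { chars <- take_tree(chars, 1L); ntree <- 1L }
  pr <- prior_spec(prior, prior_par)
  beta <- ((0:K) / K)^(1 / 0.3)  # quantiles of Beta(0.3, 1)
  mu <- 1; step <- 0.5
  terms <- numeric(K)
  for (k in seq_len(K)) {
    ch <- .mcmc_cpp(chars, ntree, pr$type, pr$par,
                    burn_per_stone + iters, burn_per_stone, 1L,
                    mu, step, beta[k],  # sample at the lower power beta_{k-1}
                    tree_moves = tree_mode == "random")
    mu <- ch$mu[length(ch$mu)]; step <- ch$step
    w <- (beta[k + 1] - beta[k]) * ch$loglik
    terms[k] <- log_mean_exp(w)
  }
  if (any(!is.finite(terms))) warning("degenerate likelihood in stepping-stone")
  structure(list(log_ml = sum(terms), beta = beta, terms = terms,
                 K = K, iters = iters, prior = pr$label, seed = seed),
            class = "stepping_stone")
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat("Stepping-stone log marginal likelihood:", signif(x$log_ml, 6),
      sprintf("(%d stones x %d iterations, prior %s)\n", x$K, x$iters,
              x$prior))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic (split-chain PSRF)
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed from the between- and within-chain variances of the split
#' chains. Values near 1 indicate convergence; the pass threshold is 1.1.
#'
#' @param chains List of at least 2 equal-length numeric vectors (or
#'   `rate_posterior` objects, whose `R` draws are used).
#' @return A `convergence_report`: `psrf`, `n_chains`, `pass`.
#' @export
gelman_rubin <- function(chains) {
  chains <- lapply(chains, function(ch)
    if (inherits(ch, "rate_posterior")) ch$R else as.numeric(ch))
  if (length(chains) < 2) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 4) stop("chains too short to split")
  half <- floor(n / 2)
  split_chains <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(half)], ch[(n - half + 1):n])), recursive = FALSE)
  m <- length(split_chains)
  means <- vapply(split_chains, mean, 1)
  vars <- vapply(split_chains, stats::var, 1)
  W <- mean(vars)
  B <- half * stats::var(means)
  psrf <- if (W <= 0) 1 else sqrt(((half - 1) / half * W + B / half) / W)
  structure(list(psrf = psrf, n_chains = length(chains),
                 pass = psrf < 1.1),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Gelman-Rubin PSRF = %.4f over %d chains: %s\n", x$psrf,
              x$n_chains, if (x$pass) "pass (< 1.1)" else "FAIL (>= 1.1)"))
  invisible(x)
}

#' Summarize replicate chains for one meaning
#'
#' Pools the post-burn-in draws of the replicate chains (the study runs 3
#' per meaning) and reports the posterior mean and 95% equal-tail credible
#' interval of the replacement rate per 10 kyr, with the split-chain PSRF.
#' A warning is issued if the diagnostic fails.
#'
#' @param chains List of `rate_posterior` objects (or numeric draw vectors)
#'   for one meaning.
#' @return Data frame with `meaning`, `mean_rate`, `ci_lower`, `ci_upper`,
#'   `psrf`, `n_draws`.
#' @export
summarize_rates <- function(chains) {
  meaning <- NA_character_
  if (inherits(chains[[1]], "rate_posterior")) meaning <- chains[[1]]$meaning
  draws <- lapply(chains, function(ch)
    if (inherits(ch, "rate_posterior")) ch$R else as.numeric(ch))
  gr <- if (length(draws) >= 2) gelman_rubin(draws) else
    list(psrf = NA_real_, pass = TRUE)
  if (!gr$pass)
    warning("chains have not converged (PSRF = ", signif(gr$psrf, 4), ")")
  pooled <- unlist(draws)
  ci <- unname(stats::quantile(pooled, c(0.025, 0.975)))
  data.frame(meaning = meaning, mean_rate = mean(pooled),
             ci_lower = ci[1], ci_upper = ci[2], psrf = gr$psrf,
             n_draws = length(pooled), stringsAsFactors = FALSE)
}
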