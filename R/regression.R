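#' Assemble the rate-by-frequency regression table
#'
#' Inner join of per-meaning mean replacement rates with the per-language
#' clfpm table: one row per (language, meaning) present in both.
#'
#' @param rates Data frame with `meaning` and `mean_rate` (per 10 kyr), as
#'   produced by [summarize_rates()] row-bound over meanings; for
#'   core-vocabulary items rates may come from an external source.
#' @param clfpm Data frame from [aggregate_clfpm()] (after any exclusions).
#' @return Data frame (`language`, `meaning`, `lexical_class`, `clfpm`,
#'   `mean_rate`); meanings lacking a rate are dropped with a warning.
#' @export
build_regression_table <- function(rates, clfpm) {
  if (anyDuplicated(rates$meaning)) stop("duplicated meaning in rates")
  lost <- setdiff(unique(clfpm$meaning), rates$meaning)
  if (length(lost))
    warning("meaning(s) without a rate dropped: ",
            paste(lost, collapse = ", "))
  out <- merge(clfpm, rates[c("meaning", "mean_rate")], by = "meaning")
  if (!nrow(out)) stop("no meanings shared between rates and clfpm tables")
  if (anyDuplicated(paste(out$language, out$meaning, sep = "\r")))
    stop("duplicated (language, meaning) rows after join")
  if (any(is.na(out$clfpm))) stop("missing clfpm in regression table")
  if (any(out$mean_rate <= 0)) stop("mean_rate must be positive")
  out[order(out$language, out$meaning),
      c("language", "meaning", "lexical_class", "clfpm", "mean_rate")]
}

#' Fit the mixed-effects rate-frequency model
#'
#' Maximum-likelihood fit of `outcome ~ clfpm * lexical_class` with the
#' given random-effect structure via [lme4::lmer()]. The default outcome is
#' the natural log of the mean replacement rate (Gaussian response); a
#' logit-of-normalized-rate alternative (`log(p/(1-p))` with
#' `p = rate / (1.01 * max rate)`) is available. With an empty random
#' structure an ordinary least-squares fit is returned.
#'
#' @param table Regression table from [build_regression_table()].
#' @param outcome `"log"` (default) or `"logit"`.
#' @param random Random-effects formula fragment, e.g. `"(1 | language)"`
#'   (default); `""` for plain OLS.
#' @return A `fit_result`: coefficient table (estimate, std. error, t),
#'   AIC, log-likelihood, convergence flag, the fitted model object, and
#'   the formula used.
#' @export
fit_model <- function(table, outcome = c("log", "logit"),
                      random = "(1 | language)") {
  outcome <- match.arg(outcome)
  table$lexical_class <- factor(table$lexical_class)
  if (nlevels(table$lexical_class) < 2)
    stop("interaction clfpm:lexical_class is inestimable with a single ",
         "lexical class")
  table$y <- switch(outcome,
    log = log(table$mean_rate),
    logit = {
      p <- table$mean_rate / (1.01 * max(table$mean_rate))
      log(p / (1 - p))
    })
  fixed <- "y ~ clfpm * lexical_class"
  if (nzchar(random)) {
    fml <- stats::as.formula(paste(fixed, "+", random))
    fit <- lme4::lmer(fml, data = table, REML = FALSE)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    coefs <- summary(fit)$coefficients
  } else {
    fml <- stats::as.formula(fixed)
    fit <- stats::lm(fml, data = table)
    conv <- TRUE
    coefs <- summary(fit)$coefficients[, 1:3, drop = FALSE]
  }
  colnames(coefs) <- c("estimate", "std_error", "t_value")
  structure(list(coefficients = coefs, random = random, outcome = outcome,
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 converged = conv, n = nrow(table), model = fit,
                 formula = deparse(fml)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Rate ~ frequency x class fit (", x$outcome, " outcome, random: ",
      if (nzchar(x$random)) x$random else "none", ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("AIC %.2f  logLik %.2f  n = %d%s\n", x$aic, x$loglik, x$n,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' AIC-guided random-effect selection
#'
#' Fits each candidate random-effect structure by maximum likelihood and
#' returns the fit with the lowest AIC; within 2 AIC units of the best, the
#' structure with fewer parameters wins. Candidates that fail to fit are
#' recorded and skipped.
#'
#' @param table Regression table.
#' @param candidates Character vector of random-effect fragments; defaults
#'   to a by-language intercept, a by-language intercept + clfpm slope, and
#'   crossed language and meaning intercepts.
#' @param outcome Passed to [fit_model()].
#' @return The winning `fit_result`, with the comparison table in
#'   `$aic_table`.
#' @export
select_random_effects <- function(table,
    candidates = c("(1 | language)",
                   "(1 + clfpm | language)",
                   "(1 | language) + (1 | meaning)"),
    outcome = "log") {
  if (!length(candidates)) stop("candidate set is empty")
  fits <- lapply(candidates, function(r)
    tryCatch(fit_model(table, outcome = outcome, random = r),
             error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) stop("no candidate random-effect structure could be fitted")
  aic <- vapply(fits[ok], `[[`, 1, "aic")
  npar <- vapply(fits[ok], function(f)
    attr(stats::logLik(f$model), "df"), 1)
  tab <- data.frame(random = candidates[ok], aic = aic, delta_aic = aic - min(aic),
                    n_par = npar, stringsAsFactors = FALSE)
  near <- which(tab$delta_aic < 2)
  win <- near[which.min(tab$n_par[near])]
  best <- fits[ok][[win]]
  best$aic_table <- tab[order(tab$aic), ]
  best
}
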