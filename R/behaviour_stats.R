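# Behavioural and perceptual statistics: linear models with F tests on
# (optionally log10) responses, and binomial GLMs of matching success.

#' Encode matching success for one choice trial
#'
#' @param larval_colour,chosen_colour Each `"brown"` or `"green"`
#'   (vectorised).
#' @return Integer 0/1: 1 when the chosen background colour equals the
#'   larva's own colour.
#' @export
encode_matching <- function(larval_colour, chosen_colour) {
  ok <- c("brown", "green")
  if (!all(larval_colour %in% ok) || !all(chosen_colour %in% ok)) {
    bad <- setdiff(unique(c(larval_colour, chosen_colour)), ok)
    stop("unknown colour label(s): ", paste(bad, collapse = ", "))
  }
  as.integer(larval_colour == chosen_colour)
}

#' Linear model with per-term F tests
#'
#' Ordinary least squares of a (optionally log10-transformed) response on
#' categorical predictors, with marginal (Type II) F tests by default;
#' sequential (Type I) tests are available. A zero-residual perfect fit
#' reports infinite F with a warning. Data for a normal quantile plot of
#' the residuals is returned for diagnostics.
#'
#' @param response Numeric response vector.
#' @param factors Data frame of predictors (one column per term).
#' @param log10 Transform the response to log10 before fitting? Requires
#'   strictly positive responses.
#' @param anova_type 2 (marginal, default) or 1 (sequential).
#' @param ids Optional observation ids used in error messages.
#' @return A `model_fit`: list with `family = "gaussian_lm"`, a `terms`
#'   data frame (term, df1, df2, statistic, p_value), `coefficients`,
#'   `n`, `df_residual`, `qq` (theoretical/sample residual quantiles) and
#'   the underlying `stats::lm` fit.
#' @export
fit_lm <- function(response, factors, log10 = FALSE, anova_type = 2,
                   ids = NULL) {
  factors <- as.data.frame(factors)
  stopifnot(length(response) == nrow(factors), anova_type %in% c(1, 2))
  if (log10) {
    bad <- which(!(response > 0))
    if (length(bad)) {
      lab <- if (is.null(ids)) bad else ids[bad]
      stop("log10 requested but response is not positive for: ",
           paste(lab, collapse = ", "))
    }
    response <- log10(response)
  }
  dat <- cbind(.y = response, factors)
  fit <- lm(.y ~ ., data = dat)
  n <- length(response)
  df_res <- fit$df.residual
  rss <- sum(fit$residuals^2)
  perfect <- rss < 1e-12 * max(1, sum(response^2))
  if (perfect) warning("zero residual variance: F statistics are infinite")

  terms_tab <- if (anova_type == 1) {
    a <- anova(fit)
    k <- setdiff(rownames(a), "Residuals")
    data.frame(term = k, df1 = a[k, "Df"], df2 = df_res,
               statistic = a[k, "F value"], p_value = a[k, "Pr(>F)"])
  } else {
    # Type II: full model vs model with the term removed
    full_rss <- rss
    k <- names(factors)
    rows <- lapply(k, function(tm) {
      red <- lm(.y ~ ., data = dat[, c(".y", setdiff(k, tm)), drop = FALSE])
      red_rss <- sum(red$residuals^2)
      df1 <- red$df.residual - df_res
      Fv <- ((red_rss - full_rss) / df1) / (full_rss / df_res)
      data.frame(term = tm, df1 = df1, df2 = df_res, statistic = Fv,
                 p_value = pf(Fv, df1, df_res, lower.tail = FALSE))
    })
    do.call(rbind, rows)
  }
  if (perfect) {
    terms_tab$statistic <- Inf
    terms_tab$p_value <- 0
  }
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                   sample = sort(fit$residuals))
  structure(list(family = "gaussian_lm", terms = terms_tab,
                 coefficients = suppressWarnings(coef(summary(fit))),
                 n = n, df_residual = df_res, qq = qq, fit = fit,
                 flags = character(0)),
            class = "model_fit")
}

#' Binomial GLM of matching success
#'
#' Logit-link maximum likelihood (iteratively reweighted least squares)
#' with Wald z statistics per coefficient. Complete or quasi-complete
#' separation (any |coefficient| > 15 on the logit scale) is flagged in
#' the output rather than raised as an error.
#'
#' @param trials Data frame of choice trials with a `matching` 0/1 column
#'   (see [simulate_choice_trials()]) or, if absent, `larval_colour` and
#'   `chosen_colour` columns from which matching is encoded.
#' @param predictors Character vector naming columns of `trials` to use as
#'   predictors; empty for an intercept-only model.
#' @return A `model_fit` with `family = "binomial_glm"` and a `terms`
#'   data frame (term, estimate, se, statistic = Wald z, p_value).
#' @export
fit_binomial_glm <- function(trials,
                             predictors = intersect(
                               c("larval_colour", "blindfold", "position"),
                               names(trials))) {
  trials <- as.data.frame(trials)
  if (!"matching" %in% names(trials)) {
    trials$matching <- encode_matching(trials$larval_colour,
                                       trials$chosen_colour)
  }
  if (nrow(trials) < 10L) stop("need at least 10 trials")
  keep <- predictors[vapply(predictors, function(p)
    length(unique(trials[[p]])) > 1L, logical(1))]
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  fit <- glm(stats::as.formula(paste("matching ~", rhs)),
             family = binomial(), data = trials,
             control = list(epsilon = 1e-8, maxit = 50))
  sm <- coef(summary(fit))
  terms_tab <- data.frame(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], statistic = sm[, 3],
                          p_value = sm[, 4], row.names = NULL)
  flags <- character(0)
  if (any(abs(sm[, 1]) > 15)) flags <- c(flags, "separation")
  if (!fit$converged) flags <- c(flags, "non_convergence")
  structure(list(family = "binomial_glm", terms = terms_tab,
                 n = nrow(trials), df_residual = fit$df.residual,
                 deviance = fit$deviance, fit = fit, flags = flags),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$family, ", n = ", x$n,
      ", residual df = ", x$df_residual, "\n", sep = "")
  print(x$terms, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a model term table as CSV
#'
#' @param fit A `model_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model_csv <- function(fit, path) {
  write.csv(fit$terms, path, row.names = FALSE)
  invisible(path)
}
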