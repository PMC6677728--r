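# RT-qPCR relative quantification, dermal-proportion construction, beta
# regression of stage effects, and log10 stage contrasts.

VALID_TISSUES <- c("head", "thorax", "abdomen", "claspers_or_genitalia")
DERMAL_TISSUES <- setdiff(VALID_TISSUES, "head")
REFERENCE_GENE <- "spectrin"

#' Relative expression from crossing points
#'
#' `(E_ref ^ Cp_ref) / (E_target ^ Cp_target)`: the target's template
#' abundance relative to the reference gene, with amplification
#' efficiencies idealised to 2 by default (a one-cycle Cp difference is a
#' two-fold expression difference).
#'
#' @param cp_ref,cp_target Crossing point (cycles), in (0, 45\].
#' @param e_ref,e_target Amplification efficiencies, in (1, 2\].
#' @return Positive relative expression ratio (vectorised).
#' @export
relative_expression <- function(cp_ref, cp_target, e_ref = 2, e_target = 2) {
  if (any(cp_ref <= 0 | cp_ref > 45) || any(cp_target <= 0 | cp_target > 45)) {
    stop("Cp values must lie in (0, 45]")
  }
  if (any(e_ref <= 1 | e_ref > 2) || any(e_target <= 1 | e_target > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  (e_ref^cp_ref) / (e_target^cp_target)
}

#' Collapse triplicate Cp measurements to a mean
#'
#' @param cp Numeric vector of replicate crossing points (>= 1 usable,
#'   NA allowed and dropped).
#' @param sd_flag_threshold Replicate SD (cycles) above which the
#'   measurement is flagged as noisy (lab convention, default 0.5).
#' @return List with `mean_cp`, `sd_cp` (0 for a single replicate) and
#'   logical `flag`.
#' @export
collapse_triplicates <- function(cp, sd_flag_threshold = 0.5) {
  cp <- cp[!is.na(cp)]
  if (length(cp) == 0L) stop("no usable replicate Cp values")
  s <- if (length(cp) == 1L) 0 else sd(cp)
  list(mean_cp = mean(cp), sd_cp = s, flag = s > sd_flag_threshold)
}

#' Dermal proportion of total expression
#'
#' `sum(dermal) / (head + sum(dermal))`, the share of a gene's expression
#' contributed by the dermal tissues (thorax, abdomen,
#' claspers/genitalia). Values landing exactly on 0 or 1 through floating
#' rounding are nudged 1e-6 into the open interval, since the beta
#' likelihood is zero on the boundary.
#'
#' @param head Relative expression ratio of the head sample (> 0).
#' @param body Named numeric of dermal-tissue ratios; all of `thorax`,
#'   `abdomen`, `claspers_or_genitalia` must be present.
#' @return Proportion strictly inside (0, 1).
#' @export
dermal_proportion <- function(head, body) {
  missing_t <- setdiff(DERMAL_TISSUES, names(body))
  if (length(missing_t)) {
    stop("missing dermal tissue(s): ", paste(missing_t, collapse = ", "))
  }
  if (head <= 0 || any(body[DERMAL_TISSUES] <= 0)) {
    stop("all expression ratios must be positive")
  }
  p <- sum(body[DERMAL_TISSUES]) / (head + sum(body[DERMAL_TISSUES]))
  min(max(p, 1e-6), 1 - 1e-6)
}

#' Relative expression table from a long qPCR table
#'
#' Collapses replicate Cp values to a per-(sample, tissue, gene) mean and
#' quantifies every target gene against the reference gene measured in the
#' same sample and tissue.
#'
#' @param qpcr Data frame with columns `sample`, `stage`, `tissue`,
#'   `gene`, `rep`, `cp` (long format, one row per replicate well).
#' @param efficiency Amplification efficiency used for all genes
#'   (default 2); a named vector gives per-gene efficiencies.
#' @return Data frame with columns `sample`, `stage`, `tissue`, `gene`,
#'   `ratio`, `cp_sd_flag`.
#' @export
expression_ratios <- function(qpcr, efficiency = 2) {
  need <- c("sample", "stage", "tissue", "gene", "cp")
  if (!all(need %in% names(qpcr))) {
    stop("qpcr table must have columns: ", paste(need, collapse = ", "))
  }
  eff <- function(g) {
    if (length(efficiency) == 1L && is.null(names(efficiency))) return(efficiency)
    if (!g %in% names(efficiency)) stop("no efficiency for gene ", g)
    efficiency[[g]]
  }
  key <- interaction(qpcr$sample, qpcr$tissue, qpcr$gene, drop = TRUE)
  agg <- lapply(split(qpcr, key), function(d) {
    cc <- collapse_triplicates(d$cp)
    data.frame(sample = d$sample[1L], stage = d$stage[1L],
               tissue = d$tissue[1L], gene = d$gene[1L],
               mean_cp = cc$mean_cp, cp_sd_flag = cc$flag)
  })
  agg <- do.call(rbind, agg)
  ref <- agg[agg$gene == REFERENCE_GENE, c("sample", "tissue", "mean_cp")]
  names(ref)[3L] <- "ref_cp"
  tgt <- agg[agg$gene != REFERENCE_GENE, ]
  out <- merge(tgt, ref, by = c("sample", "tissue"))
  if (nrow(out) < nrow(tgt)) {
    stop("reference gene '", REFERENCE_GENE,
         "' missing for some sample/tissue combinations")
  }
  out$ratio <- mapply(function(rcp, tcp, g)
    relative_expression(rcp, tcp, eff(REFERENCE_GENE), eff(g)),
    out$ref_cp, out$mean_cp, out$gene)
  out <- out[order(out$sample, out$gene, out$tissue),
             c("sample", "stage", "tissue", "gene", "ratio", "cp_sd_flag")]
  rownames(out) <- NULL
  out
}

#' Dermal-proportion table from an expression-ratio table
#'
#' @param ratios Output of [expression_ratios()].
#' @return Data frame with columns `sample`, `stage`, `gene`,
#'   `proportion`, one row per sample x gene.
#' @export
dermal_proportions <- function(ratios) {
  key <- interaction(ratios$sample, ratios$gene, drop = TRUE)
  rows <- lapply(split(ratios, key), function(d) {
    head_r <- d$ratio[d$tissue == "head"]
    if (length(head_r) != 1L) stop("missing dermal tissue(s): head (sample ",
                                   d$sample[1L], ", gene ", d$gene[1L], ")")
    body <- setNames(d$ratio[match(DERMAL_TISSUES, d$tissue)], DERMAL_TISSUES)
    if (anyNA(body)) {
      stop("missing dermal tissue(s): ",
           paste(DERMAL_TISSUES[is.na(body)], collapse = ", "),
           " (sample ", d$sample[1L], ", gene ", d$gene[1L], ")")
    }
    data.frame(sample = d$sample[1L], stage = d$stage[1L], gene = d$gene[1L],
               proportion = dermal_proportion(head_r, body))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Beta regression of proportions on life stage
#'
#' Mean submodel `logit(mu) = b0 + b1 * stage` with a constant precision
#' `phi`; the beta log-likelihood `f(y; mu * phi, (1 - mu) * phi)` is
#' maximised numerically (BFGS on `(b0, b1, log phi)`), with Wald z
#' statistics from the inverse observed information. The stage coefficient
#' is the larval shift relative to the adult reference level.
#'
#' @param proportions Data frame with columns `proportion` (in (0, 1))
#'   and, unless `intercept_only`, `stage` (two levels; `"adult"` is the
#'   reference).
#' @param intercept_only Fit the null model with no stage term?
#' @param max_iter Iteration cap for the optimiser.
#' @return A `model_fit` with `family = "beta_regression"`, a `terms`
#'   table (term, estimate, se, statistic = Wald z, p_value), `phi` and
#'   `loglik`.
#' @export
beta_regression <- function(proportions, intercept_only = FALSE,
                            max_iter = 200) {
  y <- proportions$proportion
  if (any(y <= 0 | y >= 1)) stop("proportions must lie strictly in (0, 1)")
  if (length(y) < 6L) stop("need n >= 6 proportions")
  if (intercept_only) {
    X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stage <- factor(proportions$stage)
    if ("adult" %in% levels(stage)) stage <- stats::relevel(stage, "adult")
    if (nlevels(stage) != 2L) stop("stage must have exactly two levels")
    X <- model.matrix(~stage)
    colnames(X) <- c("(Intercept)", paste0("stage", levels(stage)[2L]))
  }
  p <- ncol(X)
  negll <- function(par) {
    mu <- plogis(drop(X %*% par[seq_len(p)]))
    phi <- exp(par[p + 1L])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(qlogis(mean(y)), rep(0, p - 1L), log(5))
  opt <- optim(start, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("beta regression did not converge after ", max_iter,
         " iterations (optim code ", opt$convergence, ")")
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    stop("beta regression information matrix is singular"))
  est <- opt$par[seq_len(p)]
  se <- sqrt(diag(vc)[seq_len(p)])
  z <- est / se
  terms_tab <- data.frame(term = colnames(X), estimate = est, se = se,
                          statistic = z,
                          p_value = 2 * pnorm(-abs(z)), row.names = NULL)
  structure(list(family = "beta_regression", terms = terms_tab,
                 phi = exp(opt$par[p + 1L]), loglik = -opt$value,
                 n = length(y), df_residual = length(y) - p,
                 flags = character(0)),
            class = "model_fit")
}

#' Stage contrast on log10 expression
#'
#' Two-level linear model of `log10(expression)` on life stage. The
#' reported t statistic is for the larval level against the adult
#' reference (sign convention: larva minus adult, so higher adult
#' expression gives a negative t).
#'
#' @param expression Positive expression ratios.
#' @param stage Factor or character with levels `adult` / `larva`.
#' @return A `model_fit` with `family = "gaussian_lm"` and a `terms`
#'   table holding the stage t test (term, estimate, se, statistic = t,
#'   df, p_value).
#' @export
stage_contrast <- function(expression, stage) {
  if (any(expression <= 0)) stop("expression values must be positive")
  stage <- factor(stage)
  if ("adult" %in% levels(stage)) stage <- stats::relevel(stage, "adult")
  if (nlevels(stage) != 2L) stop("stage must have exactly two levels")
  fit <- lm(log10(expression) ~ stage)
  sm <- coef(summary(fit))
  i <- 2L
  terms_tab <- data.frame(term = rownames(sm)[i], estimate = sm[i, 1],
                          se = sm[i, 2], statistic = sm[i, 3],
                          df = fit$df.residual, p_value = sm[i, 4],
                          row.names = NULL)
  structure(list(family = "gaussian_lm", terms = terms_tab,
                 coefficients = sm, n = length(expression),
                 df_residual = fit$df.residual, fit = fit,
                 flags = character(0)),
            class = "model_fit")
}
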