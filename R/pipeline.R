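# End-to-end orchestration: simulate -> spectra -> perceive -> stats ->
# expression -> report, with deterministic seeded outputs and a manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. With
#' `simulate = TRUE` (the default) every input table is generated by the
#' seeded synthetic module; otherwise `spectra_path`/`metadata_path`/
#' `choice_path`/`qpcr_path` must point at existing delimited files. The
#' global seed expands into fixed per-stream seeds (spectra +1000, choice
#' +2000, qPCR +3000) so the streams are independent.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param simulate Generate inputs synthetically?
#' @param viewer `"bluetit"` (D65) or `"bluetit_ideal"` (flat-quanta
#'   illuminant).
#' @param aggregate `"individual"` or `"measurement"` spectra aggregation.
#' @param anova_type 1 or 2.
#' @param rho,delta,noise_sd Synthetic colour-experiment parameters (see
#'   [simulate_colour_experiment()]).
#' @param p_match,position_effect Synthetic choice parameters.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("mothvision_run_"),
                           simulate = TRUE, viewer = "bluetit",
                           aggregate = "individual", anova_type = 2,
                           rho = 0.7, delta = 0, noise_sd = 0.04,
                           p_match = 0.75, position_effect = 0) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, viewer = viewer,
                 aggregate = aggregate, anova_type = anova_type,
                 rho = rho, delta = delta, noise_sd = noise_sd,
                 p_match = p_match, position_effect = position_effect,
                 spectra_path = NULL, metadata_path = NULL,
                 choice_path = NULL, qpcr_path = NULL),
            class = "run_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (!isTRUE(config$simulate)) {
    for (p in c("spectra_path", "metadata_path", "choice_path", "qpcr_path")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]])) {
        stop("config validation: ", p, " missing or does not exist (",
             if (is.null(config[[p]])) "NULL" else config[[p]], ")")
      }
    }
  }
  if (!config$viewer %in% c("bluetit", "bluetit_ideal")) {
    stop("config validation: unknown viewer '", config$viewer, "'")
  }
  if (!config$aggregate %in% c("individual", "measurement")) {
    stop("config validation: aggregate must be 'individual' or 'measurement'")
  }
  invisible(config)
}

config_viewer <- function(config) {
  switch(config$viewer,
         bluetit = bluetit_viewer(),
         bluetit_ideal = bluetit_viewer(illum = illuminant("ideal")))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Perceptual analysis of one rearing experiment
#'
#' Resamples and aggregates the measurements, computes per-individual
#' greenness / luminance / tetrahedral coordinates, and the JND of each
#' larva against its own rearing dowel.
#'
#' @param table A `spectrum_table` with attached metadata (columns
#'   `individual_id`, `treatment`, `blindfold`).
#' @param dowels Named list of dowel [refl_spectrum()], one per treatment.
#' @param viewer A [viewer_model()].
#' @param aggregate Passed to [individual_spectra()].
#' @return Data frame: per-individual perceptual summary joined with
#'   metadata plus `jnd_chromatic` and `jnd_achromatic` against the own
#'   dowel.
#' @export
perceive_experiment <- function(table, dowels, viewer = bluetit_viewer(),
                                aggregate = "individual") {
  spectra <- individual_spectra(table, aggregate = aggregate)
  summ <- perceptual_summary(spectra, viewer)
  meta <- table$metadata
  if (aggregate == "measurement") {
    summ$measurement_id <- summ$individual_id
    summ$individual_id <- sub("_[^_]*$", "", summ$individual_id)
  }
  out <- merge(summ, meta, by = "individual_id", sort = FALSE)
  dowel_catch <- lapply(dowels, catch_vector, viewer = viewer)
  sp_catch <- lapply(spectra, catch_vector, viewer = viewer)
  idx <- match(if (aggregate == "measurement") paste0(out$measurement_id)
               else out$individual_id, names(sp_catch))
  out$jnd_chromatic <- vapply(seq_len(nrow(out)), function(i)
    chromatic_jnd(sp_catch[[idx[i]]], dowel_catch[[out$treatment[i]]], viewer),
    numeric(1))
  out$jnd_achromatic <- vapply(seq_len(nrow(out)), function(i)
    achromatic_jnd(sp_catch[[idx[i]]], dowel_catch[[out$treatment[i]]], viewer),
    numeric(1))
  out
}

#' Fit the colour-response models of one experiment
#'
#' Linear models with per-term F tests of log10 response on treatment and
#' blindfold: greenness for a chromatic (brown/green) experiment,
#' luminance for an achromatic (black/white) one, and the matching JND in
#' both cases (chromatic JND against chromatic dowels, achromatic JND
#' against achromatic dowels).
#'
#' @param perceived Output of [perceive_experiment()].
#' @param experiment `"chromatic"` or `"achromatic"`.
#' @param anova_type 1 or 2.
#' @return Named list of `model_fit` objects (`response` and `jnd`).
#' @export
fit_colour_models <- function(perceived,
                              experiment = c("chromatic", "achromatic"),
                              anova_type = 2) {
  experiment <- match.arg(experiment)
  fac <- perceived[, c("treatment", "blindfold")]
  fac$treatment <- factor(fac$treatment)
  fac$blindfold <- factor(fac$blindfold)
  resp <- if (experiment == "chromatic") perceived$greenness else perceived$luminance
  jnd <- if (experiment == "chromatic") perceived$jnd_chromatic else perceived$jnd_achromatic
  list(response = fit_lm(resp, fac, log10 = TRUE, anova_type = anova_type,
                         ids = perceived$individual_id),
       jnd = fit_lm(jnd, fac, log10 = TRUE, anova_type = anova_type,
                    ids = perceived$individual_id))
}

#' Run the full pipeline
#'
#' Executes every stage (simulate or load inputs, spectral processing,
#' perceptual modelling, behaviour and expression statistics), writes all
#' tables, a text report and a manifest into `config$out_dir`, and returns
#' the results invisibly. Identical configs (including seed) produce
#' byte-identical outputs.
#'
#' @param config A [default_config()] list (possibly modified).
#' @return Invisibly, a list with elements `perceived_chromatic`,
#'   `perceived_achromatic`, `models`, `choice_models`, `expression`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  viewer <- config_viewer(config)
  seed <- config$seed

  # --- inputs -------------------------------------------------------------
  inputs <- stage_try("inputs", {
    if (isTRUE(config$simulate)) {
      chrom <- simulate_colour_experiment(default_colour_design("chromatic"),
                                          rho = config$rho, delta = config$delta,
                                          noise_sd = config$noise_sd,
                                          seed = seed + 1000L)
      achrom <- simulate_colour_experiment(default_colour_design("achromatic"),
                                           rho = config$rho, delta = config$delta,
                                           noise_sd = config$noise_sd,
                                           seed = seed + 1500L)
      trials <- simulate_choice_trials(p_match = config$p_match,
                                       position_effect = config$position_effect,
                                       seed = seed + 2000L)
      qpcr <- simulate_qpcr(seed = seed + 3000L)
      list(chromatic = chrom, achromatic = achrom, trials = trials, qpcr = qpcr)
    } else {
      meta <- read.table(config$metadata_path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
      tab <- read_spectra(config$spectra_path, metadata = meta)
      dowels <- lapply(setNames(nm = unique(meta$treatment)), make_dowel_spectrum)
      trials <- read.table(config$choice_path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
      qpcr <- read.table(config$qpcr_path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
      list(chromatic = list(table = tab, metadata = meta, dowels = dowels),
           achromatic = NULL, trials = trials, qpcr = qpcr)
    }
  })

  # --- perceive -----------------------------------------------------------
  perceived <- stage_try("perceive", {
    lapply(Filter(Negate(is.null),
                  inputs[c("chromatic", "achromatic")]), function(exp)
      perceive_experiment(exp$table, exp$dowels, viewer,
                          aggregate = config$aggregate))
  })

  # --- colour statistics ---------------------------------------------------
  models <- stage_try("stats", {
    out <- list()
    if (!is.null(perceived$chromatic)) {
      out$chromatic <- fit_colour_models(perceived$chromatic, "chromatic",
                                         config$anova_type)
    }
    if (!is.null(perceived$achromatic)) {
      out$achromatic <- fit_colour_models(perceived$achromatic, "achromatic",
                                          config$anova_type)
    }
    out
  })

  # --- choice statistics ---------------------------------------------------
  choice_models <- stage_try("choice", {
    tr <- inputs$trials
    list(diagonal = fit_binomial_glm(tr[tr$arena == "diagonal", ],
                                     c("larval_colour", "blindfold")),
         horizontal = fit_binomial_glm(tr[tr$arena == "horizontal", ],
                                       c("larval_colour", "blindfold",
                                         "position")))
  })

  # --- expression ----------------------------------------------------------
  expr_res <- stage_try("expression", {
    ratios <- expression_ratios(inputs$qpcr)
    props <- dermal_proportions(ratios)
    beta_fit <- beta_regression(props)
    head_r <- ratios[ratios$tissue == "head", ]
    dermal_mean <- stats::aggregate(
      ratio ~ sample + stage + gene,
      data = ratios[ratios$tissue != "head", ], FUN = mean)
    list(ratios = ratios, proportions = props, beta = beta_fit,
         head_contrast = stage_contrast(head_r$ratio, head_r$stage),
         dermal_contrast = stage_contrast(dermal_mean$ratio, dermal_mean$stage))
  })

  # --- outputs -------------------------------------------------------------
  stage_try("report", {
    for (nm in names(perceived)) {
      write.csv(perceived[[nm]],
                file.path(out_dir, paste0("perceptual_", nm, ".csv")),
                row.names = FALSE)
    }
    write.csv(inputs$trials, file.path(out_dir, "choice_trials.csv"),
              row.names = FALSE)
    write.csv(expr_res$ratios, file.path(out_dir, "expression_ratios.csv"),
              row.names = FALSE)
    write.csv(expr_res$proportions,
              file.path(out_dir, "dermal_proportions.csv"), row.names = FALSE)
    for (nm in names(models)) {
      write_model_csv(models[[nm]]$response,
                      file.path(out_dir, paste0("model_", nm, "_response.csv")))
      write_model_csv(models[[nm]]$jnd,
                      file.path(out_dir, paste0("model_", nm, "_jnd.csv")))
    }
    write_model_csv(choice_models$diagonal,
                    file.path(out_dir, "model_choice_diagonal.csv"))
    write_model_csv(choice_models$horizontal,
                    file.path(out_dir, "model_choice_horizontal.csv"))
    write_model_csv(expr_res$beta, file.path(out_dir, "model_beta_stage.csv"))
    writeLines(render_report(models, choice_models, expr_res),
               file.path(out_dir, "report.txt"))
  })

  manifest <- stage_try("manifest", {
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 null = "null")
    cfg_path <- file.path(out_dir, "config.json")
    writeLines(cfg_json, cfg_path)
    m <- list(config_hash = unname(tools::md5sum(cfg_path)),
              seed = seed,
              package = "mothvision",
              version = as.character(packageVersion("mothvision")))
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    m
  })

  invisible(list(perceived_chromatic = perceived$chromatic,
                 perceived_achromatic = perceived$achromatic,
                 models = models, choice_models = choice_models,
                 expression = expr_res, manifest = manifest,
                 out_dir = out_dir))
}

fmt_term <- function(fit, label) {
  t <- fit$terms
  lines <- character(0)
  for (i in seq_len(nrow(t))) {
    if (fit$family == "gaussian_lm" && "df1" %in% names(t)) {
      lines <- c(lines, sprintf("  %s %s: F_%d,%d = %.4g, P = %.4g",
                                label, t$term[i], t$df1[i], t$df2[i],
                                t$statistic[i], t$p_value[i]))
    } else {
      lines <- c(lines, sprintf("  %s %s: estimate = %.4g, Z = %.4g, P = %.4g",
                                label, t$term[i], t$estimate[i],
                                t$statistic[i], t$p_value[i]))
    }
  }
  lines
}

render_report <- function(models, choice_models, expr_res) {
  out <- c("mothvision pipeline report", "==========================", "")
  for (nm in names(models)) {
    out <- c(out, paste0("Colour response (", nm, " experiment):"),
             fmt_term(models[[nm]]$response, "response ~"),
             fmt_term(models[[nm]]$jnd, "log10 JND ~"), "")
  }
  out <- c(out, "Background choice (binomial GLM):",
           fmt_term(choice_models$diagonal, "diagonal:"),
           fmt_term(choice_models$horizontal, "horizontal:"), "",
           "Gene expression:",
           fmt_term(expr_res$beta, "beta regression:"),
           sprintf("  head stage contrast: t_%d = %.4g, P = %.4g",
                   expr_res$head_contrast$terms$df,
                   expr_res$head_contrast$terms$statistic,
                   expr_res$head_contrast$terms$p_value),
           sprintf("  dermal stage contrast: t_%d = %.4g, P = %.4g",
                   expr_res$dermal_contrast$terms$df,
                   expr_res$dermal_contrast$terms$statistic,
                   expr_res$dermal_contrast$terms$p_value))
  out
}
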