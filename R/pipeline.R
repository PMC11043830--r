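# Orchestration: simulate or load a dataset, run every analysis stage,
# and write the figure-equivalent tables (alpha by scale, beta by scale,
# SCBD ranking, variance-ratio / pairwise-association report, growth-form
# table, permutation tests) plus a JSON run manifest.

#' Pipeline configuration
#'
#' @param input `"simulate"` to generate data from `synthetic`, or a path
#'   to an abundance CSV.
#' @param registry optional path to a registry CSV when `input` is a file.
#' @param synthetic a [synthetic_config()] used when `input = "simulate"`.
#' @param scales character subset of `c("cell", "quadrat", "exclosure")`;
#'   non-empty.
#' @param n_perm permutation count for PERMANOVA and paired contrasts
#'   (>= 99).
#' @param seed integer seed governing all pipeline randomness.
#' @param output_dir directory for the report bundle.
#' @param alpha_level significance threshold (default 0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate", registry = NULL,
                            synthetic = default_config(),
                            scales = SCALE_LEVELS, n_perm = 999,
                            seed = 1, output_dir = tempfile("mossdiv_"),
                            alpha_level = 0.05) {
  scales <- match.arg(scales, SCALE_LEVELS, several.ok = TRUE)
  if (!length(scales)) stop("scales must be non-empty")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, synthetic)
  structure(list(input = input, registry = registry,
                 synthetic = synthetic, scales = scales,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 output_dir = output_dir, alpha_level = alpha_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `synthetic`
#' key holds [synthetic_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  do.call(pipeline_config, y)
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the dataset; alpha diversity by scale; beta
#' diversity by scale; SCBD; variance-ratio and pairwise Spearman
#' associations per treatment; growth-form summaries; PERMANOVA on
#' quadrat-scale Bray-Curtis distances; paired permutation contrasts of
#' per-plot mean statistics. Writes seven CSV tables plus
#' `manifest.json` (configuration, seed, package and R versions, output
#' inventory) into `config$output_dir`. All randomness derives from
#' `config$seed`, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the dataset and every stage result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dataset <- stage("input", {
    if (identical(config$input, "simulate"))
      simulate_dataset(config$synthetic)
    else
      read_abundance_table(config$input, config$registry)
  })

  alpha <- stage("alpha_diversity", alpha_by_scale(dataset, config$scales))
  beta <- stage("beta_diversity", {
    res <- lapply(config$scales, function(sc)
      per_unit_beta(aggregate_counts(dataset, sc)))
    names(res) <- config$scales
    res
  })
  beta_summary <- do.call(rbind, lapply(beta, `[[`, "summary"))
  rownames(beta_summary) <- NULL

  scbd_scale <- if ("quadrat" %in% config$scales) "quadrat"
                else config$scales[1]
  scbd_tab <- stage("scbd", scbd(aggregate_counts(dataset, scbd_scale)))
  scbd_tab$scale <- scbd_scale

  assoc_scale <- scbd_scale
  assoc_cm <- aggregate_counts(dataset, assoc_scale)
  treatments <- intersect(TREATMENT_LEVELS,
                          unique(dataset$records$treatment))
  vr_tab <- stage("variance_ratio", do.call(rbind, lapply(
    treatments, function(trt) {
      v <- variance_ratio_test(assoc_cm, treatment = trt)
      data.frame(treatment = trt, scale = assoc_scale, VR = v$VR,
                 W = v$W, N = v$N, S = v$S, chi2_low = v$chi2_low,
                 chi2_high = v$chi2_high, verdict = v$verdict)
    })))
  pairwise_tab <- stage("pairwise_spearman", do.call(rbind, lapply(
    treatments, function(trt) {
      p <- pairwise_spearman(assoc_cm, alpha = config$alpha_level,
                             treatment = trt)
      if (nrow(p)) cbind(treatment = trt, p) else NULL
    })))
  if (is.null(pairwise_tab))
    pairwise_tab <- data.frame(treatment = character(),
                               species_a = character(),
                               species_b = character())

  growth <- stage("growth_forms", if (!is.null(dataset$registry)) {
    do.call(rbind, lapply(config$scales, function(sc)
      growth_form_summary(dataset, sc)$summary))
  })

  tests_tab <- stage("composition_tests", {
    rows <- list()
    if (length(treatments) == 2) {
      labels <- assoc_cm$units$treatment
      pm <- permanova(bray_curtis_dist(assoc_cm), labels,
                      n_perm = config$n_perm,
                      seed = sub_seed(config$seed, 900001L))
      rows[[1]] <- data.frame(
        test = "permanova", statistic = "pseudo_F", scale = assoc_scale,
        value = pm$pseudo_F, p_value = pm$p_perm, n_perm = pm$n_perm)
      excl <- aggregate_counts(dataset, "exclosure")
      au <- alpha$units
      k <- 2L
      for (sc in config$scales) {
        sub <- au[au$scale == sc, ]
        plot_key <- paste(sub$pair_id, sub$treatment)
        for (statn in c("S", "E", "inv_simpson")) {
          vals <- tapply(sub[[statn]], plot_key, mean, na.rm = TRUE)
          meta <- sub[!duplicated(plot_key), c("pair_id", "treatment")]
          meta <- meta[match(names(vals), paste(meta$pair_id,
                                                meta$treatment)), ]
          ct <- paired_permutation_contrast(
            as.numeric(vals), meta$treatment, meta$pair_id,
            n_perm = config$n_perm,
            seed = sub_seed(config$seed, 900001L + k))
          k <- k + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            test = "paired_contrast", statistic = statn, scale = sc,
            value = ct$effect, p_value = ct$p_value, n_perm = ct$n_perm)
        }
        bu <- beta[[sc]]$units
        plot_key <- paste(bu$pair_id, bu$treatment)
        for (statn in c("beta_bc", "beta_bal", "beta_gra")) {
          vals <- tapply(bu[[statn]], plot_key, mean, na.rm = TRUE)
          meta <- bu[!duplicated(plot_key), c("pair_id", "treatment")]
          meta <- meta[match(names(vals), paste(meta$pair_id,
                                                meta$treatment)), ]
          ct <- paired_permutation_contrast(
            as.numeric(vals), meta$treatment, meta$pair_id,
            n_perm = config$n_perm,
            seed = sub_seed(config$seed, 900001L + k))
          k <- k + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            test = "paired_contrast", statistic = statn, scale = sc,
            value = ct$effect, p_value = ct$p_value, n_perm = ct$n_perm)
        }
      }
    }
    do.call(rbind, rows)
  })

  dir <- config$output_dir
  files <- c(
    write_table(alpha$summary, dir, "alpha_by_scale.csv"),
    write_table(beta_summary, dir, "beta_by_scale.csv"),
    write_table(scbd_tab, dir, "scbd.csv"),
    write_table(vr_tab, dir, "variance_ratio.csv"),
    write_table(pairwise_tab, dir, "pairwise_associations.csv"),
    if (!is.null(growth)) write_table(growth, dir, "growth_forms.csv"),
    if (!is.null(tests_tab))
      write_table(tests_tab, dir, "composition_tests.csv"))

  manifest <- list(
    input = config$input, scales = config$scales,
    n_perm = config$n_perm, seed = config$seed,
    alpha_level = config$alpha_level,
    synthetic = if (identical(config$input, "simulate"))
      unclass(config$synthetic),
    outputs = basename(files),
    package_version = as.character(utils::packageVersion("mossdiv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, alpha = alpha, beta = beta,
                 scbd = scbd_tab, variance_ratio = vr_tab,
                 pairwise = pairwise_tab, growth_forms = growth,
                 tests = tests_tab, manifest = manifest))
}
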