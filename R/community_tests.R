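# Permutation-based inference on community structure: PERMANOVA on a
# distance matrix, a stratified paired permutation contrast (the
# package's treatment-effect test), and growth-form summaries.

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance. The total sum of
#' squares is \eqn{\sum_{i<j} d_{ij}^2 / n}; the within-group sum of
#' squares is the analogous quantity restricted to within-group pairs;
#' pseudo-F is \eqn{(SS_B / (k - 1)) / (SS_W / (n - k))}. The p-value is
#' obtained by permuting the group labels (`(count of permuted F >=
#' observed) + 1) / (n_perm + 1)`, so it can never be zero. Permutations
#' may optionally be restricted within strata (e.g. plot pairs).
#'
#' @param dist a `dist` object or square symmetric zero-diagonal matrix
#'   of pairwise dissimilarities (e.g. from [bray_curtis_dist()]).
#' @param labels group labels, one per unit; >= 2 groups with >= 2 units.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional blocking factor; labels are shuffled only
#'   within each stratum.
#' @return A list of class `permanova_result` with `pseudo_F`,
#'   `df_between`, `df_within`, `p_perm`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed, strata = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(labels) != n) stop("labels must match the distance matrix")
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(table(labels) < 2)) stop("each group needs >= 2 units")
  d2 <- d^2
  if (all(d2 == 0)) stop("all distances are zero; statistic undefined")
  k <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  pseudo_f <- function(lab) {
    ss_within <- 0
    for (g in groups) {
      idx <- which(lab == g)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- pseudo_f(labels)
  if (!missing(seed)) set.seed(seed) else seed <- NA_integer_
  perm_indices <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (s in unique(strata)) {
      w <- which(strata == s)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (pseudo_f(labels[perm_indices()]) >= f_obs) exceed <- exceed + 1L
  structure(list(pseudo_F = f_obs, df_between = k - 1, df_within = n - k,
                 p_perm = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df = %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_perm, x$n_perm))
  invisible(x)
}

#' Paired permutation contrast
#'
#' The package's treatment-effect test for the paired exclosure/control
#' design. The observed effect is `mean(presence) - mean(absence)` of a
#' per-unit statistic; the null distribution is built by independently
#' swapping the two treatment labels within each pair (block), which
#' respects the pairing exactly. The two-sided p-value uses the add-one
#' rule and can never be zero.
#'
#' @param values numeric per-unit statistic.
#' @param treatment `"absence"` / `"presence"` label per unit.
#' @param pair block label per unit; every block must contain both
#'   treatments.
#' @param n_perm number of label-swap permutations (default 999).
#' @param seed integer seed.
#' @return A list of class `paired_contrast` with `effect` (presence
#'   minus absence), `p_value`, `n_perm`, `n_pairs`, `seed`.
#' @export
paired_permutation_contrast <- function(values, treatment, pair,
                                        n_perm = 999, seed) {
  stopifnot(length(values) == length(treatment),
            length(values) == length(pair))
  treatment <- as.character(treatment)
  if (!all(treatment %in% TREATMENT_LEVELS))
    stop("treatment labels must be 'absence' or 'presence'")
  pair <- as.character(pair)
  blocks <- unique(pair)
  for (b in blocks)
    if (length(unique(treatment[pair == b])) < 2)
      stop("block '", b, "' does not contain both treatments")
  is_pres <- treatment == "presence"
  observed <- mean(values[is_pres]) - mean(values[!is_pres])
  if (!missing(seed)) set.seed(seed) else seed <- NA_integer_
  block_idx <- lapply(blocks, function(b) which(pair == b))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    flip <- stats::runif(length(blocks)) < 0.5
    ip <- is_pres
    for (bi in which(flip)) ip[block_idx[[bi]]] <- !ip[block_idx[[bi]]]
    eff <- mean(values[ip]) - mean(values[!ip])
    if (abs(eff) >= abs(observed)) exceed <- exceed + 1L
  }
  structure(list(effect = observed, p_value = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, n_pairs = length(blocks), seed = seed),
            class = "paired_contrast")
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("paired contrast: effect (presence - absence) = %.4g, p = %.4g (%d pairs, %d permutations)\n",
              x$effect, x$p_value, x$n_pairs, x$n_perm))
  invisible(x)
}

#' Growth-form summaries per unit and treatment
#'
#' For every sampling unit at the requested scale, the relative shoot
#' abundance (proportion of shoots belonging to each growth form, summing
#' to 1 over forms within a unit) and the species richness per growth
#' form, followed by treatment-level means and standard errors. The
#' acrocarp/pleurocarp dichotomy is the ecological contrast of interest;
#' Sphagnum is reported as its own category.
#'
#' @param dataset a [community_dataset()] whose registry covers every
#'   species in the records.
#' @param scale `"cell"`, `"quadrat"` or `"exclosure"`.
#' @return A list of class `growth_form_summary` with `units` (one row
#'   per unit x form) and `summary` (treatment x form means +- SE of
#'   relative abundance and richness). Units with zero total shoots have
#'   `NA` relative abundance.
#' @export
growth_form_summary <- function(dataset, scale = c("cell", "quadrat",
                                                   "exclosure")) {
  stopifnot(inherits(dataset, "community_dataset"))
  scale <- match.arg(scale)
  if (is.null(dataset$registry))
    stop("growth-form analyses require a species registry")
  cm <- aggregate_counts(dataset, scale)
  missing_sp <- setdiff(colnames(cm$x), dataset$registry$species)
  if (length(missing_sp))
    stop("species missing from registry: ",
         paste(missing_sp, collapse = ", "))
  form <- dataset$registry$growth_form[
    match(colnames(cm$x), dataset$registry$species)]
  forms_present <- intersect(GROWTH_FORMS, unique(form))
  totals <- rowSums(cm$x)
  units <- do.call(rbind, lapply(forms_present, function(f) {
    xs <- cm$x[, form == f, drop = FALSE]
    data.frame(cm$units, form = f,
               rel_abundance = ifelse(totals > 0,
                                      rowSums(xs) / totals, NA_real_),
               richness = as.integer(rowSums(xs > 0)))
  }))
  rownames(units) <- NULL
  summary <- do.call(rbind, lapply(
    split(units, list(units$treatment, units$form), drop = TRUE),
    function(g) {
      ra <- g$rel_abundance[!is.na(g$rel_abundance)]
      data.frame(treatment = g$treatment[1], scale = scale,
                 form = g$form[1],
                 rel_abundance_mean = mean(ra), rel_abundance_se = se(ra),
                 richness_mean = mean(g$richness),
                 richness_se = se(g$richness), n = nrow(g))
    }))
  rownames(summary) <- NULL
  structure(list(units = units, summary = summary, scale = scale),
            class = "growth_form_summary")
}

#' @export
print.growth_form_summary <- function(x, ...) {
  cat("growth-form summary (", x$scale, " scale)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
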