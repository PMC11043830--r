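# Interspecific association: the variance-ratio test of overall
# co-occurrence structure with its chi-square (W) criterion, and pairwise
# Spearman rank-correlation screening.

#' Variance-ratio test of overall interspecific association
#'
#' Works on presence/absence (`count > 0`) across N plots. With
#' \eqn{p_i = n_i / N} the occupancy of species `i`, \eqn{T_j} the number
#' of species in plot `j` and \eqn{\bar t} its mean:
#' \deqn{S_T^2 = \frac{1}{N}\sum_j (T_j - \bar t)^2, \quad
#'       \delta_T^2 = \sum_i p_i (1 - p_i), \quad
#'       VR = S_T^2 / \delta_T^2, \quad W = VR \times N}
#' Under independent occurrence VR is close to 1; VR > 1 indicates overall
#' positive association and VR < 1 negative association. Significance at
#' the 5% level uses the two-sided chi-square criterion with N degrees of
#' freedom: the association is positive when `VR > 1` and
#' \eqn{W > \chi^2_{0.05(N)}} (the upper-tail critical value, i.e. the
#' 0.95 quantile), negative when `VR < 1` and
#' \eqn{W < \chi^2_{0.95(N)}} (the 0.05 quantile), and otherwise the
#' species are judged independent.
#'
#' @param matrix a `community_matrix` (any scale; quadrat scale gives the
#'   design's N = 50 per treatment), or a plain units-by-species matrix.
#' @param treatment optional: restrict to one treatment before testing
#'   (requires a `community_matrix`).
#' @return A list of class `variance_ratio` with elements `VR`, `W`, `N`,
#'   `S`, `ST2`, `dT2`, `t_bar`, `chi2_low`, `chi2_high` and `verdict`
#'   (`"positive"`, `"negative"` or `"independent"`).
#' @export
variance_ratio_test <- function(matrix, treatment = NULL) {
  x <- if (inherits(matrix, "community_matrix")) {
    if (!is.null(treatment)) {
      treatment <- match.arg(treatment, TREATMENT_LEVELS)
      keep <- matrix$units$treatment == treatment
      if (!any(keep)) stop("no units with treatment '", treatment, "'")
      matrix$x[keep, , drop = FALSE]
    } else matrix$x
  } else matrix
  pres <- x > 0
  n_plots <- nrow(pres)
  n_species <- ncol(pres)
  if (n_plots < 2 || n_species < 2)
    stop("variance-ratio test needs >= 2 plots and >= 2 species")
  p <- colMeans(pres)
  t_j <- rowSums(pres)
  st2 <- mean((t_j - mean(t_j))^2)
  dt2 <- sum(p * (1 - p))
  if (dt2 == 0)
    stop("expected variance is zero: every species occurs in all plots ",
         "or in none")
  vr <- st2 / dt2
  w <- vr * n_plots
  chi2_low <- stats::qchisq(0.05, df = n_plots)
  chi2_high <- stats::qchisq(0.95, df = n_plots)
  verdict <- if (vr > 1 && w > chi2_high) "positive"
             else if (vr < 1 && w < chi2_low) "negative"
             else "independent"
  structure(list(VR = vr, W = w, N = n_plots, S = n_species, ST2 = st2,
                 dT2 = dt2, t_bar = mean(t_j), chi2_low = chi2_low,
                 chi2_high = chi2_high, verdict = verdict),
            class = "variance_ratio")
}

#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf("variance ratio VR = %.3f, W = %.2f, N = %d, S = %d\n",
              x$VR, x$W, x$N, x$S))
  cat(sprintf("chi-square bounds (df = N): [%.2f, %.2f]; verdict: %s\n",
              x$chi2_low, x$chi2_high, x$verdict))
  invisible(x)
}

#' Pairwise Spearman associations between species
#'
#' Scores every unordered pair of species by the Spearman rank correlation
#' of their abundances across units (average ranks for ties), with a
#' two-sided p-value, multiple-testing adjustment, and a classification:
#' `"positive"` / `"negative"` when the adjusted p-value is below `alpha`
#' with the matching sign of rho, `"neutral"` otherwise. A classification
#' on the raw p-value is reported alongside (`classification_raw`).
#'
#' Species occurring in fewer than `min_occurrences` units are excluded
#' (degenerate ranks); the number of pairs skipped for that reason is
#' returned as an attribute. A constant species inside a pair yields an
#' undefined (`NA`) rho classified as neutral.
#'
#' @param matrix a `community_matrix` or plain units-by-species matrix
#'   (>= 3 units, >= 2 species).
#' @param alpha significance level for classification (default 0.05).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @param treatment optional treatment filter (community_matrix input).
#' @param min_occurrences minimum number of occupied units for a species
#'   to enter the pairwise screen (default 3).
#' @return data.frame with columns `species_a`, `species_b`, `rho`,
#'   `p_raw`, `p_adj`, `classification`, `classification_raw`; attribute
#'   `n_skipped_pairs` counts pairs dropped by the occurrence filter.
#' @export
pairwise_spearman <- function(matrix, alpha = 0.05, adjust = "holm",
                              treatment = NULL, min_occurrences = 3) {
  x <- if (inherits(matrix, "community_matrix")) {
    if (!is.null(treatment)) {
      treatment <- match.arg(treatment, TREATMENT_LEVELS)
      matrix$x[matrix$units$treatment == treatment, , drop = FALSE]
    } else matrix$x
  } else matrix
  if (nrow(x) < 3) stop("pairwise associations need >= 3 units")
  if (ncol(x) < 2) stop("pairwise associations need >= 2 species")
  occ <- colSums(x > 0)
  eligible <- which(occ >= min_occurrences)
  n_total_pairs <- choose(ncol(x), 2)
  n_kept_pairs <- choose(length(eligible), 2)
  pairs <- if (length(eligible) >= 2)
    utils::combn(eligible, 2) else matrix(integer(), 2, 0)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    va <- x[, a]; vb <- x[, b]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      return(data.frame(species_a = colnames(x)[a],
                        species_b = colnames(x)[b],
                        rho = NA_real_, p_raw = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(va, vb, method = "spearman", exact = FALSE))
    data.frame(species_a = colnames(x)[a], species_b = colnames(x)[b],
               rho = unname(ct$estimate), p_raw = ct$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species_a = character(), species_b = character(),
                      rho = numeric(), p_raw = numeric())
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  classify <- function(p) {
    cls <- rep("neutral", nrow(out))
    sig <- !is.na(p) & p < alpha & !is.na(out$rho)
    cls[sig & out$rho > 0] <- "positive"
    cls[sig & out$rho < 0] <- "negative"
    cls
  }
  out$classification <- classify(out$p_adj)
  out$classification_raw <- classify(out$p_raw)
  rownames(out) <- NULL
  attr(out, "n_skipped_pairs") <- n_total_pairs - n_kept_pairs
  out
}
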