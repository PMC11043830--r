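# Alpha diversity per sampling unit: richness, log-variance evenness,
# and the bias-corrected inverse Simpson index.

#' Species richness of an abundance vector
#'
#' Number of species with abundance greater than zero.
#'
#' @param abundances non-negative numeric vector of species abundances.
#' @return Integer richness.
#' @examples
#' richness(c(3, 0, 1))  # 2
#' @export
richness <- function(abundances) {
  check_abundances(abundances)
  sum(abundances > 0)
}

#' Log-variance evenness
#'
#' Evenness index based on the variance of log abundance across the
#' species present:
#' \deqn{E = 1 - \frac{2}{\pi}\arctan(V), \quad
#'       V = \frac{1}{S}\sum_{i=1}^{S}\Big(\ln x_i -
#'           \frac{1}{S}\sum_{j=1}^{S} \ln x_j\Big)^2}
#' where the sums run over the `S` species with `x > 0` and `V` is the
#' population (divide-by-S) variance. `E` is 1 when all abundances are
#' equal and decreases toward 0 as abundances become more uneven. A unit
#' with a single species has zero log-variance, so `E = 1`; such values
#' are degenerate and flagged in [alpha_by_scale()].
#'
#' Because `V` depends only on differences of log abundances, `E` is
#' invariant to multiplying all abundances by a positive constant.
#'
#' @param abundances non-negative numeric vector; at least one value > 0.
#' @return Evenness in `[0, 1]`.
#' @examples
#' evenness(c(7, 7, 7, 7, 7))  # 1
#' evenness(c(1, exp(1)))      # 1 - (2/pi) * atan(0.25)
#' @export
evenness <- function(abundances) {
  check_abundances(abundances)
  x <- abundances[abundances > 0]
  if (!length(x)) stop("evenness undefined for an all-zero unit")
  lx <- log(x)
  v <- mean((lx - mean(lx))^2)
  1 - (2 / pi) * atan(v)
}

#' Bias-corrected inverse Simpson index
#'
#' Computes \eqn{1/\lambda} with the small-sample (bias-corrected)
#' concentration estimator
#' \deqn{\lambda = \sum_i \frac{n_i (n_i - 1)}{T (T - 1)}}
#' where \eqn{n_i} is the shoot count of species `i` and
#' \eqn{T = \sum n_i}. The index equals the number of species for a
#' perfectly even community and grows with both richness and evenness.
#'
#' The estimator is undefined (returns `NA`) when `T < 2` or when every
#' species is a singleton (\eqn{\lambda = 0}); undefined values propagate
#' as missing, never as zero.
#'
#' @param abundances non-negative integer vector of species counts.
#' @return Positive numeric (`>= 1`), or `NA_real_` when undefined.
#' @examples
#' inverse_simpson(c(2, 2))  # 3
#' inverse_simpson(c(5))     # 1
#' inverse_simpson(c(1, 1))  # NA: all singletons
#' @export
inverse_simpson <- function(abundances) {
  check_abundances(abundances)
  n <- abundances[abundances > 0]
  total <- sum(n)
  if (total < 2) return(NA_real_)
  lambda <- sum(n * (n - 1)) / (total * (total - 1))
  if (lambda == 0) return(NA_real_)
  1 / lambda
}

check_abundances <- function(abundances) {
  if (!is.numeric(abundances))
    stop("abundances must be numeric")
  if (any(is.na(abundances)) || any(abundances < 0))
    stop("abundances must be non-negative and non-missing")
  invisible(abundances)
}

alpha_unit_table <- function(cm) {
  x <- cm$x
  s <- apply(x, 1, richness)
  total <- rowSums(x)
  e <- rep(NA_real_, nrow(x))
  e[total > 0] <- apply(x[total > 0, , drop = FALSE], 1, evenness)
  invs <- apply(x, 1, inverse_simpson)
  cbind(cm$units,
        data.frame(scale = cm$scale, S = as.integer(s), E = e,
                   inv_simpson = invs, total = as.integer(total),
                   degenerate_evenness = s == 1))
}

se <- function(v) stats::sd(v) / sqrt(length(v))

#' Alpha diversity at every spatial scale
#'
#' Computes richness `S`, evenness `E` and the bias-corrected inverse
#' Simpson index for every sampling unit at each requested scale, plus
#' per treatment-by-scale means and standard errors. Units where the
#' inverse Simpson estimator is undefined are excluded from its mean, and
#' the number excluded is reported (`n_excluded_inv_simpson`). Single
#' species units have `E = 1` by construction and are flagged
#' (`degenerate_evenness`).
#'
#' @param dataset a [community_dataset()].
#' @param scales character subset of `c("cell", "quadrat", "exclosure")`.
#' @return A list of class `alpha_by_scale` with `units` (one row per unit
#'   per scale) and `summary` (one row per treatment x scale x statistic,
#'   with `mean`, `se`, `n`).
#' @export
alpha_by_scale <- function(dataset, scales = SCALE_LEVELS) {
  stopifnot(inherits(dataset, "community_dataset"))
  scales <- match.arg(scales, SCALE_LEVELS, several.ok = TRUE)
  units <- do.call(rbind, lapply(scales, function(sc) {
    tab <- alpha_unit_table(aggregate_counts(dataset, sc))
    keep <- c("pair_id", "treatment", "plot_id", "quadrat_id", "cell_id")
    for (col in setdiff(keep, names(tab))) tab[[col]] <- NA_character_
    tab[c("unit_id", keep, "scale", "S", "E", "inv_simpson", "total",
          "degenerate_evenness")]
  }))
  rownames(units) <- NULL
  summary <- do.call(rbind, lapply(split(
    units, list(units$treatment, units$scale), drop = TRUE),
    function(g) {
      invs <- g$inv_simpson[!is.na(g$inv_simpson)]
      data.frame(
        treatment = g$treatment[1], scale = g$scale[1],
        statistic = c("richness", "evenness", "inv_simpson"),
        mean = c(mean(g$S), mean(g$E), mean(invs)),
        se = c(se(g$S), se(g$E), se(invs)),
        n = c(nrow(g), nrow(g), length(invs)),
        n_excluded_inv_simpson = sum(is.na(g$inv_simpson)))
    }))
  rownames(summary) <- NULL
  structure(list(units = units, summary = summary),
            class = "alpha_by_scale")
}

#' @export
print.alpha_by_scale <- function(x, ...) {
  cat("alpha diversity:", nrow(x$units), "unit rows across scales",
      paste(unique(x$units$scale), collapse = "/"), "\n")
  print(x$summary, digits = 4)
  invisible(x)
}
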