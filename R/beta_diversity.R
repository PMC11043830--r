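# Abundance-based beta diversity: Bray-Curtis dissimilarity partitioned
# into balanced-variation (turnover) and abundance-gradient (nestedness)
# components, per-unit multi-scale summaries, and species contributions
# to beta diversity (SCBD).

#' Partition Bray-Curtis dissimilarity between two plots
#'
#' For abundance vectors \eqn{x_j}, \eqn{x_k} over the same species list:
#' \deqn{A = \sum_i \min(x_{ij}, x_{ik}), \quad
#'       B = \sum_i (x_{ij} - \min), \quad C = \sum_i (x_{ik} - \min)}
#' \deqn{\beta_{BC} = \frac{B + C}{2A + B + C} = \beta_{bal} + \beta_{gra}}
#' \deqn{\beta_{bal} = \frac{\min(B, C)}{A + \min(B, C)}, \quad
#'       \beta_{gra} = \frac{|B - C|}{2A + B + C}\cdot
#'                     \frac{A}{A + \min(B, C)}}
#' The balanced-variation component \eqn{\beta_{bal}} captures turnover
#' (individuals of some species substituted by equal numbers of others);
#' the abundance-gradient component \eqn{\beta_{gra}} captures nestedness
#' (individuals lost from one plot without substitution). All three lie in
#' `[0, 1]` and the two components sum exactly to \eqn{\beta_{BC}}.
#'
#' @param x_j,x_k non-negative abundance vectors of equal length.
#' @return data.frame with columns `A`, `B`, `C`, `beta_bc`, `beta_bal`,
#'   `beta_gra`. If both plots are entirely empty the three dissimilarity
#'   values are `NA` (undefined, not zero).
#' @examples
#' bray_curtis_partition(c(3, 0), c(0, 3))  # pure substitution
#' bray_curtis_partition(c(4, 2), c(2, 2))  # pure abundance loss
#' @export
bray_curtis_partition <- function(x_j, x_k) {
  if (length(x_j) != length(x_k))
    stop("abundance vectors must cover the same species list")
  check_abundances(x_j); check_abundances(x_k)
  m <- pmin(x_j, x_k)
  a <- sum(m)
  b <- sum(x_j - m)
  cc <- sum(x_k - m)
  if (a + b + cc == 0)
    return(data.frame(A = 0, B = 0, C = 0, beta_bc = NA_real_,
                      beta_bal = NA_real_, beta_gra = NA_real_))
  mbc <- min(b, cc)
  # when one plot is empty, A = min(B, C) = 0: the turnover component is 0
  # and the gradient factor A / (A + min(B, C)) tends to 1, so the whole
  # dissimilarity is an abundance gradient
  beta_bal <- if (a + mbc > 0) mbc / (a + mbc) else 0
  grad_factor <- if (a + mbc > 0) a / (a + mbc) else 1
  beta_gra <- (abs(b - cc) / (2 * a + b + cc)) * grad_factor
  data.frame(A = a, B = b, C = cc,
             beta_bc = (b + cc) / (2 * a + b + cc),
             beta_bal = beta_bal, beta_gra = beta_gra)
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Classical abundance-based Bray-Curtis dissimilarity between all unit
#' pairs of a community matrix, as needed by [permanova()].
#'
#' @param matrix a `community_matrix` from [aggregate_counts()], or a
#'   plain units-by-species numeric matrix.
#' @return A `dist` object.
#' @export
bray_curtis_dist <- function(matrix) {
  x <- if (inherits(matrix, "community_matrix")) matrix$x else matrix
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(n - 1)) {
    xi <- x[j, ]
    rest <- x[(j + 1):n, , drop = FALSE]
    m <- sweep(rest, 2, xi, pmin)
    tot <- rowSums(rest) + sum(xi)
    bc <- ifelse(tot > 0, 1 - 2 * rowSums(m) / tot, NA_real_)
    d[(j + 1):n, j] <- d[j, (j + 1):n] <- bc
  }
  stats::as.dist(d)
}

# mean pairwise partition of each unit against the other units in its
# comparison group; pairs with both units empty are excluded.
group_mean_partition <- function(x) {
  n <- nrow(x)
  sums <- matrix(0, n, 3,
                 dimnames = list(rownames(x),
                                 c("beta_bc", "beta_bal", "beta_gra")))
  counts <- numeric(n)
  empty_pairs <- 0L
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    p <- bray_curtis_partition(x[j, ], x[k, ])
    if (is.na(p$beta_bc)) { empty_pairs <- empty_pairs + 1L; next }
    v <- c(p$beta_bc, p$beta_bal, p$beta_gra)
    sums[j, ] <- sums[j, ] + v
    sums[k, ] <- sums[k, ] + v
    counts[j] <- counts[j] + 1
    counts[k] <- counts[k] + 1
  }
  means <- sums / ifelse(counts > 0, counts, NA_real_)
  list(means = means, n_pairs = counts, empty_pairs = empty_pairs)
}

beta_comparison_group <- function(units, scale) {
  switch(scale,
    cell      = paste(units$pair_id, units$treatment, units$plot_id,
                      units$quadrat_id, sep = "|"),
    quadrat   = paste(units$pair_id, units$treatment, units$plot_id,
                      sep = "|"),
    exclosure = units$treatment)
}

#' Per-unit beta diversity at one scale
#'
#' Each unit's beta diversity is the mean of its pairwise Bray-Curtis
#' partitions against all other units of its comparison group: cells are
#' compared within their quadrat, quadrats within their plot, and
#' exclosure-scale plots within their treatment. This grouping yields one
#' value per sampling unit, i.e. N = 1250 / 50 / 10 per treatment for the
#' full design. Cross-treatment pairs are never formed.
#'
#' @param matrix a `community_matrix` from [aggregate_counts()].
#' @return A list of class `per_unit_beta` with `units` (per-unit mean
#'   `beta_bc`, `beta_bal`, `beta_gra` plus the number of pairs used) and
#'   `summary` (treatment means and standard errors). Units whose group
#'   has a single member are skipped with a warning; pairs in which both
#'   units are empty are excluded and counted in
#'   `attr(, "n_empty_pairs")`.
#' @export
per_unit_beta <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  groups <- beta_comparison_group(matrix$units, matrix$scale)
  out <- vector("list", length(unique(groups)))
  empty_pairs <- 0L
  singletons <- 0L
  idx <- split(seq_len(nrow(matrix$x)), groups)
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    if (length(rows) < 2) { singletons <- singletons + 1L; next }
    gm <- group_mean_partition(matrix$x[rows, , drop = FALSE])
    empty_pairs <- empty_pairs + gm$empty_pairs
    out[[i]] <- cbind(matrix$units[rows, , drop = FALSE],
                      as.data.frame(gm$means),
                      n_pairs = gm$n_pairs)
  }
  if (singletons > 0)
    warning(singletons, " comparison group(s) of size 1 skipped")
  units <- do.call(rbind, out)
  rownames(units) <- NULL
  summary <- do.call(rbind, lapply(
    split(units, units$treatment, drop = TRUE), function(g) {
      data.frame(treatment = g$treatment[1], scale = matrix$scale,
                 statistic = c("beta_bc", "beta_bal", "beta_gra"),
                 mean = c(mean(g$beta_bc, na.rm = TRUE),
                          mean(g$beta_bal, na.rm = TRUE),
                          mean(g$beta_gra, na.rm = TRUE)),
                 se = c(se(g$beta_bc[!is.na(g$beta_bc)]),
                        se(g$beta_bal[!is.na(g$beta_bal)]),
                        se(g$beta_gra[!is.na(g$beta_gra)])),
                 n = sum(!is.na(g$beta_bc)))
    }))
  rownames(summary) <- NULL
  structure(list(units = units, summary = summary, scale = matrix$scale),
            class = "per_unit_beta", n_empty_pairs = empty_pairs)
}

#' @export
print.per_unit_beta <- function(x, ...) {
  cat("per-unit beta diversity (", x$scale, " scale), ", nrow(x$units),
      " units\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Species contributions to beta diversity (SCBD)
#'
#' The contribution of species `i` is its share of the total among-unit
#' sum of squares of the raw abundance matrix:
#' \deqn{SCBD_i = \frac{\sum_j (x_{ij} - \bar x_i)^2}
#'                    {\sum_i \sum_j (x_{ij} - \bar x_i)^2}}
#' Raw abundances are used, with no transformation. Values lie in
#' `[0, 1]` and sum to 1.
#'
#' @param matrix a `community_matrix`, or a plain units-by-species matrix
#'   with at least 2 units.
#' @return data.frame with columns `species` and `scbd`, sorted by
#'   decreasing contribution.
#' @export
scbd <- function(matrix) {
  x <- if (inherits(matrix, "community_matrix")) matrix$x else matrix
  if (nrow(x) < 2) stop("SCBD needs at least 2 units")
  ss <- colSums(sweep(x, 2, colMeans(x))^2)
  if (sum(ss) == 0)
    stop("total sum of squares is zero (all units identical)")
  out <- data.frame(species = colnames(x), scbd = ss / sum(ss))
  out <- out[order(-out$scbd, out$species), ]
  rownames(out) <- NULL
  out
}
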