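# Hierarchical synthetic-data generator emulating a paired
# exclosure/control design: a lognormal species-abundance distribution,
# lognormal plot- and quadrat-level compositional patchiness, occupancy
# thinning, and tunable treatment effects (richness boost, dominance
# flattening, homogenization, shoot-density multiplier), with Poisson
# shoot counts per 4 cm^2 cell.

# occupancy saturation rate: a species with global relative abundance g
# occupies a quadrat with baseline probability 1 - exp(-OCC_RATE * g),
# so dominants are near-ubiquitous and rare species patchy.
OCC_RATE <- 25

#' Configuration for the synthetic community generator
#'
#' Defaults reproduce the dimensions and magnitudes of the emulated field
#' design: 10 exclosure/control pairs, 5 quadrats (10 x 10 cm) per plot,
#' 25 cells (2 x 2 cm) per quadrat (2500 cells in total over both
#' treatments), a 52-species pool (34 acrocarps, 16 pleurocarps,
#' 2 Sphagnum) with a skewed lognormal abundance distribution, an
#' expected 9.0 shoots per cm^2 in absence of geese (36 per cell) and a
#' 1.7-fold density multiplier in their presence.
#'
#' @param n_pairs number of paired exclosure/control plots.
#' @param quadrats_per_plot quadrats per plot.
#' @param cells_per_quadrat cells per quadrat (5 x 5 grid, row-major).
#' @param n_species,n_acrocarp,n_pleurocarp,n_sphagnum species pool and
#'   its growth-form composition (`n_species` must equal the sum).
#' @param sad_sigma lognormal shape of global species relative
#'   abundances; larger = more skewed.
#' @param base_density expected shoots per cell in the absence treatment
#'   (36 shoots per 4 cm^2 cell = 9.0 per cm^2).
#' @param density_multiplier presence/absence shoot-density ratio.
#' @param richness_effect occupancy-probability boost, in presence, for
#'   subordinate species (those below median global relative abundance);
#'   `>= 0`.
#' @param evenness_effect dominance-flattening exponent in presence: the
#'   species weights are raised to the power `1 - evenness_effect`;
#'   in `[0, 1]`.
#' @param homogenization mixing weight, in presence, of quadrat-specific
#'   species weights toward the plot-shared pool; in `[0, 1]`.
#' @param patchiness_sigma sd of the lognormal plot- and quadrat-level
#'   random effects on species weights (compositional patchiness).
#' @param seed master integer seed; per-plot and per-quadrat substreams
#'   are derived from it by fixed hashing, so enlarging the design does
#'   not scramble earlier units.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 10, quadrats_per_plot = 5,
                             cells_per_quadrat = 25, n_species = 52,
                             n_acrocarp = 34, n_pleurocarp = 16,
                             n_sphagnum = 2, sad_sigma = 1.5,
                             base_density = 36, density_multiplier = 1.7,
                             richness_effect = 0.15,
                             evenness_effect = 0.3, homogenization = 0.5,
                             patchiness_sigma = 0.8, seed = 1) {
  cfg <- list(n_pairs = n_pairs, quadrats_per_plot = quadrats_per_plot,
              cells_per_quadrat = cells_per_quadrat,
              n_species = n_species, n_acrocarp = n_acrocarp,
              n_pleurocarp = n_pleurocarp, n_sphagnum = n_sphagnum,
              sad_sigma = sad_sigma, base_density = base_density,
              density_multiplier = density_multiplier,
              richness_effect = richness_effect,
              evenness_effect = evenness_effect,
              homogenization = homogenization,
              patchiness_sigma = patchiness_sigma, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Default generator configuration
#'
#' @return `synthetic_config()` with all defaults.
#' @export
default_config <- function() synthetic_config()

validate_config <- function(cfg) {
  num1 <- function(field, min = NULL, max = NULL, integer = FALSE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1 && !is.na(v) &&
      (is.null(min) || v >= min) && (is.null(max) || v <= max) &&
      (!integer || v == round(v))
    if (!ok) stop("invalid config field '", field, "'")
  }
  for (f in c("n_pairs", "quadrats_per_plot", "cells_per_quadrat",
              "n_species"))
    num1(f, min = 1, integer = TRUE)
  for (f in c("n_acrocarp", "n_pleurocarp", "n_sphagnum"))
    num1(f, min = 0, integer = TRUE)
  if (cfg$n_acrocarp + cfg$n_pleurocarp + cfg$n_sphagnum != cfg$n_species)
    stop("growth-form counts must sum to n_species")
  num1("sad_sigma", min = 0)
  num1("base_density", min = 0)
  num1("density_multiplier", min = 0)
  num1("richness_effect", min = 0, max = 1)
  num1("evenness_effect", min = 0, max = 1)
  num1("homogenization", min = 0, max = 1)
  num1("patchiness_sigma", min = 0)
  num1("seed", integer = TRUE)
  invisible(cfg)
}

# deterministic substream seed; coefficients keep products exact in
# double precision for master seeds below 2^31
sub_seed <- function(seed, idx) {
  as.integer((abs(as.numeric(seed)) * 48271 + idx * 16807) %% 2147483629)
}

#' Simulate a hierarchical community dataset
#'
#' Fully deterministic given the configuration (which includes the master
#' seed). The generative model:
#' 1. global species relative abundances are drawn from a lognormal SAD
#'    (`sad_sigma`) and normalised;
#' 2. every plot, and every quadrat within it, receives independent
#'    lognormal random effects (`patchiness_sigma`) multiplying the
#'    species weights (compositional patchiness);
#' 3. in presence plots the quadrat weights are flattened by raising to
#'    the power `1 - evenness_effect`, subordinate species (below median
#'    global abundance) get `richness_effect` added to their occupancy
#'    probability, and quadrat weights are mixed toward the plot-shared
#'    pool with weight `homogenization`;
#' 4. species occupancy per quadrat is Bernoulli with baseline
#'    probability `1 - exp(-25 g_s)` in the global relative abundance
#'    `g_s`;
#' 5. occupied-species weights are renormalised so the expected total per
#'    cell equals `base_density` (times `density_multiplier` in
#'    presence), and cell counts are independent Poisson draws;
#' 6. growth forms are assigned from the configured pool composition.
#'
#' Only positive counts are recorded, except that a cell with no shoots
#' at all is registered by a single zero-count row so that every cell of
#' the design appears in the dataset.
#'
#' @param config a [synthetic_config()].
#' @return A [community_dataset()] with registry.
#' @export
simulate_dataset <- function(config = default_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  n_sp <- cfg$n_species
  species <- sprintf("species_%02d", seq_len(n_sp))
  registry <- data.frame(
    species = species,
    genus = sprintf("genus_%02d", ceiling(seq_len(n_sp) / 2)),
    growth_form = rep(GROWTH_FORMS,
                      c(cfg$n_acrocarp, cfg$n_pleurocarp, cfg$n_sphagnum)))

  set.seed(sub_seed(cfg$seed, 0))
  g <- exp(stats::rnorm(n_sp, 0, cfg$sad_sigma))
  g <- g / sum(g)
  subordinate <- g < stats::median(g)
  occ_base <- 1 - exp(-OCC_RATE * g)

  q_per_plot <- cfg$quadrats_per_plot
  n_cells <- cfg$cells_per_quadrat
  chunks <- list()
  ci <- 0L
  for (pair in seq_len(cfg$n_pairs)) {
    for (ti in 1:2) {
      trt <- TREATMENT_LEVELS[ti]
      presence <- trt == "presence"
      plot_idx <- (pair - 1L) * 2L + ti
      set.seed(sub_seed(cfg$seed, plot_idx * (q_per_plot + 1L)))
      w_plot <- g * stats::rlnorm(n_sp, 0, cfg$patchiness_sigma)
      pool <- if (presence) w_plot^(1 - cfg$evenness_effect) else w_plot
      pool <- pool / sum(pool)
      occ <- occ_base
      if (presence)
        occ[subordinate] <- pmin(1, occ[subordinate] + cfg$richness_effect)
      target <- cfg$base_density *
        if (presence) cfg$density_multiplier else 1
      for (q in seq_len(q_per_plot)) {
        set.seed(sub_seed(cfg$seed, plot_idx * (q_per_plot + 1L) + q))
        w_q <- w_plot * stats::rlnorm(n_sp, 0, cfg$patchiness_sigma)
        if (presence) {
          w_q <- w_q^(1 - cfg$evenness_effect)
          w_q <- w_q / sum(w_q)
          w_q <- (1 - cfg$homogenization) * w_q +
            cfg$homogenization * pool
        } else {
          w_q <- w_q / sum(w_q)
        }
        z <- stats::rbinom(n_sp, 1, occ)
        w_eff <- w_q * z
        if (sum(w_eff) == 0) w_eff[which.max(w_q)] <- w_q[which.max(w_q)]
        m <- target * w_eff / sum(w_eff)
        counts <- matrix(stats::rpois(n_cells * n_sp,
                                      rep(m, each = n_cells)),
                         nrow = n_cells)
        nz <- which(counts > 0, arr.ind = TRUE)
        empty_cells <- which(rowSums(counts) == 0)
        if (length(empty_cells))
          nz <- rbind(nz, cbind(empty_cells,
                                rep(which.max(g), length(empty_cells))))
        ci <- ci + 1L
        chunks[[ci]] <- data.frame(
          pair_id = sprintf("pair_%02d", pair),
          treatment = trt,
          plot_id = sprintf("plot_%02d_%s", pair, substr(trt, 1, 3)),
          quadrat_id = as.character(q),
          cell_id = as.character(nz[, 1]),
          species = species[nz[, 2]],
          count = counts[nz])
      }
    }
  }
  records <- do.call(rbind, chunks)
  community_dataset(records, registry)
}
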