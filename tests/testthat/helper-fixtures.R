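# Fixture builders shared across the suite. All fixtures are built in
# code; nothing is read from disk except in roundtrip tests that write
# their own temporary files.

make_records <- function(pair_id = "p1", treatment = "absence",
                         plot_id = "plot1", quadrat_id = "1",
                         cell_id = "1", species = "sp1", count = 1L) {
  data.frame(pair_id = pair_id, treatment = treatment, plot_id = plot_id,
             quadrat_id = quadrat_id, cell_id = cell_id,
             species = species, count = count,
             stringsAsFactors = FALSE)
}

# one quadrat of 25 cells, two species with fixed counts
one_quadrat_dataset <- function(count_a = 3L, count_b = 1L) {
  rec <- rbind(
    make_records(cell_id = as.character(1:25), species = "spA",
                 count = count_a),
    make_records(cell_id = as.character(1:25), species = "spB",
                 count = count_b))
  community_dataset(rec)
}

random_dataset <- function(seed = 1, n_pairs = 2, n_species = 8) {
  set.seed(seed)
  grid <- expand.grid(pair = seq_len(n_pairs),
                      treatment = c("absence", "presence"),
                      quadrat = 1:2, cell = 1:4,
                      species = sprintf("sp%02d", seq_len(n_species)),
                      stringsAsFactors = FALSE)
  rec <- data.frame(pair_id = paste0("p", grid$pair),
                    treatment = grid$treatment,
                    plot_id = paste0("p", grid$pair, "_",
                                     substr(grid$treatment, 1, 3)),
                    quadrat_id = as.character(grid$quadrat),
                    cell_id = as.character(grid$cell),
                    species = grid$species,
                    count = rpois(nrow(grid), 2))
  community_dataset(rec)
}

# cached default-design simulation so several files can share one draw
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(synthetic_config(seed = seed))
  .sim_cache[[key]]
}

small_config <- function(seed = 1, ...) {
  synthetic_config(n_pairs = 3, quadrats_per_plot = 3,
                   cells_per_quadrat = 9, n_species = 12,
                   n_acrocarp = 8, n_pleurocarp = 3, n_sphagnum = 1,
                   seed = seed, ...)
}
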