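# Data model and I/O for hierarchically sampled shoot-count data:
# cells (4 cm^2, 25 per quadrat) within quadrats (100 cm^2, 5 per plot)
# within paired exclosure (goose absence) / control (goose presence) plots.

#' @keywords internal
"_PACKAGE"

TREATMENT_LEVELS <- c("absence", "presence")
GROWTH_FORMS <- c("acrocarp", "pleurocarp", "sphagnum")
SCALE_LEVELS <- c("cell", "quadrat", "exclosure")
CELL_AREA_CM2 <- 4

ABUNDANCE_COLUMNS <- c("pair_id", "treatment", "plot_id", "quadrat_id",
                       "cell_id", "species", "count")
REGISTRY_COLUMNS <- c("species", "genus", "growth_form")

#' Construct a community dataset
#'
#' Bundles a long-format table of shoot counts with an optional species
#' registry (genus and growth form per species). One record is one
#' (pair, treatment, plot, quadrat, cell, species) combination; `count` is
#' the number of individual shoots of that species in that 4 cm^2 cell.
#' Zero counts are legal and mean recorded absence; presence always means
#' `count > 0`.
#'
#' @param records data.frame with columns `pair_id`, `treatment`
#'   (`"absence"` = inside the exclosure, `"presence"` = grazed control),
#'   `plot_id`, `quadrat_id`, `cell_id`, `species`, `count`.
#' @param registry optional data.frame with columns `species`, `genus`,
#'   `growth_form` (one of `"acrocarp"`, `"pleurocarp"`, `"sphagnum"`).
#' @param cell_area cell area in cm^2 (fixed at 4 in the sampling design).
#' @return An object of class `community_dataset`: a list with elements
#'   `records`, `registry` and `cell_area`.
#' @examples
#' rec <- data.frame(pair_id = 1, treatment = "absence", plot_id = "p1",
#'                   quadrat_id = 1, cell_id = 1:2,
#'                   species = "sp1", count = c(3L, 4L))
#' community_dataset(rec)
#' @export
community_dataset <- function(records, registry = NULL,
                              cell_area = CELL_AREA_CM2) {
  records <- validate_records(records)
  if (!is.null(registry)) registry <- validate_registry(registry)
  structure(list(records = records, registry = registry,
                 cell_area = cell_area),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  r <- x$records
  cat("community_dataset:", nrow(r), "records,",
      length(unique(r$species)), "species,",
      length(unique(interaction(r$pair_id, r$treatment, r$plot_id))),
      "plots\n")
  cat("treatments:", paste(sort(unique(r$treatment)), collapse = ", "), "\n")
  if (!is.null(x$registry))
    cat("registry:", nrow(x$registry), "species\n")
  invisible(x)
}

validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  missing_cols <- setdiff(ABUNDANCE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[ABUNDANCE_COLUMNS]
  for (col in c("pair_id", "plot_id", "quadrat_id", "cell_id", "species",
                "treatment"))
    records[[col]] <- as.character(records[[col]])
  bad_trt <- !records$treatment %in% TREATMENT_LEVELS
  if (any(bad_trt))
    stop("invalid treatment at row(s) ",
         paste(utils::head(which(bad_trt), 5), collapse = ", "),
         " (must be 'absence' or 'presence')")
  cnt <- records$count
  if (!is.numeric(cnt)) stop("count must be numeric")
  bad <- is.na(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad))
    stop("count must be a non-negative integer; offending row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  records$count <- as.integer(round(cnt))
  key <- do.call(paste, c(records[c("pair_id", "treatment", "plot_id",
                                    "quadrat_id", "cell_id", "species")],
                          sep = "\r"))
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (pair, treatment, plot, quadrat, cell, species) key ",
         "at row(s): ", paste(utils::head(which(dup), 5), collapse = ", "))
  rownames(records) <- NULL
  records
}

validate_registry <- function(registry) {
  if (!is.data.frame(registry)) stop("registry must be a data.frame")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(registry))
  if (length(missing_cols))
    stop("registry missing column(s): ",
         paste(missing_cols, collapse = ", "))
  registry <- registry[REGISTRY_COLUMNS]
  for (col in REGISTRY_COLUMNS)
    registry[[col]] <- as.character(registry[[col]])
  if (anyDuplicated(registry$species))
    stop("duplicate species in registry: ",
         paste(unique(registry$species[duplicated(registry$species)]),
               collapse = ", "))
  bad <- !registry$growth_form %in% GROWTH_FORMS
  if (any(bad))
    stop("unknown growth_form: ",
         paste(unique(registry$growth_form[bad]), collapse = ", "))
  rownames(registry) <- NULL
  registry
}

#' Read an abundance table (and optional species registry) from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row naming the seven
#' record fields (`pair_id`, `treatment`, `plot_id`, `quadrat_id`,
#' `cell_id`, `species`, `count`). Rows with `count = 0` are retained as
#' explicit absences. Validation failures (missing column, negative or
#' non-integer count, duplicated key) raise an error naming the offending
#' rows.
#'
#' @param path path to the abundance CSV.
#' @param registry_path optional path to a species registry CSV with
#'   columns `species`, `genus`, `growth_form`.
#' @return A [community_dataset()].
#' @export
read_abundance_table <- function(path, registry_path = NULL) {
  records <- utils::read.csv(path, colClasses = "character",
                             fileEncoding = "UTF-8")
  if ("count" %in% names(records))
    records$count <- suppressWarnings(as.numeric(records$count))
  registry <- if (!is.null(registry_path))
    read_species_registry(registry_path)
  community_dataset(records, registry)
}

#' Read a species registry CSV
#'
#' @param path path to a CSV with columns `species`, `genus`, `growth_form`.
#' @return Validated registry data.frame.
#' @export
read_species_registry <- function(path) {
  validate_registry(utils::read.csv(path, colClasses = "character",
                                    fileEncoding = "UTF-8"))
}

#' Write a community dataset back to CSV
#'
#' Emits the same comma-separated dialect that [read_abundance_table()]
#' reads, so that read -> write -> read is the identity on records.
#'
#' @param dataset a [community_dataset()].
#' @param path output path for the abundance table.
#' @param registry_path optional output path for the registry.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(dataset, path, registry_path = NULL) {
  stopifnot(inherits(dataset, "community_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(registry_path) && !is.null(dataset$registry))
    utils::write.csv(dataset$registry, registry_path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

unit_key <- function(records, scale) {
  scale <- match.arg(scale, SCALE_LEVELS)
  cols <- switch(scale,
    cell      = c("pair_id", "treatment", "plot_id", "quadrat_id", "cell_id"),
    quadrat   = c("pair_id", "treatment", "plot_id", "quadrat_id"),
    exclosure = c("pair_id", "treatment", "plot_id"))
  list(cols = cols,
       key = do.call(paste, c(records[cols], sep = "|")))
}

#' Aggregate shoot counts to one of the three spatial scales
#'
#' Sums raw counts within each sampling unit at the requested scale of the
#' nested design (cells within quadrats within exclosure-scale plots).
#' Totals are conserved exactly across scales. With the full default
#' design this yields 1250 cells, 50 quadrats or 10 exclosure-scale plots
#' per treatment.
#'
#' @param dataset a [community_dataset()].
#' @param scale one of `"cell"`, `"quadrat"`, `"exclosure"`.
#' @return An object of class `community_matrix`: a list with `x`, a
#'   units-by-species integer matrix of summed counts; `units`, a
#'   data.frame of unit hierarchy labels (one row per matrix row); and
#'   `scale`.
#' @examples
#' rec <- data.frame(pair_id = 1, treatment = "absence", plot_id = "p1",
#'                   quadrat_id = 1, cell_id = 1:2,
#'                   species = "sp1", count = c(3L, 4L))
#' aggregate_counts(community_dataset(rec), "quadrat")$x
#' @export
aggregate_counts <- function(dataset, scale = c("cell", "quadrat",
                                                "exclosure")) {
  stopifnot(inherits(dataset, "community_dataset"))
  scale <- match.arg(scale)
  records <- dataset$records
  uk <- unit_key(records, scale)
  unit_f <- factor(uk$key, levels = unique(uk$key))
  species_f <- factor(records$species, levels = sort(unique(records$species)))
  x <- tapply(records$count, list(unit_f, species_f), sum, default = 0L)
  x <- matrix(as.integer(x), nrow = nlevels(unit_f),
              dimnames = list(levels(unit_f), levels(species_f)))
  units <- records[!duplicated(uk$key), uk$cols, drop = FALSE]
  units <- units[match(levels(unit_f), uk$key[!duplicated(uk$key)]), ,
                 drop = FALSE]
  units$unit_id <- levels(unit_f)
  rownames(units) <- NULL
  structure(list(x = x, units = units, scale = scale),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix (", x$scale, " scale): ", nrow(x$x), " units x ",
      ncol(x$x), " species, total count ", sum(x$x), "\n", sep = "")
  invisible(x)
}

#' Overall relative frequency of each species
#'
#' The frequency of a species is the number of cells in which it occurs
#' (`count > 0`); its relative frequency is that frequency divided by the
#' sum of all species frequencies, so the values sum to 1.
#'
#' @param dataset a [community_dataset()].
#' @return data.frame with columns `species`, `frequency` (cells occupied)
#'   and `relative_frequency`, sorted by decreasing relative frequency.
#' @export
relative_frequency <- function(dataset) {
  stopifnot(inherits(dataset, "community_dataset"))
  cm <- aggregate_counts(dataset, "cell")
  freq <- colSums(cm$x > 0)
  if (sum(freq) == 0) stop("all counts are zero; frequencies undefined")
  out <- data.frame(species = colnames(cm$x), frequency = as.integer(freq),
                    relative_frequency = freq / sum(freq))
  out <- out[order(-out$relative_frequency, out$species), ]
  rownames(out) <- NULL
  out
}

#' Mean shoot density for one treatment
#'
#' Averages, over all cells of the treatment, the total shoot count of the
#' cell divided by the cell area (4 cm^2). Cells whose total count is zero
#' are included in the mean.
#'
#' @param dataset a [community_dataset()].
#' @param treatment `"absence"` or `"presence"`.
#' @return Mean shoots per cm^2 (single numeric).
#' @examples
#' rec <- data.frame(pair_id = 1, treatment = "absence", plot_id = "p1",
#'                   quadrat_id = 1, cell_id = 1, species = "sp1",
#'                   count = 36L)
#' shoot_density(community_dataset(rec), "absence")  # 9 shoots / cm^2
#' @export
shoot_density <- function(dataset, treatment = c("absence", "presence")) {
  stopifnot(inherits(dataset, "community_dataset"))
  treatment <- match.arg(treatment)
  cm <- aggregate_counts(dataset, "cell")
  keep <- cm$units$treatment == treatment
  if (!any(keep)) stop("no cells with treatment '", treatment, "'")
  totals <- rowSums(cm$x[keep, , drop = FALSE])
  mean(totals) / dataset$cell_area
}
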