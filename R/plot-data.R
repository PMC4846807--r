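#' Read a stem-level inventory table
#'
#' Reads a comma-separated, UTF-8, headered stem table with columns
#' `plot_id`, `stand_code`, `species`, `dbh_cm` and optionally `belt`,
#' `height_m`, `crown_m`.  The belt is always re-derived from the stand code
#' via [stand_design()]; a `belt` column in the file is checked for
#' consistency.
#'
#' @param path Path to the stems CSV.
#' @return A tibble of stem records (one row per measured tree) with columns
#'   `plot_id`, `stand_code`, `belt`, `species`, `dbh_cm`, `height_m`,
#'   `crown_m`.
#' @export
read_stems <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("plot_id", "stand_code", "species", "dbh_cm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Stems file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  design <- stand_design()
  bad_code <- !raw$stand_code %in% design$stand_code
  if (any(bad_code)) {
    abort(paste0(
      "Unknown stand_code in row(s) ", paste(head(which(bad_code), 5), collapse = ", "),
      ": ", paste(unique(raw$stand_code[bad_code]), collapse = ", "),
      ". Valid codes: ", paste(design$stand_code, collapse = ", "), "."
    ))
  }
  if (any(!is.finite(raw$dbh_cm)) || any(raw$dbh_cm <= 0)) {
    abort(paste0("Nonpositive or missing dbh_cm in row(s): ",
                 paste(head(which(!is.finite(raw$dbh_cm) | raw$dbh_cm <= 0), 5),
                       collapse = ", ")))
  }
  stems <- as_tibble(raw) %>%
    mutate(
      plot_id = as.character(plot_id),
      belt = belt_of(stand_code)
    )
  if ("belt" %in% names(raw)) {
    mism <- raw$belt != stems$belt
    if (any(mism)) {
      warn(paste0("belt column disagrees with stand_code in ",
                  sum(mism), " row(s); stand_code takes precedence"))
    }
  }
  for (col in c("height_m", "crown_m")) {
    if (!col %in% names(stems)) stems[[col]] <- NA_real_
  }
  stems %>%
    select(plot_id, stand_code, belt, species, dbh_cm, height_m, crown_m)
}

#' Read a plot parameter table
#'
#' @param path Path to the plots CSV with columns `plot_id`, `stand_code`,
#'   `area_m2` and optionally `elevation_m`.
#' @return Tibble with one row per plot.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  plots <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("plot_id", "stand_code", "area_m2")
  missing <- setdiff(required, names(plots))
  if (length(missing) > 0) {
    abort(paste0("Plots file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(plots$area_m2 <= 0)) abort("area_m2 must be positive")
  plots <- as_tibble(plots) %>%
    mutate(plot_id = as.character(plot_id), belt = belt_of(stand_code))
  if (!"elevation_m" %in% names(plots)) plots$elevation_m <- NA_real_
  plots %>% select(plot_id, stand_code, belt, area_m2, elevation_m)
}

#' Filter stems by diameter at breast height
#'
#' Retains stems whose DBH is at or above the census threshold (the reference
#' protocol includes every stem with DBH >= 5 cm); row order is preserved and
#' the operation is idempotent.
#'
#' @param stems Stem tibble (needs a `dbh_cm` column).
#' @param threshold_cm Inclusive lower DBH bound in cm (default 5).
#' @return Filtered stem tibble.
#' @export
filter_dbh <- function(stems, threshold_cm = 5) {
  if (!is.numeric(threshold_cm) || threshold_cm < 0) {
    abort("threshold_cm must be a nonnegative number")
  }
  dplyr::filter(stems, dbh_cm >= threshold_cm)
}

#' Basal area of a stem from its DBH
#'
#' Cross-sectional area at breast height, `pi * (dbh / 200)^2` square metres
#' for a DBH in centimetres.
#'
#' @param dbh_cm Numeric vector of DBH values in cm (all > 0).
#' @return Basal areas in m^2.
#' @export
#' @examples
#' basal_area(20) # 0.0314 m^2
basal_area <- function(dbh_cm) {
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0)) {
    abort("dbh_cm must be positive and finite")
  }
  pi * (dbh_cm / 200)^2
}

#' Species-by-unit abundance table
#'
#' Cross-tabulates stems into species x sampling-unit counts, where the unit
#' is the plot, the stand, or the belt.
#'
#' @param stems Stem tibble.
#' @param group_by Sampling unit: `"plot"`, `"stand"`, or `"belt"`.
#' @return A tibble with columns `species`, `unit`, `count`; total count
#'   equals `nrow(stems)`.  Use [pooled_abundance()] for per-species totals.
#' @export
abundance_table <- function(stems, group_by = c("plot", "stand", "belt")) {
  group_by <- arg_match(group_by)
  if (nrow(stems) == 0) abort("No stems to tabulate")
  unit_col <- switch(group_by, plot = "plot_id", stand = "stand_code", belt = "belt")
  stems %>%
    mutate(unit = .data[[unit_col]]) %>%
    count(species, unit, name = "count") %>%
    arrange(species, unit)
}

#' Pooled per-species abundances
#'
#' @param x Either a stem tibble or an abundance table from
#'   [abundance_table()].
#' @return Tibble with columns `species`, `n_i`, sorted by decreasing `n_i`;
#'   attributes `N` (total individuals) and `S_obs`.
#' @export
pooled_abundance <- function(x) {
  counts <- if (all(c("species", "count") %in% names(x))) {
    x %>% group_by(species) %>% summarise(n_i = sum(count), .groups = "drop")
  } else {
    x %>% count(species, name = "n_i")
  }
  counts <- counts %>%
    filter(n_i > 0) %>%
    arrange(desc(n_i), species)
  structure(counts, N = sum(counts$n_i), S_obs = nrow(counts))
}

#' Species incidence frequencies across sampling units
#'
#' For sample-based (incidence) diversity analyses: the number of sampling
#' units in which each species occurs.
#'
#' @param stems Stem tibble.
#' @param unit Sampling unit, `"plot"` (default) or `"stand"`.
#' @param n_units Total number of sampling units `T`; defaults to the number
#'   of distinct units present in `stems`, but should be supplied from the
#'   plot table when some units hold no stems.
#' @return Tibble with columns `species`, `Y_i`; attributes `T` (units) and
#'   `U` (total incidences).
#' @export
incidence_table <- function(stems, unit = c("plot", "stand"), n_units = NULL) {
  unit <- arg_match(unit)
  unit_col <- switch(unit, plot = "plot_id", stand = "stand_code")
  if (is.null(n_units)) n_units <- n_distinct(stems[[unit_col]])
  inc <- stems %>%
    distinct(species, .data[[unit_col]]) %>%
    count(species, name = "Y_i") %>%
    arrange(desc(Y_i), species)
  if (any(inc$Y_i > n_units)) abort("Incidence frequency exceeds unit count")
  structure(inc, T = n_units, U = sum(inc$Y_i))
}

#' Per-stand summary attributes
#'
#' Summarises each stand over its plots: numbers of families, genera and
#' species, stem-level and plot-mean DBH statistics, basal area and stem
#' density per hectare.  Density and basal area are scaled by the plot areas
#' recorded in `plots`, never by a hard-coded constant.  DBH `dbh_min`,
#' `dbh_max`, `dbh_mean` follow the convention of published stand tables:
#' minimum, maximum and mean across the stand's plots of the plot-mean DBH;
#' stem-level extremes are reported as `dbh_stem_min` / `dbh_stem_max`.
#'
#' @param stems Stem tibble.
#' @param plots Plot tibble from [read_plots()] (or the generator).
#' @param taxonomy Taxonomy lookup tibble; defaults to
#'   [reference_taxonomy()].
#' @return One row per stand.
#' @export
stand_summary <- function(stems, plots, taxonomy = reference_taxonomy()) {
  tax <- resolve_taxonomy(stems$species, taxonomy)
  stems2 <- stems %>% left_join(tax, by = "species")
  plot_stats <- stems2 %>%
    group_by(stand_code, plot_id) %>%
    summarise(
      n_stems = n(),
      dbh_plot_mean = mean(dbh_cm),
      ba_m2 = sum(basal_area(dbh_cm)),
      .groups = "drop"
    ) %>%
    left_join(select(plots, plot_id, area_m2), by = "plot_id") %>%
    mutate(
      density_ha = n_stems / (area_m2 / 1e4),
      ba_ha = ba_m2 / (area_m2 / 1e4)
    )
  stand_plot <- plot_stats %>%
    group_by(stand_code) %>%
    summarise(
      n_plots = n(),
      dbh_min = min(dbh_plot_mean),
      dbh_max = max(dbh_plot_mean),
      dbh_mean = mean(dbh_plot_mean),
      density_ha = mean(density_ha),
      basal_area_ha = mean(ba_ha),
      .groups = "drop"
    )
  stand_tax <- stems2 %>%
    group_by(stand_code) %>%
    summarise(
      n_stems = n(),
      n_species = n_distinct(species),
      n_genera = n_distinct(genus),
      n_families = n_distinct(family),
      dbh_stem_min = min(dbh_cm),
      dbh_stem_max = max(dbh_cm),
      .groups = "drop"
    )
  stand_tax %>%
    left_join(stand_plot, by = "stand_code") %>%
    mutate(belt = belt_of(stand_code)) %>%
    select(stand_code, belt, n_plots, n_stems, n_species, n_genera, n_families,
           dbh_min, dbh_max, dbh_mean, dbh_stem_min, dbh_stem_max,
           basal_area_ha, density_ha) %>%
    arrange(belt, stand_code)
}

#' Stand-by-species abundance matrix
#'
#' @param stems Stem tibble.
#' @return Numeric matrix, stands in rows (codes as rownames), species in
#'   columns.
#' @export
stand_species_matrix <- function(stems) {
  ab <- abundance_table(stems, group_by = "stand")
  wide <- ab %>%
    tidyr::pivot_wider(names_from = species, values_from = count,
                       values_fill = 0L) %>%
    arrange(unit)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$unit
  m
}
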