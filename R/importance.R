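#' Species importance values
#'
#' The importance value (IV) of a species is the mean of its relative
#' density, relative frequency, and relative dominance:
#' \deqn{IV_i = (RD_i + RF_i + Rd_i)/3}
#' with \eqn{RD_i = 100 n_i/N} (share of individuals),
#' \eqn{RF_i = 100 F_i/\sum_j F_j} where \eqn{F_i} is the fraction of
#' quadrats occupied, and \eqn{Rd_i = 100 d_i/\sum_j d_j} where \eqn{d_i} is
#' the species' total basal area.  With these definitions each relative
#' column sums to 100, so \eqn{\sum_i IV_i = 100}.
#'
#' An alternative convention that normalises frequency by the number of
#' species instead of by total frequency is available as
#' `rf_method = "per_species"`; its RF column does not sum to 100 and it is
#' provided only for comparability with sources that print that formula.
#'
#' @param stems Stem tibble (one row per tree; needs `plot_id`, `species`,
#'   `dbh_cm`).
#' @param quadrat Column used as the frequency quadrat, default `"plot_id"`.
#' @param rf_method `"share"` (default; relative to total frequency) or
#'   `"per_species"`.
#' @return Tibble with columns `species`, `n_i`, `RD`, `F_i`, `RF`, `d_i`,
#'   `Rd`, `IV`, sorted by decreasing IV.  Values are percentages at full
#'   precision; round only for reporting.
#' @export
species_importance <- function(stems, quadrat = "plot_id",
                               rf_method = c("share", "per_species")) {
  rf_method <- arg_match(rf_method)
  if (nrow(stems) == 0) abort("No stems")
  n_quadrats <- n_distinct(stems[[quadrat]])
  if (n_quadrats == 0) abort("No quadrats")
  per_species <- stems %>%
    mutate(.q = .data[[quadrat]]) %>%
    group_by(species) %>%
    summarise(
      n_i = n(),
      F_i = n_distinct(.q) / n_quadrats,
      d_i = sum(basal_area(dbh_cm)),
      .groups = "drop"
    )
  if (sum(per_species$d_i) <= 0) abort("Total basal area is zero")
  S <- nrow(per_species)
  per_species %>%
    mutate(
      RD = 100 * n_i / sum(n_i),
      RF = if (rf_method == "share") 100 * F_i / sum(F_i) else 100 * F_i / S,
      Rd = 100 * d_i / sum(d_i),
      IV = (RD + RF + Rd) / 3
    ) %>%
    select(species, n_i, RD, F_i, RF, d_i, Rd, IV) %>%
    arrange(desc(IV), species)
}

#' Combine relative abundance and relative frequency into ORI
#'
#' Overall relative importance of a family or genus is the sum of its
#' relative abundance and relative frequency (both in percent).
#'
#' @param r_ab Relative abundance (%).
#' @param r_fr Relative frequency (%).
#' @return `r_ab + r_fr`.
#' @export
#' @examples
#' ori_combine(46.84, 17.24)
ori_combine <- function(r_ab, r_fr) {
  r_ab + r_fr
}

#' Family or genus overall relative importance
#'
#' Aggregates stems to a higher taxon and computes relative abundance
#' (`r_ab`, % of individuals), relative frequency (`r_fr`, % of summed
#' quadrat frequencies) and their sum, the overall relative importance
#' (`ori`).
#'
#' @param stems Stem tibble.
#' @param level `"family"` or `"genus"`.
#' @param quadrat Frequency quadrat column, default `"plot_id"`.
#' @param taxonomy Taxonomy lookup; defaults to [reference_taxonomy()].
#' @return Tibble with columns `taxon`, `n_i`, `r_ab`, `r_fr`, `ori`, sorted
#'   by decreasing `ori`.
#' @export
taxon_importance <- function(stems, level = c("family", "genus"),
                             quadrat = "plot_id",
                             taxonomy = reference_taxonomy()) {
  level <- arg_match(level)
  tax <- resolve_taxonomy(stems$species, taxonomy)
  n_quadrats <- n_distinct(stems[[quadrat]])
  stems %>%
    left_join(tax, by = "species") %>%
    mutate(taxon = .data[[level]], .q = .data[[quadrat]]) %>%
    group_by(taxon) %>%
    summarise(
      n_i = n(),
      F_i = n_distinct(.q) / n_quadrats,
      .groups = "drop"
    ) %>%
    mutate(
      r_ab = 100 * n_i / sum(n_i),
      r_fr = 100 * F_i / sum(F_i),
      ori = ori_combine(r_ab, r_fr)
    ) %>%
    select(taxon, n_i, r_ab, r_fr, ori) %>%
    arrange(desc(ori), taxon)
}
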