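#' Published family/genus importance tables for the Qinling two-belt survey
#'
#' The ten most important tree families and genera per belt, as published for
#' the Qinling mid-altitude secondary-forest survey: relative abundance
#' (`r_ab`, %), relative frequency (`r_fr`, %), and overall relative
#' importance (`ori = r_ab + r_fr`).  Bundled so the overall-relative-
#' importance arithmetic can be validated without the raw stem data.
#'
#' @param level `"family"` or `"genus"`.
#' @return A tibble with columns `belt`, `rank`, `taxon`, `r_ab`, `r_fr`, `ori`.
#' @seealso [ori_combine()], [published_importance_totals()]
#' @export
#' @examples
#' published_taxon_importance("family")
published_taxon_importance <- function(level = c("family", "genus")) {
  level <- arg_match(level)
  file <- switch(level,
    family = "qinling_family_importance.csv",
    genus  = "qinling_genus_importance.csv"
  )
  path <- system.file("extdata", file, package = "forestdiv")
  readr::read_csv(path, col_types = "cicddd", progress = FALSE)
}

#' Published column totals of the importance tables
#'
#' Top-ten and remainder row sums of relative abundance, relative frequency
#' and overall relative importance for the published family and genus tables.
#'
#' @return A tibble with columns `level`, `belt`, `rows`, `r_ab`, `r_fr`, `ori`.
#' @export
published_importance_totals <- function() {
  path <- system.file("extdata", "qinling_importance_totals.csv",
                      package = "forestdiv")
  readr::read_csv(path, col_types = "cccddd", progress = FALSE)
}
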