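#' Reference stand design of the two-belt survey
#'
#' The reference sampling design covers two altitudinal vegetation belts
#' (birch and pine-oak) of the Qinling mid-altitude zone, each with five
#' secondary-forest stand types and five 30 x 30 m plots per stand type.
#' Stand codes are abbreviations of the dominant species combination
#' (e.g. `BA` = *Betula albosinensis*, `PTQA` = *Pinus tabuliformis* +
#' *Quercus aliena* var. *acutiserrata*).
#'
#' @return A tibble with columns `stand_code`, `belt`
#'   (`"birch"` or `"pine-oak"`), and `stand_name`.
#' @export
#' @examples
#' stand_design()
stand_design <- function() {
  tibble::tribble(
    ~stand_code, ~belt,      ~stand_name,
    "BA",        "birch",    "Betula albosinensis",
    "TCBA",      "birch",    "Tsuga chinensis + Betula albosinensis",
    "PABA",      "birch",    "Pinus armandii + Betula albosinensis",
    "CTBA",      "birch",    "Carpinus turczaninowii + Betula albosinensis",
    "AFBA",      "birch",    "Abies fargesii + Betula albosinensis",
    "PA",        "pine-oak", "Pinus armandii",
    "PT",        "pine-oak", "Pinus tabuliformis",
    "QA",        "pine-oak", "Quercus aliena var. acutiserrata",
    "PAQA",      "pine-oak", "Pinus armandii + Quercus aliena var. acutiserrata",
    "PTQA",      "pine-oak", "Pinus tabuliformis + Quercus aliena var. acutiserrata"
  )
}

#' Look up the belt of a stand code
#'
#' @param stand_code Character vector of stand codes.
#' @return Character vector of belts (`"birch"` / `"pine-oak"`).
#' @export
belt_of <- function(stand_code) {
  design <- stand_design()
  idx <- match(stand_code, design$stand_code)
  if (anyNA(idx)) {
    bad <- unique(stand_code[is.na(idx)])
    abort(paste0(
      "Unknown stand code(s): ", paste(bad, collapse = ", "),
      ". Valid codes: ", paste(design$stand_code, collapse = ", "), "."
    ))
  }
  design$belt[idx]
}

#' Packaged taxonomy lookup for mid-altitude Qinling tree species
#'
#' A species -> genus -> family lookup covering the tree flora typical of
#' secondary birch and pine-oak belts (Betulaceae, Pinaceae, Fagaceae,
#' Aceraceae, ...).  The genus is also derivable from the binomial; the table
#' mainly supplies the genus -> family mapping used by [stand_summary()] and
#' [taxon_importance()].  Species in user data that are absent from the table
#' are assigned their binomial's genus and family `"unknown"` with a warning.
#'
#' @return A tibble with columns `species`, `genus`, `family`.
#' @export
#' @examples
#' head(reference_taxonomy())
reference_taxonomy <- function() {
  path <- system.file("extdata", "qinling_taxonomy.csv", package = "forestdiv")
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Attach genus and family to a species vector
#'
#' @param species Character vector of binomial names.
#' @param taxonomy Optional taxonomy tibble (`species`, `genus`, `family`);
#'   defaults to [reference_taxonomy()].
#' @return Tibble with columns `species`, `genus`, `family`.
#' @export
resolve_taxonomy <- function(species, taxonomy = reference_taxonomy()) {
  out <- tibble(species = unique(species)) %>%
    left_join(taxonomy, by = "species")
  missing <- is.na(out$family)
  if (any(missing)) {
    warn(paste0(
      "Species not in taxonomy lookup, assigned family 'unknown': ",
      paste(out$species[missing], collapse = ", ")
    ))
    out$genus[missing] <- vapply(
      strsplit(out$species[missing], "\\s+"), `[`, character(1), 1
    )
    out$family[missing] <- "unknown"
  }
  out
}
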