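# In-code fixtures shared across test files.

tiny_stems <- function() {
  tibble::tibble(
    plot_id = c("BA-1", "BA-1", "PT-1"),
    stand_code = c("BA", "BA", "PT"),
    belt = c("birch", "birch", "pine-oak"),
    species = c("Betula albosinensis", "Acer davidii", "Pinus tabuliformis"),
    dbh_cm = c(12.5, 8.1, 20),
    height_m = c(11, 7.5, 14),
    crown_m = c(3.2, 2.1, 4)
  )
}

write_tiny_stems_csv <- function(path = tempfile(fileext = ".csv")) {
  readr::write_csv(tiny_stems(), path)
  path
}

# Reduced-size survey for fast integration tests: same design and dominance
# structure as the defaults, fewer stems per plot.
small_survey <- function(seed = 1, stems_per_plot = c(birch = 30, pineoak = 28)) {
  specs <- default_belt_specs()
  specs$birch$stems_per_plot <- stems_per_plot[["birch"]]
  specs$pineoak$stems_per_plot <- stems_per_plot[["pineoak"]]
  gen_survey(specs$birch, specs$pineoak, seed = seed)
}
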