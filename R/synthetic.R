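# Synthetic two-belt stem survey generator with known ground truth.
#
# The default specifications emulate the reference survey design: two belts
# of 5 stand types x 5 plots of 30 x 30 m, ~117 and ~110 stems per plot
# (N ~ 2900 and ~2750 per belt), 43- and 41-species pools sharing 34 species
# (50 overall), a flat log-normal dominance structure for the birch belt and
# a concentrated Zipf dominance structure (gamma = -1.5, top three species
# ~ 63% of stems, every pool species still detectable) for the pine-oak
# belt.

#' Specification of one synthetic survey belt
#'
#' @param belt Belt name (`"birch"` or `"pine-oak"`).
#' @param stand_codes Five stand codes from [stand_design()] belonging to
#'   the belt.
#' @param species Species pool in rank order (rank 1 receives the largest
#'   expected relative abundance).
#' @param sad_model SAD model generating expected relative abundances:
#'   `"broken-stick"`, `"preemption"`, `"lognormal"`, `"zipf"`,
#'   `"zipf-mandelbrot"`, or `"neutral"`.
#' @param sad_params Named list of model parameters (e.g.
#'   `list(alpha = 0.35)` or `list(sigma = exp(1))`).
#' @param stems_per_plot Expected stems per plot (Poisson-distributed).
#' @param plots_per_stand Plots per stand (default 5).
#' @param plot_area_m2 Plot area (default 900 = 30 x 30 m).
#' @param dbh_meanlog,dbh_sdlog Log-normal DBH parameters (cm); draws below
#'   the 5-cm census threshold are redrawn (truncated log-normal).
#' @param elevation_range Plot elevation range in m.
#' @return A `belt_spec` list.
#' @export
belt_spec <- function(belt, stand_codes, species, sad_model, sad_params,
                      stems_per_plot, plots_per_stand = 5, plot_area_m2 = 900,
                      dbh_meanlog = log(16), dbh_sdlog = 0.3,
                      elevation_range = c(1400, 2400)) {
  if (length(stand_codes) < 1) abort("Need at least one stand code")
  if (stems_per_plot <= 0) abort("stems_per_plot must be positive")
  structure(
    list(
      belt = belt, stand_codes = stand_codes, species = species,
      sad_model = sad_model, sad_params = sad_params,
      stems_per_plot = stems_per_plot, plots_per_stand = plots_per_stand,
      plot_area_m2 = plot_area_m2, dbh_meanlog = dbh_meanlog,
      dbh_sdlog = dbh_sdlog, elevation_range = elevation_range
    ),
    class = "belt_spec"
  )
}

.default_pools <- function() {
  all_sp <- reference_taxonomy()$species
  excluded <- c("Schima superba", "Albizia kalkora", "Pterostyrax hispidus",
                "Betula utilis", "Quercus spinosa", "Picea wilsonii")
  birch_only <- c("Betula platyphylla", "Betula luminifera", "Populus purdomii",
                  "Rhododendron purdomii", "Abies fargesii", "Salix wallichiana",
                  "Sorbus koehneana", "Acer caudatum", "Euonymus phellomanus")
  po_only <- c("Quercus variabilis", "Castanea seguinii", "Larix chinensis",
               "Pterocarya stenoptera", "Celtis sinensis", "Ulmus pumila",
               "Cornus kousa")
  shared <- setdiff(all_sp, c(excluded, birch_only, po_only))
  birch_top <- c("Betula albosinensis", "Pinus armandii", "Acer davidii",
                 "Toxicodendron vernicifluum", "Sorbus folgneri",
                 "Tsuga chinensis", "Quercus aliena var. acutiserrata",
                 "Carpinus turczaninowii", "Cerasus polytricha",
                 "Populus davidiana")
  po_top <- c("Quercus aliena var. acutiserrata", "Pinus tabuliformis",
              "Pinus armandii", "Toxicodendron vernicifluum",
              "Carpinus turczaninowii", "Lindera obtusiloba",
              "Juglans cathayensis", "Acer davidii", "Tsuga chinensis",
              "Betula albosinensis")
  birch_pool <- c(birch_top, setdiff(shared, birch_top), birch_only)
  po_pool <- c(po_top, setdiff(shared, po_top), po_only)
  list(birch = birch_pool, pineoak = po_pool)
}

#' Default belt specifications emulating the reference survey
#'
#' Birch belt: 43 species, flat log-normal dominance (`sigma = e`, so the
#' top species holds ~13% of individuals); pine-oak belt: 41 species, Zipf
#' dominance with `gamma = -1.5` (top three species hold ~ 63%, the rarest
#' rank still expects a handful of stems, so observed richness stays ~ 41).
#' The pools share 34 species (50 overall).
#'
#' @return Named list with elements `birch` and `pineoak`.
#' @export
default_belt_specs <- function() {
  pools <- .default_pools()
  design <- stand_design()
  list(
    birch = belt_spec(
      belt = "birch",
      stand_codes = design$stand_code[design$belt == "birch"],
      species = pools$birch,
      sad_model = "lognormal", sad_params = list(sigma = exp(1)),
      stems_per_plot = 117,
      dbh_meanlog = log(15.5), dbh_sdlog = 0.3,
      elevation_range = c(1800, 2400)
    ),
    pineoak = belt_spec(
      belt = "pine-oak",
      stand_codes = design$stand_code[design$belt == "pine-oak"],
      species = pools$pineoak,
      sad_model = "zipf", sad_params = list(gamma = -1.5),
      stems_per_plot = 110,
      dbh_meanlog = log(17.5), dbh_sdlog = 0.3,
      elevation_range = c(1300, 2000)
    )
  )
}

.sad_rel_abundance <- function(S, sad_model, params) {
  p <- switch(sad_model,
    "broken-stick" = expected_broken_stick(S, S),
    "preemption" = expected_preemption(1, S, params$alpha),
    "lognormal" = expected_lognormal(S, 1, params$sigma),
    "zipf" = expected_zipf(1, S, params$p1 %||% 0.3, params$gamma),
    "zipf-mandelbrot" = expected_zm(1, S, params$c %||% 0.3, params$beta,
                                    params$gamma),
    abort(paste0("No closed-form relative abundances for model ", sad_model))
  )
  p / sum(p)
}

#' Draw one community abundance vector from an SAD model
#'
#' For the five parametric models, a multinomial draw of `N` individuals
#' from the model's expected relative abundances over `S` ranks.  For the
#' neutral model, a sequential urn construction of a local community of size
#' `N`: the j-th individual is an immigrant from a metacommunity Ewens urn
#' (biodiversity number `theta`) with probability `I/(I + j - 1)` where
#' `I = m (N - 1)/(1 - m)`, otherwise a copy of a random established
#' individual; `S` is emergent.
#'
#' @param S Species pool size (ignored by the neutral model).
#' @param N Community size (individuals).
#' @param sad_model Model name (see [belt_spec()]).
#' @param params Named parameter list (`alpha`; `sigma`; `p1`, `gamma`;
#'   `c`, `beta`, `gamma`; `theta`, `m`).
#' @param seed Optional seed.
#' @return Integer abundance vector (length `S`, or emergent for
#'   `"neutral"`), summing to `N`.
#' @export
gen_community <- function(S, N, sad_model, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sad_model == "neutral") {
    if (is.null(params$theta) || is.null(params$m)) {
      abort("Neutral model needs params theta and m")
    }
    return(.neutral_urn(N, params$theta, params$m))
  }
  if (S == 1) return(N)
  p <- .sad_rel_abundance(S, sad_model, params)
  as.integer(rmultinom(1, N, p))
}

.neutral_urn <- function(J, theta, m) {
  if (theta <= 0 || m <= 0 || m > 1) abort("Need theta > 0 and 0 < m <= 1")
  # dispersal-limited sequential construction: the j-th individual is an
  # immigrant with probability I/(I + j - 1), I = m(J-1)/(1-m), so the
  # assembled community follows the dispersal-limited sampling formula
  I <- if (m < 1) m * (J - 1) / (1 - m) else Inf
  meta <- integer(0)    # metacommunity species counts (Ewens urn)
  local <- integer(J)   # species id of each local individual
  n_sp <- 0L
  for (j in seq_len(J)) {
    if (j == 1L || runif(1) < I / (I + j - 1)) {
      n_meta <- sum(meta)
      if (runif(1) < theta / (theta + n_meta)) {
        n_sp <- n_sp + 1L
        meta <- c(meta, 0L)
        sp <- n_sp
      } else {
        sp <- sample.int(n_sp, 1, prob = meta)
      }
      meta[sp] <- meta[sp] + 1L
      local[j] <- sp
    } else {
      local[j] <- local[sample.int(j - 1L, 1)]
    }
  }
  as.integer(tabulate(local, nbins = n_sp))
}

.truncated_lnorm <- function(n, meanlog, sdlog, lower = 5) {
  out <- rlnorm(n, meanlog, sdlog)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    bad <- out < lower
  }
  out
}

.gen_belt <- function(spec) {
  S <- length(spec$species)
  p <- .sad_rel_abundance(S, spec$sad_model, spec$sad_params)
  stems <- list(); plots <- list()
  for (sc in spec$stand_codes) {
    for (pl in seq_len(spec$plots_per_stand)) {
      plot_id <- paste0(sc, "-", pl)
      n_plot <- max(1L, rpois(1, spec$stems_per_plot))
      counts <- as.integer(rmultinom(1, n_plot, p))
      sp <- rep(spec$species, counts)
      dbh <- .truncated_lnorm(n_plot, spec$dbh_meanlog, spec$dbh_sdlog)
      height <- pmax(1.5, 1.3 + 1.2 * dbh^0.75 + stats::rnorm(n_plot, 0, 1))
      crown <- pmax(0.3, 0.25 * dbh + stats::rnorm(n_plot, 0, 0.8))
      stems[[plot_id]] <- tibble(
        plot_id = plot_id, stand_code = sc, belt = spec$belt,
        species = sp, dbh_cm = round(dbh, 1),
        height_m = round(height, 1), crown_m = round(crown, 1)
      )
      plots[[plot_id]] <- tibble(
        plot_id = plot_id, stand_code = sc, belt = spec$belt,
        area_m2 = spec$plot_area_m2,
        elevation_m = round(runif(1, spec$elevation_range[1],
                                  spec$elevation_range[2]))
      )
    }
  }
  list(stems = bind_rows(stems), plots = bind_rows(plots))
}

#' Generate a synthetic two-belt stem survey with known ground truth
#'
#' @param birch,pineoak Belt specifications (see [belt_spec()]); defaults
#'   from [default_belt_specs()].
#' @param shared_fraction Optional override of the species-pool overlap: the
#'   shared pool is the first `round(f * min(S1, S2))` species of the merged
#'   pool, assigned to the same ranks in both belts; `0` gives disjoint
#'   pools, `1` identical pools.  `NULL` (default) keeps the pools given in
#'   the specifications.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `stems` (tibble, one row per tree), `plots` (tibble,
#'   one row per plot), and `truth` (generating models, parameters, pools,
#'   shared species, seed).
#' @export
gen_survey <- function(birch = default_belt_specs()$birch,
                       pineoak = default_belt_specs()$pineoak,
                       shared_fraction = NULL, seed = 1) {
  if (!is.null(shared_fraction)) {
    if (shared_fraction < 0 || shared_fraction > 1) {
      abort("shared_fraction must lie in [0, 1]")
    }
    s1 <- length(birch$species); s2 <- length(pineoak$species)
    n_shared <- round(shared_fraction * min(s1, s2))
    master <- unique(c(birch$species, pineoak$species))
    need <- n_shared + (s1 - n_shared) + (s2 - n_shared)
    if (length(master) < need) {
      master <- c(master, paste("Synthetica species", seq_len(need - length(master))))
    }
    shared <- master[seq_len(n_shared)]
    rest <- setdiff(master, shared)
    birch$species <- c(shared, rest[seq_len(s1 - n_shared)])
    pineoak$species <- c(shared, rest[seq_len(s2 - n_shared) + (s1 - n_shared)])
  }
  set.seed(seed)
  b <- .gen_belt(birch)
  p <- .gen_belt(pineoak)
  stems <- bind_rows(b$stems, p$stems)
  plots <- bind_rows(b$plots, p$plots)
  truth <- list(
    seed = seed,
    birch = list(sad_model = birch$sad_model, sad_params = birch$sad_params,
                 species = birch$species,
                 stems_per_plot = birch$stems_per_plot),
    pineoak = list(sad_model = pineoak$sad_model,
                   sad_params = pineoak$sad_params,
                   species = pineoak$species,
                   stems_per_plot = pineoak$stems_per_plot),
    shared_species = intersect(birch$species, pineoak$species)
  )
  list(stems = stems, plots = plots, truth = truth)
}

#' Write a synthetic survey to CSV/JSON files
#'
#' Emits `stems.csv` and `plots.csv` in the dialect read by [read_stems()] /
#' [read_plots()], and the ground truth as `truth.json`.
#'
#' @param survey Result of [gen_survey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    stems = file.path(dir, "stems.csv"),
    plots = file.path(dir, "plots.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(survey$stems, paths[["stems"]])
  readr::write_csv(survey$plots, paths[["plots"]])
  jsonlite::write_json(survey$truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
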