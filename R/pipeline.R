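#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis; the defaults
#' reproduce the reference protocol (DBH >= 5 cm, Hill orders 0/1/2, 200
#' bootstrap replications, 95% confidence level, extrapolation to twice the
#' smaller reference sample, Bray-Curtis distance, two stand groups).
#'
#' @param stems_path,plots_path Input CSVs (omit to analyse an in-memory
#'   survey passed to [run_pipeline()]).
#' @param dbh_threshold_cm Census DBH threshold (cm).
#' @param q Hill orders.
#' @param bootstrap_reps Bootstrap replications for diversity bands.
#' @param conf Confidence level.
#' @param knots Size-grid knots for the diversity curves.
#' @param sad_models SAD models to fit.
#' @param distance_metric `"bray"` or `"chisq"`.
#' @param k_groups Groups for the dendrogram cut.
#' @param seed Seed applied to every stochastic step.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(stems_path = NULL, plots_path = NULL,
                       dbh_threshold_cm = 5, q = c(0, 1, 2),
                       bootstrap_reps = 200, conf = 0.95, knots = 40,
                       sad_models = .sad_models,
                       distance_metric = "bray", k_groups = 2,
                       seed = 1, out_dir = tempfile("forestdiv-run-")) {
  structure(
    list(
      stems_path = stems_path, plots_path = plots_path,
      dbh_threshold_cm = dbh_threshold_cm, q = q,
      bootstrap_reps = bootstrap_reps, conf = conf, knots = knots,
      sad_models = sad_models, distance_metric = distance_metric,
      k_groups = k_groups, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full community-assembly pipeline
#'
#' Stages: ingest and DBH-filter the stem table; species importance values
#' and family/genus overall relative importance per belt; Hill-number
#' rarefaction/extrapolation curves (abundance basis per belt, extended to
#' twice the smaller reference sample); SAD model comparison per belt;
#' stand clustering and correspondence analysis.  All tables are written as
#' CSV (plus a Newick dendrogram) into `config$out_dir`, together with a
#' JSON manifest of parameters, seed and output checksums.
#'
#' @param config A [run_config()].
#' @param survey Optional in-memory survey (list with `stems`, `plots`,
#'   e.g. from [gen_survey()]) used when no input paths are configured.
#' @return Invisibly, a list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), survey = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$stems_path)) {
    stems <- read_stems(config$stems_path)
    plots <- read_plots(config$plots_path)
  } else if (!is.null(survey)) {
    stems <- survey$stems
    plots <- survey$plots
  } else {
    abort("Provide stems_path/plots_path in the config or a survey object")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stems <- filter_dbh(stems, config$dbh_threshold_cm)
  belts <- sort(unique(stems$belt))

  iv <- purrr::map(setNames(belts, belts), function(b) {
    species_importance(dplyr::filter(stems, belt == b))
  })
  ori_family <- purrr::map(setNames(belts, belts), function(b) {
    taxon_importance(dplyr::filter(stems, belt == b), "family")
  })
  ori_genus <- purrr::map(setNames(belts, belts), function(b) {
    taxon_importance(dplyr::filter(stems, belt == b), "genus")
  })

  pooled <- purrr::map(setNames(belts, belts), function(b) {
    pooled_abundance(dplyr::filter(stems, belt == b))
  })
  refs <- vapply(pooled, function(p) attr(p, "N"), numeric(1))
  endpoint <- if (length(refs) > 1) extrapolation_limit(refs) else 2 * refs[1]
  diversity <- purrr::imap_dfr(pooled, function(p, b) {
    hill_curve(p$n_i, q = config$q, knots = config$knots,
               endpoint = endpoint, reps = config$bootstrap_reps,
               conf = config$conf, seed = config$seed) %>%
      mutate(belt = b, .before = 1)
  })

  sad <- purrr::map(setNames(belts, belts), function(b) {
    compare_sad_models(pooled[[b]]$n_i, models = config$sad_models)
  })

  mat <- stand_species_matrix(stems)
  d <- stand_distance(mat, config$distance_metric)
  clust <- cluster_stands(d, k = config$k_groups)
  ca <- correspondence_analysis(mat)

  results <- list(
    stand_summary = stand_summary(stems, plots),
    importance = iv, ori_family = ori_family, ori_genus = ori_genus,
    diversity = diversity, sad = sad, clustering = clust, ca = ca
  )

  paths <- c(
    stand_summary = "stand_summary.csv",
    diversity = "diversity_curves.csv",
    dendrogram = "dendrogram.nwk",
    groups = "stand_groups.csv",
    ca_scores = "ca_scores.csv",
    ca_eigen = "ca_eigenvalues.csv"
  )
  paths <- setNames(file.path(config$out_dir, paths), names(paths))
  readr::write_csv(results$stand_summary, paths[["stand_summary"]])
  readr::write_csv(diversity, paths[["diversity"]])
  writeLines(as_newick(clust), paths[["dendrogram"]])
  readr::write_csv(tidy(clust), paths[["groups"]])
  readr::write_csv(tidy(ca), paths[["ca_scores"]])
  readr::write_csv(
    tibble(axis = seq_along(ca$eigenvalues), eigenvalue = ca$eigenvalues,
           prop_inertia = ca$prop_inertia),
    paths[["ca_eigen"]]
  )
  for (b in belts) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(b))
    p_iv <- file.path(config$out_dir, paste0("importance_", slug, ".csv"))
    readr::write_csv(iv[[b]], p_iv)
    paths[[paste0("importance_", slug)]] <- p_iv
    p_sad <- file.path(config$out_dir, paste0("sad_comparison_", slug, ".csv"))
    readr::write_csv(as_tibble(sad[[b]]), p_sad)
    paths[[paste0("sad_", slug)]] <- p_sad
    for (lev in c("family", "genus")) {
      p_ori <- file.path(config$out_dir, paste0("ori_", lev, "_", slug, ".csv"))
      readr::write_csv(get(paste0("ori_", lev))[[b]], p_ori)
      paths[[paste0("ori_", lev, "_", slug)]] <- p_ori
    }
  }

  manifest <- list(
    package = "forestdiv",
    version = as.character(utils::packageVersion("forestdiv")),
    seed = config$seed,
    parameters = config[c("dbh_threshold_cm", "q", "bootstrap_reps", "conf",
                          "knots", "sad_models", "distance_metric",
                          "k_groups")],
    n_stems = nrow(stems),
    belts = as.list(setNames(refs, belts)),
    outputs = as.list(setNames(unname(tools::md5sum(unlist(paths))),
                               names(paths)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
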