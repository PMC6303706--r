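#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis: orientation standardization, per-female
#' traits with replicate averaging, quality control, population aggregation,
#' the species/sympatry statistical battery, pairwise population KDE
#' comparisons with FDR adjustment, and population mean plate shapes. Every
#' stochastic stage draws its seed deterministically from the master seed, so
#' a run is reproducible from its configuration alone.
#'
#' @name cli_pipeline
#' @keywords internal
NULL

#' Pipeline run configuration
#'
#' @param min_n minimum females per population for the spatial (KDE) and
#'   shape stages (default 4, the study's eligibility rule).
#' @param n_perm permutations per KDE test (default 999, >= 99).
#' @param seed master seed for replicate selection and permutation streams.
#' @param bandwidth bandwidth selector (\code{"normal_scale"} or
#'   \code{"plugin"}).
#' @param landmark_mode semilandmark placement (\code{"arc_length"} default,
#'   \code{"random"} for the legacy vertex-subsampling procedure).
#' @param qc_threshold replicate-concordance QC gate (default 0.9).
#' @param kde_species species whose populations enter the pairwise KDE and
#'   shape comparisons (default \code{"E_carunculatum"}).
#' @param alpha significance level for flags (default 0.05).
#' @param exclude_populations population_ids dropped from the spatial stage
#'   before testing (the outlier-exclusion switch; FDR is recomputed on the
#'   remaining pairs).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(min_n = 4L, n_perm = 999L, seed = 1L,
                       bandwidth = c("normal_scale", "plugin"),
                       landmark_mode = c("arc_length", "random"),
                       qc_threshold = 0.9,
                       kde_species = "E_carunculatum",
                       alpha = 0.05,
                       exclude_populations = character(0)) {
  stopifnot(n_perm >= 99L, min_n >= 2L)
  structure(list(min_n = as.integer(min_n), n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 bandwidth = match.arg(bandwidth),
                 landmark_mode = match.arg(landmark_mode),
                 qc_threshold = qc_threshold, kde_species = kde_species,
                 alpha = alpha, exclude_populations = exclude_populations),
            class = "run_config")
}

#' Quality-control report for a loaded study
#'
#' Replicate-concordance correlations per trait, the count of left
#' (mirrored) plates, and specimens whose replicate pairs disagree beyond
#' the QC gate.
#'
#' @param records list of \code{plate_record}s.
#' @param qc_threshold concordance gate (default 0.9).
#' @return List with \code{n_left_mirrored}, \code{replicate_correlations},
#'   and \code{failing_specimens} (specimens whose replicate count ratio
#'   falls outside [threshold, 1/threshold]).
#' @export
qc_report <- function(records, qc_threshold = 0.9) {
  n_left <- sum(vapply(records, function(r)
    r$side == "left" || isTRUE(r$mirrored), TRUE)) / 2
  per_rep <- do.call(rbind, lapply(records, function(r)
    compute_traits(standardize_plate_orientation(r))))
  r1 <- per_rep[per_rep$replicate_id == 1L, ]
  r2 <- per_rep[per_rep$replicate_id == 2L, ]
  common <- intersect(r1$specimen_id, r2$specimen_id)
  r1 <- r1[match(common, r1$specimen_id), ]
  r2 <- r2[match(common, r2$specimen_id), ]
  cors <- vapply(c("sensilla_count", "plate_area", "abdomen_length"),
                 function(col) {
                   tryCatch(replicate_concordance(r1[[col]], r2[[col]]),
                            error = function(e) NA_real_)
                 }, numeric(1))
  ratio <- pmin(r1$sensilla_count, r2$sensilla_count) /
    pmax(r1$sensilla_count, r2$sensilla_count)
  failing <- common[!is.na(ratio) & ratio < qc_threshold]
  list(n_left_mirrored = n_left, replicate_correlations = cors,
       failing_specimens = failing)
}

# one replicate per female, chosen at random (seeded), skipping counts_only
# plates: the spatial and shape stages use a single digitization per female.
select_replicates <- function(records, seed) {
  usable <- Filter(function(r) !r$counts_only, records)
  by_spec <- split(usable, vapply(usable, `[[`, "", "specimen_id"))
  with_seed(seed, lapply(by_spec, function(recs)
    recs[[sample.int(length(recs), 1L)]]))
}

#' Run the full pipeline
#'
#' @param records list of \code{plate_record}s (e.g. from
#'   \code{\link{generate_study}} or \code{\link{read_study}}).
#' @param manifest the matching \code{study_manifest}.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, all tables are written as
#'   delimited text plus a JSON run summary.
#' @return List of class \code{pipeline_result} with elements
#'   \code{trait_table} (per female), \code{population_means},
#'   \code{battery} (comparison rows), \code{kde_table}
#'   (pairwise comparisons, or NULL with a logged reason),
#'   \code{density_models}, \code{mean_shapes}, \code{qc}, \code{config},
#'   and \code{log} (stage-tagged messages).
#' @export
run_pipeline <- function(records, manifest, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  say("[ingest] ", length(records), " plate records, ",
      nrow(manifest), " manifest populations")
  oriented <- lapply(records, standardize_plate_orientation)
  say("[ingest] mirrored ", sum(vapply(oriented, `[[`, TRUE, "mirrored")),
      " left plates")

  qc <- qc_report(records, config$qc_threshold)
  say("[qc] replicate correlations: ",
      paste(names(qc$replicate_correlations),
            round(qc$replicate_correlations, 3), collapse = ", "))

  trait_table <- compute_trait_table(oriented)
  pop_means <- aggregate_populations(trait_table, manifest)
  say("[traits] ", nrow(trait_table), " females, ",
      nrow(pop_means), " populations")

  battery <- tryCatch(run_comparison_battery(pop_means),
                      error = function(e) {
                        say("[stats] battery failed: ", conditionMessage(e))
                        NULL
                      })

  chosen <- select_replicates(oriented, config$seed)
  keep <- !vapply(chosen, function(r)
    r$population_id %in% config$exclude_populations, TRUE)
  chosen <- chosen[keep]
  kde_recs <- Filter(function(r) r$species %in% config$kde_species, chosen)
  clouds_by_pop <- lapply(
    split(kde_recs, vapply(kde_recs, `[[`, "", "population_id")),
    function(recs) lapply(recs, function(r)
      standardize_cloud(r$outline, r$sensilla, r$specimen_id)))
  eligible <- names(clouds_by_pop)[
    vapply(clouds_by_pop, length, 0L) >= config$min_n]

  kde_table <- NULL; density_models <- NULL; mean_shapes <- NULL
  if (length(eligible) < 2L) {
    say("[spatial] skipped: ", length(eligible),
        " population(s) with >= ", config$min_n, " females")
  } else {
    kde_table <- pairwise_kde_tests(clouds_by_pop[eligible],
                                    min_n = config$min_n,
                                    n_perm = config$n_perm,
                                    seed = config$seed,
                                    alpha = config$alpha,
                                    bandwidth = config$bandwidth)
    say("[spatial] ", nrow(kde_table), " population pairs tested, ",
        sum(kde_table$significant), " significant at FDR ", config$alpha)
    density_models <- lapply(eligible, function(pop) {
      pts <- pool_population(clouds_by_pop[[pop]])
      evaluate_kde(pts, select_bandwidth(pts, config$bandwidth),
                   population_id = pop)
    })
    names(density_models) <- eligible

    lms_by_pop <- lapply(clouds_by_pop[eligible], function(cls) {
      lapply(seq_along(cls), function(i) {
        outline <- cls[[i]]$outline
        resample_outline(outline, detect_plate_corners(outline),
                         mode = config$landmark_mode,
                         seed = config$seed + i,
                         specimen_id = cls[[i]]$specimen_id)
      })
    })
    mean_shapes <- population_mean_shapes(lms_by_pop, min_n = config$min_n)
    say("[shapes] ", length(mean_shapes), " population mean shapes")
  }

  result <- structure(list(trait_table = trait_table,
                           population_means = pop_means,
                           battery = battery, kde_table = kde_table,
                           density_models = density_models,
                           mean_shapes = mean_shapes,
                           qc = qc, config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) if (!is.null(df))
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  wt(result$trait_table, "trait_table.csv")
  wt(result$population_means, "population_means.csv")
  wt(result$battery, "battery.csv")
  wt(result$kde_table, "kde_pairs.csv")
  if (!is.null(result$mean_shapes))
    for (pop in names(result$mean_shapes))
      write_coordinate_file(result$mean_shapes[[pop]],
                            file.path(out_dir, paste0("mean_shape_", pop,
                                                      ".csv")))
  summary <- list(
    config = unclass(result$config),
    qc = list(n_left_mirrored = result$qc$n_left_mirrored,
              replicate_correlations =
                as.list(result$qc$replicate_correlations)),
    n_females = nrow(result$trait_table),
    n_populations = nrow(result$population_means),
    kde_pairs = if (!is.null(result$kde_table)) nrow(result$kde_table) else 0,
    log = result$log)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
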