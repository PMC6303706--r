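#' Per-female scalar sensilla phenotypes
#'
#' Four headline traits per plate: sensilla count, the proportion of the plate
#' covered by sensilla, sensilla density within the covered region, and the
#' mean nearest-neighbor distance between sensilla. The covered region is the
#' convex hull of the sensilla — the unique parameter-free reading of "the
#' polygon connecting the outermost sensilla". Density is reported per
#' 1000 square micrometres. Broken-socket sensilla count as sensilla.
#'
#' @name traits
#' @keywords internal
NULL

TRAIT_COLS <- c("sensilla_count", "plate_area", "sensilla_region_area",
                "coverage_proportion", "density", "mean_nnd", "median_nnd",
                "abdomen_length")

#' Compute the trait record for one plate
#'
#' Plates with fewer than three non-collinear sensilla keep their count and
#' (if possible) nearest-neighbor summaries but get missing hull-based traits
#' rather than zeros, so downstream aggregates stay unbiased. Plates flagged
#' \code{counts_only} get only the count and abdomen length.
#'
#' @param rec a \code{plate_record} in right (standardized) orientation.
#' @return One-row data frame with columns \code{specimen_id, species,
#'   population_id, replicate_id, sensilla_count, plate_area,
#'   sensilla_region_area, coverage_proportion, density, mean_nnd, median_nnd,
#'   abdomen_length, counts_only}. Units: areas in square micrometres, density
#'   in sensilla per 1000 square micrometres, distances in micrometres.
#' @export
compute_traits <- function(rec) {
  stopifnot(inherits(rec, "plate_record"))
  if (rec$side != "right")
    stop("standardize plate orientation before computing traits", call. = FALSE)
  n <- nrow(rec$sensilla)
  out <- data.frame(specimen_id = rec$specimen_id, species = rec$species,
                    population_id = rec$population_id,
                    replicate_id = rec$replicate_id,
                    sensilla_count = as.numeric(n),
                    plate_area = NA_real_, sensilla_region_area = NA_real_,
                    coverage_proportion = NA_real_, density = NA_real_,
                    mean_nnd = NA_real_, median_nnd = NA_real_,
                    abdomen_length = rec$abdomen_length,
                    counts_only = rec$counts_only,
                    stringsAsFactors = FALSE)
  if (rec$counts_only) return(out)
  out$plate_area <- polygon_area(rec$outline)
  if (n >= 2L) {
    nnd <- nearest_neighbor_distances(rec$sensilla)
    out$mean_nnd <- mean(nnd)
    out$median_nnd <- stats::median(nnd)
  }
  hull <- tryCatch(convex_hull(rec$sensilla), error = function(e) NULL)
  if (!is.null(hull)) {
    out$sensilla_region_area <- polygon_area(hull)
    out$coverage_proportion <- out$sensilla_region_area / out$plate_area
    out$density <- 1000 * n / out$sensilla_region_area
  }
  out
}

#' Average the two technical replicates of a specimen
#'
#' Field-wise arithmetic mean of two trait records for the same specimen.
#' Counts may become non-integral and are kept as real numbers. A trait
#' missing in either replicate is missing in the mean.
#'
#' @param r1,r2 one-row trait data frames from \code{\link{compute_traits}}
#'   for the same specimen.
#' @return One-row trait data frame with \code{replicate_id = NA}.
#' @export
average_replicates <- function(r1, r2) {
  if (!identical(r1$specimen_id, r2$specimen_id))
    stop("replicates belong to different specimens: ",
         r1$specimen_id, " vs ", r2$specimen_id, call. = FALSE)
  out <- r1
  for (col in TRAIT_COLS) out[[col]] <- (r1[[col]] + r2[[col]]) / 2
  out$replicate_id <- NA_integer_
  out$counts_only <- r1$counts_only || r2$counts_only
  out
}

#' Per-female trait table from a set of plate records
#'
#' Standardizes orientation, computes per-replicate traits, and averages
#' replicate pairs, yielding one row per female.
#'
#' @param records list of \code{plate_record}s (any mix of replicates).
#' @return Data frame with one row per specimen.
#' @export
compute_trait_table <- function(records) {
  stopifnot(length(records) > 0L)
  rows <- lapply(records, function(r)
    compute_traits(standardize_plate_orientation(r)))
  tab <- do.call(rbind, rows)
  out <- lapply(split(tab, tab$specimen_id), function(g) {
    if (nrow(g) == 1L) return(g)
    Reduce(average_replicates, split(g, seq_len(nrow(g))))
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab[order(tab$population_id, tab$specimen_id), , drop = FALSE]
}

#' Concordance between technical replicates
#'
#' Pearson correlation across specimens of a trait measured in both
#' replicates; used as a quality-control gate (the study design expects
#' correlations of roughly 0.95).
#'
#' @param value1,value2 paired numeric vectors (one entry per specimen).
#' @return Pearson r.
#' @export
replicate_concordance <- function(value1, value2) {
  ok <- stats::complete.cases(value1, value2)
  value1 <- value1[ok]; value2 <- value2[ok]
  if (length(value1) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(value1) == 0 || stats::var(value2) == 0)
    stop("zero variance: concordance undefined", call. = FALSE)
  stats::cor(value1, value2)
}

#' Aggregate female traits to population means
#'
#' One row per (species, population): the field-wise mean over that
#' population's females, so each population contributes a single measurement
#' to the between-population statistics (populations with one female
#' contribute that single value). Missing trait values are dropped from the
#' population mean (they mark degenerate plates).
#'
#' @param trait_table per-female trait table (see
#'   \code{\link{compute_trait_table}}).
#' @param manifest a \code{study_manifest}; every record must map to one of
#'   its populations.
#' @param min_n keep only populations with at least this many measured
#'   females (the sensitivity-analysis switch; default 1 keeps all).
#' @return Data frame with population metadata, \code{n_females}, and mean
#'   trait columns.
#' @export
aggregate_populations <- function(trait_table, manifest, min_n = 1L) {
  stopifnot(inherits(manifest, "study_manifest"))
  key <- paste(trait_table$population_id, trait_table$species)
  mkey <- paste(manifest$population_id, manifest$species)
  unknown <- setdiff(unique(key), mkey)
  if (length(unknown))
    stop("records reference unknown population(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  groups <- split(trait_table, key)
  rows <- lapply(groups, function(g) {
    out <- data.frame(population_id = g$population_id[1L],
                      species = g$species[1L],
                      n_females = nrow(g), stringsAsFactors = FALSE)
    for (col in TRAIT_COLS)
      out[[col]] <- if (all(is.na(g[[col]]))) NA_real_ else
        mean(g[[col]], na.rm = TRUE)
    out
  })
  agg <- do.call(rbind, rows)
  agg <- merge(agg,
               manifest[, c("population_id", "species", "patry")],
               by = c("population_id", "species"), sort = FALSE)
  agg <- agg[agg$n_females >= min_n, , drop = FALSE]
  rownames(agg) <- NULL
  agg[order(agg$species, agg$population_id), , drop = FALSE]
}

#' Combinatorial tactile pattern capacity
#'
#' Number of distinct tactile patterns a female can in principle discriminate
#' if each of \code{n_sensilla} mechanoreceptors has \code{states} response
#' states: \code{states^n_sensilla}. With binary sensilla, every additional
#' sensillum doubles the capacity. Exact up to 2^53 (the double-precision
#' integer limit), which comfortably covers observed plate counts.
#'
#' @param n_sensilla non-negative integer count of sensilla.
#' @param states integer number of response states per sensillum (>= 2).
#' @return List with \code{count} (exact number) and \code{scientific}
#'   (two-significant-figure rendering, e.g. \code{"3.4e+07"}).
#' @examples
#' tactile_pattern_capacity(25)  # 33554432, ~3.4e7
#' @export
tactile_pattern_capacity <- function(n_sensilla, states = 2L) {
  stopifnot(n_sensilla >= 0, n_sensilla == round(n_sensilla),
            states >= 2, states == round(states))
  if (n_sensilla * log2(states) > 53)
    stop("capacity exceeds exact double-precision range (2^53)", call. = FALSE)
  count <- as.numeric(states)^n_sensilla
  list(count = count,
       scientific = format(signif(count, 2), scientific = TRUE))
}
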