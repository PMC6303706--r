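#' Study data model and coordinate-file input/output
#'
#' A study consists of per-female digitized plates (`plate_record`) plus a
#' manifest of populations (`study_manifest`). Coordinate files are delimited
#' text (comma or tab, optional single header row, UTF-8) with columns
#' `x,y[,broken]`; one file per (specimen, replicate, kind). Coordinates are
#' stored as digitized, in the image frame (the vertical axis orientation of
#' the source images is preserved as-is).
#'
#' @name data_model
#' @keywords internal
NULL

SPECIES_LEVELS <- c("E_anna", "E_carunculatum")
PATRY_LEVELS <- c("sympatric", "locally_allopatric", "allopatric")

#' Construct a plate record
#'
#' One female's digitized mesostigmal plate for one technical replicate: the
#' traced outline polygon, the sensilla point set (broken sockets flagged but
#' counted), and specimen metadata. Cheap invariants are checked on
#' construction: at least three non-collinear outline vertices and all
#' sensilla inside or on the outline. Full polygon simplicity is checked by
#' \code{\link{is_simple_polygon}} where needed (it is O(n^2) in the vertex
#' count).
#'
#' @param specimen_id character scalar.
#' @param species species label (free-form; the bundled study uses
#'   \code{"E_anna"} and \code{"E_carunculatum"}).
#' @param population_id population identifier matching the manifest.
#' @param side \code{"left"} or \code{"right"} plate.
#' @param outline two-column matrix of ordered outline vertices (micrometres).
#' @param sensilla two-column matrix of sensilla coordinates (micrometres).
#' @param broken logical vector flagging broken-socket sensilla (they are
#'   counted as sensilla; the flag is kept for QC only).
#' @param replicate_id technical replicate number (1 or 2 in this design).
#' @param abdomen_length optional body-size proxy in millimetres.
#' @param counts_only flag for plates imaged at an angle that permits counting
#'   but distorts geometry; such plates enter count analyses only.
#' @return Object of class \code{plate_record}.
#' @export
plate_record <- function(specimen_id, species, population_id, side,
                         outline, sensilla,
                         broken = NULL, replicate_id = 1L,
                         abdomen_length = NA_real_, counts_only = FALSE) {
  side <- match.arg(side, c("left", "right"))
  outline <- as_xy_matrix(outline, "outline vertices")
  sensilla <- as_xy_matrix(sensilla, "sensilla points")
  if (nrow(outline) < 3L) stop("outline needs >= 3 vertices", call. = FALSE)
  polygon_area(outline)  # errors if collinear/degenerate
  if (nrow(sensilla) < 1L) stop("plate has no sensilla", call. = FALSE)
  if (is.null(broken)) broken <- rep(FALSE, nrow(sensilla))
  stopifnot(is.logical(broken), length(broken) == nrow(sensilla))
  scale <- sqrt(polygon_area(outline))
  if (!all(points_in_polygon(sensilla, outline, tol = 1e-6 * scale)))
    stop("all sensilla must lie inside or on the plate outline", call. = FALSE)
  replicate_id <- as.integer(replicate_id)
  stopifnot(length(replicate_id) == 1L, replicate_id >= 1L)
  structure(list(specimen_id = as.character(specimen_id),
                 species = as.character(species),
                 population_id = as.character(population_id),
                 side = side,
                 outline = outline,
                 sensilla = sensilla,
                 broken = broken,
                 replicate_id = replicate_id,
                 abdomen_length = as.numeric(abdomen_length),
                 counts_only = isTRUE(counts_only),
                 mirrored = FALSE),
            class = "plate_record")
}

#' @export
print.plate_record <- function(x, ...) {
  cat("<plate_record> ", x$specimen_id, " (", x$species, ", pop ",
      x$population_id, ", ", x$side, " plate, replicate ", x$replicate_id,
      ")\n  outline: ", nrow(x$outline), " vertices; sensilla: ",
      nrow(x$sensilla), " (", sum(x$broken), " broken)",
      if (x$mirrored) "; mirrored", "\n", sep = "")
  invisible(x)
}

.detect_sep <- function(lines) if (any(grepl("\t", lines))) "\t" else ","

#' Read a coordinate file
#'
#' Reads a delimited text file of digitized coordinates: two numeric columns
#' (x, y), an optional single header row, and for sensilla files an optional
#' third 0/1 column flagging broken sockets. Units are micrometres unless
#' \code{scale_um_per_unit} rescales them.
#'
#' @param path file path.
#' @param kind \code{"outline"} (>= 3 vertices required) or \code{"sensilla"}
#'   (>= 1 point required; a plate with zero sensilla is treated as a
#'   digitization error).
#' @param scale_um_per_unit micrometres per coordinate unit (default 1).
#' @return Two-column coordinate matrix; for sensilla files the logical
#'   attribute \code{"broken"} carries the flags.
#' @export
load_coordinate_file <- function(path, kind = c("outline", "sensilla"),
                                 scale_um_per_unit = 1) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("coordinate file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    if (kind == "sensilla") stop("empty sensilla file: ", path, call. = FALSE)
    stop("outline needs >= 3 vertices: ", path, call. = FALSE)
  }
  sep <- .detect_sep(lines)
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  has_header <- all(is.na(suppressWarnings(as.numeric(first[1:2]))))
  if (has_header) lines <- lines[-1L]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) stop("rows with fewer than two columns in ", path, call. = FALSE)
  xy <- suppressWarnings(cbind(
    as.numeric(vapply(parts, `[[`, "", 1L)),
    as.numeric(vapply(parts, `[[`, "", 2L))))
  if (anyNA(xy)) stop("non-numeric coordinate rows in ", path, call. = FALSE)
  xy <- xy * scale_um_per_unit
  colnames(xy) <- c("x", "y")
  if (kind == "outline") {
    if (nrow(xy) < 3L) stop("outline needs >= 3 vertices: ", path, call. = FALSE)
    return(xy)
  }
  broken <- rep(FALSE, nrow(xy))
  if (all(ncols >= 3L)) {
    flags <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(flags)) stop("non-numeric broken flags in ", path, call. = FALSE)
    broken <- flags != 0
  }
  attr(xy, "broken") <- broken
  xy
}

#' Write a coordinate file
#'
#' Counterpart of \code{\link{load_coordinate_file}}; writes comma-delimited
#' full-precision coordinates with a header, plus a broken-flag column when
#' flags are supplied.
#'
#' @param points two-column coordinate matrix.
#' @param path destination file.
#' @param broken optional logical broken-socket flags.
#' @export
write_coordinate_file <- function(points, path, broken = NULL) {
  points <- as_xy_matrix(points)
  df <- data.frame(x = sprintf("%.17g", points[, 1L]),
                   y = sprintf("%.17g", points[, 2L]))
  if (!is.null(broken)) df$broken <- as.integer(broken)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a plate record as coordinate files
#'
#' \code{write_plate_record} emits the on-disk layout the loader reads: an
#' outline file and a sensilla file named
#' \code{<specimen>_rep<k>_<kind>.csv}, plus a one-line JSON metadata file.
#' \code{read_plate_record} reassembles the record.
#'
#' @param rec a \code{plate_record}.
#' @param dir destination directory (created if needed).
#' @return \code{write_plate_record}: the metadata path, invisibly.
#'   \code{read_plate_record}: a \code{plate_record}.
#' @export
write_plate_record <- function(rec, dir) {
  stopifnot(inherits(rec, "plate_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("%s_rep%d", rec$specimen_id, rec$replicate_id))
  write_coordinate_file(rec$outline, paste0(stem, "_outline.csv"))
  write_coordinate_file(rec$sensilla, paste0(stem, "_sensilla.csv"), rec$broken)
  meta <- rec[c("specimen_id", "species", "population_id", "side",
                "replicate_id", "abdomen_length", "counts_only")]
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, "_meta.json"))
}

#' @rdname write_plate_record
#' @param meta_path path to a \code{*_meta.json} written by
#'   \code{write_plate_record}.
#' @export
read_plate_record <- function(meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stem <- sub("_meta\\.json$", "", meta_path)
  outline <- load_coordinate_file(paste0(stem, "_outline.csv"), "outline")
  sensilla <- load_coordinate_file(paste0(stem, "_sensilla.csv"), "sensilla")
  plate_record(meta$specimen_id, meta$species, meta$population_id, meta$side,
               outline, sensilla, broken = attr(sensilla, "broken"),
               replicate_id = meta$replicate_id,
               abdomen_length = meta$abdomen_length,
               counts_only = isTRUE(meta$counts_only))
}

#' Load a study manifest
#'
#' Reads a population manifest (delimited text or JSON) with the sampling-site
#' columns: \code{population_id}, \code{site_name}, \code{species},
#' \code{latitude}, \code{longitude}, \code{year}, \code{patry}
#' (\code{sympatric} / \code{locally_allopatric} / \code{allopatric}) and
#' \code{n_specimens}.
#'
#' @param path manifest file (.csv/.tsv/.txt or .json).
#' @return A \code{study_manifest}: a data frame with one row per
#'   (site, species) population.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    sep <- .detect_sep(readLines(path, n = 1L, warn = FALSE))
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
  }
  as_study_manifest(df)
}

#' @rdname load_manifest
#' @param df data frame with the manifest columns.
#' @export
as_study_manifest <- function(df) {
  required <- c("population_id", "species", "patry", "n_specimens")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$patry), PATRY_LEVELS)
  if (length(bad))
    stop("unknown patry label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(df$population_id, df$species)
  if (anyDuplicated(key))
    stop("duplicate (population_id, species) rows in manifest", call. = FALSE)
  if (any(df$n_specimens < 1))
    stop("manifest rows must have n_specimens >= 1", call. = FALSE)
  df$n_specimens <- as.integer(df$n_specimens)
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' @export
print.study_manifest <- function(x, ...) {
  cat("<study_manifest> ", nrow(x), " populations, ",
      sum(x$n_specimens), " specimens, species: ",
      paste(sort(unique(x$species)), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Bundled sampling-site manifest
#'
#' The package's fixture manifest of the two-species study design: 13
#' \emph{E. anna} populations (29 females) and 19 \emph{E. carunculatum}
#' populations (74 females) over 28 distinct sites, each classified as
#' sympatric, locally allopatric, or allopatric. Published summaries of this
#' design sometimes count 28 populations for \emph{E. carunculatum}; 28 is
#' the number of distinct sites pooled over both species, while the site
#' table itself lists 19 \emph{E. carunculatum} populations — this manifest
#' follows the site table.
#'
#' @return A \code{study_manifest}.
#' @export
table1_manifest <- function() {
  path <- system.file("extdata", "table1_manifest.csv", package = "sensimorph",
                      mustWork = TRUE)
  load_manifest(path)
}

#' Standardize plate orientation to right-equivalent
#'
#' Left plates are mirrored about the vertical midline of the outline's
#' bounding box so that every plate downstream is in right-plate orientation;
#' right plates pass through unchanged. Mirroring preserves all inter-point
#' distances; the arbitrary translation implicit in the choice of mirror axis
#' is removed downstream by centroid standardization. The operation is an
#' involution on left plates.
#'
#' @param rec a \code{plate_record}.
#' @return The record in right orientation, with \code{mirrored} flagged.
#' @export
standardize_plate_orientation <- function(rec) {
  stopifnot(inherits(rec, "plate_record"))
  if (rec$side == "right") return(rec)
  mid <- mean(range(rec$outline[, 1L]))
  rec$outline[, 1L] <- 2 * mid - rec$outline[, 1L]
  rec$sensilla[, 1L] <- 2 * mid - rec$sensilla[, 1L]
  rec$side <- "right"
  rec$mirrored <- TRUE
  rec
}
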