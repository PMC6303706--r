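#' Synthetic study generator
#'
#' Generates complete synthetic studies with the statistical structure the
#' pipeline assumes: two species templates differing in per-plate sensilla
#' count (defaults 49 vs 28), plate size, coverage, and medial-versus-lateral
#' sensilla placement; per-population count offsets; two noisy digitization
#' replicates per female; occasional broken-socket flags; and a share of left
#' plates stored in left orientation so the mirroring path is exercised
#' end-to-end. Plantable sympatry effects (count shift, placement shift) are
#' zero by default — the null world.
#'
#' Plate outlines are superellipses with low-order radial perturbation,
#' radial about their center and therefore simple by construction, with
#' 600-1100 vertices emulating freehand tracing. Sensilla placement is a
#' two-component truncated Gaussian mixture in plate-relative coordinates,
#' rejected against the outline.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Species template for the generator
#'
#' @param name species label.
#' @param count_mean,count_sd_within mean and within-population SD of the
#'   per-female sensilla count (truncated at 3, rounded).
#' @param count_sd_between SD of population-level count offsets.
#' @param plate_area_mean,plate_area_cv lognormal plate area (square
#'   micrometres) and coefficient of variation.
#' @param aspect outline height/width ratio.
#' @param exponent superellipse exponent (> 2 gives flattened corners).
#' @param perturb_amp amplitudes of low-order radial harmonics.
#' @param mixture_means K x 2 matrix of component means in plate-relative
#'   units (fractions of the half-extents; negative x = medial).
#' @param mixture_sds K x 2 matrix of component SDs, same units.
#' @param mixture_weights component weights (sum to 1).
#' @param digit_noise_um replicate digitization jitter SD, micrometres.
#' @param count_noise_sd SD of the per-replicate recount error (sensilla).
#' @param broken_rate per-sensillum broken-socket probability per replicate.
#' @param left_plate_prob probability a female is digitized from her left
#'   plate.
#' @param abdomen_mean,abdomen_sd,abdomen_noise body-size proxy (mm): latent
#'   distribution and per-replicate measurement SD.
#' @param n_vertices integer range of outline vertex counts.
#' @return List of class \code{species_template}.
#' @export
species_template <- function(name,
                             count_mean, count_sd_within, count_sd_between,
                             plate_area_mean, plate_area_cv = 0.12,
                             aspect = 0.55, exponent = 2.5,
                             perturb_amp = c(0.03, 0.02),
                             mixture_means, mixture_sds,
                             mixture_weights = NULL,
                             digit_noise_um = 1.0, count_noise_sd = 1.5,
                             broken_rate = 0.02, left_plate_prob = 0.19,
                             abdomen_mean = 23, abdomen_sd = 1.5,
                             abdomen_noise = 0.35,
                             n_vertices = c(600L, 1100L)) {
  mixture_means <- as.matrix(mixture_means)
  mixture_sds <- as.matrix(mixture_sds)
  K <- nrow(mixture_means)
  if (is.null(mixture_weights)) mixture_weights <- rep(1 / K, K)
  stopifnot(abs(sum(mixture_weights) - 1) < 1e-9,
            nrow(mixture_sds) == K, all(mixture_sds > 0),
            count_mean >= 3, count_sd_within >= 0, count_sd_between >= 0)
  structure(as.list(environment()), class = "species_template")
}

#' Default two-species templates
#'
#' The generator's stated world: \emph{E. anna} with ~49 sensilla per plate
#' spread medially over a large fraction of a larger plate (density near
#' 1.6 per 1000 square micrometres), \emph{E. carunculatum} with ~28 sensilla
#' in a compact lateral cluster of a smaller plate (denser, lower coverage).
#' Within-population count SDs make a twofold count range within a
#' population unremarkable; replicate noise is tuned so replicate trait
#' correlations sit near 0.95.
#'
#' @return Named list of two \code{species_template}s.
#' @export
default_templates <- function() {
  list(
    E_anna = species_template(
      "E_anna", count_mean = 49, count_sd_within = 9, count_sd_between = 4,
      plate_area_mean = 43000, abdomen_mean = 24,
      mixture_means = rbind(c(-0.25, 0.30), c(-0.20, -0.32)),
      mixture_sds = rbind(c(0.60, 0.55), c(0.62, 0.52))),
    E_carunculatum = species_template(
      "E_carunculatum", count_mean = 28, count_sd_within = 7,
      count_sd_between = 3.5, plate_area_mean = 30000, abdomen_mean = 23,
      mixture_means = rbind(c(0.42, 0.18), c(0.40, -0.20)),
      mixture_sds = rbind(c(0.33, 0.36), c(0.34, 0.32))))
}

#' Plantable sympatry effects
#'
#' Additive effects applied to sympatric populations only; both default to
#' zero (no reproductive character displacement — the null world).
#'
#' @param sympatry_count_shift added to the count mean in sympatric
#'   populations.
#' @param sympatry_location_shift length-2 displacement of the placement
#'   mixture means for sympatric populations, in unit-area standardized-frame
#'   units.
#' @return List of class \code{effect_config}.
#' @export
effect_config <- function(sympatry_count_shift = 0,
                          sympatry_location_shift = c(0, 0)) {
  stopifnot(length(sympatry_location_shift) == 2L)
  structure(list(sympatry_count_shift = sympatry_count_shift,
                 sympatry_location_shift = as.numeric(sympatry_location_shift)),
            class = "effect_config")
}

superellipse_radius <- function(theta, a, b, p) {
  (abs(cos(theta) / a)^p + abs(sin(theta) / b)^p)^(-1 / p)
}

#' Generate one synthetic plate outline
#'
#' Simple closed polygon of \code{n_vertices} vertices: a superellipse with
#' the template's aspect and exponent, modulated by low-order radial
#' harmonics with random phases, scaled to a lognormal plate area and offset
#' to an arbitrary image position. Two vertices are designated as the lower
#' and upper medial corners (medial is the negative-x side in right-plate
#' orientation) and returned in the \code{"corners"} attribute.
#'
#' @param template a \code{species_template}.
#' @param seed integer seed (optional; uses the current RNG stream if NULL).
#' @param n_vertices override the template's vertex-count range (scalar).
#' @return Polygon matrix with attribute \code{corners} =
#'   (lower medial index, upper medial index).
#' @export
make_plate_outline <- function(template, seed = NULL, n_vertices = NULL) {
  with_seed(seed, {
    nv <- if (!is.null(n_vertices)) as.integer(n_vertices) else
      sample(template$n_vertices[1L]:template$n_vertices[2L], 1L)
    theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    r <- superellipse_radius(theta, 1, template$aspect, template$exponent)
    amp <- template$perturb_amp
    if (length(amp) && any(amp > 0)) {
      phases <- stats::runif(length(amp), 0, 2 * pi)
      for (j in seq_along(amp))
        r <- r * (1 + amp[j] * stats::runif(1) * sin(j * theta + phases[j]))
    }
    xy <- cbind(r * cos(theta), r * sin(theta))
    area_target <- stats::rlnorm(1, log(template$plate_area_mean),
                                 template$plate_area_cv)
    xy <- xy * sqrt(area_target / polygon_area(xy))
    center <- c(300, 250) + stats::runif(2, -30, 30)
    xy <- sweep(xy, 2L, center, `+`)
    lower <- which.min(xy[, 1L] + xy[, 2L])   # medial = low x, lower = low y
    upper <- which.min(xy[, 1L] - xy[, 2L])
    structure(xy, corners = c(lower, upper))
  })
}

#' Detect the medial corner vertices of a right-oriented plate outline
#'
#' Heuristic used when corners are not supplied with the data: the lower
#' medial corner minimizes x + y and the upper medial corner minimizes
#' x - y (medial is the low-x side in right orientation).
#'
#' @param outline polygon matrix in right-plate orientation.
#' @return Integer vector (lower medial index, upper medial index).
#' @export
detect_plate_corners <- function(outline) {
  outline <- as_xy_matrix(outline, "outline vertices")
  c(which.min(outline[, 1L] + outline[, 2L]),
    which.min(outline[, 1L] - outline[, 2L]))
}

# component means/covariances in absolute coordinates for a given outline
mixture_absolute <- function(template, outline, location_shift_um = c(0, 0)) {
  ctr <- polygon_centroid(outline)
  wx <- diff(range(outline[, 1L])) / 2
  wy <- diff(range(outline[, 2L])) / 2
  means <- sweep(template$mixture_means %*% diag(c(wx, wy)), 2L, ctr, `+`)
  means <- sweep(means, 2L, location_shift_um, `+`)
  sds <- template$mixture_sds %*% diag(c(wx, wy))
  list(means = means, sds = sds, weights = template$mixture_weights)
}

#' Sample sensilla positions inside an outline
#'
#' Draws \code{n} points from the template's Gaussian mixture (means and
#' spreads expressed relative to the outline's extent) by rejection against
#' the outline polygon.
#'
#' @param template a \code{species_template}.
#' @param outline polygon matrix.
#' @param n number of sensilla (>= 1).
#' @param seed optional integer seed.
#' @param location_shift_um displacement of all component means,
#'   micrometres.
#' @return n x 2 point matrix, all points inside the outline.
#' @export
sample_sensilla <- function(template, outline, n, seed = NULL,
                            location_shift_um = c(0, 0)) {
  stopifnot(n >= 1)
  mix <- mixture_absolute(template, outline, location_shift_um)
  with_seed(seed, {
    out <- matrix(NA_real_, 0L, 2L)
    for (round in 1:200) {
      need <- n - nrow(out)
      if (need <= 0L) break
      comp <- sample.int(length(mix$weights), 2L * need + 10L,
                         replace = TRUE, prob = mix$weights)
      cand <- cbind(stats::rnorm(length(comp), mix$means[comp, 1L],
                                 mix$sds[comp, 1L]),
                    stats::rnorm(length(comp), mix$means[comp, 2L],
                                 mix$sds[comp, 2L]))
      keep <- .pip_crossing(cand, outline)  # strict inside is fine here
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    if (nrow(out) < n) {
      acc <- vapply(seq_along(mix$weights), function(k) {
        pts <- cbind(stats::rnorm(200, mix$means[k, 1L], mix$sds[k, 1L]),
                     stats::rnorm(200, mix$means[k, 2L], mix$sds[k, 2L]))
        mean(points_in_polygon(pts, outline))
      }, numeric(1))
      stop("rejection sampling failed; mixture component ", which.min(acc),
           " places most of its mass outside the plate", call. = FALSE)
    }
    out[seq_len(n), , drop = FALSE]
  })
}

# Jitter an outline radially (keeps it star-shaped, hence simple) and jitter
# sensilla, pulling strays back inside.
jitter_replicate <- function(outline, points, noise_sd) {
  if (noise_sd <= 0) return(list(outline = outline, points = points))
  ctr <- polygon_centroid(outline)
  rel <- sweep(outline, 2L, ctr)
  rad <- sqrt(rowSums(rel^2))
  rad_new <- pmax(rad + stats::rnorm(length(rad), 0, noise_sd), 0.1 * rad)
  out2 <- sweep(rel * (rad_new / rad), 2L, ctr, `+`)
  pts2 <- points + matrix(stats::rnorm(length(points), 0, noise_sd),
                          ncol = 2L)
  ctr2 <- polygon_centroid(out2)
  for (k in 1:60) {  # pull jittered strays back toward the plate center
    outside <- which(!.pip_crossing(pts2, out2))
    if (!length(outside)) break
    pts2[outside, ] <- rep(ctr2, each = length(outside)) +
      sweep(pts2[outside, , drop = FALSE], 2L, ctr2) * 0.97
  }
  list(outline = out2, points = pts2)
}

#' Generate one synthetic female (two replicate plate records)
#'
#' Draws a latent truth (outline, sensilla, count, abdomen length, plate
#' side) and two replicate measurements with independent digitization noise:
#' coordinate jitter, a small recount error (points dropped or added), and
#' broken-socket flags. Left-sided females are stored mirrored, as digitized.
#'
#' @param template a \code{species_template}.
#' @param specimen_id,population_id identifiers.
#' @param seed optional integer seed.
#' @param count_shift additive shift of the count mean (population effect).
#' @param location_shift placement displacement in unit-area
#'   standardized-frame units (converted to micrometres via the plate area).
#' @param n_vertices optional outline vertex-count override.
#' @return List with \code{records} (two \code{plate_record}s) and
#'   \code{latent} (one-row data frame of the latent truth).
#' @export
generate_female <- function(template, specimen_id, population_id,
                            seed = NULL, count_shift = 0,
                            location_shift = c(0, 0), n_vertices = NULL) {
  with_seed(seed, {
    outline <- make_plate_outline(template, n_vertices = n_vertices)
    corners <- attr(outline, "corners")
    shift_um <- location_shift * sqrt(polygon_area(outline))
    n_true <- max(3L, as.integer(round(stats::rnorm(
      1, template$count_mean + count_shift, template$count_sd_within))))
    pts <- sample_sensilla(template, outline, n_true,
                           location_shift_um = shift_um)
    side <- if (stats::runif(1) < template$left_plate_prob) "left" else "right"
    abdomen <- stats::rnorm(1, template$abdomen_mean, template$abdomen_sd)
    recs <- lapply(1:2, function(rep_id) {
      jit <- jitter_replicate(outline, pts, template$digit_noise_um)
      o <- jit$outline; p <- jit$points
      dn <- as.integer(round(stats::rnorm(1, 0, template$count_noise_sd)))
      if (dn < 0 && nrow(p) + dn >= 3L) {
        p <- p[-sample.int(nrow(p), -dn), , drop = FALSE]
      } else if (dn > 0) {
        extra <- sample_sensilla(template, o, dn, location_shift_um = shift_um)
        p <- rbind(p, extra)
      }
      broken <- stats::runif(nrow(p)) < template$broken_rate
      if (side == "left") {
        mid <- mean(range(o[, 1L]))
        o[, 1L] <- 2 * mid - o[, 1L]
        p[, 1L] <- 2 * mid - p[, 1L]
      }
      plate_record(specimen_id, template$name, population_id, side,
                   o, p, broken = broken, replicate_id = rep_id,
                   abdomen_length = abdomen +
                     stats::rnorm(1, 0, template$abdomen_noise))
    })
    latent <- data.frame(specimen_id = specimen_id,
                         population_id = population_id,
                         species = template$name, true_count = n_true,
                         plate_area = polygon_area(outline), side = side,
                         abdomen_length = abdomen, stringsAsFactors = FALSE)
    list(records = recs, latent = latent,
         truth = list(outline = outline, points = pts, corners = corners))
  })
}

#' Generate a full synthetic study
#'
#' One synthetic female per specimen slot of the manifest, with per-population
#' random count offsets and, for sympatric populations, the planted effects
#' of \code{effects}. Per-population seeds are derived deterministically from
#' the master seed and the manifest row, so any subset of populations is
#' reproducible in isolation.
#'
#' @param manifest a \code{study_manifest} (e.g.
#'   \code{\link{table1_manifest}()}).
#' @param templates named list of \code{species_template}s covering every
#'   species in the manifest.
#' @param effects an \code{\link{effect_config}}.
#' @param seed master integer seed.
#' @param n_vertices optional outline vertex-count override (scaled-down
#'   simulations).
#' @return List of class \code{synthetic_study}: \code{manifest},
#'   \code{records} (flat list of plate records, two per female),
#'   \code{latent} (data frame of latent truths), \code{seed}.
#' @export
generate_study <- function(manifest, templates = default_templates(),
                           effects = effect_config(), seed = 1L,
                           n_vertices = NULL) {
  stopifnot(inherits(manifest, "study_manifest"))
  missing_tpl <- setdiff(unique(manifest$species), names(templates))
  if (length(missing_tpl))
    stop("no template for species: ", paste(missing_tpl, collapse = ", "),
         call. = FALSE)
  records <- list(); latent <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    tpl <- templates[[row$species]]
    pop_seed <- derive_seed(seed, paste(row$population_id, row$species))
    sympatric <- row$patry == "sympatric"
    res <- with_seed(pop_seed, {
      pop_dev <- stats::rnorm(1, 0, tpl$count_sd_between)
      lapply(seq_len(row$n_specimens), function(f) {
        generate_female(
          tpl,
          specimen_id = sprintf("%s_f%02d", row$population_id, f),
          population_id = row$population_id,
          count_shift = pop_dev +
            if (sympatric) effects$sympatry_count_shift else 0,
          location_shift = if (sympatric) effects$sympatry_location_shift
                           else c(0, 0),
          n_vertices = n_vertices)
      })
    })
    records <- c(records, unlist(lapply(res, `[[`, "records"),
                                 recursive = FALSE))
    latent <- c(latent, lapply(res, `[[`, "latent"))
  }
  structure(list(manifest = manifest, records = records,
                 latent = do.call(rbind, latent), seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$latent), " females, ",
      length(x$records), " plate records, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate per-female standardized clouds for one population
#'
#' Convenience wrapper for calibration and power simulations: generates
#' \code{n_females} single-replicate plates from a template and returns their
#' unit-area, centroid-origin sensilla clouds.
#'
#' @param template a \code{species_template}.
#' @param n_females number of females.
#' @param seed integer seed.
#' @param location_shift placement shift in standardized-frame units.
#' @param count_mean optional override of the template count mean.
#' @param n_vertices optional outline vertex-count override.
#' @return List of \code{standardized_cloud}s.
#' @export
simulate_population_clouds <- function(template, n_females, seed = NULL,
                                       location_shift = c(0, 0),
                                       count_mean = NULL, n_vertices = NULL) {
  if (!is.null(count_mean)) template$count_mean <- count_mean
  with_seed(seed, {
    lapply(seq_len(n_females), function(f) {
      outline <- make_plate_outline(template, n_vertices = n_vertices)
      shift_um <- location_shift * sqrt(polygon_area(outline))
      n <- max(3L, as.integer(round(stats::rnorm(
        1, template$count_mean, template$count_sd_within))))
      pts <- sample_sensilla(template, outline, n,
                             location_shift_um = shift_um)
      standardize_cloud(outline, pts, specimen_id = paste0("f", f))
    })
  })
}

#' Write a synthetic study to disk in the loader's layout
#'
#' Emits the manifest and one pair of coordinate files (plus metadata) per
#' plate record, so the pipeline can be exercised end-to-end through its
#' file-reading entry points.
#'
#' @param study a \code{synthetic_study}.
#' @param dir destination directory.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(study$manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  for (rec in study$records) write_plate_record(rec, file.path(dir, "plates"))
  invisible(dir)
}

#' Read a study written by \code{\link{write_study}}
#'
#' @param dir study directory containing \code{manifest.csv} and
#'   \code{plates/}.
#' @return List with \code{manifest} and \code{records}.
#' @export
read_study <- function(dir) {
  manifest <- load_manifest(file.path(dir, "manifest.csv"))
  metas <- sort(list.files(file.path(dir, "plates"), "_meta\\.json$",
                           full.names = TRUE))
  records <- lapply(metas, read_plate_record)
  list(manifest = manifest, records = records)
}
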