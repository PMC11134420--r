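# Synthetic-cohort simulator. Generates ellipsoidal scalps spanning a
# realistic head-circumference range, a 25-optode / 24-channel layout laid
# down as a serpentine chain at exactly the configured chord spacing, the
# three anatomical fiducials, an MRI truth set and repeat scan sets with
# controllable cap-placement jitter (between subjects) and digitization
# noise (within subjects). All randomness is driven by deterministic
# substreams derived from (seed, subject, stream), so cohorts are
# bit-reproducible and the noise components can be varied independently.

ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

#' Ellipsoidal head model
#'
#' Builds an ellipsoidal scalp whose axial (horizontal) ellipse has the
#' requested perimeter -- the head circumference. Axes are RAS: x lateral
#' (left-right), y antero-posterior, z vertical; the ellipsoid is centered
#' at the origin with the ear-level plane at z = 0. The vertical semi-axis
#' is fixed at 1.4x the lateral semi-axis, a typical scalp proportion.
#' Fiducials sit at the lateral extremes (LPA/RPA) and at the front pole
#' raised by 10% of the vertical semi-axis (nasion).
#'
#' @param circumference axial perimeter in mm, in (400, 700).
#' @param eccentricity front-back semi-axis relative to left-right, in
#'   (0.5, 1.5); ~1.25 for typical heads.
#' @return object of class `head_model` with `semi_axes` (mm),
#'   `circumference` (realized, mm) and `fiducials` (data frame).
#' @export
#' @examples
#' h <- make_head(565, 1.25)
#' h$circumference
make_head <- function(circumference, eccentricity = 1.25) {
  if (!is.finite(circumference) || circumference <= 400 ||
      circumference >= 700) {
    stop("circumference must be in (400, 700) mm, got ", circumference,
         call. = FALSE)
  }
  if (!is.finite(eccentricity) || eccentricity <= 0.5 ||
      eccentricity >= 1.5) {
    stop("eccentricity must be in (0.5, 1.5), got ", eccentricity,
         call. = FALSE)
  }
  a <- circumference / ellipse_perimeter(1, eccentricity)
  b <- eccentricity * a
  cz <- 1.4 * a
  realized <- ellipse_perimeter(a, b)
  if (abs(realized - circumference) > 0.1) {
    stop("perimeter solve failed: realized ", realized, call. = FALSE)
  }
  fid <- data.frame(
    label = c("Nasion", "LPA", "RPA"),
    x = c(0, -a, a),
    y = c(b * sqrt(1 - 0.01), 0, 0),
    z = c(0.1 * cz, 0, 0),
    stringsAsFactors = FALSE)
  structure(list(semi_axes = c(a, b, cz), circumference = realized,
                 fiducials = fid),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> semi-axes %.1f x %.1f x %.1f mm, circumference %.1f mm\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$circumference))
  invisible(x)
}

# point on the scalp spiral at parameter u: azimuth u (0 = front, winding
# toward the right), height fraction rising linearly with u
spiral_point <- function(head, u, f0 = 0.15, slope = 0.045) {
  ax <- head$semi_axes
  f <- f0 + slope * u
  s <- sqrt(pmax(0, 1 - f^2))
  cbind(ax[1] * s * sin(u), ax[2] * s * cos(u), ax[3] * f)
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study design this toolkit validates: 5 subjects,
#' 3 repeat scans each, 25 optodes forming 24 channels at a fixed 30 mm
#' chord spacing, head circumferences ~56.6 +/- 2.9 cm in a 54-61 cm range.
#' The jitter/noise defaults emulate the qualitative error structure of
#' real cap use -- cap placement varies by several mm between subjects,
#' digitization adds ~1 mm per point -- and are not estimates of any
#' particular device.
#'
#' @param n_subjects number of subjects (default 5).
#' @param n_scans repeat scans per subject (default 3).
#' @param n_optodes optodes in the layout (default 25, >= 4).
#' @param channel_spacing source-detector chord spacing in mm (default 30).
#' @param cap_shift_sd between-subject tangential cap shift SD, mm.
#' @param cap_rotation_sd between-subject cap rotation about the vertical
#'   axis, degrees.
#' @param digitization_noise_sd isotropic per-point, per-scan noise SD, mm.
#' @param fiducial_noise_sd noise SD on MRI fiducials only, mm.
#' @param circumference_mean,circumference_sd,circumference_range head
#'   circumference law (normal, clipped), mm.
#' @param eccentricity head front-back/left-right axis ratio.
#' @param seed integer master seed (mandatory for reproducible fixtures).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5, n_scans = 3, n_optodes = 25,
                          channel_spacing = 30,
                          cap_shift_sd = 6, cap_rotation_sd = 3,
                          digitization_noise_sd = 1.2,
                          fiducial_noise_sd = 2.5,
                          circumference_mean = 566,
                          circumference_sd = 29,
                          circumference_range = c(540, 610),
                          eccentricity = 1.25,
                          seed = 1L) {
  sds <- c(cap_shift_sd, cap_rotation_sd, digitization_noise_sd,
           fiducial_noise_sd, circumference_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise SDs must be finite and >= 0", call. = FALSE)
  }
  if (n_optodes < 4) stop("n_optodes must be >= 4", call. = FALSE)
  if (n_subjects < 1 || n_scans < 1) {
    stop("n_subjects and n_scans must be >= 1", call. = FALSE)
  }
  if (channel_spacing <= 0) stop("channel_spacing must be > 0",
                                 call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_scans = as.integer(n_scans),
                 n_optodes = as.integer(n_optodes),
                 channel_spacing = channel_spacing,
                 cap_shift_sd = cap_shift_sd,
                 cap_rotation_sd = cap_rotation_sd,
                 digitization_noise_sd = digitization_noise_sd,
                 fiducial_noise_sd = fiducial_noise_sd,
                 circumference_mean = circumference_mean,
                 circumference_sd = circumference_sd,
                 circumference_range = circumference_range,
                 eccentricity = eccentricity,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic substream seed from (seed, subject, stream); Lehmer-style
# mixing, exact in doubles, result < 2^31 - 1
derive_seed <- function(...) {
  k <- 0
  for (v in c(...)) k <- (k * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(k)
}

#' Place the optode layout on a head
#'
#' Lays `n_optodes` optodes along a serpentine spiral path over the scalp
#' surface, traversing the prefrontal, temporal and visual regions.
#' Successive optodes are positioned by root-bracketing (bisection) along
#' the surface curve so that every consecutive chord equals
#' `channel_spacing` to within 1e-6 mm. Labels alternate detector/source
#' (D1, S1, D2, ...) so that each of the `n_optodes - 1` consecutive pairs
#' is a source-detector channel.
#'
#' @param head a [make_head()] model.
#' @param config a [cohort_config()].
#' @return list with `probe_set` (optodes plus fiducials, space `"head"`),
#'   `channels` (a [channel_table()]) and `regions` (named character vector
#'   tagging each optode prefrontal/temporal/visual).
#' @export
place_optodes <- function(head, config = cohort_config()) {
  stopifnot(inherits(head, "head_model"), inherits(config, "cohort_config"))
  n <- config$n_optodes
  spacing <- config$channel_spacing
  f0 <- 0.15
  slope <- 0.045
  u <- numeric(n)
  u[1] <- 0
  for (k in seq.int(2, n)) {
    g <- function(d) {
      sqrt(sum((spiral_point(head, u[k - 1] + d, f0, slope) -
                  spiral_point(head, u[k - 1], f0, slope))^2)) - spacing
    }
    upper <- 0.2
    while (g(upper) < 0) {
      upper <- upper * 2
      if (f0 + slope * (u[k - 1] + upper) >= 0.92 && g(upper) < 0) {
        stop("channel spacing unachievable on this head surface",
             call. = FALSE)
      }
    }
    u[k] <- u[k - 1] +
      stats::uniroot(g, c(1e-9, upper), tol = 1e-12)$root
    if (f0 + slope * u[k] >= 0.92) {
      stop("channel spacing unachievable on this head surface",
           call. = FALSE)
    }
  }
  pos <- spiral_point(head, u, f0, slope)
  chords <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-n, , drop = FALSE])^2))
  stopifnot(all(abs(chords - spacing) < 1e-6))
  labels <- ifelse(seq_len(n) %% 2 == 1,
                   paste0("D", (seq_len(n) + 1) %/% 2),
                   paste0("S", seq_len(n) %/% 2))
  az <- abs(((atan2(pos[, 1], pos[, 2]) + pi) %% (2 * pi)) - pi)
  regions <- ifelse(az < pi / 3, "prefrontal",
                    ifelse(az < 2 * pi / 3, "temporal", "visual"))
  names(regions) <- labels
  pts <- rbind(
    data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE),
    head$fiducials)
  first <- labels[-n]
  second <- labels[-1]
  is_src <- startsWith(first, "S")
  channels <- channel_table(source = ifelse(is_src, first, second),
                            detector = ifelse(is_src, second, first))
  list(probe_set = probe_set(pts, space = "head", subject_id = "template",
                             modality = "ir3d", scan_index = 0L),
       channels = channels,
       regions = regions)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

reproject_to_ellipsoid <- function(coords, semi_axes) {
  t <- 1 / sqrt(rowSums(sweep(coords, 2, semi_axes, "/")^2))
  coords * t
}

add_noise <- function(points, sd, rows = seq_len(nrow(points))) {
  if (sd > 0 && length(rows) > 0) {
    noise <- matrix(stats::rnorm(3 * length(rows), sd = sd),
                    ncol = 3)
    points[rows, c("x", "y", "z")] <-
      points[rows, c("x", "y", "z")] + noise
  }
  points
}

#' Simulate one subject
#'
#' Draws a subject head (circumference from the cohort's clipped normal
#' law), lays down the optode layout, applies a subject-specific cap
#' perturbation (tangential shift plus rotation about the vertical axis,
#' re-projected onto the scalp) to the optodes -- fiducials stay at their
#' anatomical positions -- and produces the MRI set (exact optodes,
#' fiducials perturbed by `fiducial_noise_sd`) and `n_scans` repeat scan
#' sets (independent isotropic noise of `digitization_noise_sd` on every
#' point including fiducials). Randomness comes from three deterministic
#' substreams (head/cap, fiducial noise, digitization noise) derived from
#' `(config$seed, subject_index)`, so cohorts are bit-reproducible and
#' changing one noise SD leaves the other streams' draws untouched.
#'
#' @param config a [cohort_config()].
#' @param subject_index positive integer.
#' @return list with `subject_id`, `mri` ([probe_set()]), `scans` (list of
#'   [probe_set()]), `truth`, `channels`, `regions`, `head`.
#' @export
simulate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"), subject_index >= 1)
  id <- sprintf("sub-%02d", subject_index)

  set.seed(derive_seed(config$seed, subject_index, 1))
  circ <- clip(stats::rnorm(1, config$circumference_mean,
                            config$circumference_sd),
               config$circumference_range[1], config$circumference_range[2])
  head <- make_head(circ, config$eccentricity)
  layout <- place_optodes(head, config)
  rot <- stats::rnorm(1, 0, config$cap_rotation_sd) * pi / 180
  shift <- stats::rnorm(2, 0, config$cap_shift_sd)

  pts <- layout$probe_set$points
  fid <- is_fiducial(pts$label)
  opt <- as.matrix(pts[!fid, c("x", "y", "z")])
  Rz <- matrix(c(cos(rot), sin(rot), 0,
                 -sin(rot), cos(rot), 0,
                 0, 0, 1), 3, 3)
  opt <- opt %*% t(Rz)
  opt[, 1] <- opt[, 1] + shift[1]
  opt[, 2] <- opt[, 2] + shift[2]
  opt <- reproject_to_ellipsoid(opt, head$semi_axes)
  pts[!fid, c("x", "y", "z")] <- opt

  truth <- probe_set(pts, space = "head", subject_id = id,
                     modality = "ir3d", scan_index = 0L)

  set.seed(derive_seed(config$seed, subject_index, 2))
  mri_pts <- add_noise(pts, config$fiducial_noise_sd, rows = which(fid))
  mri <- probe_set(mri_pts, space = "mri", subject_id = id,
                   modality = "mri", scan_index = 0L)

  set.seed(derive_seed(config$seed, subject_index, 3))
  scans <- lapply(seq_len(config$n_scans), function(k) {
    scan_pts <- add_noise(pts, config$digitization_noise_sd)
    probe_set(scan_pts, space = "scanner", subject_id = id,
              modality = "ir3d", scan_index = k)
  })

  list(subject_id = id, mri = mri, scans = scans, truth = truth,
       channels = layout$channels, regions = layout$regions, head = head)
}

#' Simulate a cohort
#'
#' Generates `n_subjects` independent subjects under one configuration and,
#' optionally, writes an on-disk fixture tree
#' (`<dir>/<subject>/mri.csv`, `<dir>/<subject>/scan<k>.pp`,
#' `<dir>/channels.csv`, `<dir>/config.json`) consumable by the
#' command-line interface. Two runs with the same configuration produce
#' byte-identical trees.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory for the fixture tree.
#' @return object of class `probe_cohort`: list with `subjects`, `channels`,
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL) {
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config, i))
  cohort <- structure(list(subjects = subjects,
                           channels = subjects[[1]]$channels,
                           config = config),
                      class = "probe_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.probe_cohort <- function(x, ...) {
  cat(sprintf("<probe_cohort> %d subjects x (1 MRI + %d scans), %d optodes, %d channels\n",
              length(x$subjects), x$config$n_scans, x$config$n_optodes,
              nrow(x$channels)))
  invisible(x)
}

#' Write a cohort fixture tree
#'
#' @param cohort a `probe_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "probe_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_marker_csv(s$mri, file.path(sdir, "mri.csv"))
    for (k in seq_along(s$scans)) {
      write_pp(s$scans[[k]], file.path(sdir, sprintf("scan%d.pp", k)))
    }
  }
  write_channel_csv(cohort$channels, file.path(dir, "channels.csv"))
  cfg <- unclass(cohort$config)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a cohort fixture tree
#'
#' @param dir directory written by [write_cohort()] (or arranged in the
#'   same layout from external data).
#' @return a `probe_cohort`; the `config` is reconstructed from
#'   `config.json` when present.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir,
                             call. = FALSE)
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    do.call(cohort_config, jsonlite::fromJSON(cfg_path))
  } else {
    NULL
  }
  channels <- read_channel_csv(file.path(dir, "channels.csv"))
  subj_dirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- lapply(subj_dirs, function(sdir) {
    id <- basename(sdir)
    mri <- read_marker_csv(file.path(sdir, "mri.csv"), space = "mri",
                           subject_id = id, modality = "mri",
                           scan_index = 0L)
    scan_files <- sort(list.files(sdir, pattern = "^scan[0-9]+\\.pp$",
                                  full.names = TRUE))
    scans <- lapply(seq_along(scan_files), function(k) {
      parse_pp(scan_files[k], space = "scanner", subject_id = id,
               modality = "ir3d", scan_index = k)
    })
    list(subject_id = id, mri = mri, scans = scans)
  })
  structure(list(subjects = subjects, channels = channels, config = config),
            class = "probe_cohort")
}
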