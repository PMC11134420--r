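# Cohort-level wrappers: run the four analyses across a multi-subject
# cohort (synthetic or read from disk), concatenating per-subject distance
# collections before pooling.

#' Cap-fixation variability across a cohort
#'
#' Aligns every subject's MRI-derived set landmark-based onto the template
#' montage (bringing all subjects to one common space), then computes the
#' between-subject variability of each optode position.
#'
#' @param cohort a `probe_cohort` (see [simulate_cohort()],
#'   [read_cohort()]).
#' @param template a [montage()] (default the bundled idealized 10-05
#'   template).
#' @param method,pooling see [cap_fixation_variability()].
#' @param allow_scaling see [align()].
#' @return a [metric_report()].
#' @export
cohort_cap_fixation <- function(cohort,
                                template = load_montage("standard_1005"),
                                method = "pairwise", pooling = "flat",
                                allow_scaling = FALSE) {
  stopifnot(inherits(cohort, "probe_cohort"))
  aligned <- lapply(cohort$subjects, function(s) {
    align(s$mri, template, mode = "landmark_based",
          allow_scaling = allow_scaling)$probe_set
  })
  cap_fixation_variability(aligned, method = method, pooling = pooling)
}

#' Scan-versus-MRI accuracy across a cohort
#'
#' @inheritParams cohort_cap_fixation
#' @param mode alignment mode, see [align()].
#' @return a [metric_report()] pooling all subjects' distances.
#' @export
cohort_accuracy <- function(cohort, mode = "landmark_free",
                            allow_scaling = FALSE, pooling = "flat") {
  stopifnot(inherits(cohort, "probe_cohort"))
  reports <- lapply(cohort$subjects, function(s) {
    accuracy(s$scans, s$mri, mode = mode, allow_scaling = allow_scaling)
  })
  merge_reports(reports, pooling = pooling)
}

#' Scan-rescan reproducibility across a cohort
#'
#' @inheritParams cohort_accuracy
#' @return a [metric_report()] pooling all subjects' distances.
#' @export
cohort_reproducibility <- function(cohort, mode = "landmark_free",
                                   allow_scaling = FALSE, pooling = "flat") {
  stopifnot(inherits(cohort, "probe_cohort"))
  reports <- lapply(cohort$subjects, function(s) {
    reproducibility(s$scans, mode = mode, allow_scaling = allow_scaling)
  })
  merge_reports(reports, pooling = pooling)
}

#' Inter-optode channel distances across a cohort
#'
#' @inheritParams cohort_cap_fixation
#' @param sets which point sets to measure: `"scan"`, `"mri"`, or `"all"`.
#' @return a [metric_report()] pooling one distance per channel per set.
#' @export
cohort_inter_optode <- function(cohort, sets = c("scan", "mri", "all"),
                                pooling = "flat") {
  stopifnot(inherits(cohort, "probe_cohort"))
  sets <- match.arg(sets)
  pick <- function(s) {
    switch(sets,
           scan = s$scans,
           mri = list(s$mri),
           all = c(list(s$mri), s$scans))
  }
  reports <- unlist(lapply(cohort$subjects, function(s) {
    lapply(pick(s), inter_optode_distances, channels = cohort$channels)
  }), recursive = FALSE)
  merge_reports(reports, pooling = pooling)
}

#' Full metric battery on a cohort
#'
#' Runs all four analyses: cap fixation (after landmark-based alignment of
#' the MRI sets onto the template), accuracy and reproducibility under both
#' alignment modes, inter-optode distances on MRI and on scan sets, plus
#' the Welch comparison of standard-cap variability against landmark-based
#' accuracy.
#'
#' @inheritParams cohort_cap_fixation
#' @return named list of [metric_report()] objects
#'   (`cap_fixation`, `accuracy_landmark_based`, `accuracy_landmark_free`,
#'   `reproducibility_landmark_based`, `reproducibility_landmark_free`,
#'   `inter_optode_mri`, `inter_optode_scan`) and `welch_cap_vs_accuracy`.
#' @export
metric_battery <- function(cohort, method = "pairwise", pooling = "flat",
                           allow_scaling = FALSE,
                           template = load_montage("standard_1005")) {
  out <- list(
    cap_fixation = cohort_cap_fixation(cohort, template = template,
                                       method = method, pooling = pooling,
                                       allow_scaling = allow_scaling),
    accuracy_landmark_based = cohort_accuracy(
      cohort, mode = "landmark_based", allow_scaling = allow_scaling,
      pooling = pooling),
    accuracy_landmark_free = cohort_accuracy(
      cohort, mode = "landmark_free", allow_scaling = allow_scaling,
      pooling = pooling),
    reproducibility_landmark_based = cohort_reproducibility(
      cohort, mode = "landmark_based", allow_scaling = allow_scaling,
      pooling = pooling),
    reproducibility_landmark_free = cohort_reproducibility(
      cohort, mode = "landmark_free", allow_scaling = allow_scaling,
      pooling = pooling),
    inter_optode_mri = cohort_inter_optode(cohort, sets = "mri",
                                           pooling = pooling),
    inter_optode_scan = cohort_inter_optode(cohort, sets = "scan",
                                            pooling = pooling))
  out$welch_cap_vs_accuracy <- compare_distances(
    out$cap_fixation, out$accuracy_landmark_based)
  out
}

#' Serialize a metric report to JSON
#'
#' @param report a [metric_report()].
#' @param file optional path; when `NULL` the JSON text is returned.
#' @return JSON text, invisibly when written.
#' @export
report_to_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "metric_report"))
  payload <- list(
    analysis = report$analysis,
    alignment = report$alignment,
    pooling = report$pooling,
    pooled_mean_mm = report$pooled_mean,
    pooled_sd_mm = report$pooled_sd,
    n_distances = report$n_distances,
    per_label = report$per_label)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows", na = "null")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

fmt_mean_sd <- function(mean, sd, digits = 2) {
  ifelse(is.na(mean), "",
         sprintf("%.*f (%.*f)", digits, mean, digits,
                 ifelse(is.na(sd), 0, sd)))
}

#' Write a summary table of the full metric battery
#'
#' One row per optode label with its mean registered position (mean and SD
#' of each coordinate across subjects) followed by the five metric columns
#' -- standard-cap variability (with the per-optode maximum rounded to an
#' integer for display), landmark-based accuracy and reproducibility,
#' landmark-free accuracy and reproducibility -- and a footer row with the
#' pooled averages. Stored report values keep full precision; rounding is
#' display-only.
#'
#' @param battery result of [metric_battery()].
#' @param positions optional list of aligned [probe_set()]s in a common
#'   space used for the coordinate columns; when `NULL` those columns are
#'   left blank.
#' @param file optional path; when `NULL` the TSV text is returned.
#' @return TSV text, invisibly when written.
#' @export
battery_to_tsv <- function(battery, positions = NULL, file = NULL) {
  cap <- battery$cap_fixation
  labels <- sort(cap$per_label$label)
  coord_summary <- NULL
  if (!is.null(positions)) {
    coord_summary <- summarize_positions(positions)
  }
  cell <- function(report, l, with_max = FALSE) {
    row <- report$per_label[report$per_label$label == l, ]
    if (nrow(row) == 0) return("")
    base <- fmt_mean_sd(row$mean, row$sd)
    if (with_max) paste0(base, ", ", round(row$max)) else base
  }
  coord_cell <- function(l, axis) {
    if (is.null(coord_summary)) return("")
    row <- coord_summary[coord_summary$label == l, ]
    if (nrow(row) == 0) return("")
    sprintf("%.0f (%.2f)", row[[paste0(axis, "_mean")]],
            row[[paste0(axis, "_sd")]])
  }
  header <- paste(c("Name", "X (SD)", "Y (SD)", "Z (SD)",
                    "Standard cap fixation",
                    "Landmark-based accuracy",
                    "Landmark-based reproducibility",
                    "Landmark-free accuracy",
                    "Landmark-free reproducibility"), collapse = "\t")
  body <- vapply(labels, function(l) {
    paste(c(l, coord_cell(l, "x"), coord_cell(l, "y"), coord_cell(l, "z"),
            cell(cap, l, with_max = TRUE),
            cell(battery$accuracy_landmark_based, l),
            cell(battery$reproducibility_landmark_based, l),
            cell(battery$accuracy_landmark_free, l),
            cell(battery$reproducibility_landmark_free, l)),
          collapse = "\t")
  }, character(1))
  footer <- paste(c("Average distance (mm)", "", "", "",
                    fmt_mean_sd(cap$pooled_mean, cap$pooled_sd),
                    fmt_mean_sd(battery$accuracy_landmark_based$pooled_mean,
                                battery$accuracy_landmark_based$pooled_sd),
                    fmt_mean_sd(
                      battery$reproducibility_landmark_based$pooled_mean,
                      battery$reproducibility_landmark_based$pooled_sd),
                    fmt_mean_sd(battery$accuracy_landmark_free$pooled_mean,
                                battery$accuracy_landmark_free$pooled_sd),
                    fmt_mean_sd(
                      battery$reproducibility_landmark_free$pooled_mean,
                      battery$reproducibility_landmark_free$pooled_sd)),
                  collapse = "\t")
  txt <- paste0(paste(c(header, body, footer), collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Per-label position summary across aligned sets
#'
#' @param sets list of [probe_set()]s in one common space.
#' @return data frame with per-label mean and SD of each coordinate.
#' @export
summarize_positions <- function(sets) {
  stopifnot(length(sets) >= 1)
  labels <- unique(unlist(lapply(sets, function(s) s$points$label)))
  labels <- labels[!is_fiducial(labels)]
  do.call(rbind, lapply(labels, function(l) {
    pos <- do.call(rbind, lapply(sets, function(s) {
      row <- s$points[s$points$label == l, ]
      if (nrow(row) == 1) as.numeric(row[, c("x", "y", "z")]) else NULL
    }))
    data.frame(label = l,
               x_mean = mean(pos[, 1]),
               x_sd = stats::sd(pos[, 1]),
               y_mean = mean(pos[, 2]),
               y_sd = stats::sd(pos[, 2]),
               z_mean = mean(pos[, 3]),
               z_sd = stats::sd(pos[, 3]),
               n = nrow(pos), stringsAsFactors = FALSE)
  }))
}
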