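# The four spatial-error analyses: between-subject cap-fixation
# variability, scan-vs-MRI accuracy, scan-rescan reproducibility, and
# inter-optode channel distances, plus the Welch comparison between
# analyses. Every analysis reduces to a flat collection of Euclidean
# distances tagged by optode label and by grouping unit (subject or pair),
# summarized per label and pooled.

#' Euclidean distance between two points
#'
#' @param p,q length-3 numeric positions (mm).
#' @return distance in mm.
#' @export
#' @examples
#' euclidean(c(0, 0, 0), c(3, 4, 0))  # 5
euclidean <- function(p, q) {
  stopifnot(length(p) == 3, length(q) == 3,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Build a metric report from tagged distances
#'
#' @param analysis one of `"cap_fixation"`, `"accuracy"`,
#'   `"reproducibility"`, `"inter_optode"`.
#' @param alignment `"landmark_based"`, `"landmark_free"`, or `"none"`.
#' @param distances data frame with columns `label`, `group`, `distance`.
#' @param pooling `"flat"` (pool all individual distances; default) or
#'   `"per_subject"` (summarize per-group means).
#' @return object of class `metric_report` with per-label summaries
#'   (mean/sd/max/n), pooled mean and SD, and the raw distance collection.
#'   SDs use the n-1 denominator.
#' @export
metric_report <- function(analysis, alignment, distances,
                          pooling = c("flat", "per_subject")) {
  analysis <- match.arg(analysis, c("cap_fixation", "accuracy",
                                    "reproducibility", "inter_optode"))
  alignment <- match.arg(alignment, c("landmark_based", "landmark_free",
                                      "none"))
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(distances),
            all(c("label", "group", "distance") %in% names(distances)))
  if (nrow(distances) == 0) stop("no distances to report", call. = FALSE)
  if (any(distances$distance < 0)) stop("distances must be >= 0",
                                        call. = FALSE)
  labels <- unique(distances$label)
  per_label <- do.call(rbind, lapply(labels, function(l) {
    d <- distances$distance[distances$label == l]
    data.frame(label = l, mean = mean(d),
               sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               max = max(d), n = length(d), stringsAsFactors = FALSE)
  }))
  if (pooling == "flat") {
    pooled_mean <- mean(distances$distance)
    pooled_sd <- if (nrow(distances) > 1) stats::sd(distances$distance)
                 else NA_real_
  } else {
    gm <- tapply(distances$distance, distances$group, mean)
    pooled_mean <- mean(gm)
    pooled_sd <- if (length(gm) > 1) stats::sd(gm) else NA_real_
  }
  structure(list(analysis = analysis, alignment = alignment,
                 per_label = per_label,
                 pooled_mean = pooled_mean, pooled_sd = pooled_sd,
                 n_distances = nrow(distances),
                 pooling = pooling, distances = distances),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s (%s alignment, %s pooling)\n",
              x$analysis, x$alignment, x$pooling))
  cat(sprintf("  pooled: %.2f (SD %.2f) mm over %d distances, %d labels\n",
              x$pooled_mean, x$pooled_sd, x$n_distances,
              nrow(x$per_label)))
  invisible(x)
}

#' Distances carried by a report
#'
#' @param report a [metric_report()].
#' @return numeric vector of the individual distances (mm).
#' @export
report_distances <- function(report) {
  stopifnot(inherits(report, "metric_report"))
  report$distances$distance
}

#' Merge reports by concatenating their distance collections
#'
#' Used by the cohort-level wrappers: per-subject distance collections are
#' concatenated and the pooled statistics recomputed over the combined
#' collection.
#'
#' @param reports list of [metric_report()] objects sharing analysis and
#'   alignment.
#' @param pooling pooling rule for the merged report.
#' @return a [metric_report()].
#' @export
merge_reports <- function(reports, pooling = "flat") {
  stopifnot(length(reports) >= 1)
  analysis <- unique(vapply(reports, `[[`, "", "analysis"))
  alignment <- unique(vapply(reports, `[[`, "", "alignment"))
  if (length(analysis) != 1 || length(alignment) != 1) {
    stop("reports to merge must share analysis and alignment", call. = FALSE)
  }
  metric_report(analysis, alignment,
                do.call(rbind, lapply(reports, `[[`, "distances")),
                pooling = pooling)
}

# shared-label optode distances between two probe sets (fiducials excluded)
paired_label_distances <- function(a, b) {
  la <- split_fiducials(a)$optodes
  lb <- split_fiducials(b)$optodes
  shared <- intersect(la$label, lb$label)
  ca <- as.matrix(la[match(shared, la$label), c("x", "y", "z")])
  cb <- as.matrix(lb[match(shared, lb$label), c("x", "y", "z")])
  data.frame(label = shared,
             distance = sqrt(rowSums((ca - cb)^2)),
             stringsAsFactors = FALSE)
}

#' Between-subject cap-fixation variability
#'
#' Quantifies how differently the cap sits on different heads when no
#' spatial registration is performed: the spread of each optode's position
#' across subjects, after all subjects' MRI-derived sets have been brought
#' to a common (template) space beforehand. Fiducials are excluded.
#'
#' @param mri_sets list of [probe_set()] objects (one per subject), already
#'   aligned to a common space.
#' @param method `"pairwise"` (default): Euclidean distances over all
#'   unordered subject pairs per label; `"centroid"`: distance from each
#'   subject's point to the across-subject mean position.
#' @param pooling see [metric_report()].
#' @return a [metric_report()] with `analysis = "cap_fixation"`.
#' @export
cap_fixation_variability <- function(mri_sets,
                                     method = c("pairwise", "centroid"),
                                     pooling = "flat") {
  method <- match.arg(method)
  if (length(mri_sets) < 2) {
    stop("cap-fixation variability needs >= 2 subjects", call. = FALSE)
  }
  spaces <- unique(vapply(mri_sets, `[[`, "", "space"))
  if (length(spaces) != 1) {
    stop("all sets must be in one common space; got: ",
         paste(spaces, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(mri_sets, `[[`, "", "subject_id")
  opt <- lapply(mri_sets, function(s) split_fiducials(s)$optodes)
  labels <- unique(unlist(lapply(opt, `[[`, "label")))
  skipped <- character(0)
  rows <- list()
  for (l in labels) {
    have <- which(vapply(opt, function(o) l %in% o$label, logical(1)))
    if (length(have) < 2) {
      skipped <- c(skipped, l)
      next
    }
    pos <- t(vapply(have, function(i) {
      as.numeric(opt[[i]][opt[[i]]$label == l, c("x", "y", "z")])
    }, numeric(3)))
    if (method == "pairwise") {
      for (i in seq_along(have)[-length(have)]) {
        for (j in seq.int(i + 1, length(have))) {
          rows[[length(rows) + 1]] <- data.frame(
            label = l,
            group = paste(ids[have[i]], ids[have[j]], sep = "|"),
            distance = euclidean(pos[i, ], pos[j, ]),
            stringsAsFactors = FALSE)
        }
      }
    } else {
      ctr <- colMeans(pos)
      for (i in seq_along(have)) {
        rows[[length(rows) + 1]] <- data.frame(
          label = l, group = ids[have[i]],
          distance = euclidean(pos[i, ], ctr),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(skipped) > 0) {
    warning("labels present in fewer than 2 subjects skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0) stop("no label shared by >= 2 subjects",
                              call. = FALSE)
  metric_report("cap_fixation", "landmark_based", do.call(rbind, rows),
                pooling = pooling)
}

#' Scan-versus-MRI accuracy for one subject
#'
#' Aligns each repeat 3D-scan set to the subject's MRI-derived reference
#' under the chosen alignment mode, then collects the per-optode Euclidean
#' distances between the aligned scan positions and the MRI positions.
#'
#' @param scan_sets list of [probe_set()] repeat scans for one subject.
#' @param mri_set the subject's MRI-derived [probe_set()].
#' @param mode alignment mode, see [align()].
#' @param allow_scaling see [align()].
#' @param pooling see [metric_report()].
#' @return a [metric_report()] with `analysis = "accuracy"`.
#' @export
accuracy <- function(scan_sets, mri_set,
                     mode = c("landmark_based", "landmark_free"),
                     allow_scaling = FALSE, pooling = "flat") {
  mode <- match.arg(mode)
  stopifnot(length(scan_sets) >= 1, inherits(mri_set, "probe_set"))
  rows <- lapply(scan_sets, function(scan) {
    aligned <- align(scan, mri_set, mode = mode,
                     allow_scaling = allow_scaling)$probe_set
    d <- paired_label_distances(aligned, mri_set)
    d$group <- mri_set$subject_id
    d
  })
  metric_report("accuracy", mode, do.call(rbind, rows), pooling = pooling)
}

#' Scan-rescan reproducibility for one subject
#'
#' For every unordered pair of repeat scans, aligns the second onto the
#' first under the chosen mode and collects per-optode distances.
#'
#' @param scan_sets list of >= 2 repeat [probe_set()] scans for one subject.
#' @inheritParams accuracy
#' @return a [metric_report()] with `analysis = "reproducibility"`.
#' @export
reproducibility <- function(scan_sets,
                            mode = c("landmark_based", "landmark_free"),
                            allow_scaling = FALSE, pooling = "flat") {
  mode <- match.arg(mode)
  if (length(scan_sets) < 2) {
    stop("reproducibility needs >= 2 scans per subject", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(scan_sets)[-length(scan_sets)]) {
    for (j in seq.int(i + 1, length(scan_sets))) {
      aligned <- align(scan_sets[[j]], scan_sets[[i]], mode = mode,
                       allow_scaling = allow_scaling)$probe_set
      d <- paired_label_distances(aligned, scan_sets[[i]])
      d$group <- scan_sets[[i]]$subject_id
      rows[[length(rows) + 1]] <- d
    }
  }
  metric_report("reproducibility", mode, do.call(rbind, rows),
                pooling = pooling)
}

#' Inter-optode channel distances
#'
#' One Euclidean (chord) distance per source-detector channel; no alignment
#' is applied since chord lengths are invariant under rigid motion.
#'
#' @param ps a [probe_set()].
#' @param channels a [channel_table()]; every referenced label must be
#'   present in `ps`.
#' @param pooling see [metric_report()].
#' @return a [metric_report()] with `analysis = "inter_optode"`; per-label
#'   entries are keyed `"source-detector"`.
#' @export
inter_optode_distances <- function(ps, channels, pooling = "flat") {
  stopifnot(inherits(ps, "probe_set"), inherits(channels, "channel_table"))
  labels <- union(channels$source, channels$detector)
  missing <- setdiff(labels, ps$points$label)
  if (length(missing) > 0) {
    bad <- channels$source %in% missing | channels$detector %in% missing
    stop("channel labels missing from probe set: ",
         paste(missing, collapse = ", "), " (channels ",
         paste(paste0(channels$source[bad], "-", channels$detector[bad]),
               collapse = ", "), ")", call. = FALSE)
  }
  cs <- probe_coords(ps, channels$source)
  cd <- probe_coords(ps, channels$detector)
  d <- data.frame(label = paste0(channels$source, "-", channels$detector),
                  group = ps$subject_id,
                  distance = sqrt(rowSums((cs - cd)^2)),
                  stringsAsFactors = FALSE)
  metric_report("inter_optode", "none", d, pooling = pooling)
}

#' Welch two-sample comparison of distance collections
#'
#' Two-sided Welch (unequal-variance) t-test between the flat distance
#' collections of two analyses, e.g. standard-cap variability versus
#' landmark-based accuracy.
#'
#' @param a,b numeric distance vectors (mm) or [metric_report()] objects.
#' @return list with `statistic`, `p_value`, `df`, `n_a`, `n_b`,
#'   `test_name = "welch_t"`.
#' @export
compare_distances <- function(a, b) {
  if (inherits(a, "metric_report")) a <- report_distances(a)
  if (inherits(b, "metric_report")) b <- report_distances(b)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each distance collection needs >= 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate constant samples: Welch statistic is 0/0 or +-Inf
    delta <- mean(a) - mean(b)
    return(list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
                p_value = if (delta == 0) 1 else 0,
                df = NA_real_, n_a = length(a), n_b = length(b),
                test_name = "welch_t"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(tt$statistic),
       p_value = unname(tt$p.value),
       df = unname(tt$parameter),
       n_a = length(a), n_b = length(b),
       test_name = "welch_t")
}
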