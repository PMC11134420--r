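# Control-point alignment of a probe set onto a reference (another probe
# set or the template montage). Correspondences are always known by label;
# no iterative closest point is used anywhere.

reference_points <- function(reference) {
  if (inherits(reference, "montage")) {
    list(fiducials = reference$fiducials,
         optodes = reference$entries,
         space = "mni")
  } else if (inherits(reference, "probe_set")) {
    parts <- split_fiducials(reference)
    list(fiducials = parts$fiducials,
         optodes = parts$optodes,
         space = reference$space)
  } else {
    stop("reference must be a probe_set or montage", call. = FALSE)
  }
}

#' Align a probe set onto a reference by control-point mapping
#'
#' Two alignment strategies are supported. *Landmark-based* fits the rigid
#' transform on exactly the three anatomical fiducial pairs
#' (Nasion/LPA/RPA), anchoring the probes to the anatomy; this mirrors
#' realistic experimental use. *Landmark-free* excludes the fiducials and
#' fits on all shared probe labels, isolating device and labeling error from
#' fiducial-placement error. In both cases the fitted transform is applied
#' to every point of the set and the result is retagged to the reference's
#' space.
#'
#' @param ps the [probe_set()] to align.
#' @param reference a [probe_set()] or [montage()] providing target
#'   positions.
#' @param mode `"landmark_based"` or `"landmark_free"`.
#' @param allow_scaling permit a uniform scale in the fit (default `FALSE`:
#'   strictly rigid).
#' @return list with elements `probe_set` (aligned) and `transform` (the
#'   fitted [rigid_transform()], carrying the RMS residual of the
#'   control points, see [fit_residual()]).
#' @export
align <- function(ps, reference,
                  mode = c("landmark_based", "landmark_free"),
                  allow_scaling = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ps, "probe_set"))
  ref <- reference_points(reference)
  parts <- split_fiducials(ps)
  if (mode == "landmark_based") {
    have <- intersect(FIDUCIAL_LABELS, parts$fiducials$label)
    have_ref <- intersect(FIDUCIAL_LABELS, ref$fiducials$label)
    missing <- setdiff(FIDUCIAL_LABELS, intersect(have, have_ref))
    if (length(missing) > 0) {
      stop("landmark_based alignment requires all three fiducials in both ",
           "sets; missing: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    src <- as.matrix(parts$fiducials[match(FIDUCIAL_LABELS,
                                           parts$fiducials$label),
                                     c("x", "y", "z")])
    tgt <- as.matrix(ref$fiducials[match(FIDUCIAL_LABELS,
                                         ref$fiducials$label),
                                   c("x", "y", "z")])
  } else {
    shared <- intersect(parts$optodes$label, ref$optodes$label)
    if (length(shared) < 3) {
      stop("landmark_free alignment requires >= 3 shared non-fiducial ",
           "labels; found ", length(shared), call. = FALSE)
    }
    unmatched <- setdiff(parts$optodes$label, shared)
    if (length(unmatched) > 0) {
      warning("labels without a reference match dropped from the fit: ",
              paste(unmatched, collapse = ", "), call. = FALSE)
    }
    # keep the probe set's own ordering of the shared labels
    shared <- parts$optodes$label[parts$optodes$label %in% shared]
    src <- as.matrix(parts$optodes[match(shared, parts$optodes$label),
                                   c("x", "y", "z")])
    tgt <- as.matrix(ref$optodes[match(shared, ref$optodes$label),
                                 c("x", "y", "z")])
  }
  transform <- fit_rigid(src, tgt, allow_scaling = allow_scaling)
  aligned <- apply_transform(transform, ps, new_space = ref$space)
  list(probe_set = aligned, transform = transform)
}
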