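#' @keywords internal
"_PACKAGE"

# Canonical anatomical landmark names. All file readers map case-insensitive
# variants onto these; every other label is free-form.
FIDUCIAL_LABELS <- c("Nasion", "LPA", "RPA")

VALID_SPACES <- c("scanner", "mri", "head", "mni")
VALID_MODALITIES <- c("mri", "ir3d")

#' Normalize fiducial label spellings
#'
#' Maps case-insensitive variants of the three anatomical landmark names onto
#' the canonical spellings `"Nasion"`, `"LPA"`, `"RPA"`. Any other label is
#' returned unchanged. The mapping is idempotent.
#'
#' @param labels character vector of point labels.
#' @return character vector with fiducial labels normalized.
#' @export
#' @examples
#' normalize_fiducial_labels(c("nasion", "lpa", "RPA", "S1"))
normalize_fiducial_labels <- function(labels) {
  stopifnot(is.character(labels))
  idx <- match(tolower(labels), tolower(FIDUCIAL_LABELS))
  out <- labels
  out[!is.na(idx)] <- FIDUCIAL_LABELS[idx[!is.na(idx)]]
  out
}

#' Test whether labels are anatomical fiducials
#'
#' @param labels character vector (canonical or variant spellings).
#' @return logical vector.
#' @export
is_fiducial <- function(labels) {
  normalize_fiducial_labels(labels) %in% FIDUCIAL_LABELS
}

#' Construct a labeled probe-point collection
#'
#' A `probe_set` holds one subject/modality/scan's labeled 3D points
#' (optodes plus, optionally, the three anatomical fiducials) in a declared
#' coordinate space. Coordinates are millimeters throughout.
#'
#' @param points data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param space coordinate space, one of `"scanner"`, `"mri"`, `"head"`,
#'   `"mni"`.
#' @param subject_id subject identifier string.
#' @param modality `"mri"` or `"ir3d"`.
#' @param scan_index non-negative integer; 0 for the MRI reference set,
#'   1..k for repeat scans.
#' @return an object of class `probe_set`.
#' @export
#' @examples
#' ps <- probe_set(data.frame(label = c("S1", "D1"),
#'                            x = c(0, 30), y = c(0, 0), z = c(100, 100)),
#'                 space = "scanner")
#' ps
probe_set <- function(points, space, subject_id = "subject",
                      modality = c("ir3d", "mri"), scan_index = 0L) {
  modality <- match.arg(modality)
  space <- match.arg(space, VALID_SPACES)
  stopifnot(is.data.frame(points))
  required <- c("label", "x", "y", "z")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    stop("probe_set points must have columns label, x, y, z; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- points[, required, drop = FALSE]
  points$label <- normalize_fiducial_labels(as.character(points$label))
  for (col in c("x", "y", "z")) points[[col]] <- as.numeric(points[[col]])
  validate_points(points)
  if (scan_index < 0) stop("scan_index must be non-negative", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         modality = modality,
         scan_index = as.integer(scan_index),
         space = space,
         points = points),
    class = "probe_set")
}

validate_points <- function(points) {
  if (any(!nzchar(points$label))) {
    stop("point labels must be non-empty", call. = FALSE)
  }
  dup <- unique(points$label[duplicated(points$label)])
  if (length(dup) > 0) {
    stop("duplicate point labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(points[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  fids <- points$label[is_fiducial(points$label)]
  if (length(fids) > 0 && !all(fids %in% FIDUCIAL_LABELS)) {
    stop("fiducial labels must normalize to Nasion/LPA/RPA", call. = FALSE)
  }
  invisible(points)
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> subject=%s modality=%s scan=%d space=%s\n",
              x$subject_id, x$modality, x$scan_index, x$space))
  cat(sprintf("  %d points (%d fiducials)\n",
              nrow(x$points), sum(is_fiducial(x$points$label))))
  invisible(x)
}

#' Coordinate matrix of a probe set
#'
#' @param ps a `probe_set`.
#' @param labels optional character vector selecting (and ordering) points.
#' @return numeric matrix, one row per point, columns x/y/z (mm), row names
#'   set to labels.
#' @export
probe_coords <- function(ps, labels = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  pts <- ps$points
  if (!is.null(labels)) {
    idx <- match(labels, pts$label)
    if (anyNA(idx)) {
      stop("labels not present in probe_set: ",
           paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    pts <- pts[idx, , drop = FALSE]
  }
  m <- as.matrix(pts[, c("x", "y", "z")])
  rownames(m) <- pts$label
  m
}

#' Split a probe set into fiducials and probe points
#'
#' @param ps a `probe_set`.
#' @return list with data frames `fiducials` and `optodes`.
#' @export
split_fiducials <- function(ps) {
  stopifnot(inherits(ps, "probe_set"))
  fid <- is_fiducial(ps$points$label)
  list(fiducials = ps$points[fid, , drop = FALSE],
       optodes = ps$points[!fid, , drop = FALSE])
}

#' Fiducial positions of a probe set or montage
#'
#' @param x a `probe_set` or `montage`.
#' @return 3x3 numeric matrix with rows Nasion, LPA, RPA; rows of missing
#'   fiducials are dropped.
#' @export
fiducial_coords <- function(x) {
  if (inherits(x, "montage")) {
    m <- as.matrix(x$fiducials[, c("x", "y", "z")])
    rownames(m) <- x$fiducials$label
  } else {
    pts <- split_fiducials(x)$fiducials
    m <- as.matrix(pts[, c("x", "y", "z")])
    rownames(m) <- pts$label
  }
  m[rownames(m)[order(match(rownames(m), FIDUCIAL_LABELS))], , drop = FALSE]
}

#' Construct a source-detector channel table
#'
#' @param source character vector of source labels.
#' @param detector character vector of detector labels, same length.
#' @return object of class `channel_table` (a data frame with columns
#'   `source`, `detector`).
#' @export
channel_table <- function(source, detector) {
  stopifnot(length(source) == length(detector))
  df <- data.frame(source = as.character(source),
                   detector = as.character(detector),
                   stringsAsFactors = FALSE)
  key <- paste(df$source, df$detector, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate channel pairs in channel table", call. = FALSE)
  }
  class(df) <- c("channel_table", "data.frame")
  df
}
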