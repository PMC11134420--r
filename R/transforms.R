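# Rigid (optionally uniformly scaled) transforms and their closed-form
# least-squares estimation from corresponded point pairs.

#' Construct a rigid transform
#'
#' Represents the map p -> scale * R p + translation. The rotation must be
#' proper (orthonormal, det +1); reflections are never represented.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @param scale positive scalar; 1 for a strictly rigid motion.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3, length(scale) == 1)
  if (!is.finite(scale) || scale <= 0) {
    stop("scale must be a positive finite scalar", call. = FALSE)
  }
  orth_err <- max(abs(crossprod(rotation) - diag(3)))
  if (orth_err > 1e-9) {
    stop("rotation is not orthonormal (max deviation ",
         format(orth_err), ")", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det +1); got det = ",
         format(det(rotation)), call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle=%.4f rad, |t|=%.3f mm, scale=%.6f\n",
              rotation_angle(x$rotation), sqrt(sum(x$translation^2)),
              x$scale))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Apply a transform to a coordinate matrix
#'
#' @param transform a [rigid_transform()].
#' @param coords n x 3 numeric matrix (rows are points, mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_coords <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = dimnames(coords))
  out <- transform$scale * coords %*% t(transform$rotation)
  sweep(out, 2, transform$translation, "+")
}

#' Apply a transform to a probe set
#'
#' Maps every position, preserving labels and order, and retags the
#' coordinate space.
#'
#' @param transform a [rigid_transform()].
#' @param ps a [probe_set()].
#' @param new_space coordinate space of the result.
#' @return a transformed [probe_set()].
#' @export
apply_transform <- function(transform, ps, new_space = ps$space) {
  stopifnot(inherits(ps, "probe_set"))
  new_space <- match.arg(new_space, VALID_SPACES)
  xyz <- transform_coords(transform, probe_coords(ps))
  out <- ps
  out$points$x <- xyz[, 1]
  out$points$y <- xyz[, 2]
  out$points$z <- xyz[, 3]
  out$space <- new_space
  out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
transform_invert <- function(transform) {
  Rinv <- t(transform$rotation)
  s <- 1 / transform$scale
  rigid_transform(Rinv, -s * as.numeric(Rinv %*% transform$translation), s)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
transform_compose <- function(a, b) {
  rigid_transform(
    a$rotation %*% b$rotation,
    as.numeric(a$scale * a$rotation %*% b$translation) + a$translation,
    a$scale * b$scale)
}

#' Least-squares rigid fit between corresponded point sets
#'
#' Closed-form orthogonal-Procrustes (Kabsch) solution: the rotation comes
#' from the SVD of the cross-covariance of the centered point sets, with the
#' reflection corrected to a proper rotation by negating the last singular
#' direction when needed; the translation matches the centroids. With
#' `allow_scaling` the least-squares uniform scale (Umeyama) is estimated,
#' otherwise scale is exactly 1.
#'
#' @param source n x 3 matrix of source positions (mm), n >= 3.
#' @param target n x 3 matrix of target positions, paired by row.
#' @param allow_scaling estimate a uniform scale factor (default `FALSE`).
#' @return a [rigid_transform()] with attribute-free fields plus the RMS
#'   residual accessible via [fit_residual()].
#' @export
#' @examples
#' src <- matrix(rnorm(12), 4, 3)
#' fit_rigid(src, src)  # identity
fit_rigid <- function(source, target, allow_scaling = FALSE) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (!identical(dim(source), dim(target))) {
    stop("source and target must have identical dimensions", call. = FALSE)
  }
  if (ncol(source) != 3) stop("point sets must be n x 3", call. = FALSE)
  n <- nrow(source)
  if (n < 3) stop("at least 3 point pairs are required, got ", n,
                  call. = FALSE)
  if (any(!is.finite(source)) || any(!is.finite(target))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  cs <- colMeans(source)
  ct <- colMeans(target)
  X <- sweep(source, 2, cs)
  Y <- sweep(target, 2, ct)
  varX <- sum(X^2)
  if (varX < 1e-18) {
    stop("degenerate geometry: all source points coincide", call. = FALSE)
  }
  H <- crossprod(X, Y)  # 3x3 cross-covariance (times n)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allow_scaling) sum(sv$d * c(1, 1, d)) / varX else 1
  tr <- ct - s * as.numeric(R %*% cs)
  out <- rigid_transform(R, tr, s)
  fitted <- transform_coords(out, source)
  attr(out, "rms_residual") <- sqrt(sum((fitted - target)^2) / n)
  out
}

#' RMS residual of a fitted transform
#'
#' @param transform result of [fit_rigid()] (or [align()]).
#' @return root-mean-square point residual in mm, or `NA` if the transform
#'   was not produced by a fit.
#' @export
fit_residual <- function(transform) {
  r <- attr(transform, "rms_residual")
  if (is.null(r)) NA_real_ else r
}

#' Anatomical head frame from the three fiducials
#'
#' Builds the transform into the standard fiducial-based head coordinate
#' frame: origin at the LPA-RPA midpoint, +X from LPA toward RPA, +Y from
#' the origin toward the nasion (orthogonalized against X), +Z = X x Y
#' (superior). Applying the returned transform maps the input coordinates
#' into this frame.
#'
#' @param nasion,lpa,rpa length-3 fiducial positions (mm).
#' @return a [rigid_transform()].
#' @export
#' @examples
#' t <- build_head_frame(c(0, 100, 0), c(-70, 0, 0), c(70, 0, 0))
#' t$rotation  # identity: inputs already in the head frame
build_head_frame <- function(nasion, lpa, rpa) {
  nasion <- as.numeric(nasion); lpa <- as.numeric(lpa); rpa <- as.numeric(rpa)
  stopifnot(length(nasion) == 3, length(lpa) == 3, length(rpa) == 3)
  origin <- (lpa + rpa) / 2
  xraw <- rpa - lpa
  if (vnorm(xraw) < 1e-9) {
    stop("degenerate geometry: LPA and RPA coincide", call. = FALSE)
  }
  x <- unit(xraw)
  yraw <- nasion - origin
  y <- yraw - sum(yraw * x) * x
  if (vnorm(y) < 1e-9) {
    stop("degenerate geometry: fiducials are collinear", call. = FALSE)
  }
  y <- unit(y)
  z <- cross3(x, y)
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% origin), 1)
}

#' Export a transform as a homogeneous-matrix JSON document
#'
#' Writes the 4x4 homogeneous matrix (row-major, mm) together with the
#' rotation/translation/scale decomposition, matching common neuroimaging
#' transform-exchange conventions.
#'
#' @param transform a [rigid_transform()].
#' @param file optional path; when `NULL` the JSON text is returned.
#' @return JSON text, invisibly when written to `file`.
#' @export
transform_to_json <- function(transform, file = NULL) {
  stopifnot(inherits(transform, "rigid_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- transform$scale * transform$rotation
  M[1:3, 4] <- transform$translation
  payload <- list(
    matrix = lapply(seq_len(4), function(i) M[i, ]),
    rotation = lapply(seq_len(3), function(i) transform$rotation[i, ]),
    translation = transform$translation,
    scale = transform$scale,
    units = "mm",
    convention = "row_major_homogeneous")
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a transform from its JSON export
#'
#' @param file path or JSON text produced by [transform_to_json()].
#' @return a [rigid_transform()].
#' @export
transform_from_json <- function(file) {
  doc <- jsonlite::fromJSON(file)
  rigid_transform(doc$rotation, doc$translation, doc$scale)
}
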