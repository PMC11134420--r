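# Head-mesh defacing: reorientation to a nasion-on-X convention, plane
# split, and face-region removal that preserves the three anatomical
# landmark regions. Geometry-only OBJ IO (vertices, optional per-vertex
# color, triangular faces); texture files are carried alongside untouched.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param colors optional n x 3 matrix of per-vertex RGB in `[0, 1]`.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(!is.finite(vertices))) stop("vertices must be finite",
                                      call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (!is.null(colors)) {
    colors <- matrix(as.numeric(colors), ncol = 3)
    stopifnot(nrow(colors) == nrow(vertices))
  }
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", per-vertex color"))
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Reads vertex positions (with optional per-vertex color extensions on the
#' `v` lines) and faces; texture/normal indices on face fields are ignored
#' and polygons are fan-triangulated. Material and texture statements are
#' skipped.
#'
#' @param file path to an `.obj` file.
#' @return a [tri_mesh()].
#' @export
read_obj <- function(file) {
  lines <- readLines(file, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  verts <- list(); cols <- list(); faces <- list()
  for (tk in toks) {
    if (length(tk) == 0) next
    if (tk[1] == "v") {
      if (length(tk) < 4) stop("malformed vertex line in OBJ",
                               call. = FALSE)
      v <- as.numeric(tk[2:4])
      if (anyNA(v)) stop("non-numeric vertex coordinate in OBJ",
                         call. = FALSE)
      verts[[length(verts) + 1]] <- v
      cols[[length(cols) + 1]] <-
        if (length(tk) >= 7) as.numeric(tk[5:7]) else rep(NA_real_, 3)
    } else if (tk[1] == "f") {
      idx <- as.integer(vapply(tk[-1],
                               function(f) strsplit(f, "/", fixed = TRUE)[[1]][1],
                               character(1)))
      if (anyNA(idx) || length(idx) < 3) {
        stop("malformed face line in OBJ", call. = FALSE)
      }
      for (k in seq.int(2, length(idx) - 1)) {
        faces[[length(faces) + 1]] <- c(idx[1], idx[k], idx[k + 1])
      }
    }
  }
  if (length(verts) == 0) stop("OBJ contains no vertices", call. = FALSE)
  V <- do.call(rbind, verts)
  C <- do.call(rbind, cols)
  if (all(is.na(C))) C <- NULL
  F <- if (length(faces) > 0) do.call(rbind, faces) else
    matrix(integer(0), 0, 3)
  tri_mesh(V, F, C)
}

#' Write a Wavefront OBJ mesh
#'
#' @param mesh a [tri_mesh()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_obj <- function(mesh, file) {
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- mesh$vertices
  vlines <- if (is.null(mesh$colors)) {
    sprintf("v %.9f %.9f %.9f", V[, 1], V[, 2], V[, 3])
  } else {
    C <- mesh$colors
    sprintf("v %.9f %.9f %.9f %.6f %.6f %.6f",
            V[, 1], V[, 2], V[, 3], C[, 1], C[, 2], C[, 3])
  }
  flines <- if (nrow(mesh$faces) > 0) {
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
            mesh$faces[, 3])
  } else character(0)
  writeLines(c("# probereg mesh export", vlines, flines), file)
  invisible(file)
}

prune_orphans <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[mesh$faces], ncol = 3),
           if (is.null(mesh$colors)) NULL else
             mesh$colors[used, , drop = FALSE])
}

#' Rotate a mesh so the nasion lies on the +X axis
#'
#' Rotates about the +Z (vertical) axis so that the nasion's image has
#' y = 0 and x > 0; the first step of the defacing procedure. Returns the
#' rotated mesh together with the applied transform so labeled points can
#' be moved losslessly between the original and reoriented frames.
#'
#' @param mesh a [tri_mesh()].
#' @param nasion length-3 nasion position in the mesh's coordinates.
#' @return list with `mesh` and `transform` (a [rigid_transform()]).
#' @export
orient_to_nasion <- function(mesh, nasion) {
  stopifnot(inherits(mesh, "tri_mesh"), length(nasion) == 3)
  nasion <- as.numeric(nasion)
  if (sqrt(nasion[1]^2 + nasion[2]^2) < 1e-9) {
    stop("degenerate geometry: nasion lies on the Z-axis", call. = FALSE)
  }
  ang <- -atan2(nasion[2], nasion[1])
  Rz <- matrix(c(cos(ang), sin(ang), 0,
                 -sin(ang), cos(ang), 0,
                 0, 0, 1), 3, 3)
  transform <- rigid_transform(Rz, c(0, 0, 0), 1)
  out <- mesh
  out$vertices <- transform_coords(transform, mesh$vertices)
  list(mesh = out, transform = transform)
}

#' Remove the part of a mesh below a horizontal plane
#'
#' Deletes every face whose three vertices lie strictly below `plane_z`;
#' faces straddling the plane are kept intact (no re-triangulation).
#' Orphaned vertices are pruned and face indices remapped.
#'
#' @param mesh a [tri_mesh()].
#' @param plane_z cutting-plane height (mm).
#' @return the cut [tri_mesh()]; with a warning, the input unchanged when
#'   the plane lies below the whole mesh, or an empty mesh when above it.
#' @export
split_below_plane <- function(mesh, plane_z) {
  stopifnot(inherits(mesh, "tri_mesh"), is.finite(plane_z))
  z <- mesh$vertices[, 3]
  if (plane_z <= min(z)) {
    warning("cutting plane below the whole mesh; nothing removed",
            call. = FALSE)
    return(mesh)
  }
  if (plane_z > max(z)) {
    warning("cutting plane above the whole mesh; all faces removed",
            call. = FALSE)
  }
  below <- z < plane_z
  drop <- below[mesh$faces[, 1]] & below[mesh$faces[, 2]] &
    below[mesh$faces[, 3]]
  out <- mesh
  out$faces <- mesh$faces[!drop, , drop = FALSE]
  prune_orphans(out)
}

#' Remove a cylindrical face region while protecting landmarks
#'
#' Deletes every face having any vertex inside the finite cylinder defined
#' by an axis point, unit direction, radius and length -- except faces with
#' a vertex within `keep_radius` of any protected point (the anatomical
#' fiducials), which are retained. This face-region deletion replaces a
#' boolean mesh subtraction: downstream labeling needs landmark visibility,
#' not watertightness.
#'
#' @param mesh a [tri_mesh()].
#' @param axis_point point on the cylinder axis (mm).
#' @param axis_dir axis direction (normalized internally).
#' @param radius,length cylinder radius and length, mm (> 0).
#' @param keep_points optional k x 3 matrix (or length-3 vector) of
#'   protected positions.
#' @param keep_radius protection radius around each keep point, mm.
#' @return the edited [tri_mesh()].
#' @export
remove_cylinder <- function(mesh, axis_point, axis_dir, radius, length,
                            keep_points = NULL, keep_radius = 15) {
  stopifnot(inherits(mesh, "tri_mesh"),
            radius > 0, length > 0, keep_radius > 0)
  axis_point <- as.numeric(axis_point)
  axis_dir <- unit(as.numeric(axis_dir))
  V <- mesh$vertices
  d <- sweep(V, 2, axis_point)
  h <- as.numeric(d %*% axis_dir)
  radial2 <- rowSums(d^2) - h^2
  inside <- h >= 0 & h <= length & radial2 <= radius^2
  protected <- rep(FALSE, nrow(V))
  if (!is.null(keep_points)) {
    K <- matrix(as.numeric(keep_points), ncol = 3)
    for (i in seq_len(nrow(K))) {
      protected <- protected |
        rowSums(sweep(V, 2, K[i, ])^2) <= keep_radius^2
    }
  }
  f <- mesh$faces
  face_inside <- inside[f[, 1]] | inside[f[, 2]] | inside[f[, 3]]
  face_protected <- protected[f[, 1]] | protected[f[, 2]] |
    protected[f[, 3]]
  keep <- !face_inside | face_protected
  if (!any(keep)) {
    stop("cylinder removal would delete the whole mesh; ",
         "use a smaller cylinder or protect landmark regions",
         call. = FALSE)
  }
  out <- mesh
  out$faces <- f[keep, , drop = FALSE]
  prune_orphans(out)
}

#' Triangulated ellipsoid head-surface mesh
#'
#' Latitude/longitude triangulation of a [make_head()] model; used to
#' exercise and demonstrate the defacing operations without external mesh
#' data.
#'
#' @param head a [make_head()] model.
#' @param n_lat,n_lon tessellation resolution.
#' @param z_min lowest height fraction of the vertical semi-axis to mesh
#'   (default -0.6, i.e. the surface continues below the ear plane).
#' @return a [tri_mesh()].
#' @export
ellipsoid_mesh <- function(head, n_lat = 24, n_lon = 48, z_min = -0.6) {
  stopifnot(inherits(head, "head_model"), n_lat >= 3, n_lon >= 3)
  ax <- head$semi_axes
  f <- seq(z_min, 0.999, length.out = n_lat)
  th <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(th = th, f = f)
  s <- sqrt(pmax(0, 1 - grid$f^2))
  V <- cbind(ax[1] * s * sin(grid$th),
             ax[2] * s * cos(grid$th),
             ax[3] * grid$f)
  idx <- function(i, j) (j - 1) * n_lon + ((i - 1) %% n_lon) + 1
  faces <- list()
  for (j in seq_len(n_lat - 1)) {
    for (i in seq_len(n_lon)) {
      faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j),
                                      idx(i, j + 1))
      faces[[length(faces) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1),
                                      idx(i, j + 1))
    }
  }
  tri_mesh(V, do.call(rbind, faces))
}
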