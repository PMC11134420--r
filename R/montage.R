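# Template montage handling.
#
# The bundled "standard_1005" table is a synthetic, idealized spherical
# realization of the 10-05 positioning system: positions are constructed by
# proportional subdivision of arcs on a 90 mm sphere (head circumference
# ~56.5 cm), in RAS axes (+x right, +y anterior, +z superior), millimeters.
# It carries the full-density 10-05 midline and central coronal chains plus
# the 10-10-density circumferential ring and interior rows, and idealizes
# the anatomical fiducials at Nz / T9 / T10. It is a geometric template for
# control-point alignment, not a measured electrode atlas.

#' Construct a montage object
#'
#' @param entries data frame `label,x,y,z` of template positions (mm),
#'   fiducial rows included or supplied separately.
#' @param name montage identifier.
#' @return object of class `montage` with `entries` (non-fiducial positions)
#'   and `fiducials` (Nasion/LPA/RPA rows).
#' @export
montage <- function(entries, name = "montage") {
  stopifnot(is.data.frame(entries),
            all(c("label", "x", "y", "z") %in% names(entries)))
  entries <- entries[, c("label", "x", "y", "z")]
  entries$label <- as.character(entries$label)
  xyz <- as.matrix(entries[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("montage positions must be finite",
                                 call. = FALSE)
  fid_rows <- is_fiducial(entries$label)
  fiducials <- entries[fid_rows, , drop = FALSE]
  fiducials$label <- normalize_fiducial_labels(fiducials$label)
  missing <- setdiff(FIDUCIAL_LABELS, fiducials$label)
  if (length(missing) > 0) {
    stop("montage must contain the fiducials ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name,
                 entries = entries[!fid_rows, , drop = FALSE],
                 fiducials = fiducials),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %s: %d positions + %d fiducials (MNI mm)\n",
              x$name, nrow(x$entries), nrow(x$fiducials)))
  invisible(x)
}

#' Load a bundled template montage
#'
#' @param name montage identifier; currently `"standard_1005"`, the
#'   idealized spherical 10-05 template bundled with the package (see
#'   [spherical_1005_montage()]).
#' @return a [montage()].
#' @export
#' @examples
#' m <- load_montage("standard_1005")
#' "Cz" %in% m$entries$label
load_montage <- function(name) {
  available <- c(standard_1005 = "standard_1005_synthetic.csv")
  if (!name %in% names(available)) {
    stop("unknown montage '", name, "'; available: ",
         paste(names(available), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", available[[name]], package = "probereg",
                      mustWork = TRUE)
  entries <- utils::read.csv(path, stringsAsFactors = FALSE)
  montage(entries, name = name)
}

# --- idealized spherical 10-05 construction ---------------------------------

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Points along the circle through A, B, C, at fractions of the arc from A
# to C that passes through B. This is the classic proportional-distance
# construction used to define 10-20-family positions along head contours.
arc_points <- function(A, B, C, fracs) {
  a <- A - C
  b <- B - C
  axb <- cross3(a, b)
  den <- 2 * sum(axb^2)
  if (den < 1e-12) stop("arc_points: collinear anchors", call. = FALSE)
  O <- C + cross3(sum(a^2) * b - sum(b^2) * a, axb) / den
  r <- vnorm(A - O)
  u <- unit(A - O)
  n <- unit(cross3(A - O, B - O))
  w <- cross3(n, u)
  ang <- function(P) {
    th <- atan2(sum((P - O) * w), sum((P - O) * u))
    if (th < 0) th <- th + 2 * pi
    th
  }
  thB <- ang(B)
  thC <- ang(C)
  if (thB > thC) {  # wrong orientation: flip the traversal direction
    w <- -w
    thB <- ang(B)
    thC <- ang(C)
  }
  t(vapply(fracs, function(f) O + r * (cos(f * thC) * u + sin(f * thC) * w),
           numeric(3)))
}

#' Idealized spherical 10-05 montage
#'
#' Constructs template positions on a sphere by proportional subdivision of
#' arcs: the full 10-05 midline (Nz..Iz) and central coronal (T9..T10)
#' chains at 5% steps, the circumferential ring through Fpz/T7/Oz/T8 at
#' 10-10 density, and the interior AF/F/FC/CP/P/PO rows. Fiducials are
#' idealized at Nz (Nasion), T9 (LPA) and T10 (RPA). This synthetic template
#' stands in for measured 10-05 electrode atlases; distances are millimeters
#' and axes RAS, matching MNI conventions.
#'
#' @param radius sphere radius in mm (default 90, i.e. ~56.5 cm
#'   circumference).
#' @return a [montage()].
#' @export
spherical_1005_montage <- function(radius = 90) {
  stopifnot(radius > 0)
  R <- radius
  Nz <- c(0, R, 0); Iz <- c(0, -R, 0)
  T9 <- c(-R, 0, 0); T10 <- c(R, 0, 0)
  Cz <- c(0, 0, R)

  rows <- list()
  add <- function(labels, coords) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = labels, x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }

  midline <- c("Nz", "NFpz", "Fpz", "AFpz", "AFz", "AFFz", "Fz", "FFCz",
               "FCz", "FCCz", "Cz", "CCPz", "CPz", "CPPz", "Pz", "PPOz",
               "POz", "POOz", "Oz", "OIz", "Iz")
  add(midline, arc_points(Nz, Cz, Iz, seq(0, 1, by = 0.05)))

  coronal <- c("T9", "T9h", "T7", "T7h", "C5", "C5h", "C3", "C3h", "C1",
               "C1h", "Cz", "C2h", "C2", "C4h", "C4", "C6h", "C6", "T8h",
               "T8", "T10h", "T10")
  add(coronal, arc_points(T9, Cz, T10, seq(0, 1, by = 0.05)))

  named <- function(lbl) {
    df <- do.call(rbind, rows)
    as.numeric(df[match(lbl, df$label), c("x", "y", "z")])
  }
  Fpz <- named("Fpz"); Ozp <- named("Oz")
  T7 <- named("T7"); T8 <- named("T8")

  ring_left <- c("Fpz", "Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7",
                 "O1", "Oz")
  add(ring_left, arc_points(Fpz, T7, Ozp, seq(0, 1, by = 0.1)))
  ring_right <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8",
                  "O2", "Oz")
  add(ring_right, arc_points(Fpz, T8, Ozp, seq(0, 1, by = 0.1)))

  row_specs <- list(
    list(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), "Fz"),
    list(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         "FCz"),
    list(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
         "CPz"),
    list(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), "Pz"),
    list(c("AF7", "AF3", "AFz", "AF4", "AF8"), "AFz"),
    list(c("PO7", "PO3", "POz", "PO4", "PO8"), "POz"))
  for (spec in row_specs) {
    labels <- spec[[1]]
    left <- named(labels[1]); right <- named(labels[length(labels)])
    mid <- named(spec[[2]])
    add(labels, arc_points(left, mid, right,
                           seq(0, 1, length.out = length(labels))))
  }

  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$label), , drop = FALSE]
  fid <- data.frame(label = c("Nasion", "LPA", "RPA"),
                    x = c(Nz[1], T9[1], T10[1]),
                    y = c(Nz[2], T9[2], T10[2]),
                    z = c(Nz[3], T9[3], T10[3]),
                    stringsAsFactors = FALSE)
  montage(rbind(df, fid), name = "standard_1005")
}

#' Write a montage as CSV
#'
#' @param m a [montage()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_montage_csv <- function(m, file) {
  stopifnot(inherits(m, "montage"))
  df <- rbind(m$entries, m$fiducials)
  txt <- paste0("label,x,y,z\n",
                paste(sprintf("%s,%.9f,%.9f,%.9f", df$label, df$x, df$y,
                              df$z), collapse = "\n"),
                "\n")
  writeLines(txt, file, sep = "")
  invisible(file)
}
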