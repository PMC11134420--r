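# MeshLab PickPoints (.pp) XML IO.
#
# Dialect notes: MeshLab writes a <!DOCTYPE PickedPoints> document with a
# <PickedPoints> root holding an optional <DocumentData> block and one
# <point .../> element per marker, carrying x/y/z/name attributes and an
# "active" flag. Both self-closing and paired <point></point> elements are
# accepted; DocumentData is ignored. Coordinates are millimeters.

#' Parse a MeshLab PickPoints (.pp) document
#'
#' Reads labeled marker positions from the XML dialect MeshLab's PickPoints
#' tool saves. Points flagged `active="0"` are excluded; fiducial labels are
#' normalized case-insensitively to `Nasion`/`LPA`/`RPA`.
#'
#' @param file path to a `.pp` file, or a length-1 character string of XML.
#' @param space coordinate space tag for the resulting set (default
#'   `"scanner"`).
#' @param subject_id,modality,scan_index metadata passed to [probe_set()].
#' @return a [probe_set()].
#' @export
#' @examples
#' xml <- paste0('<!DOCTYPE PickedPoints><PickedPoints>',
#'               '<point x="10" y="-5" z="3.5" name="D1" active="1"/>',
#'               '</PickedPoints>')
#' parse_pp(xml)
parse_pp <- function(file, space = "scanner", subject_id = "subject",
                     modality = "ir3d", scan_index = 0L) {
  doc <- tryCatch(
    xml2::read_xml(file),
    error = function(e) {
      stop("malformed PickPoints XML: ", conditionMessage(e), call. = FALSE)
    })
  root <- xml2::xml_name(doc)
  if (!identical(root, "PickedPoints")) {
    stop("expected a <PickedPoints> root element, found <", root, ">",
         call. = FALSE)
  }
  nodes <- xml2::xml_find_all(doc, ".//point")
  if (length(nodes) == 0) {
    stop("PickPoints document contains no <point> elements", call. = FALSE)
  }
  active <- xml2::xml_attr(nodes, "active")
  keep <- is.na(active) | active != "0"
  nodes <- nodes[keep]
  if (length(nodes) == 0) {
    stop("all points in PickPoints document are inactive", call. = FALSE)
  }
  get_coord <- function(attr) {
    raw <- xml2::xml_attr(nodes, attr)
    if (anyNA(raw)) {
      bad <- xml2::xml_attr(nodes, "name")[is.na(raw)]
      stop("point element missing ", attr, " attribute (name: ",
           paste(ifelse(is.na(bad), "<unnamed>", bad), collapse = ", "), ")",
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      stop("non-numeric ", attr, " attribute in point element: ",
           paste(raw[is.na(val)], collapse = ", "), call. = FALSE)
    }
    val
  }
  nm <- xml2::xml_attr(nodes, "name")
  if (anyNA(nm)) stop("point element missing name attribute", call. = FALSE)
  pts <- data.frame(label = nm,
                    x = get_coord("x"),
                    y = get_coord("y"),
                    z = get_coord("z"),
                    stringsAsFactors = FALSE)
  probe_set(pts, space = space, subject_id = subject_id,
            modality = modality, scan_index = scan_index)
}

#' Write a probe set as MeshLab PickPoints XML
#'
#' Emits a PickPoints document readable both by [parse_pp()] and by MeshLab.
#' One `<point>` element per point, in input order, with `active="1"`.
#' Coordinates are printed with 9 decimal places so that a write/parse round
#' trip preserves positions to well below 1e-9 mm.
#'
#' @param ps a [probe_set()]; must contain at least one point.
#' @param file optional path; when `NULL` the XML is returned as a string.
#' @return the XML text, invisibly when written to `file`.
#' @export
write_pp <- function(ps, file = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  if (nrow(ps$points) == 0) {
    stop("cannot write an empty probe_set as PickPoints", call. = FALSE)
  }
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  pts <- ps$points
  lines <- c(
    "<!DOCTYPE PickedPoints>",
    "<PickedPoints>",
    " <DocumentData>",
    sprintf("  <DataFileName name=\"%s\"/>", esc(ps$subject_id)),
    "  <templateName name=\"\"/>",
    " </DocumentData>",
    sprintf(" <point x=\"%.9f\" y=\"%.9f\" z=\"%.9f\" active=\"1\" name=\"%s\"/>",
            pts$x, pts$y, pts$z, esc(pts$label)),
    "</PickedPoints>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}
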