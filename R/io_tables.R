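# Marker CSV and positions TSV IO. All coordinates millimeters, decimal
# point only; comma-delimited with tab accepted.

#' Read a fiducial/marker CSV table
#'
#' Reads `label,x,y,z` tables such as marker positions exported after MRI
#' labeling. The delimiter may be a comma or a tab; coordinates are
#' millimeters with a decimal point.
#'
#' @param file path to the file, or a character string containing the text.
#' @param space coordinate space of the table; required, `"mri"` or
#'   `"scanner"` (also accepts `"head"`/`"mni"` for intermediate products).
#' @param subject_id,modality,scan_index metadata passed to [probe_set()].
#' @return a [probe_set()].
#' @export
#' @examples
#' read_marker_csv("label,x,y,z\nNasion,0,95,10", space = "mri")
read_marker_csv <- function(file, space, subject_id = "subject",
                            modality = if (space == "mri") "mri" else "ir3d",
                            scan_index = 0L) {
  space <- match.arg(space, VALID_SPACES)
  txt <- if (length(file) == 1 && grepl("\n", file)) {
    file
  } else {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty marker table", call. = FALSE)
  split_row <- function(line) {
    sep <- if (grepl("\t", line, fixed = TRUE)) "\t" else ","
    trimws(strsplit(line, sep, fixed = TRUE)[[1]])
  }
  header <- tolower(split_row(lines[1]))
  if (!identical(header[1:4], c("label", "x", "y", "z"))) {
    stop("marker table must start with a 'label,x,y,z' header row",
         call. = FALSE)
  }
  if (length(lines) < 2) stop("marker table has no data rows", call. = FALSE)
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    f <- split_row(lines[i])
    if (length(f) < 4) {
      stop("row ", i, " has fewer than 4 fields: '", lines[i], "'",
           call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(coords)) {
      stop("non-numeric coordinate in row ", i, " (label '", f[1], "'): ",
           paste(f[2:4][is.na(coords)], collapse = ", "), call. = FALSE)
    }
    data.frame(label = f[1], x = coords[1], y = coords[2], z = coords[3],
               stringsAsFactors = FALSE)
  })
  probe_set(do.call(rbind, rows), space = space, subject_id = subject_id,
            modality = modality, scan_index = scan_index)
}

#' Write a marker CSV table
#'
#' Inverse of [read_marker_csv()]: `label,x,y,z` header, 9 decimal places.
#'
#' @param ps a [probe_set()].
#' @param file optional output path; when `NULL` the text is returned.
#' @return the CSV text, invisibly when written to `file`.
#' @export
write_marker_csv <- function(ps, file = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  if (nrow(ps$points) == 0) stop("cannot write an empty probe_set",
                                 call. = FALSE)
  pts <- ps$points
  txt <- paste0(
    "label,x,y,z\n",
    paste(sprintf("%s,%.9f,%.9f,%.9f", pts$label, pts$x, pts$y, pts$z),
          collapse = "\n"),
    "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Write MNI positions as TSV
#'
#' Tab-separated `label\\tx\\ty\\tz` table for hand-off to downstream
#' neuroimaging toolchains. Requires the set to be in MNI space; coordinates
#' are printed with fixed 6-decimal precision in input order, so identical
#' inputs give byte-identical output.
#'
#' @param ps a [probe_set()] in `"mni"` space.
#' @param file optional output path; when `NULL` the text is returned.
#' @return the TSV text, invisibly when written to `file`.
#' @export
write_positions_tsv <- function(ps, file = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  if (!identical(ps$space, "mni")) {
    stop("write_positions_tsv requires a probe_set in 'mni' space, got '",
         ps$space, "'", call. = FALSE)
  }
  pts <- ps$points
  txt <- paste0(
    "label\tx\ty\tz\n",
    paste(sprintf("%s\t%.6f\t%.6f\t%.6f", pts$label, pts$x, pts$y, pts$z),
          collapse = "\n"),
    "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Read a channel table CSV
#'
#' @param file path or text with a `source,detector` header.
#' @return a [channel_table()].
#' @export
read_channel_csv <- function(file) {
  txt <- if (length(file) == 1 && grepl("\n", file)) {
    file
  } else {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  if (!all(c("source", "detector") %in% names(df))) {
    stop("channel table must have 'source,detector' columns", call. = FALSE)
  }
  channel_table(df$source, df$detector)
}

#' Write a channel table CSV
#'
#' @param channels a [channel_table()].
#' @param file optional output path; when `NULL` the text is returned.
#' @return the CSV text, invisibly when written to `file`.
#' @export
write_channel_csv <- function(channels, file = NULL) {
  stopifnot(inherits(channels, "channel_table"))
  txt <- paste0("source,detector\n",
                paste(sprintf("%s,%s", channels$source, channels$detector),
                      collapse = "\n"),
                "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}
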