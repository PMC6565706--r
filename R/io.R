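# Readers/writers for Slicer Markups fiducial files (.fcsv v4 dialect and
# .mrk.json) and the cohort CSV. Canonical internal frame is RAS
# millimetres; LPS inputs are converted at the boundary (negate x and y).

.lps_to_ras <- function(points) { points[, 1:2] <- -points[, 1:2]; points }

# Interpret a Slicer CoordinateSystem token: 0/RAS -> "RAS", 1/LPS -> "LPS".
.coord_system <- function(token, path) {
  token <- toupper(trimws(token))
  if (token %in% c("0", "RAS")) return("RAS")
  if (token %in% c("1", "LPS")) return("LPS")
  stop("unknown coordinate system \"", token, "\" in ", path)
}

#' Read a Slicer Markups fiducial CSV (.fcsv)
#'
#' Parses the v4 `.fcsv` dialect: `#`-prefixed header lines followed by
#' comma-separated rows `id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,...`.
#' The `# CoordinateSystem` header is honoured (`0`/`RAS` or `1`/`LPS`;
#' LPS coordinates are converted to RAS by negating x and y); if absent,
#' RAS is assumed with a warning. Points are matched to P1..P6 by label
#' when all six labels are present, otherwise taken in row order with a
#' warning.
#'
#' @param path file path.
#' @param subject_id,side optional metadata for the returned set.
#' @return a [fiducial_set] in RAS mm.
#' @export
read_slicer_fcsv <- function(path, subject_id = NA_character_, side = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body_idx <- grep("^[^#]", lines)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  cs <- if (length(cs_line)) {
    .coord_system(sub(".*=", "", cs_line[1]), path)
  } else {
    warning("no # CoordinateSystem header in ", path, "; assuming RAS")
    "RAS"
  }
  if (length(body_idx) != 6L)
    stop("fcsv format error in ", path, ": expected 6 fiducial rows, found ",
         length(body_idx))
  pts <- matrix(NA_real_, 6, 3); labels <- character(6)
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(fields) < 4L)
      stop("fcsv format error in ", path, " at line ", i, ": fewer than 4 fields")
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz)))
      stop("fcsv format error in ", path, " at line ", i,
           ": non-numeric coordinates")
    pts[k, ] <- xyz
    labels[k] <- if (length(fields) >= 12L) trimws(fields[12]) else ""
  }
  if (setequal(labels, paste0("P", 1:6))) {
    pts <- pts[match(paste0("P", 1:6), labels), , drop = FALSE]
  } else {
    warning("fiducials in ", path, " are not labelled P1..P6; using row order")
  }
  if (cs == "LPS") pts <- .lps_to_ras(pts)
  fiducial_set(pts, subject_id = subject_id, side = side)
}

#' Write a fiducial set as a Slicer .fcsv file
#'
#' @param fs a [fiducial_set] (RAS mm).
#' @param path output path.
#' @param coordinate_system `"RAS"` or `"LPS"` for the written file.
#' @return `path`, invisibly.
#' @export
write_slicer_fcsv <- function(fs, path, coordinate_system = c("RAS", "LPS")) {
  stopifnot(inherits(fs, "fiducial_set"))
  coordinate_system <- match.arg(coordinate_system)
  pts <- fs$points
  if (coordinate_system == "LPS") pts <- .lps_to_ras(pts)  # involution
  lines <- c(
    "# Markups fiducial file version = 4.10",
    paste0("# CoordinateSystem = ", if (coordinate_system == "RAS") "0" else "1"),
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  for (i in 1:6) {
    lines <- c(lines, paste(
      sprintf("vtkMRMLMarkupsFiducialNode_%d", i - 1L),
      sprintf("%.17g", pts[i, 1]), sprintf("%.17g", pts[i, 2]),
      sprintf("%.17g", pts[i, 3]),
      "0", "0", "0", "1", "1", "1", "0", paste0("P", i), "", "", sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Slicer Markups JSON file (.mrk.json)
#'
#' Reads the first markup's control points and its embedded
#' `coordinateSystem` field (LPS converted to RAS; absent assumes RAS
#' with a warning). Points are matched to P1..P6 by label when possible.
#'
#' @inheritParams read_slicer_fcsv
#' @return a [fiducial_set] in RAS mm.
#' @export
read_slicer_markups_json <- function(path, subject_id = NA_character_,
                                     side = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$markups) || length(doc$markups) < 1L)
    stop("markups JSON error in ", path, ": no markups entry")
  mk <- doc$markups[[1]]
  cs <- if (!is.null(mk$coordinateSystem)) {
    .coord_system(mk$coordinateSystem, path)
  } else {
    warning("no coordinateSystem field in ", path, "; assuming RAS")
    "RAS"
  }
  cps <- mk$controlPoints
  if (is.null(cps) || length(cps) != 6L)
    stop("markups JSON error in ", path, ": expected 6 control points, found ",
         length(cps))
  pts <- matrix(NA_real_, 6, 3); labels <- character(6)
  for (k in seq_along(cps)) {
    pos <- unlist(cps[[k]]$position)
    if (is.null(pos) || length(pos) != 3L || any(!is.finite(pos)))
      stop("markups JSON error in ", path, ": control point ", k,
           " has no valid position")
    pts[k, ] <- pos
    labels[k] <- if (!is.null(cps[[k]]$label)) cps[[k]]$label else ""
  }
  if (setequal(labels, paste0("P", 1:6))) {
    pts <- pts[match(paste0("P", 1:6), labels), , drop = FALSE]
  } else {
    warning("control points in ", path, " are not labelled P1..P6; using order")
  }
  if (cs == "LPS") pts <- .lps_to_ras(pts)
  fiducial_set(pts, subject_id = subject_id, side = side)
}

#' Write a fiducial set as a Slicer .mrk.json file
#'
#' @inheritParams write_slicer_fcsv
#' @export
write_slicer_markups_json <- function(fs, path,
                                      coordinate_system = c("LPS", "RAS")) {
  stopifnot(inherits(fs, "fiducial_set"))
  coordinate_system <- match.arg(coordinate_system)
  pts <- fs$points
  if (coordinate_system == "LPS") pts <- .lps_to_ras(pts)
  cps <- lapply(1:6, function(i) list(
    id = as.character(i), label = paste0("P", i),
    position = as.numeric(pts[i, ])))
  doc <- list(markups = list(list(
    type = "Fiducial", coordinateSystem = coordinate_system,
    controlPoints = cps)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a fiducial file, dispatching on extension
#'
#' `.fcsv` goes to [read_slicer_fcsv], `.json`/`.mrk.json` to
#' [read_slicer_markups_json].
#' @inheritParams read_slicer_fcsv
#' @export
read_fiducials <- function(path, subject_id = NA_character_, side = NA_character_) {
  if (grepl("\\.fcsv$", path, ignore.case = TRUE))
    read_slicer_fcsv(path, subject_id, side)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    read_slicer_markups_json(path, subject_id, side)
  else stop("unrecognised fiducial file extension: ", path)
}

#' Write a cohort to disk
#'
#' Writes the cohort CSV (one row per subject, columns subject_id,
#' diagnosis, genotype, age, sex, suzuki_left, suzuki_right, unilateral,
#' prior_revascularization, fiducial_file_left, fiducial_file_right) and
#' one fiducial file per vessel under `dir/fiducials/`.
#'
#' @param cohort list with `subjects` and `fiducials` as returned by
#'   [simulate_cohort].
#' @param dir output directory (created if needed).
#' @param format `"fcsv"` or `"mrk.json"`.
#' @return path of the written cohort CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("fcsv", "mrk.json")) {
  format <- match.arg(format)
  fdir <- file.path(dir, "fiducials")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  subjects <- cohort$subjects
  for (side in c("left", "right")) {
    files <- character(nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      key <- paste0(subjects$subject_id[i], "_", side)
      fs <- cohort$fiducials[[key]]
      if (is.null(fs)) { files[i] <- ""; next }
      fname <- file.path("fiducials", paste0(key, ".", format))
      if (format == "fcsv") write_slicer_fcsv(fs, file.path(dir, fname))
      else write_slicer_markups_json(fs, file.path(dir, fname))
      files[i] <- fname
    }
    subjects[[paste0("fiducial_file_", side)]] <- files
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(subjects, csv, row.names = FALSE, na = "")
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, na = "")
  invisible(csv)
}

#' Read a cohort CSV and its referenced fiducial files
#'
#' @param path cohort CSV path; fiducial file paths are resolved relative
#'   to its directory.
#' @return list with `subjects` (data.frame) and `fiducials` (named list
#'   of [fiducial_set]s).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  subjects <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("subject_id", "diagnosis")
  if (!all(need %in% names(subjects)))
    stop("cohort CSV ", path, " lacks required columns: ",
         paste(setdiff(need, names(subjects)), collapse = ", "))
  for (col in c("unilateral", "prior_revascularization"))
    if (col %in% names(subjects)) subjects[[col]] <- as.logical(subjects[[col]])
  base <- dirname(path)
  fiducials <- list()
  for (side in c("left", "right")) {
    col <- paste0("fiducial_file_", side)
    if (!col %in% names(subjects)) next
    for (i in seq_len(nrow(subjects))) {
      f <- subjects[[col]][i]
      if (is.na(f) || !nzchar(f)) next
      fp <- if (file.exists(f)) f else file.path(base, f)
      if (!file.exists(fp))
        stop("fiducial file referenced by cohort CSV not found: ", f)
      key <- paste0(subjects$subject_id[i], "_", side)
      fiducials[[key]] <- read_fiducials(fp, subjects$subject_id[i], side)
    }
  }
  list(subjects = subjects, fiducials = fiducials)
}
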