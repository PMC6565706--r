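# Landmark geometry: segment vectors, turning angles, arc-chord tortuosity.
# All coordinates are RAS millimetres; angles are degrees.

#' Minimal consecutive-landmark separation (mm)
#'
#' Consecutive fiducials closer than this are treated as digitization
#' duplicates: they would make turning angles and the tortuosity
#' denominator numerically meaningless.
#' @keywords internal
EPS_SEP <- 1e-6

#' Construct a six-landmark fiducial set
#'
#' A fiducial set holds one vessel's six ordered anatomical landmarks
#' P1--P6 in RAS millimetre coordinates: P1 the start of the vertical
#' petrous ICA at the carotid canal, P2 the petrous vertical/horizontal
#' inflection, P3 the petrous/cavernous inflection, P4 the cavernous
#' vertical/horizontal inflection, P5 the anteriormost point of the
#' carotid siphon, and P6 the emergence of the anterior choroidal artery.
#'
#' @param points 6x3 numeric matrix (rows P1..P6, columns x,y,z) or a
#'   data frame with columns x, y, z.
#' @param subject_id subject identifier (character scalar).
#' @param side `"left"` or `"right"`.
#' @return An object of class `fiducial_set`: a list with elements
#'   `points` (6x3 matrix, rownames `P1`..`P6`), `subject_id`, `side`.
#' @examples
#' fs <- fiducial_set(rbind(c(0,0,0), c(0,0,10), c(0,10,10),
#'                          c(0,10,20), c(0,20,20), c(0,20,30)))
#' measure_vessel(fs)
#' @export
fiducial_set <- function(points, subject_id = NA_character_, side = NA_character_) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  points <- unname(as.matrix(points))
  storage.mode(points) <- "double"
  if (!identical(dim(points), c(6L, 3L)))
    stop("a fiducial set requires exactly six 3D points (got ",
         nrow(points), "x", ncol(points), ")")
  if (!all(is.finite(points)))
    stop("fiducial coordinates must all be finite")
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be \"left\" or \"right\"")
  seps <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-6, , drop = FALSE])^2))
  if (any(seps <= EPS_SEP))
    stop("consecutive landmarks P", which(seps <= EPS_SEP)[1], "-P",
         which(seps <= EPS_SEP)[1] + 1L,
         " are closer than ", EPS_SEP, " mm (duplicate placement?)")
  dimnames(points) <- list(paste0("P", 1:6), c("x", "y", "z"))
  structure(list(points = points,
                 subject_id = as.character(subject_id),
                 side = as.character(side)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("Fiducial set", if (!is.na(x$subject_id)) paste0("[", x$subject_id, ", ", x$side, "]"),
      "- 6 landmarks (RAS mm)\n")
  print(round(x$points, 3))
  invisible(x)
}

#' Segment vector between consecutive landmarks
#'
#' Returns the vector from landmark P(i) to P(i+1); e.g. `i = 1` gives the
#' vertical petrous segment vector (P2 - P1).
#'
#' @param fs a [fiducial_set].
#' @param i segment index, 1 to 5.
#' @return numeric length-3 vector in mm.
#' @export
segment_vector <- function(fs, i) {
  stopifnot(inherits(fs, "fiducial_set"))
  if (length(i) != 1L || !is.finite(i) || i != as.integer(i) || i < 1 || i > 5)
    stop("segment index must be a single integer in 1..5")
  unname(fs$points[i + 1L, ] - fs$points[i, ])
}

#' Turning angle between two direction vectors
#'
#' The deflection angle between successive segment directions,
#' acos(a.b / (|a||b|)) in degrees: 0 means straight continuation, 180 a
#' full reversal. The cosine is clamped to \[-1, 1\] before the arccos so
#' that floating-point round-off on near-(anti)parallel vectors cannot
#' produce NaN.
#'
#' @param a,b numeric length-3 vectors with positive norm.
#' @param joint optional label used in the degenerate-geometry error.
#' @return angle in degrees, in \[0, 180\].
#' @export
turning_angle <- function(a, b, joint = NULL) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na <= EPS_SEP || nb <= EPS_SEP)
    stop("degenerate geometry: zero-length segment vector",
         if (!is.null(joint)) paste0(" at joint ", joint))
  cosv <- sum(a * b) / (na * nb)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Measure one vessel from its six landmarks
#'
#' Computes the five segment lengths |V12|..|V56| (vertical petrous,
#' horizontal petrous, vertical cavernous, horizontal cavernous and
#' intracranial segments), the four turning angles (inter-petrous,
#' petro-cavernous, inter-cavernous and siphon angles), the actual length
#' ALEN = sum of segment lengths, the linear length LLEN = |P6 - P1|, the
#' arc-chord tortuosity (ALEN - LLEN)/LLEN x 100 (percent) and the total
#' flow-direction change (sum of the four angles).
#'
#' @param fs a [fiducial_set].
#' @return An object of class `vessel_morphometry`: a list with
#'   `seg_lengths` (5, mm), `angles` (4, degrees), `alen`, `llen` (mm),
#'   `tortuosity` (percent), `total_angle` (degrees), plus the set's
#'   `subject_id` and `side`.
#' @export
measure_vessel <- function(fs) {
  stopifnot(inherits(fs, "fiducial_set"))
  p <- fs$points
  v <- p[-1, , drop = FALSE] - p[-6, , drop = FALSE]   # rows: V12..V56
  seg_lengths <- sqrt(rowSums(v * v))
  angles <- vapply(1:4, function(i)
    turning_angle(v[i, ], v[i + 1L, ], joint = paste0("P", i + 1L)), numeric(1))
  alen <- sum(seg_lengths)
  llen <- sqrt(sum((p[6, ] - p[1, ])^2))
  if (llen <= EPS_SEP)
    stop("degenerate geometry: P1 and P6 coincide (LLEN < ", EPS_SEP, " mm)")
  structure(list(
    subject_id = fs$subject_id, side = fs$side,
    seg_lengths = setNames(unname(seg_lengths), c("v12", "v23", "v34", "v45", "v56")),
    angles = setNames(unname(angles), c("a123", "a234", "a345", "a456")),
    alen = alen, llen = llen,
    tortuosity = (alen - llen) / llen * 100,
    total_angle = sum(angles)), class = "vessel_morphometry")
}

#' @export
print.vessel_morphometry <- function(x, ...) {
  cat("Vessel morphometry",
      if (!is.na(x$subject_id)) paste0("[", x$subject_id, ", ", x$side, "]"), "\n")
  cat("  segment lengths (mm):", paste(sprintf("%.2f", x$seg_lengths), collapse = " "), "\n")
  cat("  turning angles (deg):", paste(sprintf("%.2f", x$angles), collapse = " "), "\n")
  cat(sprintf("  ALEN %.2f mm  LLEN %.2f mm  tortuosity %.2f%%  total angle %.2f deg\n",
              x$alen, x$llen, x$tortuosity, x$total_angle))
  invisible(x)
}

#' Flatten vessel morphometry to a one-row data frame
#'
#' @param x a `vessel_morphometry` object.
#' @param ... unused.
#' @return one-row data.frame with columns subject_id, side, v12..v56,
#'   a123..a456, alen, llen, tortuosity, total_angle.
#' @export
as.data.frame.vessel_morphometry <- function(x, ...) {
  data.frame(subject_id = x$subject_id, side = x$side,
             as.list(x$seg_lengths), as.list(x$angles),
             alen = x$alen, llen = x$llen,
             tortuosity = x$tortuosity, total_angle = x$total_angle,
             stringsAsFactors = FALSE)
}

#' Names of the morphometric parameters
#'
#' The five segment lengths, four turning angles, ALEN, LLEN, tortuosity
#' and total angle, in reporting order.
#' @return character vector of column names.
#' @export
morphometry_parameters <- function() {
  c("v12", "v23", "v34", "v45", "v56", "alen", "llen", "tortuosity",
    "a123", "a234", "a345", "a456", "total_angle")
}
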