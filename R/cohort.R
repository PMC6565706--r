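# Cohort rules: genotype grouping, representative Suzuki grade, bilateral
# averaging, exclusion filtering.

#' Assign the analysis group from diagnosis and genotype
#'
#' MMD carriers of the RNF213 c.14429G>A variant (genotype GA or AA,
#' regardless of zygosity) form the mutant group; MMD non-carriers (GG)
#' the wild-type group; controls form their own group and carry no
#' genotype.
#'
#' @param diagnosis `"MMD"` or `"control"` (vectorised).
#' @param genotype `"GG"`, `"GA"`, `"AA"`, or `NA` (required `NA` for
#'   controls, required non-`NA` for MMD).
#' @return character vector: `"mutant"`, `"wild"` or `"control"`.
#' @export
assign_group <- function(diagnosis, genotype) {
  n <- max(length(diagnosis), length(genotype))
  diagnosis <- rep_len(as.character(diagnosis), n)
  genotype <- rep_len(as.character(genotype), n)
  if (!all(diagnosis %in% c("MMD", "control")))
    stop("diagnosis must be \"MMD\" or \"control\"")
  bad <- diagnosis == "MMD" & (is.na(genotype) | !genotype %in% c("GG", "GA", "AA"))
  if (any(bad))
    stop("MMD subjects require a genotype in {GG, GA, AA} (",
         sum(bad), " missing/invalid)")
  ifelse(diagnosis == "control", "control",
         ifelse(genotype == "GG", "wild", "mutant"))
}

#' Representative Suzuki grade of a subject
#'
#' The more advanced (higher) grade of the two sides; if only one side is
#' graded that grade is used (with a message).
#'
#' @param left,right integer grades 1--6 or `NA` (vectorised).
#' @return integer vector of representative grades.
#' @export
representative_suzuki <- function(left, right) {
  n <- max(length(left), length(right))
  left <- rep_len(as.integer(left), n); right <- rep_len(as.integer(right), n)
  ok <- function(g) is.na(g) | (g >= 1L & g <= 6L)
  if (!all(ok(left) & ok(right)))
    stop("Suzuki grades must be in 1..6 or NA")
  if (any(is.na(left) & is.na(right)))
    stop("representative Suzuki grade undefined: both sides ungraded")
  one_sided <- xor(is.na(left), is.na(right))
  if (any(one_sided))
    message(sum(one_sided), " subject(s) graded on one side only; using that grade")
  pmax(left, right, na.rm = TRUE)
}

#' Average left and right vessel measurements into subject-level values
#'
#' Each of the morphometric parameters is the arithmetic mean of the two
#' sides' values of that same parameter. Derived quantities (tortuosity,
#' ALEN, total angle) are averaged as measured per side, never recomputed
#' from averaged lengths.
#'
#' @param left,right `vessel_morphometry` objects for the same subject.
#' @return one-row data.frame with subject_id and the averaged parameters.
#' @export
average_bilateral <- function(left, right) {
  if (is.null(left) || is.null(right) ||
      !inherits(left, "vessel_morphometry") || !inherits(right, "vessel_morphometry"))
    stop("bilateral averaging requires measurements from both sides")
  if (!is.na(left$subject_id) && !is.na(right$subject_id) &&
      left$subject_id != right$subject_id)
    stop("left and right measurements belong to different subjects")
  l <- as.data.frame(left); r <- as.data.frame(right)
  pars <- morphometry_parameters()
  out <- data.frame(subject_id = left$subject_id, stringsAsFactors = FALSE)
  out[pars] <- (l[pars] + r[pars]) / 2
  out
}

#' Apply the cohort exclusion rules
#'
#' In both modes, MMD subjects with unilateral disease or prior
#' revascularization surgery are excluded. In `mode = "main"`, MMD
#' subjects whose representative Suzuki grade is outside 2--4 are
#' additionally excluded; `mode = "supplementary"` keeps them. Controls
#' are never excluded. When several rules apply, the logged reason
#' follows the fixed precedence unilateral > prior surgery > grade, so
#' exclusion logs are deterministic.
#'
#' @param subjects data.frame with columns `subject_id`, `diagnosis`, and
#'   for MMD rows `unilateral`, `prior_revascularization` (logical) and
#'   `representative_suzuki` (integer).
#' @param mode `"main"` or `"supplementary"`.
#' @return list with `retained` (data.frame) and `log` (data.frame of
#'   `subject_id`, `reason`), where `reason` is one of `"unilateral"`,
#'   `"prior_revascularization"`, `"suzuki_out_of_range"`.
#' @export
apply_exclusions <- function(subjects, mode = c("main", "supplementary")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "diagnosis") %in% names(subjects)))
  n <- nrow(subjects)
  get_flag <- function(col) {
    if (col %in% names(subjects)) {
      v <- subjects[[col]]
      if (is.character(v)) v <- as.logical(toupper(v) %in% c("TRUE", "T", "1", "YES"))
      v[is.na(v)] <- FALSE
      v
    } else rep(FALSE, n)
  }
  mmd <- subjects$diagnosis == "MMD"
  uni <- get_flag("unilateral") & mmd
  surg <- get_flag("prior_revascularization") & mmd
  grade_bad <- rep(FALSE, n)
  if (mode == "main") {
    g <- if ("representative_suzuki" %in% names(subjects))
      suppressWarnings(as.integer(subjects$representative_suzuki)) else rep(NA_integer_, n)
    grade_bad <- mmd & !is.na(g) & !(g %in% 2:4)
  }
  reason <- rep(NA_character_, n)
  reason[grade_bad] <- "suzuki_out_of_range"
  reason[surg] <- "prior_revascularization"
  reason[uni] <- "unilateral"
  drop <- !is.na(reason)
  retained <- subjects[!drop, , drop = FALSE]
  if (nrow(retained) == 0L) warning("all subjects excluded")
  list(retained = retained,
       log = data.frame(subject_id = subjects$subject_id[drop],
                        reason = reason[drop], stringsAsFactors = FALSE))
}

#' Build the per-subject analysis table from per-vessel measurements
#'
#' Joins the cohort metadata with the vessel measurements, assigns the
#' analysis group, computes the representative Suzuki grade and, for
#' `unit = "subject"` (the default), averages the two sides per subject.
#' `unit = "vessel"` treats the two ICAs of one subject as independent
#' observations.
#'
#' @param subjects cohort metadata data.frame (columns `subject_id`,
#'   `diagnosis`, `genotype`, `age`, `sex`, `suzuki_left`, `suzuki_right`,
#'   `unilateral`, `prior_revascularization`).
#' @param measurements data.frame of per-vessel rows as returned by
#'   [as.data.frame.vessel_morphometry] (columns `subject_id`, `side`,
#'   and the morphometric parameters).
#' @param unit `"subject"` (bilateral averaging) or `"vessel"`.
#' @return data.frame with metadata (`group`, `age`, `sex`,
#'   `representative_suzuki`, exclusion flags) and the morphometric
#'   parameter columns; one row per subject or per vessel.
#' @export
subject_morphometry <- function(subjects, measurements, unit = c("subject", "vessel")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(subjects), is.data.frame(measurements))
  pars <- morphometry_parameters()
  stopifnot(all(c("subject_id", "side") %in% names(measurements)),
            all(pars %in% names(measurements)))
  subjects$group <- assign_group(subjects$diagnosis, subjects$genotype)
  is_ctl <- subjects$group == "control"
  if (any(is_ctl & (!is.na(subjects$suzuki_left) | !is.na(subjects$suzuki_right)))) {
    warning("Suzuki grades given for control subjects are ignored")
    subjects$suzuki_left[is_ctl] <- NA_integer_
    subjects$suzuki_right[is_ctl] <- NA_integer_
  }
  subjects$representative_suzuki <- NA_integer_
  mmd <- !is_ctl
  if (any(mmd))
    subjects$representative_suzuki[mmd] <-
      representative_suzuki(subjects$suzuki_left[mmd], subjects$suzuki_right[mmd])

  meta_cols <- intersect(c("subject_id", "group", "diagnosis", "genotype", "age",
                           "sex", "representative_suzuki", "unilateral",
                           "prior_revascularization"), names(subjects))
  if (unit == "vessel") {
    out <- merge(subjects[meta_cols], measurements[c("subject_id", "side", pars)],
                 by = "subject_id", sort = FALSE)
    return(out[order(match(out$subject_id, subjects$subject_id)), , drop = FALSE])
  }
  avg <- lapply(subjects$subject_id, function(id) {
    rows <- measurements[measurements$subject_id == id, , drop = FALSE]
    l <- rows[rows$side == "left", pars, drop = FALSE]
    r <- rows[rows$side == "right", pars, drop = FALSE]
    if (nrow(l) != 1L || nrow(r) != 1L)
      stop("subject ", id, " lacks a measured vessel on one side; ",
           "exclude unilateral subjects before averaging")
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), (l + r) / 2)
  })
  avg <- do.call(rbind, avg)
  merge(subjects[meta_cols], avg, by = "subject_id", sort = FALSE)
}
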