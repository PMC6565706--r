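# Synthetic cohort generation: vessel parameters drawn from distributions
# moment-matched to published group summaries, fiducial chains built from
# internal coordinates (segment lengths, turning angles, dihedrals).

# Per-group targets: median (q1-q3) of the five segment lengths (mm) and
# four turning angles (degrees), from the cohort summary table.
.target_block <- function(v12, v23, v34, v45, v56, a123, a234, a345, a456) {
  m <- rbind(v12, v23, v34, v45, v56, a123, a234, a345, a456)
  colnames(m) <- c("median", "q1", "q3")
  m
}

.default_targets <- list(
  mutant = .target_block(
    v12 = c(6.90, 5.32, 8.14),   v23 = c(17.75, 15.51, 18.69),
    v34 = c(11.41, 9.66, 13.12), v45 = c(11.01, 9.76, 12.06),
    v56 = c(7.60, 6.20, 9.26),
    a123 = c(56.18, 46.11, 67.10), a234 = c(44.32, 36.21, 56.67),
    a345 = c(41.37, 26.26, 58.13), a456 = c(108.18, 96.99, 119.95)),
  wild = .target_block(
    v12 = c(6.37, 5.53, 7.18),   v23 = c(19.62, 18.91, 21.20),
    v34 = c(12.73, 10.67, 14.81), v45 = c(11.44, 10.66, 11.80),
    v56 = c(8.08, 7.40, 9.65),
    a123 = c(70.45, 64.40, 80.54), a234 = c(58.89, 52.34, 65.00),
    a345 = c(49.91, 42.56, 65.79), a456 = c(111.99, 104.55, 126.06)),
  control = .target_block(
    v12 = c(7.67, 6.07, 8.78),   v23 = c(19.24, 18.23, 20.45),
    v34 = c(13.41, 11.71, 15.73), v45 = c(11.87, 10.66, 13.13),
    v56 = c(10.78, 9.72, 11.72),
    a123 = c(72.09, 61.33, 82.82), a234 = c(60.51, 54.35, 66.53),
    a345 = c(61.08, 42.66, 68.82), a456 = c(126.46, 118.83, 136.79)))

.default_ages <- list(mutant = c(34.0, 26.8, 48.3),
                      wild = c(42.5, 35.0, 44.5),
                      control = c(35.5, 28.0, 47.0))

#' Synthetic-cohort generator configuration
#'
#' Defaults reproduce the study composition: analysis groups of 44 mutant
#' (RNF213 c.14429G>A carriers, all heterozygous), 14 wild-type and 58
#' control subjects; Suzuki grades 2/3/4 at 12/19/13 (mutant) and 9/3/2
#' (wild-type); 27/44 and 8/14 females; segment-length and turning-angle
#' targets per group from the published medians and IQRs. With
#' `full_flow = TRUE` (default) the generator also emits the screened-out
#' part of the patient stream: 8 extra mutant subjects with Suzuki grade
#' 1 or 5 (retained only in the supplementary analysis) and 27 subjects
#' excluded for unilateral disease or prior revascularization, so the
#' exclusion stage reproduces the published 93 -> 66 -> 58 flow.
#'
#' Lengths are drawn log-normal (median matched exactly, spread from the
#' quartile ratio); angles from a normal truncated to (0, 180) solved to
#' match median and IQR width; left and right vessels share a
#' subject-level latent factor with correlation `rho`. Dihedral (torsion)
#' angles shape the out-of-plane 3D course and are shared across groups.
#'
#' @param n named group sizes (mutant, wild, control).
#' @param targets per-group 9x3 matrices (rows v12..v56, a123..a456;
#'   columns median, q1, q3).
#' @param ages per-group `c(median, q1, q3)` in years.
#' @param n_female named per-group female counts.
#' @param suzuki_counts per-group named integer vectors of representative
#'   grade counts (must sum to the group size).
#' @param dihedral_mean,dihedral_sd torsion profile (degrees) at the
#'   three inner joints following the first turn.
#' @param rho left-right latent correlation in \[0, 1\].
#' @param full_flow also generate the grade-1/5 and unilateral/surgery
#'   streams (counts `n_grade15`, `n_flagged`).
#' @param n_grade15,n_flagged sizes of those streams.
#' @param matched_controls copy age and sex for controls from the
#'   main-analysis MMD subjects (exact matching).
#' @param seed master seed.
#' @return object of class `generator_config` (a list).
#' @export
generator_config <- function(n = c(mutant = 44, wild = 14, control = 58),
                             targets = .default_targets,
                             ages = .default_ages,
                             n_female = c(mutant = 27, wild = 8, control = 35),
                             suzuki_counts = list(
                               mutant = c("2" = 12, "3" = 19, "4" = 13),
                               wild = c("2" = 9, "3" = 3, "4" = 2)),
                             dihedral_mean = c(90, -90, 180),
                             dihedral_sd = c(10, 10, 10),
                             rho = 0.5,
                             full_flow = TRUE,
                             n_grade15 = 8, n_flagged = 27,
                             matched_controls = TRUE,
                             seed = 20260101) {
  for (g in names(targets)) {
    tg <- targets[[g]]
    stopifnot(is.matrix(tg), nrow(tg) == 9L, ncol(tg) == 3L)
    if (any(tg[1:5, ] <= 0))
      stop("generator_config: length targets must be positive (group ", g, ")")
    if (any(tg[6:9, ] <= 0) || any(tg[6:9, ] >= 180))
      stop("generator_config: angle targets must lie in (0, 180) (group ", g, ")")
    if (any(tg[, "q1"] > tg[, "median"]) || any(tg[, "median"] > tg[, "q3"]))
      stop("generator_config: quartile targets must satisfy q1 <= median <= q3 (group ", g, ")")
  }
  stopifnot(rho >= 0, rho <= 1, length(dihedral_mean) == 3L,
            length(dihedral_sd) == 3L, all(dihedral_sd >= 0))
  for (g in names(suzuki_counts))
    if (sum(suzuki_counts[[g]]) != n[[g]])
      stop("generator_config: Suzuki counts for group ", g,
           " must sum to the group size")
  # solve all marginal distribution parameters once; draws reuse them
  marginals <- lapply(targets, function(tg) {
    lapply(1:9, function(i) {
      if (i <= 5) c(type = 1, solve_lognormal(tg[i, 1], tg[i, 2], tg[i, 3]))
      else c(type = 2, solve_truncnorm(tg[i, 1], tg[i, 2], tg[i, 3]))
    })
  })
  structure(list(marginals = marginals,
                 n = n, targets = targets, ages = ages, n_female = n_female,
                 suzuki_counts = suzuki_counts,
                 dihedral_mean = dihedral_mean, dihedral_sd = dihedral_sd,
                 rho = rho, full_flow = full_flow, n_grade15 = n_grade15,
                 n_flagged = n_flagged, matched_controls = matched_controls,
                 seed = seed),
            class = "generator_config")
}

# Log-normal parameters matching a target median exactly and the quartile
# ratio q3/q1 exactly (two parameters cannot also match both absolute
# quartiles when the target IQR is asymmetric on the log scale).
solve_lognormal <- function(median, q1, q3) {
  if (!(q1 <= median && median <= q3) || q1 <= 0)
    stop("log-normal moment matching needs 0 < q1 <= median <= q3")
  c(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# Quantile of a normal truncated to (lo, hi).
qtruncnorm <- function(p, mean, sd, lo = 0, hi = 180) {
  if (sd == 0) return(rep(mean, length(p)))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# (mean, sd) of a normal truncated to (lo, hi) whose truncated median and
# IQR width match the targets; solved numerically.
solve_truncnorm <- function(median, q1, q3, lo = 0, hi = 180) {
  if (!(lo < median && median < hi) || q1 > median || median > q3)
    stop("truncated-normal moment matching needs lo < q1 <= median <= q3 < hi")
  w <- q3 - q1
  if (w == 0) return(c(mean = median, sd = 0))
  obj <- function(par) {
    m <- par[1]; s <- exp(par[2])
    qs <- qtruncnorm(c(0.25, 0.5, 0.75), m, s, lo, hi)
    (qs[2] - median)^2 + ((qs[3] - qs[1]) - w)^2
  }
  init <- c(median, log(w / (2 * stats::qnorm(0.75))))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6)
    stop("truncated-normal moment matching failed to converge ",
         "(median ", median, ", IQR width ", w, ")")
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Map standard-normal latents to the pre-solved marginal distributions of
# one group's 9 vessel parameters. z: length-9 vector.
.latent_to_params <- function(z, marg) {
  vapply(1:9, function(i) {
    par <- marg[[i]]
    if (par[["type"]] == 1)
      stats::qlnorm(stats::pnorm(z[i]), par[[2]], par[[3]])
    else
      qtruncnorm(stats::pnorm(z[i]), par[[2]], par[[3]])
  }, numeric(1))
}

#' Draw one vessel's internal-coordinate parameters
#'
#' Samples five segment lengths (log-normal), four turning angles
#' (truncated normal) and three dihedrals (normal) from the group's
#' calibrated marginals, using the current RNG state.
#'
#' @param group `"mutant"`, `"wild"` or `"control"`.
#' @param config a [generator_config].
#' @return list with `lengths` (5), `angles` (4), `dihedrals` (3).
#' @export
sample_vessel_parameters <- function(group, config) {
  stopifnot(inherits(config, "generator_config"), group %in% names(config$targets))
  p <- .latent_to_params(stats::rnorm(9), config$marginals[[group]])
  list(lengths = p[1:5], angles = p[6:9],
       dihedrals = config$dihedral_mean + config$dihedral_sd * stats::rnorm(3))
}

# Correlated left/right vessel parameters for one subject: a Gaussian
# copula with a subject-level factor, cor(z_left, z_right) = rho, exact
# group marginals on each side.
.sample_subject_vessels <- function(group, config) {
  rho <- config$rho
  zs <- stats::rnorm(12)
  draw_side <- function() {
    z <- sqrt(rho) * zs + sqrt(1 - rho) * stats::rnorm(12)
    p <- .latent_to_params(z[1:9], config$marginals[[group]])
    list(lengths = p[1:5], angles = p[6:9],
         dihedrals = config$dihedral_mean + config$dihedral_sd * z[10:12])
  }
  list(right = draw_side(), left = draw_side())
}

# Rodrigues-style frame update used by the chain builder.
.advance_frame <- function(t, n, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  b <- c(t[2] * n[3] - t[3] * n[2],
         t[3] * n[1] - t[1] * n[3],
         t[1] * n[2] - t[2] * n[1])
  m <- cos(ph) * n + sin(ph) * b          # in-plane turn direction
  t_new <- cos(th) * t + sin(th) * m
  n_new <- cos(th) * m - sin(th) * t
  list(t = t_new, n = n_new)
}

#' Build a six-landmark chain from internal coordinates
#'
#' Places P1 at `origin` and P2 along `initial_direction`; each later
#' direction is the previous one deflected by the joint's turning angle,
#' about an axis set by the joint's dihedral within the local frame (the
#' standard construction from bond lengths, planar angles and torsions).
#' The first turn has no preceding plane, so it bends toward
#' `initial_normal` (its dihedral is fixed at 0); the three supplied
#' dihedrals apply to the remaining joints. A dihedral of 180 degrees
#' continues in the same plane on the opposite side (trans / zigzag), 0
#' curls on the same side (cis).
#'
#' Measuring the returned set with [measure_vessel] recovers the input
#' lengths and turning angles to floating-point accuracy.
#'
#' @param lengths five positive segment lengths (mm).
#' @param angles four turning angles in \[0, 180\] degrees.
#' @param dihedrals three dihedral angles (degrees) for joints P3..P5.
#' @param origin P1 position (length-3).
#' @param initial_direction unit vector of the first segment.
#' @param initial_normal unit vector orthogonal to `initial_direction`.
#' @param subject_id,side passed through to the [fiducial_set].
#' @return a [fiducial_set].
#' @export
build_fiducials <- function(lengths, angles, dihedrals,
                            origin = c(0, 0, 0),
                            initial_direction = c(0, 0, 1),
                            initial_normal = c(0, 1, 0),
                            subject_id = NA_character_, side = NA_character_) {
  stopifnot(length(lengths) == 5L, length(angles) == 4L, length(dihedrals) == 3L,
            length(origin) == 3L)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("build_fiducials: segment lengths must be positive")
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles > 180))
    stop("build_fiducials: turning angles must lie in [0, 180] degrees")
  t <- initial_direction; n <- initial_normal
  if (abs(sqrt(sum(t^2)) - 1) > 1e-8 || abs(sqrt(sum(n^2)) - 1) > 1e-8)
    stop("build_fiducials: frame vectors must be unit length")
  if (abs(sum(t * n)) > 1e-8)
    stop("build_fiducials: initial_normal must be orthogonal to initial_direction")
  pts <- matrix(NA_real_, 6, 3)
  pts[1, ] <- origin
  pts[2, ] <- origin + lengths[1] * t
  phis <- c(0, dihedrals)
  for (j in 1:4) {
    fr <- .advance_frame(t, n, angles[j], phis[j])
    t <- fr$t; n <- fr$n
    pts[j + 2L, ] <- pts[j + 1L, ] + lengths[j + 1L] * t
  }
  fiducial_set(pts, subject_id = subject_id, side = side)
}

# Clamp sampled dihedrals into (-180, 180] for tidy bookkeeping.
.wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Simulate a full synthetic cohort
#'
#' Generates subjects with bilateral six-landmark fiducial chains,
#' clinical metadata and a truth table of every sampled internal
#' coordinate. Right vessels are anchored on the +x (right) side of the
#' mid-sagittal plane; left vessels are the same construction mirrored
#' through that plane, with independently sampled (but
#' subject-correlated) parameters.
#' Group composition, sex counts and Suzuki-grade counts are exact
#' (deterministic composition, randomised assignment); ages are drawn
#' from the group's matched log-normal. With `matched_controls = TRUE`
#' each control copies age and sex from one main-analysis MMD subject.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [generator_config].
#' @return list with `subjects` (cohort metadata data.frame), `fiducials`
#'   (named list of [fiducial_set]s, names `<subject_id>_<side>`) and
#'   `truth` (data.frame of the sampled lengths/angles/dihedrals).
#' @export
simulate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subjects <- list(); fiducials <- list(); truth <- list()

  add_subject <- function(id, diagnosis, genotype, group_for_geometry,
                          age, sex, sl, sr, unilateral, surgery) {
    vp <- .sample_subject_vessels(group_for_geometry, config)
    for (side in c("right", "left")) {
      v <- vp[[side]]
      v$dihedrals <- .wrap_angle(v$dihedrals)
      ox <- if (side == "right") 25 else -25
      fs <- build_fiducials(v$lengths, v$angles, v$dihedrals,
                            origin = c(abs(ox), 0, 0),
                            subject_id = id, side = side)
      if (side == "left") {        # mirror through the mid-sagittal plane
        pts <- fs$points; pts[, 1] <- -pts[, 1]
        fs <- fiducial_set(pts, subject_id = id, side = side)
      }
      fiducials[[paste0(id, "_", side)]] <<- fs
      truth[[length(truth) + 1L]] <<- data.frame(
        subject_id = id, side = side, group = group_for_geometry,
        t(setNames(v$lengths, c("v12", "v23", "v34", "v45", "v56"))),
        t(setNames(v$angles, c("a123", "a234", "a345", "a456"))),
        t(setNames(v$dihedrals, c("d1", "d2", "d3"))),
        stringsAsFactors = FALSE)
    }
    subjects[[length(subjects) + 1L]] <<- data.frame(
      subject_id = id, diagnosis = diagnosis, genotype = genotype,
      age = age, sex = sex, suzuki_left = sl, suzuki_right = sr,
      unilateral = unilateral, prior_revascularization = surgery,
      stringsAsFactors = FALSE)
  }

  # representative grade g: one side g, the other g or g-1 (floored at 1)
  side_grades <- function(g) {
    other <- max(1L, g - stats::rbinom(1, 1, 0.5))
    if (stats::runif(1) < 0.5) c(g, other) else c(other, g)
  }
  draw_age <- function(group) {
    a <- config$ages[[group]]
    par <- solve_lognormal(a[1], a[2], a[3])
    round(stats::rlnorm(1, par[1], par[2]), 1)
  }

  idx <- 0L
  main_meta <- list()   # age/sex of main-analysis MMD, for control matching
  for (group in c("mutant", "wild")) {
    ng <- config$n[[group]]
    sexes <- sample(rep(c("female", "male"),
                        c(config$n_female[[group]], ng - config$n_female[[group]])))
    grades <- sample(rep(as.integer(names(config$suzuki_counts[[group]])),
                         config$suzuki_counts[[group]]))
    genotype <- if (group == "mutant") "GA" else "GG"
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      id <- sprintf("S%03d", idx)
      age <- draw_age(group)
      sg <- side_grades(grades[i])
      add_subject(id, "MMD", genotype, group, age, sexes[i], sg[1], sg[2],
                  FALSE, FALSE)
      main_meta[[length(main_meta) + 1L]] <- list(age = age, sex = sexes[i])
    }
  }
  if (config$full_flow) {
    # mutant subjects at Suzuki grade 1 or 5 (kept only in supplementary mode)
    g15 <- sample(rep(c(1L, 5L), length.out = config$n_grade15))
    for (i in seq_len(config$n_grade15)) {
      idx <- idx + 1L
      sg <- if (g15[i] == 1L) c(1L, 1L) else side_grades(5L)
      add_subject(sprintf("S%03d", idx), "MMD", "GA", "mutant",
                  draw_age("mutant"),
                  sample(c("female", "male"), 1, prob = c(0.6, 0.4)),
                  sg[1], sg[2], FALSE, FALSE)
    }
    # unilateral / prior-revascularization stream
    for (i in seq_len(config$n_flagged)) {
      idx <- idx + 1L
      geno <- sample(c("GA", "GG"), 1, prob = c(0.788, 0.212))
      grp <- if (geno == "GA") "mutant" else "wild"
      uni <- i <= ceiling(config$n_flagged / 2)
      sg <- side_grades(sample(2:4, 1))
      add_subject(sprintf("S%03d", idx), "MMD", geno, grp, draw_age(grp),
                  sample(c("female", "male"), 1, prob = c(0.6, 0.4)),
                  sg[1], sg[2], uni, !uni)
    }
  }
  nc <- config$n[["control"]]
  ctl_sex <- sample(rep(c("female", "male"),
                        c(config$n_female[["control"]],
                          nc - config$n_female[["control"]])))
  match_order <- sample(seq_along(main_meta))
  for (i in seq_len(nc)) {
    idx <- idx + 1L
    if (config$matched_controls && i <= length(main_meta)) {
      m <- main_meta[[match_order[i]]]
      age <- m$age; sex <- m$sex
    } else {
      age <- draw_age("control"); sex <- ctl_sex[i]
    }
    add_subject(sprintf("S%03d", idx), "control", NA_character_, "control",
                age, sex, NA_integer_, NA_integer_, FALSE, FALSE)
  }

  list(subjects = do.call(rbind, subjects),
       fiducials = fiducials,
       truth = do.call(rbind, truth))
}
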