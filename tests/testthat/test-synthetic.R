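# Calibrated generator: moment matching, chain construction, cohorts.

test_that("log-normal moment matching hits the target median and quartile ratio", {
  set.seed(201)
  for (rep in 1:20) {
    med <- runif(1, 5, 20); lo <- med * runif(1, 0.7, 0.95)
    hi <- med * runif(1, 1.05, 1.4)
    par <- solve_lognormal(med, lo, hi)
    expect_equal(qlnorm(0.5, par[1], par[2]), med, tolerance = 1e-12)
    expect_equal(qlnorm(0.75, par[1], par[2]) / qlnorm(0.25, par[1], par[2]),
                 hi / lo, tolerance = 1e-10)
  }
  expect_error(solve_lognormal(5, 6, 7), "q1 <= median")
})

test_that("truncated-normal moment matching recovers median and IQR width", {
  set.seed(211)
  for (rep in 1:15) {
    med <- runif(1, 30, 150); w <- runif(1, 5, 40)
    lo <- med - w * runif(1, 0.3, 0.7); hi <- lo + w
    par <- icamorph:::solve_truncnorm(med, lo, hi)
    qs <- icamorph:::qtruncnorm(c(0.25, 0.5, 0.75), par[1], par[2])
    expect_equal(qs[2], med, tolerance = 1e-3)
    expect_equal(qs[3] - qs[1], w, tolerance = 1e-3)
    expect_true(all(qs > 0 & qs < 180))
  }
  expect_error(icamorph:::solve_truncnorm(190, 185, 195), "moment matching")
})

test_that("moment matching round-trips through large simulated draws", {
  set.seed(221)
  par <- solve_lognormal(10.78, 9.72, 11.72)        # control |V56| targets
  x <- rlnorm(1e6, par[1], par[2])
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[2], 10.78, tolerance = 0.01)
  expect_equal(q[3] / q[1], 11.72 / 9.72, tolerance = 0.01)
  tpar <- icamorph:::solve_truncnorm(108.18, 96.99, 119.95)
  a <- icamorph:::qtruncnorm(runif(1e6), tpar[1], tpar[2])
  qa <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(qa[2], 108.18, tolerance = 0.5)
  expect_equal(qa[3] - qa[1], 119.95 - 96.99, tolerance = 0.5)
})

test_that("zero-spread targets make every draw equal the target medians", {
  tg <- .default_targets
  for (g in names(tg)) tg[[g]][, c("q1", "q3")] <- tg[[g]][, "median"]
  cfg <- generator_config(targets = tg, dihedral_sd = c(0, 0, 0), seed = 5)
  set.seed(5)
  for (g in c("mutant", "wild", "control")) {
    v <- sample_vessel_parameters(g, cfg)
    expect_equal(v$lengths, unname(tg[[g]][1:5, "median"]), tolerance = 1e-9)
    expect_equal(v$angles, unname(tg[[g]][6:9, "median"]), tolerance = 1e-9)
    expect_equal(v$dihedrals, c(90, -90, 180))
  }
})

test_that("sampled vessel parameters track their group targets in distribution", {
  cfg <- generator_config(seed = 1)
  set.seed(231)
  draws <- replicate(3000, sample_vessel_parameters("control", cfg)$lengths)
  med <- apply(draws, 1, median)
  target <- .default_targets$control[1:5, "median"]
  expect_true(all(abs(med - target) / target < 0.02))  # |V56| target 10.78 etc.
})

test_that("chain construction is exact: collinear and planar closed forms", {
  # zero turning: collinear, zero tortuosity
  fs <- build_fiducials(c(5, 8, 11, 7, 9), rep(0, 4), rep(0, 3))
  m <- measure_vessel(fs)
  expect_equal(m$tortuosity, 0, tolerance = 1e-9)
  expect_equal(m$total_angle, 0, tolerance = 1e-6)
  # right-angle planar chain (trans dihedrals reproduce the worked chain)
  fs2 <- build_fiducials(rep(10, 5), rep(90, 4), rep(180, 3))
  expect_equal(unname(fs2$points),
               rbind(c(0, 0, 0), c(0, 0, 10), c(0, 10, 10), c(0, 10, 20),
                     c(0, 20, 20), c(0, 20, 30)), tolerance = 1e-9)
  m2 <- measure_vessel(fs2)
  expect_equal(m2$alen, 50); expect_equal(m2$total_angle, 360, tolerance = 1e-9)
  # cis dihedrals: still planar, same lengths/angles, different course
  m3 <- measure_vessel(build_fiducials(rep(10, 5), rep(90, 4), rep(0, 3)))
  expect_equal(m3$alen, 50); expect_equal(m3$total_angle, 360, tolerance = 1e-9)
  expect_error(build_fiducials(rep(10, 5), rep(90, 4), rep(0, 3),
                               initial_direction = c(0, 0, 2)), "unit")
  expect_error(build_fiducials(rep(10, 5), rep(90, 4), rep(0, 3),
                               initial_normal = c(0, 0, 1)), "orthogonal")
  expect_error(build_fiducials(c(-1, 1, 1, 1, 1), rep(90, 4), rep(0, 3)),
               "positive")
})

test_that("construction and measurement round-trip on random parameters", {
  set.seed(241)
  for (rep in 1:300) {
    lens <- runif(5, 2, 25)
    angs <- runif(4, 1, 179)
    dihs <- runif(3, -180, 180)
    m <- measure_vessel(build_fiducials(lens, angs, dihs))
    expect_equal(unname(m$seg_lengths), lens, tolerance = 1e-9)
    expect_equal(unname(m$angles), angs, tolerance = 1e-9)
  }
})

test_that("cohort simulation is deterministic and has the published composition", {
  cfg <- generator_config(seed = 99)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$truth, co2$truth)
  expect_identical(lapply(co1$fiducials, `[[`, "points"),
                   lapply(co2$fiducials, `[[`, "points"))
  s <- co1$subjects
  grp <- assign_group(s$diagnosis, s$genotype)
  expect_equal(sum(grp == "control"), 58L)
  eligible <- !s$unilateral & !s$prior_revascularization & s$diagnosis == "MMD"
  rep_grade <- rep(NA_integer_, nrow(s))
  rep_grade[s$diagnosis == "MMD"] <-
    representative_suzuki(s$suzuki_left[s$diagnosis == "MMD"],
                          s$suzuki_right[s$diagnosis == "MMD"])
  main <- eligible & rep_grade %in% 2:4
  expect_equal(sum(main & grp == "mutant"), 44L)
  expect_equal(sum(main & grp == "wild"), 14L)
  # exact categorical composition: sex and Suzuki counts as published
  expect_equal(sum(s$sex[main & grp == "mutant"] == "female"), 27L)
  expect_equal(sum(s$sex[main & grp == "wild"] == "female"), 8L)
  expect_equal(as.vector(table(rep_grade[main & grp == "mutant"])), c(12L, 19L, 13L))
  expect_equal(as.vector(table(rep_grade[main & grp == "wild"])), c(9L, 3L, 2L))
  # controls matched on age and sex to the main-analysis MMD subjects
  expect_equal(sort(s$age[grp == "control"]), sort(s$age[main]))
  expect_equal(sum(s$sex[grp == "control"] == "female"),
               sum(s$sex[main] == "female"))
})

test_that("measured vessels agree with the generator's truth table", {
  co <- simulate_cohort(small_config(seed = 6))
  for (i in sample(nrow(co$truth), 10)) {
    tr <- co$truth[i, ]
    fs <- co$fiducials[[paste0(tr$subject_id, "_", tr$side)]]
    m <- measure_vessel(fs)
    expect_equal(unname(m$seg_lengths),
                 as.numeric(tr[c("v12", "v23", "v34", "v45", "v56")]),
                 tolerance = 1e-9)
    expect_equal(unname(m$angles),
                 as.numeric(tr[c("a123", "a234", "a345", "a456")]),
                 tolerance = 1e-9)
  }
})

test_that("left vessels are mirror images with identical morphometry distribution", {
  co <- simulate_cohort(small_config(seed = 7, full_flow = FALSE))
  v <- measure_cohort(co)
  # right vessels anchored on the +x (right) side, left on -x
  for (key in names(co$fiducials)) {
    x1 <- co$fiducials[[key]]$points[1, 1]
    if (grepl("_right$", key)) expect_gt(x1, 0) else expect_lt(x1, 0)
  }
  # left/right marginals share the same generator: summaries agree loosely
  expect_lt(abs(median(v$tortuosity[v$side == "left"]) -
                median(v$tortuosity[v$side == "right"])), 15)
})

test_that("invalid generator targets are rejected", {
  tg <- .default_targets
  tg$mutant[6, ] <- c(190, 185, 195)
  expect_error(generator_config(targets = tg), "\\(0, 180\\)")
  tg <- .default_targets
  tg$wild[2, "q1"] <- 25    # q1 above the median
  expect_error(generator_config(targets = tg), "q1 <= median")
  expect_error(generator_config(suzuki_counts = list(mutant = c("2" = 1),
                                                     wild = c("2" = 14))),
               "sum to the group size")
})

test_that("cohort medians land inside the published IQR bands for most parameters", {
  # IQR bands for the derived whole-vessel quantities per group
  bands <- list(
    alen = list(mutant = c(50.38, 58.41), wild = c(56.20, 61.00),
                control = c(58.43, 67.06)),
    llen = list(mutant = c(40.40, 43.54), wild = c(40.91, 44.07),
                control = c(40.38, 43.87)),
    tortuosity = list(mutant = c(21.51, 35.58), wild = c(31.36, 42.57),
                      control = c(43.04, 59.21)),
    total_angle = list(mutant = c(213.20, 283.53), wild = c(277.78, 315.11),
                       control = c(279.75, 352.10)))
  cfg <- generator_config(seed = 314, full_flow = FALSE)
  co <- simulate_cohort(cfg)
  tab <- subject_morphometry(co$subjects, measure_cohort(co))
  inside <- 0; total <- 0
  par_names <- morphometry_parameters()
  for (g in c("mutant", "wild", "control")) {
    med <- vapply(par_names, function(p) median(tab[[p]][tab$group == g]),
                  numeric(1))
    tg <- .default_targets[[g]]
    for (i in 1:9) {   # directly calibrated segment lengths and angles
      total <- total + 1
      inside <- inside + (med[[rownames(tg)[i]]] >= tg[i, "q1"] &&
                          med[[rownames(tg)[i]]] <= tg[i, "q3"])
    }
    for (p in names(bands)) {     # derived quantities
      total <- total + 1
      b <- bands[[p]][[g]]
      inside <- inside + (med[[p]] >= b[1] && med[[p]] <= b[2])
    }
  }
  expect_equal(total, 39L)
  expect_gte(inside, 10L)
})
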