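# Nonparametric group-comparison battery: median/IQR descriptives,
# Fisher's exact test, Wilcoxon rank-sum (exact with midranks under ties),
# Kruskal-Wallis, Bonferroni correction, Lilliefors-style normality screen.

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (`stats::quantile` type 7). The reported IQRs of a cohort
#' table depend on this choice, so it is fixed and documented.
#'
#' @param values nonempty numeric vector (NAs dropped).
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("median_iqr: empty sample")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact p by the Freeman-Halton rule: the sum of the
#' probabilities, conditional on the margins, of all tables no more
#' probable than the observed one. Rows/columns whose margin is zero are
#' dropped first (an empty category cannot change the conditional
#' distribution). Tables too large for exact computation fall back to a
#' seeded Monte-Carlo estimate when `monte_carlo = TRUE`.
#'
#' @param table matrix of nonnegative integer counts, at least 2x2 after
#'   dropping empty margins.
#' @param monte_carlo use Monte-Carlo estimation (B tables) instead of
#'   exact enumeration; required above the exact bound (total n = 200).
#' @param B number of Monte-Carlo tables.
#' @return list with `p.value`, `method` (`"exact"` or `"monte_carlo"`),
#'   and for Monte-Carlo the standard error `se`.
#' @export
fisher_exact <- function(table, monte_carlo = FALSE, B = 1e5) {
  table <- as.matrix(table)
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    stop("fisher_exact: counts must be nonnegative integers")
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("fisher_exact: need at least 2 nonempty rows and columns")
  n <- sum(table)
  if (!monte_carlo && n > 200)
    stop("fisher_exact: table total ", n, " exceeds the exact bound (200); ",
         "use monte_carlo = TRUE")
  if (monte_carlo) {
    ft <- stats::fisher.test(table, simulate.p.value = TRUE, B = as.integer(B))
    p <- ft$p.value
    return(list(p.value = p, method = "monte_carlo",
                se = sqrt(p * (1 - p) / B)))
  }
  ft <- stats::fisher.test(table, workspace = 2e7)
  list(p.value = ft$p.value, method = "exact")
}

# Exact null distribution of the rank sum of a size-k subset of the
# (doubled, hence integer) midranks, by subset-sum dynamic programming.
# Returns counts over sums 0..S for exactly k chosen items.
rank_sum_counts <- function(ranks2, k) {
  S <- sum(ranks2)
  # dp[[j]] = count vector over sums for j chosen items (index 1 = sum 0)
  dp <- vector("list", k + 1L)
  dp[[1L]] <- c(1, numeric(S))
  for (j in seq_len(k)) dp[[j + 1L]] <- numeric(S + 1L)
  for (r in ranks2) {
    for (j in rev(seq_len(k))) {
      shifted <- c(numeric(r), dp[[j]][seq_len(S + 1L - r)])
      dp[[j + 1L]] <- dp[[j + 1L]] + shifted
    }
  }
  dp[[k + 1L]]
}

#' Wilcoxon rank-sum test with midranks
#'
#' Two-sided test that two samples come from the same distribution.
#' Ties receive midranks in both modes. When the combined size is at most
#' `exact_max` the p-value is exact: the permutation distribution of the
#' rank sum over all subsets is computed by dynamic programming (valid
#' under ties, where the classical no-tie tables do not apply). Larger
#' samples use the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param x,y nonempty numeric samples (NAs dropped).
#' @param exact_max combined-size bound for the exact mode.
#' @return list with `statistic` (rank sum W of `x`), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("wilcoxon_rank_sum: empty sample")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))                     # midranks
  W <- sum(r[seq_len(nx)])
  if (N <= exact_max) {
    ranks2 <- as.integer(round(2 * r))   # midranks are multiples of 1/2
    cnt <- rank_sum_counts(ranks2, nx)
    total <- sum(cnt)
    W2 <- as.integer(round(2 * W))
    sums <- seq_along(cnt) - 1L
    p_le <- sum(cnt[sums <= W2]) / total
    p_ge <- sum(cnt[sums >= W2]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)                        # all observations identical
    return(list(statistic = W, p.value = 1, method = "normal"))
  z <- W - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)   # continuity correction
  list(statistic = W, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Kruskal-Wallis rank test across k groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. A cohort in which every observation is
#' identical yields H = 0, p = 1.
#'
#' @param groups list of k >= 2 nonempty numeric samples.
#' @return list with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("kruskal_wallis: empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param m number of comparisons, at least `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("bonferroni: p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("bonferroni: m smaller than the number of tests")
  pmin(1, p_values * m)
}

# Lilliefors statistic: sup distance between the ECDF and the normal CDF
# with sample-estimated mean/sd.
lilliefors_D <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Kolmogorov-Smirnov normality screen (Lilliefors-calibrated)
#'
#' One-sample KS distance between the data and a normal distribution with
#' sample-estimated mean and standard deviation. Because the parameters
#' are estimated, the classical KS null distribution is wrong; the
#' p-value is calibrated by Monte-Carlo simulation of the same statistic
#' on normal samples of the same size (Lilliefors procedure). The screen
#' is advisory only: the analysis pipeline is nonparametric throughout
#' regardless of the verdict.
#'
#' @param x numeric sample, n >= 5.
#' @param B number of Monte-Carlo replicates.
#' @param alpha significance level for the verdict.
#' @return list with `statistic` (D), `p.value`, `verdict` (`"normal"`,
#'   `"non-normal"` or `"degenerate"`).
#' @export
ks_normality <- function(x, B = 1e4, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("ks_normality: need at least 5 observations")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, verdict = "degenerate"))
  D <- lilliefors_D(x)
  n <- length(x)
  sims <- matrix(stats::rnorm(n * B), nrow = n)
  Dnull <- apply(sims, 2, lilliefors_D)
  p <- (sum(Dnull >= D) + 1) / (B + 1)
  list(statistic = D, p.value = p,
       verdict = if (p < alpha) "non-normal" else "normal")
}

#' Three-group comparison table
#'
#' The cohort summary-and-test table: continuous variables are summarised
#' as median (IQR) per group and compared by the Kruskal-Wallis test;
#' when the overall p falls below `alpha` (or `always_pairwise = TRUE`),
#' pairwise Wilcoxon rank-sum tests with Bonferroni correction (m = 3)
#' are run for (mutant, wild), (mutant, control), (wild, control).
#' Categorical variables are summarised as count (percent) and compared
#' by Fisher's exact test; the Suzuki-grade row compares the mutant and
#' wild-type groups only, since controls carry no grade.
#'
#' @param table per-subject (or per-vessel) data.frame with a `group`
#'   column (`mutant`/`wild`/`control`) and the variables.
#' @param variables character vector of variable names; defaults to the
#'   cohort-table order: age, sex, Suzuki grade, then the morphometric
#'   parameters.
#' @param alpha significance level gating the pairwise tests.
#' @param always_pairwise run pairwise tests regardless of the overall p.
#' @return object of class `comparison_table`: list with `continuous`
#'   (data.frame: variable, per-group median/q1/q3, p_overall and pairwise
#'   adjusted p's), `categorical` (data.frame of per-level counts and the
#'   Fisher p), `alpha`, `groups` (group sizes).
#' @export
compare_groups <- function(table, variables = NULL, alpha = 0.05,
                           always_pairwise = FALSE) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  groups <- c("mutant", "wild", "control")
  present <- groups[groups %in% table$group]
  if (length(present) < 2L) stop("compare_groups: need at least 2 nonempty groups")
  if (is.null(variables))
    variables <- c(intersect(c("age", "sex"), names(table)),
                   if ("representative_suzuki" %in% names(table)) "suzuki",
                   intersect(morphometry_parameters(), names(table)))
  pairs <- list(c("mutant", "wild"), c("mutant", "control"), c("wild", "control"))

  cont <- list(); cat <- list()
  for (v in variables) {
    if (!(v %in% names(table)) && !v %in% c("suzuki", "representative_suzuki"))
      stop("compare_groups: unknown variable \"", v, "\"")
    if (v == "suzuki" || v == "representative_suzuki") {
      mw <- intersect(c("mutant", "wild"), present)
      g <- table$representative_suzuki[table$group %in% mw]
      lab <- factor(table$group[table$group %in% mw], levels = mw)
      keep <- !is.na(g)
      tab <- base::table(factor(g[keep]), lab[keep])
      p <- if (length(mw) == 2L && nrow(tab) >= 2L) fisher_exact(t(tab))$p.value else NA_real_
      for (lev in rownames(tab)) {
        counts <- setNames(rep(NA_real_, 3), paste0("n_", groups))
        pct <- setNames(rep(NA_real_, 3), paste0("pct_", groups))
        for (gr in mw) {
          counts[paste0("n_", gr)] <- tab[lev, gr]
          pct[paste0("pct_", gr)] <- 100 * tab[lev, gr] / sum(tab[, gr])
        }
        cat[[length(cat) + 1L]] <- data.frame(
          variable = "suzuki_grade", level = lev, t(counts), t(pct),
          p_overall = if (lev == rownames(tab)[1]) p else NA_real_,
          test = "fisher_exact", stringsAsFactors = FALSE)
      }
    } else if (!is.numeric(table[[v]])) {
      f <- factor(table[[v]])
      tab <- base::table(table$group, f)[present, , drop = FALSE]
      p <- fisher_exact(tab)$p.value
      lev <- colnames(tab)[1]           # report the first level (e.g. female)
      counts <- setNames(rep(NA_real_, 3), paste0("n_", groups))
      pct <- setNames(rep(NA_real_, 3), paste0("pct_", groups))
      for (gr in present) {
        counts[paste0("n_", gr)] <- tab[gr, lev]
        pct[paste0("pct_", gr)] <- 100 * tab[gr, lev] / sum(tab[gr, ])
      }
      cat[[length(cat) + 1L]] <- data.frame(
        variable = v, level = lev, t(counts), t(pct), p_overall = p,
        test = "fisher_exact", stringsAsFactors = FALSE)
    } else {
      samples <- lapply(present, function(gr) table[[v]][table$group == gr])
      names(samples) <- present
      kw <- kruskal_wallis(samples)
      row <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (gr in groups) {
        mi <- if (gr %in% present) median_iqr(samples[[gr]]) else
          c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
        row[paste0(c("median_", "q1_", "q3_"), gr)] <- as.list(unname(mi))
      }
      row$p_overall <- kw$p.value
      padj <- setNames(rep(NA_real_, 3), vapply(pairs, paste, "", collapse = "_"))
      if (kw$p.value < alpha || always_pairwise) {
        praw <- vapply(pairs, function(pr) {
          if (!all(pr %in% present)) return(NA_real_)
          wilcoxon_rank_sum(samples[[pr[1]]], samples[[pr[2]]])$p.value
        }, numeric(1))
        padj[!is.na(praw)] <- bonferroni(praw[!is.na(praw)], m = 3)
      }
      row[paste0("p_", names(padj))] <- as.list(unname(padj))
      row$test <- "kruskal_wallis"
      cont[[length(cont) + 1L]] <- row
    }
  }
  structure(list(
    continuous = if (length(cont)) do.call(rbind, cont) else NULL,
    categorical = if (length(cat)) do.call(rbind, cat) else NULL,
    alpha = alpha,
    groups = vapply(present, function(gr) sum(table$group == gr), integer(1))),
    class = "comparison_table")
}

#' Format a p-value for display
#'
#' Three decimals; values below 0.0005 print as `<0.001`.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 5e-4, "<0.001", sprintf("%.3f", p)))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Group comparison (n =",
      paste(paste0(names(x$groups), ":", x$groups), collapse = ", "), ")\n\n")
  fmt_mi <- function(m, q1, q3)
    ifelse(is.na(m), "", sprintf("%.2f (%.2f-%.2f)", m, q1, q3))
  if (!is.null(x$categorical)) {
    for (i in seq_len(nrow(x$categorical))) {
      r <- x$categorical[i, ]
      cells <- vapply(c("mutant", "wild", "control"), function(gr) {
        n <- r[[paste0("n_", gr)]]
        if (is.na(n)) "" else sprintf("%d (%.1f%%)", as.integer(n), r[[paste0("pct_", gr)]])
      }, "")
      cat(sprintf("%-22s %-16s %-16s %-16s %s\n",
                  paste(r$variable, r$level), cells[1], cells[2], cells[3],
                  format_pvalue(r$p_overall)))
    }
    cat("\n")
  }
  if (!is.null(x$continuous)) {
    cat(sprintf("%-14s %-22s %-22s %-22s %7s %11s %14s %12s\n", "variable",
                "mutant", "wild", "control", "overall", "mut/wild",
                "mut/control", "wild/control"))
    for (i in seq_len(nrow(x$continuous))) {
      r <- x$continuous[i, ]
      cat(sprintf("%-14s %-22s %-22s %-22s %7s %11s %14s %12s\n", r$variable,
                  fmt_mi(r$median_mutant, r$q1_mutant, r$q3_mutant),
                  fmt_mi(r$median_wild, r$q1_wild, r$q3_wild),
                  fmt_mi(r$median_control, r$q1_control, r$q3_control),
                  format_pvalue(r$p_overall),
                  format_pvalue(r$p_mutant_wild),
                  format_pvalue(r$p_mutant_control),
                  format_pvalue(r$p_wild_control)))
    }
  }
  invisible(x)
}

#' Tortuosity and total angle across Suzuki grades
#'
#' Per-grade median/IQR of tortuosity and total angle among MMD subjects
#' with a representative grade, plus Wilcoxon rank-sum tests between each
#' pair of adjacent grades, starred at 0.05 (*) and 0.01 (**).
#'
#' @param table per-subject data.frame with `representative_suzuki`,
#'   `tortuosity` and `total_angle` columns.
#' @param variables variables to summarise and test.
#' @return list with `summaries` (per grade x variable median/q1/q3/n)
#'   and `tests` (adjacent-pair Wilcoxon p's with significance stars;
#'   pairs where either grade has fewer than 2 subjects are skipped with
#'   a warning).
#' @export
suzuki_trend <- function(table, variables = c("tortuosity", "total_angle")) {
  stopifnot(is.data.frame(table), "representative_suzuki" %in% names(table))
  tab <- table[!is.na(table$representative_suzuki), , drop = FALSE]
  if (nrow(tab) == 0L) stop("suzuki_trend: no graded subjects")
  grades <- sort(unique(tab$representative_suzuki))
  summaries <- do.call(rbind, lapply(grades, function(g) {
    sub <- tab[tab$representative_suzuki == g, , drop = FALSE]
    do.call(rbind, lapply(variables, function(v) {
      mi <- median_iqr(sub[[v]])
      data.frame(grade = g, variable = v, n = nrow(sub),
                 median = mi[["median"]], q1 = mi[["q1"]], q3 = mi[["q3"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (length(grades) >= 2L) {
    adj <- cbind(grades[-length(grades)], grades[-1])
    tests <- do.call(rbind, lapply(seq_len(nrow(adj)), function(i) {
      g1 <- adj[i, 1]; g2 <- adj[i, 2]
      do.call(rbind, lapply(variables, function(v) {
        x <- tab[[v]][tab$representative_suzuki == g1]
        y <- tab[[v]][tab$representative_suzuki == g2]
        if (length(x) < 2L || length(y) < 2L) {
          warning("adjacent-grade test ", g1, " vs ", g2,
                  " skipped: fewer than 2 subjects in a grade")
          return(data.frame(grade_low = g1, grade_high = g2, variable = v,
                            p.value = NA_real_, signif = "",
                            stringsAsFactors = FALSE))
        }
        p <- wilcoxon_rank_sum(x, y)$p.value
        data.frame(grade_low = g1, grade_high = g2, variable = v, p.value = p,
                   signif = if (is.na(p)) "" else if (p < 0.01) "**"
                            else if (p < 0.05) "*" else "ns",
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(summaries = summaries, tests = tests)
}
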