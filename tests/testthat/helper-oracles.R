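# Independent oracles used across the suite. These are deliberately coded
# from first principles (cross products, explicit enumeration) and share no
# code path with the package implementation.

# --- geometry -------------------------------------------------------------

# Angle via atan2(|a x b|, a.b) — numerically independent of the acos route.
oracle_angle <- function(a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

# Formula-by-formula vessel measurement from a 6x3 point matrix.
oracle_measure <- function(p) {
  segs <- lapply(1:5, function(i) p[i + 1, ] - p[i, ])
  lens <- vapply(segs, function(v) sqrt(sum(v^2)), numeric(1))
  angs <- vapply(1:4, function(i) oracle_angle(segs[[i]], segs[[i + 1]]), numeric(1))
  alen <- sum(lens)
  llen <- sqrt(sum((p[6, ] - p[1, ])^2))
  list(seg_lengths = lens, angles = angs, alen = alen, llen = llen,
       tortuosity = (alen - llen) / llen * 100, total_angle = sum(angs))
}

# Random well-separated six-point chain (random walk, steps 5-20 mm).
random_points <- function() {
  p <- matrix(0, 6, 3)
  p[1, ] <- runif(3, -30, 30)
  for (i in 2:6) {
    step <- rnorm(3)
    step <- step / sqrt(sum(step^2)) * runif(1, 5, 20)
    p[i, ] <- p[i - 1, ] + step
  }
  if (sqrt(sum((p[6, ] - p[1, ])^2)) < 1) return(random_points())
  p
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- statistics -----------------------------------------------------------

# Freeman-Halton exact p by full recursive enumeration of tables with the
# observed margins. Probability of a table conditional on margins is
# multivariate hypergeometric; "as or less probable" uses the conventional
# (1 + 1e-7) relative slack for floating-point ties.
oracle_fisher <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logprob <- function(m)
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) - sum(lgamma(m + 1))
  p_obs <- exp(logprob(tab))
  total <- 0
  recurse <- function(m, r, c) {
    # fill row r, column c with all feasible values
    if (r == nrow(tab)) {
      # last row forced by column margins
      m[r, ] <- cs - colSums(m[-r, , drop = FALSE])
      if (any(m[r, ] < 0)) return(invisible(NULL))
      p <- exp(logprob(m))
      if (p <= p_obs * (1 + 1e-7)) total <<- total + p
      return(invisible(NULL))
    }
    if (c == ncol(tab)) {
      m[r, c] <- rs[r] - sum(m[r, -c])
      if (m[r, c] < 0) return(invisible(NULL))
      if (sum(m[, c]) > cs[c]) return(invisible(NULL))
      return(recurse(m, r + 1, 1))
    }
    free_col <- cs[c] - sum(m[seq_len(r - 1), c])
    free_row <- rs[r] - sum(m[r, seq_len(c - 1)])
    for (v in 0:min(free_col, free_row)) {
      m[r, c] <- v
      recurse(m, r, c + 1)
    }
  }
  recurse(matrix(0L, nrow(tab), ncol(tab)), 1, 1)
  min(1, total)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every subset of the
# combined midranks (the same two-sided convention as the implementation:
# doubled minimal tail, capped at 1).
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  sums <- combn(N, nx, function(idx) sum(r[idx]))
  p_le <- mean(sums <= W + 1e-9)
  p_ge <- mean(sums >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Tie-corrected Kruskal-Wallis H from the textbook formula.
oracle_kw_H <- function(groups) {
  N <- sum(lengths(groups))
  r <- rank(unlist(groups))
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), numeric(1))) -
    3 * (N + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# --- cohorts --------------------------------------------------------------

# Small generator for fast pipeline tests.
small_config <- function(seed = 1, ...) {
  generator_config(
    n = c(mutant = 10, wild = 6, control = 10),
    n_female = c(mutant = 6, wild = 3, control = 6),
    suzuki_counts = list(mutant = c("2" = 3, "3" = 4, "4" = 3),
                         wild = c("2" = 3, "3" = 2, "4" = 1)),
    n_grade15 = 2, n_flagged = 4,
    seed = seed, ...)
}
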