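# Small-sample statistical primitives: exact one-tailed Fisher,
# Benjamini-Hochberg adjustment, exact Wilcoxon signed-rank, Spearman
# correlation with exact small-n p, Shapiro-Wilk normality gate, and the
# Bonferroni threshold.

not_testable <- function(...) {
  abort(sprintf(...), class = "drawmetry_not_testable")
}

new_drawmetry_test <- function(test, ...) {
  structure(c(list(test = test), list(...)), class = "drawmetry_test")
}

#' @export
print.drawmetry_test <- function(x, ...) {
  cat(sprintf("<%s>\n", x$test))
  for (f in setdiff(names(x), "test")) {
    v <- x[[f]]
    if (is.numeric(v)) v <- format(v, digits = 6)
    cat(sprintf("  %s: %s\n", f, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.drawmetry_test <- function(x, ...) {
  scalars <- x[vapply(x, function(v) length(v) == 1L && is.atomic(v), TRUE)]
  as_tibble(scalars)
}

#' @export
glance.drawmetry_test <- function(x, ...) tidy(x, ...)

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability for the top-left cell of a 2x2
#' count table, conditioning on the margins. With rows = groups and columns
#' = (present, absent), `direction = "greater"` tests whether the first
#' row's feature prevalence exceeds the second row's.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param direction `"greater"` (upper tail on `table[1,1]`) or `"less"`.
#' @return The exact p-value, in `(0, 1]`.
#' @export
fisher_exact_one_tailed <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("table must be 2x2")
  if (any(is.na(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8)) {
    abort("table cells must be non-negative integers")
  }
  table <- round(table)
  m <- sum(table[, 1])  # first-column margin
  n <- sum(table[, 2])
  k <- sum(table[1, ])  # first-row margin
  a <- table[1, 1]
  if (direction == "greater") {
    phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    phyper(a, m, n, k, lower.tail = TRUE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, order-preserving with the
#' input, each in `[0, 1]` and never below its raw p.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# exact null distribution of the positive-rank sum statistic W for (possibly
# midranked) ranks r: probabilities over the doubled support 0..sum(2r)
wilcoxon_w_distribution <- function(r) {
  s <- as.integer(round(2 * r))
  total <- sum(s)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (si in s) {
    shifted <- c(numeric(si), f[seq_len(total + 1L - si)])
    f <- f + shifted
  }
  f / 2^length(s)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are discarded before ranking (Wilcoxon's
#' original policy) and ties among absolute differences receive midranks.
#' For `n_effective <= exact_n_max` (default 25) the two-sided p-value is
#' exact — the null distribution of the positive-rank sum W over all
#' 2^n sign assignments, `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. For
#' larger samples a normal approximation with continuity correction and a
#' tie-corrected variance is used, and the reported `z` matches that
#' approximation.
#'
#' @param x,y Paired numeric vectors; or a vector of differences in `x` with
#'   `y = NULL`.
#' @param alpha Significance threshold recorded in the report.
#' @param exact_n_max Largest `n_effective` for which the exact p is used.
#' @return A `drawmetry_test` object with fields `n_effective`, `statistic`
#'   (W), `z`, `p_value`, `alpha_threshold`, `significant`
#'   (`p_value < alpha_threshold`), and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, alpha = 0.05, exact_n_max = 25L) {
  if (is.null(y)) {
    d <- x
  } else {
    if (length(x) != length(y)) abort("x and y must have equal length")
    d <- x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    not_testable("all paired differences are zero; nothing to test")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_counts <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_counts^3 - tie_counts) / 48
  sigma <- sqrt(sigma2)

  if (n <= exact_n_max) {
    f <- wilcoxon_w_distribution(r)
    wsc <- as.integer(round(2 * W))
    p_lo <- sum(f[seq_len(wsc + 1L)])
    p_hi <- sum(f[(wsc + 1L):length(f)])
    p <- min(1, 2 * min(p_lo, p_hi))
    z <- if (sigma > 0) (W - mu) / sigma else 0
    method <- "exact"
  } else {
    cc <- 0.5 * sign(W - mu)
    z <- if (sigma > 0) (W - mu - cc) / sigma else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  new_drawmetry_test(
    "wilcoxon_signed_rank",
    n_effective = n, statistic = W, z = z, p_value = p,
    alpha_threshold = alpha, significant = p < alpha, method = method
  )
}

# all permutations of 1..n as an n!-row matrix (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of midranked data. For `n <= exact_n_max`
#' (default 8) the two-sided p-value is exact: the proportion of all n!
#' permutations of one variable whose |rho| is at least the observed |rho|.
#' Larger samples use the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; pairs with `NA` in
#'   either coordinate are dropped.
#' @param exact_n_max Largest n for which the permutation-exact p is used.
#' @return A `drawmetry_test` object with fields `rho`, `p_value`,
#'   `n_pairs`, `method`.
#' @export
spearman_corr <- function(x, y, exact_n_max = 8L) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) not_testable("need at least 3 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0) {
    not_testable("rho is undefined for a constant sequence")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)

  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    sums <- matrix(ry[perms], nrow(perms)) %*% rx
    rho_all <- (sums / n - mean(rx) * mean(ry)) * n / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "permutation exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  new_drawmetry_test("spearman_correlation",
                     rho = rho, p_value = p, n_pairs = n, method = method)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and flags whether downstream analyses should
#' fall back to nonparametric tests: `use_nonparametric = (p < alpha)`, i.e.
#' evidence against normality routes to rank-based tests.
#'
#' @param x Numeric vector, `3 <= n <= 5000`, non-constant.
#' @param alpha Gate level (default 0.05).
#' @return A one-row tibble: `W`, `p_value`, `n`, `use_nonparametric`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    not_testable("Shapiro-Wilk needs 3 <= n <= 5000 (got %d)", n)
  }
  if (sd(x) == 0) not_testable("constant sequence is not testable")
  st <- shapiro.test(x)
  tibble(W = unname(st$statistic), p_value = st$p.value, n = n,
         use_nonparametric = st$p.value < alpha)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' @param family_alpha Family-wise error rate, in `(0, 1)`.
#' @param m Number of comparisons, `>= 1`.
#' @return `family_alpha / m`.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, m = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 ||
      abs(m - round(m)) > 1e-8) {
    abort("m must be a positive integer")
  }
  if (!is.numeric(family_alpha) || length(family_alpha) != 1L ||
      family_alpha <= 0 || family_alpha >= 1) {
    abort("family_alpha must lie in (0, 1)")
  }
  family_alpha / round(m)
}
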