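# Independent brute-force oracles for the exact tests. These deliberately
# avoid the package's code paths: direct enumeration with choose(), explicit
# 2^n sign patterns, and Heap's algorithm permutations scored with cor().

# one-tailed Fisher p by enumerating every table with the observed margins
oracle_fisher_p <- function(tab, direction = "greater") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, support) * choose(n - c1, r1 - support) / choose(n, r1)
  if (direction == "greater") sum(probs[support >= a]) else sum(probs[support <= a])
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# all permutations of 1..n via Heap's algorithm (iterative)
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  out[1, ] <- a
  c_ <- integer(n)
  i <- 1L; row <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# exact two-sided permutation p for Spearman's rho
oracle_spearman_p <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  perms <- heap_permutations(length(y))
  rhos <- apply(perms, 1, function(idx) cor(x, y[idx], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# textbook step-up BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
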