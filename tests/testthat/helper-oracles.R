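# Independent brute-force / closed-form oracles shared across test files.

wpli_naive <- function(d) {
  num <- 0; den <- 0
  for (x in d) {
    s <- sin(x)
    num <- num + abs(s) * sign(s)
    den <- den + abs(s)
  }
  if (den == 0) 0 else abs(num / length(d)) / (den / length(d))
}

plv_naive <- function(d) {
  re <- 0; im <- 0
  for (x in d) { re <- re + cos(x); im <- im + sin(x) }
  sqrt(re^2 + im^2) / length(d)
}

friedman_oracle <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  rs <- colSums(r)
  12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

welch_df_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
}

paired_t_oracle <- function(d) {
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p_less = pt(tt, n - 1))
}

# Exact two-sided signed-rank p by enumeration (no ties/zeros assumed).
wilcoxon_enum_oracle <- function(d) {
  n <- length(d)
  ranks <- rank(abs(d))
  sums <- sapply(0:(2^n - 1), function(mask) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    sum(ranks[sel])
  })
  W <- min(sum(ranks[d > 0]), sum(ranks[d < 0]))
  list(W = W, p = min(1, 2 * mean(sums <= W)))
}
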