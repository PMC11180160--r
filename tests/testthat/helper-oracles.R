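# independent hand-rolled oracles used to cross-check the implementation

# plain-formula Pearson goodness-of-fit (independent of chisq.test)
hand_gof <- function(observed, ratio) {
  e <- sum(observed) * ratio / sum(ratio)
  stat <- sum((observed - e)^2 / e)
  list(statistic = stat, df = length(observed) - 1L,
       p_value = pchisq(stat, length(observed) - 1L, lower.tail = FALSE))
}

# pairwise Jaccard distance by explicit a/b/c counting
hand_jaccard <- function(x, y) {
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  if (a + b + c == 0) return(NA_real_)
  1 - a / (a + b + c)
}

# canonical (left-aligned) form of a known clean deletion interval:
# shift left while the base before the deletion equals the last deleted base
left_align_interval <- function(ref_seq, interval) {
  a <- interval[1]; b <- interval[2] # 0-based half-open
  while (a > 0 && substr(ref_seq, a, a) == substr(ref_seq, b, b)) {
    a <- a - 1; b <- b - 1
  }
  c(a, b)
}

# naive per-base depth by looping over reads
hand_depth <- function(starts, ends, n) {
  d <- integer(n)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):ends[i]
    d[idx] <- d[idx] + 1L
  }
  d
}
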