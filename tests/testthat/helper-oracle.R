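# Independent brute-force oracle for the rank-sum test: enumerate every
# assignment of group labels to the pooled observations and read the
# permutation p-value off the resulting U distribution.
enum_ranksum <- function(x, y,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  eps <- 1e-9
  lo <- mean(us <= u_obs + eps)
  hi <- mean(us >= u_obs - eps)
  switch(alternative,
         less = lo, greater = hi, two.sided = min(1, 2 * min(lo, hi)))
}
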