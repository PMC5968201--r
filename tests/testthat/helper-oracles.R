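# Brute-force rank-sum oracle: enumerates every labeling of the pooled
# observations and scores each with the Mann-Whitney U statistic computed
# from pairwise comparisons (ties count one half). Independent of the
# implementation, which works on mid-rank sums.
oracle_rank_sum_p <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  p_greater <- mean(u_all >= u_obs - eps)
  p_less <- mean(u_all <= u_obs + eps)
  switch(alternative,
         two_sided = min(1, 2 * min(p_less, p_greater)),
         less = p_less,
         greater = p_greater)
}
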