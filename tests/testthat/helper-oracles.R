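# Independent brute-force oracles used across the suite. These stay naive
# on purpose: enumeration and per-base averaging, no shared code with R/.

# Per-base average copy number over [arm_start, arm_end) minus exclusions,
# by explicit enumeration of integer positions (tiny coordinates only).
oracle_arm_index <- function(start, end, cn, arm_start, arm_end,
                             excl_start = numeric(), excl_end = numeric()) {
  pos <- seq.int(arm_start, arm_end - 1L)
  keep <- rep(TRUE, length(pos))
  for (i in seq_along(excl_start))
    keep <- keep & !(pos >= excl_start[i] & pos < excl_end[i])
  pos <- pos[keep]
  val <- rep(NA_real_, length(pos))
  for (i in seq_along(start)) {
    inside <- pos >= start[i] & pos < end[i]
    val[inside] <- cn[i]
  }
  covered <- !is.na(val)
  list(index = if (any(covered)) mean(val[covered]) else NA_real_,
       covered_fraction = mean(covered))
}

# Two-sided Fisher p for a 2x2 table by explicit enumeration of every table
# with the observed margins, probabilities via choose() products.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- pr[match(tab[1, 1], ks)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by summation of choose() products.
oracle_hyper_tail <- function(k, K, n, N) {
  is <- k:min(n, K)
  sum(vapply(is, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
}

# Small deterministic random genome + segments for oracle comparisons.
random_genome_case <- function() {
  n_arms <- sample(2:5, 1)
  arm_len <- sample(50:200, n_arms, replace = TRUE)
  gaps <- sample(0:20, max(n_arms - 1, 1), replace = TRUE)
  starts <- cumsum(c(0, head(arm_len, -1) + gaps[seq_len(n_arms - 1)]))
  arms <- data.frame(arm_start = starts, arm_end = starts + arm_len)
  n_seg <- sample(1:20, 1)
  lo <- sample.int(max(arms$arm_end) + 20, n_seg) - 10L
  len <- sample(5:80, n_seg, replace = TRUE)
  # disjoint-ify crudely by sorting and clipping
  o <- order(lo); lo <- lo[o]; hi <- lo + len[o]
  hi <- pmin(hi, c(lo[-1], max(hi)))
  keep <- hi > lo
  data_seg <- data.frame(start = pmax(0L, lo[keep]), end = hi[keep],
                         cn = round(runif(sum(keep), 0, 4), 3))
  data_seg <- data_seg[data_seg$end > data_seg$start, ]
  list(arms = arms, segments = data_seg)
}

# Shared small cohort bundle, built once per test run.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_config(
        n_samples = 120, n_genes = 400, n_immune_genes = 40,
        n_redox_genes = 20, seed = 42))
    cache
  }
})
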