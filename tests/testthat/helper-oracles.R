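# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-apply the stated rules literally and share no code
# with the package internals.

# consensus: count every base, apply the family-size and strict-majority
# rules as written
oracle_consensus <- function(bases, quals, min_family_size = 3, max_qual = 40) {
  n <- length(bases)
  if (n < min_family_size) return(NULL)
  best <- ""
  best_count <- -1L
  for (b in unique(bases)) {
    cnt <- sum(bases == b)
    if (cnt > best_count) {
      best <- b
      best_count <- cnt
    }
  }
  if (best_count > n / 2) {
    q <- mean(quals[bases == best])
    q <- floor(q + 0.5)
    list(base = best, qual = as.integer(min(max_qual, q)), family_size = n)
  } else {
    list(base = "N", qual = 0L, family_size = n)
  }
}

# AUC: explicit comparison of every (disease, control) score pair, ties half
oracle_auc <- function(scores, disease) {
  pos <- scores[disease]
  neg <- scores[!disease]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}

# exact one-sided Mann-Whitney p-value by enumeration of group assignments
oracle_rank_sum_p <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  r_obs <- sum(rank(pooled)[seq_along(a)])
  combos <- utils::combn(n, length(a))
  stats_all <- apply(combos, 2, function(i) sum(rank(pooled)[i]))
  mean(stats_all <= r_obs)
}

# analytic probability that one sample is called positive at `threshold`,
# for a lognormal true-VAF distribution observed through Poisson depth and
# binomial sampling (Monte Carlo integration over the generating model;
# independent of the simulation code path)
oracle_detection_prob <- function(vaf_median, vaf_logsd, prevalence,
                                  depth_mean, per_base_error,
                                  threshold = 0.02, n_mc = 2e5) {
  v <- pmin(1, stats::rlnorm(n_mc, log(vaf_median), vaf_logsd))
  d <- stats::rpois(n_mc, depth_mean)
  p <- v + per_base_error / 3 * (1 - v)
  det <- stats::pbinom(floor(threshold * d), d, p, lower.tail = FALSE)
  prevalence * mean(det)
}

random_family <- function(max_size = 8) {
  n <- sample.int(max_size, 1)
  list(bases = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
       quals = sample(10:45, n, replace = TRUE))
}

# training vector engineered so thresholds (1%, 1.5%, 2%) give specificities
# (68%, 86%, 90%): of 50 samples, 34 at/below 1%, 9 in (1, 1.5], 2 in
# (1.5, 2], 5 above 2%
engineered_training <- function() {
  c(rep(0.002, 30), rep(0.01, 4), rep(0.013, 9), rep(0.02, 2),
    rep(0.035, 5))
}

tiny_panel <- function() {
  hotspot_panel(data.frame(
    gene = c("TBC1D12", "WDR74", "PLEKHS1"),
    chrom = c("chr10", "chr11", "chr10"),
    pos = c(96162368L, 62609254L, 115511590L),
    ref = c("C", "G", "G"),
    alt = c("T", "A", "A")
  ))
}
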