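# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths (and the stats:: routines) that
# the package itself calls.

# Two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    gx <- pooled[idx]
    gy <- pooled[-idx]
    sum(outer(gx, gy, ">")) + 0.5 * sum(outer(gx, gy, "=="))
  }
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(nx))
  mid <- nx * (n - nx) / 2
  p <- if (u_obs <= mid) 2 * mean(us <= u_obs) else 2 * mean(us >= u_obs)
  min(1, p)
}

# Kruskal-Wallis H from first principles (midranks, tie correction).
kw_hand_h <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  n <- length(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rsums <- mapply(function(s, e) sum(r[s:e]), starts, ends)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / sizes) - 3 * (n + 1)
  tie_sizes <- table(pooled)
  h / (1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n))
}

# KS one-sample statistic against a fitted normal, by direct ECDF sweep.
ks_sweep_stat <- function(x) {
  n <- length(x)
  s <- sort(x)
  fx <- pnorm(s, mean(x), sd(x))
  max(pmax(seq_len(n) / n - fx, fx - (seq_len(n) - 1) / n))
}

# Exhaustive order-statistic CI search: the narrowest pair (l, u) with
# binomial coverage sum(dbinom(l:(u-1))) >= conf, ties broken toward equal
# tails then smaller l. Plain double loop, independent of the package's
# vectorized search.
rank_ci_enum <- function(n, p, conf) {
  best <- NULL
  for (l in 1:(n - 1)) {
    for (u in (l + 1):n) {
      cov <- sum(dbinom(l:(u - 1), n, p))
      if (cov >= conf) {
        bal <- abs(pbinom(l - 1, n, p) - (1 - pbinom(u - 1, n, p)))
        cand <- list(l = l, u = u, w = u - l, bal = bal)
        if (is.null(best) || cand$w < best$w ||
            (cand$w == best$w && cand$bal < best$bal - 1e-12) ||
            (cand$w == best$w && abs(cand$bal - best$bal) <= 1e-12 &&
               cand$l < best$l)) {
          best <- cand
        }
      }
    }
  }
  best
}

# Percentile by sorting and linear interpolation at rank p*(n+1), written
# independently of value_at_rank().
sort_interp_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  r <- min(max(p * (n + 1), 1), n)
  f <- floor(r)
  c <- ceiling(r)
  if (f == c) s[f] else s[f] * (c - r) + s[c] * (r - f)
}

# Cohort with zero random ineligibility whose first k records per partition
# are made serology-positive, reproducing a chosen exclusion pattern.
make_flow_cohort <- function(excluded = c(T1 = 14, T2 = 20, T3 = 19,
                                          NP = 14),
                             n_per_partition = 150, seed = 20190601) {
  cfg <- cohort_config(n_per_partition = n_per_partition,
                       ineligible_fraction = 0, outlier_rate = 0,
                       random_seed = seed)
  cohort <- generate_study(cfg)
  for (p in names(excluded)) {
    rows <- which(cohort$partition == p)[seq_len(excluded[[p]])]
    cohort$hbsag[rows] <- TRUE
  }
  cohort
}
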