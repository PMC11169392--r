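# Independent oracles used across the suite. These deliberately recompute
# quantities by the most direct brute-force route (per-base loops, full
# enumeration) so they share no code with the package implementations.

# Per-base pileup: count reads covering each position of [start, end).
oracle_mean_depth <- function(reads, contig, start, end) {
  rd <- reads[reads$contig == contig, , drop = FALSE]
  depth <- vapply(start:(end - 1L), function(p) {
    sum(rd$start <= p & rd$start + rd$width > p)
  }, numeric(1))
  mean(depth)
}

# Sigma-ratio regional methylation with explicit loops.
oracle_region_meth <- function(records, start, end, min_coverage,
                               weighting = "coverage") {
  m_tot <- 0; cov_tot <- 0; fracs <- c(); used <- integer(0)
  for (i in seq_len(nrow(records))) {
    p <- records$pos[i]
    if (p >= start && p < end) {
      cov <- records$methylated[i] + records$unmethylated[i]
      if (cov >= min_coverage) {
        m_tot <- m_tot + records$methylated[i]
        cov_tot <- cov_tot + cov
        fracs <- c(fracs, records$methylated[i] / cov)
        used <- c(used, i)
      }
    }
  }
  list(mean = if (!length(used)) NA_real_
       else if (weighting == "coverage") m_tot / cov_tot else mean(fracs),
       used = used)
}

# Full-enumeration Spearman permutation p using plain loops and cor().
oracle_spearman_p <- function(x, y) {
  r_obs <- cor(rank(x), rank(y))
  perms <- ribocn:::all_permutations(length(y))
  hits <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(cor(rank(x), rank(y)[perms[i, ]])) >= abs(r_obs) - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / nrow(perms)
}

# Exact Mann-Whitney p by enumerating every group assignment.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  ranks <- rank(c(x, y))
  U_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(N, n1)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    U <- sum(ranks[combs[, j]]) - n1 * (n1 + 1) / 2
    if (abs(U - mu) >= abs(U_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combs)
}

# Exact signed-rank p by enumerating every sign assignment.
oracle_wsr_p <- function(x, y) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    W <- sum(r[bits == 1L])
    if (abs(W - mu) >= abs(W_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cpg_table <- function(n, contig = "rDNA_looped", max_pos = 2000L) {
  pos <- sort(sample.int(max_pos, n)) - 1L
  cov <- rpois(n, 60)
  meth <- rbinom(n, cov, runif(n))
  data.frame(contig = contig, pos = pos, methylated = meth,
             unmethylated = cov - meth, stringsAsFactors = FALSE)
}
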