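# Independent oracles used to cross-check the package's statistics.

# Pearson chi-square on a 2x2 table through stats::chisq.test (independent
# of the package's closed-form implementation).
oracle_chi2_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

# Naive quadratic Benjamini-Hochberg step-up: the adjusted value of p_i is
# min over all sorted positions t with p_(t) >= p_i of m * p_(t) / t,
# capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    vals <- m * ps / seq_len(m)
    min(1, vals[ps >= pi])
  }, 0)
}

# Exact hypergeometric upper tail by direct summation of choose() terms in
# log space.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Strain-summed per-site counts computed independently of the package's
# internal reshaping (simple aggregate over the long table).
reshape_counts_wide_oracle <- function(counts) {
  agg <- aggregate(cbind(ref_count, alt_count) ~ chrom + pos + strain,
                   counts, sum)
  r <- agg[agg$strain == "R", ]
  s <- agg[agg$strain == "S", ]
  m <- match(paste(r$chrom, r$pos), paste(s$chrom, s$pos))
  data.frame(chrom = r$chrom, pos = r$pos,
             ref_R = r$ref_count, alt_R = r$alt_count,
             ref_S = s$ref_count[m], alt_S = s$alt_count[m])
}

# Random 2x2 count tables with positive row totals.
random_2x2 <- function(max_count = 200) {
  repeat {
    m <- matrix(sample(0:max_count, 4, replace = TRUE), 2)
    if (all(rowSums(m) > 0)) return(m)
  }
}

# Minimal readcounts file writer for parser tests (dialect: header +
# chrom, pos, ref, depth, base:count fields).
write_readcounts_file <- function(path, rows) {
  writeLines(c("chrom\tpos\tref\tdepth\tcounts", rows), path)
}

# A small site_counts data.frame built directly (2 libraries per strain).
# counts: list with one element per library id (R1, R2, S1, S2), each a
# length-2 c(ref, alt).
make_site <- function(chrom, pos, counts, ref = "A", alt = "G") {
  libs <- data.frame(library_id = c("R1", "R2", "S1", "S2"),
                     strain = c("R", "R", "S", "S"),
                     replicate = c(1L, 2L, 1L, 2L))
  do.call(rbind, lapply(seq_len(nrow(libs)), function(i) {
    ct <- counts[[libs$library_id[i]]]
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               library_id = libs$library_id[i], strain = libs$strain[i],
               replicate = libs$replicate[i],
               ref_count = ct[1], alt_count = ct[2], depth = sum(ct),
               multiallelic = FALSE)
  }))
}
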