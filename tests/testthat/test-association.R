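test_that("gene scores are depth-weighted means bounded by the site scores", {
  single <- gene_score(12.3, 500, "g", "chr1")
  expect_equal(single$weighted_score, 12.3)

  two <- gene_score(c(10, 20), c(100, 300), "g", "chr1")
  expect_equal(two$weighted_score, 17.5)

  uniform <- gene_score(c(10, 20), c(100, 300), "g", "chr1",
                        params = filter_params(weighting = "uniform"))
  expect_equal(uniform$weighted_score, 15)

  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    sc <- runif(n, 0, 30)
    dp <- sample(50:500, n, replace = TRUE)
    ws <- gene_score(sc, dp)$weighted_score
    expect_gte(ws, min(sc))
    expect_lte(ws, max(sc))
  }
})

default_genes <- function() {
  g <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(500, 1500),
                  name = c("geneA", "geneB"), kind = "gene")
  class(g) <- c("genomic_intervals", "data.frame")
  g
}

test_that("a gene whose only site is replicate-discordant is omitted and reported", {
  sites <- rbind(
    make_site("chr1", 200, list(R1 = c(90, 10), R2 = c(10, 90),
                                S1 = c(50, 50), S2 = c(50, 50))),
    make_site("chr1", 1200, list(R1 = c(80, 20), R2 = c(78, 22),
                                 S1 = c(30, 70), S2 = c(32, 68))))
  res <- run_association(sites, default_genes())
  expect_equal(res$site_table$status[res$site_table$pos == 200],
               "replicate_discordant")
  expect_false("geneA" %in% res$gene_table$gene_id)
  expect_true("geneA" %in% res$skipped_genes$gene_id)
  expect_equal(res$skipped_genes$reason[res$skipped_genes$gene_id == "geneA"],
               "no_passing_sites")
  expect_true("geneB" %in% res$gene_table$gene_id)
})

test_that("low-coverage sites are excluded from scores", {
  sites <- make_site("chr1", 200, list(R1 = c(10, 10), R2 = c(60, 40),
                                       S1 = c(50, 50), S2 = c(50, 50)))
  expect_warning(res <- run_association(sites, default_genes()),
                 "no site passed")
  expect_equal(res$site_table$status, "low_coverage")
  expect_false(res$success)
  expect_equal(nrow(res$gene_table), 0)
})

test_that("site scores are invariant to strain relabelling", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 10, sites_per_gene = 4, n_selected_sites = 5, delta_f = 0.6,
    sampling = "single_stage", seed = 15))
  res <- run_association(sim$counts, sim$genes)

  flipped <- sim$counts
  flipped$strain <- ifelse(flipped$strain == "R", "S", "R")
  flipped$library_id <- paste0(flipped$strain, flipped$replicate)
  res_f <- run_association(flipped, sim$genes)
  expect_equal(res$site_table$neg_log10_p, res_f$site_table$neg_log10_p)

  swapped <- sim$counts
  tmp <- swapped$ref_count
  swapped$ref_count <- swapped$alt_count
  swapped$alt_count <- tmp
  r2 <- swapped$ref; swapped$ref <- swapped$alt; swapped$alt <- r2
  res_s <- run_association(swapped, sim$genes)
  expect_equal(res$site_table$chi2, res_s$site_table$chi2)
})

test_that("a planted high-differentiation gene is recovered at rank 1", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 40, sites_per_gene = 3, depth_mean = 200,
    base_freq_sampler = function(n) rep(0.5, n),
    n_selected_sites = 4, delta_f = 0.8,
    sampling = "single_stage", seed = 23))
  res <- run_association(sim$counts, sim$genes)
  top <- res$gene_table[1, ]
  expect_equal(top$gene_id, "gene0001")
  expect_gte(top$weighted_score, 15)
  expect_true(top$passes_threshold)
  expect_true(top$bh_significant)
})

test_that("per-chromosome tallies sum to the genome-wide total", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 60, sites_per_gene = 4, n_selected_sites = 10, delta_f = 0.7,
    sampling = "single_stage", seed = 29))
  res <- run_association(sim$counts, sim$genes)
  expect_equal(sum(unlist(res$tallies$per_chromosome)), res$tallies$total)
  expect_equal(res$tallies$total, sum(res$gene_table$passes_threshold))
})

test_that("single-stage null sites are calibrated at the 5% level", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 150, sites_per_gene = 10, depth_mean = 100,
    n_selected_sites = 0, delta_f = 0, sampling = "single_stage", seed = 41))
  res <- run_association(sim$counts, sim$genes)
  p <- res$site_table$p[res$site_table$status == "pass"]
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("two-stage pooling is anti-conservative relative to single-stage", {
  frac_reject <- function(sampling) {
    sim <- simulate_pool_readcounts(pool_sim_params(
      n_genes = 150, sites_per_gene = 8, depth_mean = 150,
      n_selected_sites = 0, delta_f = 0, sampling = sampling, seed = 43))
    w <- reshape_counts_wide_oracle(sim$counts)
    p <- vapply(seq_len(nrow(w)), function(i) {
      if (w$alt_R[i] + w$alt_S[i] == 0) return(1)
      oracle_chi2_2x2(w$ref_R[i], w$alt_R[i], w$ref_S[i], w$alt_S[i])$p
    }, 0)
    mean(p < 0.05, na.rm = TRUE)
  }
  expect_gte(frac_reject("two_stage"), frac_reject("single_stage"))
})

test_that("the small-count Fisher fallback replaces the asymptotic p when asked", {
  sites <- make_site("chr1", 200, list(R1 = c(20, 2), R2 = c(21, 1),
                                       S1 = c(15, 7), S2 = c(16, 6)))
  asym <- run_association(sites, default_genes())
  exact <- run_association(sites, default_genes(),
                           filter_params(fisher_min_expected = 10))
  tab <- matrix(c(41, 3, 31, 13), 2, byrow = TRUE)
  expect_equal(exact$site_table$p, stats::fisher.test(tab)$p.value,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(asym$site_table$p, exact$site_table$p)))
})

test_that("the scan demands exactly two replicate libraries per strain", {
  sites <- make_site("chr1", 200, list(R1 = c(50, 50), R2 = c(50, 50),
                                       S1 = c(50, 50), S2 = c(50, 50)))
  three <- sites[sites$library_id != "S2", ]
  expect_error(run_association(three, default_genes()),
               class = "poolscan_validation_error")
})
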