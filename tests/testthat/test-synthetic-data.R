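test_that("the pool simulator is bit-identical under a fixed seed", {
  p <- pool_sim_params(n_genes = 20, sites_per_gene = 4, seed = 9)
  a <- simulate_pool_readcounts(p)
  b <- simulate_pool_readcounts(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("read counts conserve depth and truth marks the planted structure", {
  p <- pool_sim_params(n_genes = 30, sites_per_gene = 5,
                       n_selected_sites = 8, delta_f = 0.4, seed = 2)
  sim <- simulate_pool_readcounts(p)
  expect_true(all(sim$counts$ref_count + sim$counts$alt_count ==
                    sim$counts$depth))
  expect_equal(sum(sim$truth$selected), 8)
  # the planted pre-miRNA selected site
  planted <- sim$truth[sim$truth$selected & sim$truth$in_premirna, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$pos, 50888906)
  # selected sites differ by exactly delta_f, others not at all
  expect_equal(abs(sim$truth$f_R - sim$truth$f_S)[sim$truth$selected],
               rep(0.4, 8))
  expect_true(all(sim$truth$f_R[!sim$truth$selected] ==
                    sim$truth$f_S[!sim$truth$selected]))
  expect_true(all(sim$truth$f_R >= 0 & sim$truth$f_R <= 1))
  expect_true(all(sim$truth$f_S >= 0 & sim$truth$f_S <= 1))
})

test_that("a null simulation has equal strain frequencies everywhere", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 15, sites_per_gene = 3, n_selected_sites = 0, delta_f = 0,
    seed = 4))
  expect_true(all(sim$truth$f_R == sim$truth$f_S))
  expect_false(any(sim$truth$selected))
})

test_that("empirical allele frequencies converge to truth at extreme depth", {
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 40, sites_per_gene = 5, depth_mean = 10000,
    depth_dispersion = 1e6, n_selected_sites = 0,
    sampling = "single_stage", seed = 12))
  lib <- sim$counts[sim$counts$library_id == "R1", ]
  m <- match(paste(lib$chrom, lib$pos), paste(sim$truth$chrom, sim$truth$pos))
  emp <- lib$alt_count / lib$depth
  expect_lt(max(abs(emp - sim$truth$f_R[m])), 0.02)
})

test_that("two-stage pooling overdisperses replicate frequencies beyond read sampling", {
  # matched seeds: the only difference is the pool-sampling stage
  p2 <- pool_sim_params(n_genes = 250, sites_per_gene = 4, depth_mean = 200,
                        depth_dispersion = 1e6, n_selected_sites = 0,
                        sampling = "two_stage", seed = 31)
  p1 <- pool_sim_params(n_genes = 250, sites_per_gene = 4, depth_mean = 200,
                        depth_dispersion = 1e6, n_selected_sites = 0,
                        sampling = "single_stage", seed = 31)
  var_between_reps <- function(sim) {
    r1 <- sim$counts[sim$counts$library_id == "R1", ]
    r2 <- sim$counts[sim$counts$library_id == "R2", ]
    f1 <- r1$alt_count / pmax(r1$depth, 1)
    f2 <- r2$alt_count / pmax(r2$depth, 1)
    mean((f1 - f2)^2)
  }
  expect_gt(var_between_reps(simulate_pool_readcounts(p2)),
            var_between_reps(simulate_pool_readcounts(p1)))
})

test_that("selected sites carry far larger chi-square than null sites", {
  # 1000 gene sites, 50 selected with delta_f = 0.8 at depth 200
  sim <- simulate_pool_readcounts(pool_sim_params(
    n_genes = 200, sites_per_gene = 5, depth_mean = 200,
    n_selected_sites = 50, delta_f = 0.8, seed = 21))
  w <- reshape_counts_wide_oracle(sim$counts)
  m <- match(paste(w$chrom, w$pos), paste(sim$truth$chrom, sim$truth$pos))
  chi2 <- vapply(seq_len(nrow(w)), function(i) {
    oracle_chi2_2x2(w$ref_R[i], w$alt_R[i], w$ref_S[i], w$alt_S[i])$chi2
  }, 0)
  sel <- sim$truth$selected[m]
  expect_gt(mean(chi2[sel], na.rm = TRUE), 10 * mean(chi2[!sel], na.rm = TRUE))
})

test_that("noise-free dose response gives 50% mortality at the LC50", {
  p <- bioassay_sim_params(true_lc50 = 25, probit_slope = 3,
                           doses = c(6.25, 12.5, 25, 50, 100))
  dr <- simulate_dose_response(p, noise_free = TRUE)
  at_lc50 <- dr[dr$dose == 25, ]
  expect_true(all(at_lc50$n_dead == at_lc50$n_exposed / 2))
})

test_that("dose-response simulation is seed-deterministic and validates inputs", {
  p <- bioassay_sim_params(true_lc50 = 2.41, probit_slope = 3, seed = 8)
  expect_identical(simulate_dose_response(p), simulate_dose_response(p))
  expect_error(bioassay_sim_params(true_lc50 = -1, probit_slope = 3),
               class = "poolscan_validation_error")
  expect_error(bioassay_sim_params(true_lc50 = 1, probit_slope = 0),
               class = "poolscan_validation_error")
  expect_error(bioassay_sim_params(true_lc50 = 1, probit_slope = 2,
                                   doses = c(0, 1, 2)),
               class = "poolscan_validation_error")
})

test_that("probit refits recover the resistant-scale LC50 across seeds", {
  ok <- 0L
  for (s in 1:100) {
    p <- bioassay_sim_params(true_lc50 = 25, probit_slope = 3, seed = s)
    fit <- fit_probit_lc50(simulate_dose_response(p))
    if (isTRUE(fit$converged) && abs(fit$lc50 - 25) / 25 <= 0.20) ok <- ok + 1L
  }
  expect_gte(ok, 90)
})

test_that("assay table simulator reproduces class frequencies and fold changes", {
  tabs <- simulate_assay_tables(class_freqs = c(hom_resistant = 0.67,
                                                heterozygous = 0.25,
                                                hom_susceptible = 0.08),
                                n_individuals = 1000, ct_noise_sd = 0,
                                seed = 6)
  g <- tabs$genotypes[tabs$genotypes$locus == "V410L", ]
  expect_lt(abs(mean(g$genotype == "hom_resistant") - 0.67), 0.04)

  rq <- ddct_relative_quantity(tabs$cts, target = "VGSC",
                               reference_genes = c("ACTIN", "RPS7"),
                               calibrator_group = "control")
  treated <- rq$per_group$rq[rq$per_group$group == "treated"]
  expect_equal(treated, 4, tolerance = 1e-12)

  expect_identical(simulate_assay_tables(seed = 7),
                   simulate_assay_tables(seed = 7))
  expect_error(simulate_assay_tables(class_freqs = c(hom_resistant = 0.7,
                                                     heterozygous = 0.7)),
               class = "poolscan_validation_error")
})
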