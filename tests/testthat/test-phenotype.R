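test_that("noise-free dose-response data invert to the generating LC50", {
  p <- bioassay_sim_params(true_lc50 = 10, probit_slope = 2,
                           doses = c(1, 10, 100), n_per_bottle = 100,
                           n_replicates = 1)
  fit <- fit_probit_lc50(simulate_dose_response(p, noise_free = TRUE))
  expect_equal(fit$lc50, 10, tolerance = 1e-6)
})

test_that("the probit fit is scale-equivariant in dose", {
  p <- bioassay_sim_params(true_lc50 = 2.41, probit_slope = 3, seed = 5)
  dr <- simulate_dose_response(p)
  fit <- fit_probit_lc50(dr)
  dr10 <- dr; dr10$dose <- dr$dose * 10
  fit10 <- fit_probit_lc50(dr10)
  expect_equal(fit10$lc50, 10 * fit$lc50, tolerance = 1e-8)
  expect_equal(fit10$ci_lower, 10 * fit$ci_lower, tolerance = 1e-6)
  expect_equal(fit10$slope, fit$slope, tolerance = 1e-8)
})

test_that("degenerate dose-response designs are refused or flagged", {
  const <- data.frame(dose = 5, n_exposed = 20, n_dead = c(3, 9, 16))
  expect_error(fit_probit_lc50(const), class = "poolscan_validation_error")

  all_dead <- data.frame(dose = c(1, 10, 100), n_exposed = 20, n_dead = 20)
  fit <- fit_probit_lc50(all_dead)
  expect_false(fit$converged)
  expect_match(fit$message, "non-identifiable")
})

test_that("Fieller and delta intervals agree to first order on clean data", {
  p <- bioassay_sim_params(true_lc50 = 25, probit_slope = 3,
                           n_per_bottle = 50, seed = 9)
  dr <- simulate_dose_response(p)
  d <- fit_probit_lc50(dr, ci_method = "delta")
  f <- fit_probit_lc50(dr, ci_method = "fieller")
  expect_equal(d$lc50, f$lc50)
  expect_lt(abs(log10(d$ci_lower) - log10(f$ci_lower)), 0.05)
  expect_lt(abs(log10(d$ci_upper) - log10(f$ci_upper)), 0.05)
})

test_that("resistance ratios reproduce the strain comparison", {
  mk_fit <- function(lc50) {
    structure(list(lc50 = lc50, converged = TRUE), class = "probit_fit")
  }
  expect_equal(resistance_ratio(mk_fit(24.92), mk_fit(2.41)), 10.34)
  expect_equal(resistance_ratio(mk_fit(5), mk_fit(5)), 1.00)
  expect_error(resistance_ratio(mk_fit(5), mk_fit(0)),
               class = "poolscan_validation_error")
  bad <- structure(list(lc50 = 2, converged = FALSE), class = "probit_fit")
  expect_error(resistance_ratio(mk_fit(5), bad),
               class = "poolscan_validation_error")
})

test_that("Fisher's exact test matches enumeration and conventions", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 9, 7, 1), 2)),
               0.0198, tolerance = 1e-2)
  expect_equal(fisher_exact_2x2(matrix(c(3, 9, 7, 1), 2)),
               stats::fisher.test(matrix(c(3, 9, 7, 1), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 8, 8), 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "poolscan_validation_error")
  expect_error(fisher_exact_2x2(matrix(c(0, 5, 0, 8), 2)),
               class = "poolscan_validation_error")
})

test_that("hypergeometric table probabilities sum to 1 over fixed margins", {
  set.seed(23)
  for (i in 1:10) {
    m <- random_2x2(40)
    mm <- sum(m[, 1]); n2 <- sum(m[, 2]); r1 <- sum(m[1, ])
    support <- max(0, r1 - n2):min(r1, mm)
    expect_equal(sum(dhyper(support, mm, n2, r1)), 1, tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches the two-group t-test identity", {
  set.seed(31)
  g1 <- rnorm(8); g2 <- rnorm(8, 0.5)
  res <- oneway_anova(list(a = g1, b = g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # identical group arrangements: zero between-group variance
  same <- oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(oneway_anova(list(a = c(1, 2))),
               class = "poolscan_validation_error")
  expect_error(oneway_anova(list(a = c(1, 2), b = 3)),
               class = "poolscan_validation_error")
  expect_error(oneway_anova(list(a = c(1, 1), b = c(1, 1))),
               class = "poolscan_validation_error")
})

test_that("genotype frequencies summarise composite KDR classes", {
  loci <- c("V410L", "V1016I", "F1534C")
  inds <- sprintf("i%02d", 1:20)
  cls <- c(rep("heterozygous", 5), rep("hom_resistant", 12),
           rep("hom_susceptible", 3))
  rec <- expand.grid(individual = inds, locus = loci,
                     stringsAsFactors = FALSE)
  rec$genotype <- rep(cls, times = 3)
  res <- genotype_frequencies(rec, loci)
  comp <- res$composite
  expect_equal(comp$proportion[comp$class == "heterozygous_all"], 0.25)
  expect_equal(comp$proportion[comp$class == "hom_resistant_all"], 0.60)
  af <- res$allele_freq$resistant_allele_freq[1]
  expect_equal(af, (12 + 0.5 * 5) / 20)

  # all individuals identical -> one class at 100%
  rec1 <- rec; rec1$genotype <- "hom_resistant"
  res1 <- genotype_frequencies(rec1, loci)
  expect_equal(res1$composite$proportion[res1$composite$class ==
                                           "hom_resistant_all"], 1)

  # a missing genotype shrinks the composite denominator with a note
  rec_na <- rec
  rec_na$genotype[rec_na$individual == "i01" & rec_na$locus == "V410L"] <- NA
  expect_message(res_na <- genotype_frequencies(rec_na, loci), "excluded")
  expect_equal(sum(res_na$composite$n), 19)
  expect_equal(res_na$n_excluded, 1)

  expect_error(genotype_frequencies(rec, c("V410L", "V9999X")),
               class = "poolscan_validation_error")
  rec_bad <- rec; rec_bad$genotype[1] <- "weird"
  expect_error(genotype_frequencies(rec_bad),
               class = "poolscan_validation_error")
})

test_that("ddCt relative quantities follow the comparative-Ct arithmetic", {
  cts <- rbind(
    data.frame(sample_id = "cal1", group = "control",
               gene = c("VGSC", "ACTIN", "RPS7"), ct = c(22, 18, 18),
               tech_rep = 1),
    data.frame(sample_id = "trt1", group = "treated",
               gene = c("VGSC", "ACTIN", "RPS7"), ct = c(20, 18, 18),
               tech_rep = 1))
  res <- ddct_relative_quantity(cts, "VGSC", c("ACTIN", "RPS7"), "control")
  expect_equal(res$per_sample$rq[res$per_sample$sample_id == "cal1"], 1)
  trt <- res$per_sample[res$per_sample$sample_id == "trt1", ]
  expect_equal(trt$ddct, -2)
  expect_equal(trt$rq, 4)

  # amplifier offset invariance: adding a constant to every Ct changes nothing
  shifted <- cts; shifted$ct <- shifted$ct + 3.7
  res_s <- ddct_relative_quantity(shifted, "VGSC", c("ACTIN", "RPS7"),
                                  "control")
  expect_equal(res_s$per_sample$rq, res$per_sample$rq)

  missing_ref <- cts[!(cts$sample_id == "trt1" & cts$gene == "RPS7"), ]
  err <- tryCatch(ddct_relative_quantity(missing_ref, "VGSC",
                                         c("ACTIN", "RPS7"), "control"),
                  error = function(e) e)
  expect_s3_class(err, "poolscan_validation_error")
  expect_match(conditionMessage(err), "trt1")
  expect_error(ddct_relative_quantity(cts, "VGSC", c("ACTIN", "RPS7"),
                                      "nonexistent"),
               class = "poolscan_validation_error")
})

test_that("knockdown summaries stay in [0, 1] and feed the group ANOVA", {
  kd <- simulate_knockdown(c(control = 0.8, treated = 0.95),
                           n_per_rep = 20, n_replicates = 3, seed = 2)
  res <- knockdown_summary(kd)
  expect_true(all(res$proportions$prop >= 0 & res$proportions$prop <= 1))
  # cumulative knockdown is nondecreasing in time within a replicate
  for (g in unique(kd$group)) {
    for (r in unique(kd$replicate)) {
      sub <- kd[kd$group == g & kd$replicate == r, ]
      expect_true(all(diff(sub$n_down[order(sub$timepoint)]) >= 0))
    }
  }
  expect_true(is.list(res$anova))
  expect_true(res$anova$p >= 0 && res$anova$p <= 1)
})
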