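#' Parameters for the dose-response bioassay simulator
#'
#' Emulates the CDC bottle bioassay design used for LC50 estimation:
#' 20 mosquitoes per bottle, 3 biological replicate bottles per dose, five
#' doses per population, knockdown scored every 10 min for 1 h and
#' mortality at 24 h.
#'
#' @param true_lc50 true LC50 in ug permethrin per bottle (> 0).
#' @param probit_slope probit regression slope per log10 dose (> 0).
#' @param doses vector of bottle doses in ug (> 0); default a two-fold
#'   series spanning `true_lc50` (lc50/4 ... lc50*4).
#' @param n_per_bottle mosquitoes per bottle (default 20).
#' @param n_replicates replicate bottles per dose (default 3).
#' @param seed integer RNG seed.
#' @return object of class `bioassay_sim_params`.
#' @export
bioassay_sim_params <- function(true_lc50, probit_slope,
                                doses = true_lc50 * c(1/4, 1/2, 1, 2, 4),
                                n_per_bottle = 20, n_replicates = 3,
                                seed = 1) {
  if (!is.numeric(true_lc50) || true_lc50 <= 0) {
    ps_validation_error("true_lc50 must be positive")
  }
  if (!is.numeric(probit_slope) || probit_slope <= 0) {
    ps_validation_error("probit_slope must be positive")
  }
  if (length(doses) < 1 || any(doses <= 0)) {
    ps_validation_error("doses must be strictly positive")
  }
  if (!is_count(n_per_bottle) || !is_count(n_replicates)) {
    ps_validation_error("n_per_bottle and n_replicates must be positive integers")
  }
  if (!is_count(seed, positive = FALSE) || seed >= 2^31) {
    ps_validation_error("seed must be a non-negative 32-bit integer")
  }
  structure(list(true_lc50 = true_lc50, probit_slope = probit_slope,
                 doses = doses, n_per_bottle = n_per_bottle,
                 n_replicates = n_replicates, seed = seed),
            class = "bioassay_sim_params")
}

#' Simulate dose-response mortality records
#'
#' Deaths per bottle are binomial with probability
#' `pnorm(slope * (log10(dose) - log10(true_lc50)))`. In noise-free mode the
#' expected number of deaths per bottle is rounded half-up (2.5 -> 3) to
#' give a deterministic fixture; at `dose == true_lc50` this yields exactly
#' 50% mortality.
#'
#' @param params a [bioassay_sim_params()] object.
#' @param noise_free logical; if `TRUE` return rounded expected deaths
#'   instead of binomial draws.
#' @param population optional population label attached to the records.
#' @return data.frame of dose-response records: `population`, `dose`,
#'   `replicate`, `n_exposed`, `n_dead`.
#' @export
simulate_dose_response <- function(params, noise_free = FALSE,
                                   population = "sim") {
  if (!inherits(params, "bioassay_sim_params")) {
    ps_validation_error("params must be created with bioassay_sim_params()")
  }
  set.seed(params$seed)
  grid <- expand.grid(replicate = seq_len(params$n_replicates),
                      dose = params$doses)
  p_dead <- pnorm(params$probit_slope *
                    (log10(grid$dose) - log10(params$true_lc50)))
  n_dead <- if (noise_free) {
    as.integer(round_half_up(params$n_per_bottle * p_dead))
  } else {
    rbinom(nrow(grid), params$n_per_bottle, p_dead)
  }
  data.frame(population = population, dose = grid$dose,
             replicate = grid$replicate,
             n_exposed = params$n_per_bottle, n_dead = n_dead)
}

#' Simulate genotype and qPCR Ct fixture tables
#'
#' Generates the molecular-assay inputs consumed by
#' [genotype_frequencies()] and [ddct_relative_quantity()].
#'
#' Individuals are drawn multinomially over composite genotype classes
#' (each class fixes the genotype at every locus: `hom_resistant`,
#' `heterozygous`, `hom_susceptible`). Ct values are built so that a chosen
#' true fold-change is encoded: reference-gene Cts around `ref_ct`, target
#' Cts offset by `-log2(fold_change)` in each treated group relative to the
#' calibrator, plus Gaussian noise of sd `ct_noise_sd`.
#'
#' @param class_freqs named numeric vector of composite-class frequencies
#'   over `c("hom_resistant", "heterozygous", "hom_susceptible")`; must sum
#'   to 1.
#' @param n_individuals individuals to genotype.
#' @param loci loci genotyped per individual (default the three KDR loci
#'   V410L, V1016I, F1534C).
#' @param fold_changes named numeric vector: true target fold-change of
#'   each treated group relative to the calibrator group.
#' @param calibrator calibrator group name (default `"control"`).
#' @param n_per_group biological samples per group.
#' @param target,reference_genes gene labels used in the Ct table.
#' @param ref_ct baseline reference-gene Ct (cycles).
#' @param ct_noise_sd Gaussian Ct noise sd (cycles); 0 gives exact
#'   fold-change recovery.
#' @param n_tech_reps technical replicates per sample and gene.
#' @param seed integer RNG seed.
#' @return list with `genotypes` (data.frame `individual`, `locus`,
#'   `genotype`) and `cts` (data.frame `sample_id`, `group`, `gene`, `ct`,
#'   `tech_rep`).
#' @export
simulate_assay_tables <- function(class_freqs = c(hom_resistant = 0.67,
                                                  heterozygous = 0.25,
                                                  hom_susceptible = 0.08),
                                  n_individuals = 100,
                                  loci = c("V410L", "V1016I", "F1534C"),
                                  fold_changes = c(treated = 4),
                                  calibrator = "control",
                                  n_per_group = 3,
                                  target = "VGSC",
                                  reference_genes = c("ACTIN", "RPS7"),
                                  ref_ct = 18,
                                  ct_noise_sd = 0.1,
                                  n_tech_reps = 3,
                                  seed = 1) {
  classes <- c("hom_resistant", "heterozygous", "hom_susceptible")
  if (!all(names(class_freqs) %in% classes) || length(class_freqs) == 0) {
    ps_validation_error("class_freqs must be named over %s",
                        paste(classes, collapse = ", "))
  }
  if (any(class_freqs < 0) || abs(sum(class_freqs) - 1) > 1e-8) {
    ps_validation_error("class_freqs must be non-negative and sum to 1")
  }
  if (!is_count(n_individuals)) {
    ps_validation_error("n_individuals must be a positive integer")
  }
  if (ct_noise_sd < 0) ps_validation_error("ct_noise_sd must be >= 0")
  set.seed(seed)

  draws <- rmultinom(1, n_individuals, class_freqs)[, 1]
  cls <- rep(names(class_freqs), draws)
  cls <- sample(cls)  # shuffle individual order
  geno_map <- c(hom_resistant = "hom_resistant",
                heterozygous = "heterozygous",
                hom_susceptible = "hom_susceptible")
  genotypes <- expand.grid(individual = sprintf("ind%03d", seq_len(n_individuals)),
                           locus = loci, stringsAsFactors = FALSE)
  genotypes$genotype <- geno_map[rep(cls, times = length(loci))]
  rownames(genotypes) <- NULL

  groups <- c(calibrator, names(fold_changes))
  offsets <- c(0, -log2(fold_changes))
  names(offsets) <- groups
  ct_rows <- list()
  for (g in groups) {
    for (s in seq_len(n_per_group)) {
      sid <- sprintf("%s_s%d", g, s)
      for (gene in c(target, reference_genes)) {
        base <- if (gene %in% reference_genes) ref_ct else ref_ct + 2 + offsets[[g]]
        noise <- if (ct_noise_sd > 0) rnorm(n_tech_reps, 0, ct_noise_sd) else rep(0, n_tech_reps)
        ct_rows[[length(ct_rows) + 1L]] <-
          data.frame(sample_id = sid, group = g, gene = gene,
                     ct = base + noise, tech_rep = seq_len(n_tech_reps))
      }
    }
  }
  list(genotypes = genotypes, cts = do.call(rbind, ct_rows))
}
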