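#' Parameters for the pooled-sequencing simulator
#'
#' Bundles the full parameterization of the two-stage pool-seq simulator:
#' the study design it emulates is two strains (resistant `R`, susceptible
#' `S`), each sequenced as dual replicate pools of 22 diploid females, with
#' deep exome coverage and biallelic SNPs. Selected ("planted") sites carry
#' a true allele-frequency difference `delta_f` between strains; all other
#' sites share one ancestral frequency.
#'
#' @param n_genes number of gene intervals.
#' @param sites_per_gene SNP sites per gene (a single count, or an integer
#'   vector of length `n_genes`).
#' @param n_diploids_per_pool diploid individuals per pooled library
#'   (default 22, i.e. 44 chromosomes per pool).
#' @param n_replicates_per_strain replicate pooled libraries per strain
#'   (default 2).
#' @param depth_mean mean sequencing depth per site and library (reads).
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   model (`variance = mu + mu^2/size`); smaller values give more
#'   heterogeneous capture coverage.
#' @param base_freq_sampler function `n -> n` ancestral allele frequencies
#'   in (0, 1); default `runif(n, 0.05, 0.95)`.
#' @param n_selected_sites number of sites carrying a strain difference
#'   (includes the planted pre-miRNA site).
#' @param delta_f absolute true allele-frequency difference between strains
#'   at selected sites, in \[0, 1\]. Frequencies are shifted symmetrically
#'   around the ancestral value and re-anchored at the \[0, 1\] boundary so
#'   that the realised difference is exactly `delta_f`.
#' @param premirna_intervals data.frame of pre-miRNA hairpin intervals
#'   (`chrom`, `start`, `end`, `name`, 1-based inclusive) or `NULL` for the
#'   default layout: seven hairpins on chr1, one of which (`aae-mir-33`,
#'   chr1:50888851-50888950) always contains a planted selected site at
#'   position 50888906.
#' @param sampling `"two_stage"` (default) draws each pool's allele count
#'   binomially from the strain frequency over `2 * n_diploids_per_pool`
#'   chromosomes and then draws reads binomially at the realised pool
#'   frequency -- the process implied by pooling individuals before library
#'   prep. `"single_stage"` draws reads directly from the strain frequency,
#'   which makes the per-site chi-square exactly calibrated and is used for
#'   calibration and recovery checks.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return object of class `pool_sim_params`.
#' @export
pool_sim_params <- function(n_genes = 200,
                            sites_per_gene = 5,
                            n_diploids_per_pool = 22,
                            n_replicates_per_strain = 2,
                            depth_mean = 100,
                            depth_dispersion = 10,
                            base_freq_sampler = function(n) runif(n, 0.05, 0.95),
                            n_selected_sites = 20,
                            delta_f = 0.5,
                            premirna_intervals = NULL,
                            sampling = c("two_stage", "single_stage"),
                            seed = 20210331) {
  sampling <- match.arg(sampling)
  if (!is_count(n_genes)) ps_validation_error("n_genes must be a positive integer")
  if (!(length(sites_per_gene) %in% c(1L, n_genes)) ||
      any(sites_per_gene < 1) || any(sites_per_gene != floor(sites_per_gene))) {
    ps_validation_error("sites_per_gene must be positive integer(s) of length 1 or n_genes")
  }
  if (!is_count(n_diploids_per_pool)) {
    ps_validation_error("n_diploids_per_pool must be a positive integer")
  }
  if (!is_count(n_replicates_per_strain) || n_replicates_per_strain < 2) {
    ps_validation_error("n_replicates_per_strain must be an integer >= 2")
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    ps_validation_error("depth_mean must be positive")
  }
  if (!is.numeric(depth_dispersion) || depth_dispersion <= 0) {
    ps_validation_error("depth_dispersion must be positive")
  }
  if (!is.function(base_freq_sampler)) {
    ps_validation_error("base_freq_sampler must be a function")
  }
  if (!is.numeric(delta_f) || delta_f < 0 || delta_f > 1) {
    ps_validation_error("delta_f must lie in [0, 1]")
  }
  if (is.null(premirna_intervals)) premirna_intervals <- default_premirnas()
  require_columns(premirna_intervals, c("chrom", "start", "end", "name"),
                  "premirna_intervals")
  n_gene_sites <- if (length(sites_per_gene) == 1L) {
    n_genes * sites_per_gene
  } else {
    sum(sites_per_gene)
  }
  n_sites <- n_gene_sites + nrow(premirna_intervals) * 2L
  if (!is_count(n_selected_sites, positive = FALSE) ||
      n_selected_sites > n_sites) {
    ps_validation_error("n_selected_sites must be an integer in [0, n_sites]")
  }
  if (!is_count(seed, positive = FALSE) || seed >= 2^31) {
    ps_validation_error("seed must be a non-negative 32-bit integer")
  }
  structure(list(n_genes = n_genes, sites_per_gene = sites_per_gene,
                 n_diploids_per_pool = n_diploids_per_pool,
                 n_replicates_per_strain = n_replicates_per_strain,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 base_freq_sampler = base_freq_sampler,
                 n_selected_sites = n_selected_sites, delta_f = delta_f,
                 premirna_intervals = premirna_intervals,
                 sampling = sampling, n_sites = n_sites, seed = seed),
            class = "pool_sim_params")
}

# Default hairpin layout: seven pre-miRNA intervals on chr1, two simulated
# SNP sites each; the mir-33 hairpin carries the planted selected site at
# 1-based position 50888906.
#' @noRd
default_premirnas <- function() {
  data.frame(
    chrom = "chr1",
    start = c(50888851, 51000001, 52000001, 53000001, 54000001, 55000001, 56000001),
    end   = c(50888950, 51000090, 52000090, 53000090, 54000090, 55000090, 56000090),
    name  = c("aae-mir-33", sprintf("aae-mir-sim%d", 1:6)),
    kind  = "pre_miRNA"
  )
}

MIR33_PLANTED_POS <- 50888906L

#' Simulate pooled-library readcount tables with known truth
#'
#' Generates the per-site, per-library biallelic read counts the association
#' pipeline consumes, together with the ground truth used by recovery tests.
#'
#' Genes are laid out as non-overlapping 2 kb intervals split across chr1,
#' chr2 and chr3, with `sites_per_gene` evenly spaced SNP sites each. Every
#' pre-miRNA hairpin interval additionally contains two SNP sites. Selected
#' sites (`n_selected_sites` of them, always including the planted site
#' inside the `aae-mir-33` hairpin) differ in true allele frequency between
#' strains by exactly `delta_f`; the remaining selected sites are assigned
#' to the lowest-index genes so that whole genes carry signal.
#'
#' Sampling per library and site: depth ~ NegBin(mean = `depth_mean`,
#' size = `depth_dispersion`); under two-stage sampling the pool's allele
#' frequency is first drawn binomially over the pool's chromosomes, then
#' alt reads binomially at that realised frequency; under single-stage
#' sampling alt reads are drawn directly at the strain frequency. At every
#' site and library `ref_count + alt_count = depth`.
#'
#' @param params a [pool_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{counts}{`site_counts` data.frame (site x library long form).}
#'     \item{truth}{per-site truth: `chrom`, `pos`, `gene_id`, `f_R`,
#'       `f_S`, `selected`, `in_premirna`.}
#'     \item{genes}{gene intervals (`genomic_intervals`).}
#'     \item{premirnas}{pre-miRNA intervals (`genomic_intervals`).}
#'     \item{libraries}{library description table.}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_pool_readcounts <- function(params) {
  if (!inherits(params, "pool_sim_params")) {
    ps_validation_error("params must be created with pool_sim_params()")
  }
  set.seed(params$seed)

  spg <- if (length(params$sites_per_gene) == 1L) {
    rep(params$sites_per_gene, params$n_genes)
  } else {
    params$sites_per_gene
  }

  # gene layout: 2 kb genes every 10 kb, round-robin across three chromosomes
  chroms <- rep(c("chr1", "chr2", "chr3"), length.out = params$n_genes)
  idx_on_chrom <- stats::ave(seq_len(params$n_genes), chroms, FUN = seq_along)
  gene_start <- 1e6 + (idx_on_chrom - 1) * 1e4
  genes <- data.frame(chrom = chroms,
                      start = as.integer(gene_start),
                      end = as.integer(gene_start + 1999),
                      name = sprintf("gene%04d", seq_len(params$n_genes)),
                      kind = "gene")
  class(genes) <- c("genomic_intervals", "data.frame")

  gene_site_pos <- unlist(lapply(seq_len(params$n_genes), function(g) {
    as.integer(round(seq(genes$start[g] + 10, genes$end[g] - 10,
                         length.out = spg[g])))
  }))
  gene_site_chrom <- rep(genes$chrom, spg)
  gene_site_gene <- rep(genes$name, spg)

  pm <- params$premirna_intervals
  pm_site_pos <- unlist(lapply(seq_len(nrow(pm)), function(i) {
    if (pm$name[i] == "aae-mir-33" &&
        pm$start[i] <= MIR33_PLANTED_POS && pm$end[i] >= MIR33_PLANTED_POS) {
      c(MIR33_PLANTED_POS, as.integer(pm$start[i] + 10))
    } else {
      as.integer(c(pm$start[i] + 10, pm$end[i] - 10))
    }
  }))
  pm_site_chrom <- rep(pm$chrom, each = 2)
  pm_site_mirna <- rep(pm$name, each = 2)

  chrom <- c(gene_site_chrom, pm_site_chrom)
  pos <- c(gene_site_pos, pm_site_pos)
  gene_id <- c(gene_site_gene, rep(NA_character_, length(pm_site_pos)))
  in_premirna <- c(rep(FALSE, length(gene_site_pos)),
                   rep(TRUE, length(pm_site_pos)))
  n_sites <- length(pos)

  # truth frequencies
  f0 <- params$base_freq_sampler(n_sites)
  if (any(f0 <= 0) || any(f0 >= 1)) {
    ps_validation_error("base_freq_sampler must return frequencies in (0, 1)")
  }
  selected <- rep(FALSE, n_sites)
  if (params$n_selected_sites > 0) {
    planted_mir <- which(in_premirna & pos == MIR33_PLANTED_POS)
    n_gene_selected <- params$n_selected_sites - as.integer(length(planted_mir) > 0)
    selected[utils::head(seq_along(gene_site_pos), n_gene_selected)] <- TRUE
    selected[planted_mir] <- TRUE
  }
  half <- params$delta_f / 2
  f_R <- ifelse(selected, pmin(f0 + half, 1), f0)
  f_S <- ifelse(selected, f_R - params$delta_f, f0)
  low <- selected & f_S < 0
  f_S[low] <- 0
  f_R[low] <- params$delta_f

  truth <- data.frame(chrom = chrom, pos = pos, gene_id = gene_id,
                      f_R = f_R, f_S = f_S, selected = selected,
                      in_premirna = in_premirna)

  # alleles: ref/alt drawn per site, alt frequency is the strain frequency
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  n_chrom_pool <- 2L * params$n_diploids_per_pool
  libs <- expand.grid(replicate = seq_len(params$n_replicates_per_strain),
                      strain = c("R", "S"), stringsAsFactors = FALSE)
  libs$library_id <- sprintf("%s%d", libs$strain, libs$replicate)

  count_rows <- vector("list", nrow(libs))
  for (li in seq_len(nrow(libs))) {
    f_true <- if (libs$strain[li] == "R") truth$f_R else truth$f_S
    depth <- rnbinom(n_sites, mu = params$depth_mean,
                     size = params$depth_dispersion)
    f_pool <- if (params$sampling == "two_stage") {
      rbinom(n_sites, n_chrom_pool, f_true) / n_chrom_pool
    } else {
      f_true
    }
    alt_count <- rbinom(n_sites, depth, f_pool)
    count_rows[[li]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      library_id = libs$library_id[li], strain = libs$strain[li],
      replicate = libs$replicate[li],
      ref_count = as.integer(depth - alt_count),
      alt_count = as.integer(alt_count),
      depth = as.integer(depth),
      multiallelic = FALSE)
  }
  counts <- do.call(rbind, count_rows)
  counts <- counts[order(counts$chrom, counts$pos, counts$library_id), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  class(counts) <- c("site_counts", "data.frame")

  pm_out <- pm
  if (!"kind" %in% names(pm_out)) pm_out$kind <- "pre_miRNA"
  class(pm_out) <- c("genomic_intervals", "data.frame")

  list(counts = counts, truth = truth, genes = genes, premirnas = pm_out,
       libraries = libs[, c("library_id", "strain", "replicate")],
       params = params)
}
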