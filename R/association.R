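#' Filter and threshold parameters of the association scan
#'
#' @param min_coverage minimum total depth per library for a site to enter
#'   the scan (reads; default 22, matching the number of diploid genomes
#'   per pool).
#' @param rep_p_cutoff between-replicate chi-square p-value cutoff: a site
#'   is dropped when the replicate test p is strictly below this value in
#'   either strain (default 0.10).
#' @param bh_cutoff Benjamini-Hochberg adjusted-p significance cutoff over
#'   site p values (default 0.001).
#' @param gene_threshold gene-wise weighted `-log10(p)` score call
#'   threshold (default 15).
#' @param mirna_threshold per-SNP score threshold of the pre-miRNA scan
#'   (default 3.0, applied strictly: hits require score > threshold).
#' @param weighting `"depth"` (default) weights each site's score by its
#'   total cross-library depth when averaging within a gene; `"uniform"`
#'   gives every passing site equal weight.
#' @param fisher_min_expected sites whose 2x2 strain table has a minimum
#'   expected cell count below this value use Fisher's exact p instead of
#'   the chi-square tail (default 0 = never; expected counts are large at
#'   the mandated minimum coverage, so the asymptotic test is the default).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(min_coverage = 22, rep_p_cutoff = 0.10,
                          bh_cutoff = 0.001, gene_threshold = 15,
                          mirna_threshold = 3.0,
                          weighting = c("depth", "uniform"),
                          fisher_min_expected = 0) {
  weighting <- match.arg(weighting)
  if (!is.numeric(fisher_min_expected) || fisher_min_expected < 0) {
    ps_validation_error("fisher_min_expected must be >= 0")
  }
  if (!is_count(min_coverage, positive = FALSE)) {
    ps_validation_error("min_coverage must be a non-negative integer")
  }
  if (!is_prob(rep_p_cutoff) || !is_prob(bh_cutoff)) {
    ps_validation_error("rep_p_cutoff and bh_cutoff must be probabilities in (0, 1)")
  }
  if (gene_threshold < 0 || mirna_threshold < 0) {
    ps_validation_error("score thresholds must be >= 0")
  }
  structure(list(min_coverage = min_coverage, rep_p_cutoff = rep_p_cutoff,
                 bh_cutoff = bh_cutoff, gene_threshold = gene_threshold,
                 mirna_threshold = mirna_threshold, weighting = weighting,
                 fisher_min_expected = fisher_min_expected),
            class = "filter_params")
}

#' Gene-wise weighted association score
#'
#' Aggregates the passing sites of one gene into the gene-wise score:
#' the weighted mean of site `-log10(p)` scores with weights `w_i` equal to
#' each site's total cross-library depth (or uniform weights). The weighted
#' mean always lies between the minimum and maximum site score.
#'
#' @param scores numeric site scores (`-log10(p)`), one per passing site.
#' @param depths total cross-library depth per site (ignored for uniform
#'   weighting).
#' @param gene_id,chrom identifiers carried into the result.
#' @param params a [filter_params()] object (threshold and weighting).
#' @return one-row data.frame: `gene_id`, `chrom`, `weighted_score`,
#'   `n_sites_pass`, `total_depth_weight`, `passes_threshold`.
#' @examples
#' gene_score(c(10, 20), c(100, 300), "g1", "chr1")  # weighted score 17.5
#' @export
gene_score <- function(scores, depths, gene_id = NA_character_,
                       chrom = NA_character_, params = filter_params()) {
  if (length(scores) < 1) {
    ps_validation_error("gene_score() requires at least one passing site")
  }
  if (length(depths) != length(scores)) {
    ps_validation_error("scores and depths must have equal length")
  }
  w <- if (params$weighting == "depth") as.numeric(depths) else rep(1, length(scores))
  if (any(w <= 0)) ps_validation_error("site depth weights must be positive")
  ws <- sum(scores * w) / sum(w)
  data.frame(gene_id = gene_id, chrom = chrom, weighted_score = ws,
             n_sites_pass = length(scores), total_depth_weight = sum(depths),
             passes_threshold = ws >= params$gene_threshold)
}

#' Run the pooled association scan
#'
#' Applies the full per-site analysis in order: coverage filter,
#' between-replicate consistency filter in each strain, strain-vs-strain
#' contingency chi-square on replicate-summed counts, Benjamini-Hochberg
#' adjustment over the passing sites' p values, then gene aggregation of
#' passing sites into depth-weighted gene scores with the call threshold.
#'
#' Sites are assigned to genes by interval overlap of their position; a
#' site inside two overlapping genes contributes to both. Genes with no
#' passing site are omitted from the gene table and listed in the skipped
#' report. A gene is flagged `bh_significant` when at least one of its
#' passing sites is BH-significant.
#'
#' @param sites `site_counts` data.frame (from [read_readcounts()] or
#'   [simulate_pool_readcounts()]); must contain two replicate libraries
#'   per strain.
#' @param gene_intervals gene intervals (`genomic_intervals` data.frame).
#' @param params a [filter_params()] object.
#' @return list of class `pool_association`:
#'   \describe{
#'     \item{site_table}{per-site results: position, alleles, per-strain
#'       pooled counts, replicate p values, `chi2`, `p`, `neg_log10_p`,
#'       `bh_p`, `bh_significant`, `status`
#'       (`pass`/`low_coverage`/`replicate_discordant`).}
#'     \item{gene_table}{ranked gene results (descending weighted score).}
#'     \item{tallies}{per-chromosome and total counts of genes at the
#'       score threshold.}
#'     \item{skipped_genes}{genes omitted, with reason.}
#'     \item{success}{`FALSE` when no site passed all filters.}
#'   }
#' @export
run_association <- function(sites, gene_intervals, params = filter_params()) {
  require_columns(sites, c("chrom", "pos", "ref", "alt", "library_id",
                           "strain", "replicate", "ref_count", "alt_count",
                           "depth"), "site_counts table")
  require_columns(gene_intervals, c("chrom", "start", "end", "name"),
                  "gene intervals")
  if (nrow(gene_intervals) == 0) {
    ps_validation_error("gene interval set must be non-empty")
  }
  libs <- unique(sites[, c("library_id", "strain", "replicate")])
  for (st in c("R", "S")) {
    n <- sum(libs$strain == st)
    if (n != 2) {
      ps_validation_error(
        "strain %s has %d libraries; the replicate filter requires exactly 2 per strain",
        st, n)
    }
  }

  wide <- reshape_counts_wide(sites, libs)
  n_sites <- nrow(wide)

  status <- rep("pass", n_sites)
  min_depth <- pmin(wide$depth_R1, wide$depth_R2, wide$depth_S1, wide$depth_S2)
  # zero-depth libraries are uninformative even when min_coverage = 0
  status[min_depth < max(params$min_coverage, 1)] <- "low_coverage"

  cov_ok <- status == "pass"
  rep_p_R <- rep_p_S <- rep(NA_real_, n_sites)
  if (any(cov_ok)) {
    rr <- chi2_2x2(wide$ref_R1[cov_ok], wide$alt_R1[cov_ok],
                   wide$ref_R2[cov_ok], wide$alt_R2[cov_ok])
    ss <- chi2_2x2(wide$ref_S1[cov_ok], wide$alt_S1[cov_ok],
                   wide$ref_S2[cov_ok], wide$alt_S2[cov_ok])
    rep_p_R[cov_ok] <- rr$p
    rep_p_S[cov_ok] <- ss$p
    discordant <- cov_ok & (rep_p_R < params$rep_p_cutoff |
                              rep_p_S < params$rep_p_cutoff)
    status[discordant] <- "replicate_discordant"
  }

  ref_R <- wide$ref_R1 + wide$ref_R2
  alt_R <- wide$alt_R1 + wide$alt_R2
  ref_S <- wide$ref_S1 + wide$ref_S2
  alt_S <- wide$alt_S1 + wide$alt_S2
  chi2 <- p <- score <- rep(NA_real_, n_sites)
  pass <- status == "pass"
  if (any(pass)) {
    st <- chi2_2x2(ref_R[pass], alt_R[pass], ref_S[pass], alt_S[pass])
    chi2[pass] <- st$chi2
    p[pass] <- st$p
    if (params$fisher_min_expected > 0) {
      idx <- which(pass)
      for (i in idx) {
        tab <- matrix(c(ref_R[i], alt_R[i], ref_S[i], alt_S[i]), 2,
                      byrow = TRUE)
        expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (min(expd) < params$fisher_min_expected) {
          p[i] <- fisher_exact_2x2(tab)
        }
      }
    }
    score[pass] <- -log10(pmax(p[pass], P_FLOOR))
  }

  bh_p <- rep(NA_real_, n_sites)
  bh_sig <- rep(NA, n_sites)
  if (any(pass)) {
    adj <- bh_adjust(p[pass], params$bh_cutoff)
    bh_p[pass] <- adj$p_adjusted
    bh_sig[pass] <- adj$significant
  }

  site_table <- data.frame(
    chrom = wide$chrom, pos = wide$pos, ref = wide$ref, alt = wide$alt,
    ref_R = ref_R, alt_R = alt_R, ref_S = ref_S, alt_S = alt_S,
    total_depth = wide$depth_R1 + wide$depth_R2 + wide$depth_S1 + wide$depth_S2,
    rep_p_R = rep_p_R, rep_p_S = rep_p_S,
    chi2 = chi2, p = p, neg_log10_p = score,
    bh_p = bh_p, bh_significant = bh_sig, status = status)

  assign <- assign_sites_to_intervals(site_table, gene_intervals)
  gene_rows <- list()
  skipped <- list()
  for (gi in seq_len(nrow(gene_intervals))) {
    idx <- assign[[gi]]
    if (length(idx) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gene_intervals$name[gi],
                   chrom = gene_intervals$chrom[gi], reason = "no_sites")
      next
    }
    pass_idx <- idx[site_table$status[idx] == "pass"]
    if (length(pass_idx) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gene_intervals$name[gi],
                   chrom = gene_intervals$chrom[gi],
                   reason = "no_passing_sites")
      next
    }
    g <- gene_score(site_table$neg_log10_p[pass_idx],
                    site_table$total_depth[pass_idx],
                    gene_id = gene_intervals$name[gi],
                    chrom = gene_intervals$chrom[gi], params = params)
    g$bh_significant <- any(site_table$bh_significant[pass_idx])
    gene_rows[[length(gene_rows) + 1L]] <- g
  }
  gene_table <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               weighted_score = numeric(0), n_sites_pass = integer(0),
               total_depth_weight = numeric(0), passes_threshold = logical(0),
               bh_significant = logical(0))
  gene_table <- gene_table[order(-gene_table$weighted_score,
                                 gene_table$gene_id), , drop = FALSE]
  gene_table$rank <- seq_len(nrow(gene_table))
  rownames(gene_table) <- NULL

  called <- gene_table[gene_table$passes_threshold, , drop = FALSE]
  by_chrom <- table(factor(called$chrom,
                           levels = sort(unique(gene_intervals$chrom))))
  tallies <- list(per_chromosome = as.list(setNames(as.integer(by_chrom),
                                                    names(by_chrom))),
                  total = nrow(called))

  success <- any(pass)
  if (!success) {
    warning("no site passed all filters; association tables are empty",
            call. = FALSE)
  }
  structure(list(site_table = site_table, gene_table = gene_table,
                 tallies = tallies,
                 skipped_genes = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(gene_id = character(0), chrom = character(0),
                                 reason = character(0)),
                 params = params, success = success),
            class = "pool_association")
}

# site x library long form -> one row per site with per-library count columns
#' @noRd
reshape_counts_wide <- function(sites, libs) {
  libs <- libs[order(libs$strain, libs$replicate), , drop = FALSE]
  lib_tag <- paste0(libs$strain, libs$replicate)
  key <- paste(sites$chrom, sites$pos, sep = "\r")
  first <- !duplicated(key)
  base <- sites[first, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  ord_key <- key[first]
  for (i in seq_len(nrow(libs))) {
    sub <- sites[sites$library_id == libs$library_id[i], , drop = FALSE]
    m <- match(ord_key, paste(sub$chrom, sub$pos, sep = "\r"))
    rc <- ifelse(is.na(m), 0L, sub$ref_count[m])
    ac <- ifelse(is.na(m), 0L, sub$alt_count[m])
    base[[paste0("ref_", lib_tag[i])]] <- rc
    base[[paste0("alt_", lib_tag[i])]] <- ac
    base[[paste0("depth_", lib_tag[i])]] <- rc + ac
  }
  rownames(base) <- NULL
  base
}

# positions -> list of site indices per interval (overlaps duplicated)
#' @noRd
assign_sites_to_intervals <- function(site_table, intervals) {
  out <- vector("list", nrow(intervals))
  if (nrow(site_table) == 0) return(lapply(out, function(x) integer(0)))
  site_gr <- GenomicRanges::GRanges(site_table$chrom,
                                    IRanges::IRanges(site_table$pos,
                                                     site_table$pos))
  int_gr <- GenomicRanges::GRanges(intervals$chrom,
                                   IRanges::IRanges(intervals$start,
                                                    intervals$end))
  ov <- GenomicRanges::findOverlaps(int_gr, site_gr)
  hits <- split(S4Vectors::subjectHits(ov),
                factor(S4Vectors::queryHits(ov), seq_len(nrow(intervals))))
  lapply(hits, as.integer)
}
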