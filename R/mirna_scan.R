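#' Scan pre-miRNA hairpin intervals for associated SNPs
#'
#' Reports every passing site of the association scan that falls inside a
#' pre-miRNA hairpin interval and whose `-log10(p)` score strictly exceeds
#' the discovery threshold (default 3.0), together with a per-hairpin
#' coverage report.
#'
#' A hairpin is considered to have sufficient coverage for association when
#' at least `coverage_min_fraction` of its bases reach `min_coverage` in
#' every library; hairpins below that are still reported (flagged) but a
#' discovered SNP inside them should be treated with caution.
#'
#' @param site_table per-site results from [run_association()] (the
#'   `site_table` element).
#' @param premirna_intervals pre-miRNA intervals (`genomic_intervals`
#'   data.frame, kind `pre_miRNA`).
#' @param depth optional `depth_table` for the coverage report; when
#'   `NULL`, coverage columns are `NA`.
#' @param params a [filter_params()] object (`mirna_threshold`,
#'   `min_coverage`).
#' @param coverage_min_fraction fraction of covered bases required to call
#'   a hairpin sufficiently covered (default 0.8).
#' @return list with
#'   \describe{
#'     \item{hits}{data.frame sorted by descending score: `mirna`, `chrom`,
#'       `pos`, `ref`, `alt`, `neg_log10_p`, `mean_depth`,
#'       `covered_fraction`.}
#'     \item{coverage}{per-hairpin report: `mirna`, `chrom`, `start`,
#'       `end`, `mean_depth`, `covered_fraction`, `sufficient`.}
#'   }
#' @export
scan_premirna_snps <- function(site_table, premirna_intervals, depth = NULL,
                               params = filter_params(),
                               coverage_min_fraction = 0.8) {
  require_columns(site_table, c("chrom", "pos", "neg_log10_p", "status"),
                  "site table")
  if (is.null(premirna_intervals) || nrow(premirna_intervals) == 0) {
    ps_config_error("no pre-miRNA intervals supplied")
  }
  require_columns(premirna_intervals, c("chrom", "start", "end", "name"),
                  "pre-miRNA intervals")

  cov <- data.frame(mirna = premirna_intervals$name,
                    chrom = premirna_intervals$chrom,
                    start = premirna_intervals$start,
                    end = premirna_intervals$end,
                    mean_depth = NA_real_, covered_fraction = NA_real_,
                    sufficient = NA)
  if (!is.null(depth)) {
    for (i in seq_len(nrow(premirna_intervals))) {
      d <- interval_mean_depth(depth, premirna_intervals[i, ],
                               min_coverage = params$min_coverage)
      cov$mean_depth[i] <- d$mean_depth
      cov$covered_fraction[i] <- d$covered_fraction
    }
    cov$sufficient <- cov$covered_fraction >= coverage_min_fraction
  }

  assign <- assign_sites_to_intervals(site_table, premirna_intervals)
  hit_rows <- list()
  for (i in seq_len(nrow(premirna_intervals))) {
    idx <- assign[[i]]
    idx <- idx[site_table$status[idx] == "pass" &
                 site_table$neg_log10_p[idx] > params$mirna_threshold]
    if (length(idx) == 0) next
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      mirna = premirna_intervals$name[i],
      chrom = site_table$chrom[idx], pos = site_table$pos[idx],
      ref = site_table$ref[idx], alt = site_table$alt[idx],
      neg_log10_p = site_table$neg_log10_p[idx],
      mean_depth = cov$mean_depth[i],
      covered_fraction = cov$covered_fraction[i])
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(mirna = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               neg_log10_p = numeric(0), mean_depth = numeric(0),
               covered_fraction = numeric(0))
  hits <- hits[order(-hits$neg_log10_p), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, coverage = cov)
}
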