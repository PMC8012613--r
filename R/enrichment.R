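#' Controlled vocabulary of curated functional categories
#'
#' Primary labels assignable to genes: chemosensory response (CSR),
#' cytoskeletal/structural (CYT/STR), diverse (DIV), uncharacterized (UNK),
#' detoxification and oxidation/reduction subsets (Detox, Detox/Redox,
#' ReDox), mitochondrial (MIT), proteolysis/proteosomal (PROT),
#' replication/repair/transcription/translation (RRTT), RNA processing
#' (RNA_PROC, a subset of RRTT curated separately), signal transduction
#' (SIGT), metabolism/lipid (MET/LIPID), transport (TRP) and immunity
#' (IMM).
#' @export
CATEGORY_VOCABULARY <- c("CSR", "CYT/STR", "DIV", "UNK", "Detox",
                         "Detox/Redox", "ReDox", "MIT", "PROT", "RRTT",
                         "RNA_PROC", "SIGT", "MET/LIPID", "TRP", "IMM")

# Tested category groups: the oxidation/reduction subsets and mitochondrial
# labels are pooled into one Redox/MIT group for enrichment testing.
#' @noRd
default_tested_categories <- function() {
  list("TRP" = "TRP",
       "MET/LIPID" = "MET/LIPID",
       "SIGT" = "SIGT",
       "Redox/MIT" = c("ReDox", "Detox", "Detox/Redox", "MIT"),
       "RRTT" = c("RRTT", "RNA_PROC"),
       "CYT/STR" = "CYT/STR")
}

#' Upper tail of the hypergeometric distribution
#'
#' One-tailed cumulative probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` genes without replacement
#' from a background of `N` genes of which `K` belong to the category.
#' Computed through [stats::phyper()], which works in log space internally
#' and is stable for genome-scale `N`.
#'
#' @param k observed category members in the drawn set.
#' @param K category members in the background.
#' @param n drawn set size.
#' @param N background size.
#' @return `P(X >= k)`, in (0, 1].
#' @examples
#' hypergeom_upper_tail(4, 5, 10, 20)  # 28028/184756 ~ 0.1517
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != floor(vals)) || any(vals < 0)) {
    ps_validation_error("hypergeometric arguments must be non-negative integers")
  }
  if (K > N || n > N) ps_validation_error("K and n must not exceed N")
  if (k > min(K, n)) ps_validation_error("k must not exceed min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Category over-representation by the cumulative hypergeometric test
#'
#' For each tested category, counts its members in the selected gene set
#' (`k`) and in the background (`K`) and computes the one-tailed cumulative
#' hypergeometric probability of observing at least `k` members when
#' drawing `n = |set|` genes from the `N = |background|` background.
#' Significance is called at a Bonferroni-style alpha (default 0.007).
#'
#' @param gene_set character vector of selected genes (must be a subset of
#'   the background).
#' @param background character vector of all genes with sufficient coverage
#'   to have been testable.
#' @param assignments category map: data.frame with columns `gene_id`,
#'   `category` (primary labels from [CATEGORY_VOCABULARY]), or a named
#'   character vector.
#' @param categories named list of tested category groups; each element is
#'   the set of primary labels pooled into that group. Defaults to the six
#'   tested groups TRP, MET/LIPID, SIGT, Redox/MIT, RRTT and CYT/STR.
#' @param bonferroni_alpha significance threshold on the unadjusted
#'   one-tailed p (default 0.007).
#' @return data.frame sorted by p: `category`, `k`, `K`, `n`, `N`,
#'   `p_upper`, `bonferroni_alpha`, `significant`.
#' @export
enrich_categories <- function(gene_set, background, assignments,
                              categories = default_tested_categories(),
                              bonferroni_alpha = 0.007) {
  assignments <- normalize_assignments(assignments)
  missing_bg <- setdiff(gene_set, background)
  if (length(missing_bg) > 0) {
    ps_validation_error("gene set member(s) absent from background: %s",
                        paste(utils::head(missing_bg, 5), collapse = ", "))
  }
  if (!is_prob(bonferroni_alpha)) {
    ps_validation_error("bonferroni_alpha must be a probability in (0, 1)")
  }
  bad <- setdiff(unlist(categories), CATEGORY_VOCABULARY)
  if (length(bad) > 0) {
    ps_validation_error("unknown category label(s): %s",
                        paste(bad, collapse = ", "))
  }
  n <- length(unique(gene_set))
  N <- length(unique(background))
  cat_of <- assignments$category[match(background, assignments$gene_id)]
  cat_of_set <- assignments$category[match(gene_set, assignments$gene_id)]
  rows <- lapply(names(categories), function(grp) {
    labels <- categories[[grp]]
    K <- sum(cat_of %in% labels, na.rm = TRUE)
    k <- sum(cat_of_set %in% labels, na.rm = TRUE)
    p <- hypergeom_upper_tail(k, K, n, N)
    data.frame(category = grp, k = k, K = K, n = n, N = N, p_upper = p,
               bonferroni_alpha = bonferroni_alpha,
               significant = p <= bonferroni_alpha)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_upper), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage breakdown of a gene set by functional category
#'
#' Percentages are reported to one decimal; after rounding they sum to
#' within \[99.0, 101.0\]. Genes without an assignment are counted as UNK
#' with a warning.
#'
#' @param gene_set character vector of genes (non-empty).
#' @param assignments category map (see [enrich_categories()]).
#' @return data.frame `category`, `n_genes`, `percent`, sorted by
#'   descending percentage.
#' @export
category_percentages <- function(gene_set, assignments) {
  if (length(gene_set) == 0) {
    ps_validation_error("gene set must be non-empty")
  }
  assignments <- normalize_assignments(assignments)
  cats <- assignments$category[match(gene_set, assignments$gene_id)]
  if (any(is.na(cats))) {
    warning(sprintf("%d gene(s) without category assignment counted as UNK",
                    sum(is.na(cats))), call. = FALSE)
    cats[is.na(cats)] <- "UNK"
  }
  tab <- table(cats)
  out <- data.frame(category = names(tab), n_genes = as.integer(tab),
                    percent = round(100 * as.integer(tab) / length(gene_set), 1))
  out <- out[order(-out$percent, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
normalize_assignments <- function(assignments) {
  if (is.character(assignments) && !is.null(names(assignments))) {
    assignments <- data.frame(gene_id = names(assignments),
                              category = unname(assignments))
  }
  require_columns(assignments, c("gene_id", "category"), "category map")
  bad <- setdiff(unique(assignments$category), CATEGORY_VOCABULARY)
  if (length(bad) > 0) {
    ps_validation_error("category label(s) outside the vocabulary: %s",
                        paste(bad, collapse = ", "))
  }
  if (anyDuplicated(assignments$gene_id)) {
    ps_validation_error("each gene must carry exactly one primary category label")
  }
  assignments
}
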