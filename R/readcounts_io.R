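#' Read per-site allele readcount tables
#'
#' Parses the readcounts TSV dialect (one file per pooled library) and
#' assembles a long per-site, per-library table of biallelic ref/alt counts.
#'
#' ## Dialect
#' A header line `chrom  pos  ref  depth  counts`, then one tab-separated
#' row per site: chromosome, 1-based position, reference base, total read
#' depth, and one or more `base:count` fields (e.g. `A:120`). Files may be
#' gzip-compressed. Base qualities are assumed to have been applied by the
#' readcount producer (e.g. a `--min-base-qual 30` upstream filter) and are
#' not part of the dialect.
#'
#' ## Filtering and biallelic reduction
#' Sites whose total depth is below `min_coverage` in *any* library are
#' excluded (the default of 22 reads matches the number of diploid genomes
#' per pool). Remaining sites are reduced to biallelic form: the alleles
#' kept are the stated reference base plus the non-reference allele with the
#' largest count pooled across all libraries; sites where any other allele
#' was observed are flagged `multiallelic`. After reduction
#' `depth = ref_count + alt_count`. Ref/alt orientation is fixed by the
#' stated reference base, never by frequency, which keeps the downstream
#' chi-square invariant to allele labelling.
#'
#' @param files data.frame describing the libraries, with columns `path`,
#'   `library_id`, `strain` (values `"R"` or `"S"`) and `replicate`
#'   (integer index within strain).
#' @param min_coverage minimum total depth required in every library for a
#'   site to be retained (reads; default 22).
#' @return A data.frame of class `site_counts` with one row per site and
#'   library: `chrom`, `pos`, `ref`, `alt`, `library_id`, `strain`,
#'   `replicate`, `ref_count`, `alt_count`, `depth`, `multiallelic`.
#' @export
read_readcounts <- function(files, min_coverage = 22) {
  if (!is.data.frame(files)) {
    ps_schema_error("`files` must be a data.frame of library descriptions")
  }
  require_columns(files, c("path", "library_id", "strain", "replicate"),
                  "library description table")
  if (!all(files$strain %in% c("R", "S"))) {
    ps_schema_error("strain labels must be 'R' or 'S'")
  }
  if (!is_count(min_coverage, positive = FALSE)) {
    ps_validation_error("min_coverage must be a non-negative integer")
  }
  per_lib <- lapply(seq_len(nrow(files)), function(i) {
    tab <- parse_readcounts_file(files$path[i])
    tab$library_id <- files$library_id[i]
    tab$strain <- files$strain[i]
    tab$replicate <- files$replicate[i]
    tab
  })
  long <- do.call(rbind, per_lib)
  assemble_site_counts(long, min_coverage)
}

# Parse one readcounts file into a long (chrom, pos, ref, base, count) table.
#' @noRd
parse_readcounts_file <- function(path) {
  if (!file.exists(path)) ps_parse_error("readcounts file not found: %s", path)
  lines <- readLines(path)   # file() auto-detects gzip
  if (length(lines) == 0 || !startsWith(lines[1], "chrom")) {
    ps_parse_error("%s: missing 'chrom ...' header line", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineno <- i + 1L
    if (length(fields) < 5) {
      ps_parse_error("%s line %d: expected at least 5 tab-separated fields",
                     path, lineno)
    }
    pos <- suppressWarnings(as.integer(fields[2]))
    depth <- suppressWarnings(as.integer(fields[4]))
    if (is.na(pos) || pos < 1 || is.na(depth) || depth < 0) {
      ps_parse_error("%s line %d: malformed position or depth", path, lineno)
    }
    ref <- fields[3]
    if (!ref %in% c("A", "C", "G", "T")) {
      ps_parse_error("%s line %d: unknown reference base '%s'", path, lineno, ref)
    }
    pairs <- strsplit(fields[-(1:4)], ":", fixed = TRUE)
    if (any(lengths(pairs) != 2)) {
      ps_parse_error("%s line %d: malformed base:count field", path, lineno)
    }
    bases <- vapply(pairs, `[`, "", 1)
    counts <- suppressWarnings(as.integer(vapply(pairs, `[`, "", 2)))
    if (!all(bases %in% c("A", "C", "G", "T"))) {
      ps_parse_error("%s line %d: unknown base symbol '%s'", path, lineno,
                     paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ","))
    }
    if (any(is.na(counts)) || any(counts < 0)) {
      ps_parse_error("%s line %d: allele counts must be non-negative integers",
                     path, lineno)
    }
    out[[i]] <- data.frame(chrom = fields[1], pos = pos, ref = ref,
                           base = bases, count = counts)
  }
  do.call(rbind, out)
}

# Coverage filter + biallelic reduction over the combined long allele table.
#' @noRd
assemble_site_counts <- function(long, min_coverage) {
  libs <- unique(long[, c("library_id", "strain", "replicate")])
  n_lib <- nrow(libs)
  key <- paste(long$chrom, long$pos, sep = "\r")
  idx_by_site <- split(seq_len(nrow(long)), key)

  rows <- vector("list", length(idx_by_site))
  ri <- 0L
  for (idx in idx_by_site) {
    sub <- long[idx, , drop = FALSE]
    ref <- unique(sub$ref)
    if (length(ref) != 1) {
      ps_parse_error("site %s:%d: inconsistent reference base across libraries",
                     sub$chrom[1], sub$pos[1])
    }
    # a site absent from a library has depth 0 there
    depth_by_lib <- tapply(sub$count, factor(sub$library_id, libs$library_id),
                           sum, default = 0)
    if (length(unique(sub$library_id)) < n_lib ||
        any(depth_by_lib < min_coverage)) next

    pooled <- tapply(sub$count, sub$base, sum)
    non_ref <- pooled[setdiff(names(pooled), ref)]
    if (length(non_ref) == 0 || max(non_ref) == 0) next  # monomorphic site
    alt <- names(non_ref)[which.max(non_ref)]
    multi <- sum(pooled > 0) > 2

    lib_f <- factor(sub$library_id, libs$library_id)
    rc <- tapply(sub$count * (sub$base == ref), lib_f, sum, default = 0)
    ac <- tapply(sub$count * (sub$base == alt), lib_f, sum, default = 0)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(chrom = sub$chrom[1], pos = sub$pos[1],
                             ref = ref, alt = alt,
                             library_id = libs$library_id,
                             strain = libs$strain,
                             replicate = libs$replicate,
                             ref_count = as.integer(rc),
                             alt_count = as.integer(ac),
                             depth = as.integer(rc + ac),
                             multiallelic = multi)
  }
  out <- if (ri > 0) do.call(rbind, rows[seq_len(ri)]) else empty_site_counts()
  out <- out[order(out$chrom, out$pos, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_counts", "data.frame")
  out
}

#' @noRd
empty_site_counts <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), library_id = character(0),
             strain = character(0), replicate = integer(0),
             ref_count = integer(0), alt_count = integer(0),
             depth = integer(0), multiallelic = logical(0))
}

#' Write per-library readcount tables in the readcounts TSV dialect
#'
#' Inverse of [read_readcounts()]: writes one file per library so that
#' reading them back reproduces identical counts.
#'
#' @param sites a `site_counts` data.frame (long, per site x library).
#' @param dir output directory (created if needed).
#' @return the library description data.frame accepted by
#'   [read_readcounts()] (columns `path`, `library_id`, `strain`,
#'   `replicate`).
#' @export
write_readcounts <- function(sites, dir) {
  require_columns(sites, c("chrom", "pos", "ref", "alt", "library_id",
                           "strain", "replicate", "ref_count", "alt_count"),
                  "site_counts table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  libs <- unique(sites[, c("library_id", "strain", "replicate")])
  paths <- character(nrow(libs))
  for (i in seq_len(nrow(libs))) {
    sub <- sites[sites$library_id == libs$library_id[i], , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$pos), , drop = FALSE]
    lines <- c("chrom\tpos\tref\tdepth\tcounts",
               sprintf("%s\t%d\t%s\t%d\t%s:%d\t%s:%d",
                       sub$chrom, sub$pos, sub$ref,
                       sub$ref_count + sub$alt_count,
                       sub$ref, sub$ref_count, sub$alt, sub$alt_count))
    paths[i] <- file.path(dir, paste0(libs$library_id[i], ".readcounts.tsv"))
    writeLines(lines, paths[i])
  }
  data.frame(path = paths, library_id = libs$library_id,
             strain = libs$strain, replicate = libs$replicate,
             row.names = NULL)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ input (0-based half-open) is converted at this boundary to the
#' package's internal 1-based inclusive coordinates; everything downstream
#' (SNP positions, interval membership) is 1-based. Ordering is preserved
#' and overlapping intervals are permitted. Unnamed rows receive synthetic
#' names `<kind>_<i>`.
#'
#' @param path BED file (may be gzip-compressed, extension `.bed`/`.bed.gz`).
#' @param kind interval kind, `"gene"` or `"pre_miRNA"`.
#' @return data.frame of class `genomic_intervals` with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `name`, `kind`.
#' @export
read_intervals <- function(path, kind = c("gene", "pre_miRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) ps_parse_error("BED file not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) ps_parse_error("failed to parse BED file %s: %s",
                                       path, conditionMessage(e))
  )
  if (any(GenomicRanges::width(gr) < 1)) {
    ps_parse_error("%s: interval with end <= start", path)
  }
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) S4Vectors::mcols(gr)$name else NA
  nm <- as.character(nm)
  nm[is.na(nm)] <- sprintf("%s_%d", kind, which(is.na(nm)))
  if (anyDuplicated(nm)) {
    ps_validation_error("%s: duplicate interval name(s) within kind '%s'",
                        path, kind)
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    name = nm, kind = kind)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write genomic intervals to a BED file
#'
#' Converts the internal 1-based inclusive coordinates back to BED's
#' 0-based half-open convention.
#' @param intervals data.frame with `chrom`, `start`, `end`, `name`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  require_columns(intervals, c("chrom", "start", "end", "name"), "interval table")
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start) - 1L,
                     as.integer(intervals$end), intervals$name),
             path)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Tab-separated with header `chrom`, `pos`, then one depth column per
#' library (the layout produced by `samtools depth` with a header added).
#' Positions are 1-based; depths must be non-negative.
#'
#' @param path TSV path (may be gzip-compressed).
#' @return data.frame of class `depth_table`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) ps_parse_error("depth table not found: %s", path)
  tab <- read.delim(path, check.names = FALSE)
  require_columns(tab, c("chrom", "pos"), "depth table")
  depth_cols <- setdiff(names(tab), c("chrom", "pos"))
  if (length(depth_cols) == 0) ps_schema_error("depth table has no library columns")
  for (cc in depth_cols) {
    if (any(is.na(tab[[cc]])) || any(tab[[cc]] < 0)) {
      ps_validation_error("depth table column '%s' has missing or negative depths", cc)
    }
  }
  class(tab) <- c("depth_table", "data.frame")
  tab
}

#' Mean depth and covered fraction of an interval
#'
#' Averages per-base depth over *all* positions of the interval; positions
#' absent from the depth table count as depth 0. `covered_fraction` is the
#' fraction of interval bases at which every library reaches
#' `min_coverage`; `mean_depth` averages the per-library means. A
#' chromosome absent from the table yields mean 0 with a warning (sparse
#' tables are expected), not an error.
#'
#' @param depth a `depth_table` data.frame (`chrom`, `pos`, one column per
#'   library).
#' @param interval single interval: one-row data.frame or list with
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @param min_coverage per-library depth required for a base to count as
#'   covered (default 22).
#' @return list with `mean_depth`, `covered_fraction`, and `per_library`
#'   (data.frame of per-library means and covered fractions).
#' @export
interval_mean_depth <- function(depth, interval, min_coverage = 22) {
  require_columns(depth, c("chrom", "pos"), "depth table")
  depth_cols <- setdiff(names(depth), c("chrom", "pos"))
  start <- as.integer(interval$start)
  end <- as.integer(interval$end)
  if (is.na(start) || is.na(end) || start > end) {
    ps_validation_error("invalid interval coordinates")
  }
  width <- end - start + 1L
  sub <- depth[depth$chrom == interval$chrom &
                 depth$pos >= start & depth$pos <= end, , drop = FALSE]
  if (!any(depth$chrom == interval$chrom)) {
    warning(sprintf("chromosome '%s' absent from depth table; mean depth 0",
                    interval$chrom), call. = FALSE)
  }
  if (length(depth_cols) == 0) ps_schema_error("depth table has no library columns")
  per_lib_mean <- vapply(depth_cols, function(cc) sum(sub[[cc]]) / width, 0)
  per_lib_cov <- vapply(depth_cols, function(cc) {
    sum(sub[[cc]] >= min_coverage) / width
  }, 0)
  covered <- if (nrow(sub) == 0) 0 else {
    ok <- rowSums(as.matrix(sub[, depth_cols, drop = FALSE]) >= min_coverage) ==
      length(depth_cols)
    sum(ok) / width
  }
  list(mean_depth = mean(per_lib_mean),
       covered_fraction = covered,
       per_library = data.frame(library_id = depth_cols,
                                mean_depth = unname(per_lib_mean),
                                covered_fraction = unname(per_lib_cov)))
}
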