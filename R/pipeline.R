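#' Simulate knockdown time-course records
#'
#' Each insect that will be knocked down by the end of the 1-hour assay
#' (probability `kd60` per group) is assigned a knockdown time uniformly on
#' the 10-minute observation grid, giving nondecreasing cumulative counts
#' per replicate bottle.
#'
#' @param group_kd60 named numeric vector: probability of knockdown by
#'   60 min per treatment group.
#' @param n_per_rep insects per replicate bottle.
#' @param n_replicates replicate bottles per group.
#' @param seed integer RNG seed.
#' @return data.frame of knockdown records: `group`, `replicate`,
#'   `timepoint`, `n_down`, `n_total`.
#' @export
simulate_knockdown <- function(group_kd60, n_per_rep = 20, n_replicates = 3,
                               seed = 1) {
  if (is.null(names(group_kd60)) || any(group_kd60 < 0) || any(group_kd60 > 1)) {
    ps_validation_error("group_kd60 must be a named vector of probabilities")
  }
  set.seed(seed)
  grid <- seq(10, 60, by = 10)
  rows <- list()
  for (g in names(group_kd60)) {
    for (r in seq_len(n_replicates)) {
      n_down_total <- rbinom(1, n_per_rep, group_kd60[[g]])
      times <- sample(grid, n_down_total, replace = TRUE)
      cum <- vapply(grid, function(t) sum(times <= t), 0L)
      rows[[length(rows) + 1L]] <- data.frame(group = g, replicate = r,
                                              timepoint = grid,
                                              n_down = cum,
                                              n_total = n_per_rep)
    }
  }
  do.call(rbind, rows)
}

#' Write a self-contained fixture bundle
#'
#' Generates every input the pipeline consumes into one directory:
#' per-library readcount TSVs plus a library description table, gene and
#' pre-miRNA BED files, a per-base depth table over the hairpin intervals,
#' dose-response / genotype / Ct / knockdown CSV tables, a gene category
#' map, and a ready-to-run `config.yaml`.
#'
#' The bundled bioassays use the two strains' LC50 scales (susceptible
#' ~2.41 ug, resistant ~24.92 ug per bottle, slope 3 per log10 dose) and
#' the resistant colony's KDR genotype composition (67% homozygous
#' resistant, 25% fully heterozygous). The category map plants a transport
#' (TRP) enrichment among the genes carrying selected sites so the
#' enrichment stage has signal to find.
#'
#' @param dir output directory.
#' @param sim_params a [pool_sim_params()] object; the default fixture
#'   configuration uses single-stage sampling so that site p values are
#'   calibrated (see the methods vignette for the rationale).
#' @param seed integer seed for the assay-side simulations.
#' @return path of the written `config.yaml`, invisibly.
#' @export
write_fixture_bundle <- function(dir,
                                 sim_params = pool_sim_params(sampling = "single_stage"),
                                 seed = sim_params$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_pool_readcounts(sim_params)

  files <- write_readcounts(sim$counts, file.path(dir, "readcounts"))
  files$path <- file.path("readcounts", basename(files$path))
  write.table(files, file.path(dir, "libraries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_intervals(sim$genes, file.path(dir, "genes.bed"))
  write_intervals(sim$premirnas, file.path(dir, "premirnas.bed"))

  # per-base depth over the hairpin intervals, one column per library
  set.seed(seed + 1)
  pm <- sim$premirnas
  pos_list <- lapply(seq_len(nrow(pm)), function(i) {
    data.frame(chrom = pm$chrom[i], pos = seq(pm$start[i], pm$end[i]))
  })
  depth_tab <- do.call(rbind, pos_list)
  for (lib in sim$libraries$library_id) {
    depth_tab[[lib]] <- rnbinom(nrow(depth_tab),
                                mu = sim$params$depth_mean,
                                size = sim$params$depth_dispersion)
  }
  # make the simulated site depths consistent with the site table
  for (i in seq_len(nrow(depth_tab))) {
    hit <- sim$counts$pos == depth_tab$pos[i] &
      sim$counts$chrom == depth_tab$chrom[i]
    if (any(hit)) {
      sub <- sim$counts[hit, ]
      depth_tab[i, sub$library_id] <- sub$depth
    }
  }
  write.table(depth_tab, file.path(dir, "depth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # category map: TRP planted among genes that carry selected sites
  set.seed(seed + 2)
  sel_genes <- unique(sim$truth$gene_id[sim$truth$selected &
                                          !is.na(sim$truth$gene_id)])
  base_cats <- c("DIV", "UNK", "RRTT", "MET/LIPID", "SIGT", "CYT/STR",
                 "PROT", "ReDox", "MIT", "TRP", "IMM", "CSR")
  base_w <- c(0.25, 0.18, 0.12, 0.09, 0.08, 0.07, 0.07, 0.05, 0.03, 0.03,
              0.015, 0.015)
  cats <- sample(base_cats, sim_params$n_genes, replace = TRUE,
                 prob = base_w / sum(base_w))
  names(cats) <- sim$genes$name
  cats[sel_genes] <- sample(c("TRP", "MET/LIPID"), length(sel_genes),
                            replace = TRUE, prob = c(0.8, 0.2))
  cat_map <- data.frame(gene_id = sim$genes$name, category = unname(cats))
  write.csv(cat_map, file.path(dir, "category_map.csv"), row.names = FALSE)

  # bioassays at the two strains' LC50 scales
  dr_s <- simulate_dose_response(
    bioassay_sim_params(true_lc50 = 2.41, probit_slope = 3, seed = seed + 3),
    population = "S")
  dr_r <- simulate_dose_response(
    bioassay_sim_params(true_lc50 = 24.92, probit_slope = 3, seed = seed + 4),
    population = "R")
  write.csv(rbind(dr_s, dr_r), file.path(dir, "dose_response.csv"),
            row.names = FALSE)

  assays <- simulate_assay_tables(seed = seed + 5)
  write.csv(assays$genotypes, file.path(dir, "genotypes.csv"),
            row.names = FALSE)
  write.csv(assays$cts, file.path(dir, "cts.csv"), row.names = FALSE)

  kd <- simulate_knockdown(c(control = 0.85, G_mir33 = 0.98, C_mir33 = 0.65),
                           seed = seed + 6)
  write.csv(kd, file.path(dir, "knockdown.csv"), row.names = FALSE)

  config <- list(
    seed = seed,
    out_dir = "output",
    inputs = list(libraries = "libraries.tsv",
                  genes_bed = "genes.bed",
                  premirnas_bed = "premirnas.bed",
                  depth = "depth.tsv",
                  category_map = "category_map.csv",
                  dose_response = "dose_response.csv",
                  genotypes = "genotypes.csv",
                  cts = "cts.csv",
                  knockdown = "knockdown.csv"),
    filters = list(min_coverage = 22, rep_p_cutoff = 0.10,
                   bh_cutoff = 0.001, gene_threshold = 15,
                   mirna_threshold = 3.0, weighting = "depth"),
    enrichment = list(bonferroni_alpha = 0.007),
    assays = list(target = "VGSC",
                  reference_genes = c("ACTIN", "RPS7"),
                  calibrator_group = "control",
                  resistant_population = "R",
                  susceptible_population = "S")
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

PIPELINE_CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "inputs", "filters", "enrichment", "assays"),
  inputs = c("libraries", "genes_bed", "premirnas_bed", "depth",
             "category_map", "dose_response", "genotypes", "cts",
             "knockdown"),
  filters = c("min_coverage", "rep_p_cutoff", "bh_cutoff", "gene_threshold",
              "mirna_threshold", "weighting"),
  enrichment = c("bonferroni_alpha", "categories"),
  assays = c("target", "reference_genes", "calibrator_group",
             "resistant_population", "susceptible_population")
)

#' @noRd
validate_config <- function(config) {
  check <- function(keys, valid, section) {
    unknown <- setdiff(keys, valid)
    if (length(unknown) > 0) {
      ps_config_error("unknown config key(s) in %s: %s (valid keys: %s)",
                      section, paste(unknown, collapse = ", "),
                      paste(valid, collapse = ", "))
    }
  }
  check(names(config), PIPELINE_CONFIG_KEYS$top, "top level")
  for (sec in c("inputs", "filters", "enrichment", "assays")) {
    if (!is.null(config[[sec]])) {
      check(names(config[[sec]]), PIPELINE_CONFIG_KEYS[[sec]], sec)
    }
  }
  if (is.null(config$inputs)) ps_config_error("config must define an 'inputs' section")
  invisible(config)
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates, in order: read inputs, association scan, pre-miRNA scan,
#' category enrichment, bioassay and molecular-assay statistics. All stage
#' outputs are written under the configured output directory, each CSV
#' carrying a provenance header (tool version, seed, config hash), plus a
#' `summary.json` that is byte-identical across runs with the same config
#' and seed.
#'
#' @param config path to a YAML config (as written by
#'   [write_fixture_bundle()]) or an equivalent named list. Relative input
#'   paths are resolved against the config file's directory.
#' @param out_dir optional override of the configured output directory.
#' @return list of class `pipeline_result` with elements `association`,
#'   `mirna`, `enrichment`, `percentages`, `assays`, `summary`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) ps_config_error("config file not found: %s", config)
    base_dir <- dirname(config)
    cfg_hash <- unname(md5sum(config))
    config <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(config, tmp)
    cfg_hash <- unname(md5sum(tmp))
  } else {
    ps_config_error("config must be a file path or a named list")
  }
  validate_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(out_dir)) {
    out_dir <- config$out_dir
    if (is.null(out_dir)) out_dir <- "output"
    if (!grepl("^(/|[A-Za-z]:)", out_dir)) out_dir <- file.path(base_dir, out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ps_stop("stage '%s' failed: %s", "poolscan_stage_error", name,
              conditionMessage(e))
    })
  }
  provenance <- sprintf("# poolscan %s; seed=%d; config_md5=%s",
                        as.character(packageVersion("poolscan")), seed,
                        cfg_hash)
  write_stage_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(provenance, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  log_lines <- c(provenance,
                 sprintf("# R %s", paste(R.version$major, R.version$minor,
                                         sep = ".")))

  fp_args <- config$filters
  params <- if (is.null(fp_args)) filter_params() else do.call(filter_params, fp_args)

  # --- associate ---
  assoc <- stage("associate", {
    libs <- read.delim(resolve(config$inputs$libraries))
    require_columns(libs, c("path", "library_id", "strain", "replicate"),
                    "libraries table")
    libs$path <- vapply(libs$path, resolve, "")
    sites <- read_readcounts(libs, min_coverage = params$min_coverage)
    genes <- read_intervals(resolve(config$inputs$genes_bed), kind = "gene")
    run_association(sites, genes, params)
  })
  write_stage_csv(assoc$site_table, "site_table.csv")
  write_stage_csv(assoc$gene_table, "gene_table.csv")
  write_stage_csv(assoc$skipped_genes, "skipped_genes.csv")
  log_lines <- c(log_lines,
                 sprintf("associate: %d sites, %d genes scored, %d at threshold",
                         nrow(assoc$site_table), nrow(assoc$gene_table),
                         assoc$tallies$total))

  # --- scan-mirna ---
  mirna <- stage("scan-mirna", {
    pms <- read_intervals(resolve(config$inputs$premirnas_bed),
                          kind = "pre_miRNA")
    depth <- if (!is.null(config$inputs$depth)) {
      read_depth_table(resolve(config$inputs$depth))
    } else {
      NULL
    }
    scan_premirna_snps(assoc$site_table, pms, depth, params)
  })
  write_stage_csv(mirna$hits, "mirna_hits.csv")
  write_stage_csv(mirna$coverage, "mirna_coverage.csv")
  log_lines <- c(log_lines, sprintf("scan-mirna: %d hit(s)", nrow(mirna$hits)))

  # --- enrich ---
  enr <- perc <- NULL
  if (!is.null(config$inputs$category_map)) {
    enr_alpha <- config$enrichment$bonferroni_alpha
    if (is.null(enr_alpha)) enr_alpha <- 0.007
    enr <- stage("enrich", {
      cat_map <- read.csv(resolve(config$inputs$category_map))
      background <- assoc$gene_table$gene_id
      gene_set <- assoc$gene_table$gene_id[assoc$gene_table$passes_threshold]
      if (length(gene_set) == 0) {
        NULL
      } else {
        list(result = enrich_categories(gene_set, background, cat_map,
                                        bonferroni_alpha = enr_alpha),
             percentages = category_percentages(gene_set, cat_map))
      }
    })
    if (!is.null(enr)) {
      perc <- enr$percentages
      enr <- enr$result
      write_stage_csv(enr, "enrichment.csv")
      write_stage_csv(perc, "category_percentages.csv")
    }
  }

  # --- assays ---
  assays <- stage("assays", {
    out <- list()
    if (!is.null(config$inputs$dose_response)) {
      dr <- read.csv(resolve(config$inputs$dose_response))
      fits <- lapply(split(dr, dr$population), fit_probit_lc50)
      out$lc50 <- data.frame(
        population = names(fits),
        lc50 = vapply(fits, function(f) f$lc50, 0),
        ci_lower = vapply(fits, function(f) f$ci_lower, 0),
        ci_upper = vapply(fits, function(f) f$ci_upper, 0),
        slope = vapply(fits, function(f) f$slope, 0),
        converged = vapply(fits, function(f) f$converged, TRUE))
      rp <- config$assays$resistant_population
      sp <- config$assays$susceptible_population
      if (!is.null(rp) && !is.null(sp) && all(c(rp, sp) %in% names(fits))) {
        out$resistance_ratio <- resistance_ratio(fits[[rp]], fits[[sp]])
      }
    }
    if (!is.null(config$inputs$genotypes)) {
      out$genotypes <- genotype_frequencies(
        read.csv(resolve(config$inputs$genotypes)))
    }
    if (!is.null(config$inputs$cts)) {
      out$ddct <- ddct_relative_quantity(
        read.csv(resolve(config$inputs$cts)),
        target = config$assays$target,
        reference_genes = unlist(config$assays$reference_genes),
        calibrator_group = config$assays$calibrator_group)
    }
    if (!is.null(config$inputs$knockdown)) {
      out$knockdown <- knockdown_summary(read.csv(resolve(config$inputs$knockdown)))
    }
    out
  })
  if (!is.null(assays$lc50)) write_stage_csv(assays$lc50, "lc50.csv")

  summary <- list(
    provenance = list(tool = "poolscan",
                      version = as.character(packageVersion("poolscan")),
                      seed = seed, config_md5 = cfg_hash),
    association = list(n_sites = nrow(assoc$site_table),
                       n_sites_pass = sum(assoc$site_table$status == "pass"),
                       genes_scored = nrow(assoc$gene_table),
                       tallies = assoc$tallies),
    mirna = list(n_hits = nrow(mirna$hits),
                 top_hit = if (nrow(mirna$hits) > 0) {
                   list(mirna = mirna$hits$mirna[1],
                        chrom = mirna$hits$chrom[1],
                        pos = mirna$hits$pos[1],
                        neg_log10_p = round(mirna$hits$neg_log10_p[1], 4))
                 } else {
                   NULL
                 }),
    enrichment = if (!is.null(enr)) {
      list(top_category = enr$category[1],
           p_upper = signif(enr$p_upper[1], 6),
           significant = enr$significant[1])
    } else {
      NULL
    },
    assays = list(
      lc50 = if (!is.null(assays$lc50)) {
        lapply(split(assays$lc50, assays$lc50$population), function(r) {
          list(lc50 = round(r$lc50, 4), ci_lower = round(r$ci_lower, 4),
               ci_upper = round(r$ci_upper, 4))
        })
      } else {
        NULL
      },
      resistance_ratio = assays$resistance_ratio,
      calibrator_rq = if (!is.null(assays$ddct)) {
        cal <- config$assays$calibrator_group
        round(assays$ddct$per_group$rq[assays$ddct$per_group$group == cal], 6)
      } else {
        NULL
      })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  structure(list(association = assoc, mirna = mirna, enrichment = enr,
                 percentages = perc, assays = assays, summary = summary,
                 out_dir = out_dir),
            class = "pipeline_result")
}
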