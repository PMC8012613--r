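#' Log-dose probit LC50 fit
#'
#' Maximum-likelihood probit regression of death probability on
#' `log10(dose)`, the standard analysis of CDC bottle bioassays. The LC50
#' is `10^(-intercept/slope)`; its 95% confidence interval is obtained by
#' the delta method on `log10(LC50)` and exponentiated (Fieller's method is
#' available via `ci_method = "fieller"`).
#'
#' The fit is reported as non-converged when the glm does not converge,
#' the slope is not positive, or every dose shows complete mortality or
#' complete survival (non-identifiable). Records with no dose at partial
#' mortality are flagged with a warning (the LC50 is then an
#' extrapolation).
#'
#' @param records data.frame of dose-response records with columns `dose`
#'   (ug per bottle, > 0), `n_exposed`, `n_dead` (one row per bottle;
#'   additional columns such as `population`/`replicate` are ignored).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"delta"` (default) or `"fieller"`.
#' @return object of class `probit_fit`: list with `intercept`, `slope`
#'   (per log10 dose), `lc50`, `ci_lower`, `ci_upper`, `converged`,
#'   `message`, `n_doses`, `model`.
#' @export
fit_probit_lc50 <- function(records, conf_level = 0.95,
                            ci_method = c("delta", "fieller")) {
  ci_method <- match.arg(ci_method)
  require_columns(records, c("dose", "n_exposed", "n_dead"),
                  "dose-response table")
  if (any(records$dose <= 0)) ps_validation_error("doses must be positive")
  if (any(records$n_dead < 0) || any(records$n_dead > records$n_exposed)) {
    ps_validation_error("n_dead must lie in [0, n_exposed]")
  }
  doses <- unique(records$dose)
  if (length(doses) < 3) {
    ps_validation_error("at least 3 distinct doses are required (got %d)",
                        length(doses))
  }

  per_dose_dead <- tapply(records$n_dead, records$dose, sum)
  per_dose_n <- tapply(records$n_exposed, records$dose, sum)
  all_dead <- all(per_dose_dead == per_dose_n)
  all_alive <- all(per_dose_dead == 0)
  if (all_dead || all_alive) {
    return(structure(list(intercept = NA_real_, slope = NA_real_,
                          lc50 = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, converged = FALSE,
                          message = "non-identifiable: complete mortality or complete survival at every dose",
                          n_doses = length(doses), model = NULL),
                     class = "probit_fit"))
  }
  if (!any(per_dose_dead > 0 & per_dose_dead < per_dose_n)) {
    warning("no dose shows partial mortality; LC50 is interpolated between extreme doses",
            call. = FALSE)
  }

  x <- log10(records$dose)
  fit <- suppressWarnings(
    glm(cbind(records$n_dead, records$n_exposed - records$n_dead) ~ x,
        family = binomial(link = "probit"))
  )
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  converged <- isTRUE(fit$converged) && is.finite(b) && b > 0
  msg <- if (converged) "ok" else if (!is.finite(b) || b <= 0) {
    "invalid fit: non-positive dose slope"
  } else {
    "glm did not converge"
  }

  log_lc50 <- -a / b
  lc50 <- 10^log_lc50
  ci <- c(NA_real_, NA_real_)
  if (is.finite(b) && b > 0) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    V <- vcov(fit)
    if (ci_method == "delta") {
      grad <- c(-1 / b, a / b^2)
      se <- sqrt(drop(t(grad) %*% V %*% grad))
      ci <- 10^(log_lc50 + c(-1, 1) * z * se)
    } else {
      # Fieller interval: rho = -a/b satisfies a + rho*b = 0; invert the
      # quadratic (b^2 - z^2 v22) rho^2 + 2(ab - z^2 v12) rho + (a^2 - z^2 v11) <= 0
      A <- b^2 - z^2 * V[2, 2]
      B <- 2 * (a * b - z^2 * V[1, 2])
      C <- a^2 - z^2 * V[1, 1]
      disc <- B^2 - 4 * A * C
      if (A > 0 && disc >= 0) {
        roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
        ci <- 10^roots
      }
    }
  }
  structure(list(intercept = a, slope = b, lc50 = lc50,
                 ci_lower = ci[1], ci_upper = ci[2], converged = converged,
                 message = msg, n_doses = length(doses), model = fit),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Log-dose probit fit\n")
  cat(sprintf("  LC50: %.4g (%.0f%% CI %.4g - %.4g)\n", x$lc50,
              100 * 0.95, x$ci_lower, x$ci_upper))
  cat(sprintf("  slope (per log10 dose): %.4g; converged: %s\n",
              x$slope, x$converged))
  invisible(x)
}

#' Resistance ratio of two probit fits
#'
#' Ratio of the resistant strain's LC50 to the susceptible strain's,
#' reported to two decimals.
#'
#' @param fit_R,fit_S converged [fit_probit_lc50()] results (resistant and
#'   susceptible populations).
#' @return numeric ratio rounded to two decimals.
#' @examples
#' \dontrun{resistance_ratio(fit_vr, fit_vu)}
#' @export
resistance_ratio <- function(fit_R, fit_S) {
  if (!inherits(fit_R, "probit_fit") || !inherits(fit_S, "probit_fit")) {
    ps_validation_error("resistance_ratio() expects two probit_fit objects")
  }
  if (!isTRUE(fit_R$converged) || !isTRUE(fit_S$converged)) {
    ps_validation_error("both probit fits must have converged")
  }
  if (!is.finite(fit_S$lc50) || fit_S$lc50 <= 0) {
    ps_validation_error("susceptible LC50 must be positive")
  }
  round(fit_R$lc50 / fit_S$lc50, 2)
}

#' Fisher's exact test for a 2x2 mortality table
#'
#' Exact two-sided p computed by enumerating all tables with the observed
#' margins and summing the hypergeometric probabilities of those no more
#' probable than the observed table (with the conventional relative
#' tolerance of 1e-7 for ties). [stats::fisher.test()] implements the same
#' definition and serves as an independent cross-check in the test suite.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = outcome
#'   (e.g. dead/alive), columns = groups.
#' @return two-sided p value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 9, 7, 1), 2))  # ~ 0.0198
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) ps_validation_error("table must be 2x2")
  if (any(tab < 0) || any(tab != floor(tab))) {
    ps_validation_error("cells must be non-negative integers")
  }
  if (any(rowSums(tab) == 0)) {
    ps_validation_error("zero row margin (no subjects with one outcome label in any group)")
  }
  m <- sum(tab[, 1])   # column-1 margin
  n2 <- sum(tab[, 2])
  r1 <- sum(tab[1, ])  # row-1 margin
  support <- max(0, r1 - n2):min(r1, m)
  dens <- dhyper(support, m, n2, r1)
  d_obs <- dhyper(tab[1, 1], m, n2, r1)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

#' Classical one-way ANOVA
#'
#' One-way fixed-effects F test with the pooled (equal-variance) error
#' term, as used to compare knockdown or expression levels between
#' treatment groups. With two groups the F statistic equals the square of
#' the pooled-variance t statistic.
#'
#' @param groups either a named list of numeric vectors (one per group) or
#'   a data.frame with columns `group` and `value`.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(groups) {
  if (is.data.frame(groups)) {
    require_columns(groups, c("group", "value"), "ANOVA table")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2) {
    ps_validation_error("at least 2 groups are required")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    ps_validation_error("every group needs at least 2 observations")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  grand <- mean(y)
  means <- vapply(groups, mean, 0)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((y - means[as.integer(g)])^2)
  if (ssb == 0 && ssw == 0) {
    ps_validation_error("zero within- and between-group variance")
  }
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df_between = df1, df_within = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Genotype and allele frequencies from multi-locus genotype records
#'
#' Summarises genotype records (one row per individual and locus) into
#' per-locus genotype-class proportions, per-locus resistant-allele
#' frequencies, and composite multi-locus classes: individuals homozygous
#' resistant at every requested locus, heterozygous at every locus,
#' homozygous susceptible at every locus, or mixed. Individuals missing a
#' genotype at any requested locus are excluded from composite denominators
#' (a note reports how many).
#'
#' @param records data.frame with columns `individual`, `locus`,
#'   `genotype` (values `hom_susceptible`, `heterozygous`,
#'   `hom_resistant`).
#' @param loci loci to summarise (default: all in `records`).
#' @return list with
#'   \describe{
#'     \item{per_locus}{genotype-class counts and proportions per locus.}
#'     \item{allele_freq}{per-locus resistant-allele frequency
#'       (`hom_resistant + heterozygous/2`).}
#'     \item{composite}{multi-locus class proportions over fully genotyped
#'       individuals.}
#'     \item{n_excluded}{individuals dropped for missing genotypes.}
#'   }
#' @export
genotype_frequencies <- function(records, loci = NULL) {
  require_columns(records, c("individual", "locus", "genotype"),
                  "genotype table")
  classes <- c("hom_susceptible", "heterozygous", "hom_resistant")
  bad <- setdiff(unique(records$genotype), c(classes, NA))
  if (length(bad) > 0) {
    ps_validation_error("unknown genotype code(s): %s", paste(bad, collapse = ", "))
  }
  if (is.null(loci)) loci <- unique(records$locus)
  unknown <- setdiff(loci, unique(records$locus))
  if (length(unknown) > 0) {
    ps_validation_error("unknown locus(es): %s", paste(unknown, collapse = ", "))
  }
  records <- records[records$locus %in% loci & !is.na(records$genotype), ,
                     drop = FALSE]
  if (nrow(records) == 0) {
    ps_validation_error("no genotyped individuals at the requested loci")
  }

  per_locus <- do.call(rbind, lapply(loci, function(l) {
    sub <- records[records$locus == l, ]
    tab <- table(factor(sub$genotype, classes))
    data.frame(locus = l, genotype = names(tab), n = as.integer(tab),
               proportion = as.integer(tab) / nrow(sub))
  }))
  allele_freq <- do.call(rbind, lapply(loci, function(l) {
    sub <- records[records$locus == l, ]
    f <- (sum(sub$genotype == "hom_resistant") +
            0.5 * sum(sub$genotype == "heterozygous")) / nrow(sub)
    data.frame(locus = l, resistant_allele_freq = f, n = nrow(sub))
  }))

  # composite classes over fully genotyped individuals
  inds <- unique(records$individual)
  geno_by_ind <- lapply(inds, function(i) {
    sub <- records[records$individual == i, ]
    sub$genotype[match(loci, sub$locus)]
  })
  complete <- vapply(geno_by_ind, function(g) !any(is.na(g)), TRUE)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("%d individual(s) excluded from composite classes (missing genotypes)",
                    n_excluded))
  }
  comp <- vapply(geno_by_ind[complete], function(g) {
    if (all(g == "hom_resistant")) "hom_resistant_all" else
      if (all(g == "heterozygous")) "heterozygous_all" else
        if (all(g == "hom_susceptible")) "hom_susceptible_all" else "mixed"
  }, "")
  comp_tab <- table(factor(comp, c("hom_resistant_all", "heterozygous_all",
                                   "hom_susceptible_all", "mixed")))
  composite <- data.frame(class = names(comp_tab), n = as.integer(comp_tab),
                          proportion = as.integer(comp_tab) / sum(comp_tab))
  list(per_locus = per_locus, allele_freq = allele_freq,
       composite = composite, n_excluded = n_excluded)
}

#' Relative quantitation by the comparative Ct (delta-delta-Ct) method
#'
#' Technical replicates are averaged per sample and gene; then
#' `dCt = Ct_target - mean(Ct_references)` per sample,
#' `ddCt = dCt_sample - mean(dCt over calibrator samples)`, and the
#' relative quantity is `RQ = 2^(-ddCt)`. Multiple reference genes are
#' combined by the arithmetic mean of their Cts (equivalent to a geometric
#' mean of quantities at equal amplification efficiency). RQ is invariant
#' to adding a constant to every Ct, and the calibrator group has mean
#' `dCt` offset zero so a calibrator sample at the group-mean `dCt` has
#' RQ = 1.
#'
#' @param cts data.frame of Ct records: `sample_id`, `group`, `gene`, `ct`
#'   (and optionally `tech_rep`).
#' @param target target gene name.
#' @param reference_genes character vector of reference gene names.
#' @param calibrator_group calibrator group label.
#' @return list with `per_sample` (data.frame `sample_id`, `group`, `dct`,
#'   `ddct`, `rq`) and `per_group` (mean RQ and mean ddCt per group).
#' @export
ddct_relative_quantity <- function(cts, target, reference_genes,
                                   calibrator_group) {
  require_columns(cts, c("sample_id", "group", "gene", "ct"), "Ct table")
  if (any(cts$ct <= 0)) ps_validation_error("Ct values must be positive")
  if (!any(cts$group == calibrator_group)) {
    ps_validation_error("calibrator group '%s' has no samples", calibrator_group)
  }
  samples <- unique(cts[, c("sample_id", "group")])
  dct <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sub <- cts[cts$sample_id == samples$sample_id[i], ]
    t_ct <- sub$ct[sub$gene == target]
    if (length(t_ct) == 0) {
      ps_validation_error("sample '%s' lacks target gene '%s'",
                          samples$sample_id[i], target)
    }
    ref_means <- vapply(reference_genes, function(g) {
      r <- sub$ct[sub$gene == g]
      if (length(r) == 0) {
        ps_validation_error("sample '%s' lacks reference gene '%s'",
                            samples$sample_id[i], g)
      }
      mean(r)
    }, 0)
    dct[i] <- mean(t_ct) - mean(ref_means)
  }
  cal_mean <- mean(dct[samples$group == calibrator_group])
  ddct <- dct - cal_mean
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           dct = dct, ddct = ddct, rq = 2^(-ddct))
  per_group <- aggregate(ddct ~ group, per_sample, mean)
  # group RQ from the group-mean ddCt (geometric-mean style), so the
  # calibrator group has RQ exactly 1
  per_group$rq <- 2^(-per_group$ddct)
  list(per_sample = per_sample, per_group = per_group)
}

#' Knockdown time-course summary and group comparison
#'
#' Summarises knockdown records (insects down / total, per treatment
#' group, replicate and 10-minute timepoint) into per-group, per-timepoint
#' proportions, and compares groups with [oneway_anova()] on the
#' replicate-level knockdown proportions at a chosen timepoint (default
#' 60 min, the end of the standard 1-hour bottle assay).
#'
#' @param records data.frame: `group`, `replicate`, `timepoint` (minutes on
#'   the 10-minute grid), `n_down`, `n_total`.
#' @param anova_timepoint timepoint used for the group comparison.
#' @return list with `proportions` (per group x timepoint) and `anova`
#'   (result of [oneway_anova()] at `anova_timepoint`, or `NULL` with
#'   fewer than two groups).
#' @export
knockdown_summary <- function(records, anova_timepoint = 60) {
  require_columns(records, c("group", "replicate", "timepoint", "n_down",
                             "n_total"), "knockdown table")
  if (any(records$n_down < 0) || any(records$n_down > records$n_total)) {
    ps_validation_error("n_down must lie in [0, n_total]")
  }
  if (any(records$timepoint %% 10 != 0)) {
    ps_validation_error("timepoints must lie on the 10-minute grid")
  }
  records$prop <- records$n_down / records$n_total
  props <- aggregate(prop ~ group + timepoint, records, mean)
  props <- props[order(props$group, props$timepoint), , drop = FALSE]
  rownames(props) <- NULL
  sub <- records[records$timepoint == anova_timepoint, , drop = FALSE]
  an <- if (length(unique(sub$group)) >= 2) {
    oneway_anova(data.frame(group = sub$group, value = sub$prop))
  } else {
    NULL
  }
  list(proportions = props, anova = an)
}
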