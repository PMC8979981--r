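#' Per-module ploidy relative to the reference module ensemble
#'
#' Ploidy of module i is `2 * count_i / mean(reference counts)`: the
#' reference set is assumed diploid, so equal counts mean ploidy 2.
#'
#' @param counts `molecule_counts` data.frame carrying `role` (from a panel
#'   merge) or used together with `panel`.
#' @param panel `qaseq_panel`
#' @return named numeric vector of per-module ploidies (all non-excluded
#'   modules).
#' @export
module_ploidy <- function(counts, panel) {
  stopifnot(inherits(panel, "qaseq_panel"))
  cnt <- setNames(counts$molecule_count, counts$module_id)
  ref_ids <- reference_module_ids(panel)
  ref_mean <- mean(cnt[ref_ids], na.rm = TRUE)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("module_ploidy: reference mean count is zero")
  keep <- panel$modules$module_id[panel$modules$role != "excluded"]
  2 * cnt[keep] / ref_mean
}

#' Gene-level ploidy estimate
#'
#' `2 x mean(counts over the gene's modules) / mean(counts over reference
#' modules)`; the 2-plex special case reduces to
#' `2 x target count / reference count`.
#'
#' @inheritParams module_ploidy
#' @param gene gene symbol.
#' @param estimator `"mean"` (default, matching the module-ensemble
#'   definition) or `"median"` for outlier-heavy data.
#' @return numeric ploidy estimate.
#' @export
gene_ploidy <- function(counts, panel, gene, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  agg <- if (estimator == "mean") mean else median
  cnt <- setNames(counts$molecule_count, counts$module_id)
  ids <- gene_module_ids(panel, gene)
  if (length(ids) == 0L) stop("gene_ploidy: no modules for gene ", gene)
  ref_mean <- mean(cnt[reference_module_ids(panel)], na.rm = TRUE)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("gene_ploidy: reference mean count is zero")
  2 * agg(cnt[ids], na.rm = TRUE) / ref_mean
}

#' Two-sided Mann-Whitney U test of gene modules against the reference
#'
#' Exact null distribution (via the Wilcoxon rank-sum distribution) when
#' both samples have at most 8 values and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' Genes with fewer than `min_n` modules are refused: too few modules per
#' gene make the rank test meaningless, and such genes are reported
#' untestable rather than tested badly.
#'
#' @param gene_values per-module ploidies (or counts) of the gene.
#' @param ref_values per-module ploidies (or counts) of the reference set.
#' @param min_n minimum gene modules required (default 3).
#' @param exact_max largest sample size for which the exact distribution is
#'   used.
#' @return two-sided p-value.
#' @export
mw_test_gene <- function(gene_values, ref_values, min_n = 3L,
                         exact_max = 8L) {
  n1 <- length(gene_values)
  n2 <- length(ref_values)
  if (n1 < min_n)
    stop("mw_test_gene: gene has ", n1, " modules; at least ", min_n,
         " required (untestable)")
  if (n2 < 1L) stop("mw_test_gene: empty reference")
  r <- rank(c(gene_values, ref_values))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(gene_values, ref_values)))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2))
    return(min(1, p))
  }
  # normal approximation with tie correction (+ continuity correction)
  nt <- n1 + n2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * pnorm(-z))
}

#' Call copy-number variations over a panel
#'
#' Procedure: (1) per-module ploidies against the full reference ensemble;
#' (2) testable genes ranked by effect size `|gene ploidy - 2|`,
#' descending; (3) each gene's module ploidies tested against the
#' (panel-fixed) reference module ploidies with the Mann-Whitney U test;
#' (4) Benjamini-Hochberg correction across tested genes; (5) significant
#' genes report their point estimate and a gain/loss call, all others are
#' reported at exactly 2.00 (neutral): without statistical support the
#' ploidy is not distinguishable from normal and must not be reported as
#' abnormal.
#'
#' @inheritParams module_ploidy
#' @param alpha significance level on adjusted p-values.
#' @param correction multiple-testing correction passed to
#'   [stats::p.adjust()].
#' @param estimator gene point estimator, see [gene_ploidy()].
#' @return data.frame of class `ploidy_calls`: `gene`, `n_modules`,
#'   `ploidy_estimate`, `p_value`, `adjusted_p`, `call`
#'   (loss/neutral/gain), `reported_ploidy`.
#' @export
call_cnvs <- function(counts, panel, alpha = 0.05, correction = "BH",
                      estimator = "mean") {
  stopifnot(inherits(panel, "qaseq_panel"))
  genes <- testable_genes(panel)
  if (length(genes) == 0L) {
    warning("call_cnvs: no testable genes in panel")
    out <- data.frame(gene = character(0), n_modules = integer(0),
                      ploidy_estimate = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), call = character(0),
                      reported_ploidy = numeric(0))
    class(out) <- c("ploidy_calls", "data.frame")
    return(out)
  }
  mp <- module_ploidy(counts, panel)
  ref_p <- mp[reference_module_ids(panel)]
  est <- vapply(genes, function(g)
    gene_ploidy(counts, panel, g, estimator = estimator), 0)
  ord <- order(abs(est - 2), decreasing = TRUE)  # sequential: largest effect first
  genes <- genes[ord]
  est <- est[ord]
  pvals <- vapply(genes, function(g)
    mw_test_gene(mp[gene_module_ids(panel, g)], ref_p), 0)
  adj <- p.adjust(pvals, method = correction)
  sig <- adj < alpha
  out <- data.frame(
    gene = genes,
    n_modules = vapply(genes, function(g) length(gene_module_ids(panel, g)), 0L),
    ploidy_estimate = est,
    p_value = pvals,
    adjusted_p = adj,
    call = ifelse(!sig, "neutral", ifelse(est > 2, "gain", "loss")),
    reported_ploidy = ifelse(sig, est, 2.00),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ploidy_calls", "data.frame")
  out
}

#' Limit of detection from replicate gene ploidies
#'
#' `lod_loss = mean - k_sigma * sd`, `lod_gain = mean + k_sigma * sd`
#' (sample standard deviation): a single-sample ploidy outside this band is
#' distinguishable from replicate-level technical variation.
#'
#' @param ploidies replicate gene-ploidy estimates (at least 3).
#' @param k_sigma band half-width in standard deviations (default 3).
#' @return list of class `lod_estimate`: `mean_ploidy`, `sd_ploidy`,
#'   `lod_loss`, `lod_gain`, `k_sigma`, `n`.
#' @export
lod_from_replicates <- function(ploidies, k_sigma = 3) {
  if (length(ploidies) < 3L)
    stop("lod_from_replicates: at least 3 replicates required")
  m <- mean(ploidies)
  s <- sd(ploidies)
  structure(list(mean_ploidy = m, sd_ploidy = s,
                 lod_loss = m - k_sigma * s, lod_gain = m + k_sigma * s,
                 k_sigma = k_sigma, n = length(ploidies)),
            class = "lod_estimate")
}

#' Ploidy CV as a function of the number of quantitation modules
#'
#' For each module count `m`, random `m`-subsets of the gene's modules are
#' drawn; the gene ploidy is computed per replicate from each subset (full
#' reference ensemble), the coefficient of variation is taken across
#' replicates, and CVs are averaged over the random selections.  The
#' theoretical curve is the Poisson prediction
#' `sqrt(1/(m N) + 1/(m_ref N))` with `N` the mean molecule count per
#' module.
#'
#' @param count_tables list of `molecule_counts` data.frames, one per
#'   technical replicate (at least 2).
#' @param panel `qaseq_panel`
#' @param gene target gene.
#' @param m_values integer vector of module counts to evaluate.
#' @param n_random random subset draws per `m` (default 30).
#' @param seed optional seed for the subset draws.
#' @return data.frame of class `cv_curve`: `m`, `cv`, `theoretical_cv`,
#'   with attributes `n_random` and `n_replicates`.
#' @export
cv_vs_modules <- function(count_tables, panel, gene, m_values,
                          n_random = 30L, seed = NULL) {
  stopifnot(inherits(panel, "qaseq_panel"))
  if (length(count_tables) < 2L)
    stop("cv_vs_modules: at least 2 replicates required")
  if (!is.null(seed)) set.seed(seed)
  ids <- gene_module_ids(panel, gene)
  ref_ids <- reference_module_ids(panel)
  if (any(m_values > length(ids)))
    stop("cv_vs_modules: m exceeds the ", length(ids),
         " available modules for ", gene)
  cnt <- lapply(count_tables, function(ct)
    setNames(ct$molecule_count, ct$module_id))
  ref_means <- vapply(cnt, function(x) mean(x[ref_ids], na.rm = TRUE), 0)
  N <- mean(vapply(cnt, function(x) mean(x[c(ids, ref_ids)], na.rm = TRUE), 0))
  cv <- vapply(m_values, function(m) {
    cvs <- vapply(seq_len(n_random), function(k) {
      sub <- sample(ids, m)
      pl <- vapply(seq_along(cnt), function(r)
        2 * mean(cnt[[r]][sub]) / ref_means[r], 0)
      sd(pl) / mean(pl)
    }, 0)
    mean(cvs)
  }, 0)
  out <- data.frame(m = as.integer(m_values), cv = cv,
                    theoretical_cv = sqrt(1 / (m_values * N) +
                                            1 / (length(ref_ids) * N)))
  attr(out, "n_random") <- n_random
  attr(out, "n_replicates") <- length(count_tables)
  class(out) <- c("cv_curve", "data.frame")
  out
}

#' Number of pairwise ddPCR-equivalent CNV assays in an n-module panel
#'
#' Every ordered pair of modules is one target/reference CNV assay, so an
#' n-plex panel is equivalent to `choose(n, 2)` two-channel digital PCR
#' assays.
#'
#' @param n_modules number of quantitation modules (>= 2).
#' @return integer `n (n - 1) / 2`.
#' @export
equivalent_assay_count <- function(n_modules) {
  if (any(n_modules < 2)) stop("equivalent_assay_count: n must be >= 2")
  as.integer(n_modules * (n_modules - 1) / 2)
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' No Yates continuity correction by default.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param continuity apply the Yates correction.
#' @return list: `statistic`, `p_value`, `df` (= 1).
#' @export
chi_square_independence <- function(tab, continuity = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("chi_square_independence: negative cell")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("chi_square_independence: zero margin")
  E <- outer(rs, cs) / sum(tab)
  dev <- abs(tab - E)
  if (continuity) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Welch two-sided t-test p-value for two replicate groups
#'
#' @param group_a,group_b numeric vectors (each at least 2 values).
#' @return two-sided p-value; degenerate zero-variance inputs give 1 for
#'   equal means and 0 otherwise.
#' @export
two_sample_t <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("two_sample_t: each group needs >= 2 values")
  v1 <- stats::var(group_a)
  v2 <- stats::var(group_b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (mean(group_a) == mean(group_b)) 1 else 0)
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

#' Write a CNV call table
#' @param calls `ploidy_calls`
#' @param path TSV path.
#' @param meta named character vector of `# key=value` metadata lines.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# qaseq CNV calls",
               if (!is.null(meta)) paste0("# ", names(meta), "=", meta)), con)
  write.table(calls, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
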