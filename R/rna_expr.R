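#' Yield-adjusted gene-level molecule count
#'
#' A gene's expression count is the mean over its amplicons of
#' `molecule count / conversion yield`; dividing by the per-amplicon yield
#' converts observed UMI families back to input cDNA molecules.
#'
#' @param amplicon_counts molecule counts, one per amplicon.
#' @param yields per-amplicon conversion yields in (0, 1\]; default 1
#'   (raw counts).
#' @return numeric gene count.
#' @export
gene_count <- function(amplicon_counts, yields = rep(1, length(amplicon_counts))) {
  if (length(amplicon_counts) != length(yields))
    stop("gene_count: counts and yields must have equal length")
  if (any(yields <= 0)) stop("gene_count: yields must be > 0")
  mean(amplicon_counts / yields)
}

#' Relative expression in log2 scale, normalized to reference genes
#'
#' `expr(g) = log2(count_g) - mean(log2(count_r))` over the reference
#' genes; equivalently, expression relative to the geometric mean of the
#' reference counts.  The reference aggregate is 0 by construction, so
#' values are comparable across libraries of different depth.
#'
#' @param gene_counts named numeric vector of gene-level counts.
#' @param reference_genes character vector of reference gene symbols (all
#'   must be present with positive counts).
#' @return named numeric vector of log2 relative expression; genes with
#'   non-positive counts are returned as NA with a warning.
#' @export
relative_log2 <- function(gene_counts, reference_genes) {
  if (length(reference_genes) == 0L)
    stop("relative_log2: reference gene set is empty")
  missing_ref <- setdiff(reference_genes, names(gene_counts))
  if (length(missing_ref) > 0L)
    stop("relative_log2: reference gene(s) absent: ",
         paste(missing_ref, collapse = ", "))
  if (any(gene_counts[reference_genes] <= 0))
    stop("relative_log2: reference gene(s) with non-positive counts")
  bad <- gene_counts <= 0
  if (any(bad)) {
    warning("relative_log2: non-positive counts reported as NA for: ",
            paste(names(gene_counts)[bad], collapse = ", "))
  }
  ref_level <- mean(log2(gene_counts[reference_genes]))
  out <- ifelse(bad, NA_real_, log2(pmax(gene_counts, .Machine$double.xmin)) -
                  ref_level)
  setNames(out, names(gene_counts))
}

#' Replicate standard deviation of expression vs amplicons per gene
#'
#' Recomputes relative expression using only the first `m` amplicons per
#' gene (amplicon order in the tables is 5'-most first) and reports the
#' per-gene standard deviation across replicates, plus its median over
#' genes.  More amplicons per gene average away per-amplicon sampling
#' noise, so the sd should fall as `m` grows.
#'
#' @param replicates list (>= 2) of data.frames with columns `gene`,
#'   `count` and optionally `yield`; rows within a gene ordered 5' to 3'.
#' @param m_values integer vector of amplicon counts to evaluate.
#' @param reference_genes reference gene symbols.
#' @return list: `per_gene` (matrix genes x m of sds), `median_sd` (named
#'   vector over `m`).
#' @export
replicate_sd_vs_amplicons <- function(replicates, m_values, reference_genes) {
  if (length(replicates) < 2L)
    stop("replicate_sd_vs_amplicons: at least 2 replicates required")
  genes <- unique(replicates[[1L]]$gene)
  avail <- table(replicates[[1L]]$gene)
  per_gene <- matrix(NA_real_, nrow = length(genes), ncol = length(m_values),
                     dimnames = list(genes, as.character(m_values)))
  for (mi in seq_along(m_values)) {
    m <- m_values[mi]
    usable <- names(avail)[avail >= m]
    skipped <- setdiff(genes, usable)
    if (length(skipped) > 0L)
      warning("m = ", m, ": gene(s) with fewer amplicons skipped: ",
              paste(skipped, collapse = ", "))
    if (!all(reference_genes %in% usable)) next
    expr <- vapply(replicates, function(rep_df) {
      gc <- vapply(usable, function(g) {
        rows <- which(rep_df$gene == g)[seq_len(m)]
        y <- if ("yield" %in% names(rep_df)) rep_df$yield[rows] else rep(1, m)
        gene_count(rep_df$count[rows], y)
      }, 0)
      relative_log2(gc, reference_genes)
    }, numeric(length(usable)))
    expr <- matrix(expr, nrow = length(usable))
    per_gene[usable, mi] <- apply(expr, 1L, sd)
  }
  med <- apply(per_gene, 2L, median, na.rm = TRUE)
  list(per_gene = per_gene, median_sd = med)
}

#' Dynamic-range check against known-abundance spike-ins
#'
#' Least-squares fit of `log10(observed)` on `log10(expected)` over paired
#' counts (e.g. ERCC spike-ins); accurate absolute quantitation gives slope
#' 1 and correlation near 1 across the full input range.
#'
#' @param expected,observed paired molecule counts; non-positive pairs are
#'   excluded.
#' @param min_pairs,min_decades minimum usable pairs and expected-value
#'   decades.
#' @return list: `slope`, `intercept`, `correlation`, `n`.
#' @export
dynamic_range_check <- function(expected, observed, min_pairs = 5L,
                                min_decades = 2) {
  stopifnot(length(expected) == length(observed))
  keep <- expected > 0 & observed > 0
  x <- log10(expected[keep])
  y <- log10(observed[keep])
  if (length(x) < min_pairs)
    stop("dynamic_range_check: fewer than ", min_pairs, " usable pairs")
  if (diff(range(x)) < min_decades)
    stop("dynamic_range_check: expected counts span fewer than ",
         min_decades, " decades")
  if (sd(y) == 0)
    stop("dynamic_range_check: constant observed counts; correlation undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       correlation = stats::cor(x, y), n = length(x))
}
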