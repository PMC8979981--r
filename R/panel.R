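#' @importFrom data.table data.table as.data.table setDT := .N .SD
#' @importFrom stats rpois rbinom rnorm rbeta rmultinom runif sd p.adjust
#'   pwilcox pnorm pchisq pt qnorm ks.test complete.cases median setNames
#' @importFrom utils read.delim write.table head
NULL

PANEL_COLUMNS <- c("module_id", "gene", "role", "chrom", "start", "end",
                   "fwd_primer", "rev_primer", "amplicon_seq", "variant_loci")
PANEL_ROLES <- c("target", "reference", "excluded")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct and validate a quantitation panel
#'
#' A panel is the set of quantitation modules (amplicons) used for absolute
#' molecule counting.  Each module is one primer pair / amplicon acting as an
#' independent counting unit; genes of interest are covered by several
#' modules, and a separate set of modules elsewhere in the genome serves as
#' the copy-number reference.  Modules marked `excluded` (e.g. sex-chromosome
#' amplicons) never enter CNV statistics.
#'
#' @param modules data.frame with columns `module_id`, `gene`, `role`
#'   (target/reference/excluded, case-insensitive), `chrom`, `start`, `end`
#'   (0-based half-open, informational only), `fwd_primer`, `rev_primer`,
#'   `amplicon_seq` (insert between primers) and `variant_loci`
#'   (string `"offset:refbase;offset:refbase"`, 0-based offsets into
#'   `amplicon_seq`; empty string for none).
#' @param umi_length length of the unique molecular identifier in bases.
#' @param min_modules_per_gene_for_test minimum number of non-excluded
#'   modules a gene needs before its ploidy can be rank-tested.
#' @return object of class `qaseq_panel`.
#' @export
qaseq_panel <- function(modules, umi_length = 12L,
                        min_modules_per_gene_for_test = 3L) {
  modules <- as.data.frame(modules, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(modules))
  if (length(missing_cols) > 0L) {
    stop("panel format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  modules <- modules[, PANEL_COLUMNS]
  modules$role <- tolower(trimws(modules$role))
  modules$start <- as.integer(modules$start)
  modules$end <- as.integer(modules$end)
  if (!is.numeric(umi_length) || umi_length < 1L)
    stop("umi_length must be a positive integer")
  if (!is.numeric(min_modules_per_gene_for_test) ||
      min_modules_per_gene_for_test < 1L)
    stop("min_modules_per_gene_for_test must be a positive integer")

  issues <- panel_issues(modules)
  if (length(issues) > 0L)
    stop("panel validation error:\n  ", paste(issues, collapse = "\n  "))

  panel <- structure(
    list(modules = modules,
         umi_length = as.integer(umi_length),
         min_modules_per_gene_for_test = as.integer(min_modules_per_gene_for_test)),
    class = "qaseq_panel")
  panel
}

# all validation issues for a module table; character(0) when clean
panel_issues <- function(modules) {
  issues <- character(0)
  bad_role <- !modules$role %in% PANEL_ROLES
  if (any(bad_role))
    issues <- c(issues, paste0("invalid role(s): ",
                               paste(unique(modules$role[bad_role]), collapse = ", ")))
  dup <- unique(modules$module_id[duplicated(modules$module_id)])
  if (length(dup) > 0L)
    issues <- c(issues, paste0("duplicate module_id: ", paste(dup, collapse = ", ")))
  for (col in c("fwd_primer", "rev_primer", "amplicon_seq")) {
    bad <- !grepl("^[ACGT]+$", modules[[col]])
    if (any(bad))
      issues <- c(issues, paste0("non-ACGT ", col, " in module(s): ",
                                 paste(modules$module_id[bad], collapse = ", ")))
  }
  bad_coord <- !(modules$end > modules$start)
  if (any(bad_coord, na.rm = TRUE) || anyNA(bad_coord))
    issues <- c(issues, paste0("amplicon_end must exceed amplicon_start in: ",
                               paste(modules$module_id[bad_coord | is.na(bad_coord)],
                                     collapse = ", ")))
  if (!any(modules$role == "reference"))
    issues <- c(issues, "panel needs at least 1 reference module")
  for (i in seq_len(nrow(modules))) {
    vl <- parse_variant_loci(modules$variant_loci[i])
    if (nrow(vl) == 0L) next
    amp <- modules$amplicon_seq[i]
    if (is.na(amp) || !nzchar(amp)) next
    bad_off <- vl$offset < 0L | vl$offset >= nchar(amp)
    if (any(bad_off)) {
      issues <- c(issues, paste0("variant locus offset out of range in ",
                                 modules$module_id[i]))
      next
    }
    ref_obs <- substring(amp, vl$offset + 1L, vl$offset + 1L)
    if (any(ref_obs != vl$ref))
      issues <- c(issues, paste0("variant locus ref base mismatch in ",
                                 modules$module_id[i]))
  }
  issues
}

# "12:A;45:G" -> data.frame(offset, ref); 0-based offsets
parse_variant_loci <- function(x) {
  if (is.na(x) || !nzchar(trimws(x)))
    return(data.frame(offset = integer(0), ref = character(0)))
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(offset = as.integer(vapply(kv, `[`, "", 1L)),
             ref = toupper(vapply(kv, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' @export
print.qaseq_panel <- function(x, ...) {
  tab <- table(x$modules$role)
  cat("QASeq panel:", nrow(x$modules), "modules (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  cat("UMI length:", x$umi_length,
      "| min modules/gene for CNV test:", x$min_modules_per_gene_for_test, "\n")
  invisible(x)
}

#' Read a panel from a tab-separated file
#'
#' The file must carry a header row with the ten canonical columns (see
#' [qaseq_panel()]); lines starting with `#` are treated as metadata and
#' skipped.
#'
#' @param path panel TSV file.
#' @inheritParams qaseq_panel
#' @return `qaseq_panel`
#' @export
read_panel <- function(path, umi_length = 12L,
                       min_modules_per_gene_for_test = 3L) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("panel format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  qaseq_panel(df, umi_length = umi_length,
              min_modules_per_gene_for_test = min_modules_per_gene_for_test)
}

#' Write a panel to a tab-separated file
#'
#' @param panel `qaseq_panel`
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "qaseq_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# qaseq panel | umi_length=", panel$umi_length,
                    " min_modules_per_gene_for_test=",
                    panel$min_modules_per_gene_for_test), con)
  write.table(panel$modules, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Module ids of the copy-number reference set
#' @param panel `qaseq_panel`
#' @return character vector of module ids with role `reference`.
#' @export
reference_module_ids <- function(panel) {
  stopifnot(inherits(panel, "qaseq_panel"))
  panel$modules$module_id[panel$modules$role == "reference"]
}

#' Genes eligible for rank-based CNV testing
#'
#' A gene of interest can only be tested with a Mann-Whitney U test when it
#' is covered by enough quantitation modules; genes below the threshold are
#' reported as untestable rather than silently called neutral.
#'
#' @param panel `qaseq_panel`
#' @return character vector of gene symbols with at least one `target`
#'   module and at least `min_modules_per_gene_for_test` non-excluded
#'   modules.
#' @export
testable_genes <- function(panel) {
  stopifnot(inherits(panel, "qaseq_panel"))
  m <- panel$modules
  target_genes <- unique(m$gene[m$role == "target"])
  keep <- m$role != "excluded" & m$gene %in% target_genes
  counts <- table(m$gene[keep])
  sort(names(counts)[counts >= panel$min_modules_per_gene_for_test])
}

# modules usable in CNV statistics for a given gene (non-excluded)
gene_module_ids <- function(panel, gene) {
  m <- panel$modules
  m$module_id[m$gene == gene & m$role != "excluded"]
}
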