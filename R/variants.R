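#' Consensus sequence of a single UMI family
#'
#' Per position the consensus is the modal base when its fraction of the
#' family's reads reaches `min_concordance`, else `N`.  Because all reads
#' of a family derive from one input molecule, positions where the family
#' disagrees are amplification/sequencing artifacts, not biology.
#'
#' @param family `umi_family` object (see [umi_family()]).
#' @param min_concordance minimum modal-base fraction (default 0.8).
#' @return list of class `consensus_family`: `module_id`, `umi`, `size`,
#'   `consensus_seq`, `min_position_concordance`.
#' @export
family_consensus <- function(family, min_concordance = 0.8) {
  stopifnot(inherits(family, "umi_family"))
  bc <- family$base_counts[DNA_BASES, , drop = FALSE]
  tot <- colSums(family$base_counts)
  top <- apply(bc, 2L, which.max)
  frac <- bc[cbind(top, seq_len(ncol(bc)))] / pmax(tot, 1L)
  cons <- ifelse(tot > 0L & frac >= min_concordance, DNA_BASES[top], "N")
  structure(list(module_id = family$module_id, umi = family$umi,
                 size = family$size,
                 consensus_seq = paste(cons, collapse = ""),
                 min_position_concordance = min(frac[tot > 0L])),
            class = "consensus_family")
}

#' Collapse all UMI families of a run to consensus sequences
#'
#' Applies the per-module family-size cutoff first (only families that
#' count as molecules vote), then builds the per-position consensus for
#' every surviving family.
#'
#' @param assignments `read_assignments` data.frame.
#' @param panel `qaseq_panel`
#' @param min_concordance minimum modal-base fraction per position.
#' @param fraction,min_reads family-size cutoff parameters, see
#'   [family_size_cutoff()].
#' @return data.frame of class `consensus_families`: `module_id`, `umi`,
#'   `size`, `consensus_seq` (length = module amplicon length, `N` at
#'   ambiguous or missing positions).
#' @export
consensus_families <- function(assignments, panel, min_concordance = 0.8,
                               fraction = 0.05, min_reads = 3) {
  stopifnot(inherits(panel, "qaseq_panel"))
  dt <- data.table::as.data.table(assignments)
  dt <- dt[!is.na(dt$module_id)]
  if (nrow(dt) == 0L)
    return(empty_consensus())
  fam <- dt[, list(size = .N), by = c("module_id", "umi")]
  fam[, keep := size >= family_size_cutoff(size, fraction, min_reads),
      by = "module_id"]
  fam <- fam[fam$keep == TRUE]
  if (nrow(fam) == 0L) return(empty_consensus())
  dt <- merge(dt, fam[, c("module_id", "umi", "size")],
              by = c("module_id", "umi"))
  amp_len <- setNames(nchar(panel$modules$amplicon_seq),
                      panel$modules$module_id)
  fam <- fam[order(fam$module_id, fam$umi)]
  fam_key <- paste(fam$module_id, fam$umi)
  L_max <- max(amp_len[unique(fam$module_id)])
  cons <- matrix("N", nrow = nrow(fam), ncol = L_max)
  dt_key <- paste(dt$module_id, dt$umi)
  for (p in seq_len(L_max)) {
    b <- substring(dt$insert, p, p)
    ok <- b %in% DNA_BASES
    if (!any(ok)) next
    sub <- data.table::data.table(fkey = dt_key[ok], b = b[ok])
    agg <- sub[, list(n = .N), by = c("fkey", "b")]
    agg <- agg[order(agg$fkey, -agg$n)]
    topb <- agg[!duplicated(agg$fkey)]
    fi <- match(topb$fkey, fam_key)
    frac <- topb$n / fam$size[fi]
    pass <- frac >= min_concordance
    cons[fi[pass], p] <- topb$b[pass]
  }
  # positions beyond a module's amplicon stay N; trim per module on output
  seqs <- apply(cons, 1L, paste, collapse = "")
  seqs <- substr(seqs, 1L, amp_len[fam$module_id])
  out <- data.frame(module_id = fam$module_id, umi = fam$umi,
                    size = fam$size, consensus_seq = seqs,
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_families", "data.frame")
  out
}

empty_consensus <- function() {
  out <- data.frame(module_id = character(0), umi = character(0),
                    size = integer(0), consensus_seq = character(0))
  class(out) <- c("consensus_families", "data.frame")
  out
}

#' Call variants at molecule (UMI-family) level
#'
#' Per (module, offset), families whose consensus base differs from the
#' panel reference (and is not `N`) are alt families; a call is emitted
#' when at least `min_alt_families` agree, with
#' `VAF = alt families / non-N families at that offset`.  Counting
#' molecules rather than reads is what UMI error correction buys: a
#' sequencing error must dominate a whole family to survive consensus.
#'
#' @param consensus `consensus_families` data.frame.
#' @param panel `qaseq_panel`
#' @param min_alt_families minimum supporting molecules per call
#'   (default 3, suppressing residual consensus errors).
#' @return data.frame of class `variant_calls`: `module_id`, `offset`
#'   (0-based into the amplicon insert), `ref`, `alt`, `alt_families`,
#'   `total_families`, `vaf`.
#' @export
call_variants <- function(consensus, panel, min_alt_families = 3L) {
  stopifnot(inherits(panel, "qaseq_panel"))
  res <- list()
  for (mod in unique(consensus$module_id)) {
    cs <- consensus$consensus_seq[consensus$module_id == mod]
    ref <- panel$modules$amplicon_seq[panel$modules$module_id == mod]
    if (length(ref) == 0L) next
    L <- nchar(ref)
    for (p in seq_len(L)) {
      b <- substring(cs, p, p)
      b <- b[nzchar(b)]
      informative <- b %in% DNA_BASES
      total <- sum(informative)
      if (total == 0L) next
      rb <- substring(ref, p, p)
      alt_tab <- table(b[informative & b != rb])
      for (ab in names(alt_tab)) {
        if (alt_tab[[ab]] >= min_alt_families) {
          res[[length(res) + 1L]] <- data.frame(
            module_id = mod, offset = p - 1L, ref = rb, alt = ab,
            alt_families = as.integer(alt_tab[[ab]]),
            total_families = as.integer(total),
            vaf = alt_tab[[ab]] / total, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(module_id = character(0), offset = integer(0),
               ref = character(0), alt = character(0),
               alt_families = integer(0), total_families = integer(0),
               vaf = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Fold change between two VAF measurements
#'
#' @param vaf_t1 follow-up VAF.
#' @param vaf_t0 baseline VAF.
#' @return `vaf_t1 / vaf_t0`; a zero baseline warns and returns `Inf`.
#' @export
vaf_fold_change <- function(vaf_t1, vaf_t0) {
  if (vaf_t0 == 0) {
    warning("vaf_fold_change: zero baseline VAF; fold change is infinite")
    return(Inf)
  }
  vaf_t1 / vaf_t0
}
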