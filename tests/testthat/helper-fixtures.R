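# shared fixtures and small numeric helpers

skewness <- function(x) {
  m <- mean(x)
  s <- sd(x)
  mean((x - m)^3) / s^3
}

# deterministic 2-plex panel (ERBB2 target, EIF2C1 reference)
two_plex_panel <- function() {
  qaseq_panel(data.frame(
    module_id = c("ERBB2_1", "EIF2C1_1"),
    gene = c("ERBB2", "EIF2C1"),
    role = c("target", "reference"),
    chrom = c("chr17", "chr1"),
    start = c(100L, 200L),
    end = c(130L, 230L),
    fwd_primer = c("ACGTACGTACGTACGTACGT", "TTGGCCAATTGGCCAATTGG"),
    rev_primer = c("GGGGTTTTCCCCAAAAGGGG", "AAAACCCCGGGGTTTTAAAA"),
    amplicon_seq = c("ACGTTGCAGGTCCATGGATCAACGGTTCCA",
                     "TGCATGCATGCAGGCCTTAAGGCCAATTGC"),
    variant_loci = c("4:T;10:T", ""),
    stringsAsFactors = FALSE))
}

# assignment table built directly (bypassing FASTQ) for grouping tests
make_assignments <- function(module_id, umi, insert = NULL) {
  n <- length(umi)
  if (is.null(insert)) insert <- strrep("A", 30)
  df <- data.frame(read_id = sprintf("r%04d", seq_len(n)),
                   module_id = module_id, umi = umi,
                   insert = rep_len(insert, n),
                   mismatches = ifelse(is.na(module_id), NA_integer_, 0L),
                   reason = ifelse(is.na(module_id), "no_match", "assigned"),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_assignments", "data.frame")
  df
}

# reads laid out exactly as the simulator emits them
make_read <- function(panel, module_row, umi) {
  m <- panel$modules[module_row, ]
  paste0(umi, m$fwd_primer, m$amplicon_seq)
}
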