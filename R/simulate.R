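#' Simulator configuration
#'
#' Bundles every stochastic layer of a synthetic QASeq run: Poisson sampling
#' of input molecules from a mass/ploidy model, incomplete UMI barcoding
#' (conversion yield), PCR amplification as a branching process with
#' per-molecule yield variation (producing log-normal family sizes),
#' multinomial sequencing-depth sampling, per-base substitution errors,
#' off-target reads, and variants spiked at known VAF.
#'
#' Exactly one of `input_mass_ng` / `input_copies` must be given.
#'
#' @param input_mass_ng DNA input mass in nanograms.
#' @param input_copies expected haploid genome copies (alternative to mass).
#' @param haploid_genome_mass_pg mass of one haploid human genome in
#'   picograms; the default 3.584 makes 10 ng correspond to 2,790 copies.
#' @param ploidy_map named numeric vector gene -> ploidy; genes absent from
#'   the map are diploid (2.0).
#' @param conversion_yield probability that an input duplex is barcoded and
#'   recovered as a countable UMI family (default 0.86).
#' @param pcr_cycles post-barcoding PCR cycles.
#' @param per_cycle_efficiency mean per-cycle duplication probability in the
#'   variable-efficiency phase.
#' @param efficiency_sd per-molecule standard deviation of the duplication
#'   probability (drawn once per family, truncated to \[0, 1\]).  Random
#'   per-molecule yield differences amplified over the cycles are what make
#'   family sizes log-normal; set to 0 for a classical single-efficiency
#'   Galton-Watson process.
#' @param high_eff_cycles number of initial near-unit-efficiency cycles
#'   (long-annealing barcoding/nested steps), run at efficiency
#'   `max(per_cycle_efficiency, 0.995)`.
#' @param mean_depth_per_module expected sequenced reads per module.
#' @param per_base_error_rate substitution probability per sequenced base.
#' @param off_target_fraction fraction of all reads that are primer dimers /
#'   off-target products unassignable to any module.
#' @param spiked_variants data.frame with columns `module_id`, `offset`
#'   (0-based into the amplicon insert), `alt` (base) and `vaf` (true
#'   molecule-level variant allele frequency), or NULL.
#' @param seed integer seed; every simulator draw flows from it.
#' @return object of class `qaseq_sim_config`.
#' @export
sim_config <- function(input_mass_ng = NULL, input_copies = NULL,
                       haploid_genome_mass_pg = 3.584,
                       ploidy_map = NULL,
                       conversion_yield = 0.86,
                       pcr_cycles = 12L,
                       per_cycle_efficiency = 0.80,
                       efficiency_sd = 0.05,
                       high_eff_cycles = 5L,
                       mean_depth_per_module = 90000,
                       per_base_error_rate = 0.002,
                       off_target_fraction = 0.4,
                       spiked_variants = NULL,
                       seed = 1L) {
  if (is.null(input_mass_ng) == is.null(input_copies))
    stop("exactly one of input_mass_ng / input_copies must be set")
  if (!is.null(input_mass_ng) && input_mass_ng < 0)
    stop("input_mass_ng must be non-negative")
  if (!is.null(input_copies) && input_copies < 0)
    stop("input_copies must be non-negative")
  for (p in c(conversion_yield, per_base_error_rate, off_target_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (per_cycle_efficiency <= 0 || per_cycle_efficiency > 1)
    stop("per_cycle_efficiency must lie in (0, 1]")
  if (pcr_cycles < 1L) stop("pcr_cycles must be >= 1")
  if (!is.null(spiked_variants)) {
    spiked_variants <- as.data.frame(spiked_variants)
    stopifnot(all(c("module_id", "offset", "alt", "vaf") %in%
                    names(spiked_variants)))
    if (any(spiked_variants$vaf < 0 | spiked_variants$vaf > 1))
      stop("spiked VAFs must lie in [0, 1]")
  }
  structure(list(
    input_mass_ng = input_mass_ng, input_copies = input_copies,
    haploid_genome_mass_pg = haploid_genome_mass_pg,
    ploidy_map = ploidy_map,
    conversion_yield = conversion_yield,
    pcr_cycles = as.integer(pcr_cycles),
    per_cycle_efficiency = per_cycle_efficiency,
    efficiency_sd = efficiency_sd,
    high_eff_cycles = as.integer(high_eff_cycles),
    mean_depth_per_module = mean_depth_per_module,
    per_base_error_rate = per_base_error_rate,
    off_target_fraction = off_target_fraction,
    spiked_variants = spiked_variants,
    seed = as.integer(seed)), class = "qaseq_sim_config")
}

#' Convert DNA mass to expected haploid genome copies
#'
#' @param mass_ng input mass in nanograms.
#' @param haploid_genome_mass_pg picograms per haploid genome (default
#'   3.584, under which 10 ng corresponds to 2,790 haploid copies).
#' @return integer `round(mass_ng * 1000 / haploid_genome_mass_pg)`.
#' @export
mass_to_copies <- function(mass_ng, haploid_genome_mass_pg = 3.584) {
  if (any(mass_ng <= 0) || any(haploid_genome_mass_pg <= 0))
    stop("mass_to_copies: arguments must be positive")
  as.integer(round(mass_ng * 1000 / haploid_genome_mass_pg))
}

expected_copies <- function(cfg) {
  if (!is.null(cfg$input_copies)) return(as.numeric(cfg$input_copies))
  if (cfg$input_mass_ng == 0) return(0)
  as.numeric(mass_to_copies(cfg$input_mass_ng, cfg$haploid_genome_mass_pg))
}

ploidy_of <- function(cfg, genes) {
  p <- rep(2.0, length(genes))
  if (!is.null(cfg$ploidy_map)) {
    hit <- match(genes, names(cfg$ploidy_map))
    p[!is.na(hit)] <- as.numeric(cfg$ploidy_map[hit[!is.na(hit)]])
  }
  p
}

#' Draw the number of input molecules per module
#'
#' Molecule sampling into the reaction is Poisson: a module on a gene with
#' ploidy `p` sees on average `expected_copies * p / 2` molecules.
#'
#' @param cfg `qaseq_sim_config`
#' @param panel `qaseq_panel`
#' @return named integer vector, one count per module (panel row order).
#' @export
sample_input_molecules <- function(cfg, panel) {
  stopifnot(inherits(cfg, "qaseq_sim_config"), inherits(panel, "qaseq_panel"))
  lambda <- expected_copies(cfg) * ploidy_of(cfg, panel$modules$gene) / 2
  setNames(rpois(nrow(panel$modules), lambda), panel$modules$module_id)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Barcode input molecules with UMIs
#'
#' Each molecule is independently recovered as a barcoded family with
#' probability `conversion_yield`; its UMI is drawn uniformly over
#' `4^umi_length` sequences (collisions are allowed and negligible at
#' panel-typical scales).
#'
#' @param counts named integer vector of input molecules per module.
#' @param cfg `qaseq_sim_config`
#' @param umi_length UMI length in bases.
#' @return named list: per module, character vector of UMIs (one per
#'   barcoded molecule).
#' @export
attach_umis <- function(counts, cfg, umi_length = 12L) {
  stopifnot(all(counts >= 0))
  n_bar <- rbinom(length(counts), counts, cfg$conversion_yield)
  out <- lapply(n_bar, random_dna, len = umi_length)
  names(out) <- names(counts)
  out
}

#' Amplify barcoded molecules into UMI families
#'
#' Branching-process PCR: a family starts from one barcoded copy, runs
#' `high_eff_cycles` near-deterministic doubling cycles (the long-annealing
#' barcoding/nested steps of the protocol), then the remaining cycles in
#' which every copy duplicates independently with the family's own
#' efficiency, drawn once from TruncNormal(`efficiency`, `efficiency_sd`)
#' on \[0, 1\].  The exponential amplification of per-family efficiency
#' differences is what makes the family-size distribution log-normal above
#' the small-family cutoff.
#'
#' @param n number of families to draw.
#' @param cycles total PCR cycles.
#' @param efficiency mean per-cycle duplication probability.
#' @param efficiency_sd per-family efficiency standard deviation (0 recovers
#'   the classical fixed-efficiency Galton-Watson process).
#' @param high_eff_cycles initial cycles run at
#'   `max(efficiency, 0.995)`.
#' @return integer vector of `n` final family sizes (copies).
#' @export
amplify_family <- function(n = 1L, cycles = 12L, efficiency = 0.80,
                           efficiency_sd = 0.05, high_eff_cycles = 5L) {
  if (cycles < 0L) stop("cycles must be >= 0")
  if (n == 0L) return(integer(0))
  hi <- min(high_eff_cycles, cycles)
  e_hi <- max(efficiency, 0.995)
  if (efficiency_sd > 0) {
    ei <- pmin(1, pmax(0, rnorm(n, efficiency, efficiency_sd)))
  } else {
    ei <- rep(efficiency, n)
  }
  z <- rep(1, n)
  for (i in seq_len(hi)) z <- z + rbinom(n, z, e_hi)
  for (i in seq_len(cycles - hi)) z <- z + rbinom(n, z, ei)
  as.integer(z)
}

amplify_with_cfg <- function(n, cfg) {
  amplify_family(n, cycles = cfg$pcr_cycles,
                 efficiency = cfg$per_cycle_efficiency,
                 efficiency_sd = cfg$efficiency_sd,
                 high_eff_cycles = cfg$high_eff_cycles)
}

# per-base substitution errors on a character vector of sequences
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs)
  k <- rbinom(length(seqs), L, rate)
  r <- 1L
  while (any(k >= r)) {
    sel <- which(k >= r)
    pos <- floor(runif(length(sel)) * L[sel]) + 1L
    old <- substring(seqs[sel], pos, pos)
    oi <- match(old, DNA_BASES)
    new <- DNA_BASES[((oi - 1L + sample.int(3L, length(sel), replace = TRUE)) %% 4L) + 1L]
    substr(seqs[sel], pos, pos) <- new
    r <- r + 1L
  }
  seqs
}

#' Simulate a full QASeq sequencing run
#'
#' Composes all stochastic layers and optionally writes a standard 4-line
#' FASTQ (gzipped when the filename ends in `.gz`; constant Q30 qualities)
#' plus a ground-truth table.  Read layout is
#' `[UMI][fwd_primer][amplicon_seq]` (single-end; the UMI sits 5' of the
#' gene-specific primer).  Off-target reads carry a random primer-length
#' region and insert.  Fully reproducible given `cfg$seed`.
#'
#' @param cfg `qaseq_sim_config`
#' @param panel `qaseq_panel`
#' @param out_fastq path for the FASTQ output, or NULL to skip writing.
#' @param out_truth path for the module-level truth TSV, or NULL.
#' @return object of class `qaseq_sim_truth`: `$modules` (per-module input,
#'   barcoded and read counts), `$families` (per-family pre-sampling size,
#'   sampled read count, alt status), `$variants` (true alt-family counts
#'   per spiked variant), `$reads` (character vector of read sequences) and
#'   `$read_ids`.
#' @export
simulate_run <- function(cfg, panel, out_fastq = NULL, out_truth = NULL) {
  stopifnot(inherits(cfg, "qaseq_sim_config"), inherits(panel, "qaseq_panel"))
  set.seed(cfg$seed)
  mods <- panel$modules
  n_input <- sample_input_molecules(cfg, panel)
  umis <- attach_umis(n_input, cfg, panel$umi_length)
  n_bar <- lengths(umis)

  fam_list <- vector("list", nrow(mods))
  var_truth <- list()
  for (i in seq_len(nrow(mods))) {
    nb <- n_bar[i]
    if (nb == 0L) {
      fam_list[[i]] <- data.frame(module_id = character(0), umi = character(0),
                                  size_pre = integer(0), alt_offset = integer(0),
                                  alt_base = character(0), stringsAsFactors = FALSE)
      next
    }
    sizes <- amplify_with_cfg(nb, cfg)
    fam <- data.frame(module_id = mods$module_id[i], umi = umis[[i]],
                      size_pre = sizes, alt_offset = NA_integer_,
                      alt_base = NA_character_, stringsAsFactors = FALSE)
    sv <- cfg$spiked_variants
    if (!is.null(sv)) {
      sv_i <- sv[sv$module_id == mods$module_id[i], , drop = FALSE]
      for (j in seq_len(nrow(sv_i))) {
        if (sv_i$vaf[j] * nb < 1)
          warning("spiked variant in ", mods$module_id[i],
                  " expects < 1 molecule; it may be absent")
        n_alt <- rbinom(1L, nb, sv_i$vaf[j])
        if (n_alt > 0L) {
          free <- which(is.na(fam$alt_offset))
          pick <- free[sample.int(length(free), min(n_alt, length(free)))]
          fam$alt_offset[pick] <- as.integer(sv_i$offset[j])
          fam$alt_base[pick] <- sv_i$alt[j]
        }
        var_truth[[length(var_truth) + 1L]] <- data.frame(
          module_id = mods$module_id[i], offset = as.integer(sv_i$offset[j]),
          alt = sv_i$alt[j], true_vaf = sv_i$vaf[j],
          true_alt_families = n_alt, stringsAsFactors = FALSE)
      }
    }
    fam_list[[i]] <- fam
  }
  families <- do.call(rbind, fam_list)

  # multinomial sequencing-depth sampling per module over family sizes
  families$size_sampled <- 0L
  reads_mod <- character(0)
  fam_read_idx <- integer(0)
  for (i in seq_len(nrow(mods))) {
    rows <- which(families$module_id == mods$module_id[i])
    if (length(rows) == 0L) next
    total <- as.integer(round(cfg$mean_depth_per_module))
    if (total <= 0L) next
    s <- as.vector(rmultinom(1L, total, families$size_pre[rows]))
    families$size_sampled[rows] <- s
    fam_read_idx <- c(fam_read_idx, rep(rows, s))
  }

  # assemble on-target reads
  if (length(fam_read_idx) > 0L) {
    mrow <- match(families$module_id[fam_read_idx], mods$module_id)
    insert <- mods$amplicon_seq[mrow]
    has_alt <- !is.na(families$alt_offset[fam_read_idx])
    if (any(has_alt)) {
      off <- families$alt_offset[fam_read_idx[has_alt]] + 1L
      ins_alt <- insert[has_alt]
      substr(ins_alt, off, off) <- families$alt_base[fam_read_idx[has_alt]]
      insert[has_alt] <- ins_alt
    }
    reads_mod <- paste0(families$umi[fam_read_idx], mods$fwd_primer[mrow], insert)
  }

  # off-target reads: random UMI + random primer-length region + insert
  n_on <- length(reads_mod)
  f_off <- cfg$off_target_fraction
  n_off <- if (f_off >= 1) stop("off_target_fraction must be < 1") else
    as.integer(round(n_on * f_off / (1 - f_off)))
  prim_len <- max(nchar(mods$fwd_primer))
  ins_len <- as.integer(round(median(nchar(mods$amplicon_seq))))
  reads_off <- if (n_off > 0L)
    paste0(random_dna(n_off, panel$umi_length),
           random_dna(n_off, prim_len + ins_len)) else character(0)

  reads <- c(reads_mod, reads_off)
  is_off <- c(rep(FALSE, n_on), rep(TRUE, n_off))
  reads <- add_seq_errors(reads, cfg$per_base_error_rate)
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  is_off <- is_off[ord]
  read_ids <- sprintf("sim_%07d", seq_along(reads))

  reads_per_mod <- vapply(mods$module_id, function(m)
    sum(families$size_sampled[families$module_id == m]), 0L)
  truth <- structure(list(
    modules = data.frame(module_id = mods$module_id,
                         gene = mods$gene, role = mods$role,
                         true_input_molecules = as.integer(n_input),
                         true_barcoded_molecules = as.integer(n_bar),
                         n_reads_on_target = as.integer(reads_per_mod),
                         stringsAsFactors = FALSE),
    families = families,
    variants = if (length(var_truth)) do.call(rbind, var_truth) else
      data.frame(module_id = character(0), offset = integer(0),
                 alt = character(0), true_vaf = numeric(0),
                 true_alt_families = integer(0)),
    reads = reads, read_ids = read_ids, n_off_target = n_off,
    seed = cfg$seed), class = "qaseq_sim_truth")

  if (!is.null(out_fastq)) write_fastq(reads, read_ids, out_fastq)
  if (!is.null(out_truth)) write_sim_truth(truth, out_truth)
  truth
}

write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  q <- Biostrings::BStringSet(strrep("?", nchar(seqs)))  # constant Q30
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "qaseq_sim_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# qaseq simulation truth | seed=", truth$seed,
                    " off_target_reads=", truth$n_off_target), con)
  write.table(truth$modules, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  if (nrow(truth$variants) > 0L) {
    vpath <- paste0(sub("\\.tsv$", "", path), ".variants.tsv")
    write.table(truth$variants, vpath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Simulate per-module molecule-count tables without read-level detail
#'
#' Runs only the molecular layers (Poisson input sampling and binomial
#' barcoding), returning the counts that UMI family counting would recover
#' in a clean run.  Orders of magnitude faster than [simulate_run()]; used
#' for replicate-level studies (CV curves, limit of detection, replicate
#' t-tests) where read-level noise is not the quantity under study.
#'
#' @param cfg `qaseq_sim_config`
#' @param panel `qaseq_panel`
#' @param seed optional seed overriding `cfg$seed`.
#' @return `molecule_counts` data.frame (module_id, gene, role,
#'   n_families_raw, size_cutoff, molecule_count).
#' @export
simulate_counts <- function(cfg, panel, seed = NULL) {
  stopifnot(inherits(cfg, "qaseq_sim_config"), inherits(panel, "qaseq_panel"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  n_input <- sample_input_molecules(cfg, panel)
  n_bar <- rbinom(length(n_input), n_input, cfg$conversion_yield)
  out <- data.frame(module_id = panel$modules$module_id,
                    gene = panel$modules$gene, role = panel$modules$role,
                    n_families_raw = as.integer(n_bar),
                    size_cutoff = NA_real_,
                    molecule_count = as.integer(n_bar),
                    stringsAsFactors = FALSE)
  class(out) <- c("molecule_counts", "data.frame")
  out
}

#' Generate a random synthetic panel
#'
#' Primer and insert sequences are uniform random DNA; with 20-base primers
#' the pairwise Hamming distances are far above the assignment mismatch
#' tolerance, so module identity is unambiguous by construction.
#'
#' @param genes named integer vector: target gene -> number of modules,
#'   e.g. `c(ERBB2 = 49)`.
#' @param n_reference number of reference modules (each labelled with its
#'   own `REF_*` gene symbol).
#' @param n_excluded number of excluded (e.g. chromosome-X) modules.
#' @param primer_length,amplicon_length sequence lengths in bases.
#' @param umi_length UMI length.
#' @param min_modules_per_gene_for_test CNV testability threshold.
#' @param seed optional seed.
#' @return `qaseq_panel`
#' @export
random_panel <- function(genes = c(GENE1 = 4L), n_reference = 8L,
                         n_excluded = 0L, primer_length = 20L,
                         amplicon_length = 30L, umi_length = 12L,
                         min_modules_per_gene_for_test = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_names <- c(rep(names(genes), genes),
                  sprintf("REF_%03d", seq_len(n_reference)),
                  rep("CHRX", n_excluded))
  roles <- c(rep("target", sum(genes)), rep("reference", n_reference),
             rep("excluded", n_excluded))
  n <- length(gene_names)
  modules <- data.frame(
    module_id = sprintf("M%03d", seq_len(n)),
    gene = gene_names, role = roles,
    chrom = ifelse(roles == "excluded", "chrX", "chr17"),
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + amplicon_length,
    fwd_primer = random_dna(n, primer_length),
    rev_primer = random_dna(n, primer_length),
    amplicon_seq = random_dna(n, amplicon_length),
    variant_loci = "", stringsAsFactors = FALSE)
  qaseq_panel(modules, umi_length = umi_length,
              min_modules_per_gene_for_test = min_modules_per_gene_for_test)
}
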