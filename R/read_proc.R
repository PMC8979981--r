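#' Assign reads to panel modules and extract UMIs
#'
#' Alignment-free demultiplexing: for each read, the bases immediately after
#' the UMI are compared with every module's forward primer by Hamming
#' distance; the read is assigned to the unique module within
#' `max_mismatches`.  Ties and no-hits are left unassigned (conservative
#' counting: an ambiguous read must not inflate any module's molecule
#' count).  Exact primer matches are resolved by hashing first, so only
#' error-carrying reads take the mismatch scan.
#'
#' @param reads character vector of read sequences, or a path to a FASTQ
#'   file (optionally gzipped).
#' @param panel `qaseq_panel`
#' @param max_mismatches maximum primer Hamming distance for assignment.
#' @param read_ids optional read identifiers (taken from the FASTQ when
#'   reading from file).
#' @return data.frame of class `read_assignments`: `read_id`, `module_id`
#'   (NA when unassigned), `umi`, `insert`, `mismatches`, `reason`
#'   (`assigned`, `no_match`, `ambiguous`, `too_short`).
#' @export
assign_reads <- function(reads, panel, max_mismatches = 2L, read_ids = NULL) {
  stopifnot(inherits(panel, "qaseq_panel"))
  if (length(reads) == 1L && file.exists(reads) && !grepl("^[ACGT]+$", reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    read_ids <- names(x)
    reads <- as.character(x)
  }
  if (length(reads) == 0L) stop("no reads supplied")
  if (is.null(read_ids)) read_ids <- sprintf("read_%07d", seq_along(reads))

  U <- panel$umi_length
  mods <- panel$modules
  n <- length(reads)
  module_id <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  reason <- rep("no_match", n)

  rl <- nchar(reads)
  umi <- ifelse(rl >= U, substr(reads, 1L, U), NA_character_)
  insert <- rep(NA_character_, n)

  for (L in sort(unique(nchar(mods$fwd_primer)))) {
    midx <- which(nchar(mods$fwd_primer) == L)
    primers <- mods$fwd_primer[midx]
    cand <- which(is.na(module_id) & rl >= U + L)
    if (length(cand) == 0L) next
    region <- substr(reads[cand], U + 1L, U + L)

    # stage 1: exact hash lookup
    hit <- match(region, primers)
    exact <- !is.na(hit)
    if (any(exact)) {
      rows <- cand[exact]
      module_id[rows] <- mods$module_id[midx[hit[exact]]]
      mismatches[rows] <- 0L
      reason[rows] <- "assigned"
    }

    # stage 2: Hamming scan for the remainder
    rem <- cand[!exact]
    if (length(rem) > 0L && max_mismatches > 0L) {
      reg <- region[!exact]
      pos_chars <- lapply(seq_len(L), function(p) substring(reg, p, p))
      dmat <- matrix(0L, nrow = length(rem), ncol = length(primers))
      for (m in seq_along(primers)) {
        pc <- strsplit(primers[m], "")[[1]]
        d <- integer(length(rem))
        for (p in seq_len(L)) d <- d + (pos_chars[[p]] != pc[p])
        dmat[, m] <- d
      }
      best <- apply(dmat, 1L, min)
      n_best <- rowSums(dmat == best)
      ok <- best <= max_mismatches & n_best == 1L
      amb <- best <= max_mismatches & n_best > 1L
      if (any(ok)) {
        rows <- rem[ok]
        which_m <- max.col(-dmat[ok, , drop = FALSE], ties.method = "first")
        module_id[rows] <- mods$module_id[midx[which_m]]
        mismatches[rows] <- best[ok]
        reason[rows] <- "assigned"
      }
      reason[rem[amb]] <- "ambiguous"
    }
  }
  reason[rl < U + min(nchar(mods$fwd_primer))] <- "too_short"

  assigned <- !is.na(module_id)
  if (any(assigned)) {
    L_assigned <- nchar(mods$fwd_primer)[match(module_id[assigned],
                                               mods$module_id)]
    insert[assigned] <- substr(reads[assigned], U + L_assigned + 1L,
                               rl[assigned])
  }
  out <- data.frame(read_id = read_ids, module_id = module_id, umi = umi,
                    insert = insert, mismatches = mismatches,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' Assign a single read
#'
#' @inheritParams assign_reads
#' @param read one read sequence.
#' @return one-row list with `module_id` (NA when unassigned), `umi`,
#'   `insert`, `mismatches` and `reason`.
#' @export
assign_read <- function(read, panel, max_mismatches = 2L) {
  as.list(assign_reads(read, panel, max_mismatches = max_mismatches)[1L, ])
}

#' Fraction of reads assignable to panel modules
#'
#' @param assignments `read_assignments` data.frame.
#' @return fraction of assigned reads among all reads.
#' @export
on_target_rate <- function(assignments) {
  if (NROW(assignments) == 0L) stop("on_target_rate: empty assignment list")
  mean(!is.na(assignments$module_id))
}

#' Write/read an assignment table
#' @param assignments `read_assignments`
#' @param path TSV path.
#' @return `path` invisibly (write) / `read_assignments` (read).
#' @export
write_assignments <- function(assignments, path) {
  data.table::fwrite(assignments, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                         colClasses = list(character = c(
                                           "read_id", "module_id", "umi",
                                           "insert", "reason"))))
  class(out) <- c("read_assignments", "data.frame")
  out
}
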