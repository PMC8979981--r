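#' Group assigned reads into UMI families
#'
#' All reads sharing a (module, UMI) key derive from one barcoded input
#' molecule; the existence of the family, not its size, is what counts one
#' molecule.  Unassigned reads are ignored.
#'
#' @param assignments `read_assignments` data.frame.
#' @param collapse_umis merge a family into a family at Hamming distance 1
#'   within the same module when the neighbour is at least
#'   `collapse_ratio`-fold larger (UMI sequencing-error rescue).  Off by
#'   default: the family-size cutoff already absorbs error families.
#' @param collapse_ratio size ratio required for collapsing.
#' @return data.frame of class `umi_families`: `module_id`, `umi`, `size`.
#' @export
group_families <- function(assignments, collapse_umis = FALSE,
                           collapse_ratio = 10) {
  dt <- data.table::as.data.table(assignments)
  dt <- dt[!is.na(dt$module_id)]
  fam <- dt[, list(size = .N), by = c("module_id", "umi")]
  if (collapse_umis && nrow(fam) > 1L) {
    fam <- collapse_umi_errors(fam, collapse_ratio)
  }
  out <- as.data.frame(fam[order(fam$module_id, -fam$size)])
  class(out) <- c("umi_families", "data.frame")
  out
}

# merge families into >= ratio-fold larger Hamming-1 neighbours
collapse_umi_errors <- function(fam, ratio) {
  out <- vector("list", length(unique(fam$module_id)))
  k <- 0L
  for (mod in unique(fam$module_id)) {
    f <- fam[fam$module_id == mod]
    f <- f[order(-f$size)]
    if (nrow(f) > 1L) {
      um <- do.call(rbind, strsplit(f$umi, ""))
      absorbed <- rep(FALSE, nrow(f))
      for (i in rev(seq_len(nrow(f)))) {     # smallest first
        if (absorbed[i]) next
        cand <- which(!absorbed & f$size >= ratio * f$size[i])
        cand <- cand[cand != i]
        if (length(cand) == 0L) next
        d <- rowSums(um[cand, , drop = FALSE] !=
                       matrix(um[i, ], length(cand), ncol(um), byrow = TRUE))
        hit <- cand[d == 1L]
        if (length(hit) > 0L) {
          j <- hit[which.max(f$size[hit])]
          f$size[j] <- f$size[j] + f$size[i]
          absorbed[i] <- TRUE
        }
      }
      f <- f[!absorbed]
    }
    k <- k + 1L
    out[[k]] <- f
  }
  data.table::rbindlist(out)
}

#' Family-size cutoff separating true families from error families
#'
#' The cutoff is 5% of the mean of the three largest family sizes, floored
#' at the small-family threshold (families under `min_reads` reads are
#' polymerase/sequencing error products and are never counted).  With fewer
#' than three families the mean runs over what is available.
#'
#' @param sizes integer vector of family sizes (one module).
#' @param fraction fraction of the top-3 mean (default 0.05).
#' @param min_reads absolute floor (default 3).
#' @return numeric threshold; families with `size >= cutoff` are counted.
#' @export
family_size_cutoff <- function(sizes, fraction = 0.05, min_reads = 3) {
  if (length(sizes) == 0L) stop("family_size_cutoff: empty size list")
  top <- sort(sizes, decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  max(min_reads, fraction * mean(top))
}

#' Count input molecules per module from UMI families
#'
#' Per module, the molecule count is the number of UMI families passing the
#' family-size cutoff (computed per module, since amplification scale varies
#' between amplicons).  Families exactly at a non-integer cutoff pass
#' (`>=` comparison).
#'
#' @param families `umi_families` data.frame from [group_families()].
#' @param panel optional `qaseq_panel`; when given, modules with zero
#'   observed families are reported with count 0 and an NA cutoff, and
#'   gene/role columns are attached.
#' @param fraction,min_reads cutoff parameters, see [family_size_cutoff()].
#' @param expected_molecules optional named vector of expected input
#'   molecules per module (or a single value) from which conversion yields
#'   are computed.
#' @return data.frame of class `molecule_counts`: `module_id`,
#'   `n_families_raw`, `size_cutoff`, `molecule_count` and, when available,
#'   `gene`, `role`, `conversion_yield`.
#' @export
count_molecules <- function(families, panel = NULL, fraction = 0.05,
                            min_reads = 3, expected_molecules = NULL) {
  fam <- data.table::as.data.table(families)
  per_mod <- fam[, list(
    n_families_raw = .N,
    size_cutoff = family_size_cutoff(size, fraction, min_reads),
    molecule_count = sum(size >= family_size_cutoff(size, fraction, min_reads))
  ), by = "module_id"]
  out <- as.data.frame(per_mod)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "qaseq_panel"))
    base <- data.frame(module_id = panel$modules$module_id,
                       gene = panel$modules$gene,
                       role = panel$modules$role, stringsAsFactors = FALSE)
    out <- merge(base, out, by = "module_id", all.x = TRUE, sort = FALSE)
    out$n_families_raw[is.na(out$n_families_raw)] <- 0L
    out$molecule_count[is.na(out$molecule_count)] <- 0L
    out <- out[match(panel$modules$module_id, out$module_id), ]
    rownames(out) <- NULL
  }
  if (!is.null(expected_molecules)) {
    exp_m <- if (length(expected_molecules) == 1L)
      rep(as.numeric(expected_molecules), nrow(out))
    else as.numeric(expected_molecules[out$module_id])
    out$conversion_yield <- out$molecule_count / exp_m
    if (any(out$conversion_yield > 1, na.rm = TRUE))
      warning("conversion yield above 1 for module(s): ",
              paste(out$module_id[which(out$conversion_yield > 1)],
                    collapse = ", "))
  }
  class(out) <- c("molecule_counts", "data.frame")
  out
}

#' Conversion yield: observed molecules over expected input molecules
#'
#' @param count observed molecule count (filtered UMI families).
#' @param expected_molecules expected number of input molecules.
#' @return `count / expected_molecules`.
#' @export
conversion_yield <- function(count, expected_molecules) {
  if (any(expected_molecules <= 0))
    stop("conversion_yield: expected_molecules must be > 0")
  count / expected_molecules
}

#' Log-normality diagnostic for family sizes above the cutoff
#'
#' Fits a normal distribution to log family size conditional on passing the
#' cutoff and reports location, scale, skewness and a Kolmogorov-Smirnov
#' statistic against the fitted normal.  Family sizes above the cutoff are
#' expected to be log-normal (exponentially amplified per-molecule yield
#' differences); strong deviation flags an abnormal run.
#'
#' @param sizes integer family sizes.
#' @param cutoff size threshold (e.g. from [family_size_cutoff()]).
#' @param min_n minimum families above cutoff for a reliable fit.
#' @return list: `mu`, `sigma`, `skewness`, `ks_stat`, `n`, `reliable`.
#' @export
lognormal_diagnostic <- function(sizes, cutoff, min_n = 50L) {
  s <- sizes[sizes >= cutoff]
  n <- length(s)
  if (n < min_n) {
    return(list(mu = NA_real_, sigma = NA_real_, skewness = NA_real_,
                ks_stat = NA_real_, n = n, reliable = FALSE))
  }
  ls <- log(s)
  mu <- mean(ls)
  sigma <- sd(ls)
  skew <- if (sigma > 0) mean((ls - mu)^3) / sigma^3 else 0
  ks <- if (sigma > 0)
    suppressWarnings(stats::ks.test(ls, "pnorm", mean = mu, sd = sigma)$statistic)
  else 0
  list(mu = mu, sigma = sigma, skewness = as.numeric(skew),
       ks_stat = as.numeric(ks), n = n, reliable = TRUE)
}

#' Single UMI family with per-position base counts
#'
#' @param module_id,umi family key.
#' @param inserts character vector: insert sequence of every read in the
#'   family.
#' @return list of class `umi_family`: `module_id`, `umi`, `size`,
#'   `base_counts` (5 x L matrix over A,C,G,T,N).
#' @export
umi_family <- function(module_id, umi, inserts) {
  stopifnot(length(inserts) >= 1L)
  L <- max(nchar(inserts))
  bc <- matrix(0L, nrow = 5L, ncol = L,
               dimnames = list(c(DNA_BASES, "N"), NULL))
  for (p in seq_len(L)) {
    b <- substring(inserts, p, p)
    b[!b %in% DNA_BASES & nzchar(b)] <- "N"
    tab <- table(factor(b[nzchar(b)], levels = rownames(bc)))
    bc[, p] <- as.integer(tab)
  }
  structure(list(module_id = module_id, umi = umi,
                 size = length(inserts), base_counts = bc),
            class = "umi_family")
}

#' Write/read a molecule-count table
#' @param counts `molecule_counts`
#' @param path TSV path.
#' @param meta named character vector written as `# key=value` header lines.
#' @return `path` invisibly (write) / `molecule_counts` (read).
#' @export
write_counts <- function(counts, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("# qaseq molecule counts | ",
                  utils::packageName(), " ",
                  as.character(utils::packageVersion("qaseq"))),
           if (!is.null(meta)) paste0("# ", names(meta), "=", meta))
  writeLines(hdr, con)
  write.table(counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  class(out) <- c("molecule_counts", "data.frame")
  out
}
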