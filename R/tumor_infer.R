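#' Forward cfDNA ploidy under the single-clone mixture model
#'
#' Plasma cell-free DNA is a mixture of tumor-derived DNA (fraction `f`,
#' gene ploidy `p`) and normal diploid DNA, so the observed cfDNA ploidy is
#' `p * f + 2 * (1 - f)`.  Very different tumors can produce the same
#' plasma value: copy number 20 at 1% tumor fraction and copy number 5 at
#' 6% both give 2.18.
#'
#' @param tumor_ploidy gene ploidy in the pure tumor (>= 0).
#' @param tumor_fraction fraction of cfDNA derived from tumor, in \[0, 1\].
#' @return cfDNA mixture ploidy.
#' @export
cfdna_ploidy_forward <- function(tumor_ploidy, tumor_fraction) {
  if (any(tumor_fraction < 0 | tumor_fraction > 1))
    stop("tumor_fraction must lie in [0, 1]")
  if (any(tumor_ploidy < 0)) stop("tumor_ploidy must be >= 0")
  tumor_ploidy * tumor_fraction + 2.0 * (1 - tumor_fraction)
}

#' Tumor clone mixture
#'
#' @param clone_fractions cfDNA fractions per tumor subclone (sum <= 1).
#' @param clone_ploidies gene ploidy per subclone.
#' @param clone_vafs mutation VAF per subclone.
#' @return validated list of class `tumor_mixture`.
#' @export
tumor_mixture <- function(clone_fractions, clone_ploidies, clone_vafs) {
  stopifnot(length(clone_fractions) == length(clone_ploidies),
            length(clone_fractions) == length(clone_vafs))
  if (any(clone_fractions < 0 | clone_fractions > 1))
    stop("clone fractions must lie in [0, 1]")
  if (sum(clone_fractions) > 1)
    stop("clone fractions must sum to at most 1")
  if (any(clone_ploidies < 0)) stop("clone ploidies must be >= 0")
  if (any(clone_vafs < 0 | clone_vafs > 1))
    stop("clone VAFs must lie in [0, 1]")
  structure(list(clone_fractions = clone_fractions,
                 clone_ploidies = clone_ploidies,
                 clone_vafs = clone_vafs), class = "tumor_mixture")
}

#' Forward cfDNA ploidy and VAF for a multi-clone tumor
#'
#' `ploidy = sum(p_i f_i) + 2 (1 - sum f_i)`; `vaf = sum(v_i f_i)`.
#' An empty clone list is pure normal cfDNA: ploidy 2, VAF 0.
#'
#' @param mix `tumor_mixture`
#' @return list with `cfdna_ploidy` and `cfdna_vaf`.
#' @export
cfdna_forward_multiclone <- function(mix) {
  stopifnot(inherits(mix, "tumor_mixture"))
  f <- mix$clone_fractions
  list(cfdna_ploidy = sum(mix$clone_ploidies * f) + 2.0 * (1 - sum(f)),
       cfdna_vaf = sum(mix$clone_vafs * f))
}

#' Tumor fraction from plasma mutation VAF
#'
#' Under the monoallelic hypothesis (mutation VAF in the pure tumor is
#' 50%), `tumor fraction = 2 x cfDNA VAF`.  If the mutation is in fact
#' biallelic the result overestimates the true fraction exactly 2-fold;
#' the caveat travels in the `"note"` attribute.  VAFs above 50% imply a
#' germline or biallelic variant for which the inversion is invalid.
#'
#' @param cfdna_vaf mutation VAF observed in cfDNA, in \[0, 0.5\].
#' @return tumor fraction with attribute `note`.
#' @export
tumor_fraction_from_vaf <- function(cfdna_vaf) {
  if (any(cfdna_vaf < 0 | cfdna_vaf > 0.5))
    stop("cfdna_vaf must lie in [0, 0.5] for the monoallelic inversion")
  structure(2 * cfdna_vaf,
            note = "monoallelic assumption; 2-fold high if biallelic")
}

#' Infer tumor gene ploidy from plasma ploidy and mutation VAF
#'
#' Inverts the single-clone mixture: `f = 2 x VAF`, then
#' `tumor ploidy = (cfDNA ploidy - 2 (1 - f)) / f`.  Under the stated
#' assumptions (single clone, monoallelic mutation) the result is expected
#' to be within two-fold of the true value.  A negative inferred ploidy
#' signals inconsistent VAF/ploidy inputs and is returned flagged rather
#' than clamped.
#'
#' @param cfdna_ploidy observed cfDNA gene ploidy (> 0).
#' @param cfdna_vaf observed cfDNA mutation VAF in (0, 0.5\].
#' @param vaf_window admissible VAF range for a trustworthy inversion
#'   (default 1%-30%, avoiding SNPs and unquantifiable signal); values
#'   outside only produce a note, not an error.
#' @return inferred tumor ploidy, with attributes `tumor_fraction`,
#'   `valid` (FALSE when negative), and `note`.
#' @export
infer_tumor_ploidy <- function(cfdna_ploidy, cfdna_vaf,
                               vaf_window = c(0.01, 0.30)) {
  if (cfdna_ploidy <= 0) stop("cfdna_ploidy must be > 0")
  if (cfdna_vaf <= 0)
    stop("infer_tumor_ploidy: zero VAF carries no tumor signal")
  f <- as.numeric(tumor_fraction_from_vaf(cfdna_vaf))
  p <- (cfdna_ploidy - 2.0 * (1 - f)) / f
  notes <- "single-clone, monoallelic model; within two-fold of truth"
  if (cfdna_vaf < vaf_window[1] || cfdna_vaf > vaf_window[2])
    notes <- c(notes, sprintf("VAF outside the [%g, %g] eligibility window",
                              vaf_window[1], vaf_window[2]))
  structure(p, tumor_fraction = f, valid = p >= 0,
            note = paste(notes, collapse = "; "))
}
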