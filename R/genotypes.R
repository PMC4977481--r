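#' The nucleotide alphabet and the diploid genotype set
#'
#' `bases()` returns the four-letter nucleotide alphabet. `genotype_set()`
#' returns the K = 10 unordered diploid genotypes over that alphabet in the
#' package's canonical order (homozygotes first, then heterozygotes in
#' lexicographic order). The canonical order is also the deterministic
#' tie-break used whenever two genotypes reach an identical posterior.
#'
#' @return A character vector.
#' @export
#' @examples
#' genotype_set()
genotype_set <- function() GENOTYPES

#' @rdname genotype_set
#' @export
bases <- function() BASES

BASES <- c("A", "C", "G", "T")
GENOTYPES <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")

# 10 x 2 allele matrix in canonical order
GT_ALLELES <- do.call(rbind, strsplit(GENOTYPES, ""))
rownames(GT_ALLELES) <- GENOTYPES

# integer codes of the alleles, for fast column indexing
GT_A1 <- match(GT_ALLELES[, 1], BASES)
GT_A2 <- match(GT_ALLELES[, 2], BASES)

#' Categorize diploid genotypes relative to a reference base
#'
#' Every genotype falls into exactly one of four categories given the
#' reference base at the site: `hom_ref` (both alleles equal the reference),
#' `het_ref` (the reference plus one other allele), `hom_var` (two copies of
#' a single non-reference allele) or `het_var` (two distinct non-reference
#' alleles).
#'
#' @param genotype Character vector of two-letter genotypes, e.g. `"AG"`.
#' @param ref Character vector of reference bases (recycled).
#' @return Character vector with values `hom_ref`, `het_ref`, `hom_var`,
#'   `het_var`.
#' @export
#' @examples
#' genotype_category(c("AA", "AG", "GG", "CG"), "A")
genotype_category <- function(genotype, ref) {
  stopifnot(all(genotype %in% GENOTYPES | is.na(genotype)))
  n <- max(length(genotype), length(ref))
  genotype <- rep_len(genotype, n)
  ref <- rep_len(ref, n)
  a1 <- substr(genotype, 1, 1)
  a2 <- substr(genotype, 2, 2)
  hom <- a1 == a2
  has_ref <- a1 == ref | a2 == ref
  out <- ifelse(hom & has_ref, "hom_ref",
         ifelse(!hom & has_ref, "het_ref",
         ifelse(hom, "hom_var", "het_var")))
  out[is.na(genotype)] <- NA_character_
  out
}

#' Transition test for a pair of bases
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' A<->G and C<->T; all other substitutions are transversions.
#'
#' @param x,y Character vectors of bases.
#' @return Logical vector; `NA`-safe, and `FALSE` when `x == y`.
#' @export
is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

# number of allele changes between two unordered genotypes (0, 1 or 2)
gt_distance <- function(g1, g2) {
  a <- c(substr(g1, 1, 1), substr(g1, 2, 2))
  b <- c(substr(g2, 1, 1), substr(g2, 2, 2))
  if (identical(sort(a), sort(b))) return(0L)
  # shared allele under either pairing?
  if (a[1] %in% b || a[2] %in% b) 1L else 2L
}
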