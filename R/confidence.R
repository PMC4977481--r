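#' Reference substitution probability of an observed base
#'
#' Probability of the reference base \eqn{\gamma} being substituted by the
#' observed base, from the heterozygous mutation rate \eqn{\theta} and the
#' Ti/Tv ratio \eqn{\delta}: transitions get
#' \eqn{S_{ti} = \delta\theta/(1+\delta)}, transversions
#' \eqn{S_{tv} = 0.5\,\theta/(1+\delta)}, and the reference itself
#' \eqn{1-\theta}.
#'
#' @param x Observed base(s).
#' @param ref Reference base(s) (recycled).
#' @param params A [var_params()] object.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' substitution_prob(c("G", "C", "A"), "A")  # transition, transversion, ref
substitution_prob <- function(x, ref, params = var_params()) {
  s_ti <- params$delta * params$theta / (1 + params$delta)
  s_tv <- 0.5 * params$theta / (1 + params$delta)
  ifelse(x == ref, 1 - params$theta,
         ifelse(is_transition(x, ref), s_ti, s_tv))
}

#' Variant confidence score of a column under a called genotype
#'
#' The mean, over the observations whose base is an allele of the called
#' genotype, of the negative natural log of the reference substitution
#' probability ([substitution_prob()]). Defined only for genotypes with at
#' least one non-reference allele; when no observation matches the genotype
#' the score is 0 (and the variant classifies as a false positive). The
#' score depends only on base identities, never on read order or on the
#' qualities of non-matching reads.
#'
#' @param bases Character vector of observed bases at the site.
#' @param genotype Called two-letter genotype (not homozygous reference).
#' @param ref Reference base.
#' @param params A [var_params()] object.
#' @return A single non-negative score.
#' @export
#' @examples
#' vcos_score(rep("G", 10), "GG", "A")  # -log(S_ti)
vcos_score <- function(bases, genotype, ref, params = var_params()) {
  stopifnot(genotype %in% GENOTYPES)
  if (genotype_category(genotype, ref) == "hom_ref")
    stop("the variant confidence score is defined only for genotypes with ",
         "at least one non-reference allele", call. = FALSE)
  al <- unique(c(substr(genotype, 1, 1), substr(genotype, 2, 2)))
  m <- bases %in% al
  if (!any(m)) return(0)
  mean(-log(substitution_prob(bases[m], ref, params)))
}

#' High- and low-confidence score thresholds for a genotype
#'
#' Analytic thresholds against which the variant confidence score is
#' compared. Reference-heterozygous genotypes (Case 1):
#' \deqn{HC = -\tfrac12 \log((1-\theta) S_{ti}),\quad
#'       LC = -\phi \log(1-\theta) - \tfrac12 (1-\phi) \log(S_{ti} S_{tv})}
#' Genotypes without the reference allele (Case 2):
#' \deqn{HC = -\log S_{ti},\quad
#'       LC = -\tfrac12 \psi \log(S_{ti} S_{tv}) - (1-\psi) \log(1-\theta)}
#' [var_params()] rejects `phi`/`psi` values for which `HC < LC`. Natural
#' logs are used throughout; any common log base rescales scores and
#' thresholds together, so the classification is base-invariant.
#'
#' @param genotype Two-letter genotype(s) (vectorized).
#' @param ref Reference base(s) (recycled).
#' @param params A [var_params()] object.
#' @return A tibble with columns `hc` and `lc` (`NA` rows for homozygous
#'   reference genotypes).
#' @export
#' @examples
#' conf_thresholds(c("AG", "GG"), "A")
conf_thresholds <- function(genotype, ref, params = var_params()) {
  n <- max(length(genotype), length(ref))
  genotype <- rep_len(genotype, n); ref <- rep_len(ref, n)
  cat_ <- genotype_category(genotype, ref)
  th <- params$theta; d <- params$delta
  s_ti <- d * th / (1 + d); s_tv <- 0.5 * th / (1 + d)
  hc1 <- -0.5 * log((1 - th) * s_ti)
  lc1 <- -params$phi * log(1 - th) - 0.5 * (1 - params$phi) * log(s_ti * s_tv)
  hc2 <- -log(s_ti)
  lc2 <- -0.5 * params$psi * log(s_ti * s_tv) - (1 - params$psi) * log(1 - th)
  case1 <- cat_ == "het_ref"
  hc <- ifelse(case1, hc1, hc2)
  lc <- ifelse(case1, lc1, lc2)
  hc[cat_ == "hom_ref"] <- NA_real_
  lc[cat_ == "hom_ref"] <- NA_real_
  tibble::tibble(hc = hc, lc = lc)
}

#' Classify a called variant by its confidence score
#'
#' Computes the variant confidence score of the column under the called
#' genotype and grades it against the genotype's thresholds: `high` when
#' the score reaches `HC`, `low` when it reaches `LC` but not `HC`, and
#' `false_positive` otherwise. Boundary scores land on the higher grade
#' (a column of perfect transition-variant reads scores exactly `HC` and is
#' graded `high`).
#'
#' @inheritParams vcos_score
#' @return A one-row tibble of class columns `vcos`, `hc`, `lc`, `label`.
#' @export
#' @examples
#' classify_confidence(rep("G", 10), "GG", "A")
classify_confidence <- function(bases, genotype, ref, params = var_params()) {
  v <- vcos_score(bases, genotype, ref, params)
  th <- conf_thresholds(genotype, ref, params)
  tibble::tibble(vcos = v, hc = th$hc, lc = th$lc,
                 label = grade_vcos(v, th$hc, th$lc))
}

# boundary comparisons use a tiny tolerance so a score assembled as a mean
# of the exact threshold terms cannot fall to the lower grade by one ulp
grade_vcos <- function(vcos, hc, lc, tol = 1e-9) {
  ifelse(vcos >= hc - tol, "high",
         ifelse(vcos >= lc - tol, "low", "false_positive"))
}

# vectorized VCOS from a per-site base-count matrix: sum of counts of the
# genotype's alleles weighted by their substitution surprisal, divided by
# the matching count. Returns 0 where nothing matches.
vcos_from_counts <- function(counts, gt_idx, ref_idx, params) {
  n <- length(gt_idx)
  # 4x4 surprisal table: -log P(x | gamma)
  sp <- -log(outer(BASES, BASES,
                   function(x, g) substitution_prob(x, g, params)))
  a1 <- GT_A1[gt_idx]; a2 <- GT_A2[gt_idx]
  c1 <- counts[cbind(seq_len(n), a1)]
  s1 <- c1 * sp[cbind(a1, ref_idx)]
  hom <- a1 == a2
  c2 <- ifelse(hom, 0L, counts[cbind(seq_len(n), a2)])
  s2 <- ifelse(hom, 0, c2 * sp[cbind(a2, ref_idx)])
  m <- c1 + c2
  ifelse(m > 0, (s1 + s2) / m, 0)
}
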