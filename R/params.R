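#' Model parameters for germline and somatic calling
#'
#' Collects every tunable of the calling engines in one validated object.
#'
#' @param theta Heterozygous point-mutation rate \eqn{\theta} between two
#'   haploid human chromosomes. Default `1e-3`.
#' @param delta Transition/transversion ratio \eqn{\delta}; default `2.0`
#'   (human whole-genome scale).
#' @param alpha Proportion of reads sequenced from the first haploid
#'   chromosome; default `0.5` (impartial sequencing of both haplotypes).
#' @param prior_mode Genotype prior family: `"theta"` (mutation-rate priors,
#'   the default), `"flat"` (non-informative, 1/K each) or `"titv"` (the
#'   theta priors reweighted by transition/transversion status of the
#'   non-reference alleles).
#' @param phi,psi Mixing weights of the low-confidence thresholds for
#'   reference-heterozygous (`phi`) and reference-free (`psi`) genotypes.
#'   Both must keep the high-confidence threshold at or above the
#'   low-confidence threshold; `NULL` (default) picks the midpoint of the
#'   admissible interval for the given `theta` and `delta`.
#' @param purity Expected fraction of tumor-cell reads in the tumor sample,
#'   in `[0, 1]`. `NA` (default) triggers the built-in fallback estimator in
#'   somatic mode.
#' @param somatic_rate Dependency rate of the tumor-given-normal genotype
#'   prior: probability mass moved off the diagonal per changed allele.
#' @param window Sliding-window size for the optional strand-bias `alpha`
#'   mode; `use_window_alpha` switches the max-form likelihood on. Off by
#'   default.
#' @param use_window_alpha Logical; see `window`.
#' @param min_bq,min_mq Base/mapping-quality floors applied when reading
#'   pileup input. Defaults 13 and 0.
#' @param default_mq Mapping quality assumed when the input carries none.
#' @param mu,mu_indel Point-mutation and indel rates used to build the
#'   expected columns of the two Fisher's exact tests for indel candidates.
#' @param a1,a2 Significance cutoffs of the two Fisher tests (first test:
#'   substitution excess disqualifies the site; second: indel excess
#'   qualifies it).
#' @param hom_frac Indel-supporting read fraction at or above which an indel
#'   call is reported homozygous.
#' @param min_var_reads,relax_factor Relaxed post-processing constraint: a
#'   genotype confirmed by both the subtraction and the joint analysis is
#'   kept when its variant-supporting reads reach
#'   `max(min_var_reads, ceiling(f * depth))` with
#'   `f = 0.25 * purity * relax_factor` (half the expected heterozygous
#'   variant-allele fraction, scaled by purity).
#' @param min_depth Minimum retained reads required to emit a genotype call.
#' @param mua_mode Likelihood used to rank multiple ungapped alignments:
#'   `"literal"` (log2 of the summed consensus log-odds, guarded to -Inf
#'   when the sum is non-positive) or `"mean"` (mean consensus log-odds).
#'
#' @return An object of class `var_params` (a named list).
#' @export
#' @examples
#' p <- var_params()
#' p$phi   # midpoint of the admissible interval at theta = 1e-3, delta = 2
var_params <- function(theta = 1e-3, delta = 2.0, alpha = 0.5,
                       prior_mode = c("theta", "flat", "titv"),
                       phi = NULL, psi = NULL,
                       purity = NA_real_, somatic_rate = 1e-4,
                       window = 1000L, use_window_alpha = FALSE,
                       min_bq = 13L, min_mq = 0L, default_mq = 60L,
                       mu = 1e-3, mu_indel = 1e-3, a1 = 0.01, a2 = 0.01,
                       hom_frac = 0.75, min_var_reads = 2L,
                       relax_factor = 1.0, min_depth = 1L,
                       mua_mode = c("literal", "mean")) {
  prior_mode <- match.arg(prior_mode)
  mua_mode <- match.arg(mua_mode)
  stopifnot(theta > 0, theta < 1, delta > 0,
            alpha >= 0, alpha <= 1,
            is.na(purity) || (purity >= 0 && purity <= 1),
            somatic_rate >= 0, somatic_rate < 1,
            mu > 0, mu < 1, mu_indel > 0, mu_indel < 1,
            a1 > 0, a1 < 1, a2 > 0, a2 < 1,
            hom_frac > 0, hom_frac <= 1,
            min_var_reads >= 0, relax_factor > 0, min_depth >= 1)

  adm <- admissible_conf_weights(theta, delta)
  if (is.null(phi)) phi <- (adm$phi_min + 1) / 2
  if (is.null(psi)) psi <- adm$psi_max / 2
  if (phi < adm$phi_min - 1e-12 || phi > 1)
    stop("phi = ", signif(phi, 4), " violates HC >= LC for het-ref genotypes; ",
         "admissible range is [", signif(adm$phi_min, 4), ", 1] at these theta/delta",
         call. = FALSE)
  if (psi < 0 || psi > adm$psi_max + 1e-12)
    stop("psi = ", signif(psi, 4), " violates HC >= LC for reference-free genotypes; ",
         "admissible range is [0, ", signif(adm$psi_max, 4), "] at these theta/delta",
         call. = FALSE)

  structure(
    list(theta = theta, delta = delta, alpha = alpha, prior_mode = prior_mode,
         phi = phi, psi = psi, purity = purity, somatic_rate = somatic_rate,
         window = as.integer(window), use_window_alpha = use_window_alpha,
         min_bq = as.integer(min_bq), min_mq = as.integer(min_mq),
         default_mq = as.integer(default_mq),
         mu = mu, mu_indel = mu_indel, a1 = a1, a2 = a2,
         hom_frac = hom_frac, min_var_reads = as.integer(min_var_reads),
         relax_factor = relax_factor, min_depth = as.integer(min_depth),
         mua_mode = mua_mode),
    class = "var_params")
}

#' Admissible confidence-threshold weights
#'
#' The low-confidence thresholds interpolate between the reference and the
#' variant substitution surprisal; only part of the `[0, 1]` interval keeps
#' them at or below the corresponding high-confidence thresholds. This
#' returns the admissible bounds for a given mutation rate and Ti/Tv ratio:
#' `phi` must lie in `[phi_min, 1]`, `psi` in `[0, psi_max]`.
#'
#' @inheritParams var_params
#' @return A list with elements `phi_min` and `psi_max`.
#' @export
admissible_conf_weights <- function(theta, delta) {
  s_ti <- delta * theta / (1 + delta)
  s_tv <- 0.5 * theta / (1 + delta)
  a <- -log(1 - theta)            # surprisal of a reference match
  b <- -0.5 * log(s_ti * s_tv)    # mean variant surprisal
  hc1 <- -0.5 * log((1 - theta) * s_ti)
  hc2 <- -log(s_ti)
  # case 1: LC(phi) = phi*a + (1-phi)*b, decreasing in phi (b > a)
  phi_min <- max(0, min(1, (b - hc1) / (b - a)))
  # case 2: LC(psi) = psi*b + (1-psi)*a, increasing in psi
  psi_max <- max(0, min(1, (hc2 - a) / (b - a)))
  list(phi_min = phi_min, psi_max = psi_max)
}

#' @export
print.var_params <- function(x, ...) {
  cat("<var_params>\n")
  cat(sprintf("  theta %.3g  delta %.3g  alpha %.3g  priors '%s'\n",
              x$theta, x$delta, x$alpha, x$prior_mode))
  cat(sprintf("  phi %.4g  psi %.4g  purity %s  somatic_rate %.3g\n",
              x$phi, x$psi,
              if (is.na(x$purity)) "estimate" else format(x$purity),
              x$somatic_rate))
  cat(sprintf("  quality floors bq>=%d mq>=%d (default mq %d); min depth %d\n",
              x$min_bq, x$min_mq, x$default_mq, x$min_depth))
  cat(sprintf("  indel tests mu %.3g/%.3g cutoffs %.3g/%.3g; hom_frac %.2f; mua '%s'\n",
              x$mu, x$mu_indel, x$a1, x$a2, x$hom_frac, x$mua_mode))
  invisible(x)
}

#' Base substitution probability table
#'
#' The 4x4 table \eqn{\Phi}: `phi_table[x, g]` is the probability that `g`
#' is the true chromosomal base given that the observed base `x` was
#' miscalled or misaligned. The default is non-informative: each of the
#' three bases other than the observed one is equally likely (1/3). A
#' platform-specific error profile can be supplied anywhere a `phi_table`
#' argument is accepted; rows must sum to 1 over the off-diagonal cells
#' (the diagonal is unused).
#'
#' @return A 4x4 numeric matrix with dimnames `A,C,G,T`.
#' @export
#' @examples
#' flat_substitution_table()
flat_substitution_table <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  m
}

check_phi_table <- function(phi_table) {
  if (is.null(phi_table)) return(flat_substitution_table())
  stopifnot(is.matrix(phi_table), all(dim(phi_table) == c(4, 4)))
  if (is.null(dimnames(phi_table))) dimnames(phi_table) <- list(BASES, BASES)
  off <- phi_table
  diag(off) <- 0
  if (any(abs(rowSums(off) - 1) > 1e-6))
    stop("each row of the substitution table must sum to 1 over the ",
         "off-diagonal cells", call. = FALSE)
  phi_table
}
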