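#' Allele observation weight from base and mapping quality
#'
#' The weight of an observed allele combines its Phred base quality and
#' mapping quality as one minus the harmonic mean of the two implied error
#' probabilities:
#' \deqn{\omega = 1 - \frac{2 \cdot 10^{-0.1(B_q + M_q)}}{10^{-0.1 B_q} + 10^{-0.1 M_q}}}
#' Equal qualities collapse to \eqn{1 - 10^{-0.1 B_q}}; the weight always
#' lies in `[0, 1)`. Negative qualities are clamped to 0.
#'
#' @param bq,mq Phred base and mapping quality (vectors, recycled).
#' @return Numeric vector of weights.
#' @export
#' @examples
#' allele_weight(30, 30)  # 0.999
allele_weight <- function(bq, mq) {
  bq <- pmax(bq, 0)
  mq <- pmax(mq, 0)
  eb <- 10^(-0.1 * bq)
  em <- 10^(-0.1 * mq)
  1 - 2 * eb * em / (eb + em)
}

#' Probability of an observed allele given one haploid chromosome
#'
#' Returns the observation weight \eqn{\omega} when the observed base equals
#' the haploid base, and \eqn{(1-\omega)\,\Phi(x, g)} otherwise, where
#' \eqn{\Phi} is the base substitution table (see
#' [flat_substitution_table()]).
#'
#' @param base Observed base(s).
#' @param hap Haploid chromosome base(s).
#' @param omega Observation weight(s) from [allele_weight()].
#' @param phi_table Substitution table; `NULL` for the non-informative 1/3
#'   table.
#' @return Numeric vector of probabilities.
#' @export
allele_prob_haploid <- function(base, hap, omega, phi_table = NULL) {
  phi_table <- check_phi_table(phi_table)
  n <- max(length(base), length(hap), length(omega))
  base <- rep_len(base, n); hap <- rep_len(hap, n); omega <- rep_len(omega, n)
  ifelse(base == hap, omega, (1 - omega) * phi_table[cbind(base, hap)])
}

#' Probability of an observed allele given a diploid genotype
#'
#' Mixes the two haploid-chromosome probabilities with the haplotype
#' sampling proportion `alpha`:
#' \eqn{\alpha P(x|G^1) + (1-\alpha) P(x|G^2)}. When the sliding-window
#' strand mode is enabled (`params$use_window_alpha`), the max-form variant
#' is used instead, taking the larger of the two allele-order assignments so
#' the result does not depend on which haplotype the forward strand
#' represents.
#'
#' @param base Observed base(s).
#' @param genotype Two-letter genotype(s).
#' @param omega Observation weight(s).
#' @param params A [var_params()] object (supplies `alpha` and the mode).
#' @param phi_table Optional substitution table.
#' @param alpha Optional site-specific alpha overriding `params$alpha`.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' allele_prob_genotype("A", "AC", allele_weight(30, 30), var_params())
allele_prob_genotype <- function(base, genotype, omega, params = var_params(),
                                 phi_table = NULL, alpha = NULL) {
  phi_table <- check_phi_table(phi_table)
  a <- if (is.null(alpha)) params$alpha else alpha
  g1 <- substr(genotype, 1, 1)
  g2 <- substr(genotype, 2, 2)
  p1 <- allele_prob_haploid(base, g1, omega, phi_table)
  p2 <- allele_prob_haploid(base, g2, omega, phi_table)
  if (params$use_window_alpha)
    pmax(a * p1 + (1 - a) * p2, (1 - a) * p1 + a * p2)
  else
    a * p1 + (1 - a) * p2
}

#' Sliding-window strand proportion
#'
#' Site-specific haplotype sampling proportion estimated as the mean, over a
#' window of columns centred on the site, of the per-site fraction of
#' forward-strand observations. Used with the max-form genotype likelihood
#' (see [allele_prob_genotype()]); the default calling mode keeps a constant
#' `alpha = 0.5`.
#'
#' @param fwd_frac Numeric vector of per-site forward-strand fractions
#'   (sites in genomic order).
#' @param center Index of the focal site.
#' @param window Window size in sites.
#' @return A single proportion in `[0, 1]`.
#' @export
strand_alpha <- function(fwd_frac, center, window = 1000L) {
  half <- window %/% 2
  lo <- max(1L, center - half)
  hi <- min(length(fwd_frac), center + half)
  mean(fwd_frac[lo:hi], na.rm = TRUE)
}

#' Log-likelihood of a column under one genotype
#'
#' The allele-count likelihood of a site is the product over retained reads
#' of the per-read genotype probability; this returns its natural log (the
#' multinomial coefficient is constant across genotypes and omitted). Empty
#' columns return `NA` (no-call).
#'
#' @param obs Tibble of observations with columns `base`, `bq`, `mq`.
#' @param genotype Two-letter genotype.
#' @inheritParams allele_prob_genotype
#' @return A single log-likelihood, or `NA` for an empty column.
#' @export
site_log_likelihood <- function(obs, genotype, params = var_params(),
                                phi_table = NULL, alpha = NULL) {
  if (nrow(obs) == 0) return(NA_real_)
  omega <- allele_weight(obs$bq, obs$mq)
  sum(log(allele_prob_genotype(obs$base, genotype, omega, params,
                               phi_table, alpha)))
}

#' Genotype prior probabilities for a reference base
#'
#' Three prior families over the 10 diploid genotypes:
#' * `"theta"`: heterozygous-reference genotypes get \eqn{\theta},
#'   heterozygous-variant \eqn{\theta^2}, homozygous-variant
#'   \eqn{\theta/2}, and the homozygous reference the remaining mass.
#' * `"flat"`: 1/10 each.
#' * `"titv"`: the theta priors reweighted per genotype by the product over
#'   its non-reference alleles of \eqn{\delta/(1+\delta)} (transition of the
#'   reference) or \eqn{0.5/(1+\delta)} (transversion), rescaled so the
#'   total non-reference mass matches the theta mode.
#'
#' @param ref Reference base.
#' @param params A [var_params()] object.
#' @return Named numeric vector over [genotype_set()], summing to 1.
#' @export
#' @examples
#' genotype_priors("A", var_params())
genotype_priors <- function(ref, params = var_params()) {
  stopifnot(ref %in% BASES)
  theta <- params$theta
  cat10 <- genotype_category(GENOTYPES, ref)
  if (params$prior_mode == "flat") {
    pri <- rep(1 / 10, 10)
    names(pri) <- GENOTYPES
    return(pri)
  }
  pri <- numeric(10)
  pri[cat10 == "het_ref"] <- theta
  pri[cat10 == "het_var"] <- theta^2
  pri[cat10 == "hom_var"] <- theta / 2
  if (params$prior_mode == "titv") {
    d <- params$delta
    w_of <- function(x) ifelse(is_transition(ref, x), d / (1 + d), 0.5 / (1 + d))
    nonref <- cat10 != "hom_ref"
    w <- vapply(which(nonref), function(k) {
      al <- GT_ALLELES[k, ]
      prod(w_of(al[al != ref]))
    }, numeric(1))
    mass <- sum(pri[nonref])
    pri[nonref] <- pri[nonref] * w
    pri[nonref] <- pri[nonref] * mass / sum(pri[nonref])
  }
  pri[cat10 == "hom_ref"] <- 1 - sum(pri)
  names(pri) <- GENOTYPES
  pri
}

#' Infer the genotype of a single column
#'
#' Posterior over the 10 diploid genotypes: likelihood ([site_log_likelihood()])
#' times prior ([genotype_priors()]), normalized. The maximum a posteriori
#' genotype is selected; exact posterior ties break deterministically by the
#' canonical genotype order of [genotype_set()].
#'
#' @param obs Tibble of observations (`base`, `bq`, `mq`).
#' @param ref Reference base at the site.
#' @inheritParams allele_prob_genotype
#' @return A list of class `genotype_posterior` with elements
#'   `log_likelihoods`, `posteriors` (both named over the genotype set),
#'   `best` and `runner_up`, or `NULL` (no-call) for an empty column.
#' @export
#' @examples
#' col <- tibble::tibble(base = rep("A", 10), bq = 30, mq = 30)
#' infer_genotype(col, "A")$best
infer_genotype <- function(obs, ref, params = var_params(),
                           phi_table = NULL, alpha = NULL) {
  if (is.null(obs) || nrow(obs) == 0) return(NULL)
  ll <- vapply(GENOTYPES, function(g)
    site_log_likelihood(obs, g, params, phi_table, alpha), numeric(1))
  lp <- ll + log(genotype_priors(ref, params))
  m <- max(lp)
  post <- exp(lp - m)
  post <- post / sum(post)
  ord <- order(post, decreasing = TRUE)
  structure(list(log_likelihoods = ll, posteriors = post,
                 best = GENOTYPES[which.max(post)],
                 runner_up = GENOTYPES[ord[2]]),
            class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat(sprintf("<genotype_posterior> best %s (%.4g), runner-up %s (%.4g)\n",
              x$best, max(x$posteriors), x$runner_up,
              sort(x$posteriors, decreasing = TRUE)[2]))
  invisible(x)
}

# ---- vectorized batch machinery ------------------------------------------

# Per-site log-likelihood matrix (n_sites x 10), base-count matrix
# (n_sites x 4), forward-strand counts and retained depth, for a whole
# pileup in one pass. This is the production path; infer_genotype() is the
# transparent single-column form of the same model.
gt_loglik_matrix <- function(pileup, params, phi_table = NULL) {
  phi_table <- check_phi_table(phi_table)
  ns <- nrow(pileup$sites)
  obs <- pileup$obs
  L <- matrix(0, ns, 10, dimnames = list(NULL, GENOTYPES))
  counts <- matrix(0L, ns, 4, dimnames = list(NULL, BASES))
  fwd <- integer(ns)
  if (nrow(obs) > 0) {
    omega <- allele_weight(obs$bq, obs$mq)
    one_m <- 1 - omega
    bidx <- match(obs$base, BASES)
    # rowsum() keeps only groups that occur; map them back to site rows
    occ <- sort(unique(obs$site))
    # haploid probability columns P(obs | hap = h)
    phap <- matrix(0, nrow(obs), 4)
    for (h in 1:4) {
      hit <- bidx == h
      phap[, h] <- ifelse(hit, omega, one_m * phi_table[cbind(bidx, h)])
    }
    a <- params$alpha
    for (k in 1:10) {
      p1 <- phap[, GT_A1[k]]
      p2 <- phap[, GT_A2[k]]
      pg <- if (params$use_window_alpha)
        pmax(a * p1 + (1 - a) * p2, (1 - a) * p1 + a * p2)
      else a * p1 + (1 - a) * p2
      L[occ, k] <- rowsum(log(pg), obs$site)[, 1]
    }
    for (h in 1:4)
      counts[occ, h] <- rowsum((bidx == h) + 0L, obs$site)[, 1]
    fwd[occ] <- rowsum(obs$strand + 0L, obs$site)[, 1]
  }
  list(L = L, counts = counts, fwd = fwd, depth = rowSums(counts))
}

# log prior matrix, 4 reference bases x 10 genotypes
log_prior_matrix <- function(params) {
  t(vapply(BASES, function(r) log(genotype_priors(r, params)), numeric(10)))
}

# MAP genotype + posterior from a loglik matrix, vectorized over sites.
# Returns best/runner-up indices and their normalized posteriors.
map_genotype <- function(L, ref_idx, log_prior) {
  lp <- L + log_prior[ref_idx, , drop = FALSE]
  m <- do.call(pmax, as.data.frame(lp))
  w <- exp(lp - m)
  s <- rowSums(w)
  best <- max.col(lp, ties.method = "first")
  p_best <- w[cbind(seq_len(nrow(lp)), best)] / s
  w2 <- w
  w2[cbind(seq_len(nrow(lp)), best)] <- -1
  runner <- max.col(w2, ties.method = "first")
  p_runner <- w[cbind(seq_len(nrow(lp)), runner)] / s
  list(best = best, posterior = p_best,
       runner_up = runner, posterior_runner_up = p_runner)
}
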