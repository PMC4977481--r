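#' Call germline genotypes over a pileup
#'
#' Runs the Bayesian genotype model over every site of a pileup: per-site
#' multinomial allele-count likelihoods over the 10 diploid genotypes,
#' multiplied by mutation-rate genotype priors, normalized, and the maximum
#' a posteriori genotype selected. Non-reference calls are graded by the
#' variant confidence score against the genotype's analytic thresholds.
#'
#' @param pileup A [pileup_data()] object (from [read_mpileup()],
#'   [simulate_germline()], ...).
#' @param params A [var_params()] object.
#' @param phi_table Optional base substitution table
#'   ([flat_substitution_table()] by default).
#' @return A tibble of class `germline_calls`, one row per site: `chrom`,
#'   `pos`, `ref`, `depth` (retained reads), `raw_depth`, `genotype` (`NA`
#'   below the depth floor), `category`, `posterior`, `vcos`, `hc`, `lc`
#'   and `label` (`high`/`low`/`false_positive`, `NA` for homozygous
#'   reference calls).
#' @export
#' @examples
#' sim <- simulate_germline(200, coverage = 20, error_rate = 0.01, seed = 1)
#' calls <- call_germline(sim$pileup)
#' glance(calls)
call_germline <- function(pileup, params = var_params(), phi_table = NULL) {
  core <- germline_core(pileup, params, phi_table)
  new_germline_calls(core$calls, params)
}

# Full vectorized germline pass; returns the call tibble plus the internal
# matrices the somatic engine reuses (log-likelihoods, base counts).
germline_core <- function(pileup, params, phi_table = NULL) {
  st <- pileup$sites
  gl <- gt_loglik_matrix(pileup, params, phi_table)
  ref_idx <- match(st$ref, BASES)
  mp <- map_genotype(gl$L, ref_idx, log_prior_matrix(params))
  called <- gl$depth >= params$min_depth
  gt <- ifelse(called, GENOTYPES[mp$best], NA_character_)
  cat_ <- genotype_category(gt, st$ref)
  vcos <- vcos_from_counts(gl$counts, mp$best, ref_idx, params)
  th <- conf_thresholds(ifelse(is.na(gt), "AA", gt),
                        ifelse(is.na(gt), "A", st$ref), params)
  nonref <- !is.na(cat_) & cat_ != "hom_ref"
  label <- rep(NA_character_, nrow(st))
  label[nonref] <- grade_vcos(vcos[nonref], th$hc[nonref], th$lc[nonref])
  calls <- tibble::tibble(
    chrom = st$chrom, pos = st$pos, ref = st$ref,
    depth = gl$depth, raw_depth = st$raw_depth,
    genotype = gt, category = cat_,
    posterior = ifelse(called, mp$posterior, NA_real_),
    vcos = ifelse(nonref, vcos, NA_real_),
    hc = ifelse(nonref, th$hc, NA_real_),
    lc = ifelse(nonref, th$lc, NA_real_),
    label = label)
  list(calls = calls, L = gl$L, counts = gl$counts, fwd = gl$fwd,
       depth = gl$depth, ref_idx = ref_idx, map = mp)
}

new_germline_calls <- function(tbl, params) {
  structure(tbl, class = c("germline_calls", class(tibble::tibble())),
            params = params)
}

#' @export
print.germline_calls <- function(x, ...) {
  cat(sprintf("<germline_calls> %d sites, %d variant calls\n",
              nrow(x), sum(!is.na(x$category) & x$category != "hom_ref")))
  NextMethod()
}

#' Tidy germline calls into a variant table
#'
#' Keeps the non-reference genotype calls (the variants), one row per site.
#'
#' @param x A `germline_calls` tibble.
#' @param ... Unused.
#' @return A tibble of variant rows.
#' @export
tidy.germline_calls <- function(x, ...) {
  tibble::as_tibble(x)[!is.na(x$category) & x$category != "hom_ref", ]
}

#' One-row summary of a germline calling run
#'
#' @param x A `germline_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble: site, call and confidence-grade counts and the
#'   mean retained depth.
#' @export
glance.germline_calls <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_called = sum(!is.na(x$genotype)),
    n_variants = sum(!is.na(x$category) & x$category != "hom_ref"),
    n_high = sum(x$label == "high", na.rm = TRUE),
    n_low = sum(x$label == "low", na.rm = TRUE),
    n_false_positive = sum(x$label == "false_positive", na.rm = TRUE),
    mean_depth = mean(x$depth))
}

#' Plot the confidence-score distribution of germline variant calls
#'
#' Histogram of the variant confidence score per confidence grade, with the
#' two analytic thresholds of each genotype case drawn as vertical lines.
#'
#' @param object A `germline_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.germline_calls <- function(object, ...) {
  v <- tidy.germline_calls(object)
  thr <- unique(tibble::tibble(value = c(v$hc, v$lc),
                               what = rep(c("HC", "LC"), each = nrow(v))))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$vcos, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$value,
                                     linetype = .data$what)) +
    ggplot2::labs(x = "variant confidence score", y = "variant calls",
                  fill = "grade", linetype = "threshold") +
    ggplot2::theme_minimal()
}
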