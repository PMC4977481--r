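#' Simulate germline pileup columns with ground truth
#'
#' Generates per-site pileup columns with the statistical structure the
#' genotype model assumes: the reference base is uniform over A/C/G/T, the
#' diploid genotype is drawn from the genotype priors of the supplied
#' parameters (so non-reference sites appear at the rate the heterozygous
#' mutation rate implies), depth is Poisson with the requested coverage,
#' each read picks a haplotype with probability `alpha`, and the read base
#' is flipped uniformly to one of the other three bases with probability
#' `error_rate`. Base qualities are the Phred encoding of the error rate
#' (capped at 60 for error-free simulations); mapping quality is constant.
#' Output is fully reproducible from `seed`.
#'
#' @param n_sites Number of sites.
#' @param coverage Mean depth (Poisson).
#' @param error_rate Uniform per-base sequencing error probability.
#' @param params A [var_params()] object (priors, `alpha`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param chrom Chromosome name of the simulated columns.
#' @param mq Constant mapping quality.
#' @return A list: `pileup` ([pileup_data()]) and `truth` (tibble with
#'   `chrom`, `pos`, `ref`, `genotype`).
#' @export
#' @examples
#' sim <- simulate_germline(100, coverage = 10, error_rate = 0, seed = 1)
#' table(sim$truth$genotype == paste0(sim$truth$ref, sim$truth$ref))
simulate_germline <- function(n_sites, coverage = 30, error_rate = 0.01,
                              params = var_params(), seed = NULL,
                              chrom = "sim1", mq = 60L) {
  if (!is.null(seed)) set.seed(seed)
  st <- draw_sites(n_sites, coverage, params, chrom)
  obs <- draw_reads(st$genotype, st$depth, error_rate, params, mq)
  list(pileup = pileup_data(
         sites = tibble::tibble(chrom = st$chrom, pos = st$pos,
                                ref = st$ref, raw_depth = st$depth),
         obs = obs),
       truth = tibble::tibble(chrom = st$chrom, pos = st$pos, ref = st$ref,
                              genotype = st$genotype))
}

draw_sites <- function(n_sites, coverage, params, chrom) {
  ref <- sample(BASES, n_sites, replace = TRUE)
  genotype <- character(n_sites)
  for (r in BASES) {
    i <- which(ref == r)
    if (length(i))
      genotype[i] <- sample(GENOTYPES, length(i), replace = TRUE,
                            prob = genotype_priors(r, params))
  }
  tibble::tibble(chrom = chrom, pos = seq_len(n_sites), ref = ref,
                 genotype = genotype, depth = stats::rpois(n_sites, coverage))
}

# expand per-site genotypes into noisy reads
draw_reads <- function(genotype, depth, error_rate, params, mq) {
  n <- sum(depth)
  site <- rep(seq_along(depth), depth)
  gt <- genotype[site]
  hap <- stats::runif(n) < params$alpha
  true_base <- ifelse(hap, substr(gt, 1, 1), substr(gt, 2, 2))
  base <- flip_bases(true_base, error_rate)
  bq <- phred_of(error_rate)
  tibble::tibble(site = site, base = base,
                 bq = rep(bq, n), mq = rep(as.integer(mq), n),
                 strand = stats::runif(n) < 0.5,
                 ord = sequence(depth))
}

flip_bases <- function(base, error_rate) {
  if (error_rate <= 0) return(base)
  n <- length(base)
  err <- stats::runif(n) < error_rate
  if (!any(err)) return(base)
  i <- match(base[err], BASES)
  base[err] <- BASES[((i - 1L + sample.int(3L, sum(err), replace = TRUE)) %% 4L) + 1L]
  base
}

phred_of <- function(error_rate) {
  if (error_rate <= 0) 60L else as.integer(round(-10 * log10(error_rate)))
}

#' Simulate a matched tumor-normal pair with implanted somatic mutations
#'
#' The normal sample follows [simulate_germline()]. Somatic mutations are
#' implanted at `somatic_fraction` of the sites whose normal genotype is
#' homozygous reference; each is an indel with probability
#' `indel_fraction`, otherwise a heterozygous SNV for a novel allele. Indel
#' lengths are `1 + Geometric(1 - indel_ext)` (each extra base appended
#' with the extension probability), the inserted/deleted sequence drawn
#' uniformly. At every site each tumor read is drawn from the tumor
#' genotype with probability `purity` and from the normal genotype
#' otherwise; reads from the mutated haplotype of an indel site carry the
#' indel event, with per-base substitution noise at `error_rate` applied to
#' the event sequence as well.
#'
#' @inheritParams simulate_germline
#' @param purity Expected fraction of tumor-cell reads in the tumor sample.
#' @param somatic_fraction Fraction of sites receiving a somatic mutation.
#' @param indel_fraction Fraction of somatic mutations that are indels.
#' @param indel_ext Indel length extension probability.
#' @return A list: `normal` and `tumor` ([pileup_data()]) and `truth`
#'   (tibble with `chrom`, `pos`, `ref`, `normal_gt`, `tumor_gt`,
#'   `somatic`, `indel_kind` (`NA`/`ins`/`del`), `indel_seq`).
#' @export
#' @examples
#' sim <- simulate_tumor_normal(1000, somatic_fraction = 0.02, seed = 42)
#' sum(sim$truth$somatic)
simulate_tumor_normal <- function(n_sites, coverage = 30, error_rate = 0.01,
                                  purity = 0.9, somatic_fraction = 0.01,
                                  indel_fraction = 0.15, indel_ext = 0.3,
                                  params = var_params(), seed = NULL,
                                  chrom = "sim1", mq = 60L) {
  if (!is.null(seed)) set.seed(seed)
  st <- draw_sites(n_sites, coverage, params, chrom)
  normal_obs <- draw_reads(st$genotype, st$depth, error_rate, params, mq)

  hom_ref <- st$genotype == paste0(st$ref, st$ref)
  n_som <- round(n_sites * somatic_fraction)
  som_sites <- sort(sample(which(hom_ref), min(n_som, sum(hom_ref))))
  is_indel <- stats::runif(length(som_sites)) < indel_fraction

  tumor_gt <- st$genotype
  snv_sites <- som_sites[!is_indel]
  if (length(snv_sites)) {
    ref_i <- match(st$ref[snv_sites], BASES)
    alt <- BASES[((ref_i - 1L +
                   sample.int(3L, length(snv_sites), replace = TRUE)) %% 4L) + 1L]
    tumor_gt[snv_sites] <- canonical_gt(st$ref[snv_sites], alt)
  }
  ind_sites <- som_sites[is_indel]
  ind_kind <- sample(c("ins", "del"), length(ind_sites), replace = TRUE)
  ind_len <- 1L + stats::rgeom(length(ind_sites), prob = 1 - indel_ext)
  ind_seq <- vapply(ind_len, function(l)
    paste(sample(BASES, l, replace = TRUE), collapse = ""), "")

  depth_t <- stats::rpois(n_sites, coverage)
  n <- sum(depth_t)
  site <- rep(seq_len(n_sites), depth_t)
  from_tumor <- stats::runif(n) < purity
  gt_used <- ifelse(from_tumor, tumor_gt[site], st$genotype[site])
  hap <- stats::runif(n) < params$alpha
  true_base <- ifelse(hap, substr(gt_used, 1, 1), substr(gt_used, 2, 2))
  base <- flip_bases(true_base, error_rate)
  strand <- stats::runif(n) < 0.5
  ord <- sequence(depth_t)
  tumor_obs <- tibble::tibble(site = site, base = base,
                              bq = rep(phred_of(error_rate), n),
                              mq = rep(as.integer(mq), n),
                              strand = strand, ord = ord)

  # indel events ride on tumor-derived reads of the mutated haplotype
  indels <- NULL
  if (length(ind_sites)) {
    imap <- match(site, ind_sites)
    carrier <- !is.na(imap) & from_tumor & hap
    if (any(carrier)) {
      w <- which(carrier)
      seqs <- vapply(ind_seq[imap[w]], noisy_seq, "",
                     error_rate = error_rate, USE.NAMES = FALSE)
      indels <- tibble::tibble(site = site[w], kind = ind_kind[imap[w]],
                               seq = seqs, strand = strand[w],
                               after = ord[w])
    }
  }

  truth <- tibble::tibble(
    chrom = st$chrom, pos = st$pos, ref = st$ref,
    normal_gt = st$genotype, tumor_gt = tumor_gt,
    somatic = seq_len(n_sites) %in% som_sites,
    indel_kind = NA_character_, indel_seq = NA_character_)
  truth$indel_kind[ind_sites] <- ind_kind
  truth$indel_seq[ind_sites] <- ind_seq

  list(normal = pileup_data(
         sites = tibble::tibble(chrom = st$chrom, pos = st$pos,
                                ref = st$ref, raw_depth = st$depth),
         obs = normal_obs),
       tumor = pileup_data(
         sites = tibble::tibble(chrom = st$chrom, pos = st$pos,
                                ref = st$ref, raw_depth = depth_t),
         obs = tumor_obs, indels = indels),
       truth = truth)
}

canonical_gt <- function(a, b) {
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

noisy_seq <- function(s, error_rate) {
  if (error_rate <= 0) return(s)
  paste(flip_bases(strsplit(s, "")[[1]], error_rate), collapse = "")
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth tibble from [simulate_germline()] or
#'   [simulate_tumor_normal()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, file) {
  readr::write_tsv(truth, file)
  invisible(file)
}
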