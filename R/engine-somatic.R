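#' Joint prior over tumor and normal genotypes
#'
#' The joint prior factors as `P(G^N, G^T) = P(G^T | G^N) P(G^N)`, with the
#' normal marginal from [genotype_priors()] and a dependency matrix
#' parametrized by the somatic rate `s`: the tumor genotype keeps the
#' normal genotype with weight `1 - s`, differs by one allele with weight
#' `s * w`, and by two alleles with weight `s^2 * w`, where `w` is the
#' product over changed alleles of the transition weight
#' \eqn{\delta/(1+\delta)} or transversion weight \eqn{0.5/(1+\delta)}
#' (two-allele changes use the allele pairing with the larger weight).
#' Rows are normalized. As `s -> 0` the matrix tends to the identity and
#' the joint caller degenerates to "tumor genotype = normal genotype".
#'
#' @param ref Reference base.
#' @param params A [var_params()] object (`somatic_rate`, `delta`, priors).
#' @return A list: `dependency` (10 x 10 row-stochastic matrix, rows =
#'   normal genotype), `marginal` (normal genotype priors) and `log_joint`
#'   (the 10 x 10 log joint prior).
#' @export
#' @examples
#' jp <- joint_prior("A", var_params())
#' rowSums(jp$dependency)
joint_prior <- function(ref, params = var_params()) {
  s <- params$somatic_rate
  d <- params$delta
  w_ti <- d / (1 + d)
  w_tv <- 0.5 / (1 + d)
  wgt <- function(x, y) if (is_transition(x, y)) w_ti else w_tv
  dep <- matrix(0, 10, 10, dimnames = list(GENOTYPES, GENOTYPES))
  for (k in 1:10) {
    a <- GT_ALLELES[k, ]
    for (t in 1:10) {
      b <- GT_ALLELES[t, ]
      # two possible allele pairings of unordered genotypes
      score <- function(bp) {
        ch <- a != bp
        w <- 1
        for (z in which(ch)) w <- w * wgt(a[z], bp[z])
        if (sum(ch) == 0) (1 - s) else s^sum(ch) * w
      }
      dep[k, t] <- max(score(b), score(rev(b)))
    }
  }
  dep <- dep / rowSums(dep)
  marg <- genotype_priors(ref, params)
  list(dependency = dep, marginal = marg, log_joint = log(dep * marg))
}

#' Joint posterior over tumor-normal genotype pairs at one site
#'
#' The posterior over the 100 genotype pairs is proportional to
#' `P(X | G^N) P(Y | G^T) P(G^N, G^T)`, where both likelihoods are the
#' multinomial allele-count model ([site_log_likelihood()]) and the joint
#' prior comes from [joint_prior()] (the normal sample is assumed free of
#' tumor reads, and the tumor likelihood is conditioned on the tumor
#' genotype only). Exact ties break by the canonical genotype order,
#' normal genotype varying fastest.
#'
#' @param normal_obs,tumor_obs Observation tibbles (`base`, `bq`, `mq`) of
#'   the two columns; both must be non-empty.
#' @param ref Reference base.
#' @param params A [var_params()] object.
#' @param phi_table Optional substitution table.
#' @return A list of class `joint_posterior`: `posterior` (10 x 10 matrix,
#'   rows = normal genotype, summing to 1), `best_normal`, `best_tumor`.
#' @export
joint_posterior <- function(normal_obs, tumor_obs, ref,
                            params = var_params(), phi_table = NULL) {
  stopifnot(nrow(normal_obs) > 0, nrow(tumor_obs) > 0)
  ln <- vapply(GENOTYPES, function(g)
    site_log_likelihood(normal_obs, g, params, phi_table), numeric(1))
  lt <- vapply(GENOTYPES, function(g)
    site_log_likelihood(tumor_obs, g, params, phi_table), numeric(1))
  lp <- outer(ln, lt, `+`) + joint_prior(ref, params)$log_joint
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  ij <- arrayInd(which.max(post), dim(post))
  structure(list(posterior = post,
                 best_normal = GENOTYPES[ij[1]],
                 best_tumor = GENOTYPES[ij[2]]),
            class = "joint_posterior")
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat(sprintf("<joint_posterior> best (%s, %s), posterior %.4g\n",
              x$best_normal, x$best_tumor, max(x$posterior)))
  invisible(x)
}

#' Classify a tumor-normal genotype pair into a somatic type
#'
#' Maps the pair through the symbolic reference/variant classification
#' (rows = normal, columns = tumor; `A` the reference base, `B` any
#' non-reference allele): homozygous reference against a tumor variant is
#' `Somatic`; a heterozygous normal collapsing (or going homozygous
#' variant) in the tumor is `LOH`; matching variant forms are `Germline`;
#' homozygous-variant normals with a tumor that regains the reference are
#' `Unknown`; no variant anywhere is `Wild`. Heterozygous-variant
#' genotypes (two non-reference alleles) map through the homozygous
#' variant column; a heterozygous-variant normal maps through the
#' heterozygous row when it shares an allele with the tumor genotype and
#' through the homozygous-variant row otherwise. `NA` genotypes give
#' `Unknown`. The mapping is total over all 100 pairs.
#'
#' @param g_normal,g_tumor Character vectors of genotypes (recycled).
#' @param ref Reference base(s).
#' @return Character vector over
#'   `c("Wild", "Somatic", "LOH", "Germline", "Unknown")`.
#' @export
#' @examples
#' classify_somatic(c("AA", "AC", "GG"), c("AG", "AA", "GG"), "A")
classify_somatic <- function(g_normal, g_tumor, ref) {
  n <- max(length(g_normal), length(g_tumor), length(ref))
  g_normal <- rep_len(g_normal, n)
  g_tumor <- rep_len(g_tumor, n)
  ref <- rep_len(ref, n)
  cat_n <- genotype_category(g_normal, ref)
  cat_t <- genotype_category(g_tumor, ref)
  col <- match(cat_t, c("hom_ref", "het_ref", "hom_var"))
  col[cat_t == "het_var"] <- 3L
  row <- match(cat_n, c("hom_ref", "het_ref", "hom_var"))
  hv <- !is.na(cat_n) & cat_n == "het_var"
  if (any(hv)) {
    shares <- substr(g_normal, 1, 1) == substr(g_tumor, 1, 1) |
      substr(g_normal, 1, 1) == substr(g_tumor, 2, 2) |
      substr(g_normal, 2, 2) == substr(g_tumor, 1, 1) |
      substr(g_normal, 2, 2) == substr(g_tumor, 2, 2)
    row[hv] <- ifelse(shares[hv], 2L, 3L)
  }
  tab <- matrix(c("Wild",    "Somatic", "Somatic",
                  "LOH",     "Germline", "LOH",
                  "Unknown", "Unknown", "Germline"),
                3, 3, byrow = TRUE)
  out <- rep("Unknown", n)
  ok <- !is.na(row) & !is.na(col)
  out[ok] <- tab[cbind(row[ok], col[ok])]
  out
}

#' Call somatic variants from a matched tumor-normal pair
#'
#' The hybrid somatic caller:
#'
#' 1. Subtraction analysis — both samples are genotyped independently;
#'    sites where the normal is homozygous reference and the tumor carries
#'    a high-confidence variant are reported Somatic immediately.
#' 2. Joint analysis — remaining sites get the maximum a posteriori
#'    genotype pair under the joint posterior (see [joint_posterior()]).
#' 3. Post-processing — per sample: a joint genotype that contradicts the
#'    subtraction call is kept only with a high-confidence score, else
#'    demoted to homozygous reference; a joint genotype confirming the
#'    subtraction call passes under the relaxed read-count constraint
#'    (variant reads at or above `max(min_var_reads, ceiling(f * depth))`,
#'    `f = 0.25 * purity * relax_factor`) or is marked false positive.
#'    Sites where both genotypes end up false positive are discarded; the
#'    rest are typed via [classify_somatic()].
#' 4. Somatic indels — a site that is an indel candidate
#'    ([indel_candidate_test()]) in exactly one sample yields an indel
#'    record: Somatic with the tumor consensus when tumor-only, LOH-typed
#'    when normal-only.
#'
#' Sites present (or non-empty) in only one sample fall back to that
#' sample's germline call annotated `Unknown`.
#'
#' @param normal,tumor [pileup_data()] objects of the matched pair.
#' @param params A [var_params()] object. When `params$purity` is `NA` the
#'   fallback estimator ([estimate_purity()]) supplies it.
#' @param phi_table Optional substitution table.
#' @return A tibble of class `somatic_calls`, one row per reported
#'   variant: `chrom`, `pos`, `ref`, `normal_gt`, `tumor_gt`, `type`
#'   (`Somatic`/`LOH`/`Germline`/`Unknown`), `provenance` (`subtraction`,
#'   `joint` or `indel`), `kind` (`snv`/`ins`/`del`), `consensus` (indel
#'   sequence), per-sample depth, confidence score and grade, and
#'   `tumor_vaf`. The resolved purity is attached as attribute `purity`.
#' @export
#' @examples
#' sim <- simulate_tumor_normal(2000, coverage = 30, error_rate = 0.01,
#'                              purity = 0.9, somatic_fraction = 0.01,
#'                              indel_fraction = 0, seed = 11)
#' calls <- call_somatic(sim$normal, sim$tumor,
#'                       var_params(purity = 0.9))
#' glance(calls)
call_somatic <- function(normal, tumor, params = var_params(),
                         phi_table = NULL) {
  pair <- pair_sites(normal, tumor)
  ncore <- germline_core(pair$normal, params, phi_table)
  tcore <- germline_core(pair$tumor, params, phi_table)
  nref <- pair$normal$sites$ref
  ref_idx <- match(nref, BASES)

  purity <- params$purity
  if (is.na(purity))
    purity <- purity_from_cores(ncore, tcore, params)

  both <- ncore$depth >= params$min_depth & tcore$depth >= params$min_depth
  only_n <- ncore$depth >= params$min_depth & !both
  only_t <- tcore$depth >= params$min_depth & !both

  sub_somatic <- both &
    ncore$calls$category %in% "hom_ref" &
    !tcore$calls$category %in% c("hom_ref", NA) &
    tcore$calls$label %in% "high"

  joint_idx <- which(both & !sub_somatic)
  jb <- joint_argmax(ncore$L[joint_idx, , drop = FALSE],
                     tcore$L[joint_idx, , drop = FALSE],
                     ref_idx[joint_idx], params)

  snv <- postprocess_joint(joint_idx, jb, ncore, tcore, ref_idx,
                           purity, params)
  sub_rows <- somatic_rows(which(sub_somatic), ncore$map$best[sub_somatic],
                           tcore$map$best[sub_somatic], ncore, tcore,
                           nref, "subtraction", params)
  half <- half_coverage_rows(which(only_n), which(only_t), ncore, tcore,
                             nref, params)
  indels <- somatic_indel_calls(pair$normal, pair$tumor, ncore, tcore, params)

  out <- dplyr::bind_rows(sub_rows, snv, half, indels)
  if (nrow(out) == 0) out <- empty_somatic_calls()
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  structure(out, class = c("somatic_calls", class(tibble::tibble())),
            params = params, purity = purity)
}

empty_somatic_calls <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 normal_gt = character(), tumor_gt = character(),
                 type = character(), provenance = character(),
                 kind = character(), consensus = character(),
                 normal_depth = integer(), tumor_depth = integer(),
                 normal_vcos = double(), tumor_vcos = double(),
                 normal_label = character(), tumor_label = character(),
                 tumor_vaf = double())
}

# align two pileups on (chrom, pos); sites exclusive to one sample become
# zero-depth columns in the other so downstream logic sees one site list
pair_sites <- function(normal, tumor) {
  key_n <- paste(normal$sites$chrom, normal$sites$pos)
  key_t <- paste(tumor$sites$chrom, tumor$sites$pos)
  if (identical(key_n, key_t))
    return(list(normal = normal, tumor = tumor))
  keys <- union(key_n, key_t)
  reorder <- function(p, key, keys) {
    ix <- match(keys, key)
    present <- !is.na(ix)
    ref <- ifelse(present, p$sites$ref[ix], NA_character_)
    # a site absent from this sample inherits the partner's reference base
    sites <- tibble::tibble(
      chrom = sub(" .*", "", keys),
      pos = as.integer(sub(".* ", "", keys)),
      ref = ref,
      raw_depth = ifelse(present, p$sites$raw_depth[ix], 0L))
    remap <- match(seq_len(nrow(p$sites)), ix)
    obs <- p$obs
    obs$site <- remap[obs$site]
    ind <- p$indels
    if (nrow(ind)) ind$site <- remap[ind$site]
    list(sites = sites, obs = obs, indels = ind)
  }
  n2 <- reorder(normal, key_n, keys)
  t2 <- reorder(tumor, key_t, keys)
  n2$sites$ref <- ifelse(is.na(n2$sites$ref), t2$sites$ref, n2$sites$ref)
  t2$sites$ref <- n2$sites$ref
  ord <- order(n2$sites$chrom, n2$sites$pos)
  rerank <- match(seq_along(keys), ord)
  relabel <- function(x) {
    x$sites <- x$sites[ord, ]
    x$obs$site <- rerank[x$obs$site]
    if (nrow(x$indels)) x$indels$site <- rerank[x$indels$site]
    pileup_data(x$sites, x$obs, x$indels)
  }
  list(normal = relabel(n2), tumor = relabel(t2))
}

# vectorized argmax over the 100 joint-genotype cells
joint_argmax <- function(ln, lt, ref_idx, params) {
  n <- nrow(ln)
  best_val <- rep(-Inf, n)
  best_n <- best_t <- rep(1L, n)
  lj <- lapply(BASES, function(r) joint_prior(r, params)$log_joint)
  for (t in 1:10) for (k in 1:10) {
    prior_kt <- vapply(lj, function(m) m[k, t], numeric(1))[ref_idx]
    v <- ln[, k] + lt[, t] + prior_kt
    hit <- v > best_val
    best_val[hit] <- v[hit]
    best_n[hit] <- k
    best_t[hit] <- t
  }
  list(normal = best_n, tumor = best_t)
}

# post-processing of the joint calls (steps i-iv); returns the SNV rows
postprocess_joint <- function(idx, jb, ncore, tcore, ref_idx, purity,
                              params) {
  if (length(idx) == 0) return(NULL)
  f <- 0.25 * purity * params$relax_factor
  resolve <- function(core, joint_best) {
    sub_best <- core$map$best[idx]
    ref_i <- ref_idx[idx]
    depth <- core$depth[idx]
    cat_j <- genotype_category(GENOTYPES[joint_best], BASES[ref_i])
    vr <- variant_reads(core$counts[idx, , drop = FALSE], joint_best, ref_i)
    vc <- vcos_from_counts(core$counts[idx, , drop = FALSE], joint_best,
                           ref_i, params)
    th <- conf_thresholds(GENOTYPES[joint_best], BASES[ref_i], params)
    grade <- grade_vcos(vc, th$hc, th$lc)
    homref_gt <- match(paste0(BASES[ref_i], BASES[ref_i]), GENOTYPES)
    final <- joint_best
    fp <- rep(FALSE, length(idx))
    confirmed <- joint_best == sub_best
    nonref <- cat_j != "hom_ref"
    # step i: contradicting joint genotype survives only with high confidence
    demote <- !confirmed & nonref & grade != "high"
    final[demote] <- homref_gt[demote]
    # step ii: confirming genotype passes the relaxed read-count constraint
    thr <- pmax(params$min_var_reads, ceiling(f * depth))
    relax_fail <- confirmed & nonref & vr < thr
    fp[relax_fail] <- TRUE
    label <- ifelse(!nonref, NA_character_,
             ifelse(demote | relax_fail, "false_positive",
             ifelse(confirmed & grade == "false_positive", "low", grade)))
    list(final = final, fp = fp, homref = homref_gt, vcos = vc,
         label = label, depth = depth, vr = vr)
  }
  rn <- resolve(ncore, jb$normal)
  rt <- resolve(tcore, jb$tumor)
  # step iii: drop sites where both genotypes are false positives
  drop <- rn$fp & rt$fp
  gn <- ifelse(rn$fp, rn$homref, rn$final)
  gt <- ifelse(rt$fp, rt$homref, rt$final)
  type <- classify_somatic(GENOTYPES[gn], GENOTYPES[gt],
                           BASES[ref_idx[idx]])
  keep <- !drop & type != "Wild"
  if (!any(keep)) return(NULL)
  k <- which(keep)
  st <- ncore$calls[idx[k], c("chrom", "pos", "ref")]
  tibble::tibble(
    chrom = st$chrom, pos = st$pos, ref = st$ref,
    normal_gt = GENOTYPES[gn[k]], tumor_gt = GENOTYPES[gt[k]],
    type = type[k], provenance = "joint", kind = "snv",
    consensus = NA_character_,
    normal_depth = rn$depth[k], tumor_depth = rt$depth[k],
    normal_vcos = rn$vcos[k], tumor_vcos = rt$vcos[k],
    normal_label = rn$label[k], tumor_label = rt$label[k],
    tumor_vaf = rt$vr[k] / pmax(rt$depth[k], 1L))
}

# reads supporting the non-reference alleles of each site's genotype
variant_reads <- function(counts, gt_idx, ref_idx) {
  n <- length(gt_idx)
  a1 <- GT_A1[gt_idx]; a2 <- GT_A2[gt_idx]
  v1 <- ifelse(a1 != ref_idx, counts[cbind(seq_len(n), a1)], 0L)
  v2 <- ifelse(a2 != ref_idx & a2 != a1, counts[cbind(seq_len(n), a2)], 0L)
  as.integer(v1 + v2)
}

somatic_rows <- function(idx, gn_idx, gt_idx, ncore, tcore, nref,
                         provenance, params) {
  if (length(idx) == 0) return(NULL)
  st <- ncore$calls[idx, c("chrom", "pos", "ref")]
  ref_i <- match(nref[idx], BASES)
  vr_t <- variant_reads(tcore$counts[idx, , drop = FALSE], gt_idx, ref_i)
  tibble::tibble(
    chrom = st$chrom, pos = st$pos, ref = st$ref,
    normal_gt = GENOTYPES[gn_idx], tumor_gt = GENOTYPES[gt_idx],
    type = classify_somatic(GENOTYPES[gn_idx], GENOTYPES[gt_idx], nref[idx]),
    provenance = provenance, kind = "snv", consensus = NA_character_,
    normal_depth = ncore$depth[idx], tumor_depth = tcore$depth[idx],
    normal_vcos = ncore$calls$vcos[idx], tumor_vcos = tcore$calls$vcos[idx],
    normal_label = ncore$calls$label[idx],
    tumor_label = tcore$calls$label[idx],
    tumor_vaf = vr_t / pmax(tcore$depth[idx], 1L))
}

# sites covered in only one sample: the covered sample's germline variant
# calls are reported with type Unknown
half_coverage_rows <- function(idx_n, idx_t, ncore, tcore, nref, params) {
  one_side <- function(idx, core, other) {
    if (length(idx) == 0) return(NULL)
    calls <- core$calls[idx, ]
    keep <- !is.na(calls$category) & calls$category != "hom_ref" &
      calls$label %in% c("high", "low")
    if (!any(keep)) return(NULL)
    calls <- calls[keep, ]
    tibble::tibble(
      chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
      normal_gt = if (other == "tumor") calls$genotype else NA_character_,
      tumor_gt = if (other == "normal") calls$genotype else NA_character_,
      type = "Unknown", provenance = "joint", kind = "snv",
      consensus = NA_character_,
      normal_depth = if (other == "tumor") calls$depth else 0L,
      tumor_depth = if (other == "normal") calls$depth else 0L,
      normal_vcos = if (other == "tumor") calls$vcos else NA_real_,
      tumor_vcos = if (other == "normal") calls$vcos else NA_real_,
      normal_label = if (other == "tumor") calls$label else NA_character_,
      tumor_label = if (other == "normal") calls$label else NA_character_,
      tumor_vaf = NA_real_)
  }
  dplyr::bind_rows(one_side(idx_n, ncore, "tumor"),
                   one_side(idx_t, tcore, "normal"))
}

#' Somatic indel calls from a matched pair
#'
#' A site is reported when exactly one of the two samples passes the indel
#' candidate screen: tumor-only candidates are Somatic (consensus from the
#' tumor's indel sequences via [mua_search()]); normal-only candidates are
#' reported as LOH-typed indels (the tumor lost the event the normal
#' carries).
#'
#' @inheritParams call_somatic
#' @return A tibble of indel rows in the [call_somatic()] layout.
#' @export
somatic_indel <- function(normal, tumor, params = var_params()) {
  pair <- pair_sites(normal, tumor)
  ncore <- germline_core(pair$normal, params)
  tcore <- germline_core(pair$tumor, params)
  somatic_indel_calls(pair$normal, pair$tumor, ncore, tcore, params)
}

somatic_indel_calls <- function(normal, tumor, ncore, tcore, params) {
  sn <- indel_site_stats(normal)
  st <- indel_site_stats(tumor)
  sites <- sort(union(sn$site, st$site))
  if (length(sites) == 0) return(NULL)
  rows <- lapply(sites, function(i) {
    stat_of <- function(tbl, core) {
      j <- match(i, tbl$site)
      if (!is.na(j)) tbl[j, ]
      else {
        cnt <- core$counts[i, ]
        ref_i <- core$ref_idx[i]
        tibble::tibble(site = i, n_ref = cnt[ref_i],
                       n_var = sum(cnt) - cnt[ref_i],
                       depth = sum(cnt))
      }
    }
    a <- stat_of(sn, ncore)
    b <- stat_of(st, tcore)
    cand_n <- nrow(normal$indels[normal$indels$site == i, ]) > 0 &&
      indel_candidate_test(a$n_ref, a$n_var,
                           sum(normal$indels$site == i), params)$candidate
    cand_t <- nrow(tumor$indels[tumor$indels$site == i, ]) > 0 &&
      indel_candidate_test(b$n_ref, b$n_var,
                           sum(tumor$indels$site == i), params)$candidate
    if (cand_n == cand_t) return(NULL)   # both or neither: no call
    src <- if (cand_t) tumor else normal
    stat <- if (cand_t) b else a
    res <- call_indel(src$indels[src$indels$site == i, ],
                      stat$n_ref, stat$n_var, stat$depth, params)
    if (is.null(res)) return(NULL)
    site_row <- src$sites[i, ]
    tibble::tibble(
      chrom = site_row$chrom, pos = site_row$pos, ref = site_row$ref,
      normal_gt = NA_character_, tumor_gt = NA_character_,
      type = if (cand_t) "Somatic" else "LOH",
      provenance = "indel", kind = res$kind, consensus = res$consensus,
      normal_depth = a$depth, tumor_depth = b$depth,
      normal_vcos = NA_real_, tumor_vcos = NA_real_,
      normal_label = NA_character_, tumor_label = NA_character_,
      tumor_vaf = res$n_support / pmax(b$depth, 1L))
  })
  dplyr::bind_rows(rows)
}

#' Tumor purity: accept or estimate
#'
#' If `params$purity` is set it is returned unchanged. Otherwise a fallback
#' estimate is computed — the paired samples are genotyped, and over the
#' confident subtraction-Somatic sites (normal homozygous reference, tumor
#' a variant graded at least low-confidence) the purity is the median of
#' twice the tumor
#' variant-allele fraction, clamped to `(0, 1]`. With no such site the
#' estimate degenerates to 1 with a warning. This estimator is a simple
#' stand-in for a dedicated purity-estimation procedure and is only as
#' good as the somatic sites it can find.
#'
#' @inheritParams call_somatic
#' @return A single purity value in `(0, 1]`.
#' @export
estimate_purity <- function(normal, tumor, params = var_params()) {
  if (!is.na(params$purity)) return(params$purity)
  pair <- pair_sites(normal, tumor)
  ncore <- germline_core(pair$normal, params)
  tcore <- germline_core(pair$tumor, params)
  purity_from_cores(ncore, tcore, params)
}

purity_from_cores <- function(ncore, tcore, params) {
  sub_somatic <- ncore$calls$category %in% "hom_ref" &
    !tcore$calls$category %in% c("hom_ref", NA) &
    tcore$calls$label %in% c("high", "low") &
    tcore$depth > 0
  if (!any(sub_somatic)) {
    warning("no confident somatic site found; tumor purity defaults to 1.0",
            call. = FALSE)
    return(1.0)
  }
  idx <- which(sub_somatic)
  vr <- variant_reads(tcore$counts[idx, , drop = FALSE],
                      tcore$map$best[idx], ncore$ref_idx[idx])
  vaf <- vr / pmax(tcore$depth[idx], 1L)
  min(1, max(1e-3, stats::median(2 * vaf)))
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat(sprintf("<somatic_calls> %d records (purity %.3g)\n",
              nrow(x), attr(x, "purity")))
  NextMethod()
}

#' Tidy somatic calls
#' @param x A `somatic_calls` tibble.
#' @param ... Unused.
#' @return The calls as a plain tibble.
#' @export
tidy.somatic_calls <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a somatic calling run
#' @param x A `somatic_calls` tibble.
#' @param ... Unused.
#' @return Counts per somatic type plus the resolved purity.
#' @export
glance.somatic_calls <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x),
    n_somatic = sum(x$type == "Somatic" & x$kind == "snv"),
    n_somatic_indel = sum(x$type == "Somatic" & x$kind != "snv"),
    n_loh = sum(x$type == "LOH"),
    n_germline = sum(x$type == "Germline"),
    n_unknown = sum(x$type == "Unknown"),
    purity = attr(x, "purity"))
}

#' Plot somatic calls by type and tumor variant-allele fraction
#'
#' @param object A `somatic_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somatic_calls <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$tumor_vaf,
                                  colour = .data$kind)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "somatic type", y = "tumor variant-allele fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
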