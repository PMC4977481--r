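#' Identify an indel candidate site by two Fisher's exact tests
#'
#' A site carrying at least one indel event is screened in two stages, each
#' a one-sided Fisher's exact test of observed counts against the counts
#' expected under a background rate:
#'
#' 1. Substitution screen: observed `[n_var, n_ref]` against
#'    `[round(N mu), N - round(N mu)]` under the point-mutation rate `mu`
#'    (`N = n_var + n_ref`). A significant substitution excess
#'    (`p < a1`) disqualifies the site — the signal is explained by a
#'    substitution variant or alignment noise, not an indel.
#' 2. Indel test: observed `[n_indel, n_ref]` against the analogous
#'    expectation under the indel rate `mu_indel`. Significance (`p < a2`)
#'    makes the site a candidate.
#'
#' @param n_ref,n_var,n_indel Reference-matching reads, substitution reads
#'   and indel events at the site.
#' @param params A [var_params()] object (supplies `mu`, `mu_indel`, `a1`,
#'   `a2`).
#' @return A list: `candidate` (logical), `p1`, `p2` (`NA` when a stage was
#'   not reached).
#' @export
#' @examples
#' indel_candidate_test(n_ref = 18, n_var = 0, n_indel = 12)
indel_candidate_test <- function(n_ref, n_var, n_indel,
                                 params = var_params()) {
  if (n_ref + n_var + n_indel == 0)
    return(list(candidate = FALSE, p1 = NA_real_, p2 = NA_real_))
  p1 <- rate_excess_test(n_var, n_ref, params$mu)
  if (!is.na(p1) && p1 < params$a1)
    return(list(candidate = FALSE, p1 = p1, p2 = NA_real_))
  p2 <- rate_excess_test(n_indel, n_ref, params$mu_indel)
  list(candidate = !is.na(p2) && p2 < params$a2, p1 = p1, p2 = p2)
}

# one-sided Fisher's exact test of [x, y] against the expectation under
# `rate` on the same total
rate_excess_test <- function(x, y, rate) {
  n <- x + y
  if (n == 0) return(NA_real_)
  e <- round(n * rate)
  m <- matrix(c(x, e, y, n - e), 2, 2)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Score a gapless overlay of two equal-length strings
#'
#' +1 per matching position, -1 per mismatch; the minimal scoring scheme
#' for a fixed-window (ungapped) comparison.
#'
#' @param a,b Strings of equal length.
#' @return An integer score.
#' @export
#' @examples
#' ungapped_align_score("ACGT", "ACCT")  # 2
ungapped_align_score <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  sum(ifelse(x == y, 1L, -1L))
}

#' Multiple ungapped alignment of an indel sequence set
#'
#' Finds the most significant gapless consensus of a set of indel
#' sequences, in the spirit of motif-discovery starting-point search. For
#' every window length `l` from the shortest to the longest sequence
#' length, every `l`-length substring of every sequence is taken as a seed;
#' the seed is overlaid gaplessly (no overhangs) onto each sequence and the
#' best-scoring substring per sequence (leftmost on ties) joins the
#' alignment. Sequences shorter than `l` contribute no member. Each
#' alignment yields a position-specific weight matrix of log2
#' frequency/background odds, a consensus (columnwise argmax, ties broken
#' by alphabet order) and a likelihood score ([pswm_likelihood()]); the
#' alignment with the largest likelihood wins, ties going to the larger
#' `l`, then to the earlier seed (sequence index, then offset).
#'
#' @param s Character vector of sequences over A/C/G/T (at least one).
#' @param q Background character frequencies (default uniform 1/4).
#' @param mua_mode Likelihood form, see [pswm_likelihood()].
#' @return A list of class `mua`: `consensus`, `length`, `likelihood`,
#'   `pswm` (the 4 x l weight matrix), `p` (raw column frequencies, columns
#'   summing to 1), `members` (the aligned substrings), `seed`
#'   (`c(seq, offset, length)` of the winning seed) and `n` (`|S|`).
#' @export
#' @examples
#' mua_search(c("ACGT", "ACCT", "AGGT"))$consensus
mua_search <- function(s, q = rep(0.25, 4), mua_mode = c("literal", "mean")) {
  mua_mode <- match.arg(mua_mode)
  stopifnot(length(s) >= 1, all(nchar(s) >= 1))
  s <- toupper(s)
  chars <- strsplit(s, "")
  stopifnot(all(unlist(chars) %in% BASES))
  lens <- nchar(s)
  best <- NULL
  for (l in seq(min(lens), max(lens))) {
    for (i in seq_along(s)) {
      if (lens[i] < l) next
      for (j in seq_len(lens[i] - l + 1)) {
        seed <- chars[[i]][j:(j + l - 1)]
        members <- vector("list", length(s))
        for (u in seq_along(s)) {
          if (lens[u] < l) next
          offs <- seq_len(lens[u] - l + 1)
          sc <- vapply(offs, function(v) {
            w <- chars[[u]][v:(v + l - 1)]
            sum(ifelse(w == seed, 1L, -1L))
          }, integer(1))
          v <- offs[which.max(sc)]  # leftmost on ties
          members[[u]] <- chars[[u]][v:(v + l - 1)]
        }
        members <- members[!vapply(members, is.null, logical(1))]
        res <- pswm_build(members, n_total = length(s), q = q)
        lik <- pswm_likelihood(res$pswm, res$consensus, mua_mode)
        if (is.null(best) || lik > best$likelihood ||
            (lik == best$likelihood && l > best$length)) {
          best <- list(consensus = paste(res$consensus, collapse = ""),
                       length = l, likelihood = lik, pswm = res$pswm,
                       p = res$p,
                       members = vapply(members, paste, "", collapse = ""),
                       seed = c(seq = i, offset = j, length = l),
                       n = length(s))
        }
      }
    }
  }
  structure(best, class = "mua")
}

#' @export
print.mua <- function(x, ...) {
  cat(sprintf("<mua> consensus %s (l = %d, likelihood %.4g, %d/%d members)\n",
              x$consensus, x$length, x$likelihood, length(x$members), x$n))
  invisible(x)
}

# Position-specific weight matrix from aligned equal-length substrings.
# p: raw per-column character frequencies (columns sum to 1 over members);
# W: log2(p / q) with zero cells floored at the pseudo-frequency
# eps = 1/(2 n_total) inside the log only, so unanimous columns keep
# W = log2(1/q) exactly while W stays finite.
pswm_build <- function(members, n_total, q = rep(0.25, 4)) {
  l <- length(members[[1]])
  m <- length(members)
  mat <- matrix(unlist(members), nrow = m, byrow = TRUE)
  cnt <- vapply(seq_len(l), function(j)
    tabulate(match(mat[, j], BASES), nbins = 4), integer(4))
  p <- cnt / m
  eps <- 1 / (2 * n_total)
  w <- log2(pmax(p, eps) / q)
  dimnames(w) <- list(BASES, NULL)
  dimnames(p) <- list(BASES, NULL)
  cons <- BASES[apply(w, 2, which.max)]
  list(pswm = w, p = p, consensus = cons)
}

#' Likelihood score of a consensus under its weight matrix
#'
#' The literal form takes log2 of the summed consensus log-odds,
#' \eqn{L = \frac{1}{l}\log_2 \sum_j W_{S'[j], j}}, guarded to `-Inf` when
#' the inner sum is not positive (weight-matrix entries are log-odds and
#' can be negative), so such alignments rank last. The alternative
#' `"mean"` mode scores the mean consensus log-odds
#' \eqn{\frac{1}{l}\sum_j W_{S'[j], j}}.
#'
#' @param pswm A 4 x l weight matrix with rownames A/C/G/T.
#' @param consensus Consensus as a string or character vector of length l.
#' @param mua_mode `"literal"` (default) or `"mean"`.
#' @return A single score (possibly `-Inf` in literal mode).
#' @export
#' @examples
#' m <- mua_search(c("ACG", "ACG", "ACG"))
#' pswm_likelihood(m$pswm, m$consensus)  # log2(6)/3
pswm_likelihood <- function(pswm, consensus,
                            mua_mode = c("literal", "mean")) {
  mua_mode <- match.arg(mua_mode)
  cons <- if (length(consensus) == 1 && nchar(consensus) > 1)
    strsplit(consensus, "")[[1]] else consensus
  l <- ncol(pswm)
  stopifnot(length(cons) == l)
  s <- sum(pswm[cbind(match(cons, rownames(pswm)), seq_len(l))])
  if (mua_mode == "mean") return(s / l)
  if (s <= 0) -Inf else log2(s) / l
}

#' Call the consensus indel of a single column
#'
#' Runs the candidate screen ([indel_candidate_test()]) on the column; for
#' candidates, pools the indel sequences by kind (insertions and deletions
#' separately), lets the kind with more supporting events win (ties toward
#' insertion), and derives the consensus sequence by [mua_search()].
#' Zygosity: the call is homozygous when the indel-supporting read fraction
#' reaches `params$hom_frac`, heterozygous otherwise.
#'
#' @param site_indels Tibble of the column's indel events (`kind`, `seq`).
#' @param n_ref,n_var Reference-matching and substitution read counts.
#' @param depth Retained read count at the column.
#' @param params A [var_params()] object.
#' @return A one-row tibble (`kind`, `consensus`, `genotype`, `n_support`,
#'   `p1`, `p2`, `likelihood`) or `NULL` when the site is not a candidate.
#' @export
call_indel <- function(site_indels, n_ref, n_var, depth,
                       params = var_params()) {
  if (nrow(site_indels) == 0) return(NULL)
  tst <- indel_candidate_test(n_ref, n_var, nrow(site_indels), params)
  if (!tst$candidate) return(NULL)
  n_ins <- sum(site_indels$kind == "ins")
  n_del <- sum(site_indels$kind == "del")
  kind <- if (n_ins >= n_del) "ins" else "del"
  seqs <- site_indels$seq[site_indels$kind == kind]
  m <- mua_search(seqs, mua_mode = params$mua_mode)
  frac <- length(seqs) / max(depth, 1L)
  tibble::tibble(kind = kind, consensus = m$consensus,
                 genotype = if (frac >= params$hom_frac) "1/1" else "0/1",
                 n_support = length(seqs), p1 = tst$p1, p2 = tst$p2,
                 likelihood = m$likelihood)
}

#' Call indels over a pileup
#'
#' Applies [call_indel()] to every column carrying at least one indel
#' event.
#'
#' @param pileup A [pileup_data()] object.
#' @param params A [var_params()] object.
#' @return A tibble, one row per called indel: `chrom`, `pos`, `ref`,
#'   `kind`, `consensus`, `genotype`, `n_support`, `depth`, `p1`, `p2`.
#' @export
#' @examples
#' sim <- simulate_tumor_normal(300, somatic_fraction = 0.05,
#'                              indel_fraction = 1, seed = 7)
#' call_indels(sim$tumor, var_params())
call_indels <- function(pileup, params = var_params()) {
  stats_tbl <- indel_site_stats(pileup)
  rows <- purrr::pmap(stats_tbl, function(site, n_ref, n_var, depth, ...) {
    res <- call_indel(pileup$indels[pileup$indels$site == site, ],
                      n_ref, n_var, depth, params)
    if (is.null(res)) return(NULL)
    st <- pileup$sites[site, ]
    dplyr::bind_cols(tibble::tibble(chrom = st$chrom, pos = st$pos,
                                    ref = st$ref, depth = depth), res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), depth = integer(),
                          kind = character(), consensus = character(),
                          genotype = character(), n_support = integer(),
                          p1 = double(), p2 = double(), likelihood = double())
  out
}

# per-site counts feeding the candidate screen, for sites with >= 1 indel
indel_site_stats <- function(pileup) {
  if (nrow(pileup$indels) == 0)
    return(tibble::tibble(site = integer(), n_ref = integer(),
                          n_var = integer(), depth = integer()))
  sites <- sort(unique(pileup$indels$site))
  obs <- pileup$obs[pileup$obs$site %in% sites, ]
  ref <- pileup$sites$ref[obs$site]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(site = obs$site,
                                   is_ref = obs$base == ref), .data$site),
    n_ref = sum(.data$is_ref), n_var = sum(!.data$is_ref),
    .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(site = sites), agg, by = "site")
  out$n_ref[is.na(out$n_ref)] <- 0L
  out$n_var[is.na(out$n_var)] <- 0L
  out$depth <- out$n_ref + out$n_var
  out
}
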