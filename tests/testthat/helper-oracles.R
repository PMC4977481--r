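# Independent reference computations the engine is checked against.
# Everything here is written in the most direct form possible and shares no
# code path with the package internals.

ALL_BASES <- c("A", "C", "G", "T")
ALL_GT <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")

# plain Bayes evaluation of the genotype posterior for one column,
# linear-space, direct from the model definition
naive_posterior <- function(bases, bqs, mqs, ref, theta = 1e-3,
                            alpha = 0.5, prior_mode = "theta") {
  w <- function(b, m) {
    eb <- 10^(-b / 10); em <- 10^(-m / 10)
    1 - 2 * eb * em / (eb + em)
  }
  p_hap <- function(x, g, om) if (x == g) om else (1 - om) / 3
  prior <- naive_priors(ref, theta, prior_mode)
  lik <- vapply(ALL_GT, function(g) {
    g1 <- substr(g, 1, 1); g2 <- substr(g, 2, 2)
    out <- 1
    for (j in seq_along(bases)) {
      om <- w(bqs[j], mqs[j])
      out <- out * (alpha * p_hap(bases[j], g1, om) +
                    (1 - alpha) * p_hap(bases[j], g2, om))
    }
    out
  }, numeric(1))
  post <- lik * prior
  post / sum(post)
}

naive_priors <- function(ref, theta = 1e-3, prior_mode = "theta") {
  if (prior_mode == "flat") return(stats::setNames(rep(0.1, 10), ALL_GT))
  pri <- vapply(ALL_GT, function(g) {
    a <- substr(g, 1, 1); b <- substr(g, 2, 2)
    if (a == ref && b == ref) NA_real_
    else if (a == b) theta / 2
    else if (a == ref || b == ref) theta
    else theta^2
  }, numeric(1))
  pri[is.na(pri)] <- 1 - sum(pri, na.rm = TRUE)
  pri
}

# naive 100-cell joint posterior; dependency prior recomputed from its
# definition (diagonal 1-s; off-diagonal s^changes times Ti/Tv weights,
# best allele pairing; rows normalized)
naive_joint_posterior <- function(nb, nq, nm, tb, tq, tm, ref,
                                  theta = 1e-3, delta = 2, s = 1e-4) {
  w <- function(b, m) {
    eb <- 10^(-b / 10); em <- 10^(-m / 10)
    1 - 2 * eb * em / (eb + em)
  }
  col_lik <- function(bases, bqs, mqs, g) {
    g1 <- substr(g, 1, 1); g2 <- substr(g, 2, 2)
    out <- 1
    for (j in seq_along(bases)) {
      om <- w(bqs[j], mqs[j])
      ph <- function(x, gg) if (x == gg) om else (1 - om) / 3
      out <- out * (0.5 * ph(bases[j], g1) + 0.5 * ph(bases[j], g2))
    }
    out
  }
  ti <- function(x, y) (x == "A" && y == "G") || (x == "G" && y == "A") ||
    (x == "C" && y == "T") || (x == "T" && y == "C")
  wgt <- function(x, y) if (ti(x, y)) delta / (1 + delta) else 0.5 / (1 + delta)
  dep_cell <- function(gn, gt) {
    a <- strsplit(gn, "")[[1]]
    sc <- function(b) {
      ch <- which(a != b)
      v <- if (length(ch) == 0) (1 - s) else s^length(ch)
      for (z in ch) v <- v * wgt(a[z], b[z])
      v
    }
    b <- strsplit(gt, "")[[1]]
    max(sc(b), sc(rev(b)))
  }
  dep <- outer(ALL_GT, ALL_GT, Vectorize(dep_cell))
  dep <- dep / rowSums(dep)
  prior_n <- naive_priors(ref, theta)
  post <- matrix(0, 10, 10, dimnames = list(ALL_GT, ALL_GT))
  for (k in 1:10) for (t in 1:10)
    post[k, t] <- col_lik(nb, nq, nm, ALL_GT[k]) *
      col_lik(tb, tq, tm, ALL_GT[t]) * dep[k, t] * prior_n[k]
  post / sum(post)
}

# exact one-sided (excess) hypergeometric p-value for the 2x2 table
# rbind(c(a, b), c(c, d)): P(X >= a) with X the (1,1) cell under fixed margins
hyper_p_greater <- function(a, b, c, d) {
  hi <- min(a + b, a + c)
  sum(stats::dhyper(a:hi, a + c, b + d, a + b))
}

# exhaustive multiple-ungapped-alignment search, string-based, written
# independently of the package implementation
brute_mua <- function(s, q = 0.25, mode = c("literal", "mean")) {
  mode <- match.arg(mode)
  lens <- nchar(s)
  best <- NULL
  for (l in min(lens):max(lens)) {
    for (i in seq_along(s)) {
      if (lens[i] < l) next
      for (j in 1:(lens[i] - l + 1)) {
        seed <- substr(s[i], j, j + l - 1)
        members <- character(0)
        for (u in seq_along(s)) {
          if (lens[u] < l) next
          cand <- vapply(1:(lens[u] - l + 1),
                         function(v) substr(s[u], v, v + l - 1), "")
          sc <- vapply(cand, function(x) {
            xs <- strsplit(x, "")[[1]]; ss <- strsplit(seed, "")[[1]]
            sum(ifelse(xs == ss, 1, -1))
          }, numeric(1))
          members <- c(members, cand[which.max(sc)])
        }
        mm <- do.call(rbind, strsplit(members, ""))
        eps <- 1 / (2 * length(s))
        lik_cols <- vapply(1:l, function(col) {
          fr <- table(factor(mm[, col], levels = ALL_BASES)) / nrow(mm)
          wcol <- log2(pmax(as.numeric(fr), eps) / q)
          max(wcol)
        }, numeric(1))
        cons <- vapply(1:l, function(col) {
          fr <- table(factor(mm[, col], levels = ALL_BASES)) / nrow(mm)
          wcol <- log2(pmax(as.numeric(fr), eps) / q)
          ALL_BASES[which.max(wcol)]
        }, "")
        ssum <- sum(lik_cols)
        lik <- if (mode == "mean") ssum / l
        else if (ssum <= 0) -Inf else log2(ssum) / l
        if (is.null(best) || lik > best$lik ||
            (lik == best$lik && l > best$l)) {
          best <- list(lik = lik, l = l,
                       consensus = paste(cons, collapse = ""))
        }
      }
    }
  }
  best
}

# enumerate all multisets of size n over the elements of x (list of index
# vectors), via the standard combination-with-repetition bijection
multisets <- function(n, k) {
  if (n == 0) return(list(integer(0)))
  cmb <- utils::combn(k + n - 1, n)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j] - 0:(n - 1))
}

obs_tibble <- function(bases, bq, mq) {
  tibble::tibble(base = bases,
                 bq = rep_len(bq, length(bases)),
                 mq = rep_len(mq, length(bases)))
}

random_pileup <- function(n_sites, max_depth = 8, with_indels = TRUE,
                          chrom = "chrT") {
  ref <- sample(ALL_BASES, n_sites, replace = TRUE)
  depth <- sample.int(max_depth, n_sites, replace = TRUE)
  site <- rep(seq_len(n_sites), depth)
  n <- length(site)
  obs <- tibble::tibble(
    site = site,
    base = sample(ALL_BASES, n, replace = TRUE),
    bq = sample(c(13L, 20L, 30L, 40L), n, replace = TRUE),
    mq = sample(c(20L, 40L, 60L), n, replace = TRUE),
    strand = sample(c(TRUE, FALSE), n, replace = TRUE),
    ord = sequence(depth))
  ind <- NULL
  if (with_indels) {
    has <- which(stats::runif(n_sites) < 0.1)
    if (length(has)) {
      ind <- dplyr::bind_rows(lapply(has, function(i) {
        k <- sample.int(min(2L, depth[i]), 1)
        tibble::tibble(
          site = i,
          kind = sample(c("ins", "del"), k, replace = TRUE),
          seq = vapply(seq_len(k), function(z)
            paste(sample(ALL_BASES, sample.int(4L, 1), replace = TRUE),
                  collapse = ""), ""),
          strand = sample(c(TRUE, FALSE), k, replace = TRUE),
          after = sample.int(depth[i], k))
      }))
    }
  }
  pileup_data(
    sites = tibble::tibble(chrom = chrom, pos = seq_len(n_sites), ref = ref,
                           raw_depth = depth),
    obs = obs, indels = ind)
}
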