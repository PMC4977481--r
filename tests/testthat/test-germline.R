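test_that("allele weight matches the harmonic-mean error form", {
  expect_equal(allele_weight(30, 30), 0.999)
  expect_equal(allele_weight(20, 20), 0.99)
  # unequal qualities: 1 - 2(0.1 * 0.001)/(0.1 + 0.001)
  expect_equal(allele_weight(10, 30), 1 - 2 * (0.1 * 0.001) / (0.1 + 0.001),
               tolerance = 1e-12)
  expect_equal(allele_weight(10, 30), 0.998020, tolerance = 1e-6)
  # clamped negatives, range
  expect_equal(allele_weight(-5, -5), 0)
  q <- expand.grid(b = seq(0, 60, 7), m = seq(0, 60, 11))
  w <- allele_weight(q$b, q$m)
  expect_true(all(w >= 0 & w < 1))
})

test_that("haploid and genotype allele probabilities follow the mixture", {
  om <- allele_weight(30, 30)
  expect_equal(allele_prob_haploid("A", "A", om), 0.999)
  expect_equal(allele_prob_haploid("A", "C", om), 0.001 * (1 / 3))
  expect_equal(allele_prob_haploid("A", "C", 1), 0)

  expect_equal(allele_prob_genotype("A", "AA", om), 0.999)
  expect_equal(allele_prob_genotype("A", "AC", om),
               0.5 * 0.999 + 0.5 * 0.001 / 3)
  expect_equal(allele_prob_genotype("A", "AC", om), 0.499667,
               tolerance = 1e-6)
  # max-form symmetry in allele order at alpha != 0.5
  p <- var_params(alpha = 0.3, use_window_alpha = TRUE)
  expect_equal(allele_prob_genotype("A", "AC", om, p),
               allele_prob_genotype("A", "CA", om, p))
})

test_that("sliding-window strand proportion averages forward fractions", {
  expect_equal(strand_alpha(rep(1, 50), 25, 10), 1)
  expect_equal(strand_alpha(rep(0.5, 50), 25, 10), 0.5)
  expect_equal(strand_alpha(rep(0.7, 999), 500, 1000), 0.7)
})

test_that("column log-likelihood is the log product over reads", {
  om <- allele_weight(30, 30)
  col1 <- obs_tibble("A", 30, 30)
  expect_equal(site_log_likelihood(col1, "AA"), log(0.999))
  col2 <- obs_tibble(c("A", "A"), 30, 30)
  expect_equal(site_log_likelihood(col2, "AC"),
               2 * log(0.5 * 0.999 + 0.5 * 0.001 / 3))
  # brute-force product over reads for random columns
  set.seed(42)
  for (z in 1:20) {
    n <- sample(1:8, 1)
    col <- obs_tibble(sample(ALL_BASES, n, TRUE),
                      sample(c(10, 20, 30), n, TRUE),
                      sample(c(20, 40, 60), n, TRUE))
    g <- sample(ALL_GT, 1)
    direct <- prod(vapply(seq_len(n), function(j) {
      omj <- allele_weight(col$bq[j], col$mq[j])
      ph <- function(hap) if (col$base[j] == hap) omj else (1 - omj) / 3
      0.5 * ph(substr(g, 1, 1)) + 0.5 * ph(substr(g, 2, 2))
    }, numeric(1)))
    expect_equal(exp(site_log_likelihood(col, g)), direct, tolerance = 1e-12)
  }
  expect_true(is.na(site_log_likelihood(col1[0, ], "AA")))
})

test_that("genotype priors reproduce the mutation-rate family", {
  pri <- genotype_priors("A", var_params(theta = 1e-3))
  expect_equal(unname(pri[c("AC", "AG", "AT")]), rep(1e-3, 3))
  expect_equal(unname(pri[c("CC", "GG", "TT")]), rep(5e-4, 3))
  expect_equal(unname(pri[c("CG", "CT", "GT")]), rep(1e-6, 3))
  expect_equal(unname(pri["AA"]), 1 - 4.503e-3)
  expect_equal(sum(pri), 1)
  flat <- genotype_priors("C", var_params(prior_mode = "flat"))
  expect_true(all(flat == 0.1))
  for (r in ALL_BASES) {
    for (mode in c("theta", "flat", "titv")) {
      pri <- genotype_priors(r, var_params(prior_mode = mode))
      expect_equal(sum(pri), 1, tolerance = 1e-12)
    }
  }
  # Ti/Tv reweighting favors the transition heterozygote, keeps total mass
  p_titv <- genotype_priors("A", var_params(prior_mode = "titv"))
  p_theta <- genotype_priors("A", var_params())
  expect_gt(p_titv["AG"], p_titv["AC"])
  expect_equal(sum(p_titv[-1]), sum(p_theta[-1]), tolerance = 1e-15)
})

test_that("MAP genotype inference recovers clear columns", {
  expect_equal(infer_genotype(obs_tibble(rep("A", 10), 30, 30), "A")$best, "AA")
  expect_equal(infer_genotype(obs_tibble(rep(c("A", "C"), 15), 30, 30),
                              "A")$best, "AC")
  expect_equal(infer_genotype(obs_tibble(rep("C", 10), 30, 30), "A")$best, "CC")
  expect_gt(max(infer_genotype(obs_tibble(rep("A", 10), 30, 30),
                               "A")$posteriors), 0.999)
  expect_null(infer_genotype(obs_tibble(character(), 30, 30), "A"))
})

test_that("engine posteriors match the naive Bayes oracle", {
  set.seed(7)
  for (z in 1:50) {
    n <- sample(1:6, 1)
    bs <- sample(ALL_BASES, n, TRUE)
    bq <- sample(c(10, 20, 30), n, TRUE)
    mq <- sample(c(10, 20, 30), n, TRUE)
    ref <- sample(ALL_BASES, 1)
    got <- infer_genotype(obs_tibble(bs, bq, mq), ref)$posteriors
    want <- naive_posterior(bs, bq, mq, ref)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("posteriors normalize and added support is monotone", {
  set.seed(8)
  for (z in 1:20) {
    n <- sample(1:10, 1)
    col <- obs_tibble(sample(ALL_BASES, n, TRUE),
                      sample(c(13, 30, 40), n, TRUE), 60)
    gp <- infer_genotype(col, sample(ALL_BASES, 1))
    expect_equal(sum(gp$posteriors), 1, tolerance = 1e-9)
  }
  # appending a high-quality read of base b never decreases the posterior
  # of the homozygote bb under flat priors: the new read multiplies the bb
  # likelihood by the largest per-genotype factor, so renormalization can
  # only raise it (heterozygotes containing b enjoy no such guarantee:
  # their gain can be outweighed by the homozygote's larger gain)
  p_flat <- var_params(prior_mode = "flat")
  for (z in 1:10) {
    n <- sample(1:6, 1)
    col <- obs_tibble(sample(ALL_BASES, n, TRUE),
                      sample(c(20, 30), n, TRUE), 60)
    b <- sample(ALL_BASES, 1)
    before <- infer_genotype(col, "A", p_flat)$posteriors
    col2 <- dplyr::bind_rows(col, obs_tibble(b, 40, 60))
    after <- infer_genotype(col2, "A", p_flat)$posteriors
    bb <- paste0(b, b)
    expect_gte(after[bb], before[bb] - 1e-12)
  }
})

test_that("likelihoods are symmetric in allele order at alpha 0.5", {
  om <- allele_weight(25, 50)
  for (b in ALL_BASES)
    expect_equal(allele_prob_genotype(b, "AG", om),
                 allele_prob_genotype(b, "GA", om))
})

test_that("batch caller agrees with per-column inference", {
  set.seed(9)
  pu <- random_pileup(200, max_depth = 10, with_indels = FALSE)
  calls <- call_germline(pu, var_params(min_bq = 0L))
  for (i in sample(200, 25)) {
    col <- pu$obs[pu$obs$site == i, ]
    gp <- infer_genotype(col, pu$sites$ref[i])
    if (is.null(gp)) expect_true(is.na(calls$genotype[i]))
    else {
      expect_equal(calls$genotype[i], gp$best)
      expect_equal(calls$posterior[i], max(gp$posteriors), tolerance = 1e-9)
    }
  }
})

test_that("simulated columns at depth are called concordantly", {
  sim <- simulate_germline(4000, coverage = 30, error_rate = 0.01, seed = 30)
  calls <- call_germline(sim$pileup)
  ok <- !is.na(calls$genotype)
  conc <- mean(calls$genotype[ok] == sim$truth$genotype[ok])
  expect_gt(conc, 0.99)
})
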