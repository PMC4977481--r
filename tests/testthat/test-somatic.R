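test_that("joint prior rows normalize and favor transitions", {
  p <- var_params(somatic_rate = 1e-4)
  jp <- joint_prior("A", p)
  expect_equal(unname(rowSums(jp$dependency)), rep(1, 10), tolerance = 1e-12)
  # transition change outweighs transversion change off the diagonal
  expect_gt(jp$dependency["AA", "AG"], jp$dependency["AA", "AC"])
  # vanishing somatic rate degenerates to the identity
  jp0 <- joint_prior("A", var_params(somatic_rate = 1e-12))
  expect_equal(unname(diag(jp0$dependency)), rep(1, 10), tolerance = 1e-6)
  for (d in c(1, 2.5)) {
    jpd <- joint_prior("C", var_params(somatic_rate = 0.01, delta = d))
    expect_equal(unname(rowSums(jpd$dependency)), rep(1, 10),
                 tolerance = 1e-12)
  }
})

test_that("joint posterior matches the naive 100-cell oracle", {
  set.seed(31)
  for (z in 1:25) {
    nn <- sample(1:4, 1); nt <- sample(1:4, 1)
    nb <- sample(ALL_BASES, nn, TRUE); tb <- sample(ALL_BASES, nt, TRUE)
    nq <- sample(c(10, 20, 30), nn, TRUE); tq <- sample(c(10, 20, 30), nt, TRUE)
    nm <- sample(c(10, 20, 30), nn, TRUE); tm <- sample(c(10, 20, 30), nt, TRUE)
    ref <- sample(ALL_BASES, 1)
    got <- joint_posterior(obs_tibble(nb, nq, nm), obs_tibble(tb, tq, tm), ref)
    want <- naive_joint_posterior(nb, nq, nm, tb, tq, tm, ref)
    expect_equal(unname(got$posterior), unname(want), tolerance = 1e-9)
    expect_equal(sum(got$posterior), 1, tolerance = 1e-9)
  }
})

test_that("clear tumor-normal columns give the expected joint call", {
  clean <- function(b) obs_tibble(b, 30, 60)
  jp <- joint_posterior(clean(rep("A", 30)),
                        clean(rep(c("A", "G"), 15)), "A")
  expect_equal(jp$best_normal, "AA")
  expect_equal(jp$best_tumor, "AG")
  jp2 <- joint_posterior(clean(rep("A", 30)), clean(rep("A", 30)), "A")
  expect_equal(jp2$best_normal, "AA")
  expect_equal(jp2$best_tumor, "AA")
})

test_that("independent-prior joint posterior factorizes", {
  # replacing the dependency rows by the marginal makes the joint posterior
  # the outer product of the single-sample posteriors
  nb <- c("A", "A", "G"); tb <- c("G", "G", "A")
  ref <- "A"
  lik <- function(bases) vapply(ALL_GT, function(g)
    exp(site_log_likelihood(obs_tibble(bases, 30, 60), g)), numeric(1))
  pri <- naive_priors(ref)
  pn <- lik(nb) * pri; pn <- pn / sum(pn)
  pt <- lik(tb) * pri; pt <- pt / sum(pt)
  want <- outer(pn, pt)
  # joint evaluation with independent prior P(GN)P(GT)
  post <- outer(lik(nb) * pri, lik(tb) * pri)
  post <- post / sum(post)
  expect_equal(post, want, tolerance = 1e-12)
})

test_that("somatic-type classification matches the symbolic table", {
  expect_equal(classify_somatic("AA", "AG", "A"), "Somatic")
  expect_equal(classify_somatic("AA", "GG", "A"), "Somatic")
  expect_equal(classify_somatic("AA", "AA", "A"), "Wild")
  expect_equal(classify_somatic("AC", "AA", "A"), "LOH")
  expect_equal(classify_somatic("AC", "AC", "A"), "Germline")
  expect_equal(classify_somatic("AC", "CC", "A"), "LOH")
  expect_equal(classify_somatic("GG", "AA", "A"), "Unknown")
  expect_equal(classify_somatic("GG", "AG", "A"), "Unknown")
  expect_equal(classify_somatic("GG", "GG", "A"), "Germline")
  # total over all 100 pairs for every reference base
  types <- c("Wild", "Somatic", "LOH", "Germline", "Unknown")
  for (r in ALL_BASES) {
    grid <- expand.grid(gn = ALL_GT, gt = ALL_GT,
                        stringsAsFactors = FALSE)
    out <- classify_somatic(grid$gn, grid$gt, r)
    expect_equal(length(out), 100)
    expect_true(all(out %in% types))
  }
})

test_that("subtraction stage reports clear somatic sites immediately", {
  mk <- function(normal_bases, tumor_bases, ref = "A", n = 300) {
    sites <- tibble::tibble(chrom = "s", pos = 1L, ref = ref,
                            raw_depth = length(normal_bases))
    pn <- pileup_data(sites, tibble::tibble(
      site = 1L, base = normal_bases, bq = 30L, mq = 60L,
      strand = TRUE, ord = seq_along(normal_bases)))
    sites$raw_depth <- length(tumor_bases)
    pt <- pileup_data(sites, tibble::tibble(
      site = 1L, base = tumor_bases, bq = 30L, mq = 60L,
      strand = TRUE, ord = seq_along(tumor_bases)))
    call_somatic(pn, pt, var_params(purity = 0.9))
  }
  # clean somatic site: tumor het at full confidence -> subtraction call
  calls <- mk(rep("A", 30), rep(c("A", "G"), 15))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "Somatic")
  expect_equal(calls$provenance, "subtraction")
  expect_equal(calls$tumor_gt, "AG")
  # het normal defers to the joint analysis and types Germline
  calls2 <- mk(rep(c("A", "C"), 15), rep(c("A", "C"), 15))
  expect_equal(calls2$type, "Germline")
  expect_equal(calls2$provenance, "joint")
  # low-confidence tumor variant defers to the joint path
  calls3 <- mk(rep("A", 30), c(rep("A", 22), rep("G", 8)))
  expect_true(nrow(calls3) == 0 || all(calls3$provenance == "joint"))
})

test_that("post-processing enforces the relaxed read-count constraint", {
  p <- var_params(purity = 0.9)
  # threshold at depth 30, purity 0.9: max(2, ceiling(0.225 * 30)) = 7 reads
  mkcol <- function(nvar, depth = 30) {
    tibble::tibble(site = 1L, base = c(rep("G", nvar), rep("A", depth - nvar)),
                   bq = 20L, mq = 60L, strand = TRUE, ord = seq_len(depth))
  }
  sites <- tibble::tibble(chrom = "s", pos = 1L, ref = "A", raw_depth = 30L)
  pn <- pileup_data(sites, mkcol(0))
  # 13 variant reads: confirmed by joint, passes the relaxed constraint
  calls <- call_somatic(pn, pileup_data(sites, mkcol(13)), p)
  expect_equal(calls$type, "Somatic")
  # 4 variant reads at depth 30 fall below the threshold: discarded or
  # demoted, never reported Somatic
  calls2 <- call_somatic(pn, pileup_data(sites, mkcol(4)), p)
  expect_true(nrow(calls2[calls2$type == "Somatic", ]) == 0)
})

test_that("self-vs-self input yields no somatic SNV", {
  sim <- simulate_germline(3000, coverage = 30, error_rate = 0, seed = 33)
  calls <- call_somatic(sim$pileup, sim$pileup, var_params(purity = 1))
  expect_equal(sum(calls$type == "Somatic"), 0)
  # germline heterozygotes are typed Germline, not lost
  n_het <- sum(genotype_category(sim$truth$genotype, sim$truth$ref) != "hom_ref")
  expect_equal(sum(calls$type == "Germline"), n_het)
})

test_that("somatic indels require exactly one candidate sample", {
  sites <- tibble::tibble(chrom = "s", pos = 1L, ref = "A", raw_depth = 30L)
  mkp <- function(n_indel) {
    obs <- tibble::tibble(site = 1L, base = "A", bq = 30L, mq = 60L,
                          strand = TRUE, ord = 1:30)
    ind <- if (n_indel > 0)
      tibble::tibble(site = 1L, kind = "ins", seq = "TG", strand = TRUE,
                     after = seq_len(n_indel))
    pileup_data(sites, obs, ind)
  }
  p <- var_params(purity = 0.9)
  # tumor-only candidate: Somatic insertion with the tumor consensus
  r <- somatic_indel(mkp(0), mkp(12), p)
  expect_equal(r$type, "Somatic")
  expect_equal(r$kind, "ins")
  expect_equal(r$consensus, "TG")
  # both candidates: no call
  expect_equal(nrow(somatic_indel(mkp(12), mkp(12), p)), 0)
  # normal-only candidate: LOH-typed record
  r2 <- somatic_indel(mkp(12), mkp(0), p)
  expect_equal(r2$type, "LOH")
})

test_that("purity passthrough and fallback estimation behave", {
  p <- var_params(purity = 0.9)
  sim <- simulate_tumor_normal(300, coverage = 30, error_rate = 0,
                               purity = 0.8, somatic_fraction = 0.05,
                               indel_fraction = 0, seed = 34)
  expect_equal(estimate_purity(sim$normal, sim$tumor, p), 0.9)
  est <- estimate_purity(sim$normal, sim$tumor, var_params())
  expect_lt(abs(est - 0.8), 0.1)
  # degenerate input: no somatic site -> purity 1 with a warning
  g <- simulate_germline(200, coverage = 30, error_rate = 0, seed = 35)
  expect_warning(est2 <- estimate_purity(g$pileup, g$pileup, var_params()),
                 "defaults to 1")
  expect_equal(est2, 1.0)
})

test_that("half-covered sites fall back to one-sample calls typed Unknown", {
  sim <- simulate_germline(50, coverage = 30, error_rate = 0, seed = 36)
  # truncate the tumor to the first 25 sites
  keep <- sim$pileup$obs$site <= 25
  pt <- pileup_data(sim$pileup$sites[1:25, ],
                    sim$pileup$obs[keep, ])
  calls <- call_somatic(sim$pileup, pt, var_params(purity = 1))
  tail_variants <- genotype_category(sim$truth$genotype[26:50],
                                     sim$truth$ref[26:50]) != "hom_ref"
  got <- calls[calls$pos > 25, ]
  expect_true(all(got$type == "Unknown"))
  expect_equal(nrow(got), sum(tail_variants))
})
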