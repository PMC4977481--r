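test_that("mpileup read-base decoding handles the dialect", {
  # plain reference matches with a mapping-quality column
  p <- read_mpileup("chr1\t100\tA\t5\t..,.,\tIIIII\t]]]]]")
  expect_equal(nrow(p$obs), 5)
  expect_true(all(p$obs$base == "A"))
  expect_equal(p$obs$bq, rep(40L, 5))
  expect_equal(p$obs$mq, rep(60L, 5))
  expect_equal(p$obs$strand, c(TRUE, TRUE, FALSE, TRUE, FALSE))

  # insertion attached to the first read
  p <- read_mpileup("chr1\t101\tA\t3\t.+2TG.,\tIII")
  expect_equal(nrow(p$obs), 3)
  expect_true(all(p$obs$base == "A"))
  expect_equal(p$indels$kind, "ins")
  expect_equal(p$indels$seq, "TG")
  expect_equal(p$indels$after, 1L)

  # read-start marker carries the mapping quality when no column exists
  p <- read_mpileup("chr1\t102\tC\t1\t^].\tI")
  expect_equal(nrow(p$obs), 1)
  expect_equal(p$obs$mq, 60L)

  # substitutions, case = strand; deletion placeholder dropped from obs
  p <- read_mpileup("chr1\t103\tG\t4\t.Ta*\tIIII", min_base_quality = 0)
  expect_equal(p$obs$base, c("G", "T", "A"))
  expect_equal(p$obs$strand, c(TRUE, TRUE, FALSE))
  expect_equal(p$sites$raw_depth, 4L)

  # deletion tag (lower case = reverse strand), N dropped
  p <- read_mpileup("chr1\t104\tT\t2\t,-2acN\tII", min_base_quality = 0)
  expect_equal(p$indels$kind, "del")
  expect_equal(p$indels$seq, "AC")
  expect_false(p$indels$strand)
})

test_that("quality floors drop observations but keep raw depth", {
  p <- read_mpileup("chr1\t1\tA\t4\t....\tI!I!", min_base_quality = 13)
  expect_equal(nrow(p$obs), 2)
  expect_equal(p$sites$raw_depth, 4L)
  expect_true(all(nrow(p$obs) <= p$sites$raw_depth))
})

test_that("malformed lines raise a parse error naming the line", {
  expect_error(read_mpileup(c("chr1\t1\tA\t1\t.\tI", "chr1\tX\tA\t1\t.\tI")),
               "line 2", class = "varcall_parse_error")
  expect_error(read_mpileup("chr1\t1\tA\t2\t..\tIII"),
               "line 1", class = "varcall_parse_error")
  expect_error(read_mpileup("chr1\t1\tA\t1\t."),
               "column", class = "varcall_parse_error")
})

test_that("10-column pileup dialect parses with consensus columns ignored", {
  line <- "chr1\t50\tA\tM\t30\t30\t60\t3\t..C\tIII"
  p <- read_pileup(line)
  expect_equal(p$sites$pos, 50L)
  expect_equal(p$obs$base, c("A", "A", "C"))
})

test_that("ambiguous-reference sites are skipped", {
  p <- read_mpileup(c("chr1\t1\tN\t1\t.\tI", "chr1\t2\tA\t1\t.\tI"))
  expect_equal(nrow(p$sites), 1)
  expect_equal(p$sites$pos, 2L)
})

test_that("render/parse round trip preserves columns exactly", {
  set.seed(71)
  pu <- random_pileup(1000, max_depth = 8, with_indels = TRUE)
  lines <- render_mpileup(pu)
  back <- read_mpileup(lines, min_base_quality = 0, min_mapping_quality = 0)
  expect_equal(back$sites$pos, pu$sites$pos)
  expect_equal(back$sites$ref, pu$sites$ref)
  expect_equal(back$obs$base, pu$obs$base)
  expect_equal(back$obs$bq, pu$obs$bq)
  expect_equal(back$obs$mq, pu$obs$mq)
  expect_equal(back$obs$strand, pu$obs$strand)
  expect_equal(back$obs$site, pu$obs$site)
  ord_key <- function(x) x$indels[order(x$indels$site, x$indels$after,
                                        x$indels$seq), ]
  expect_equal(ord_key(back)[, c("site", "kind", "seq", "strand")],
               ord_key(pu)[, c("site", "kind", "seq", "strand")])
})

test_that("VCF output is standards-conforming and anchors indels", {
  rec <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100L, 100L, 7L),
    ref = c("A", "ATG", "C"), alt = c("C", "A", "CTT"),
    filter = "PASS", ss = c(NA, NA, "Somatic"),
    gt = c("0/1", "0/1", "1/1"), dp = c(30L, 28L, 31L),
    vcos = c(3.7, NA, 7.3))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rec, "s1", f)
  expect_no_warning(v <- VariantAnnotation::readVcf(f, genome = "sim"))
  expect_equal(nrow(v), 3)
  expect_equal(as.character(VariantAnnotation::ref(v)),
               c("A", "ATG", "C"))
  expect_equal(unname(as.character(unlist(VariantAnnotation::alt(v)))),
               c("C", "A", "CTT"))

  # empty record set still yields a parseable header-only file
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rec[0, ], "s1", f2)
  expect_no_warning(v2 <- VariantAnnotation::readVcf(f2, genome = "sim"))
  expect_equal(nrow(v2), 0)

  # unsorted input is rejected
  expect_error(write_vcf(rec[c(2, 3, 1), ], "s1", f),
               class = "varcall_data_error")
})

test_that("germline records use VCF conventions for SNVs and indels", {
  sim <- simulate_germline(500, coverage = 30, error_rate = 0, seed = 5)
  calls <- call_germline(sim$pileup)
  rec <- germline_records(calls)
  v <- tidy(calls)
  expect_equal(nrow(rec), sum(v$label %in% c("high", "low")))
  het <- rec[match(v$pos[v$category == "het_ref"], rec$pos), ]
  expect_true(all(het$gt == "0/1"))

  ind <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A",
                        kind = "del", consensus = "TG", genotype = "0/1",
                        depth = 30L, n_support = 12L, p1 = 1, p2 = 1e-5,
                        likelihood = 1)
  rec2 <- germline_records(calls[0, ], ind)
  expect_equal(rec2$ref, "ATG")
  expect_equal(rec2$alt, "A")
  expect_equal(rec2$pos, 100L)
})

test_that("BAM columns match hand-written mpileup of the same reads", {
  skip_if(Sys.which("samtools") == "", "samtools not on PATH")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">tiny", "ACGTACGTACGTACGTACGT"), fa)
  system2("samtools", c("faidx", fa))
  sam <- file.path(dir, "reads.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:tiny\tLN:20",
    paste("r1", 0, "tiny", 1, 60, "8M", "*", 0, 0,
          "ACGTACGT", "IIIIIIII", sep = "\t"),
    paste("r2", 0, "tiny", 3, 60, "8M", "*", 0, 0,
          "GTACGTAC", "IIIIIIII", sep = "\t"),
    paste("r3", 16, "tiny", 5, 60, "6M", "*", 0, 0,
          "ACGTAC", "IIIIII", sep = "\t")), sam)
  bam <- file.path(dir, "reads.bam")
  system2("samtools", c("view", "-b", "-o", bam, sam))
  system2("samtools", c("index", bam))
  p <- columns_from_bam(bam, fa, min_base_quality = 0)
  expect_equal(nrow(p$sites), 10)  # positions 1-10 covered
  # depth profile: 1 read at 1-2, 2 at 3-4, 3 at 5-8, 2 at 9-10
  expect_equal(p$sites$raw_depth,
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 2L, 2L))
  # all reads agree with the reference
  expect_true(all(p$obs$base == p$sites$ref[p$obs$site]))
  # reverse-strand read shows on positions 5-10
  expect_true(any(!p$obs$strand[p$obs$site %in% 5:10]))
  # empty region and absent contig
  expect_equal(n_sites(columns_from_bam(bam, fa, region = "tiny:15-20",
                                        min_base_quality = 0)), 0)
  expect_error(columns_from_bam(bam, fa, region = "nope:1-10"),
               class = "varcall_data_error")
})
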