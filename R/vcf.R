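#' Write variant records as VCF 4.2
#'
#' Emits a minimal, standards-conforming VCF: header lines declare every
#' INFO, FORMAT and FILTER key used, and each body line carries GT, DP and
#' VCOS per sample. Somatic records carry the somatic type in the `SS` INFO
#' tag. Indels use the left-anchored base convention: the site's reference
#' base anchors the event, so a deletion's REF includes the deleted bases
#' and an insertion's ALT includes the inserted bases.
#'
#' @param records Tibble with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic records), `filter`, optional `ss`
#'   (somatic type), and per-sample `gt` (e.g. `"0/1"`), `dp`, `vcos` —
#'   each either a vector (one sample) or a matrix with one column per
#'   sample. Must be sorted by `(chrom, pos)`.
#' @param sample_names Character vector of sample column names.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
#' @examples
#' rec <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "C",
#'                       filter = "PASS", ss = NA_character_,
#'                       gt = "0/1", dp = 30L, vcos = 3.7)
#' f <- tempfile(fileext = ".vcf")
#' write_vcf(rec, "sample1", f)
write_vcf <- function(records, sample_names, file) {
  n_s <- length(sample_names)
  as_mat <- function(x) {
    if (is.null(x)) matrix(NA, nrow(records), n_s)
    else if (is.matrix(x)) x
    else matrix(x, ncol = 1)
  }
  if (nrow(records) > 0) {
    runs <- rle(records$chrom)$values
    by_chrom <- split(records$pos, records$chrom)
    if (anyDuplicated(runs) ||
        any(vapply(by_chrom, is.unsorted, logical(1))))
      rlang::abort("records must be sorted by (chrom, pos)",
                   class = "varcall_data_error")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varcall",
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic type: Wild, Somatic, LOH, Germline or Unknown\">",
    "##FILTER=<ID=LowConf,Description=\"Low-confidence variant score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Retained read depth\">",
    "##FORMAT=<ID=VCOS,Number=1,Type=Float,Description=\"Variant confidence score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  if (nrow(records) == 0) {
    readr::write_lines(header, file)
    return(invisible(file))
  }
  stopifnot(all(records$ref != records$alt))
  gt <- as_mat(records$gt)
  dp <- as_mat(records$dp)
  vc <- as_mat(records$vcos)
  fmt_one <- function(j) {
    paste(ifelse(is.na(gt[, j]), "./.", gt[, j]),
          ifelse(is.na(dp[, j]), ".", dp[, j]),
          ifelse(is.na(vc[, j]), ".", sprintf("%.4f", vc[, j])),
          sep = ":")
  }
  samples <- do.call(paste, c(lapply(seq_len(n_s), fmt_one), sep = "\t"))
  info <- if ("ss" %in% names(records))
    ifelse(is.na(records$ss), ".", paste0("SS=", records$ss)) else "."
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", records$filter, info, "GT:DP:VCOS", samples,
                sep = "\t")
  readr::write_lines(c(header, body), file)
  invisible(file)
}

#' Germline calls as VCF-ready records
#'
#' Converts non-reference germline SNV calls plus indel calls into the
#' record layout of [write_vcf()]. High-confidence calls are `PASS`,
#' low-confidence calls `LowConf`; false positives are dropped.
#'
#' @param calls A `germline_calls` tibble from [call_germline()].
#' @param indels Optional indel tibble from [call_indels()].
#' @return A records tibble sorted by `(chrom, pos)`.
#' @export
germline_records <- function(calls, indels = NULL) {
  v <- tidy.germline_calls(calls)
  v <- v[v$label %in% c("high", "low"), ]
  rec <- NULL
  if (nrow(v) > 0) {
    a1 <- substr(v$genotype, 1, 1)
    a2 <- substr(v$genotype, 2, 2)
    alt1 <- ifelse(a1 == v$ref, NA, a1)
    alt2 <- ifelse(a2 == v$ref | a2 == a1, NA, a2)
    alt <- ifelse(is.na(alt1), alt2,
                  ifelse(is.na(alt2), alt1, paste(alt1, alt2, sep = ",")))
    gt <- ifelse(v$category == "het_ref", "0/1",
          ifelse(v$category == "hom_var", "1/1", "1/2"))
    rec <- tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref,
                          alt = alt,
                          filter = ifelse(v$label == "high", "PASS", "LowConf"),
                          ss = NA_character_, gt = gt, dp = v$depth,
                          vcos = v$vcos)
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    irec <- tibble::tibble(
      chrom = indels$chrom, pos = indels$pos,
      ref = ifelse(indels$kind == "del",
                   paste0(indels$ref, indels$consensus), indels$ref),
      alt = ifelse(indels$kind == "ins",
                   paste0(indels$ref, indels$consensus), indels$ref),
      filter = "PASS", ss = NA_character_, gt = indels$genotype,
      dp = indels$depth, vcos = NA_real_)
    rec <- dplyr::bind_rows(rec, irec)
  }
  if (is.null(rec))
    rec <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter = character(), ss = character(),
                          gt = character(), dp = integer(), vcos = double())
  dplyr::arrange(rec, match(.data$chrom, unique(.data$chrom)), .data$pos)
}

#' Somatic calls as VCF-ready records
#'
#' Two-sample (NORMAL, TUMOR) records with the somatic type in the `SS`
#' INFO tag. SNV alternates are taken from the union of non-reference
#' alleles of the two genotypes; indel records use the anchored-base
#' convention with the MUA consensus.
#'
#' @param calls A `somatic_calls` tibble from [call_somatic()].
#' @return A records tibble sorted by `(chrom, pos)`.
#' @export
somatic_records <- function(calls) {
  d <- tibble::as_tibble(calls)
  if (nrow(d) == 0)
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter = character(), ss = character(),
                          gt = matrix(character(), 0, 2),
                          dp = matrix(integer(), 0, 2),
                          vcos = matrix(double(), 0, 2)))
  is_snv <- d$kind == "snv"
  alt <- character(nrow(d))
  gt_n <- gt_t <- character(nrow(d))
  for (i in which(is_snv)) {
    alleles <- unique(c(strsplit(d$normal_gt[i], "")[[1]],
                        strsplit(d$tumor_gt[i], "")[[1]]))
    alleles <- alleles[!is.na(alleles) & alleles != d$ref[i]]
    alt[i] <- paste(alleles, collapse = ",")
    code <- function(g) {
      if (is.na(g)) return("./.")
      idx <- match(strsplit(g, "")[[1]], c(d$ref[i], alleles)) - 1L
      paste(sort(idx), collapse = "/")
    }
    gt_n[i] <- code(d$normal_gt[i])
    gt_t[i] <- code(d$tumor_gt[i])
  }
  ref_out <- ifelse(is_snv, d$ref,
                    ifelse(d$kind == "del", paste0(d$ref, d$consensus), d$ref))
  alt_out <- ifelse(is_snv, alt,
                    ifelse(d$kind == "ins", paste0(d$ref, d$consensus), d$ref))
  gt_n[!is_snv] <- "0/0"
  gt_t[!is_snv] <- "0/1"
  keep <- alt_out != "" & alt_out != ref_out
  tibble::tibble(
    chrom = d$chrom[keep], pos = d$pos[keep], ref = ref_out[keep],
    alt = alt_out[keep], filter = "PASS", ss = d$type[keep],
    gt = cbind(gt_n[keep], gt_t[keep]),
    dp = cbind(d$normal_depth[keep], d$tumor_depth[keep]),
    vcos = cbind(d$normal_vcos[keep], d$tumor_vcos[keep]))
}
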