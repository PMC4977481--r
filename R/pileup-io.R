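#' Read SAMtools mpileup text into a pileup
#'
#' Parses the 6-column SAMtools mpileup dialect (chrom, pos, ref, depth,
#' read bases, base qualities), plus the optional 7th mapping-quality column
#' produced by `samtools mpileup -s`. Read-base strings are decoded in full:
#' `.`/`,` are reference matches on the forward/reverse strand,
#' `ACGT`/`acgt` substitutions, `^X` consumes the read-start mapping
#' quality, `$` marks a read end, `+nSEQ`/`-nSEQ` attach an indel to the
#' preceding read, and `*` deletion placeholders count toward raw depth but
#' never become observations. Qualities are Phred+33. Observations below
#' either quality floor are dropped (raw depth keeps the declared value).
#' Sites whose reference base is not one of A/C/G/T are skipped.
#'
#' @param file Path to an mpileup file, or a character vector of mpileup
#'   lines.
#' @param min_base_quality,min_mapping_quality Quality floors; defaults 13
#'   and 0.
#' @param default_mq Mapping quality assumed for reads when the input has
#'   neither a mapping-quality column nor a `^X` read-start marker.
#' @return A [pileup_data()] object.
#' @export
#' @examples
#' p <- read_mpileup(c("chr1\t100\tA\t3\t..,\tIII"))
#' p$obs
read_mpileup <- function(file, min_base_quality = 13L,
                         min_mapping_quality = 0L, default_mq = 60L) {
  lines <- if (length(file) == 1 && !grepl("\t", file[1]))
    readr::read_lines(file) else file
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(empty_pileup())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols < 6 | ncols > 7)
  if (length(bad))
    stop_parse(bad[1], "expected 6 or 7 tab-separated columns, found ",
               ncols[bad[1]])
  m <- matrix("", length(parts), 7)
  for (j in 1:6) m[, j] <- vapply(parts, `[[`, "", j)
  has_mq <- ncols == 7
  if (any(has_mq) && !all(has_mq))
    stop_parse(which(!has_mq)[1], "inconsistent column count across lines")
  if (all(has_mq)) m[, 7] <- vapply(parts, `[[`, "", 7)
  build_pileup(chrom = m[, 1], pos = m[, 2], ref = m[, 3], depth = m[, 4],
               bases = m[, 5], quals = m[, 6],
               mapq = if (all(has_mq)) m[, 7] else character(),
               min_bq = min_base_quality, min_mq = min_mapping_quality,
               default_mq = default_mq)
}

#' Read MAQ-style 10-column pileup text
#'
#' The consensus-annotated pileup dialect carries, per line: chrom, pos,
#' reference base, consensus base, consensus quality, SNP quality, maximum
#' mapping quality, depth, read bases and base qualities. The consensus
#' columns are ignored; the read-base and quality strings are decoded
#' exactly as in [read_mpileup()].
#'
#' @inheritParams read_mpileup
#' @return A [pileup_data()] object.
#' @export
read_pileup <- function(file, min_base_quality = 13L,
                        min_mapping_quality = 0L, default_mq = 60L) {
  lines <- if (length(file) == 1 && !grepl("\t", file[1]))
    readr::read_lines(file) else file
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_pileup())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 10)
  if (length(bad))
    stop_parse(bad[1], "expected 10 tab-separated columns, found ",
               lengths(parts)[bad[1]])
  get <- function(j) vapply(parts, `[[`, "", j)
  build_pileup(chrom = get(1), pos = get(2), ref = get(3), depth = get(8),
               bases = get(9), quals = get(10), mapq = character(),
               min_bq = min_base_quality, min_mq = min_mapping_quality,
               default_mq = default_mq)
}

stop_parse <- function(line, ...) {
  rlang::abort(paste0("pileup parse error at line ", line, ": ", ...),
               class = "varcall_parse_error")
}

empty_pileup <- function() {
  pileup_data(
    sites = tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), raw_depth = integer()),
    obs = tibble::tibble(site = integer(), base = character(),
                         bq = integer(), mq = integer(), strand = logical(),
                         ord = integer()))
}

build_pileup <- function(chrom, pos, ref, depth, bases, quals, mapq,
                         min_bq, min_mq, default_mq) {
  pos_n <- suppressWarnings(as.integer(pos))
  if (anyNA(pos_n))
    stop_parse(which(is.na(pos_n))[1], "non-numeric position '",
               pos[which(is.na(pos_n))[1]], "'")
  depth_n <- suppressWarnings(as.integer(depth))
  if (anyNA(depth_n))
    stop_parse(which(is.na(depth_n))[1], "non-numeric depth")

  ref <- toupper(ref)
  keep <- ref %in% BASES
  idx <- which(keep)
  dec <- decode_pileup_cpp(bases[idx], quals[idx],
                           if (length(mapq)) mapq[idx] else character(),
                           ref[idx], as.integer(default_mq))
  if (dec$err_line > 0)
    stop_parse(idx[dec$err_line], dec$err_msg)

  sites <- tibble::tibble(chrom = chrom[idx], pos = pos_n[idx],
                          ref = ref[idx], raw_depth = depth_n[idx])
  obs <- tibble::tibble(site = dec$site, base = BASES[dec$base],
                        bq = dec$bq, mq = dec$mq,
                        strand = dec$strand == 1L, ord = dec$ord)
  retain <- obs$bq >= min_bq & obs$mq >= min_mq
  obs <- obs[retain, ]
  indels <- tibble::tibble(site = dec$indel_site,
                           kind = c("ins", "del")[dec$indel_kind],
                           seq = dec$indel_seq,
                           strand = dec$indel_strand == 1L,
                           after = dec$indel_after)
  pileup_data(sites, obs, indels)
}

#' Render a pileup as mpileup text
#'
#' Writes valid 7-column mpileup (with the `-s` mapping-quality column) that
#' [read_mpileup()] round-trips exactly: bases, strands, qualities and indel
#' events are all preserved. Indel events are emitted as `+nSEQ`/`-nSEQ`
#' immediately after the read they are attached to, with sequence case
#' encoding the strand.
#'
#' @param pileup A [pileup_data()] object.
#' @param file Output path, or `NULL` to return the lines invisibly.
#' @return The rendered lines, invisibly.
#' @export
render_mpileup <- function(pileup, file = NULL) {
  st <- pileup$sites
  if (nrow(st) == 0) {
    if (!is.null(file)) readr::write_lines(character(), file)
    return(invisible(character()))
  }
  obs <- pileup$obs
  ref <- st$ref[obs$site]
  ch <- ifelse(obs$base == ref,
               ifelse(obs$strand, ".", ","),
               ifelse(obs$strand, obs$base, tolower(obs$base)))
  ind <- pileup$indels
  if (nrow(ind)) {
    tag <- paste0(ifelse(ind$kind == "ins", "+", "-"), nchar(ind$seq),
                  ifelse(ind$strand, ind$seq, tolower(ind$seq)))
    key <- match(paste(ind$site, ind$after), paste(obs$site, obs$ord))
    ok <- !is.na(key)
    # several events can ride on the same read; concatenate their tags
    agg <- vapply(split(tag[ok], key[ok]), paste, "", collapse = "")
    at <- as.integer(names(agg))
    ch[at] <- paste0(ch[at], agg)
  }
  f <- factor(obs$site, levels = seq_len(nrow(st)))
  collapse <- function(v) vapply(split(v, f), paste, "", collapse = "")
  bases_str <- collapse(ch)
  quals_str <- collapse(intToUtf8(obs$bq + 33L, multiple = TRUE))
  mq_str <- collapse(intToUtf8(pmin(obs$mq, 93L) + 33L, multiple = TRUE))
  n_obs <- tabulate(obs$site, nbins = nrow(st))
  lines <- paste(st$chrom, st$pos, st$ref, pmax(st$raw_depth, n_obs),
                 ifelse(nzchar(bases_str), bases_str, "*"),
                 ifelse(nzchar(quals_str), quals_str, "*"),
                 ifelse(nzchar(mq_str), mq_str, "*"),
                 sep = "\t")
  if (!is.null(file)) readr::write_lines(lines, file)
  invisible(lines)
}

#' Pileup columns from a coordinate-sorted BAM
#'
#' Converts a BAM region to the package's column representation by running
#' `samtools mpileup -s` (the per-read base and mapping qualities the
#' likelihood model needs are not exposed by count-level pileup interfaces)
#' and feeding the result to [read_mpileup()]. The text path is the
#' reference implementation; this wrapper inherits samtools' own policies on
#' duplicates and overlapping mates (overlapping mate bases are counted
#' once, samtools' default overlap correction).
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param fasta_path Indexed reference FASTA.
#' @param region Optional `chr:start-end` region string.
#' @inheritParams read_mpileup
#' @return A [pileup_data()] object.
#' @export
columns_from_bam <- function(bam_path, fasta_path, region = NULL,
                             min_base_quality = 13L,
                             min_mapping_quality = 0L) {
  if (Sys.which("samtools") == "")
    rlang::abort("samtools not found on PATH; use the mpileup text path",
                 class = "varcall_data_error")
  if (!file.exists(bam_path) || !file.exists(paste0(bam_path, ".bai")))
    rlang::abort("BAM or its .bai index is missing", class = "varcall_data_error")
  if (!file.exists(fasta_path))
    rlang::abort("reference FASTA is missing", class = "varcall_data_error")
  args <- c("mpileup", "-s", "-B", "-Q", "0", "-q", "0",
            "-f", fasta_path, if (!is.null(region)) c("-r", region), bam_path)
  out <- suppressWarnings(
    system2("samtools", shQuote(args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  body <- out[!grepl("^\\[", out)]
  if (!is.null(status) && status != 0)
    rlang::abort(paste0("samtools mpileup failed: ",
                        paste(out[grepl("^\\[", out)], collapse = "; ")),
                 class = "varcall_data_error")
  if (length(body) == 0) return(empty_pileup())
  read_mpileup(c(body, ""), min_base_quality = min_base_quality,
               min_mapping_quality = min_mapping_quality)
}
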