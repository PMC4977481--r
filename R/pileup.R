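#' Pileup column container
#'
#' A `pileup` bundles the per-site column stream of one sample as three
#' linked tibbles:
#'
#' * `sites`: one row per genomic site — `chrom`, `pos` (1-based), `ref`
#'   (reference base, one of A/C/G/T) and `raw_depth` (the depth declared in
#'   the input, which may exceed the retained observations when reads were
#'   quality-filtered or were deletion placeholders).
#' * `obs`: one row per retained allele observation — `site` (row index into
#'   `sites`), `base`, `bq` and `mq` (Phred base and mapping quality),
#'   `strand` (`TRUE` = forward) and `ord` (the read's ordinal within the
#'   column, which ties indel events to the read carrying them).
#' * `indels`: one row per insertion/deletion event — `site`, `kind`
#'   (`"ins"` or `"del"`), `seq` (the inserted bases, or the deleted
#'   reference bases), `strand` and `after` (ordinal of the carrying read).
#'
#' @param sites,obs,indels Tibbles as described above; `indels` may be
#'   omitted.
#' @return An object of class `pileup`.
#' @export
pileup_data <- function(sites, obs, indels = NULL) {
  sites <- tibble::as_tibble(sites)
  obs <- tibble::as_tibble(obs)
  if (is.null(indels))
    indels <- tibble::tibble(site = integer(), kind = character(),
                             seq = character(), strand = logical(),
                             after = integer())
  indels <- tibble::as_tibble(indels)
  stopifnot(all(c("chrom", "pos", "ref") %in% names(sites)),
            all(c("site", "base", "bq", "mq", "strand") %in% names(obs)))
  if (!"raw_depth" %in% names(sites))
    sites$raw_depth <- tabulate(obs$site, nbins = nrow(sites))
  if (!"ord" %in% names(obs))
    obs$ord <- stats::ave(seq_len(nrow(obs)), obs$site, FUN = seq_along)
  stopifnot(all(sites$pos >= 1), all(sites$ref %in% BASES),
            all(obs$base %in% BASES), all(obs$bq >= 0), all(obs$mq >= 0))
  structure(list(sites = sites, obs = obs, indels = indels),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d sites, %d observations, %d indel events\n",
              nrow(x$sites), nrow(x$obs), nrow(x$indels)))
  print(utils::head(x$sites, 5))
  invisible(x)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.pileup <- function(x, ...) {
  dplyr::left_join(
    dplyr::mutate(x$sites, site = dplyr::row_number()),
    x$obs, by = "site")
}

#' Number of sites in a pileup
#' @param x A `pileup`.
#' @param ... Unused.
#' @export
n_sites <- function(x, ...) UseMethod("n_sites")

#' @export
n_sites.pileup <- function(x, ...) nrow(x$sites)

# extract the observations of a single site as a plain tibble
site_obs <- function(pileup, i) {
  dplyr::filter(pileup$obs, .data$site == i)
}
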