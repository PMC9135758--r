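#' Build a binned genome layout
#'
#' Tiles each chromosome with fixed-width bins (0-based, half-open). The last
#' bin of a chromosome may be shorter than `bin_size`. All observation tracks
#' (depth log ratios, MAP copy-number profiles) are indexed on this layout, so
#' paired lesions must be generated and analysed on the same layout.
#'
#' @param n_chrom Number of chromosomes (all of length `chrom_len`), or a
#'   named numeric vector of chromosome lengths in bp (names become
#'   chromosome names; `chrom_len` is then ignored).
#' @param chrom_len Chromosome length in bp (used when `n_chrom` is a count).
#' @param bin_size Bin width in bp.
#' @return An object of class `ggn_layout`: a list with `chromosomes`
#'   (data.frame of `name`, `length`), `bin_size`, and `bins` (data.frame of
#'   `chrom`, `start`, `end`, `bin` with 0-based half-open coordinates and a
#'   global 1-based bin index).
#' @examples
#' layout <- make_genome(2, 1e6, 1e4)
#' nrow(layout$bins)  # 200
#' @export
make_genome <- function(n_chrom, chrom_len = NULL, bin_size = NULL) {
  if (length(n_chrom) > 1L || !is.null(names(n_chrom))) {
    lens <- n_chrom
    if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
  } else {
    if (!is.numeric(n_chrom) || n_chrom < 1)
      stop("n_chrom must be a positive count")
    if (is.null(chrom_len)) stop("chrom_len is required")
    lens <- rep(chrom_len, n_chrom)
    names(lens) <- paste0("chr", seq_len(n_chrom))
  }
  if (any(lens <= 0)) stop("chromosome lengths must be positive")
  if (is.null(bin_size) || bin_size <= 0) stop("bin_size must be positive")
  if (bin_size > min(lens)) stop("bin_size must not exceed chromosome length")

  bins <- do.call(rbind, lapply(names(lens), function(ch) {
    len <- lens[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  }))
  bins$bin <- seq_len(nrow(bins))
  structure(
    list(chromosomes = data.frame(name = names(lens), length = unname(lens),
                                  stringsAsFactors = FALSE),
         bin_size = bin_size, bins = bins),
    class = "ggn_layout")
}

#' @export
print.ggn_layout <- function(x, ...) {
  cat(sprintf("ggn_layout: %d chromosome(s), bin size %g bp, %d bins\n",
              nrow(x$chromosomes), x$bin_size, nrow(x$bins)))
  invisible(x)
}

#' Map genomic positions to layout bin indices
#'
#' @param layout A `ggn_layout`.
#' @param chrom Chromosome names.
#' @param pos 1-based positions (VCF convention).
#' @return Global 1-based bin indices (NA for positions off the layout).
#' @keywords internal
bin_of_position <- function(layout, chrom, pos) {
  pos0 <- pos - 1L  # to 0-based
  offset <- c(0, cumsum(vapply(
    seq_len(nrow(layout$chromosomes)),
    function(i) sum(layout$bins$chrom == layout$chromosomes$name[i]),
    numeric(1))))
  ci <- match(chrom, layout$chromosomes$name)
  within <- pos0 %/% layout$bin_size + 1L
  idx <- offset[ci] + within
  bad <- is.na(ci) | pos0 < 0 | pos0 >= layout$chromosomes$length[ci]
  idx[bad] <- NA_integer_
  as.integer(idx)
}
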