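#' Genotype-state catalog for joint CNV/LOH inference
#'
#' Enumerates all allele-specific genotype states `(c, a)` with total copy
#' number `1 <= c <= c_max` and reference-allele copies `0 <= a <= c`, each
#' labelled with its LOH type and its copy-number type. The LOH taxonomy
#' follows the allele-specific convention used in subclonal CNV/LOH callers:
#'
#' | (c, a)            | loh_label | meaning                              |
#' |-------------------|-----------|--------------------------------------|
#' | (1,0), (1,1)      | DLOH      | hemizygous-deletion LOH              |
#' | (2,1)             | HET       | retained heterozygous (diploid)      |
#' | (2,0), (2,2)      | NLOH      | copy-neutral LOH                     |
#' | (3,1), (3,2)      | GAIN      | one-copy gain                        |
#' | (3,0), (3,3)      | ALOH      | amplification LOH                    |
#' | (4,0), (4,4)      | ALOH      | amplification LOH                    |
#' | (4,1), (4,3)      | UBCNA     | unbalanced copy-number amplification |
#' | (4,2)             | BCNA      | balanced copy-number amplification   |
#'
#' The copy-number label is `HEMD` for `c < 2`, `NEUT` for `c == 2` and `AMP`
#' for `c > 2`. The allele-specific amplified states (3,1), (3,2), (4,1) and
#' (4,3) additionally carry the coarser amplification-track alias `ASCNA` in
#' the `amp_track` column, matching how display tracks collapse them.
#'
#' @param c_max Maximum total copy number (>= 2). The default 4 gives the
#'   14-state space used throughout the package.
#' @return A data.frame with columns `c`, `a`, `loh_label`, `cnv_label`,
#'   `amp_track` and a `state` key of the form `"c3a1"`.
#' @examples
#' states <- enumerate_states()
#' nrow(states)  # 14
#' @export
enumerate_states <- function(c_max = 4) {
  if (c_max < 2) stop("c_max must be >= 2")
  if (c_max > 4) stop("states with c > 4 are not in the catalog")
  df <- do.call(rbind, lapply(seq_len(c_max), function(cc)
    data.frame(c = cc, a = 0:cc)))
  df$loh_label <- mapply(loh_label_of, df$c, df$a)
  df$cnv_label <- ifelse(df$c < 2, "HEMD", ifelse(df$c == 2, "NEUT", "AMP"))
  df$amp_track <- ifelse(df$c >= 3 & df$a > 0 & df$a < df$c & df$loh_label != "BCNA",
                         "ASCNA", df$loh_label)
  df$state <- sprintf("c%da%d", df$c, df$a)
  df
}

loh_label_of <- function(c, a) {
  stopifnot(a >= 0, a <= c)
  if (c == 1) return("DLOH")
  if (c == 2) return(if (a == 1) "HET" else "NLOH")
  if (c == 3) return(if (a %in% c(1, 2)) "GAIN" else "ALOH")
  if (c == 4) {
    if (a == 2) return("BCNA")
    if (a %in% c(1, 3)) return("UBCNA")
    return("ALOH")
  }
  stop("copy number out of catalog range")
}

#' Expected depth log ratio for a genotype state in an impure sample
#'
#' A locus whose aberration (total copy number `c`) is carried by a fraction
#' `s` of the tumor cells, in a sample with normal-cell fraction `n`, has mean
#' total copy number `cbar = 2 n + (1 - n) (s c + (1 - s) 2)` and expected
#' tumor/normal depth log ratio `log2(cbar / 2)`.
#'
#' @param c Total copy number of the aberrant genotype.
#' @param s Cellular prevalence of the carrying subclone, fraction of tumor
#'   cells in (0, 1].
#' @param n Normal contamination fraction in \[0, 1).
#' @return Expected log2 depth ratio.
#' @examples
#' expected_logratio(3, 1, 0.3)  # log2(2.7/2)
#' @export
expected_logratio <- function(c, s, n) {
  log2(mixture_copy(c, s, n) / 2)
}

#' Expected reference-allele read fraction at a germline heterozygous site
#'
#' The germline genotype contributes one reference of two copies; normal cells
#' and tumor cells without the aberration stay heterozygous, while carrier
#' cells have `a` of `c` reference copies. The expected fraction of reads
#' matching the reference is
#' `(n + (1 - n) (s a + (1 - s))) / cbar`.
#'
#' @inheritParams expected_logratio
#' @param a Reference-allele copies of the aberrant genotype (0..c).
#' @return Expected reference read fraction in \[0, 1\].
#' @examples
#' expected_reffraction(1, 1, 1, 0.3)  # 1/1.3
#' @export
expected_reffraction <- function(c, a, s, n) {
  (n * 1 + (1 - n) * (s * a + (1 - s) * 1)) / mixture_copy(c, s, n)
}

mixture_copy <- function(c, s, n) {
  2 * n + (1 - n) * (s * c + (1 - s) * 2)
}
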