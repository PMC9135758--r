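# Cross-lesion lineage deconstruction: genome-wide CNV correlation plus
# same-locus/same-type subclone feature sharing, combined into a
# parallel-vs-independent call.

#' Genome-wide Pearson correlation of two CNV profiles
#'
#' @param profile_A,profile_B Equal-length per-bin numeric profiles on a
#'   shared layout (MAP total copy number, or raw log ratios as fallback).
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
cnv_correlation <- function(profile_A, profile_B) {
  if (length(profile_A) != length(profile_B))
    stop("profiles must have equal length")
  ok <- !is.na(profile_A) & !is.na(profile_B)
  a <- profile_A[ok]; b <- profile_B[ok]
  if (length(a) < 2) stop("fewer than 2 paired bins")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a profile has zero variance")
  stats::cor(a, b)
}

#' Same-locus, same-type feature sharing between two lesions' subclones
#'
#' Rasterizes both lesions' typed segments to the shared bin grid and, for
#' every cluster pair (i in A, j in B), counts bins where both lesions carry
#' the SAME non-HET LOH type at the SAME locus (`n_shared`), and bins altered
#' in only one lesion's cluster of the pair (`n_unique_A`, `n_unique_B`).
#' Diploid heterozygous bins are uninformative about shared ancestry and are
#' excluded. `shared_fraction = n_shared / (n_shared + n_unique_A +
#' n_unique_B)`.
#'
#' @param segments_A,segments_B `ggn_typed_segments` on the same layout.
#' @param layout The shared `ggn_layout`.
#' @return Object of class `ggn_shared_report`: `pairs` (data.frame
#'   `cluster_A`, `cluster_B`, `n_shared`, `n_unique_A`, `n_unique_B`,
#'   `shared_fraction`), `top` (best pair by shared fraction, NULL when no
#'   altered bins exist in either lesion), and `n_bins`.
#' @export
shared_feature_analysis <- function(segments_A, segments_B, layout) {
  labA <- profile_from_segments(segments_A, layout, "loh_label")
  labB <- profile_from_segments(segments_B, layout, "loh_label")
  clA <- profile_from_segments(segments_A, layout, "cluster")
  clB <- profile_from_segments(segments_B, layout, "cluster")
  altA <- !is.na(labA) & labA != "HET"
  altB <- !is.na(labB) & labB != "HET"

  clusters_A <- sort(unique(segments_A$cluster))
  clusters_B <- sort(unique(segments_B$cluster))
  pairs <- expand.grid(cluster_A = clusters_A, cluster_B = clusters_B)
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$cluster_A[r]; j <- pairs$cluster_B[r]
    inA <- altA & clA == i
    inB <- altB & clB == j
    sh <- sum(inA & inB & labA == labB, na.rm = TRUE)
    uA <- sum(inA, na.rm = TRUE) - sh
    uB <- sum(inB, na.rm = TRUE) - sh
    tot <- sh + uA + uB
    data.frame(cluster_A = i, cluster_B = j, n_shared = sh,
               n_unique_A = uA, n_unique_B = uB,
               shared_fraction = if (tot > 0) sh / tot else 0)
  })
  pairs <- do.call(rbind, res)
  top <- NULL
  if (any(altA, na.rm = TRUE) || any(altB, na.rm = TRUE)) {
    top <- pairs[which.max(pairs$shared_fraction), ]
  }
  structure(list(pairs = pairs, top = top, n_bins = nrow(layout$bins)),
            class = "ggn_shared_report")
}

#' @export
print.ggn_shared_report <- function(x, ...) {
  cat("ggn_shared_report: cluster-pair feature sharing\n")
  print(x$pairs, row.names = FALSE)
  if (is.null(x$top)) cat("  (no altered bins in either lesion)\n")
  else cat(sprintf("  top pair: A-cluster %d vs B-cluster %d, shared fraction %.3f\n",
                   x$top$cluster_A, x$top$cluster_B, x$top$shared_fraction))
  invisible(x)
}

#' Classify a lesion pair as parallel or independent lineage
#'
#' Disjunctive rule: the pair is called `parallel` when the genome-wide CNV
#' correlation exceeds `r_threshold` OR the best cluster pair's shared
#' feature fraction reaches `share_threshold`; otherwise `independent`. The
#' disjunction matters: a pair can lack global CNV similarity yet still share
#' the same typed aberrations in a minor subclone, which is evidence of a
#' common founding clone.
#'
#' @param r Genome-wide Pearson correlation from [cnv_correlation()], or NA
#'   when undefined.
#' @param report A `ggn_shared_report`.
#' @param r_threshold Correlation threshold (default 0.8).
#' @param share_threshold Shared-fraction threshold (default 0.5).
#' @return Object of class `ggn_lineage_call`: `verdict` ("parallel" or
#'   "independent"), `r`, `top_shared_fraction`, `top_pair`, thresholds and
#'   evidence notes.
#' @export
call_lineage <- function(r, report, r_threshold = 0.8, share_threshold = 0.5) {
  if ((is.null(r) || is.na(r)) && is.null(report$top))
    stop("undefined correlation and empty sharing report: manual review needed")
  top_share <- if (is.null(report$top)) 0 else report$top$shared_fraction
  by_r <- !is.null(r) && !is.na(r) && r > r_threshold
  by_share <- top_share >= share_threshold
  verdict <- if (by_r || by_share) "parallel" else "independent"
  notes <- c(
    if (by_r) sprintf("global CNV correlation r=%.3f > %.2f", r, r_threshold),
    if (by_share) sprintf("top subclone pair shares %.1f%% of typed features",
                          100 * top_share),
    if (!by_r && !by_share) "neither correlation nor feature sharing reaches threshold")
  structure(list(verdict = verdict, r = r, top_shared_fraction = top_share,
                 top_pair = report$top, r_threshold = r_threshold,
                 share_threshold = share_threshold, notes = notes),
            class = "ggn_lineage_call")
}

#' @export
print.ggn_lineage_call <- function(x, ...) {
  cat(sprintf("Lineage call: %s\n", toupper(x$verdict)))
  cat(sprintf("  genome-wide CNV correlation r = %s (threshold %.2f)\n",
              if (is.null(x$r) || is.na(x$r)) "NA" else sprintf("%.3f", x$r),
              x$r_threshold))
  cat(sprintf("  top shared feature fraction = %.3f (threshold %.2f)\n",
              x$top_shared_fraction, x$share_threshold))
  for (nte in x$notes) cat("  -", nte, "\n")
  invisible(x)
}

#' Full cross-lesion comparison from two fitted clonal models
#'
#' Computes typed segments and per-bin MAP copy-number profiles for both
#' lesions, the genome-wide Pearson correlation, the subclone feature-sharing
#' report, and the lineage call.
#'
#' @param model_A,model_B Fitted `ggn_clonal_model`s of the two lesions.
#' @param layout The shared `ggn_layout`.
#' @inheritParams call_lineage
#' @return List with `segments_A`, `segments_B`, `r`, `report`, `call`.
#' @export
compare_lesions <- function(model_A, model_B, layout, r_threshold = 0.8,
                            share_threshold = 0.5) {
  segA <- typed_segments(model_A, layout)
  segB <- typed_segments(model_B, layout)
  pA <- profile_from_segments(segA, layout, "c")
  pB <- profile_from_segments(segB, layout, "c")
  r <- tryCatch(cnv_correlation(pA, pB), error = function(e) NA_real_)
  report <- shared_feature_analysis(segA, segB, layout)
  list(segments_A = segA, segments_B = segB, r = r, report = report,
       call = call_lineage(r, report, r_threshold, share_threshold))
}
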