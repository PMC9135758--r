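# 3-state depth-only CNV segmentation for low-coverage data: deleted /
# neutral / amplified states over median-centered bin log ratios.

DEPTH_STATES <- c("DEL", "NEUT", "AMP")

#' Median-center binned depth log ratios
#'
#' @param bins data.frame with a `log_ratio` column.
#' @return Same data.frame with the median (over non-NA bins) subtracted.
#' @export
normalize_depth <- function(bins) {
  if (nrow(bins) == 0) stop("no bins to normalize")
  bins$log_ratio <- bins$log_ratio -
    stats::median(bins$log_ratio, na.rm = TRUE)
  bins
}

#' Fit the 3-state depth HMM
#'
#' Decodes each bin as deleted, copy-neutral or amplified with a sticky
#' 3-state HMM over depth log ratios (Gaussian emissions with a shared SD),
#' chromosomes processed as independent chains. When `state_sd` is NULL it is
#' estimated by a one-pass method of moments on the central 50% of bins
#' (between the quartiles), which is dominated by the neutral background.
#' Viterbi ties break toward NEUT.
#'
#' @param bins data.frame with `chrom` and `log_ratio` (NA bins are decoded
#'   from the chain alone, i.e. carry a flat emission).
#' @param self_transition Self-transition probability of each state.
#' @param state_means Emission means (log2) for DEL, NEUT, AMP; must be
#'   strictly increasing.
#' @param state_sd Shared emission SD, or NULL to estimate.
#' @return List of class `ggn_depth_fit`: `path` (factor DEL/NEUT/AMP per
#'   bin), `posterior` (N x 3, rows sum to 1), `loglik`, `state_sd`, `bins`.
#' @export
fit_depth_hmm <- function(bins, self_transition = 0.999,
                          state_means = c(-0.5, 0, 0.35), state_sd = NULL) {
  stopifnot(self_transition > 0, self_transition < 1,
            length(state_means) == 3, all(diff(state_means) > 0))
  lr <- bins$log_ratio
  if (is.null(state_sd)) {
    q <- stats::quantile(lr, c(0.25, 0.75), na.rm = TRUE)
    central <- lr[!is.na(lr) & lr >= q[1] & lr <= q[2]]
    state_sd <- max(sqrt(mean((central - mean(central))^2)), 1e-3)
  }
  N <- length(lr)
  logE <- matrix(0, N, 3)
  ok <- !is.na(lr)
  for (j in 1:3) logE[ok, j] <- stats::dnorm(lr[ok], state_means[j],
                                             state_sd, log = TRUE)
  fb <- hmm_posterior(logE, self_transition, chrom = bins$chrom)
  path <- hmm_viterbi(logE, self_transition, chrom = bins$chrom,
                      pref = c(2L, 1L, 3L))  # ties toward NEUT
  structure(list(path = factor(DEPTH_STATES[path], levels = DEPTH_STATES),
                 posterior = fb$gamma, loglik = fb$loglik,
                 state_sd = state_sd, state_means = state_means,
                 self_transition = self_transition, bins = bins),
            class = "ggn_depth_fit")
}

#' Collapse a per-bin state path into CNV segments
#'
#' @param path Per-bin calls (`DEL`/`NEUT`/`AMP`), length = number of bins.
#' @param bins data.frame with `chrom`, `start`, `end`, `log_ratio` matching
#'   `path`.
#' @return data.frame of class `ggn_cnv_segments`: `chrom`, `start`, `end`
#'   (0-based half-open), `call`, `n_bins`, `median_logratio`; per chromosome
#'   the segments are sorted, non-overlapping, cover all bins, and adjacent
#'   segments differ in call.
#' @export
segments_from_path <- function(path, bins) {
  stopifnot(length(path) == nrow(bins))
  segs <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    r <- rle(as.character(path[idx]))
    stop_i <- cumsum(r$lengths); start_i <- stop_i - r$lengths + 1L
    for (j in seq_along(r$values)) {
      sel <- idx[start_i[j]:stop_i[j]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = bins$start[sel[1]], end = bins$end[sel[length(sel)]],
        call = r$values[j], n_bins = length(sel),
        median_logratio = stats::median(bins$log_ratio[sel], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("ggn_cnv_segments", "data.frame")
  out
}

#' Low-depth CNV calling pipeline for one lesion
#'
#' Convenience wrapper: [normalize_depth()], [fit_depth_hmm()],
#' [segments_from_path()].
#'
#' @inheritParams fit_depth_hmm
#' @param ... Passed to [fit_depth_hmm()].
#' @return A `ggn_cnv_segments` data.frame, with the fit in
#'   `attr(., "fit")`.
#' @export
call_cnv <- function(bins, ...) {
  bins <- normalize_depth(bins)
  fit <- fit_depth_hmm(bins, ...)
  segs <- segments_from_path(fit$path, bins)
  attr(segs, "fit") <- fit
  segs
}
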