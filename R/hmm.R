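#' @useDynLib ggnclone, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Forward-backward smoothing on a sticky exchangeable chain
#'
#' Transition kernel: self-transition probability `rho`, remaining mass spread
#' uniformly over the other states; uniform initial distribution. Chains
#' restart at chromosome boundaries. Emissions are supplied in log space and
#' rescaled internally, so arbitrarily small likelihoods do not underflow.
#'
#' @param log_emissions N x K matrix of per-locus log emission densities.
#' @param rho Self-transition probability in (0, 1).
#' @param chrom Integer/factor vector of length N; value changes mark
#'   chromosome starts.
#' @return List with `gamma` (N x K posterior state probabilities, rows sum
#'   to 1) and `loglik`.
#' @export
hmm_posterior <- function(log_emissions, rho, chrom = rep(1L, nrow(log_emissions))) {
  stopifnot(rho > 0, rho < 1, nrow(log_emissions) == length(chrom))
  .fb_cpp(as.matrix(log_emissions), rho, as.integer(as.factor(chrom)))
}

#' Viterbi decoding on a sticky exchangeable chain
#'
#' @inheritParams hmm_posterior
#' @param pref Optional integer permutation of `1:K` giving the tie-break
#'   preference order (earlier wins on exact ties). Default: state order.
#' @return Integer vector of length N of most-likely states (1-based).
#' @export
hmm_viterbi <- function(log_emissions, rho, chrom = rep(1L, nrow(log_emissions)),
                        pref = seq_len(ncol(log_emissions))) {
  stopifnot(rho > 0, rho < 1, nrow(log_emissions) == length(chrom),
            length(pref) == ncol(log_emissions))
  .viterbi_cpp(as.matrix(log_emissions), rho, as.integer(as.factor(chrom)),
               as.integer(pref) - 1L)
}
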