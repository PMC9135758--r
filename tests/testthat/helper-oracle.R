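# Brute-force HMM oracle: enumerates every state path of a short chain and
# computes exact posteriors, likelihood and the max-probability path.
# Independent of the package's forward-backward/Viterbi implementation.

bf_hmm <- function(logE, rho) {
  N <- nrow(logE)
  K <- ncol(logE)
  u <- (1 - rho) / (K - 1)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- rep(-log(K), nrow(paths))  # uniform initial distribution
  for (t in seq_len(N)) logp <- logp + logE[cbind(t, paths[, t])]
  if (N > 1) for (t in 2:N) {
    same <- paths[, t] == paths[, t - 1]
    logp <- logp + ifelse(same, log(rho), log(u))
  }
  m <- max(logp)
  w <- exp(logp - m)
  loglik <- m + log(sum(w))
  gamma <- matrix(0, N, K)
  for (t in seq_len(N)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k]) / sum(w)
  list(gamma = gamma, loglik = loglik,
       viterbi = unname(paths[which.max(logp), ]))
}

# emission matrix of the joint (genotype x cluster) model, built directly
# from the closed-form expectations (kept separate from the package's
# internal emission code on purpose)
oracle_joint_logE <- function(loci, states, s, n, sigma) {
  Z <- length(s)
  G <- nrow(states)
  logE <- matrix(0, nrow(loci), G * Z)
  for (z in seq_len(Z)) for (g in seq_len(G)) {
    k <- (z - 1) * G + g
    mu <- log2((2 * n + (1 - n) * (s[z] * states$c[g] + (1 - s[z]) * 2)) / 2)
    p <- (n + (1 - n) * (s[z] * states$a[g] + 1 - s[z])) /
      (2 * n + (1 - n) * (s[z] * states$c[g] + (1 - s[z]) * 2))
    p <- min(1 - 1e-10, max(1e-10, p))
    for (i in seq_len(nrow(loci))) {
      e <- 0
      if (!is.na(loci$log_ratio[i]))
        e <- e + dnorm(loci$log_ratio[i], mu, sigma, log = TRUE)
      if (!is.na(loci$depth[i]))
        e <- e + dbinom(loci$ref_count[i], loci$depth[i], p, log = TRUE)
      logE[i, k] <- e
    }
  }
  logE
}

# small locus grid with arbitrary but valid observations
make_test_loci <- function(n, seed, chrom = rep("chr1", n), with_het = TRUE) {
  set.seed(seed)
  data.frame(
    chrom = chrom, bin = seq_len(n), pos = if (with_het) seq_len(n) * 100
      else NA_integer_,
    log_ratio = rnorm(n, 0, 0.4),
    ref_count = if (with_het) rbinom(n, 30, runif(n, 0.2, 0.8))
      else NA_integer_,
    depth = if (with_het) rep(30L, n) else NA_integer_,
    stringsAsFactors = FALSE)
}
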