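# Joint CNV/LOH subclonal inference: an HMM over (genotype state x subclone
# cluster) with Gaussian depth-ratio emissions and binomial allelic-ratio
# emissions, EM estimation of the normal contamination n, per-cluster cellular
# prevalence s_z and emission SD sigma, and BIC selection of the cluster count.

#' Align depth bins and heterozygous sites on a common locus grid
#'
#' Depth and allelic observations are fused on one ordered locus grid:
#' every heterozygous SNP site becomes a locus carrying both its allele counts
#' and the log ratio of the bin containing it; every bin without a het site
#' becomes a depth-only locus. Loci with no usable emission (NA log ratio and
#' no counts) are dropped.
#'
#' @param bins data.frame with `chrom`, `start`, `end`, `bin`, `log_ratio`
#'   (one row per layout bin, as produced by [emit_observations()] or
#'   [read_wig()]).
#' @param het data.frame with `chrom`, `pos`, `ref_count`, `depth`.
#' @param layout The `ggn_layout` both tracks live on.
#' @return data.frame of class `ggn_loci`: `chrom`, `bin`, `pos` (NA for
#'   depth-only loci), `log_ratio`, `ref_count`, `depth`, ordered by genome
#'   position.
#' @export
build_locus_grid <- function(bins, het, layout) {
  stopifnot(nrow(bins) == nrow(layout$bins))
  hbin <- bin_of_position(layout, het$chrom, het$pos)
  keep <- !is.na(hbin)
  if (any(!keep)) warning(sum(!keep), " het site(s) outside layout dropped")
  het <- het[keep, , drop = FALSE]
  hbin <- hbin[keep]
  hl <- data.frame(chrom = het$chrom, bin = hbin, pos = het$pos,
                   log_ratio = bins$log_ratio[hbin],
                   ref_count = het$ref_count, depth = het$depth,
                   stringsAsFactors = FALSE)
  dononly <- setdiff(bins$bin, hbin)
  dl <- data.frame(chrom = bins$chrom[dononly], bin = bins$bin[dononly],
                   pos = NA_integer_, log_ratio = bins$log_ratio[dononly],
                   ref_count = NA_integer_, depth = NA_integer_,
                   stringsAsFactors = FALSE)
  g <- rbind(hl, dl)
  g <- g[order(g$bin, g$pos, na.last = FALSE), ]
  usable <- !is.na(g$log_ratio) | !is.na(g$depth)
  g <- g[usable, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("ggn_loci", "data.frame")
  g
}

# joint-space bookkeeping: K = n_states x Z, cluster-major order
joint_space <- function(states, Z) {
  G <- nrow(states)
  data.frame(k = seq_len(G * Z),
             g = rep(seq_len(G), times = Z),
             z = rep(seq_len(Z), each = G))
}

# N x K matrix of log emission densities
joint_log_emissions <- function(loci, states, s, n, sigma) {
  js <- joint_space(states, length(s))
  mu <- expected_logratio(states$c[js$g], s[js$z], n)
  p <- pmin(1 - 1e-10, pmax(1e-10,
         expected_reffraction(states$c[js$g], states$a[js$g], s[js$z], n)))
  N <- nrow(loci); K <- nrow(js)
  logE <- matrix(0, N, K)
  has_lr <- !is.na(loci$log_ratio)
  has_ad <- !is.na(loci$depth)
  for (k in seq_len(K)) {
    e <- numeric(N)
    e[has_lr] <- stats::dnorm(loci$log_ratio[has_lr], mu[k], sigma, log = TRUE)
    e[has_ad] <- e[has_ad] + stats::dbinom(loci$ref_count[has_ad],
                                           loci$depth[has_ad], p[k], log = TRUE)
    logE[, k] <- e
  }
  logE
}

#' E-step: posterior state/cluster responsibilities
#'
#' Runs scaled forward-backward over the joint (genotype x cluster) space with
#' a sticky transition kernel (self-transition `rho`, uniform otherwise) and
#' chains restarting at chromosome boundaries.
#'
#' @param loci A `ggn_loci` grid.
#' @param params List with `n`, `s` (vector of cluster prevalences), `sigma`.
#' @param states Genotype catalog from [enumerate_states()].
#' @param rho Self-transition probability.
#' @return List with `gamma` (N x K responsibilities, rows sum to 1),
#'   `loglik`, and the joint-space index.
#' @export
e_step <- function(loci, params, states = enumerate_states(), rho = 0.999) {
  logE <- joint_log_emissions(loci, states, params$s, params$n, params$sigma)
  fb <- hmm_posterior(logE, rho, chrom = loci$chrom)
  fb$space <- joint_space(states, length(params$s))
  fb
}

# sufficient statistics per joint state for the M-step
joint_suffstats <- function(loci, gamma) {
  has_lr <- !is.na(loci$log_ratio)
  has_ad <- !is.na(loci$depth)
  lr <- loci$log_ratio[has_lr]
  g_lr <- gamma[has_lr, , drop = FALSE]
  g_ad <- gamma[has_ad, , drop = FALSE]
  list(G  = colSums(g_lr),
       S1 = as.numeric(crossprod(g_lr, lr)),
       S2 = as.numeric(crossprod(g_lr, lr^2)),
       R  = as.numeric(crossprod(g_ad, loci$ref_count[has_ad])),
       A  = as.numeric(crossprod(g_ad, loci$depth[has_ad] - loci$ref_count[has_ad])))
}

# expected complete-data log-likelihood (emission part, up to constants)
q_emission <- function(ss, states, s, n, sigma) {
  js <- joint_space(states, length(s))
  mu <- expected_logratio(states$c[js$g], s[js$z], n)
  p <- pmin(1 - 1e-10, pmax(1e-10,
         expected_reffraction(states$c[js$g], states$a[js$g], s[js$z], n)))
  gaus <- -sum(ss$G) * log(sigma) -
    sum(ss$S2 - 2 * mu * ss$S1 + mu^2 * ss$G) / (2 * sigma^2)
  binom <- sum(ss$R * log(p) + ss$A * log(1 - p))
  gaus + binom
}

#' M-step: update normal fraction, prevalences and emission SD
#'
#' `n` and each cluster prevalence `s_z` are updated by bounded 1-D numeric
#' maximization of the expected complete-data log-likelihood on
#' \[0.01, 0.99\] (coordinate ascent; a candidate is only accepted if it does
#' not decrease the objective, so the EM likelihood is non-decreasing).
#' `sigma` is the closed-form responsibility-weighted residual SD. A cluster
#' whose total responsibility over informative (non-HET) states falls below
#' 1e-6 is dropped with a warning.
#'
#' @param loci A `ggn_loci` grid.
#' @param gamma Responsibilities from [e_step()].
#' @param params Current parameter list (`n`, `s`, `sigma`).
#' @inheritParams e_step
#' @return Updated parameter list; `dropped` holds ids of dropped clusters.
#' @export
m_step <- function(loci, gamma, params, states = enumerate_states()) {
  ss <- joint_suffstats(loci, gamma)
  n <- params$n; s <- params$s; sigma <- params$sigma
  js <- joint_space(states, length(s))

  informative <- states$loh_label != "HET"
  resp_z <- vapply(seq_along(s), function(z)
    sum(ss$G[js$z == z & informative[js$g]]) +
    sum(ss$R[js$z == z & informative[js$g]]) , numeric(1))
  dropped <- integer(0)
  if (any(resp_z < 1e-6) && length(s) > 1) {
    dropped <- which(resp_z < 1e-6)
    warning("dropping empty cluster(s): ", paste(dropped, collapse = ", "))
    keepk <- js$z %in% setdiff(seq_along(s), dropped)
    gamma <- gamma[, keepk, drop = FALSE]
    gamma <- gamma / rowSums(gamma)
    s <- s[-dropped]
    ss <- joint_suffstats(loci, gamma)
    js <- joint_space(states, length(s))
  }

  # with no aberrant loci the likelihood is flat in n and s: leave them at
  # their (boundary-stable) current values
  if (sum(ss$G[informative[js$g]]) + sum(ss$R[informative[js$g]]) < 1e-6) {
    warning("no aberrant loci: normal fraction and prevalences unidentifiable")
    mu <- expected_logratio(states$c[js$g], s[js$z], n)
    sig2 <- sum(ss$S2 - 2 * mu * ss$S1 + mu^2 * ss$G) / sum(ss$G)
    return(list(n = n, s = s, sigma = sqrt(max(sig2, 1e-8)),
                dropped = dropped))
  }

  # coordinate updates with accept-if-better guard
  qn <- function(x) q_emission(ss, states, s, x, sigma)
  cand <- stats::optimize(qn, c(0.01, 0.99), maximum = TRUE)
  if (cand$objective > qn(n)) n <- cand$maximum
  for (z in seq_along(s)) {
    qs <- function(x) { sz <- s; sz[z] <- x; q_emission(ss, states, sz, n, sigma) }
    cand <- stats::optimize(qs, c(0.01, 0.99), maximum = TRUE)
    if (cand$objective > qs(s[z])) s[z] <- cand$maximum
  }
  mu <- expected_logratio(states$c[js$g], s[js$z], n)
  sig2 <- sum(ss$S2 - 2 * mu * ss$S1 + mu^2 * ss$G) / sum(ss$G)
  sigma <- sqrt(max(sig2, 1e-8))

  list(n = n, s = s, sigma = sigma, dropped = dropped)
}

run_em <- function(loci, params, states, rho, max_iter, tol) {
  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  for (it in seq_len(max_iter)) {
    es <- e_step(loci, params, states, rho)
    gamma <- es$gamma
    trace <- c(trace, es$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    up <- m_step(loci, gamma, params, states)
    params <- list(n = up$n, s = up$s, sigma = up$sigma)
  }
  list(params = params, gamma = gamma, trace = trace,
       loglik = trace[length(trace)], converged = converged,
       n_iterations = length(trace))
}

#' Fit the joint CNV/LOH subclonal model by EM
#'
#' Fits normal contamination `n`, per-cluster cellular prevalences `s_z` and
#' the depth-emission SD by expectation-maximization over the joint
#' (genotype x cluster) HMM, then decodes the MAP state/cluster path by
#' Viterbi. Because the likelihood is multimodal, the default initialization
#' is a multi-start over `n` in \{0.1, 0.3, 0.5\} with prevalences equally
#' spaced in (0, 1\]; each start is burned in briefly and the best continued
#' to convergence.
#'
#' @inheritParams e_step
#' @param n_clusters Number of subclone clusters Z (>= 1).
#' @param init Optional list `(n, s, sigma)` to skip the multi-start and fit
#'   from a single initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param seed Unused source of randomness hook (the fit is deterministic);
#'   kept so that pipeline calls can thread one seed through every stage.
#' @param c_max Maximum total copy number of the genotype catalog.
#' @param burn_in Iterations given to each start before the best is chosen.
#' @return An object of class `ggn_clonal_model`: estimated `n`, `clusters`
#'   (data.frame `id`, `prevalence`, sorted by decreasing prevalence),
#'   `sigma`, `loglik`, the per-iteration log-likelihood `trace`, `converged`,
#'   `n_iterations`, the per-locus MAP assignment `map` (genotype and cluster
#'   per locus), and the inputs needed by downstream stages.
#' @export
fit_em <- function(loci, n_clusters = 2, init = NULL, max_iter = 100,
                   tol = 0.01, seed = NULL, rho = 0.999, c_max = 4,
                   burn_in = 8) {
  stopifnot(n_clusters >= 1)
  states <- enumerate_states(c_max)
  starts <- if (!is.null(init)) {
    list(list(n = init$n, s = init$s,
              sigma = if (is.null(init$sigma)) 0.15 else init$sigma))
  } else {
    s0 <- pmin(0.99, rev(seq_len(n_clusters)) / n_clusters)
    lapply(c(0.1, 0.3, 0.5), function(n0) list(n = n0, s = s0, sigma = 0.2))
  }

  best <- NULL
  if (length(starts) > 1) {
    burns <- lapply(starts, function(p)
      run_em(loci, p, states, rho, max_iter = burn_in, tol = tol))
    ll <- vapply(burns, `[[`, numeric(1), "loglik")
    pick <- which.max(ll)
    fit <- run_em(loci, burns[[pick]]$params, states, rho,
                  max_iter = max_iter - burn_in, tol = tol)
    fit$trace <- c(burns[[pick]]$trace, fit$trace)
    fit$n_iterations <- length(fit$trace)
    best <- fit
  } else {
    best <- run_em(loci, starts[[1]], states, rho, max_iter, tol)
  }

  # order clusters by decreasing prevalence
  Z <- length(best$params$s)
  ord <- order(best$params$s, decreasing = TRUE)
  s_sorted <- best$params$s[ord]

  # MAP decode (on sorted clusters; emissions only depend on s values)
  params <- list(n = best$params$n, s = s_sorted, sigma = best$params$sigma)
  logE <- joint_log_emissions(loci, states, params$s, params$n, params$sigma)
  js <- joint_space(states, Z)
  pref <- order(states$loh_label[js$g] != "HET", js$z, js$g)
  path <- hmm_viterbi(logE, rho, chrom = loci$chrom, pref = pref)
  map <- data.frame(chrom = loci$chrom, bin = loci$bin, pos = loci$pos,
                    c = states$c[js$g[path]], a = states$a[js$g[path]],
                    loh_label = states$loh_label[js$g[path]],
                    cnv_label = states$cnv_label[js$g[path]],
                    cluster = js$z[path], stringsAsFactors = FALSE)

  structure(list(
    n = params$n,
    clusters = data.frame(id = seq_len(Z), prevalence = s_sorted),
    sigma = params$sigma, loglik = best$loglik, trace = best$trace,
    converged = best$converged, n_iterations = best$n_iterations,
    map = map, loci = loci, states = states, rho = rho,
    n_loci = nrow(loci)), class = "ggn_clonal_model")
}

#' @export
print.ggn_clonal_model <- function(x, ...) {
  cat(sprintf("ggn_clonal_model: Z=%d cluster(s), n=%.3f, sigma=%.3f\n",
              nrow(x$clusters), x$n, x$sigma))
  cat(sprintf("  prevalences: %s\n",
              paste(sprintf("%.3f", x$clusters$prevalence), collapse = ", ")))
  cat(sprintf("  logL=%.2f after %d iteration(s)%s\n", x$loglik,
              x$n_iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Select the number of subclone clusters by BIC
#'
#' Fits the model for Z = 1..`z_max` clusters and returns the fit minimizing
#' `BIC = -2 logL + k log(N_loci)` with `k = Z + 2` free parameters (n, the
#' Z prevalences, sigma). Ties go to the smaller Z.
#'
#' A fit whose smallest prevalence sits at the lower optimization bound has
#' collapsed a cluster onto the diploid background: it describes the same
#' clonal structure as the model with one cluster fewer (which is already a
#' candidate) while inflating the likelihood through near-duplicate states,
#' so such fits are excluded from the comparison.
#'
#' @inheritParams fit_em
#' @param z_max Largest cluster count considered.
#' @return The selected `ggn_clonal_model`, with the BIC table (including a
#'   `degenerate` flag per candidate) in `$bic_table`.
#' @export
select_n_clusters <- function(loci, z_max = 5, seed = NULL, ...) {
  stopifnot(z_max >= 1)
  fits <- lapply(seq_len(z_max), function(Z)
    fit_em(loci, n_clusters = Z, seed = seed, ...))
  bic <- vapply(seq_len(z_max), function(Z)
    -2 * fits[[Z]]$loglik + (Z + 2) * log(nrow(loci)), numeric(1))
  degenerate <- vapply(fits, function(f)
    any(f$clusters$prevalence <= 0.011), logical(1))
  degenerate[1] <- FALSE  # the single-cluster model is always a candidate
  cand <- which(!degenerate)
  pick <- cand[which.min(bic[cand])]  # which.min: smallest Z wins ties
  out <- fits[[pick]]
  out$bic_table <- data.frame(Z = seq_len(z_max), loglik =
    vapply(fits, `[[`, numeric(1), "loglik"), bic = bic,
    degenerate = degenerate)
  out
}

#' Run-length encode the MAP path into typed segments
#'
#' Collapses the per-locus MAP (genotype, cluster) assignments to maximal
#' constant runs of layout bins. A bin containing several het-site loci takes
#' the majority assignment (first on ties); bins without any locus inherit the
#' nearest preceding bin's assignment on the same chromosome.
#'
#' @param model A `ggn_clonal_model`.
#' @param layout The `ggn_layout` the model was fitted on.
#' @return data.frame of class `ggn_typed_segments`: `chrom`, `start`, `end`
#'   (0-based half-open), `c`, `a`, `loh_label`, `cnv_label`, `cluster`,
#'   `prevalence`, `n_bins`, `n_loci`, `mean_logratio`, `mean_allelic_ratio`.
#' @export
typed_segments <- function(model, layout) {
  bins <- layout$bins
  m <- model$map
  skey <- sprintf("c%da%d.%d", m$c, m$a, m$cluster)
  bin_key <- rep(NA_character_, nrow(bins))
  sp <- split(skey, m$bin)
  vals <- vapply(sp, function(kk) {
    if (length(kk) == 1L) return(kk)
    tab <- table(factor(kk, levels = unique(kk)))  # first-appearance tie-break
    names(tab)[which.max(tab)]
  }, character(1))
  bin_key[as.integer(names(sp))] <- vals
  # fill uncovered bins from the nearest preceding covered bin per chromosome
  for (ch in layout$chromosomes$name) {
    idx <- which(bins$chrom == ch)
    last <- NA_character_
    for (b in idx) {
      if (is.na(bin_key[b])) bin_key[b] <- last else last <- bin_key[b]
    }
    firstcov <- idx[which(!is.na(bin_key[idx]))[1]]
    if (!is.na(firstcov)) {
      for (b in idx) {
        if (is.na(bin_key[b])) bin_key[b] <- bin_key[firstcov] else break
      }
    }
  }
  if (anyNA(bin_key)) stop("chromosome with no assigned loci")

  segs <- list()
  for (ch in layout$chromosomes$name) {
    idx <- which(bins$chrom == ch)
    r <- rle(bin_key[idx])
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    for (j in seq_along(r$values)) {
      bs <- idx[start_i[j]]; be <- idx[stop_i[j]]
      key <- r$values[j]
      cc <- as.integer(sub("^c(\\d)a\\d\\.\\d+$", "\\1", key))
      aa <- as.integer(sub("^c\\da(\\d)\\.\\d+$", "\\1", key))
      zz <- as.integer(sub("^c\\da\\d\\.(\\d+)$", "\\1", key))
      inseg <- m$bin >= bs & m$bin <= be
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = bins$start[bs], end = bins$end[be],
        c = cc, a = aa, loh_label = loh_label_of(cc, aa),
        cnv_label = if (cc < 2) "HEMD" else if (cc == 2) "NEUT" else "AMP",
        cluster = zz, prevalence = model$clusters$prevalence[zz],
        n_bins = be - bs + 1L, n_loci = sum(inseg),
        mean_logratio = mean(model$loci$log_ratio[inseg], na.rm = TRUE),
        mean_allelic_ratio = if (any(inseg & !is.na(model$loci$depth)))
          sum(model$loci$ref_count[inseg], na.rm = TRUE) /
          sum(model$loci$depth[inseg], na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  class(out) <- c("ggn_typed_segments", "data.frame")
  out
}

#' Per-bin MAP total copy number profile
#'
#' Rasterizes typed segments to the layout's bins; the resulting equal-length
#' integer profiles of two lesions are the inputs to [cnv_correlation()].
#'
#' @param segments A `ggn_typed_segments` data.frame.
#' @param layout The shared `ggn_layout`.
#' @param what Column to rasterize (`"c"`, `"loh_label"` or `"cluster"`).
#' @return Vector of length `nrow(layout$bins)`.
#' @export
profile_from_segments <- function(segments, layout, what = "c") {
  bins <- layout$bins
  out <- rep(if (is.numeric(segments[[what]])) NA_real_ else NA_character_,
             nrow(bins))
  for (i in seq_len(nrow(segments))) {
    sel <- bins$chrom == segments$chrom[i] & bins$start >= segments$start[i] &
      bins$end <= segments$end[i]
    out[sel] <- segments[[what]][i]
  }
  out
}
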