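# deterministic loci sitting exactly on the emission means of a known truth:
# blocks of diploid HET, cluster-1 aberrations (s1) and cluster-2 aberrations
# (s2), with allele counts at round(depth * p)
exact_loci <- function(n_truth, s_truth, block = 50, depth = 1e4) {
  blocks <- list(list(c = 2, a = 1, z = 1), list(c = 3, a = 1, z = 1),
                 list(c = 1, a = 0, z = 1), list(c = 2, a = 1, z = 1),
                 list(c = 3, a = 2, z = 2), list(c = 2, a = 0, z = 2))
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    s <- s_truth[b$z]
    mu <- expected_logratio(b$c, s, n_truth)
    p <- expected_reffraction(b$c, b$a, s, n_truth)
    data.frame(chrom = "chr1",
               bin = (i - 1) * block + seq_len(block),
               pos = ((i - 1) * block + seq_len(block)) * 100,
               log_ratio = mu, ref_count = as.integer(round(depth * p)),
               depth = as.integer(depth),
               c = b$c, a = b$a, z = b$z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

one_hot_gamma <- function(loci, states, Z) {
  G <- nrow(states)
  gamma <- matrix(0, nrow(loci), G * Z)
  g <- match(sprintf("c%da%d", loci$c, loci$a), states$state)
  gamma[cbind(seq_len(nrow(loci)), (loci$z - 1) * G + g)] <- 1
  gamma
}

test_that("M-step recovers parameters from truth-concentrated responsibilities", {
  states <- enumerate_states()
  n0 <- 0.3; s0 <- c(0.9, 0.4)
  loci <- exact_loci(n0, s0)
  gamma <- one_hot_gamma(loci, states, 2)
  up <- m_step(loci, gamma, list(n = n0, s = s0, sigma = 1e-4), states)
  expect_equal(up$n, n0, tolerance = 1e-3)
  expect_equal(up$s, s0, tolerance = 1e-3)
  # and pulls a perturbed normal fraction back to the truth
  up2 <- m_step(loci, gamma, list(n = 0.35, s = s0, sigma = 1e-4), states)
  expect_equal(up2$n, n0, tolerance = 1e-3)
})

test_that("all-diploid data leaves the contamination unidentifiable, with warning", {
  states <- enumerate_states()
  loci <- exact_loci(0.3, c(0.9, 0.4))
  loci <- loci[loci$c == 2 & loci$a == 1, ]
  loci$z <- 1
  gamma <- one_hot_gamma(loci, states, 1)
  expect_warning(up <- m_step(loci, gamma, list(n = 0.3, s = 1, sigma = 0.1),
                              states),
                 "unidentifiable")
  expect_equal(up$n, 0.3)  # boundary-stable: left at its current value
})

test_that("a cluster with no responsibility is dropped with a warning", {
  states <- enumerate_states()
  loci <- exact_loci(0.3, c(0.9, 0.4))
  loci$z <- 1L                      # put every locus in cluster 1
  gamma <- one_hot_gamma(loci, states, 2)
  expect_warning(up <- m_step(loci, gamma, list(n = 0.3, s = c(0.9, 0.4),
                                                sigma = 1e-2), states),
                 "dropping empty cluster")
  expect_length(up$s, 1)
  expect_equal(up$dropped, 2L)
})

test_that("truth-initialized EM on noise-free data is a fixed point", {
  sim <- simulate_ggn_pair("parallel", c(0.9, 0.4), c(0.9, 0.4),
                           n_shared_events = 0, n_private_events = 4,
                           event_bins = 10, layout = make_genome(1, 1e7, 1e4),
                           n_het_sites = 500, normal_fraction = 0.3,
                           sigma = 0, het_depth = 1000, seed = 8)
  loci <- build_locus_grid(sim$obs$A$bins, sim$obs$A$het, sim$layout)
  fit <- fit_em(loci, n_clusters = 2,
                init = list(n = 0.3, s = c(0.9, 0.4), sigma = 1e-3),
                max_iter = 4)
  expect_equal(fit$n, 0.3, tolerance = 0.01)
  expect_equal(fit$clusters$prevalence, c(0.9, 0.4), tolerance = 0.01)
})

test_that("the EM log-likelihood trace never decreases", {
  sim <- simulate_ggn_pair("parallel", c(1, 0.3), c(1, 0.3),
                           n_shared_events = 0, n_private_events = 4,
                           event_bins = 15, layout = make_genome(1, 1e7, 1e4),
                           n_het_sites = 500, normal_fraction = 0.3, seed = 9)
  loci <- build_locus_grid(sim$obs$A$bins, sim$obs$A$het, sim$layout)
  fit <- fit_em(loci, n_clusters = 2)
  expect_gte(min(diff(fit$trace)), -1e-6 * abs(fit$loglik))
})

test_that("BIC selects the generative cluster count", {
  layout <- make_genome(1, 1e7, 1e4)
  one <- simulate_ggn_pair("parallel", 1, 1, n_shared_events = 0,
                           n_private_events = 6, event_bins = 20,
                           layout = layout, n_het_sites = 500, seed = 14)
  loci1 <- build_locus_grid(one$obs$A$bins, one$obs$A$het, layout)
  m1 <- select_n_clusters(loci1, z_max = 2)
  expect_equal(nrow(m1$clusters), 1)
  expect_equal(nrow(m1$bic_table), 2)

  two <- simulate_ggn_pair("parallel", c(1, 0.5), c(1, 0.5),
                           n_shared_events = 0, n_private_events = 6,
                           event_bins = 20, layout = layout,
                           n_het_sites = 500, seed = 15)
  loci2 <- build_locus_grid(two$obs$A$bins, two$obs$A$het, layout)
  m2 <- select_n_clusters(loci2, z_max = 3)
  expect_equal(nrow(m2$clusters), 2)
})

fake_model <- function(map, loci, s) {
  structure(list(map = map, loci = loci,
                 clusters = data.frame(id = seq_along(s), prevalence = s),
                 n = 0.3, sigma = 0.1), class = "ggn_clonal_model")
}

test_that("typed segments are maximal runs of constant genotype and cluster", {
  layout <- make_genome(1, 2e5, 1e4)  # 20 bins
  base <- data.frame(chrom = "chr1", bin = 1:20, pos = NA_integer_,
                     log_ratio = 0, ref_count = NA_integer_,
                     depth = NA_integer_, stringsAsFactors = FALSE)

  # all heterozygous diploid: one NEUT/HET segment for the chromosome
  map <- data.frame(chrom = "chr1", bin = 1:20, pos = NA, c = 2L, a = 1L,
                    loh_label = "HET", cnv_label = "NEUT", cluster = 1L)
  segs <- typed_segments(fake_model(map, base, 1), layout)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$loh_label, "HET")
  expect_equal(segs$n_bins, 20)

  # one GAIN block assigned to cluster 2
  map2 <- map
  map2[6:10, c("c", "a", "loh_label", "cnv_label", "cluster")] <-
    list(3L, 2L, "GAIN", "AMP", 2L)
  segs2 <- typed_segments(fake_model(map2, base, c(1, 0.5)), layout)
  expect_equal(nrow(segs2), 3)
  expect_equal(segs2$loh_label[2], "GAIN")
  expect_equal(segs2$cnv_label[2], "AMP")
  expect_equal(segs2$cluster[2], 2)
  expect_equal(segs2$prevalence[2], 0.5)
  expect_equal(c(segs2$start[2], segs2$end[2]), c(5e4, 1e5))
  # invariants: sorted, non-overlapping, covering
  expect_true(all(segs2$start[-1] == segs2$end[-3]))

  # alternating assignments: one segment per bin
  map3 <- map
  map3[seq(2, 20, 2), c("c", "a", "loh_label", "cnv_label")] <-
    list(3L, 2L, "GAIN", "AMP")
  expect_equal(nrow(typed_segments(fake_model(map3, base, 1), layout)), 20)

  # rasterization back to per-bin profiles
  prof <- profile_from_segments(segs2, layout, "c")
  expect_equal(prof, rep(c(2, 3, 2), c(5, 5, 10)))
})
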