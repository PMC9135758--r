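# hand-built typed segments on a 200-bin single-chromosome layout
lineage_layout <- make_genome(1, 2e6, 1e4)

mk_typed <- function(...) {
  segs <- do.call(rbind, lapply(list(...), function(x)
    data.frame(chrom = "chr1", start = x[[1]] * 1e4, end = x[[2]] * 1e4,
               c = x[[3]], a = x[[4]], loh_label = x[[5]],
               cnv_label = if (x[[3]] < 2) "HEMD" else
                 if (x[[3]] == 2) "NEUT" else "AMP",
               cluster = x[[6]], stringsAsFactors = FALSE)))
  class(segs) <- c("ggn_typed_segments", "data.frame")
  segs
}

test_that("Pearson correlation matches the textbook formula", {
  x <- c(1, 2, 3, 2, 5)
  expect_equal(cnv_correlation(x, x), 1)
  expect_equal(cnv_correlation(x, -x), -1)
  set.seed(19)
  for (i in 1:10) {
    a <- rnorm(100); b <- rnorm(100)
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cnv_correlation(a, b), r_direct, tolerance = 1e-12)
  }
  expect_error(cnv_correlation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(cnv_correlation(1:3, 1:4), "equal length")
})

test_that("feature sharing counts same-locus same-type aberrations", {
  # A: GAIN on bins 0..99 in cluster 2; B: GAIN on bins 50..149 in cluster 1
  A <- mk_typed(list(0, 100, 3, 1, "GAIN", 2), list(100, 200, 2, 1, "HET", 1))
  B <- mk_typed(list(0, 50, 2, 1, "HET", 1), list(50, 150, 3, 1, "GAIN", 1),
                list(150, 200, 2, 1, "HET", 1))
  sfr <- shared_feature_analysis(A, B, lineage_layout)
  pair <- sfr$pairs[sfr$pairs$cluster_A == 2 & sfr$pairs$cluster_B == 1, ]
  expect_equal(pair$n_shared, 50)
  expect_equal(pair$n_unique_A, 50)
  expect_equal(pair$n_unique_B, 50)
  expect_equal(pair$shared_fraction, 1 / 3)
  expect_equal(sfr$top$cluster_A, 2)

  # identical altered segments, single cluster: full sharing
  C <- mk_typed(list(0, 80, 2, 0, "NLOH", 1), list(80, 200, 2, 1, "HET", 1))
  repC <- shared_feature_analysis(C, C, lineage_layout)
  expect_equal(repC$top$shared_fraction, 1)

  # disjoint altered regions: zero sharing
  D <- mk_typed(list(100, 180, 2, 0, "NLOH", 1), list(0, 100, 2, 1, "HET", 1),
                list(180, 200, 2, 1, "HET", 1))
  repCD <- shared_feature_analysis(C, D, lineage_layout)
  expect_equal(max(repCD$pairs$shared_fraction), 0)

  # same locus but different aberration types does not count as shared
  E <- mk_typed(list(0, 80, 3, 1, "GAIN", 1), list(80, 200, 2, 1, "HET", 1))
  repCE <- shared_feature_analysis(C, E, lineage_layout)
  expect_equal(max(repCE$pairs$n_shared), 0)

  # all-diploid lesions: zero counts, top pair undefined
  H <- mk_typed(list(0, 200, 2, 1, "HET", 1))
  repH <- shared_feature_analysis(H, H, lineage_layout)
  expect_true(all(repH$pairs$n_shared == 0))
  expect_null(repH$top)
})

test_that("sharing is symmetric: swapping lesions transposes the matrix", {
  A <- mk_typed(list(0, 60, 3, 1, "GAIN", 1), list(60, 100, 1, 0, "DLOH", 2),
                list(100, 200, 2, 1, "HET", 1))
  B <- mk_typed(list(30, 90, 3, 1, "GAIN", 2), list(90, 200, 2, 1, "HET", 1),
                list(0, 30, 2, 2, "NLOH", 1))
  ab <- shared_feature_analysis(A, B, lineage_layout)$pairs
  ba <- shared_feature_analysis(B, A, lineage_layout)$pairs
  for (i in seq_len(nrow(ab))) {
    j <- which(ba$cluster_A == ab$cluster_B[i] & ba$cluster_B == ab$cluster_A[i])
    expect_equal(ba$n_shared[j], ab$n_shared[i])
    expect_equal(ba$n_unique_A[j], ab$n_unique_B[i])
    expect_equal(ba$n_unique_B[j], ab$n_unique_A[i])
  }
})

test_that("the lineage rule is the disjunction of correlation and sharing", {
  rep_hi <- list(top = data.frame(cluster_A = 1, cluster_B = 1,
                                  shared_fraction = 0.7))
  rep_lo <- list(top = data.frame(cluster_A = 1, cluster_B = 1,
                                  shared_fraction = 0))
  expect_equal(call_lineage(0.95, rep_lo)$verdict, "parallel")
  expect_equal(call_lineage(0.1, rep_lo)$verdict, "independent")
  # sharing alone suffices: a pair without global CNV similarity is still
  # parallel when a subclone pair shares its typed features
  expect_equal(call_lineage(0.3, rep_hi)$verdict, "parallel")
  # boundary behaviour: r strictly above, share at-or-above
  expect_equal(call_lineage(0.8, rep_lo)$verdict, "independent")
  expect_equal(call_lineage(0.1, list(top = data.frame(cluster_A = 1,
    cluster_B = 1, shared_fraction = 0.5)))$verdict, "parallel")
  expect_error(call_lineage(NA, list(top = NULL)), "manual review")
})

test_that("expected correlation grows with the founder event set", {
  layout <- make_genome(1, 1e7, 1e4)  # 1000 bins
  mean_r <- sapply(c(2, 8, 20), function(nshared) {
    mean(sapply(1:5, function(rep) {
      sim <- simulate_ggn_pair("parallel", 1, 1, n_shared_events = nshared,
                               n_private_events = 2, event_bins = 10,
                               layout = layout, n_het_sites = 100,
                               seed = 100 * nshared + rep)
      cnv_correlation(sim$obs$A$bins$log_ratio, sim$obs$B$bins$log_ratio)
    }))
  })
  expect_true(all(diff(mean_r) > 0))
})
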