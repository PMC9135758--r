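small_layout <- make_genome(2, 2e6, 1e4)  # 200 bins

test_that("parallel construction forces an identical founder event set", {
  trees <- simulate_clone_trees("parallel", 1, 1, n_shared_events = 5,
                                n_private_events = 0, layout = small_layout,
                                event_bins = 5, seed = 3)
  evA <- trees$A$events; evB <- trees$B$events
  expect_equal(nrow(evA), 5)
  expect_equal(evA[c("chrom", "start", "end", "c", "a")],
               evB[c("chrom", "start", "end", "c", "a")])
  expect_equal(event_jaccard(trees$A, trees$B), 1)
})

test_that("independent construction shares no events", {
  trees <- simulate_clone_trees("independent", 1, 1, n_shared_events = 0,
                                n_private_events = 5, layout = small_layout,
                                event_bins = 5, seed = 4)
  expect_equal(event_jaccard(trees$A, trees$B), 0)
  # stronger: genomic footprints are disjoint
  binsA <- unlist(mapply(seq, trees$A$events$bin_start, trees$A$events$bin_end))
  binsB <- unlist(mapply(seq, trees$B$events$bin_start, trees$B$events$bin_end))
  expect_length(intersect(binsA, binsB), 0)
  expect_error(simulate_clone_trees("independent", 1, 1, 2, 3,
                                    layout = small_layout, seed = 1))
})

test_that("minor subclones carry the founder events in the parallel scenario", {
  trees <- simulate_clone_trees("parallel", c(0.72, 0.28), c(0.74, 0.26),
                                n_shared_events = 10, n_private_events = 5,
                                layout = small_layout, event_bins = 2, seed = 5)
  key <- function(e) sprintf("%s:%d:%d/%d", e$chrom, e$start, e$c, e$a)
  shared_keys <- intersect(key(trees$A$events), key(trees$B$events))
  expect_length(shared_keys, 10)
  carA <- trees$A$events$carrier[key(trees$A$events) %in% shared_keys]
  carB <- trees$B$events$carrier[key(trees$B$events) %in% shared_keys]
  expect_true(all(carA == 2) && all(carB == 2))
  expect_equal(trees$A$subclones$prevalence[2], 0.28)
  expect_equal(trees$B$subclones$prevalence[2], 0.26)
  # Jaccard bound: shared / (shared + both lesions' private totals)
  expect_gte(event_jaccard(trees$A, trees$B), 10 / (10 + 2 * 2 * 5))
})

test_that("prevalence lists are validated", {
  expect_error(simulate_clone_trees("parallel", numeric(0), 1, 1, 1,
                                    layout = small_layout))
  expect_error(simulate_clone_trees("parallel", c(0.5, 0.9), 1, 1, 1,
                                    layout = small_layout),
               "sum to > 1")
  expect_error(simulate_clone_trees("parallel", c(0.5, 1.2), 1, 1, 1,
                                    layout = small_layout))
  # nested chain (non-increasing) may exceed sum 1
  expect_silent(simulate_clone_trees("parallel", c(1, 0.5), c(1, 0.5), 2, 1,
                                     layout = small_layout, event_bins = 2,
                                     seed = 2))
})

test_that("noise-free emissions sit exactly on the closed-form means", {
  # diploid everywhere: all log ratios are 0
  trees <- simulate_clone_trees("parallel", 1, 1, 0, 0,
                                layout = small_layout, seed = 6)
  truth <- ggn_truth(trees, normal_fraction = 0.3, sigma = 0, seed = 6)
  obs <- emit_observations(truth, small_layout, n_het_sites = 50)
  expect_true(all(obs$A$bins$log_ratio == 0))

  # clonal gain block: log ratio log2(2.7/2) inside, 0 outside
  st <- enumerate_states()
  gain <- st[st$c == 3 & st$a == 2, ]
  trees <- simulate_clone_trees("parallel", 1, 1, n_shared_events = 1,
                                n_private_events = 0, layout = small_layout,
                                event_bins = 20, event_states = gain, seed = 7)
  truth <- ggn_truth(trees, normal_fraction = 0.3, sigma = 0, seed = 7)
  obs <- emit_observations(truth, small_layout, n_het_sites = 50)
  ev <- trees$A$events
  inside <- seq(ev$bin_start, ev$bin_end)
  expect_equal(obs$A$bins$log_ratio[inside],
               rep(log2(2.7 / 2), 20), tolerance = 1e-12)
  expect_equal(unique(obs$A$bins$log_ratio[-inside]), 0)

  # emission means match the closed-form expectation for every catalog state
  for (i in seq_len(nrow(st))) {
    mu <- expected_logratio(st$c[i], 0.6, 0.3)
    expect_equal(log2((2 * 0.3 + 0.7 * (0.6 * st$c[i] + 0.4 * 2)) / 2), mu,
                 tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce the simulation exactly", {
  s1 <- simulate_ggn_pair("parallel", c(1, 0.5), c(1, 0.5), 4, 2,
                          event_bins = 5, layout = small_layout,
                          n_het_sites = 100, seed = 11)
  s2 <- simulate_ggn_pair("parallel", c(1, 0.5), c(1, 0.5), 4, 2,
                          event_bins = 5, layout = small_layout,
                          n_het_sites = 100, seed = 11)
  expect_identical(s1$obs, s2$obs)
  expect_identical(s1$truth$trees, s2$truth$trees)
})

test_that("het sites are valid, sorted, and shared between lesions", {
  sim <- simulate_ggn_pair("independent", 1, 1, 0, 3, event_bins = 5,
                           layout = small_layout, n_het_sites = 200, seed = 12)
  for (les in sim$obs) {
    h <- les$het
    expect_true(all(h$depth > 0))
    expect_true(all(h$ref_count >= 0 & h$ref_count <= h$depth))
    expect_false(is.unsorted(order(h$chrom, h$pos)))
  }
  expect_equal(sim$obs$A$het[c("chrom", "pos")], sim$obs$B$het[c("chrom", "pos")])
})
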