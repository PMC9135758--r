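# Synthetic paired-lesion generator: clone trees carrying CNV/LOH events under
# a parallel (single founding clone) or independent (two founders) scenario,
# with Gaussian depth log-ratio and binomial allele-count emissions.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

validate_prevalences <- function(s, lesion) {
  if (length(s) == 0) stop("prevalence list must be non-empty")
  if (any(s <= 0 | s > 1)) stop("prevalences must lie in (0, 1]")
  # siblings must sum to <= 1; a non-increasing list is read as a nested
  # chain (each subclone a descendant of the previous), which has no sum bound
  if (sum(s) > 1 && any(diff(s) > 0))
    stop("prevalences in lesion ", lesion, " sum to > 1 and are not nested")
  invisible(TRUE)
}

new_clone_tree <- function(prevalences, scenario, events) {
  k <- length(prevalences)
  nested <- sum(prevalences) > 1
  structure(list(
    subclones = data.frame(
      id = seq_len(k), prevalence = prevalences,
      parent = if (nested) c(NA_integer_, seq_len(k - 1L))
               else rep(NA_integer_, k)),
    scenario = scenario,
    events = events), class = "ggn_clone_tree")
}

# draw `n_events` non-overlapping bin-aligned intervals on `layout`, avoiding
# bins already marked TRUE in `occupied`; returns events data.frame
draw_events <- function(layout, n_events, event_bins, carrier, occupied,
                        state_pool, max_tries = 10000L) {
  bins <- layout$bins
  out <- vector("list", n_events)
  if (n_events == 0)
    return(list(events = empty_events(), occupied = occupied))
  for (i in seq_len(n_events)) {
    len <- if (length(event_bins) > 1)
      sample(seq(event_bins[1], event_bins[2]), 1) else event_bins
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      b0 <- sample(nrow(bins), 1)
      b1 <- b0 + len - 1L
      if (b1 > nrow(bins)) next
      if (bins$chrom[b0] != bins$chrom[b1]) next
      if (any(occupied[b0:b1])) next
      st <- state_pool[sample(nrow(state_pool), 1), ]
      out[[i]] <- data.frame(
        chrom = bins$chrom[b0], start = bins$start[b0], end = bins$end[b1],
        bin_start = b0, bin_end = b1, c = st$c, a = st$a,
        loh_label = st$loh_label, carrier = carrier,
        stringsAsFactors = FALSE)
      occupied[b0:b1] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place event without overlap; genome too full")
  }
  list(events = do.call(rbind, out), occupied = occupied)
}

empty_events <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             bin_start = integer(), bin_end = integer(), c = integer(),
             a = integer(), loh_label = character(), carrier = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate clone trees for a paired-lesion scenario
#'
#' Builds one clone tree per lesion. Under the `parallel` scenario a founder
#' event set is drawn once and planted in both lesions (carried by each
#' lesion's lowest-prevalence subclone, mirroring founder aberrations that
#' persist in a minor descendant subclone); each subclone additionally
#' receives private events. Under the `independent` scenario the two lesions'
#' event sets are drawn with disjoint genomic footprints, so no event is
#' shared. Events are bin-aligned intervals with genotype states drawn from
#' the non-HET catalog, rejection-sampled so that events within a lesion never
#' overlap.
#'
#' @param scenario `"parallel"` or `"independent"`.
#' @param prevalences_A,prevalences_B Cellular prevalences (fractions of tumor
#'   cells, each in (0,1]) of the subclones in lesion A / B. A non-increasing
#'   list summing to more than 1 is read as a nested chain of subclones;
#'   otherwise subclones are siblings and must sum to at most 1.
#' @param n_shared_events Founder events shared by both lesions (parallel
#'   scenario; must be 0 for independent).
#' @param n_private_events Private events per subclone per lesion.
#' @param layout A `ggn_layout`.
#' @param event_bins Event length in bins: a single value or `c(min, max)`.
#' @param event_states Optional subset of the state catalog (rows of
#'   [enumerate_states()]) to draw event genotypes from; default all non-HET
#'   states. May also be an unnamed list with one pool per subclone (pool
#'   `z` used for subclone `z`'s private events and, for the founder carrier,
#'   the shared events), e.g. to give a minor subclone one-copy-gain events
#'   only.
#' @param shared_event_bins Length of the founder (shared) events in bins;
#'   defaults to `event_bins`. Lets founder events span a large genome
#'   fraction while private events stay small.
#' @param seed Integer seed; same seed reproduces the trees exactly.
#' @return List with clone trees `A` and `B` (class `ggn_clone_tree`).
#' @export
simulate_clone_trees <- function(scenario = c("parallel", "independent"),
                                 prevalences_A, prevalences_B,
                                 n_shared_events, n_private_events,
                                 layout, event_bins = 50,
                                 event_states = NULL,
                                 shared_event_bins = event_bins,
                                 seed = NULL) {
  scenario <- match.arg(scenario)
  validate_prevalences(prevalences_A, "A")
  validate_prevalences(prevalences_B, "B")
  if (scenario == "independent" && n_shared_events > 0)
    stop("independent scenario admits no shared events")
  default_pool <- {
    st <- enumerate_states()
    st[st$loh_label != "HET", ]
  }
  pool_of <- function(z) {
    if (is.null(event_states)) return(default_pool)
    if (is.data.frame(event_states)) return(event_states)
    if (z <= length(event_states) && !is.null(event_states[[z]]))
      return(event_states[[z]])
    default_pool
  }

  with_local_seed(seed, {
    nb <- nrow(layout$bins)
    if (scenario == "parallel") {
      occ <- rep(FALSE, nb)
      sh <- draw_events(layout, n_shared_events, shared_event_bins,
                        carrier = length(prevalences_A), occ, pool_of(length(prevalences_A)))
      shared <- sh$events
      evA <- list(events = shared, occupied = sh$occupied)
      # same founder events in B, carried by B's minor subclone
      sharedB <- shared
      if (nrow(sharedB)) sharedB$carrier <- length(prevalences_B)
      evB <- list(events = sharedB, occupied = sh$occupied)
      for (z in seq_along(prevalences_A)) {
        pr <- draw_events(layout, n_private_events, event_bins, z,
                          evA$occupied, pool_of(z))
        evA <- list(events = rbind(evA$events, pr$events),
                    occupied = pr$occupied)
      }
      occB <- sh$occupied
      for (z in seq_along(prevalences_B)) {
        pr <- draw_events(layout, n_private_events, event_bins, z, occB, pool_of(z))
        occB <- pr$occupied
        evB$events <- rbind(evB$events, pr$events)
      }
      A <- new_clone_tree(prevalences_A, scenario, evA$events)
      B <- new_clone_tree(prevalences_B, scenario, evB$events)
    } else {
      occ <- rep(FALSE, nb)  # one footprint shared by both lesions ->
      evA <- empty_events()  # cross-lesion overlap impossible by construction
      for (z in seq_along(prevalences_A)) {
        pr <- draw_events(layout, n_private_events, event_bins, z, occ, pool_of(z))
        occ <- pr$occupied
        evA <- rbind(evA, pr$events)
      }
      evB <- empty_events()
      for (z in seq_along(prevalences_B)) {
        pr <- draw_events(layout, n_private_events, event_bins, z, occ, pool_of(z))
        occ <- pr$occupied
        evB <- rbind(evB, pr$events)
      }
      A <- new_clone_tree(prevalences_A, scenario, evA)
      B <- new_clone_tree(prevalences_B, scenario, evB)
    }
    list(A = A, B = B)
  })
}

#' Assemble the generative truth for a simulated lesion pair
#'
#' @param trees List with clone trees `A` and `B` from
#'   [simulate_clone_trees()].
#' @param normal_fraction Normal-cell contamination fraction n in \[0, 1).
#' @param sigma Depth log-ratio emission SD (log2 units).
#' @param het_depth Mean sequencing depth at heterozygous SNP sites.
#' @param seed Seed recorded with the truth (used by [emit_observations()]).
#' @return A `ggn_truth` object.
#' @export
ggn_truth <- function(trees, normal_fraction = 0.3, sigma = 0.15,
                      het_depth = 30, seed = NULL) {
  stopifnot(normal_fraction >= 0, normal_fraction < 1, sigma >= 0,
            het_depth > 0)
  structure(list(trees = trees, normal_fraction = normal_fraction,
                 sigma = sigma, het_depth = het_depth, seed = seed),
            class = "ggn_truth")
}

# per-bin (c, a, s, carrier) for one lesion's tree on a layout
bin_truth_states <- function(tree, layout) {
  nb <- nrow(layout$bins)
  st <- data.frame(c = rep(2L, nb), a = rep(1L, nb), s = rep(1, nb),
                   carrier = rep(NA_integer_, nb))
  ev <- tree$events
  if (nrow(ev)) for (i in seq_len(nrow(ev))) {
    idx <- ev$bin_start[i]:ev$bin_end[i]
    st$c[idx] <- ev$c[i]
    st$a[idx] <- ev$a[i]
    st$s[idx] <- tree$subclones$prevalence[ev$carrier[i]]
    st$carrier[idx] <- ev$carrier[i]
  }
  st
}

#' Emit depth and allele-count observations from a simulated truth
#'
#' For every layout bin the depth log ratio is drawn as Normal with mean equal
#' to the closed-form expected log ratio of the bin's true genotype state at
#' its carrier's prevalence and the sample's normal fraction ([expected_logratio()]),
#' and SD `truth$sigma`. Heterozygous SNP sites are placed uniformly over the
#' genome (the same germline sites in both lesions), given Poisson depths with
#' mean `truth$het_depth` (truncated at 1), and reference-allele counts drawn
#' Binomial with success probability from [expected_reffraction()].
#'
#' @param truth A `ggn_truth`.
#' @param layout The `ggn_layout` the truth was simulated on.
#' @param n_het_sites Number of germline heterozygous SNP sites.
#' @param seed Seed; defaults to the seed stored in `truth`. Identical inputs
#'   and seed give bit-identical output.
#' @return A list with one element per lesion (`A`, `B`), each containing
#'   `bins` (data.frame `chrom`, `start`, `end`, `bin`, `log_ratio`) and
#'   `het` (data.frame `chrom`, `pos`, `ref_count`, `depth`, sorted).
#' @export
emit_observations <- function(truth, layout, n_het_sites = 5000,
                              seed = truth$seed) {
  stopifnot(inherits(truth, "ggn_truth"), n_het_sites > 0)
  with_local_seed(seed, {
    bins <- layout$bins
    # shared germline het positions
    totlen <- sum(layout$chromosomes$length)
    offs <- cumsum(c(0, head(layout$chromosomes$length, -1)))
    gpos <- sort(sample.int(totlen, n_het_sites))
    ci <- findInterval(gpos - 1, offs)
    hpos <- data.frame(chrom = layout$chromosomes$name[ci],
                       pos = gpos - offs[ci], stringsAsFactors = FALSE)
    hpos$bin <- bin_of_position(layout, hpos$chrom, hpos$pos)

    lapply(truth$trees, function(tree) {
      st <- bin_truth_states(tree, layout)
      n <- truth$normal_fraction
      mu <- expected_logratio(st$c, st$s, n)
      lr <- stats::rnorm(nrow(bins), mean = mu, sd = truth$sigma)
      bd <- data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, bin = bins$bin, log_ratio = lr,
                       stringsAsFactors = FALSE)
      p <- expected_reffraction(st$c[hpos$bin], st$a[hpos$bin],
                                st$s[hpos$bin], n)
      bad <- !is.finite(p)
      if (any(bad)) {
        warning(sum(bad), " het site(s) in zero-copy regions excluded")
      }
      depth <- pmax(1L, stats::rpois(nrow(hpos), truth$het_depth))
      ref <- stats::rbinom(nrow(hpos), depth, ifelse(bad, 0.5, p))
      het <- data.frame(chrom = hpos$chrom, pos = hpos$pos,
                        ref_count = ref, depth = depth,
                        stringsAsFactors = FALSE)[!bad, ]
      list(bins = bd, het = het)
    })
  })
}

#' Simulate a complete paired-lesion dataset
#'
#' Convenience wrapper tying together [make_genome()],
#' [simulate_clone_trees()], [ggn_truth()] and [emit_observations()]. The
#' defaults are the package's reference simulation: 2 chromosomes of 50 Mb in
#' 10 kb bins, 5,000 heterozygous sites at mean depth 30, depth noise
#' sigma = 0.15 and 30% normal contamination.
#'
#' @inheritParams simulate_clone_trees
#' @inheritParams ggn_truth
#' @param layout Genome layout; default 2 x 50 Mb, 10 kb bins.
#' @param n_het_sites Heterozygous SNP sites per lesion.
#' @param seed Integer seed driving trees and emissions.
#' @return List with `layout`, `truth`, and `obs` (per-lesion observations as
#'   in [emit_observations()]).
#' @examples
#' sim <- simulate_ggn_pair("parallel", seed = 1,
#'                          layout = make_genome(1, 5e6, 1e4),
#'                          n_het_sites = 200)
#' @export
simulate_ggn_pair <- function(scenario = c("parallel", "independent"),
                              prevalences_A = 1, prevalences_B = 1,
                              n_shared_events = 10, n_private_events = 3,
                              event_bins = 50,
                              layout = make_genome(2, 5e7, 1e4),
                              n_het_sites = 5000, normal_fraction = 0.3,
                              sigma = 0.15, het_depth = 30,
                              event_states = NULL,
                              shared_event_bins = event_bins, seed = NULL) {
  scenario <- match.arg(scenario)
  trees <- simulate_clone_trees(scenario, prevalences_A, prevalences_B,
                                n_shared_events, n_private_events, layout,
                                event_bins, event_states, shared_event_bins,
                                seed = seed)
  truth <- ggn_truth(trees, normal_fraction, sigma, het_depth, seed = seed)
  obs <- emit_observations(truth, layout, n_het_sites,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  list(layout = layout, truth = truth, obs = obs)
}

#' Jaccard index of two lesions' event sets
#'
#' Events are identified by (chrom, start, end, c, a); used to verify the
#' construction of the parallel (shared founder) and independent scenarios.
#'
#' @param tree_A,tree_B `ggn_clone_tree` objects.
#' @return Jaccard index in \[0, 1\] (0 when both are empty).
#' @export
event_jaccard <- function(tree_A, tree_B) {
  key <- function(e) if (nrow(e)) sprintf("%s:%d-%d:%d/%d", e$chrom,
    as.integer(e$start), as.integer(e$end), e$c, e$a) else character()
  a <- unique(key(tree_A$events)); b <- unique(key(tree_B$events))
  if (!length(a) && !length(b)) return(0)
  length(intersect(a, b)) / length(union(a, b))
}
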