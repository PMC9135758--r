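# Format boundaries: VCF 4.2 het-site tables, fixed-step WIG log-ratio
# tracks, SEG segment files (1-based inclusive on disk, 0-based half-open in
# memory), TSV matrices/truth tables and YAML manifests/summaries.

#' Write heterozygous SNP sites as VCF 4.2
#'
#' One tumor sample with `AD` (ref,alt depths) and `DP` per-sample fields.
#' REF/ALT bases are placeholders (A/C): only the counts are data.
#'
#' @param het data.frame with `chrom`, `pos` (1-based), `ref_count`, `depth`.
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_het_vcf <- function(het, path, sample = "tumor") {
  stopifnot(all(het$ref_count >= 0), all(het$ref_count <= het$depth),
            all(het$depth > 0))
  hdr <- c("##fileformat=VCFv4.2",
    "##source=ggnclone",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- sprintf("%s\t%d\t.\tA\tC\t.\tPASS\t.\tAD:DP\t%d,%d:%d",
                  het$chrom, as.integer(het$pos), as.integer(het$ref_count),
                  as.integer(het$depth - het$ref_count), as.integer(het$depth))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read heterozygous SNP sites from a VCF
#'
#' Retains biallelic SNVs with total allele depth at or above `min_depth`;
#' multiallelic or non-SNV records are excluded with a warning and records
#' lacking an AD field raise a format error naming the record.
#'
#' @param path VCF 4.x path with a per-sample AD (ref,alt) field.
#' @param min_depth Minimum retained site depth.
#' @return data.frame `chrom`, `pos`, `ref_count`, `depth`, sorted by
#'   (chrom, pos); exclusion counts in attributes `n_excluded_depth` and
#'   `n_excluded_multiallelic`.
#' @export
read_het_vcf <- function(path, min_depth = 10) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files come back as a vector
  if (nrow(fix) == 0) stop("no records in ", path)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || all(is.na(ad)))
    stop("format error: no AD field in ", path)
  ad <- ad[, 1]
  biallelic <- vcfR::is.biallelic(v) & nchar(fix[, "REF"]) == 1 &
    !grepl(",", fix[, "ALT"]) & nchar(fix[, "ALT"]) == 1
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    warning(n_multi, " multiallelic/non-SNV record(s) excluded")
  if (anyNA(ad[biallelic])) {
    bad <- which(biallelic & is.na(ad))[1]
    stop(sprintf("format error: record %s:%s has no AD value",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  counts <- do.call(rbind, lapply(strsplit(ad[biallelic], ","),
                                  function(x) as.integer(x[1:2])))
  out <- data.frame(chrom = fix[biallelic, "CHROM"],
                    pos = as.integer(fix[biallelic, "POS"]),
                    ref_count = counts[, 1],
                    depth = counts[, 1] + counts[, 2],
                    stringsAsFactors = FALSE)
  deep <- out$depth >= min_depth
  n_shallow <- sum(!deep)
  out <- out[deep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_depth") <- n_shallow
  attr(out, "n_excluded_multiallelic") <- n_multi
  out
}

#' Write a fixed-step WIG log-ratio track
#'
#' One `fixedStep` block per chromosome with start 1 and step/span equal to
#' the layout's bin size.
#'
#' @param bins data.frame `chrom`, `start`, `end`, `log_ratio` covering all
#'   layout bins in order.
#' @param path Output path.
#' @param layout The `ggn_layout`.
#' @return `path`, invisibly.
#' @export
write_wig <- function(bins, path, layout) {
  stopifnot(nrow(bins) == nrow(layout$bins))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in layout$chromosomes$name) {
    sel <- bins$chrom == ch
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, as.integer(layout$bin_size),
                       as.integer(layout$bin_size)), con)
    writeLines(sprintf("%.6f", bins$log_ratio[sel]), con)
  }
  invisible(path)
}

#' Read a fixed-step WIG log-ratio track onto a layout
#'
#' The track's step must equal the layout's bin size (format error
#' otherwise). Bins without a value (truncated chromosomes) are NA with a
#' warning; downstream stages treat NA log ratios as missing emissions.
#'
#' @param path WIG path.
#' @param layout The `ggn_layout` to index values on.
#' @return data.frame `chrom`, `start`, `end`, `bin`, `log_ratio`.
#' @export
read_wig <- function(path, layout) {
  heads <- grep("^fixedStep", readLines(path), value = TRUE)
  if (length(heads) == 0) stop("format error: not a fixedStep WIG: ", path)
  steps <- as.integer(sub(".*step=(\\d+).*", "\\1", heads))
  if (any(steps != layout$bin_size))
    stop(sprintf("format error: WIG step %d does not match layout bin size %d",
                 steps[which(steps != layout$bin_size)[1]],
                 as.integer(layout$bin_size)))
  g <- rtracklayer::import(path, format = "wig")
  out <- layout$bins
  out$log_ratio <- NA_real_
  ch <- as.character(GenomicRanges::seqnames(g))
  st <- GenomicRanges::start(g) - 1L   # to 0-based
  en <- GenomicRanges::end(g)
  sc <- GenomicRanges::mcols(g)$score
  for (i in seq_along(sc)) {
    b0 <- bin_of_position(layout, ch[i], st[i] + 1L)
    b1 <- bin_of_position(layout, ch[i], en[i])
    if (is.na(b0) || is.na(b1)) next
    out$log_ratio[b0:b1] <- sc[i]
  }
  if (anyNA(out$log_ratio))
    warning(sum(is.na(out$log_ratio)), " layout bin(s) missing from WIG; NA-padded")
  out
}

#' Write segments as a SEG file
#'
#' IGV SEG dialect: 1-based inclusive coordinates on disk (internal
#' representation stays 0-based half-open). Depth-CNV segments add a `call`
#' column; typed segments add genotype, LOH/CNV labels, cluster and
#' prevalence.
#'
#' @param segments A `ggn_cnv_segments` or `ggn_typed_segments` data.frame.
#' @param path Output path.
#' @param sample Sample identifier for the ID column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  df <- as.data.frame(segments)
  base <- data.frame(ID = sample, chrom = df$chrom,
                     loc.start = as.integer(df$start) + 1L,
                     loc.end = as.integer(df$end),
                     num.mark = if (!is.null(df$n_bins)) df$n_bins else NA,
                     stringsAsFactors = FALSE)
  if (!is.null(df$call)) {            # depth-CNV segments
    base$seg.mean <- sprintf("%.6f", df$median_logratio)
    base$call <- df$call
  } else {                            # typed segments
    base$seg.mean <- sprintf("%.6f", df$mean_logratio)
    base$c <- df$c; base$a <- df$a
    base$loh_label <- df$loh_label; base$cnv_label <- df$cnv_label
    base$cluster <- df$cluster
    base$prevalence <- sprintf("%.6f", df$prevalence)
    base$allelic_ratio <- sprintf("%.6f", df$mean_allelic_ratio)
    base$n_loci <- df$n_loci
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#'
#' @param path SEG path.
#' @return data.frame with 0-based half-open `start`/`end` and whatever
#'   typed/call columns the file carries.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end")
  if (!all(need %in% names(df)))
    stop("format error: not a SEG file: ", path)
  df$start <- df$loc.start - 1L
  df$end <- df$loc.end
  df$loc.start <- NULL; df$loc.end <- NULL
  if (!is.null(df$n_loci)) class(df) <- c("ggn_typed_segments", "data.frame")
  if (!is.null(df$call)) class(df) <- c("ggn_cnv_segments", "data.frame")
  if (!is.null(df$num.mark)) df$n_bins <- df$num.mark
  df
}

#' Write a simulated paired-lesion dataset as a fixture directory
#'
#' Emits per-lesion VCF (het sites) and WIG (log ratios), a truth TSV
#' (scenario, normal fraction, subclone prevalences, noise, seed), an event
#' TSV, and a YAML manifest tying everything together. Writing the same
#' simulation twice gives byte-identical files.
#'
#' @param sim Result of [simulate_ggn_pair()].
#' @param out_dir Output directory (created if missing).
#' @param patient Patient identifier used in the manifest.
#' @return Path of the YAML manifest, invisibly.
#' @export
write_fixture <- function(sim, out_dir, patient = "P1") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  lesions <- names(sim$obs)
  files <- lapply(lesions, function(lab) {
    vcf <- file.path(out_dir, paste0(patient, "_", lab, ".vcf"))
    wig <- file.path(out_dir, paste0(patient, "_", lab, ".wig"))
    write_het_vcf(sim$obs[[lab]]$het, vcf, sample = paste0(patient, "_", lab))
    write_wig(sim$obs[[lab]]$bins, wig, sim$layout)
    list(label = lab, vcf = basename(vcf), wig = basename(wig))
  })

  truth <- do.call(rbind, lapply(lesions, function(lab) {
    tr <- sim$truth$trees[[lab]]
    data.frame(lesion = lab, subclone = tr$subclones$id,
               prevalence = tr$subclones$prevalence,
               parent = tr$subclones$parent,
               scenario = tr$scenario,
               normal_fraction = sim$truth$normal_fraction,
               sigma = sim$truth$sigma, het_depth = sim$truth$het_depth,
               seed = if (is.null(sim$truth$seed)) NA else sim$truth$seed,
               stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(out_dir, paste0(patient, "_truth.tsv"))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  events <- do.call(rbind, lapply(lesions, function(lab) {
    ev <- sim$truth$trees[[lab]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(lesion = lab, ev)
  }))
  events_path <- file.path(out_dir, paste0(patient, "_truth_events.tsv"))
  utils::write.table(events, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    patient = patient,
    normal = "normal",
    lesions = files,
    truth = basename(truth_path),
    truth_events = basename(events_path),
    genome = list(
      chromosomes = as.list(stats::setNames(
        as.integer(sim$layout$chromosomes$length),
        sim$layout$chromosomes$name)),
      bin_size = as.integer(sim$layout$bin_size)),
    parameters = list(
      scenario = sim$truth$trees[[1]]$scenario,
      normal_fraction = sim$truth$normal_fraction,
      sigma = sim$truth$sigma, het_depth = sim$truth$het_depth,
      n_het_sites = sum(!is.na(sim$obs[[1]]$het$pos)),
      seed = if (is.null(sim$truth$seed)) NA else sim$truth$seed))
  mpath <- file.path(out_dir, paste0(patient, "_manifest.yaml"))
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Load a fixture manifest
#'
#' Validates that every referenced file exists and that lesion labels are
#' unique, and reconstructs the genome layout.
#'
#' @param path Manifest YAML path.
#' @return List with the manifest fields plus `layout` (a `ggn_layout`) and
#'   absolute file paths.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  labs <- vapply(m$lesions, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate lesion labels in manifest")
  for (les in m$lesions) {
    for (f in c(les$vcf, les$wig)) {
      if (!file.exists(file.path(dir, f)))
        stop("manifest references missing file: ", f)
    }
  }
  lens <- unlist(m$genome$chromosomes)
  m$layout <- make_genome(stats::setNames(as.numeric(lens), names(lens)),
                          bin_size = m$genome$bin_size)
  m$dir <- dir
  m
}

#' Write a fitted clonal model summary as YAML
#'
#' @param model A `ggn_clonal_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(list(
    normal_fraction = model$n,
    clusters = lapply(seq_len(nrow(model$clusters)), function(i)
      list(id = model$clusters$id[i],
           prevalence = model$clusters$prevalence[i])),
    sigma = model$sigma, log_likelihood = model$loglik,
    n_clusters = nrow(model$clusters), n_iterations = model$n_iterations,
    converged = model$converged, n_loci = model$n_loci), path)
  invisible(path)
}

# --- run log -----------------------------------------------------------------

#' Create a pipeline run log
#'
#' An environment collecting timestamped stage records, a full parameter
#' echo, and warnings (dropped clusters, excluded sites). Exactly one log is
#' written per pipeline run.
#'
#' @param params Named list of every configurable parameter of the run.
#' @return A `ggn_runlog` environment.
#' @export
new_runlog <- function(params = list()) {
  e <- new.env(parent = emptyenv())
  e$version <- as.character(utils::packageVersion("ggnclone"))
  e$started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  e$params <- params
  e$stages <- list()
  e$warnings <- character(0)
  class(e) <- "ggn_runlog"
  e
}

#' Record a stage or a warning in a run log
#'
#' @param log A `ggn_runlog`.
#' @param stage Stage name.
#' @param message Free-text record.
#' @param warning Logical; record under warnings too.
#' @return The log, invisibly.
#' @export
log_stage <- function(log, stage, message = "", warning = FALSE) {
  log$stages[[length(log$stages) + 1L]] <-
    list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         stage = stage, message = message)
  if (warning) log$warnings <- c(log$warnings, paste0(stage, ": ", message))
  invisible(log)
}

#' Write a run log as YAML
#'
#' @param log A `ggn_runlog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_runlog <- function(log, path) {
  yaml::write_yaml(list(software = "ggnclone", version = log$version,
                        started = log$started, parameters = log$params,
                        stages = log$stages,
                        warnings = as.list(log$warnings)), path)
  invisible(path)
}
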