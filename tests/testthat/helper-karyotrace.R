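# shared fixtures: all data are generated in code, desk-scale

tiny_genome <- function(lengths = c(chr1 = 40e6, chr2 = 30e6, chr3 = 20e6),
                        spacing = 2e4) {
  toy_genome(lengths, snp_spacing = spacing)
}

deep_cov <- function(bin_size = 2e4, ...) {
  coverage_model(mean_depth = 9.45, bin_size = bin_size, ...)
}

lowpass_cov <- function(bin_size = 2e4, ...) {
  coverage_model(mean_depth = 0.15, bin_size = bin_size, ...)
}

# wrap a bare matrix as a cn_matrix on one chromosome
as_cn_matrix <- function(m, chrom = "chr1", bin_size = 1e5,
                         mask = rep(FALSE, nrow(m))) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  bins <- data.frame(chrom = chrom,
                     start = (seq_len(nrow(m)) - 1) * bin_size,
                     end = seq_len(nrow(m)) * bin_size)
  structure(list(bins = bins, cn = m, mask = mask, bin_size = bin_size),
            class = "cn_matrix")
}

# a six-row SV candidate fixture exercising every per-call filter
sv_fixture <- function() {
  data.frame(
    id = paste0("sv", 1:6),
    chromA = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    posA = c(10e6, 10e6, 10e6, 10e6, 10e6, 5e6),
    strandA = "+",
    chromB = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr3"),
    posB = c(12e6, 12e6, 12e6, 10.8e6, 11.2e6, 5e6),
    strandB = "-",
    n_reads = c(5, 2, 3, 6, 6, 8),
    max_mapq = c(60, 60, 30, 60, 60, 31),
    in_strain_background = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# exhaustive least-squares segmentation oracle for short vectors:
# minimizes RSS + penalty * (number of breakpoints) over every breakpoint
# set respecting the minimum segment width; independent of the CBS code
oracle_breakpoints <- function(x, penalty, min_width = 2) {
  n <- length(x)
  stopifnot(n <= 14)
  best <- integer(0)
  best_cost <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bps <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    edges <- c(0, bps, n)
    if (any(diff(edges) < min_width)) next
    rss <- 0
    for (k in seq_len(length(edges) - 1)) {
      seg <- x[(edges[k] + 1):edges[k + 1]]
      rss <- rss + sum((seg - mean(seg))^2)
    }
    cost <- rss + penalty * length(bps)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- bps
    }
  }
  best
}

cbs_breakpoints <- function(x, ...) {
  norm <- as_cn_matrix(matrix(x, ncol = 1))
  seg <- segment_cn(norm, ...)
  if (nrow(seg) < 2) return(integer(0))
  cumsum(seg$n_bins)[-nrow(seg)]
}

# the cross-specific SNP panel is known in simulation (it is an input of
# the generator); panel *selection* from cohort data is tested separately
true_panel <- function(genome) {
  data.frame(chrom = genome$snps$chrom, pos = genome$snps$pos,
             median_vaf = 0.5, n_covered = NA_integer_, kept = TRUE,
             stringsAsFactors = FALSE)
}

# run the full analysis chain on one simulated embryo; `ref_counts`
# (bin counts of euploid reference cells) stands in for the cohort when
# estimating the per-locus coverage median, so that events shared by all
# 8 blastomeres are not normalized away
analyze_embryo <- function(sim, cn_bin = 5e5, site = NULL,
                           chrom_lengths = NULL, half_copy_tol = 0.15,
                           granular_bin = 1e5, panel = NULL,
                           ref_counts = NULL) {
  counts <- if (granular_bin > sim$counts$bin_size)
    rebin(sim$counts, granular_bin) else sim$counts
  norm <- suppressMessages(normalize_depth(counts))
  if (is.null(ref_counts)) {
    agg <- aggregate_bins(norm, cn_bin)
  } else {
    rc <- if (granular_bin > ref_counts$bin_size)
      rebin(ref_counts, granular_bin) else ref_counts
    agg <- aggregate_bins(norm, cn_bin, cross_sample_median = FALSE)
    ref_agg <- aggregate_bins(suppressMessages(normalize_depth(rc)),
                              cn_bin, cross_sample_median = FALSE)
    bin_med <- apply(ref_agg$cn, 1, stats::median, na.rm = TRUE)
    bin_med[!is.finite(bin_med) | bin_med == 0] <- 1
    agg$cn <- sweep(agg$cn, 1, bin_med, "/")
  }
  if (is.null(panel)) panel <- true_panel(sim$truth$genome)
  bv <- bin_vaf(sim$allelic, panel, agg$bins)
  ploidy <- suppressMessages(estimate_ploidy(bv))
  hap <- compute_haplotype_cn(bv, agg, ploidy)
  segs <- segment_cn(agg)
  hseg <- annotate_haplotype_segments(segs, hap)
  hseg <- detect_half_copy_segments(hseg, tol = half_copy_tol)
  if (is.null(chrom_lengths)) {
    g <- sim$truth$genome
    chrom_lengths <- stats::setNames(g$chroms$length, g$chroms$name)
  }
  events <- classify_embryo(hseg, site, ploidy, chrom_lengths)
  list(norm = norm, agg = agg, panel = panel, bv = bv, ploidy = ploidy,
       hap = hap, hseg = hseg, events = events)
}

# did the analysis recover the single planted event (class + haplotype)?
recovered_event <- function(events, spec) {
  cls <- spec$event_class
  if (cls == "none") return(nrow(events) == 0)
  hit <- switch(cls,
    acentric_missegregation = events$event_class == "reciprocal_gain_loss" &
      events$chrom == spec$chrom & events$haplotype == spec$haplotype &
      !is.na(events$group),
    whole_chromosome_missegregation =
      events$event_class %in% c("whole_chromosome_monosomy",
                                "whole_chromosome_trisomy") &
      events$chrom == spec$chrom & events$haplotype == spec$haplotype,
    micronucleus_underreplication =
      events$event_class == "half_copy_micronucleus" &
      events$chrom == spec$chrom & events$haplotype == spec$haplotype,
    bridge_monosomy = events$event_class == "bridge_monosomy" &
      events$chrom == spec$chrom & events$haplotype == spec$haplotype,
    meiotic_trisomy = events$event_class == "meiotic_trisomy" &
      events$chrom == spec$chrom & events$haplotype == spec$haplotype,
    digyny = events$event_class == "digyny")
  any(hit)
}
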