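.default_config <- function() {
  list(
    seed = 1,
    outdir = NULL,
    embryo = "E1",
    genome = list(chrom_lengths = c(chr1 = 120e6, chr2 = 80e6, chr3 = 50e6),
                  snp_spacing = 10e3),
    simulate = list(events = list(), phase = "G1", mother_index = 1),
    coverage = list(mean_depth = 9.45, dispersion = 0.02, bin_size = 10e3,
                    repli_bias_strength = 0),
    analysis = list(
      granular_bin = 50e3,          # most granular CN level
      cn_bin = 250e3,               # analysis resolution
      platform = "deep",
      low_coverage_frac = 0.25, low_coverage_sample_frac = 0.80,
      mad_thresholds = c(low_pass = 0.15, deep = 0.3),
      vaf_window = c(0.40, 0.60), min_covered = 3,
      micro_bin = 5e3,
      triploid_window = c(2.5, 3.5),
      half_copy_tol = 0.15,
      cbs = list(alpha = 0.01, nperm = 1000, min_width = 2,
                 method = "gaussian"),
      loess_span = 0.3,
      sv = list(min_reads = 3, min_mapq = 30, min_distance = 1e6,
                presence_threshold = 1),
      target_site = NULL))
}

.merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])) && k != "events" &&
        k != "chrom_lengths" && k != "target_site") {
      base[[k]] <- .merge_config(base[[k]], user[[k]],
                                 paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys raise an error naming the key; missing keys take the
#' documented defaults (native 10 kb bins, 50 kb granular / 250 kb
#' analysis resolution, 25%/80% bin exclusion, MAD 0.15/0.3, VAF window
#' 40-60%, triploid window 2.5-3.5 with x1.5 correction, SV filters >= 3
#' reads / MAPQ > 30 / > 1 Mb, half-copy tolerance 0.15).
#'
#' @param config named list, or path to a YAML file.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  if (!is.null(cfg$genome$chrom_lengths))
    cfg$genome$chrom_lengths <- unlist(cfg$genome$chrom_lengths)
  cfg
}

#' Run the full simulation-to-events pipeline
#'
#' Simulates an embryo under the configured genome, events and coverage,
#' then runs every analysis stage in the fixed order: re-binning,
#' median normalization with bin exclusion, aggregation with cross-sample
#' median division, replication-timing correction (when a bias is
#' configured), sample QC, SNP panel selection, bin-level VAF, ploidy
#' estimation, haplotype CN, segmentation, haplotype annotation, half-copy
#' flagging, SV filtering/joint genotyping, and event classification.
#' Re-running with the same config reproduces identical tables.
#'
#' @param config a list or YAML path accepted by [pipeline_config()].
#' @return (invisibly) a result bundle: config, truth, qc, ploidy,
#'   haplotype CN, segments, events, SVs and the manifest. Tables are
#'   written under `config$outdir` when set.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  an <- cfg$analysis
  genome <- genome_model(cfg$genome$chrom_lengths,
                         snp_spacing = cfg$genome$snp_spacing)
  events <- lapply(cfg$simulate$events, function(e) do.call(event_spec, e))
  cov <- coverage_model(mean_depth = cfg$coverage$mean_depth,
                        dispersion = cfg$coverage$dispersion,
                        bin_size = cfg$coverage$bin_size,
                        repli_bias_strength = cfg$coverage$repli_bias_strength)
  sim <- simulate_embryo(genome, events, cov, phase = cfg$simulate$phase,
                         mother_index = cfg$simulate$mother_index,
                         seed = cfg$seed)

  counts <- rebin(sim$counts, an$granular_bin)
  norm <- normalize_depth(counts, an$low_coverage_frac,
                          an$low_coverage_sample_frac)
  agg <- aggregate_bins(norm, an$cn_bin)
  if (cfg$coverage$repli_bias_strength != 0) {
    track <- simulate_repliseq_track(genome, bin_size = cfg$coverage$bin_size,
                                     seed = cfg$seed)
    agg <- correct_replication_timing(agg, project_track(track, agg$bins),
                                      span = an$loess_span)
  }
  qc <- qc_sample(agg, platform = an$platform,
                  thresholds = unlist(an$mad_thresholds))
  panel <- filter_informative_snps(sim$allelic, window = an$vaf_window,
                                   min_covered = an$min_covered)
  bv <- bin_vaf(sim$allelic, panel, agg$bins, micro_bin_size = an$micro_bin)
  ploidy <- estimate_ploidy(bv, triploid_window = an$triploid_window)
  ploidy <- flag_ploidy_outliers(
    ploidy, stats::setNames(rep(cfg$embryo, nrow(ploidy)), ploidy$sample))
  hap <- compute_haplotype_cn(bv, agg, ploidy)
  segs <- segment_cn(agg, alpha = an$cbs$alpha, nperm = an$cbs$nperm,
                     min_width = an$cbs$min_width, method = an$cbs$method)
  hseg <- annotate_haplotype_segments(segs, hap)
  hseg <- detect_half_copy_segments(hseg, tol = an$half_copy_tol)
  svf <- filter_sv_candidates(sim$svs$candidates, an$sv$min_reads,
                              an$sv$min_mapq, an$sv$min_distance)
  svg <- if (nrow(svf) > 0)
    joint_genotype(svf, sim$svs$tallies, an$sv$presence_threshold)
  else NULL
  site <- if (!is.null(an$target_site)) do.call(target_site, an$target_site)
          else NULL
  keep <- ploidy$sample[!ploidy$call %in% "indeterminate" &
                        !isFALSE(ploidy$embryo_consistent)]
  ev <- classify_embryo(hseg[hseg$sample %in% keep, , drop = FALSE], site,
                        ploidy, cfg$genome$chrom_lengths)
  manifest <- list(package = "karyotrace",
                   version = as.character(utils::packageVersion("karyotrace")),
                   seed = cfg$seed, config = rapply(cfg, unclass, how = "list"))
  res <- list(config = cfg, truth = sim$truth, qc = qc, ploidy = ploidy,
              panel = panel, haplotype_cn = hap, segments = hseg,
              events = ev, svs = list(filtered = svf, genotypes = svg),
              manifest = manifest)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$outdir, f)
    write_bin_counts(sim$counts, p("counts.tsv"))
    write_allelic_depths(sim$allelic, p("allelic_depths.tsv"))
    .write_tsv(qc, p("qc.tsv"))
    .write_tsv(as.data.frame(panel), p("snp_panel.tsv"))
    .write_tsv(as.data.frame(ploidy), p("ploidy.tsv"))
    .write_tsv(hseg, p("segments.tsv"))
    write_seg(segs, p("segments.seg"))
    .write_tsv(ev, p("events.tsv"))
    write_sv_tables(sim$svs, p("svs"))
    write_ground_truth(sim$truth, p("ground_truth.yaml"))
    yaml::write_yaml(manifest, p("manifest.yaml"))
  }
  invisible(res)
}
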