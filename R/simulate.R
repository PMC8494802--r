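# Karyotypes are per-cell data frames (chrom, start, end, cn_mat, cn_pat,
# ur_mat, ur_pat): cn_* are copy numbers of the maternal (C57BL/6J) and
# paternal (129/SvJae) haplotypes, ur_* the number of those copies sitting in
# a non-replicating micronucleus at harvest. Coordinates 0-based half-open.

.base_karyotype <- function(genome) {
  data.frame(chrom = genome$chroms$name, start = 0,
             end = genome$chroms$length,
             cn_mat = 1, cn_pat = 1, ur_mat = 0, ur_pat = 0,
             stringsAsFactors = FALSE)
}

# split the interval containing pos so that pos becomes a boundary
.split_at <- function(kar, chrom, pos) {
  i <- which(kar$chrom == chrom & kar$start < pos & kar$end > pos)
  if (length(i) == 0) return(kar)
  row <- kar[i, , drop = FALSE]
  left <- row; left$end <- pos
  right <- row; right$start <- pos
  kar <- rbind(kar[seq_len(nrow(kar)) < i, , drop = FALSE], left, right,
               kar[seq_len(nrow(kar)) > i, , drop = FALSE])
  rownames(kar) <- NULL
  kar
}

.adjust <- function(kar, chrom, from, to, hap, d_cn = 0, d_ur = 0) {
  cn_col <- if (hap == "maternal") "cn_mat" else "cn_pat"
  ur_col <- if (hap == "maternal") "ur_mat" else "ur_pat"
  sel <- kar$chrom == chrom & kar$start >= from & kar$end <= to
  kar[sel, cn_col] <- pmax(0, kar[sel, cn_col] + d_cn)
  kar[sel, ur_col] <- pmax(0, pmin(kar[sel, cn_col],
                                   kar[sel, ur_col] + d_ur))
  kar
}

#' Simulate an 8-cell embryo with implanted segregation errors
#'
#' Grows a zygote through three cleavage divisions, applying the given
#' events to the lineage, and emits sequencing-like observables on the
#' realized karyotypes. Mitotic events are applied at the division they
#' specify to the mother cell given by `mother_index` (lineage-first by
#' default); the two daughters receive the reciprocal outcomes dictated by
#' the event mechanics:
#' * `acentric_missegregation`: one daughter gains the acentric fragment
#'   (distal copy number 2 on the cut haplotype), its sister loses it
#'   (copy number 0, LOH).
#' * `micronucleus_underreplication`: the acentric fragment stays with its
#'   centric partner but is partitioned into a micronucleus, so at a G2
#'   harvest that copy is unreplicated (half DNA mass).
#' * `bridge_monosomy`: sister-chromatid fusion of the cut ends forms a
#'   dicentric; one daughter receives both centric copies plus the
#'   replicated acentric fragment (in a micronucleus when
#'   `acentric_in_mn`), the other is left with zero copies of the cut
#'   homolog — a whole-chromosome monosomy.
#' * `whole_chromosome_missegregation`: reciprocal whole-chromosome
#'   gain/loss.
#' * `meiotic_trisomy` / `digyny`: applied to the zygote, hence shared by
#'   all eight blastomeres.
#'
#' @param genome a [genome_model()].
#' @param events list of [event_spec()] objects (at most one Cas9 cut per
#'   chromosome).
#' @param coverage a [coverage_model()].
#' @param phase harvest phase: `"G1"` (unreplicated) or `"G2"` (replicated;
#'   micronucleus copies stay at half mass).
#' @param mother_index index of the mother cell, within its generation, to
#'   which each mitotic event is applied.
#' @param seed integer seed for the stochastic emitters.
#' @return list with `truth` (class `embryo_truth`), `counts`
#'   (class `bin_counts`), `allelic` (allelic-depth data frame) and
#'   `svs` (candidate structural-variant table).
#' @examples
#' g <- toy_genome(c(chrA = 6e6, chrB = 4e6), snp_spacing = 2e4)
#' cov <- coverage_model(mean_depth = 2, bin_size = 1e5)
#' sim <- simulate_embryo(g, list(), cov, seed = 1)
#' sim$truth
#' @export
simulate_embryo <- function(genome, events = list(), coverage,
                            phase = c("G1", "G2"), mother_index = 1,
                            seed = 1) {
  phase <- match.arg(phase)
  .check_events(events, genome)
  zyg <- .base_karyotype(genome)
  labels <- list()

  for (e in events) {
    if (e$event_class == "meiotic_trisomy") {
      zyg <- .adjust(zyg, e$chrom, 0, genome$chroms$length[
        match(e$chrom, genome$chroms$name)], e$haplotype, d_cn = 1)
      labels[[length(labels) + 1]] <- c(cell = "zygote", e$event_class)
    } else if (e$event_class == "digyny") {
      zyg$cn_mat <- zyg$cn_mat * 2
      labels[[length(labels) + 1]] <- c(cell = "zygote", e$event_class)
    }
  }

  # generations: gen g has 2^g cells; daughters of (g,i) are (g+1,2i-1|2i)
  gens <- list(list(zyg))
  for (d in 1:3) {
    prev <- gens[[d]]
    nxt <- vector("list", 2L * length(prev))
    for (i in seq_along(prev)) {
      nxt[[2L * i - 1L]] <- prev[[i]]
      nxt[[2L * i]] <- prev[[i]]
    }
    for (e in events) {
      if (e$event_class %in% c(MEIOTIC_CLASSES, "none") ||
          e$division != d) next
      m <- mother_index
      if (m > length(prev)) stop("mother_index beyond generation size")
      a <- 2L * m - 1L; b <- 2L * m
      len <- genome$chroms$length[match(e$chrom, genome$chroms$name)]
      ka <- nxt[[a]]; kb <- nxt[[b]]
      if (!is.null(e$cut_pos)) {
        ka <- .split_at(ka, e$chrom, e$cut_pos)
        kb <- .split_at(kb, e$chrom, e$cut_pos)
      }
      if (e$event_class == "whole_chromosome_missegregation") {
        ka <- .adjust(ka, e$chrom, 0, len, e$haplotype, d_cn = 1)
        kb <- .adjust(kb, e$chrom, 0, len, e$haplotype, d_cn = -1)
      } else if (e$event_class == "acentric_missegregation") {
        ka <- .adjust(ka, e$chrom, e$cut_pos, len, e$haplotype, d_cn = 1)
        kb <- .adjust(kb, e$chrom, e$cut_pos, len, e$haplotype, d_cn = -1)
      } else if (e$event_class == "micronucleus_underreplication") {
        ka <- .adjust(ka, e$chrom, e$cut_pos, len, e$haplotype, d_ur = 1)
      } else if (e$event_class == "bridge_monosomy") {
        ka <- .adjust(ka, e$chrom, 0, e$cut_pos, e$haplotype, d_cn = 1)
        ka <- .adjust(ka, e$chrom, e$cut_pos, len, e$haplotype, d_cn = 1,
                      d_ur = if (isTRUE(e$acentric_in_mn)) 2 else 0)
        kb <- .adjust(kb, e$chrom, 0, len, e$haplotype, d_cn = -1)
      }
      nxt[[a]] <- ka; nxt[[b]] <- kb
      labels[[length(labels) + 1]] <-
        c(cell = paste0("c", d, ".", m), e$event_class)
    }
    gens[[d + 1]] <- nxt
  }

  cells <- paste0("b", 1:8)
  kar <- do.call(rbind, lapply(1:8, function(i) {
    k <- gens[[4]][[i]]
    cbind(cell = cells[i], k, stringsAsFactors = FALSE)
  }))
  rownames(kar) <- NULL
  lineage <- do.call(rbind, lapply(0:3, function(g) {
    data.frame(generation = g, index = seq_len(2^g),
               cell = if (g == 3) cells else paste0("c", g, ".", seq_len(2^g)),
               parent = if (g == 0) NA_character_ else {
                 pg <- g - 1
                 idx <- ceiling(seq_len(2^g) / 2)
                 if (pg == 0) "c0.1" else paste0("c", pg, ".", idx)
               }, stringsAsFactors = FALSE)
  }))
  truth <- structure(list(genome = genome, karyotype = kar,
                          lineage = lineage, phase = phase,
                          events = events, event_cells = labels),
                     class = "embryo_truth")
  counts <- simulate_bin_counts(truth, genome, coverage, seed = seed)
  allelic <- simulate_allelic_depths(truth, genome, coverage, seed = seed + 1)
  svs <- simulate_sv_candidates(truth, coverage, seed = seed + 2)
  list(truth = truth, counts = counts, allelic = allelic, svs = svs)
}

#' @export
print.embryo_truth <- function(x, ...) {
  n_ev <- sum(!vapply(x$events, function(e) e$event_class == "none",
                      logical(1)))
  cat("Simulated 8-cell embryo (", x$phase, " harvest), ",
      nrow(x$genome$chroms), " chromosomes, ", n_ev,
      " implanted event(s)\n", sep = "")
  invisible(x)
}

#' Sequencing coverage model for the simulator
#'
#' @param mean_depth genome-wide coverage of a diploid, fully replicated
#'   genome (0.15 for the low-pass regime, 9.45 for the deep regime).
#' @param dispersion negative-binomial overdispersion of bin counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts. The
#'   default 0.02 (14% extra-Poisson noise per native bin) reflects the
#'   bin-level variability of amplified single-cell libraries.
#' @param read_length read length in bp used to convert coverage to read
#'   counts.
#' @param bin_size native bin width in bp (10 kb in the real pipeline).
#' @param repli_bias_strength coefficient coupling expected bin counts to
#'   the replication-timing track (0 = unbiased sample).
#' @param bias_profile optional strictly positive per-bin multiplicative
#'   bias vector recycled across samples.
#' @return a `coverage_model` list.
#' @export
coverage_model <- function(mean_depth, dispersion = 0.02, read_length = 100,
                           bin_size = 10e3, repli_bias_strength = 0,
                           bias_profile = NULL) {
  stopifnot(mean_depth > 0, dispersion >= 0, read_length > 0, bin_size > 0)
  if (!is.null(bias_profile) && any(bias_profile <= 0))
    stop("bias_profile must be strictly positive")
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 read_length = read_length, bin_size = bin_size,
                 repli_bias_strength = repli_bias_strength,
                 bias_profile = bias_profile), class = "coverage_model")
}

# DNA mass of one karyotype row per haplotype at harvest; a replicated copy
# counts 2 in G2, an unreplicated (micronucleated) copy counts 1.
.mass <- function(kar, phase) {
  if (phase == "G2") {
    mat <- 2 * (kar$cn_mat - kar$ur_mat) + kar$ur_mat
    pat <- 2 * (kar$cn_pat - kar$ur_pat) + kar$ur_pat
  } else {
    mat <- kar$cn_mat
    pat <- kar$cn_pat
  }
  cbind(mat = mat, pat = pat)
}

#' Simulate binned read counts from a realized embryo karyotype
#'
#' Expected counts per bin are proportional to the harvested DNA mass
#' (haplotype copy number, doubled for replicated copies at a G2 harvest,
#' halved for micronucleated copies), the coverage depth, any per-bin bias
#' profile and a replication-timing modulation; counts are drawn from a
#' negative binomial (Poisson when `dispersion = 0`).
#'
#' @param truth an `embryo_truth`.
#' @param genome the `genome_model` used to build it.
#' @param coverage a [coverage_model()].
#' @param track optional `repliseq_track` used for count modulation when
#'   `repli_bias_strength != 0`; simulated from `seed` if absent.
#' @param seed integer seed.
#' @return a `bin_counts` object: list of `bins` (chrom, start, end) and an
#'   integer `counts` matrix (bins x cells).
#' @export
simulate_bin_counts <- function(truth, genome, coverage, track = NULL,
                                seed = 1) {
  set.seed(seed)
  bins <- make_bins(genome, coverage$bin_size)
  cells <- unique(truth$karyotype$cell)
  rb <- coverage$repli_bias_strength
  if (rb != 0 && is.null(track))
    track <- simulate_repliseq_track(genome, bin_size = coverage$bin_size,
                                     seed = seed)
  mod <- if (rb != 0) pmax(0, 1 + rb * track$value) else rep(1, nrow(bins))
  bias <- if (is.null(coverage$bias_profile)) rep(1, nrow(bins))
          else rep_len(coverage$bias_profile, nrow(bins))
  counts <- matrix(0L, nrow(bins), length(cells),
                   dimnames = list(NULL, cells))
  width <- bins$end - bins$start
  for (ci in seq_along(cells)) {
    kar <- truth$karyotype[truth$karyotype$cell == cells[ci], , drop = FALSE]
    m <- .mass(kar, truth$phase)
    mass <- numeric(nrow(bins))
    for (j in seq_len(nrow(kar))) {
      sel <- which(bins$chrom == kar$chrom[j] & bins$end > kar$start[j] &
                   bins$start < kar$end[j])
      if (length(sel) == 0) next
      ov <- pmin(bins$end[sel], kar$end[j]) - pmax(bins$start[sel], kar$start[j])
      mass[sel] <- mass[sel] + (m[j, "mat"] + m[j, "pat"]) * ov / width[sel]
    }
    mu <- coverage$mean_depth * width / coverage$read_length *
      (mass / 2) * bias * mod
    counts[, ci] <- if (coverage$dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / coverage$dispersion)
    else stats::rpois(length(mu), mu)
  }
  structure(list(bins = bins, counts = counts, bin_size = coverage$bin_size),
            class = "bin_counts")
}

#' Simulate SNP allelic depths from a realized embryo karyotype
#'
#' Total depth at each panel SNP follows the same mass model as the bin
#' counts; the alternate-allele (129/SvJae, paternal) count is binomial with
#' success probability equal to the local paternal share of the DNA mass.
#' SNPs in regions with zero copies on both haplotypes get depth 0.
#'
#' @inheritParams simulate_bin_counts
#' @return data frame (chrom, pos, ref, alt, sample, ref_count, alt_count).
#' @export
simulate_allelic_depths <- function(truth, genome, coverage, seed = 1) {
  if (nrow(genome$snps) == 0) stop("genome has an empty SNP panel")
  set.seed(seed)
  cells <- unique(truth$karyotype$cell)
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    kar <- truth$karyotype[truth$karyotype$cell == cells[ci], , drop = FALSE]
    m <- .mass(kar, truth$phase)
    snps <- genome$snps
    mat <- pat <- numeric(nrow(snps))
    for (cn in unique(snps$chrom)) {
      si <- which(snps$chrom == cn)
      ki <- which(kar$chrom == cn)
      idx <- .interval_index(kar$start[ki], kar$end[ki], snps$pos[si])
      mat[si] <- m[ki, "mat"][idx]
      pat[si] <- m[ki, "pat"][idx]
    }
    tot <- mat + pat
    mu <- coverage$mean_depth * tot / 2
    depth <- integer(nrow(snps))
    nz <- tot > 0
    depth[nz] <- if (coverage$dispersion > 0)
      stats::rnbinom(sum(nz), mu = mu[nz], size = 1 / coverage$dispersion)
    else stats::rpois(sum(nz), mu[nz])
    altc <- integer(nrow(snps))
    altc[nz] <- stats::rbinom(sum(nz), depth[nz], pat[nz] / tot[nz])
    out[[ci]] <- data.frame(chrom = snps$chrom, pos = snps$pos,
                            ref = snps$ref, alt = snps$alt,
                            sample = cells[ci],
                            ref_count = depth - altc, alt_count = altc,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a smooth replication-timing track
#'
#' An autocorrelated early/late statistic per native bin, bounded in
#' `[-1, 1]`, standing in for an E/L Repli-Seq profile. The same track is
#' used to inject coverage bias in the simulator and as the covariate for
#' the correction step, so correction can be validated against a known
#' bias.
#'
#' @param genome a `genome_model`.
#' @param bin_size bin width in bp.
#' @param seed integer seed (fixed seed gives an identical track).
#' @param rho lag-one autocorrelation of the underlying AR(1) process.
#' @return a `repliseq_track`: list of `bins` and `value`.
#' @export
simulate_repliseq_track <- function(genome, bin_size = 10e3, seed = 1,
                                    rho = 0.995) {
  set.seed(seed)
  bins <- make_bins(genome, bin_size)
  value <- numeric(nrow(bins))
  for (cn in unique(bins$chrom)) {
    sel <- which(bins$chrom == cn)
    n <- length(sel)
    x <- as.numeric(stats::filter(stats::rnorm(n), rho, method = "recursive"))
    x <- x - mean(x)
    value[sel] <- x / max(abs(x), 1e-12)
  }
  structure(list(bins = bins, value = value, bin_size = bin_size),
            class = "repliseq_track")
}

#' Simulate a candidate structural-variant table for one embryo
#'
#' Emits one junction per implanted Cas9 cut (breakpoints at the cut site;
#' a fold-back pair for bridge events) with split/discordant read tallies in
#' the blastomeres that carry the rearranged chromosome, plus artifact rows
#' designed to exercise every downstream filter: low read support, low
#' mapping quality, known strain-background variants, and short
#' (<= 1 Mb) intra-chromosomal junctions.
#'
#' @param truth an `embryo_truth`.
#' @param coverage a [coverage_model()].
#' @param embryo embryo label used to prefix SV ids.
#' @param n_artifacts number of artifact rows.
#' @param seed integer seed.
#' @return list with `candidates` (one row per SV: id, chromA, posA,
#'   strandA, chromB, posB, strandB, n_reads, max_mapq,
#'   in_strain_background) and `tallies` (long table id, sample, split,
#'   discordant).
#' @export
simulate_sv_candidates <- function(truth, coverage, embryo = "E1",
                                   n_artifacts = 6, seed = 1) {
  set.seed(seed)
  genome <- truth$genome
  cells <- unique(truth$karyotype$cell)
  cand <- list(); tall <- list()
  depth_reads <- max(3, round(coverage$mean_depth * 3))
  k <- 0
  for (e in truth$events) {
    if (is.null(e$cut_pos)) next
    k <- k + 1
    id <- sprintf("%s_sv%d", embryo, k)
    cand[[length(cand) + 1]] <- data.frame(
      id = id, chromA = e$chrom, posA = e$cut_pos, strandA = "+",
      chromB = e$chrom, posB = e$cut_pos + 1.5e6, strandB = "+",
      n_reads = depth_reads, max_mapq = 60, in_strain_background = FALSE,
      stringsAsFactors = FALSE)
    # carriers: blastomeres whose cut-haplotype CN differs from 1 anywhere
    cn_col <- if (e$haplotype == "maternal") "cn_mat" else "cn_pat"
    kar <- truth$karyotype
    carrier <- vapply(cells, function(cl) {
      kk <- kar[kar$cell == cl & kar$chrom == e$chrom, ]
      any(kk[[cn_col]] != 1) || any(kk$ur_mat + kk$ur_pat > 0)
    }, logical(1))
    if (!any(carrier)) carrier[] <- TRUE
    tall[[length(tall) + 1]] <- data.frame(
      id = id, sample = cells,
      split = ifelse(carrier, stats::rpois(length(cells), depth_reads), 0L),
      discordant = ifelse(carrier, stats::rpois(length(cells),
                                                depth_reads / 2), 0L),
      stringsAsFactors = FALSE)
  }
  for (a in seq_len(n_artifacts)) {
    k <- k + 1
    id <- sprintf("%s_art%d", embryo, a)
    ci <- sample(nrow(genome$chroms), 1)
    pos <- sample(genome$chroms$length[ci] - 2e6, 1)
    kind <- a %% 4
    cand[[length(cand) + 1]] <- data.frame(
      id = id, chromA = genome$chroms$name[ci], posA = pos, strandA = "+",
      chromB = genome$chroms$name[ci],
      posB = pos + if (kind == 3) 5e5 else 2e6, strandB = "-",
      n_reads = if (kind == 1) 2L else 5L,
      max_mapq = if (kind == 2) 25L else 60L,
      in_strain_background = kind == 0,
      stringsAsFactors = FALSE)
    tall[[length(tall) + 1]] <- data.frame(
      id = id, sample = cells,
      split = stats::rpois(length(cells), 1),
      discordant = stats::rpois(length(cells), 1),
      stringsAsFactors = FALSE)
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else
         data.frame(id = character(), chromA = character(), posA = numeric(),
                    strandA = character(), chromB = character(),
                    posB = numeric(), strandB = character(),
                    n_reads = integer(), max_mapq = numeric(),
                    in_strain_background = logical()),
       tallies = if (length(tall)) do.call(rbind, tall) else
         data.frame(id = character(), sample = character(),
                    split = integer(), discordant = integer()))
}
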