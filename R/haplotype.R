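#' Bin-level VAF with micro-bin cluster down-weighting
#'
#' Allelic depths are first averaged over SNPs within 5 kb micro-bins
#' (within each sample), so that dense clusters of SNPs with correlated
#' coverage do not dominate; micro-bin averages are then summed across each
#' copy-number bin and the bin VAF formed as
#' `alt_sum / (alt_sum + ref_sum)`. Bins with no covered SNP are missing.
#'
#' @param depths allelic-depth data frame (chrom, pos, sample, ref_count,
#'   alt_count).
#' @param panel an `snp_panel` from [filter_informative_snps()]; only kept
#'   sites contribute.
#' @param bins copy-number bin data frame (chrom, start, end), e.g. from a
#'   `cn_matrix`.
#' @param micro_bin_size micro-bin width in bp (default 5 kb).
#' @return a `bin_vaf` object: list of `bins`, `vaf` and `n_snps`
#'   matrices (bins x samples).
#' @export
bin_vaf <- function(depths, panel, bins, micro_bin_size = 5e3) {
  kept <- panel[panel$kept, c("chrom", "pos")]
  if (nrow(kept) == 0) stop("panel has no informative SNPs")
  d <- merge(depths, kept, by = c("chrom", "pos"))
  d <- d[d$ref_count + d$alt_count > 0, , drop = FALSE]
  samples <- sort(unique(depths$sample))
  vaf <- nsnp <- matrix(NA_real_, nrow(bins), length(samples),
                        dimnames = list(NULL, samples))
  # cn-bin index per (chrom, pos)
  d$bin <- NA_integer_
  for (cn in unique(d$chrom)) {
    bi <- which(bins$chrom == cn)
    si <- which(d$chrom == cn)
    if (length(bi) == 0) next
    idx <- .interval_index(bins$start[bi], bins$end[bi], d$pos[si])
    d$bin[si] <- bi[idx]
  }
  d <- d[!is.na(d$bin), , drop = FALSE]
  d$micro <- paste0(d$bin, ":", floor(d$pos / micro_bin_size))
  for (s in samples) {
    ds <- d[d$sample == s, , drop = FALSE]
    if (nrow(ds) == 0) next
    mk <- factor(ds$micro, levels = unique(ds$micro))
    ref_m <- tapply(ds$ref_count, mk, mean)
    alt_m <- tapply(ds$alt_count, mk, mean)
    n_m <- tapply(ds$ref_count, mk, length)
    bin_of <- as.integer(sub(":.*", "", levels(mk)))
    bf <- factor(bin_of, levels = seq_len(nrow(bins)))
    ref_b <- tapply(ref_m, bf, sum)
    alt_b <- tapply(alt_m, bf, sum)
    n_b <- tapply(n_m, bf, sum)
    tot <- ref_b + alt_b
    ok <- !is.na(tot) & tot > 0
    vaf[ok, s] <- alt_b[ok] / tot[ok]
    nsnp[ok, s] <- n_b[ok]
  }
  nsnp[is.na(nsnp)] <- 0
  structure(list(bins = bins, vaf = vaf, n_snps = nsnp,
                 micro_bin_size = micro_bin_size), class = "bin_vaf")
}

#' @export
print.bin_vaf <- function(x, ...) {
  cat("Bin-level VAF track:", nrow(x$bins), "bins x", ncol(x$vaf),
      "samples;", round(100 * mean(is.na(x$vaf))), "% missing\n")
  invisible(x)
}

#' Estimate sample ploidy from the genome-wide mean VAF
#'
#' The statistic `1 / min(VAF, 1 - VAF)` of the mean bin VAF is computed
#' per sample: values in the closed window `[2.5, 3.5]` call the sample
#' triploid and attach a x1.5 copy-number correction factor; anything else
#' is treated as diploid (factor 1).
#'
#' @param vaf_track a `bin_vaf`.
#' @param triploid_window closed window on the statistic (default
#'   `c(2.5, 3.5)`).
#' @param min_bins minimum non-missing bins required for a call.
#' @return a `ploidy_calls` data frame: sample, n_bins, mean_vaf,
#'   statistic, call, factor, embryo_consistent.
#' @export
estimate_ploidy <- function(vaf_track, triploid_window = c(2.5, 3.5),
                            min_bins = 20) {
  stopifnot(inherits(vaf_track, "bin_vaf"))
  samples <- colnames(vaf_track$vaf)
  out <- lapply(samples, function(s) {
    v <- vaf_track$vaf[, s]
    v <- v[!is.na(v)]
    if (length(v) < min_bins)
      return(data.frame(sample = s, n_bins = length(v),
                        mean_vaf = NA_real_, statistic = NA_real_,
                        call = "indeterminate", factor = NA_real_,
                        embryo_consistent = NA, stringsAsFactors = FALSE))
    mv <- mean(v)
    stat <- 1 / min(mv, 1 - mv)
    tri <- is.finite(stat) && stat >= triploid_window[1] &&
      stat <= triploid_window[2]
    if (is.finite(stat) && stat > triploid_window[2])
      message("sample ", s, ": allelic balance beyond the triploid window ",
              "(statistic ", round(stat, 2), "); treated as diploid")
    data.frame(sample = s, n_bins = length(v), mean_vaf = mv,
               statistic = stat,
               call = if (tri) "triploid" else "diploid",
               factor = if (tri) 1.5 else 1.0,
               embryo_consistent = NA, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ploidy_calls", "data.frame")
  res
}

#' Decompose depth copy number into parental haplotype copy numbers
#'
#' Per bin and sample, the 129/SvJae (alternate, paternal) haplotype CN is
#' `VAF x total CN` and the C57BL/6J (reference, maternal) haplotype CN is
#' `(1 - VAF) x total CN`, where total CN is the relative depth CN scaled
#' so a balanced diploid bin reads (1, 1) and multiplied by the ploidy
#' correction factor. Bins with missing VAF report total CN only.
#'
#' @param vaf_track a `bin_vaf` aligned to the same bins as `depth_cn`.
#' @param depth_cn a `cn_matrix` (relative CN, per-sample median 1).
#' @param ploidy a `ploidy_calls` table from [estimate_ploidy()].
#' @return a `haplotype_cn` object: list of `bins`, matrices `cn_129`,
#'   `cn_b6`, `total_cn`, `n_snps`, logical `mask`, and per-sample
#'   `factor`.
#' @export
compute_haplotype_cn <- function(vaf_track, depth_cn, ploidy) {
  stopifnot(inherits(vaf_track, "bin_vaf"), inherits(depth_cn, "cn_matrix"))
  if (nrow(vaf_track$bins) != nrow(depth_cn$bins))
    stop("bin indices of VAF track and depth CN are not aligned")
  samples <- intersect(colnames(depth_cn$cn), colnames(vaf_track$vaf))
  if (length(samples) == 0) stop("no shared samples")
  fac <- stats::setNames(ploidy$factor[match(samples, ploidy$sample)], samples)
  fac[is.na(fac)] <- 1.0
  total <- sweep(depth_cn$cn[, samples, drop = FALSE], 2, 2 * fac, "*")
  vaf <- vaf_track$vaf[, samples, drop = FALSE]
  cn_129 <- vaf * total
  cn_b6 <- (1 - vaf) * total
  structure(list(bins = depth_cn$bins, cn_129 = cn_129, cn_b6 = cn_b6,
                 total_cn = total, n_snps = vaf_track$n_snps[, samples,
                                                             drop = FALSE],
                 mask = depth_cn$mask, factor = fac),
            class = "haplotype_cn")
}

#' @export
print.haplotype_cn <- function(x, ...) {
  cat("Haplotype CN track:", nrow(x$bins), "bins x", ncol(x$cn_129),
      "samples (129/SvJae vs C57BL/6J)\n")
  invisible(x)
}

#' Scatter plot of per-haplotype copy number along one chromosome
#'
#' Mirrors the per-chromosome haplotype CN panels used to visualize
#' blastomere karyotypes: dark points for the 129/SvJae haplotype, light
#' for C57BL/6J.
#'
#' @param x a `haplotype_cn`.
#' @param sample sample name.
#' @param chrom chromosome name (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.haplotype_cn <- function(x, sample = colnames(x$cn_129)[1],
                              chrom = x$bins$chrom[1], ...) {
  sel <- which(x$bins$chrom == chrom & !x$mask)
  pos <- (x$bins$start[sel] + x$bins$end[sel]) / 2 / 1e6
  graphics::plot(pos, x$cn_129[sel, sample], pch = 16, cex = 0.5,
                 col = "grey25", ylim = c(0, 3), xlab = paste(chrom, "(Mb)"),
                 ylab = "haplotype copy number",
                 main = paste(sample, chrom), ...)
  graphics::points(pos, x$cn_b6[sel, sample], pch = 16, cex = 0.5,
                   col = "grey70")
  graphics::abline(h = 0:3, lty = 3, col = "grey85")
  invisible(x)
}

#' Flag blastomeres whose ploidy disagrees with their embryo
#'
#' Computes the modal ploidy call among determinate blastomeres of each
#' embryo and marks non-modal blastomeres `embryo_consistent = FALSE`
#' (they are excluded from event inference). A tie leaves the whole embryo
#' indeterminate.
#'
#' @param calls a `ploidy_calls` table.
#' @param embryo_map named character vector mapping sample to embryo.
#' @param min_calls minimum determinate calls per embryo (default 3).
#' @return the updated `ploidy_calls` table.
#' @export
flag_ploidy_outliers <- function(calls, embryo_map, min_calls = 3) {
  emb <- embryo_map[calls$sample]
  if (any(is.na(emb))) stop("unmapped sample(s): ",
                            paste(calls$sample[is.na(emb)], collapse = ", "))
  for (e in unique(emb)) {
    idx <- which(emb == e & calls$call != "indeterminate")
    if (length(idx) < min_calls) {
      calls$embryo_consistent[emb == e] <- NA
      next
    }
    tab <- table(calls$call[idx])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      calls$embryo_consistent[emb == e] <- NA
      next
    }
    calls$embryo_consistent[idx] <- calls$call[idx] == top
  }
  calls
}

#' Attach per-haplotype means to depth segments
#'
#' For every segment, the member bins' haplotype copy numbers are averaged
#' with weights proportional to the number of contributing SNPs, which is
#' unbiased in the presence of bins with missing VAF.
#'
#' @param segments a `segment_table` from [segment_cn()] (means on the
#'   relative-CN scale).
#' @param hap a `haplotype_cn` on the same bins.
#' @return the segment table with added columns `total_cn` (ploidy-scaled),
#'   `cn_129_mean`, `cn_b6_mean`.
#' @export
annotate_haplotype_segments <- function(segments, hap) {
  segments$total_cn <- NA_real_
  segments$cn_129_mean <- NA_real_
  segments$cn_b6_mean <- NA_real_
  for (r in seq_len(nrow(segments))) {
    s <- segments$sample[r]
    if (!s %in% colnames(hap$cn_129)) next
    sel <- which(hap$bins$chrom == segments$chrom[r] &
                 hap$bins$start >= segments$start[r] &
                 hap$bins$end <= segments$end[r] & !hap$mask)
    segments$total_cn[r] <- segments$mean_cn[r] * 2 * hap$factor[s]
    w <- hap$n_snps[sel, s]
    v129 <- hap$cn_129[sel, s]
    ok <- !is.na(v129) & w > 0
    if (any(ok)) {
      segments$cn_129_mean[r] <- stats::weighted.mean(v129[ok], w[ok])
      segments$cn_b6_mean[r] <- stats::weighted.mean(hap$cn_b6[sel, s][ok],
                                                     w[ok])
    }
  }
  segments
}

#' Flag segments carrying the half-copy micronucleus signature
#'
#' A segment is `half_copy` when one haplotype mean sits within `tol` of a
#' half-integer (k + 0.5) while the other sits within `tol` of an integer
#' — the signature of a chromosome fragment that was sequestered in a
#' micronucleus and failed to replicate before a G2 harvest.
#'
#' @param hap_segments segment table with `cn_129_mean` and `cn_b6_mean`.
#' @param tol tolerance window around k + 0.5 (default 0.15).
#' @return the segment table with a logical `half_copy` column.
#' @export
detect_half_copy_segments <- function(hap_segments, tol = 0.15) {
  d_half <- function(x) abs(x - (floor(x) + 0.5))
  d_int <- function(x) abs(x - round(x))
  a <- hap_segments$cn_129_mean
  b <- hap_segments$cn_b6_mean
  hap_segments$half_copy <- !is.na(a) & !is.na(b) &
    ((d_half(a) <= tol & d_int(b) <= tol) |
     (d_half(b) <= tol & d_int(a) <= tol))
  hap_segments
}
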