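#' Construct a binned read-count matrix
#'
#' @param bins data frame (chrom, start, end), 0-based half-open,
#'   non-overlapping and sorted within chromosome.
#' @param counts non-negative integer matrix, one row per bin, one column
#'   per sample (column names are sample names).
#' @param bin_size nominal bin width in bp.
#' @return a `bin_counts` object.
#' @export
bin_counts <- function(bins, counts, bin_size = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(bins) == nrow(counts), all(counts >= 0))
  for (cn in unique(bins$chrom)) {
    b <- bins[bins$chrom == cn, ]
    if (any(diff(b$start) <= 0) || any(b$start[-1] < b$end[-nrow(b)]))
      stop("bins must be sorted and non-overlapping within chromosome")
  }
  if (is.null(bin_size)) bin_size <- max(bins$end - bins$start)
  structure(list(bins = bins, counts = counts, bin_size = bin_size),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("Binned read counts:", nrow(x$bins), "bins x", ncol(x$counts),
      "samples (bin size", x$bin_size, "bp)\n")
  invisible(x)
}

# large-bin grouping key; trailing partial bins keep their true end
.rebin_key <- function(bins, target) {
  paste(bins$chrom, floor(bins$start / target))
}

#' Re-bin read counts to a coarser bin size
#'
#' Counts of constituent bins are summed. The native resolution is 10 kb;
#' copy-number analysis uses 50 kb as the most granular level and 250 kb
#' for the low-pass regime.
#'
#' @param counts a [bin_counts()] object.
#' @param target_bin_size new bin width; must be an integer multiple of the
#'   current one.
#' @return a `bin_counts` object at the coarser resolution.
#' @export
rebin <- function(counts, target_bin_size) {
  stopifnot(inherits(counts, "bin_counts"))
  if (target_bin_size %% counts$bin_size != 0)
    stop("target_bin_size must be an integer multiple of the source bin size")
  if (target_bin_size == counts$bin_size) return(counts)
  key <- .rebin_key(counts$bins, target_bin_size)
  key <- factor(key, levels = unique(key))
  new_bins <- data.frame(
    chrom = tapply(counts$bins$chrom, key, `[`, 1),
    start = as.numeric(tapply(counts$bins$start, key, min)),
    end = as.numeric(tapply(counts$bins$end, key, max)),
    stringsAsFactors = FALSE)
  rownames(new_bins) <- NULL
  new_counts <- apply(counts$counts, 2, function(v) tapply(v, key, sum))
  dimnames(new_counts) <- list(NULL, colnames(counts$counts))
  bin_counts(new_bins, new_counts, target_bin_size)
}

#' Normalize binned counts to relative copy number
#'
#' Performs, in order: (i) samples whose median count over all bins is 0
#' are dropped; (ii) each remaining sample is divided by its own median
#' across all bins, so the per-sample median of the output is exactly 1;
#' (iii) bins whose normalized coverage is below 25% of the genome-wide
#' (per-sample) median in more than 80% of samples are masked from all
#' downstream statistics.
#'
#' @param counts a [bin_counts()] object with at least 2 samples.
#' @param low_frac coverage fraction below which a bin counts as
#'   low-covered (default 0.25).
#' @param sample_frac fraction of samples that must be low-covered for the
#'   bin to be masked (strictly greater than; default 0.80).
#' @return a `cn_matrix`: list of `bins`, numeric matrix `cn`, logical
#'   `mask` (TRUE = excluded bin) and `bin_size`.
#' @export
normalize_depth <- function(counts, low_frac = 0.25, sample_frac = 0.80) {
  stopifnot(inherits(counts, "bin_counts"))
  med <- apply(counts$counts, 2, stats::median)
  keep <- med > 0
  if (!any(keep)) stop("no usable samples: all medians are zero")
  if (any(!keep))
    message("dropping ", sum(!keep), " sample(s) with zero median coverage")
  cn <- sweep(counts$counts[, keep, drop = FALSE], 2, med[keep], "/")
  low <- cn < low_frac
  mask <- rowMeans(low) > sample_frac
  structure(list(bins = counts$bins, cn = cn, mask = mask,
                 bin_size = counts$bin_size), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("Normalized CN matrix:", nrow(x$bins), "bins x", ncol(x$cn),
      "samples;", sum(x$mask), "bins masked (bin size", x$bin_size, "bp)\n")
  invisible(x)
}

#' Aggregate normalized copy number into larger bins
#'
#' Takes the mean of the unmasked constituent values per large bin, then
#' divides each large bin by its median across samples to remove
#' locus-specific coverage biases. Large bins whose constituents are all
#' masked stay masked. The cross-sample division is skipped (with a
#' message) when fewer than 3 samples are present, where a median carries
#' no locus information.
#'
#' @param norm a `cn_matrix`.
#' @param target_bin_size one of the coarser analysis resolutions
#'   (e.g. 250 kb, 1 Mb, 2 Mb, 5 Mb); must exceed the current bin size.
#' @param cross_sample_median divide each bin by its cross-sample median?
#' @return a `cn_matrix` at the coarser resolution.
#' @export
aggregate_bins <- function(norm, target_bin_size, cross_sample_median = TRUE) {
  stopifnot(inherits(norm, "cn_matrix"))
  if (target_bin_size <= norm$bin_size)
    stop("target_bin_size must exceed the current bin size")
  key <- .rebin_key(norm$bins, target_bin_size)
  key <- factor(key, levels = unique(key))
  new_bins <- data.frame(
    chrom = tapply(norm$bins$chrom, key, `[`, 1),
    start = as.numeric(tapply(norm$bins$start, key, min)),
    end = as.numeric(tapply(norm$bins$end, key, max)),
    stringsAsFactors = FALSE)
  rownames(new_bins) <- NULL
  vals <- norm$cn
  vals[norm$mask, ] <- NA
  agg <- apply(vals, 2, function(v)
    tapply(v, key, function(z) mean(z, na.rm = TRUE)))
  agg <- matrix(agg, ncol = ncol(norm$cn),
                dimnames = list(NULL, colnames(norm$cn)))
  mask <- apply(agg, 1, function(r) all(!is.finite(r)))
  agg[!is.finite(agg)] <- NA
  if (cross_sample_median) {
    if (ncol(agg) < 3) {
      message("fewer than 3 samples: skipping cross-sample median division")
    } else {
      bin_med <- apply(agg, 1, stats::median, na.rm = TRUE)
      bin_med[!is.finite(bin_med) | bin_med == 0] <- 1
      agg <- sweep(agg, 1, bin_med, "/")
    }
  }
  structure(list(bins = new_bins, cn = agg, mask = mask,
                 bin_size = target_bin_size), class = "cn_matrix")
}

#' Correct replication-timing coverage bias by local regression
#'
#' Some single-cell libraries carry a coverage bias that tracks replication
#' timing. For each sample a locally weighted regression (LOESS) of bin CN
#' on the timing statistic is fitted over unmasked bins and divided out;
#' each sample is then re-centred to median 1.
#'
#' @param norm a `cn_matrix`.
#' @param track a `repliseq_track` (or numeric vector) aligned to the bin
#'   index; see [project_track()].
#' @param span LOESS span (fraction of points; default 0.3).
#' @return a bias-corrected `cn_matrix`.
#' @export
correct_replication_timing <- function(norm, track, span = 0.3) {
  stopifnot(inherits(norm, "cn_matrix"))
  tv <- if (inherits(track, "repliseq_track")) track$value else as.numeric(track)
  if (length(tv) != nrow(norm$bins))
    stop("track not aligned to bin index; use project_track()")
  if (stats::sd(tv, na.rm = TRUE) < 1e-12) {
    warning("degenerate (constant) replication-timing track: identity transform")
    return(norm)
  }
  out <- norm$cn
  use <- !norm$mask & is.finite(tv)
  for (s in seq_len(ncol(out))) {
    ok <- use & is.finite(out[, s])
    if (sum(ok) < 30) next
    fit <- stats::loess(out[ok, s] ~ tv[ok], span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    pred <- stats::predict(fit, newdata = tv[ok])
    pred[!is.finite(pred) | pred <= 0] <- 1
    out[ok, s] <- out[ok, s] / pred
    med <- stats::median(out[ok, s])
    if (is.finite(med) && med > 0) out[, s] <- out[, s] / med
  }
  norm$cn <- out
  norm
}

#' Project a native-resolution replication-timing track onto coarser bins
#'
#' @param track a `repliseq_track`.
#' @param bins target bin data frame (chrom, start, end).
#' @return numeric vector of mean track values per target bin.
#' @export
project_track <- function(track, bins) {
  out <- numeric(nrow(bins))
  for (cn in unique(bins$chrom)) {
    ti <- which(track$bins$chrom == cn)
    bi <- which(bins$chrom == cn)
    if (length(ti) == 0) { out[bi] <- NA; next }
    mid <- (track$bins$start[ti] + track$bins$end[ti]) / 2
    grp <- findInterval(mid, bins$start[bi])
    v <- tapply(track$value[ti], factor(grp, levels = seq_along(bi)), mean)
    out[bi] <- as.numeric(v)
  }
  out
}

#' Sample-level quality control on copy-number noise
#'
#' A sample passes when the median absolute deviation (MAD) of its
#' normalized bin CN values, over unmasked bins, does not exceed the
#' platform threshold: 0.15 for the low-pass regime (250 kb bins) and 0.3
#' for the deep regime (50 kb bins).
#'
#' @param norm a `cn_matrix`.
#' @param platform `"low_pass"` or `"deep"`.
#' @param thresholds named numeric vector of MAD thresholds per platform.
#' @param min_bins minimum number of unmasked bins required for a call.
#' @return data frame (sample, platform, mad, threshold, pass, reason).
#' @export
qc_sample <- function(norm, platform = c("low_pass", "deep"),
                      thresholds = c(low_pass = 0.15, deep = 0.3),
                      min_bins = 10) {
  stopifnot(inherits(norm, "cn_matrix"))
  platform <- match.arg(platform)
  thr <- unname(thresholds[platform])
  vals <- norm$cn[!norm$mask, , drop = FALSE]
  out <- lapply(colnames(vals) %||% seq_len(ncol(vals)), function(s) {
    v <- vals[, s]
    v <- v[is.finite(v)]
    if (length(v) < min_bins)
      return(data.frame(sample = s, platform = platform, mad = NA_real_,
                        threshold = thr, pass = FALSE,
                        reason = "too few unmasked bins",
                        stringsAsFactors = FALSE))
    m <- stats::mad(v)
    data.frame(sample = s, platform = platform, mad = m, threshold = thr,
               pass = m <= thr,
               reason = if (m <= thr) "" else "MAD above threshold",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
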