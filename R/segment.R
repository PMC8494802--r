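# One split test on a sub-vector: max circular arc statistic plus a
# p-value, either by permutation or by a conservative Gaussian tail bound
# using the chromosome-wide robust noise scale (exact piecewise-constant
# steps have sigma ~ 0 and are always split).
.cbs_test <- function(x, min_width, method, nperm, alpha, sigma, df) {
  if (method == "perm")
    return(cbs_perm_cpp(x, min_width, nperm, alpha))
  res <- cbs_scan_cpp(x, min_width)
  if (res$stat <= 1e-12) { res$p <- 1; return(res) }
  if (sigma < 1e-12) { res$p <- 0; return(res) }   # exact step
  n <- length(x)
  # t tail: accounts for sigma being estimated from df differences
  res$p <- min(1, n * (n - 1) * stats::pt(-res$stat / sigma, df))
  res
}

# Recursive circular binary segmentation on one numeric vector.
# Returns internal breakpoints as positions b meaning a boundary between
# elements b and b+1 (1-based), sorted. The noise scale is estimated once
# for the whole vector from lag-one differences (robust to the few
# boundary-spanning differences) and reused at every recursion level.
.cbs_recurse <- function(x, alpha, nperm, min_width, method = "gaussian") {
  n <- length(x)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  df <- max(1L, n - 2L)
  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1]; hi <- seg[2]
    m <- hi - lo + 1L
    if (m < 2L * min_width) next
    res <- .cbs_test(x[lo:hi], min_width, method, nperm, alpha, sigma, df)
    if (res$p > alpha || res$stat <= 0) next
    i <- res$i; j <- res$j       # arc (i, j] in 0-based boundaries of x[lo:hi]
    cuts <- integer(0)
    if (i > 0) cuts <- c(cuts, lo - 1L + i)
    if (j < m) cuts <- c(cuts, lo - 1L + j)
    if (length(cuts) == 0) next
    bps <- c(bps, cuts)
    edges <- c(lo - 1L, cuts, hi)
    for (k in seq_len(length(edges) - 1L))
      stack[[length(stack) + 1L]] <- c(edges[k] + 1L, edges[k + 1L])
  }
  sort(unique(bps))
}

#' Segment normalized copy number by circular binary segmentation
#'
#' Per sample and chromosome, recursively finds the arc of bins whose mean
#' differs most from its complement (circular max-t statistic), assesses it
#' by permutation, and splits while significant. Masked and non-finite bins
#' never contribute; segments nevertheless tile each chromosome, with
#' boundaries placed at the start of the first unmasked bin after the
#' change-point. Ties in the statistic are broken toward the leftmost
#' coordinate.
#'
#' @param norm a `cn_matrix`.
#' @param alpha significance level for a split (default 0.01).
#' @param nperm permutations per test (`method = "perm"` only; default
#'   1000, with early termination once non-significance is certain).
#' @param min_width minimum segment width in bins (default 2).
#' @param method p-value method: `"gaussian"` (conservative Bonferroni
#'   tail bound on the standardized max statistic, with a robust noise
#'   scale from lag-one differences; fast, default) or `"perm"`
#'   (permutation).
#' @return a `segment_table` data frame: sample, chrom, start, end,
#'   n_bins, mean_cn.
#' @export
segment_cn <- function(norm, alpha = 0.01, nperm = 1000, min_width = 2,
                       method = c("gaussian", "perm")) {
  method <- match.arg(method)
  stopifnot(inherits(norm, "cn_matrix"))
  samples <- colnames(norm$cn) %||% as.character(seq_len(ncol(norm$cn)))
  out <- list()
  for (s in seq_along(samples)) {
    for (cn in unique(norm$bins$chrom)) {
      ci <- which(norm$bins$chrom == cn)
      use <- ci[!norm$mask[ci] & is.finite(norm$cn[ci, s])]
      if (length(use) == 0) {
        warning("no usable bins on ", cn, " for sample ", samples[s])
        next
      }
      v <- norm$cn[use, s]
      bps <- if (length(use) >= 2 * min_width)
        .cbs_recurse(v, alpha, nperm, min_width, method) else integer(0)
      edges <- c(0L, bps, length(use))
      chrom_start <- min(norm$bins$start[ci])
      chrom_end <- max(norm$bins$end[ci])
      nseg <- length(edges) - 1L
      members <- lapply(seq_len(nseg), function(k)
        use[(edges[k] + 1L):edges[k + 1L]])
      for (k in seq_len(nseg)) {
        mem <- members[[k]]
        seg_start <- if (k == 1) chrom_start
                     else norm$bins$start[members[[k]][1]]
        seg_end <- if (k == nseg) chrom_end
                   else norm$bins$start[members[[k + 1L]][1]]
        out[[length(out) + 1L]] <- data.frame(
          sample = samples[s], chrom = cn, start = seg_start, end = seg_end,
          n_bins = length(mem), mean_cn = mean(norm$cn[mem, s]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), n_bins = integer(), mean_cn = numeric())
  class(res) <- c("segment_table", "data.frame")
  res
}

#' Export a segment table in SEG format
#'
#' @param segments a `segment_table`.
#' @param file output path.
#' @export
write_seg <- function(segments, file) {
  seg <- data.frame(ID = segments$sample, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_bins, seg.mean = segments$mean_cn)
  utils::write.table(seg, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
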