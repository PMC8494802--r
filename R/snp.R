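#' Per-sample variant allele fractions at one SNP site
#'
#' VAF = alt / (ref + alt); sites with zero total depth in a sample are
#' missing (`NA`) and excluded from medians.
#'
#' @param depths allelic-depth data frame (chrom, pos, sample, ref_count,
#'   alt_count).
#' @param chrom,pos site coordinates.
#' @return named numeric vector of VAFs per sample.
#' @export
site_vaf <- function(depths, chrom, pos) {
  d <- depths[depths$chrom == chrom & depths$pos == pos, , drop = FALSE]
  if (nrow(d) == 0) stop("site not present in the depth table")
  tot <- d$ref_count + d$alt_count
  vaf <- ifelse(tot > 0, d$alt_count / tot, NA_real_)
  stats::setNames(vaf, d$sample)
}

#' Select cross-informative SNPs by median VAF
#'
#' A site is informative for the hybrid cross when its median VAF across
#' covered samples falls in the closed window (40-60% by default),
#' consistent with a balanced heterozygote. The reference allele is taken
#' as C57BL/6J (maternal) and the alternate as 129/SvJae (paternal). Sites
#' covered in fewer than `min_covered` samples are not trusted and are
#' dropped.
#'
#' @param depths allelic-depth data frame (chrom, pos, sample, ref_count,
#'   alt_count).
#' @param window closed VAF window `c(min, max)`.
#' @param min_covered minimum number of samples with nonzero depth.
#' @return an `snp_panel` data frame: chrom, pos, median_vaf, n_covered,
#'   kept.
#' @export
filter_informative_snps <- function(depths, window = c(0.40, 0.60),
                                    min_covered = 3) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  tot <- depths$ref_count + depths$alt_count
  vaf <- ifelse(tot > 0, depths$alt_count / tot, NA_real_)
  key <- paste(depths$chrom, depths$pos)
  key <- factor(key, levels = unique(key))
  med <- tapply(vaf, key, stats::median, na.rm = TRUE)
  ncov <- tapply(!is.na(vaf), key, sum)
  first <- !duplicated(key)
  panel <- data.frame(chrom = depths$chrom[first], pos = depths$pos[first],
                      median_vaf = as.numeric(med),
                      n_covered = as.integer(ncov),
                      stringsAsFactors = FALSE)
  panel$kept <- !is.na(panel$median_vaf) &
    panel$n_covered >= min_covered &
    panel$median_vaf >= window[1] & panel$median_vaf <= window[2]
  n_all_missing <- sum(is.na(panel$median_vaf))
  if (n_all_missing > 0)
    message(n_all_missing, " site(s) with no covered sample dropped")
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", sum(x$kept), "of", nrow(x), "sites informative\n")
  invisible(as.data.frame(x))
}
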