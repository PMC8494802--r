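#' Genome model for a hybrid-cross embryo
#'
#' Describes the chromosomes (all telocentric, centromere at coordinate 0, as
#' in the mouse) and the panel of SNPs that are heterozygous in a
#' C57BL/6J (maternal) x 129/SvJae (paternal) cross. All coordinates are
#' 0-based, half-open.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param snps data frame with columns `chrom`, `pos`, `ref`, `alt`, sorted
#'   by position within chromosome; `ref` is the C57BL/6J allele, `alt` the
#'   129/SvJae allele. If `NULL` a regular panel is laid down at
#'   `snp_spacing`.
#' @param snp_spacing spacing in bp of the auto-generated SNP panel.
#' @return an object of class `genome_model` with elements `chroms`
#'   (data frame `name`, `length`, `telocentric`) and `snps`.
#' @examples
#' g <- toy_genome()
#' g
#' @export
genome_model <- function(chrom_lengths, snps = NULL, snp_spacing = 10e3) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  chroms <- data.frame(name = names(chrom_lengths),
                       length = as.numeric(chrom_lengths),
                       telocentric = TRUE,
                       stringsAsFactors = FALSE)
  if (is.null(snps)) {
    snps <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      pos <- seq(from = snp_spacing / 2, to = chroms$length[i] - 1,
                 by = snp_spacing)
      data.frame(chrom = chroms$name[i], pos = floor(pos),
                 ref = "C", alt = "T", stringsAsFactors = FALSE)
    }))
  }
  snps$chrom <- as.character(snps$chrom)
  for (cn in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == cn]
    if (any(diff(p) <= 0)) stop("SNP positions must be strictly increasing")
    len <- chroms$length[match(cn, chroms$name)]
    if (is.na(len)) stop("SNP on unknown chromosome: ", cn)
    if (any(p < 0 | p >= len)) stop("SNP outside chromosome bounds on ", cn)
  }
  structure(list(chroms = chroms, snps = snps), class = "genome_model")
}

#' Default desk-scale toy genome
#'
#' Three telocentric chromosomes of 120, 80 and 50 Mb with a SNP every
#' 10 kb — a scaled stand-in for the mouse genome that keeps simulations
#' desk-sized while preserving the arithmetic of binning and haplotyping.
#'
#' @param chrom_lengths chromosome lengths in bp.
#' @param snp_spacing SNP panel spacing in bp.
#' @return a `genome_model`.
#' @export
toy_genome <- function(chrom_lengths = c(chr1 = 120e6, chr2 = 80e6, chr3 = 50e6),
                       snp_spacing = 10e3) {
  genome_model(chrom_lengths, snp_spacing = snp_spacing)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", nrow(x$chroms), "telocentric chromosomes,",
      sum(x$chroms$length) / 1e6, "Mb total,",
      nrow(x$snps), "heterozygous SNPs\n")
  invisible(x)
}

#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based, half-open; the trailing partial bin of each chromosome
#' is retained with its true end coordinate.
#'
#' @param genome a `genome_model`.
#' @param bin_size bin width in bp.
#' @return data frame with columns `chrom`, `start`, `end`.
#' @export
make_bins <- function(genome, bin_size = 10e3) {
  stopifnot(bin_size > 0)
  out <- lapply(seq_len(nrow(genome$chroms)), function(i) {
    len <- genome$chroms$length[i]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chroms$name[i], start = start,
               end = pmin(start + bin_size, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# index of the karyotype interval covering each query position (one chrom)
.interval_index <- function(starts, ends, pos) {
  idx <- findInterval(pos, starts)
  idx[idx < 1] <- NA_integer_
  bad <- !is.na(idx) & pos >= ends[idx]
  idx[bad] <- NA_integer_
  idx
}
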