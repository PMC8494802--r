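# All emitted tables carry a header line declaring the coordinate
# convention; readers skip comment lines.
.coord_header <- "# coordinates: 0-based, half-open"

.write_tsv <- function(df, file, header = .coord_header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.read_tsv <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read binned counts as TSV (sample, chrom, start, end, count)
#'
#' @param counts a `bin_counts` object.
#' @param file path.
#' @export
write_bin_counts <- function(counts, file) {
  long <- do.call(rbind, lapply(colnames(counts$counts), function(s)
    data.frame(sample = s, counts$bins, count = counts$counts[, s],
               stringsAsFactors = FALSE)))
  .write_tsv(long, file)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(file) {
  long <- .read_tsv(file)
  samples <- unique(long$sample)
  first <- long[long$sample == samples[1], c("chrom", "start", "end")]
  counts <- vapply(samples, function(s) long$count[long$sample == s],
                   numeric(nrow(first)))
  bin_counts(first, matrix(counts, ncol = length(samples),
                           dimnames = list(NULL, samples)))
}

#' Write / read allelic depths as TSV
#'
#' @param depths allelic-depth data frame.
#' @param file path.
#' @export
write_allelic_depths <- function(depths, file) .write_tsv(depths, file)

#' @rdname write_allelic_depths
#' @export
read_allelic_depths <- function(file) {
  d <- .read_tsv(file)
  # nucleotide columns must never be coerced (T is a base, not a logical)
  d$ref <- as.character(d$ref)
  d$alt <- as.character(d$alt)
  d$alt[d$alt == "TRUE"] <- "T"
  d$ref[d$ref == "TRUE"] <- "T"
  d
}

#' Write a replication-timing track as bedGraph
#'
#' @param track a `repliseq_track`.
#' @param file path.
#' @export
write_repliseq_bedgraph <- function(track, file) {
  df <- data.frame(track$bins, value = track$value)
  .write_tsv(df, file, header = c("track type=bedGraph", .coord_header))
}

#' @rdname write_repliseq_bedgraph
#' @export
read_repliseq_bedgraph <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
  structure(list(bins = df[c("chrom", "start", "end")], value = df$value,
                 bin_size = max(df$end - df$start)),
            class = "repliseq_track")
}

#' Write embryo ground truth as structured YAML
#'
#' @param truth an `embryo_truth`.
#' @param file path.
#' @export
write_ground_truth <- function(truth, file) {
  yaml::write_yaml(list(
    coordinates = "0-based, half-open",
    phase = truth$phase,
    events = lapply(truth$events, function(e) e[!vapply(e, is.null,
                                                        logical(1))]),
    karyotype = truth$karyotype,
    lineage = truth$lineage), file)
  invisible(file)
}

#' Write candidate SVs in BEDPE-like TSV form
#'
#' @param svs list with `candidates` and `tallies`.
#' @param file path prefix; writes `<file>.candidates.tsv` and
#'   `<file>.tallies.tsv`.
#' @export
write_sv_tables <- function(svs, file) {
  .write_tsv(svs$candidates, paste0(file, ".candidates.tsv"))
  .write_tsv(svs$tallies, paste0(file, ".tallies.tsv"))
  invisible(file)
}
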