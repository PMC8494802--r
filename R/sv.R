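#' Filter candidate structural variants
#'
#' Applies the discovery-stage filter chain: drop candidates that (i) match
#' a known strain-background SV (129S1/SvImJ), (ii) are supported by fewer
#' than `min_reads` reads in the discovery sample, (iii) lack any
#' supporting pair with mapping quality above `min_mapq`, or (iv) are
#' intra-chromosomal with inter-breakpoint distance of `min_distance` or
#' less (distance is undefined, and the filter vacuous, across
#' chromosomes). The four filters commute; survivor counts per filter are
#' reported via message.
#'
#' @param svs candidate table (id, chromA, posA, strandA, chromB, posB,
#'   strandB, n_reads, max_mapq, in_strain_background).
#' @param min_reads minimum supporting reads (default 3; "fewer than 3"
#'   dropped).
#' @param min_mapq mapping-quality cutoff (strictly greater than;
#'   default 30).
#' @param min_distance intra-chromosomal distance cutoff (strictly greater
#'   than; default 1 Mb).
#' @return the surviving rows.
#' @export
filter_sv_candidates <- function(svs, min_reads = 3, min_mapq = 30,
                                 min_distance = 1e6) {
  pass_bg <- !svs$in_strain_background
  pass_reads <- svs$n_reads >= min_reads
  pass_mapq <- svs$max_mapq > min_mapq
  intra <- svs$chromA == svs$chromB
  pass_dist <- !intra | abs(svs$posB - svs$posA) > min_distance
  message("SV filter survivors: background ", sum(pass_bg),
          ", reads ", sum(pass_reads), ", mapq ", sum(pass_mapq),
          ", distance ", sum(pass_dist), " of ", nrow(svs))
  svs[pass_bg & pass_reads & pass_mapq & pass_dist, , drop = FALSE]
}

#' Joint genotyping of filtered SVs across all samples
#'
#' Tallies split and discordant reads per (SV, sample); an SV is `present`
#' in a sample when the combined tally meets `threshold` (default 1
#' supporting read).
#'
#' @param svs filtered candidate table.
#' @param tallies long table (id, sample, split, discordant) covering every
#'   (SV, sample) pair.
#' @param threshold minimum combined tally for presence.
#' @return a `joint_genotypes` data frame (id, sample, split, discordant,
#'   present) restricted to the filtered SVs.
#' @export
joint_genotype <- function(svs, tallies, threshold = 1) {
  t <- tallies[tallies$id %in% svs$id, , drop = FALSE]
  missing <- setdiff(svs$id, t$id)
  if (length(missing) > 0)
    stop("no tallies for SV(s): ", paste(missing, collapse = ", "))
  samples <- unique(t$sample)
  full <- table(t$id)
  if (any(full != length(samples)))
    stop("missing sample column(s) in tallies for: ",
         paste(names(full)[full != length(samples)], collapse = ", "))
  t$present <- (t$split + t$discordant) >= threshold
  class(t) <- c("joint_genotypes", "data.frame")
  t
}

#' Retain SVs confined to a single embryo
#'
#' De novo SVs arising in an embryo can be present in one or several of
#' its blastomeres, but presence across embryos indicates background or
#' artifact: only SVs whose `present` calls all fall within one embryo
#' (and that are present somewhere) are kept.
#'
#' @param genotypes a `joint_genotypes` table.
#' @param embryo_map named character vector mapping sample to embryo.
#' @return data frame (id, embryo, n_blastomeres) of embryo-specific SVs.
#' @export
select_embryo_specific <- function(genotypes, embryo_map) {
  emb <- embryo_map[genotypes$sample]
  if (any(is.na(emb)))
    stop("unmapped sample(s): ",
         paste(unique(genotypes$sample[is.na(emb)]), collapse = ", "))
  out <- list()
  for (id in unique(genotypes$id)) {
    sel <- genotypes$id == id & genotypes$present
    embs <- unique(emb[sel])
    if (length(embs) == 1)
      out[[length(out) + 1]] <- data.frame(
        id = id, embryo = embs, n_blastomeres = sum(sel),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(id = character(), embryo = character(),
                      n_blastomeres = integer()))
  do.call(rbind, out)
}

#' Combine per-embryo candidate SV tables into one cohort table
#'
#' Optionally appends shared artifact junctions — recurrent background
#' calls with read support in more than one embryo, the class of false
#' positives that the single-embryo rule exists to remove.
#'
#' @param sims named list of `simulate_sv_candidates()` outputs (or
#'   `list(candidates=, tallies=)` pairs); names are embryo labels.
#' @param n_shared_artifacts number of cross-embryo artifact SVs to add.
#' @param artifact_chrom,artifact_pos location seed for artifact
#'   junctions.
#' @return list with pooled `candidates`, `tallies` (every SV gets a tally
#'   row for every sample in the cohort, zero where absent) and
#'   `embryo_map`.
#' @export
combine_sv_tables <- function(sims, n_shared_artifacts = 0,
                              artifact_chrom = NULL, artifact_pos = 2e6) {
  # namespace SV ids by embryo so per-embryo tables cannot collide
  for (e in names(sims)) {
    pre <- paste0(e, "_")
    fix <- function(id) ifelse(startsWith(id, pre), id, paste0(pre, id))
    sims[[e]]$candidates$id <- fix(sims[[e]]$candidates$id)
    sims[[e]]$tallies$id <- fix(sims[[e]]$tallies$id)
  }
  cand <- do.call(rbind, lapply(sims, `[[`, "candidates"))
  rownames(cand) <- NULL
  emb_map <- character(0)
  all_samples <- character(0)
  for (e in names(sims)) {
    s <- unique(sims[[e]]$tallies$sample)
    emb_map[paste0(e, ".", s)] <- e
    all_samples <- c(all_samples, paste0(e, ".", s))
  }
  tall <- list()
  for (e in names(sims)) {
    t <- sims[[e]]$tallies
    t$sample <- paste0(e, ".", t$sample)
    tall[[e]] <- t
  }
  tall <- do.call(rbind, tall)
  grid <- expand.grid(id = unique(cand$id), sample = all_samples,
                      stringsAsFactors = FALSE)
  m <- merge(grid, tall, by = c("id", "sample"), all.x = TRUE)
  m$split[is.na(m$split)] <- 0L
  m$discordant[is.na(m$discordant)] <- 0L
  if (n_shared_artifacts > 0) {
    if (is.null(artifact_chrom)) artifact_chrom <- cand$chromA[1]
    for (a in seq_len(n_shared_artifacts)) {
      id <- sprintf("shared_art%d", a)
      pos <- artifact_pos + (a - 1) * 3e6
      cand <- rbind(cand, data.frame(
        id = id, chromA = artifact_chrom, posA = pos, strandA = "+",
        chromB = artifact_chrom, posB = pos + 2e6, strandB = "-",
        n_reads = 5L, max_mapq = 60, in_strain_background = FALSE,
        stringsAsFactors = FALSE))
      # supporting reads in one blastomere of every embryo
      carriers <- vapply(names(sims), function(e)
        all_samples[emb_map[all_samples] == e][1], character(1))
      m <- rbind(m, data.frame(id = id, sample = all_samples,
                               split = ifelse(all_samples %in% carriers,
                                              3L, 0L),
                               discordant = 0L, stringsAsFactors = FALSE))
    }
  }
  m <- m[order(m$id, m$sample), ]
  rownames(m) <- NULL
  list(candidates = cand, tallies = m, embryo_map = emb_map)
}
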