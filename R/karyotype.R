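#' Describe a CRISPR-Cas9 target site
#'
#' @param name gRNA name.
#' @param chrom targeted chromosome.
#' @param cut_pos cut coordinate in bp.
#' @param tol breakpoint match tolerance in bp (default 500 kb, about two
#'   coarse bins).
#' @return a `target_site` list.
#' @export
target_site <- function(name, chrom, cut_pos, tol = 5e5) {
  stopifnot(cut_pos > 0)
  structure(list(name = name, chrom = chrom, cut_pos = cut_pos, tol = tol),
            class = "target_site")
}

#' Flag copy-number breakpoints at the Cas9 target site
#'
#' Every internal segment boundary of each sample is tested: a breakpoint
#' is on-target when it lies on the targeted chromosome within the site
#' tolerance of the cut position. All remaining arm-level breakpoints are
#' returned flagged for an external off-target cross-check.
#'
#' @param segments a `segment_table`.
#' @param site a [target_site()].
#' @return data frame (sample, chrom, pos, on_target).
#' @export
match_on_target <- function(segments, site) {
  out <- list()
  for (s in unique(segments$sample)) {
    for (cn in unique(segments$chrom)) {
      seg <- segments[segments$sample == s & segments$chrom == cn, ,
                      drop = FALSE]
      if (nrow(seg) < 2) next
      bp <- seg$start[-1]
      out[[length(out) + 1]] <- data.frame(
        sample = s, chrom = cn, pos = bp,
        on_target = cn == site$chrom & abs(bp - site$cut_pos) <= site$tol,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      pos = numeric(), on_target = logical()))
  do.call(rbind, out)
}

.empty_events <- function() {
  data.frame(blastomere = character(), chrom = character(),
             haplotype = character(), event_class = character(),
             start = numeric(), end = numeric(), direction = character(),
             side = character(), on_target = logical(),
             arm_level = logical(), division_inferred = character(),
             ambiguous = logical(), stringsAsFactors = FALSE)
}

# length-weighted whole-chromosome haplotype means for one sample
.chrom_hap_means <- function(hseg, chrom) {
  seg <- hseg[hseg$chrom == chrom, , drop = FALSE]
  w <- seg$end - seg$start
  ok <- !is.na(seg$cn_129_mean)
  if (!any(ok)) return(c(cn_129 = NA_real_, cn_b6 = NA_real_))
  c(cn_129 = sum(seg$cn_129_mean[ok] * w[ok]) / sum(w[ok]),
    cn_b6 = sum(seg$cn_b6_mean[ok] * w[ok]) / sum(w[ok]))
}

#' Classify copy-number events in one blastomere
#'
#' Rounds segment haplotype means to integers against the expected
#' baseline (1 copy per haplotype per chromosome for a diploid embryo;
#' 2 maternal for a digynic one) and emits one event per deviating
#' chromosome or segment: whole-chromosome monosomy/trisomy, distal
#' (acentric-side) gains and losses starting at a breakpoint, centric-side
#' surplus, and the half-copy micronucleus signature (which takes
#' precedence over rounding on the flagged segment).
#'
#' @param hseg haplotype-annotated (and half-copy flagged) segment table
#'   for one blastomere.
#' @param site a [target_site()] or `NULL`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param baseline named numeric `c(cn_129 =, cn_b6 =)` expected copies per
#'   chromosome (default 1 and 1).
#' @param arm_frac minimum fraction of the chromosome a segment must span
#'   to count as arm-level (default 0.3).
#' @return event data frame; zero rows for a uniform baseline genome.
#' @export
classify_blastomere <- function(hseg, site = NULL, chrom_lengths,
                                baseline = c(cn_129 = 1, cn_b6 = 1),
                                arm_frac = 0.3) {
  stopifnot(length(unique(hseg$sample)) <= 1)
  if (!"half_copy" %in% names(hseg)) hseg <- detect_half_copy_segments(hseg)
  cell <- hseg$sample[1]
  ev <- .empty_events()
  for (cn in unique(hseg$chrom)) {
    seg <- hseg[hseg$chrom == cn, , drop = FALSE]
    len <- unname(chrom_lengths[cn])
    if (is.na(len)) stop("segments on unknown chromosome ", cn)
    if (min(seg$start) > 0 || max(seg$end) < len)
      stop("segments do not tile chromosome ", cn)
    on_tgt <- function(pos) !is.null(site) && cn == site$chrom &&
      abs(pos - site$cut_pos) <= site$tol
    for (hap in c("paternal", "maternal")) {
      col <- if (hap == "paternal") "cn_129_mean" else "cn_b6_mean"
      base <- unname(baseline[if (hap == "paternal") "cn_129" else "cn_b6"])
      vals <- seg[[col]]
      if (all(is.na(vals))) next
      r <- round(vals)
      # half-copy segments: micronucleus signature on the non-integer hap
      hc <- seg$half_copy &
        abs(vals - (floor(vals) + 0.5)) < abs(vals - round(vals))
      whole <- length(unique(r[!is.na(r)])) == 1 && !any(hc, na.rm = TRUE)
      if (whole && !is.na(r[1]) && r[1] != base) {
        cls <- if (r[1] < base) "whole_chromosome_monosomy"
               else "whole_chromosome_trisomy"
        ev <- rbind(ev, data.frame(
          blastomere = cell, chrom = cn, haplotype = hap, event_class = cls,
          start = 0, end = len,
          direction = if (r[1] < base) "loss" else "gain", side = "whole",
          on_target = FALSE, arm_level = TRUE,
          division_inferred = NA_character_, ambiguous = FALSE,
          stringsAsFactors = FALSE))
        next
      }
      for (k in seq_len(nrow(seg))) {
        arm <- (seg$end[k] - seg$start[k]) >= arm_frac * len
        if (isTRUE(hc[k])) {
          ev <- rbind(ev, data.frame(
            blastomere = cell, chrom = cn, haplotype = hap,
            event_class = "half_copy_micronucleus",
            start = seg$start[k], end = seg$end[k],
            direction = if (vals[k] > base) "gain" else "loss",
            side = if (seg$start[k] == 0) "centric"
                   else if (seg$end[k] == len) "acentric" else "interstitial",
            on_target = on_tgt(seg$start[k]), arm_level = arm,
            division_inferred = NA_character_, ambiguous = FALSE,
            stringsAsFactors = FALSE))
          next
        }
        if (is.na(r[k]) || r[k] == base) next
        side <- if (seg$start[k] == 0 && seg$end[k] < len) "centric"
                else if (seg$end[k] == len && seg$start[k] > 0) "acentric"
                else "interstitial"
        boundary <- if (side == "centric") seg$end[k] else seg$start[k]
        ev <- rbind(ev, data.frame(
          blastomere = cell, chrom = cn, haplotype = hap,
          event_class = if (side == "acentric") "reciprocal_gain_loss"
                        else "segment_cn_change",
          start = seg$start[k], end = seg$end[k],
          direction = if (r[k] > base) "gain" else "loss", side = side,
          on_target = on_tgt(boundary), arm_level = arm,
          division_inferred = NA_character_, ambiguous = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  ev
}

#' Pair reciprocal gains and losses across an embryo's blastomeres
#'
#' Acentric-side gains and losses of the same haplotype segment are
#' grouped; balanced group sizes identify the division at which the
#' missegregation occurred in a 3-division lineage (4+4 blastomeres:
#' division 1; 2+2: division 2; 1+1: division 3). Unbalanced groups (e.g.
#' when blastomeres failed QC) get an ambiguous division range instead of
#' a point.
#'
#' @param events event table pooled over one embryo's blastomeres.
#' @param boundary_tol breakpoints closer than this are the same segment
#'   (default 1 Mb).
#' @return the event table with `division_inferred`, `ambiguous` and a
#'   `group` id filled in for paired rows.
#' @export
pair_reciprocal_events <- function(events, boundary_tol = 1e6) {
  events$group <- rep(NA_integer_, nrow(events))
  cand <- which(events$side %in% c("acentric", "whole") &
                events$event_class %in% c("reciprocal_gain_loss",
                                          "whole_chromosome_monosomy",
                                          "whole_chromosome_trisomy"))
  if (length(cand) == 0) return(events)
  g <- 0
  used <- rep(FALSE, nrow(events))
  for (i in cand) {
    if (used[i]) next
    mates <- cand[!used[cand] &
                  events$chrom[cand] == events$chrom[i] &
                  events$haplotype[cand] == events$haplotype[i] &
                  abs(events$start[cand] - events$start[i]) <= boundary_tol]
    gains <- mates[events$direction[mates] == "gain"]
    losses <- mates[events$direction[mates] == "loss"]
    if (length(gains) == 0 || length(losses) == 0) next
    g <- g + 1
    used[mates] <- TRUE
    events$group[mates] <- g
    ng <- length(unique(events$blastomere[gains]))
    nl <- length(unique(events$blastomere[losses]))
    if (ng == nl && ng %in% c(1, 2, 4)) {
      events$division_inferred[mates] <- as.character(3 - log2(ng))
    } else {
      lo <- max(1, 3 - floor(log2(max(ng, nl))))
      events$division_inferred[mates] <- paste0(lo, "-3")
      events$ambiguous[mates] <- TRUE
    }
  }
  events
}

#' Infer a dicentric-bridge origin for a whole-chromosome monosomy
#'
#' Cleavage of both sister chromatids followed by fusion of the centric
#' ends creates a dicentric chromosome; at the next anaphase one daughter
#' inherits both centric copies (plus, typically, the co-segregating
#' acentric fragment) and its sister is left monosomic for the cut
#' homolog. The rule fires when (i) some blastomere has zero copies of the
#' cut haplotype across the whole targeted chromosome and (ii) another
#' blastomere carries surplus (>= 2) copies of that haplotype over the
#' centric portion. Monosomy without sibling surplus is left unclassified
#' for manual review.
#'
#' @param events embryo event table (from [classify_blastomere()] rows).
#' @param hseg pooled haplotype segment table for the embryo.
#' @param site the [target_site()].
#' @return one-row bridge event data frame, or `NULL`.
#' @export
infer_bridge_monosomy <- function(events, hseg, site) {
  mono <- events[events$event_class == "whole_chromosome_monosomy" &
                 events$chrom == site$chrom, , drop = FALSE]
  if (nrow(mono) == 0) return(NULL)
  hap <- mono$haplotype[1]
  col <- if (hap == "paternal") "cn_129_mean" else "cn_b6_mean"
  surplus <- vapply(setdiff(unique(hseg$sample), mono$blastomere),
                    function(s) {
    seg <- hseg[hseg$sample == s & hseg$chrom == site$chrom &
                hseg$start < site$cut_pos, , drop = FALSE]
    any(!is.na(seg[[col]]) & round(seg[[col]]) >= 2)
  }, logical(1))
  if (!any(surplus)) return(NULL)
  n <- length(unique(mono$blastomere))
  div <- if (log2(n) %% 1 == 0 && n <= 4) as.character(3 - log2(n))
         else NA_character_
  data.frame(blastomere = paste(unique(mono$blastomere), collapse = ","),
             chrom = site$chrom, haplotype = hap,
             event_class = "bridge_monosomy", start = 0,
             end = max(hseg$end[hseg$chrom == site$chrom]),
             direction = "loss", side = "whole", on_target = TRUE,
             arm_level = TRUE, division_inferred = div, ambiguous = is.na(div),
             stringsAsFactors = FALSE)
}

#' Infer meiotic-origin trisomies and digyny from embryo-wide haplotype CN
#'
#' A whole-chromosome gain of the same haplotype shared by every
#' QC-passing blastomere predates the zygote and is called a meiotic
#' trisomy; genome-wide triploidy with the maternal haplotype doubled in
#' all blastomeres is called digyny.
#'
#' @param hseg pooled haplotype segment table for the embryo (QC-passing
#'   blastomeres only).
#' @param ploidy a `ploidy_calls` table for the same blastomeres.
#' @param tol tolerance for whole-chromosome integer matching.
#' @return event data frame (possibly zero rows) with one row per meiotic
#'   event.
#' @export
infer_meiotic_and_digyny <- function(hseg, ploidy, tol = 0.3) {
  cells <- unique(hseg$sample)
  chroms <- unique(hseg$chrom)
  means <- array(NA_real_, c(length(cells), length(chroms), 2),
                 dimnames = list(cells, chroms, c("cn_129", "cn_b6")))
  for (s in cells) for (cn in chroms)
    means[s, cn, ] <- .chrom_hap_means(hseg[hseg$sample == s, ], cn)
  ev <- .empty_events()
  all_tri <- nrow(ploidy) > 0 &&
    all(ploidy$call[ploidy$sample %in% cells] == "triploid")
  if (all_tri &&
      all(abs(means[, , "cn_b6"] - 2) <= tol, na.rm = TRUE) &&
      all(abs(means[, , "cn_129"] - 1) <= tol, na.rm = TRUE)) {
    ev <- rbind(ev, data.frame(
      blastomere = paste(cells, collapse = ","), chrom = "genome",
      haplotype = "maternal", event_class = "digyny", start = 0, end = NA,
      direction = "gain", side = "whole", on_target = FALSE,
      arm_level = TRUE, division_inferred = "meiosis", ambiguous = FALSE,
      stringsAsFactors = FALSE))
    return(ev)
  }
  base <- c(cn_129 = 1, cn_b6 = 1)
  for (cn in chroms) {
    for (hap in c("paternal", "maternal")) {
      layer <- if (hap == "paternal") "cn_129" else "cn_b6"
      v <- means[, cn, layer]
      if (all(!is.na(v)) && all(abs(v - (base[layer] + 1)) <= tol)) {
        ev <- rbind(ev, data.frame(
          blastomere = paste(cells, collapse = ","), chrom = cn,
          haplotype = hap, event_class = "meiotic_trisomy", start = 0,
          end = max(hseg$end[hseg$chrom == cn]), direction = "gain",
          side = "whole", on_target = FALSE, arm_level = TRUE,
          division_inferred = "meiosis", ambiguous = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  ev
}

#' Classify all events of one embryo
#'
#' Runs the full interpretive chain: meiotic calls first (digyny, shared
#' trisomies), then per-blastomere classification against the appropriate
#' baseline, reciprocal pairing with division inference, and the
#' dicentric-bridge monosomy rule. The most parsimonious event set is
#' reported; rows whose division could not be pinned down carry
#' `ambiguous = TRUE`.
#'
#' @param hseg pooled, haplotype-annotated, half-copy-flagged segment
#'   table for the embryo's QC-passing blastomeres.
#' @param site a [target_site()] or `NULL`.
#' @param ploidy a `ploidy_calls` table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param ... passed to [classify_blastomere()].
#' @return combined event data frame for the embryo.
#' @export
classify_embryo <- function(hseg, site = NULL, ploidy, chrom_lengths, ...) {
  meio <- infer_meiotic_and_digyny(hseg, ploidy)
  baseline <- c(cn_129 = 1, cn_b6 = 1)
  if (any(meio$event_class == "digyny")) baseline["cn_b6"] <- 2
  skip_tri <- meio$chrom[meio$event_class == "meiotic_trisomy"]
  skip_hap <- meio$haplotype[meio$event_class == "meiotic_trisomy"]
  ev <- .empty_events()
  for (s in unique(hseg$sample)) {
    e <- classify_blastomere(hseg[hseg$sample == s, , drop = FALSE], site,
                             chrom_lengths, baseline = baseline, ...)
    # shared meiotic trisomies are not per-blastomere mitotic events
    if (length(skip_tri) > 0) {
      drop <- e$event_class == "whole_chromosome_trisomy" &
        paste(e$chrom, e$haplotype) %in% paste(skip_tri, skip_hap)
      e <- e[!drop, , drop = FALSE]
    }
    ev <- rbind(ev, e)
  }
  ev <- pair_reciprocal_events(ev)
  if (!is.null(site)) {
    br <- infer_bridge_monosomy(ev, hseg, site)
    if (!is.null(br)) {
      br$group <- NA_integer_
      ev <- rbind(ev, br)
    }
  }
  meio$group <- rep(NA_integer_, nrow(meio))
  rbind(meio, ev)
}
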