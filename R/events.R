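EVENT_CLASSES <- c("acentric_missegregation", "micronucleus_underreplication",
                   "bridge_monosomy", "meiotic_trisomy", "digyny",
                   "whole_chromosome_missegregation", "none")
MEIOTIC_CLASSES <- c("meiotic_trisomy", "digyny")

#' Specify a chromosome segregation / ploidy event to implant
#'
#' Mitotic events (`acentric_missegregation`,
#' `micronucleus_underreplication`, `bridge_monosomy`,
#' `whole_chromosome_missegregation`) occur at one of the three cleavage
#' divisions; meiotic events (`meiotic_trisomy`, `digyny`) predate the
#' zygote and affect every blastomere. Cut-based events model a Cas9
#' double-strand break at `cut_pos` on a telocentric chromosome: the centric
#' fragment is `[0, cut_pos)`, the acentric fragment `[cut_pos, length)`.
#'
#' @param event_class one of the supported classes.
#' @param chrom target chromosome name (not needed for `digyny`).
#' @param cut_pos Cas9 cut coordinate in bp (cut-based events only).
#' @param division division index 1, 2 or 3 (mitotic events only).
#' @param haplotype `"maternal"` (C57BL/6J) or `"paternal"` (129/SvJae).
#' @param acentric_in_mn for `bridge_monosomy`: does the co-segregated
#'   acentric fragment end up in a micronucleus (underreplicated)?
#' @return an `event_spec` list.
#' @export
event_spec <- function(event_class, chrom = NULL, cut_pos = NULL,
                       division = NULL, haplotype = "paternal",
                       acentric_in_mn = TRUE) {
  event_class <- match.arg(event_class, EVENT_CLASSES)
  haplotype <- match.arg(haplotype, c("maternal", "paternal"))
  mitotic <- !(event_class %in% c(MEIOTIC_CLASSES, "none"))
  if (mitotic) {
    if (is.null(division) || !division %in% 1:3)
      stop("mitotic events need division in {1,2,3}")
  } else if (!is.null(division)) {
    stop("meiotic events take no division index")
  }
  cut_based <- event_class %in% c("acentric_missegregation",
                                  "micronucleus_underreplication",
                                  "bridge_monosomy")
  if (cut_based && is.null(cut_pos))
    stop(event_class, " needs a cut_pos")
  if (event_class != "digyny" && is.null(chrom) && event_class != "none")
    stop(event_class, " needs a target chromosome")
  structure(list(event_class = event_class, chrom = chrom,
                 cut_pos = cut_pos, division = division,
                 haplotype = haplotype, acentric_in_mn = acentric_in_mn),
            class = "event_spec")
}

.check_events <- function(events, genome) {
  if (length(events) == 0) return(invisible(TRUE))
  stopifnot(all(vapply(events, inherits, logical(1), "event_spec")))
  tgt <- vapply(events, function(e) e$chrom %||% NA_character_, character(1))
  cut <- !is.na(tgt) & vapply(events, function(e) !is.null(e$cut_pos), logical(1))
  if (anyDuplicated(tgt[cut]))
    stop("conflicting events: more than one Cas9 cut on chromosome ",
         tgt[cut][duplicated(tgt[cut])][1])
  for (e in events) {
    if (!is.null(e$chrom)) {
      len <- genome$chroms$length[match(e$chrom, genome$chroms$name)]
      if (is.na(len)) stop("event targets unknown chromosome ", e$chrom)
      if (!is.null(e$cut_pos) && (e$cut_pos <= 0 || e$cut_pos >= len))
        stop("cut_position outside chromosome ", e$chrom)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
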