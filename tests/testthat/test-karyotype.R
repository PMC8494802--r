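# hand-built haplotype segment tables for rule-level tests
hseg_row <- function(sample, chrom, start, end, cn129, cnb6,
                     n_bins = 20) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             n_bins = n_bins, mean_cn = (cn129 + cnb6) / 2,
             total_cn = cn129 + cnb6, cn_129_mean = cn129,
             cn_b6_mean = cnb6, stringsAsFactors = FALSE)
}
LEN <- c(chr1 = 40e6, chr2 = 30e6)

uniform_cell <- function(sample, cn129 = 1, cnb6 = 1) {
  rbind(hseg_row(sample, "chr1", 0, LEN["chr1"], cn129, cnb6),
        hseg_row(sample, "chr2", 0, LEN["chr2"], cn129, cnb6))
}

test_that("breakpoints at the cut site are flagged on-target", {
  segs <- rbind(hseg_row("b1", "chr1", 0, 20e6, 2, 1),
                hseg_row("b1", "chr1", 20e6, LEN["chr1"], 1, 1),
                hseg_row("b1", "chr2", 0, LEN["chr2"], 1, 1))
  site <- target_site("gRNA1", "chr1", 20.2e6, tol = 5e5)
  bp <- match_on_target(segs, site)
  expect_equal(nrow(bp), 1)
  expect_true(bp$on_target)
  far <- target_site("gRNA1", "chr1", 30e6, tol = 5e5)
  expect_false(match_on_target(segs, far)$on_target)
  off_chrom <- target_site("gRNA1", "chr2", 20e6, tol = 5e5)
  expect_false(match_on_target(segs, off_chrom)$on_target)
  expect_equal(nrow(match_on_target(uniform_cell("b1"), site)), 0)
})

test_that("blastomere classification covers monosomy, trisomy, reciprocal and half-copy patterns", {
  site <- target_site("g", "chr1", 20e6)
  # (0, 1) across a whole chromosome: paternal monosomy
  mono <- rbind(hseg_row("b1", "chr1", 0, LEN["chr1"], 0, 1),
                hseg_row("b1", "chr2", 0, LEN["chr2"], 1, 1))
  ev <- classify_blastomere(mono, site, LEN)
  expect_equal(ev$event_class, "whole_chromosome_monosomy")
  expect_equal(ev$haplotype, "paternal")
  # distal (2, 1) from the cut with proximal (1, 1): on-target acentric gain
  gain <- rbind(hseg_row("b2", "chr1", 0, 20e6, 1, 1),
                hseg_row("b2", "chr1", 20e6, LEN["chr1"], 2, 1),
                hseg_row("b2", "chr2", 0, LEN["chr2"], 1, 1))
  ev2 <- classify_blastomere(gain, site, LEN)
  expect_equal(ev2$event_class, "reciprocal_gain_loss")
  expect_equal(ev2$direction, "gain")
  expect_equal(ev2$side, "acentric")
  expect_true(ev2$on_target)
  expect_true(ev2$arm_level)
  # uniform (1, 1): no events
  expect_equal(nrow(classify_blastomere(uniform_cell("b3"), site, LEN)), 0)
  # half-copy flagged segment: micronucleus signature on the paternal hap
  half <- rbind(hseg_row("b4", "chr1", 0, 20e6, 1, 1),
                hseg_row("b4", "chr1", 20e6, LEN["chr1"], 0.52, 1.01),
                hseg_row("b4", "chr2", 0, LEN["chr2"], 1, 1))
  ev4 <- classify_blastomere(detect_half_copy_segments(half), site, LEN)
  expect_equal(ev4$event_class, "half_copy_micronucleus")
  expect_equal(ev4$haplotype, "paternal")
  # segments not tiling the chromosome are an error
  broken <- hseg_row("b5", "chr1", 0, 10e6, 1, 1)
  expect_error(classify_blastomere(broken, site, LEN), "tile")
})

test_that("reciprocal pairing infers the division from lineage combinatorics", {
  site <- target_site("g", "chr1", 20e6)
  make_embryo_events <- function(n_gain, n_loss) {
    cells <- list()
    for (i in seq_len(n_gain))
      cells[[length(cells) + 1]] <- rbind(
        hseg_row(paste0("g", i), "chr1", 0, 20e6, 1, 1),
        hseg_row(paste0("g", i), "chr1", 20e6, LEN["chr1"], 2, 1),
        hseg_row(paste0("g", i), "chr2", 0, LEN["chr2"], 1, 1))
    for (i in seq_len(n_loss))
      cells[[length(cells) + 1]] <- rbind(
        hseg_row(paste0("l", i), "chr1", 0, 20e6, 1, 1),
        hseg_row(paste0("l", i), "chr1", 20e6, LEN["chr1"], 0, 1),
        hseg_row(paste0("l", i), "chr2", 0, LEN["chr2"], 1, 1))
    do.call(rbind, lapply(cells, classify_blastomere, site = site,
                          chrom_lengths = LEN))
  }
  for (cfg in list(c(4, 4, 1), c(2, 2, 2), c(1, 1, 3))) {
    ev <- pair_reciprocal_events(make_embryo_events(cfg[1], cfg[2]))
    expect_true(all(ev$division_inferred == as.character(cfg[3])))
    expect_true(all(!is.na(ev$group)))
  }
  # unbalanced (missing blastomere): division degrades to a range
  ev <- pair_reciprocal_events(make_embryo_events(2, 1))
  expect_true(all(ev$ambiguous))
  expect_match(ev$division_inferred[1], "-")
  # gain on one haplotype and loss on the other never pair
  g_m <- rbind(hseg_row("x1", "chr1", 0, 20e6, 1, 1),
               hseg_row("x1", "chr1", 20e6, LEN["chr1"], 2, 1),
               hseg_row("x1", "chr2", 0, LEN["chr2"], 1, 1))
  l_p <- rbind(hseg_row("x2", "chr1", 0, 20e6, 1, 1),
               hseg_row("x2", "chr1", 20e6, LEN["chr1"], 1, 0),
               hseg_row("x2", "chr2", 0, LEN["chr2"], 1, 1))
  ev2 <- pair_reciprocal_events(rbind(
    classify_blastomere(g_m, site, LEN),
    classify_blastomere(l_p, site, LEN)))
  expect_true(all(is.na(ev2$group)))
})

test_that("bridge monosomy requires both a zero-copy homolog and a sibling centric surplus", {
  site <- target_site("g", "chr1", 25e6)
  mono1 <- rbind(hseg_row("b1", "chr1", 0, LEN["chr1"], 0, 1),
                 hseg_row("b1", "chr2", 0, LEN["chr2"], 1, 1))
  mono2 <- rbind(hseg_row("b2", "chr1", 0, LEN["chr1"], 0, 1),
                 hseg_row("b2", "chr2", 0, LEN["chr2"], 1, 1))
  surplus <- rbind(hseg_row("b3", "chr1", 0, 25e6, 2, 1),
                   hseg_row("b3", "chr1", 25e6, LEN["chr1"], 1, 1),
                   hseg_row("b3", "chr2", 0, LEN["chr2"], 1, 1))
  hseg <- rbind(mono1, mono2, surplus, uniform_cell("b4"))
  events <- do.call(rbind, lapply(c("b1", "b2", "b3", "b4"), function(s)
    classify_blastomere(hseg[hseg$sample == s, ], site, LEN)))
  br <- infer_bridge_monosomy(events, hseg, site)
  expect_equal(br$event_class, "bridge_monosomy")
  expect_equal(br$haplotype, "paternal")
  expect_equal(br$division_inferred, "2")  # two monosomic blastomeres
  # monosomy without surplus: unclassified (NULL)
  hseg2 <- rbind(mono1, uniform_cell("b3"), uniform_cell("b4"))
  events2 <- do.call(rbind, lapply(c("b1", "b3", "b4"), function(s)
    classify_blastomere(hseg2[hseg2$sample == s, ], site, LEN)))
  expect_null(infer_bridge_monosomy(events2, hseg2, site))
})

test_that("shared whole-chromosome gains are meiotic; mosaic ones are not", {
  cells <- paste0("b", 1:8)
  tris <- do.call(rbind, lapply(cells, function(s)
    rbind(hseg_row(s, "chr1", 0, LEN["chr1"], 1, 2),
          hseg_row(s, "chr2", 0, LEN["chr2"], 1, 1))))
  pl <- data.frame(sample = cells, call = "diploid", factor = 1)
  ev <- infer_meiotic_and_digyny(tris, pl)
  expect_equal(ev$event_class, "meiotic_trisomy")
  expect_equal(ev$haplotype, "maternal")
  expect_equal(ev$chrom, "chr1")
  expect_equal(ev$division_inferred, "meiosis")
  # trisomy in only 4 of 8 blastomeres is not meiotic
  mosaic <- do.call(rbind, lapply(seq_along(cells), function(i)
    rbind(hseg_row(cells[i], "chr1", 0, LEN["chr1"], 1,
                   if (i <= 4) 2 else 1),
          hseg_row(cells[i], "chr2", 0, LEN["chr2"], 1, 1))))
  expect_equal(nrow(infer_meiotic_and_digyny(mosaic, pl)), 0)
  # genome-wide 2 maternal : 1 paternal in all triploid blastomeres
  digy <- do.call(rbind, lapply(cells, function(s)
    rbind(hseg_row(s, "chr1", 0, LEN["chr1"], 1, 2),
          hseg_row(s, "chr2", 0, LEN["chr2"], 1, 2))))
  pl3 <- data.frame(sample = cells, call = "triploid", factor = 1.5)
  ev3 <- infer_meiotic_and_digyny(digy, pl3)
  expect_equal(ev3$event_class, "digyny")
})

test_that("simulated embryos are classified end-to-end with division recovery", {
  g <- tiny_genome()
  site <- target_site("g", "chr1", 20e6)
  ev <- list(event_spec("acentric_missegregation", "chr1", cut_pos = 20e6,
                        division = 2, haplotype = "paternal"))
  sim <- simulate_embryo(g, ev, deep_cov(), seed = 70)
  res <- analyze_embryo(sim, site = site)
  rec <- res$events[res$events$event_class == "reciprocal_gain_loss", ]
  expect_gte(nrow(rec), 4)  # 2 gain + 2 loss blastomeres
  expect_true(all(rec$haplotype == "paternal"))
  expect_true(all(rec$division_inferred == "2"))
  expect_true(any(rec$on_target))
  # no-event embryo: empty report
  sim0 <- simulate_embryo(g, list(), deep_cov(), seed = 71)
  res0 <- analyze_embryo(sim0, site = site)
  expect_equal(nrow(res0$events), 0)
  # bridge event recovered from simulation with its division
  simb <- simulate_embryo(g, list(event_spec("bridge_monosomy", "chr1",
                                             cut_pos = 20e6, division = 2,
                                             haplotype = "paternal")),
                          deep_cov(), seed = 72)
  resb <- analyze_embryo(simb, site = site)
  br <- resb$events[resb$events$event_class == "bridge_monosomy", ]
  expect_equal(nrow(br), 1)
  expect_equal(br$division_inferred, "2")
})
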