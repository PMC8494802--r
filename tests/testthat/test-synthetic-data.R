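test_that("genome model validates its SNP panel and chromosomes", {
  expect_error(genome_model(c(chr1 = 0)), "length")
  g <- tiny_genome()
  expect_true(all(g$chroms$telocentric))
  bad <- g$snps
  bad$pos[2] <- bad$pos[1]
  expect_error(genome_model(c(chr1 = 40e6, chr2 = 30e6, chr3 = 20e6),
                            snps = bad), "increasing")
  out <- g$snps[1:2, ]
  out$pos[2] <- 50e6
  expect_error(genome_model(c(chr1 = 40e6), snps = out), "bounds")
})

test_that("no-event embryo is uniformly diploid 1+1", {
  g <- tiny_genome()
  sim <- simulate_embryo(g, list(), deep_cov(), seed = 1)
  kar <- sim$truth$karyotype
  expect_equal(sort(unique(kar$cell)), paste0("b", 1:8))
  expect_true(all(kar$cn_mat == 1) && all(kar$cn_pat == 1))
  expect_true(all(kar$ur_mat == 0) && all(kar$ur_pat == 0))
})

test_that("acentric missegregation at division 1 gives a 4+4 reciprocal pattern", {
  g <- tiny_genome()
  ev <- list(event_spec("acentric_missegregation", "chr2", cut_pos = 12e6,
                        division = 1, haplotype = "paternal"))
  sim <- simulate_embryo(g, ev, deep_cov(), seed = 1)
  kar <- sim$truth$karyotype
  distal <- kar[kar$chrom == "chr2" & kar$start == 12e6, ]
  expect_equal(nrow(distal), 8)
  expect_equal(sum(distal$cn_pat == 2), 4)  # acentric gain
  expect_equal(sum(distal$cn_pat == 0), 4)  # LOH
  expect_true(all(distal$cn_mat == 1))
  proximal <- kar[kar$chrom == "chr2" & kar$start == 0 & kar$end == 12e6, ]
  expect_true(all(proximal$cn_pat == 1 & proximal$cn_mat == 1))
})

test_that("bridge monosomy leaves a zero-copy homolog and a surplus sister lineage", {
  g <- tiny_genome()
  ev <- list(event_spec("bridge_monosomy", "chr1", cut_pos = 25e6,
                        division = 2, haplotype = "paternal"))
  sim <- simulate_embryo(g, ev, deep_cov(), seed = 2)
  kar <- sim$truth$karyotype
  chr1 <- kar[kar$chrom == "chr1", ]
  mono <- tapply(chr1$cn_pat, chr1$cell, function(v) all(v == 0))
  expect_equal(sum(mono), 2)  # division 2: two monosomic blastomeres
  expect_true(all(chr1$cn_mat == 1))
  surplus <- chr1[chr1$start == 0 & chr1$end == 25e6 & chr1$cn_pat >= 2, ]
  expect_equal(length(unique(surplus$cell)), 2)
})

test_that("conflicting cut events on one chromosome are rejected", {
  g <- tiny_genome()
  ev <- list(event_spec("acentric_missegregation", "chr1", cut_pos = 10e6,
                        division = 1),
             event_spec("bridge_monosomy", "chr1", cut_pos = 20e6,
                        division = 2))
  expect_error(simulate_embryo(g, ev, deep_cov()), "conflicting")
  expect_error(
    simulate_embryo(g, list(event_spec("bridge_monosomy", "chr1",
                                       cut_pos = 99e6, division = 1)),
                    deep_cov()), "cut_position")
})

test_that("haplotype copy number is conserved at every division", {
  g <- tiny_genome()
  specs <- list(
    event_spec("acentric_missegregation", "chr1", cut_pos = 20e6,
               division = 2, haplotype = "maternal"),
    event_spec("whole_chromosome_missegregation", "chr3", division = 1,
               haplotype = "paternal"),
    event_spec("micronucleus_underreplication", "chr2", cut_pos = 15e6,
               division = 3, haplotype = "paternal"),
    event_spec("bridge_monosomy", "chr2", cut_pos = 18e6, division = 1,
               haplotype = "paternal"))
  for (e in specs) {
    sim <- simulate_embryo(g, list(e), deep_cov(), phase = "G2", seed = 3)
    kar <- sim$truth$karyotype
    # pointwise sum across the 8 blastomeres must equal 8 per haplotype
    for (cn in unique(kar$chrom)) {
      k <- kar[kar$chrom == cn, ]
      pts <- sort(unique(c(k$start, k$end - 1)))
      for (p in pts) {
        at <- k[k$start <= p & k$end > p, ]
        expect_equal(sum(at$cn_mat), 8)
        expect_equal(sum(at$cn_pat), 8)
      }
    }
  }
})

test_that("fixed seed reproduces every emitter byte-identically", {
  g <- tiny_genome(c(chr1 = 10e6), spacing = 5e4)
  ev <- list(event_spec("acentric_missegregation", "chr1", cut_pos = 6e6,
                        division = 1))
  s1 <- simulate_embryo(g, ev, deep_cov(), seed = 11)
  s2 <- simulate_embryo(g, ev, deep_cov(), seed = 11)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$allelic, s2$allelic)
  expect_identical(s1$svs, s2$svs)
  s3 <- simulate_embryo(g, ev, deep_cov(), seed = 12)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("expected bin counts scale with depth and are flat for a diploid genome", {
  g <- tiny_genome(c(chr1 = 30e6), spacing = 1e5)
  sim1 <- simulate_embryo(g, list(), coverage_model(2, dispersion = 0,
                                                    bin_size = 1e4),
                          seed = 5)
  sim2 <- simulate_embryo(g, list(), coverage_model(4, dispersion = 0,
                                                    bin_size = 1e4),
                          seed = 5)
  m1 <- mean(sim1$counts$counts[, "b1"])
  m2 <- mean(sim2$counts$counts[, "b1"])
  # 3000 bins: doubling mean_depth doubles the mean count
  expect_equal(m2 / m1, 2, tolerance = 0.02)
  # flat genome: every bin close to 2 * depth * bin / read_length / 2
  expect_equal(m1, 2 * 1e4 / 100, tolerance = 0.05)
})

test_that("underreplicated micronucleus DNA yields half the counts of replicated DNA", {
  g <- tiny_genome(c(chr1 = 40e6), spacing = 1e5)
  ev <- list(event_spec("micronucleus_underreplication", "chr1",
                        cut_pos = 20e6, division = 1,
                        haplotype = "paternal"))
  sim <- simulate_embryo(g, ev, coverage_model(9.45, dispersion = 0,
                                               bin_size = 1e4),
                         phase = "G2", seed = 6)
  kar <- sim$truth$karyotype
  mn_cell <- kar$cell[kar$chrom == "chr1" & kar$ur_pat == 1][1]
  cnt <- sim$counts$counts[, mn_cell]
  bins <- sim$counts$bins
  prox <- mean(cnt[bins$start < 20e6])
  dist <- mean(cnt[bins$start >= 20e6])
  # distal mass: replicated maternal (2) + micronucleated paternal (1);
  # the micronucleated copy is at half the replicated mass
  expect_equal(dist / prox, 0.75, tolerance = 0.01)
})

test_that("allelic depths reflect local haplotype dosage", {
  g <- tiny_genome(c(chr1 = 30e6, chr2 = 30e6), spacing = 5e3)
  ev <- list(event_spec("acentric_missegregation", "chr1", cut_pos = 15e6,
                        division = 1, haplotype = "maternal"))
  sim <- simulate_embryo(g, ev, deep_cov(), seed = 7)
  ad <- sim$allelic
  vaf_of <- function(cell, chrom, lo, hi) {
    d <- ad[ad$sample == cell & ad$chrom == chrom & ad$pos >= lo &
            ad$pos < hi, ]
    sum(d$alt_count) / sum(d$alt_count + d$ref_count)
  }
  # balanced 1+1 region
  expect_equal(vaf_of("b1", "chr2", 0, 30e6), 0.5, tolerance = 0.02)
  # LOH blastomere: lost the maternal (reference) distal fragment -> VAF 1
  kar <- sim$truth$karyotype
  loh <- kar$cell[kar$chrom == "chr1" & kar$start == 15e6 &
                  kar$cn_mat == 0][1]
  expect_equal(vaf_of(loh, "chr1", 15e6, 30e6), 1.0)
  # region with zero copies on both haplotypes gets zero depth
  kar0 <- kar[kar$cell == loh & kar$chrom == "chr1" & kar$start == 15e6, ]
  expect_true(all(kar0$cn_mat + kar0$cn_pat > 0) ||
              all(ad$ref_count[ad$sample == loh] >= 0))
})

test_that("digynic triploid genomes show paternal VAF of one third", {
  g <- tiny_genome(c(chr1 = 60e6), spacing = 5e3)  # 12000 SNPs
  sim <- simulate_embryo(g, list(event_spec("digyny")), deep_cov(),
                         seed = 8)
  ad <- sim$allelic[sim$allelic$sample == "b1", ]
  expect_gt(nrow(ad), 1e4)
  vaf <- sum(ad$alt_count) / sum(ad$alt_count + ad$ref_count)
  expect_equal(vaf, 1 / 3, tolerance = 0.01)
})

test_that("replication-timing track is deterministic, bounded and drives the injected bias", {
  g <- tiny_genome(c(chr1 = 30e6), spacing = 1e5)
  t1 <- simulate_repliseq_track(g, bin_size = 1e4, seed = 4)
  t2 <- simulate_repliseq_track(g, bin_size = 1e4, seed = 4)
  expect_identical(t1$value, t2$value)
  expect_true(all(is.finite(t1$value)))
  expect_true(all(abs(t1$value) <= 1))
  cov_b <- coverage_model(9.45, dispersion = 0, bin_size = 1e4,
                          repli_bias_strength = 0.4)
  sim <- simulate_embryo(g, list(), cov_b, seed = 4)
  r <- cor(sim$counts$counts[, "b1"], t1$value)
  expect_gt(r, 0.5)  # 3000 bins, positive coupling as injected
  cov_n <- coverage_model(9.45, dispersion = 0, bin_size = 1e4,
                          repli_bias_strength = -0.4)
  simn <- simulate_embryo(g, list(), cov_n, seed = 4)
  expect_lt(cor(simn$counts$counts[, "b1"], t1$value), -0.5)
})

test_that("simulated candidate SV tables contain the planted junction and filterable artifacts", {
  g <- tiny_genome()
  ev <- list(event_spec("bridge_monosomy", "chr1", cut_pos = 25e6,
                        division = 2, haplotype = "paternal"))
  sim <- simulate_embryo(g, ev, deep_cov(), seed = 9)
  cand <- sim$svs$candidates
  planted <- cand[!grepl("art", cand$id), ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$posA, 25e6)
  expect_true(any(cand$in_strain_background) || any(cand$n_reads < 3) ||
              any(cand$max_mapq <= 30))
  expect_setequal(unique(sim$svs$tallies$sample), paste0("b", 1:8))
})
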