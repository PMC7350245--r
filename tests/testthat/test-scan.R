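# Adjacent-pair genome scan and its descriptive summaries.

test_that("a fixed-difference SNP lifts itself and both neighbours to ln 2", {
  gm <- gm_fixed_difference()
  scan <- cmi_scan(gm, n_perm = 3000, seed = 2)
  s <- scan$scores
  expect_equal(s$cmi_nats, c(0, log(2), log(2), log(2), 0), tolerance = 1e-12)
  expect_equal(which(s$flagged), 2:4)
  expect_true(all(s$p_value[2:4] < 1e-3))
  # partners of the flanking SNPs point at the discriminative locus
  expect_equal(s$pair_partner_pos[2], 300L)
  expect_equal(s$pair_partner_pos[4], 300L)
})

test_that("monomorphic input scores zero everywhere and flags nothing", {
  pops <- balanced_labels(4)
  sites <- lapply(1:4, function(i) list(chrom = "1", pos = i * 100L, ref = "T",
                                        alt = "A", classes = rep("TT", 8)))
  scan <- cmi_scan(make_gm(sites, pops), n_perm = 50, seed = 1)
  expect_true(all(scan$scores$cmi_nats == 0))
  expect_false(any(scan$scores$flagged))
})

test_that("single-SNP chromosomes are reported unscored with a warning", {
  pops <- balanced_labels(4)
  sites <- list(list(chrom = "1", pos = 100L, ref = "A", alt = "G",
                     classes = ifelse(pops == "popA", "AA", "GG")),
                list(chrom = "2", pos = 100L, ref = "T", alt = "C",
                     classes = rep("TT", 8)),
                list(chrom = "2", pos = 200L, ref = "T", alt = "C",
                     classes = rep("TT", 8)))
  expect_warning(scan <- cmi_scan(make_gm(sites, pops), n_perm = 50, seed = 1),
                 "single SNP")
  s <- scan$scores
  expect_true(is.na(s$cmi_nats[s$chrom == "1"]))
  expect_false(s$flagged[s$chrom == "1"])
  expect_equal(scan$n_singleton, 1L)
})

test_that("scores are invariant to sample order and population label swap", {
  set.seed(21)
  cfg <- sim_config(seed = 21, n_chromosomes = 1, snps_per_chromosome = 30,
                    n_fixed_difference_loci = 2, n_breed_exclusive_het_loci = 2,
                    sweep = NULL, mito = NULL)
  gm <- simulate_breeds(cfg, tempfile())$gm
  base <- cmi_scan(gm, n_perm = 10, seed = 1)$scores$cmi_nats

  perm <- sample(length(gm$samples))
  gm_perm <- genotype_matrix(gm$sites, gm$classes[, perm], gm$samples[perm],
                             gm$populations[perm])
  expect_equal(cmi_scan(gm_perm, n_perm = 10, seed = 1)$scores$cmi_nats, base,
               tolerance = 1e-12)

  swapped <- factor(ifelse(gm$populations == "popA", "popB", "popA"))
  gm_swap <- genotype_matrix(gm$sites, gm$classes, gm$samples, swapped)
  expect_equal(cmi_scan(gm_swap, n_perm = 10, seed = 1)$scores$cmi_nats, base,
               tolerance = 1e-12)
})

test_that("per-chromosome pair count equals SNPs minus one", {
  cfg <- sim_config(seed = 4, n_chromosomes = 2, snps_per_chromosome = 25,
                    n_fixed_difference_loci = 0, n_breed_exclusive_het_loci = 0,
                    sweep = NULL, mito = NULL)
  gm <- simulate_breeds(cfg, tempfile())$gm
  scan <- cmi_scan(gm, n_perm = 10, seed = 1)
  # every SNP scored; each interior SNP's partner is one of its two
  # coordinate neighbours
  s <- scan$scores
  expect_false(any(is.na(s$cmi_nats)))
  for (chr in unique(s$chrom)) {
    sub <- s[s$chrom == chr, ]
    gaps <- match(sub$pair_partner_pos, sub$pos) - seq_len(nrow(sub))
    expect_true(all(abs(gaps) == 1))
  }
})

test_that("class distribution records each population's majority class per flagged SNP", {
  gm <- gm_fixed_difference()
  scan <- cmi_scan(gm, n_perm = 3000, seed = 2)
  dist <- genotype_class_distribution(scan, gm)
  get <- function(pop, cls) dist$count[dist$population == pop & dist$class == cls]
  # flagged SNPs: the AA/GG fixed difference plus two monomorphic TT partners
  expect_equal(get("popA", "AA"), 1L)
  expect_equal(get("popA", "TT"), 2L)
  expect_equal(get("popB", "GG"), 1L)
  expect_equal(get("popB", "TT"), 2L)
  expect_equal(sum(dist$count), 2L * 3L)  # one class per flagged SNP per population

  # no flagged SNPs -> all-zero table
  pops <- balanced_labels(4)
  mono <- make_gm(lapply(1:3, function(i) list(chrom = "1", pos = i * 10L,
                                               ref = "T", alt = "A",
                                               classes = rep("TT", 8))), pops)
  scan0 <- cmi_scan(mono, n_perm = 10, seed = 1)
  expect_true(all(genotype_class_distribution(scan0, mono)$count == 0L))
})

test_that("heterozygosity table reproduces the exclusive-heterozygosity pattern", {
  pops <- balanced_labels()
  # three adjacent discriminative loci on one chromosome:
  #   locus 1: popA mixes 3 het / 7 hom-ref, popB fixed hom-alt
  #   locus 2: popB mixes 2 het / 8 hom-ref, popA fixed hom-alt
  #   locus 3: fixed difference, no heterozygotes anywhere
  l1 <- c(rep("AG", 3), rep("AA", 7), rep("GG", 10))
  l2 <- c(rep("GG", 10), rep("AG", 2), rep("AA", 8))
  l3 <- c(rep("AA", 10), rep("GG", 10))
  gm <- make_gm(list(list(chrom = "1", pos = 100L, ref = "A", alt = "G", classes = l1),
                     list(chrom = "1", pos = 200L, ref = "A", alt = "G", classes = l2),
                     list(chrom = "1", pos = 300L, ref = "A", alt = "G", classes = l3)),
                pops)
  scan <- cmi_scan(gm, n_perm = 3000, seed = 5)
  expect_equal(which(scan$scores$flagged), 1:3)
  het <- heterozygosity_table(scan, gm)
  a <- het[het$population == "popA", ]
  b <- het[het$population == "popB", ]
  expect_equal(a$total_mean_het, mean(c(3, 0, 0)))
  expect_equal(a$mean_het_other_all_hom, mean(c(3, 0)))  # loci 1 and 3
  expect_equal(a$mean_het_other_any_het, 0)              # locus 2
  expect_equal(b$total_mean_het, mean(c(0, 2, 0)))
  expect_equal(b$mean_het_other_all_hom, mean(c(2, 0)))  # loci 2 and 3
  expect_equal(b$mean_het_other_any_het, 0)              # locus 1

  # with only the fixed difference flagged, the any-het partition is
  # empty and reported as undefined rather than zero
  gm3 <- gm_fixed_difference()
  scan3 <- cmi_scan(gm3, n_perm = 3000, seed = 5)
  het3 <- heterozygosity_table(scan3, gm3)
  expect_true(all(is.na(het3$mean_het_other_any_het)))
  expect_true(all(het3$total_mean_het == 0))
})

test_that("genotype profiles count individuals per class and conserve population size", {
  pops <- balanced_labels()
  l1 <- c(rep("AG", 4), rep("AA", 6), rep("GG", 10))
  l2 <- rep("TT", 20)
  gm <- make_gm(list(list(chrom = "1", pos = 150L, ref = "A", alt = "G", classes = l1),
                     list(chrom = "1", pos = 180L, ref = "T", alt = "C", classes = l2)),
                pops)
  gene <- list(chrom = "1", start = 100L, end = 200L)
  prof_a <- genotype_profile(gm, gene, "popA")
  expect_equal(prof_a["150", "AG"], 4L)
  expect_equal(prof_a["150", "AA"], 6L)
  expect_equal(prof_a["180", "TT"], 10L)
  both <- genotype_profile(gm, gene)
  for (pop in names(both)) expect_true(all(rowSums(both[[pop]]) == 10L))
  expect_warning(genotype_profile(gm, list(chrom = "1", start = 5000L, end = 6000L)),
                 "no SNPs")
})

test_that("mitochondrial summary reports flagged fraction to one decimal", {
  gm <- gm_fixed_difference(chrom = "MT")
  scan <- cmi_scan(gm, n_perm = 3000, seed = 2)
  ms <- mito_summary(scan)
  expect_equal(ms$n_total, 5L)
  expect_equal(ms$n_flagged, 3L)
  expect_equal(ms$percent_flagged, 60.0)

  # all flagged -> 100%
  pops <- balanced_labels()
  fix <- ifelse(pops == "popA", "AA", "GG")
  gm2 <- make_gm(list(list(chrom = "MT", pos = 10L, ref = "A", alt = "G", classes = fix),
                      list(chrom = "MT", pos = 20L, ref = "A", alt = "G", classes = fix)),
                 pops)
  expect_equal(mito_summary(cmi_scan(gm2, n_perm = 3000, seed = 2))$percent_flagged, 100.0)

  # none flagged -> 0%; absent contig -> empty summary
  scan0 <- cmi_scan(gm_fixed_difference(chrom = "1"), n_perm = 10, seed = 1)
  expect_true(is.na(mito_summary(scan0)$percent_flagged))
  expect_equal(mito_summary(cmi_scan(gm, n_perm = 10, seed = 1),
                            mito_name = "MT")$n_total, 5L)
})

test_that("gene annotation propagates into scan output", {
  gm <- gm_fixed_difference()
  genes <- data.frame(name = "CASN", chrom = "1", start = 250L, end = 350L,
                      strand = "+")
  scan <- cmi_scan(gm, n_perm = 3000, seed = 2, genes = genes)
  expect_equal(scan$scores$gene[3], "CASN")
  expect_true(is.na(scan$scores$gene[1]))
  het <- heterozygosity_table(scan, gm, genes = "CASN")
  expect_equal(unique(het$n_loci), 1L)
})
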