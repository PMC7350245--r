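# EHH curves, iHH integration, the cross-population scan, extreme
# selection and the overlap report.

test_that("EHH is 1 for identical haplotypes and collapses by group counting", {
  # all haplotypes identical over the window
  al <- matrix(0L, nrow = 5, ncol = 4)
  pos <- c(100L, 200L, 300L, 400L, 500L)
  curve <- ehh(al, pos, core_index = 1, direction = "downstream")
  expect_equal(curve$ehh, rep(1, 5))
  expect_equal(curve$distance_bp, c(0, 100, 200, 300, 400))

  # 4 haplotypes split 4 -> (2,2) -> singletons: EHH 1, 2/6, 0
  al2 <- rbind(c(0L, 0L, 0L, 0L),   # core
               c(0L, 0L, 1L, 1L),   # groups (2,2): sum C(2,2)*2 / C(4,2) = 2/6
               c(0L, 1L, 0L, 1L))   # all four extended haplotypes distinct
  curve2 <- ehh(al2, c(10L, 20L, 35L), core_index = 1, direction = "downstream")
  expect_equal(curve2$ehh, c(1, 2 / 6, 0))
  expect_equal(curve2$distance_bp, c(0, 10, 25))

  # chromosome edge: length-1 curve
  up <- ehh(al2, c(10L, 20L, 35L), core_index = 1, direction = "upstream")
  expect_equal(nrow(up), 1L)
  expect_equal(up$ehh, 1)
})

test_that("EHH is monotone non-increasing in both directions on random haplotypes", {
  set.seed(31)
  for (r in 1:20) {
    m <- 30; nh <- 12
    al <- matrix(rbinom(m * nh, 1, runif(m, 0.1, 0.9)), nrow = m)
    pos <- sort(sample.int(1e5, m))
    core <- sample(2:(m - 1), 1)
    for (dir in c("downstream", "upstream")) {
      e <- ehh(al, pos, core, dir)$ehh
      expect_true(all(diff(e) <= 1e-12))
    }
  }
})

test_that("iHH follows the truncated trapezoid rule", {
  up <- data.frame(distance_bp = 0, ehh = 1)
  # worked example: 75 + 27 including the first sub-threshold trapezoid;
  # the length-1 upstream curve (chromosome edge) contributes 0 area and
  # raises the edge flag
  down <- data.frame(distance_bp = c(0, 100, 200), ehh = c(1, 0.5, 0.04))
  res <- ihh(down, up, truncation_ehh = 0.05)
  expect_equal(res$area, 102)
  expect_true(res$edge_warning)
  # both directions truncated: no edge flag
  up2 <- data.frame(distance_bp = c(0, 50), ehh = c(1, 0.01))
  res_b <- ihh(down, up2, truncation_ehh = 0.05)
  expect_equal(res_b$area, 102 + 0.5 * (1 + 0.01) * 50)
  expect_false(res_b$edge_warning)

  # EHH identically 1 over 1000 bp, never truncated: rectangle + edge flag
  flat <- data.frame(distance_bp = c(0, 400, 1000), ehh = c(1, 1, 1))
  res2 <- ihh(flat, up, truncation_ehh = 0.05)
  expect_equal(res2$area, 1000)
  expect_true(res2$edge_warning)

  # integration stops at the first sub-threshold point
  long <- data.frame(distance_bp = c(0, 100, 200, 300), ehh = c(1, 0.02, 0.9, 1))
  expect_equal(ihh(long, up, truncation_ehh = 0.05)$area, 0.5 * (1 + 0.02) * 100)

  expect_error(ihh(down, up, truncation_ehh = 1.2))
})

test_that("iHH scales covariantly with physical distance", {
  set.seed(77)
  m <- 40; nh <- 10
  al <- matrix(rbinom(m * nh, 1, runif(m, 0.2, 0.8)), nrow = m)
  pos <- sort(sample.int(1e5, m))
  core <- 20
  area1 <- ihh(ehh(al, pos, core, "downstream"), ehh(al, pos, core, "upstream"))$area
  for (c_fac in c(3, 10)) {
    area_c <- ihh(ehh(al, pos * c_fac, core, "downstream"),
                  ehh(al, pos * c_fac, core, "upstream"))$area
    expect_equal(area_c, c_fac * area1, tolerance = 1e-9)
  }
})

test_that("identical haplotype sets give zero raw scores and a degeneracy warning", {
  set.seed(13)
  m <- 20; n <- 4
  al_a <- matrix(rbinom(m * 2 * n, 1, 0.5), nrow = m)
  haps <- cbind(al_a, al_a)  # population B is a copy of population A
  sites <- data.frame(chrom = "1", pos = sort(sample.int(1e5, m)),
                      ref = "A", alt = "G")
  classes <- matrix("AA", m, 2 * n)
  for (s in seq_len(2 * n)) {
    ab <- haps[, 2 * s - 1] + haps[, 2 * s]
    classes[, s] <- c("AA", "AG", "GG")[ab + 1]
  }
  gm <- genotype_matrix(sites, classes, sprintf("s%d", 1:(2 * n)),
                        rep(c("a", "b"), each = n), haplotypes = haps)
  expect_warning(xp <- xpehh_scan(gm), "degenerate")
  expect_true(all(xp$scores$raw == 0))
  # degenerate score distribution yields empty extreme sets
  ext <- select_extremes(xp, 0.01)
  expect_equal(nrow(ext$pop_a), 0L)
})

test_that("raw scores are antisymmetric under population swap and z is standardised", {
  sim <- simulate_breeds(sim_config(seed = 8, n_fixed_difference_loci = 0,
                                    n_breed_exclusive_het_loci = 0, mito = NULL),
                         tempfile())
  xp_ab <- xpehh_scan(sim$gm, pop_a = "popA", pop_b = "popB")
  xp_ba <- xpehh_scan(sim$gm, pop_a = "popB", pop_b = "popA")
  expect_equal(xp_ab$scores$raw, -xp_ba$scores$raw, tolerance = 1e-12)
  expect_equal(mean(xp_ab$scores$z), 0, tolerance = 1e-9)
  expect_equal(stats::var(xp_ab$scores$z), 1, tolerance = 1e-9)
})

test_that("a planted sweep in population A is recovered as the strongest positive signal", {
  sim <- simulate_breeds(sim_config(seed = 15, n_fixed_difference_loci = 0,
                                    n_breed_exclusive_het_loci = 0, mito = NULL),
                         tempfile())
  xp <- xpehh_scan(sim$gm)
  s <- xp$scores
  core <- sim$truth$pos[sim$truth$role == "sweep_core"]
  cfg <- sim$config
  half <- cfg$sweep$length_bp / 2 + cfg$chrom_length_bp / cfg$snps_per_chromosome
  top <- s[which.max(s$z), ]
  expect_equal(top$chrom, "2")
  expect_lte(abs(top$pos - core), half)
  expect_gt(top$z, 0)
  # the extreme set for population A contains the maximum
  ext <- select_extremes(xp, 0.01)
  expect_true(top$pos %in% ext$pop_a$pos)
  expect_true(all(ext$pop_a$z > 0))
})

test_that("select_extremes takes floor(n * q) sites per tail and annotates genes", {
  set.seed(55)
  raw <- rnorm(1000)
  fake <- structure(list(scores = data.frame(chrom = "1", pos = seq_len(1000) * 100L,
                                             ihh_a = 1, ihh_b = 1, raw = raw,
                                             z = as.numeric(scale(raw))),
                         n_dropped = 0L, pop_a = "a", pop_b = "b",
                         truncation = 0.05, min_ihh = 1e-8),
                    class = "xpehh_scan")
  ext <- select_extremes(fake, 0.01)
  expect_equal(nrow(ext$pop_a), 10L)
  expect_equal(nrow(ext$pop_b), 10L)
  expect_true(min(ext$pop_a$z) >= max(fake$scores$z[!fake$scores$pos %in% ext$pop_a$pos]))

  genes <- data.frame(name = "NEARBY", chrom = "1", start = 0L, end = 100100L,
                      strand = "+")
  ext_g <- select_extremes(fake, 0.01, genes = genes)
  expect_true("gene" %in% names(ext_g$pop_a))
})

test_that("overlap report intersects candidate lists and drops structural RNAs", {
  rep1 <- overlap_sets(c("A", "B", "C"), c("B", "C", "D"), c("E"))
  expect_setequal(rep1$cmi_xpehh_a, c("B", "C"))
  expect_equal(unname(rep1$counts["cmi_xpehh_a"]), 2L)
  expect_equal(length(rep1$cmi_xpehh_b), 0L)

  rep2 <- overlap_sets(c("FASN", "5S_rRNA", "U6", "7SK"), c("FASN", "5S_rRNA"),
                       character(0))
  expect_equal(rep2$cmi, "FASN")
  expect_equal(rep2$cmi_xpehh_a, "FASN")

  rep3 <- overlap_sets(character(0), c("A"), c("B"), c("A"), c("B"))
  expect_equal(length(rep3$three_way_a), 0L)
  expect_equal(length(rep3$three_way_b), 0L)

  # three-way intersection with XP-CLR lists
  rep4 <- overlap_sets(c("X", "Y", "Z"), c("X", "Y"), c("Z"), c("Y"), c("Z", "Q"))
  expect_equal(rep4$three_way_a, "Y")
  expect_equal(rep4$three_way_b, "Z")
})
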