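# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# Balanced two-population label vector.
balanced_labels <- function(n_per_pop = 10, pops = c("popA", "popB")) {
  rep(pops, each = n_per_pop)
}

# Build a genotype matrix from a list of per-site class vectors.
# sites_classes: list of list(chrom=, pos=, ref=, alt=, classes=character(n)).
make_gm <- function(sites_classes, populations) {
  sites <- do.call(rbind, lapply(sites_classes, function(s) {
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               stringsAsFactors = FALSE)
  }))
  classes <- do.call(rbind, lapply(sites_classes, function(s) s$classes))
  genotype_matrix(sites, classes,
                  samples = sprintf("s%02d", seq_along(populations)),
                  populations = populations)
}

# A 5-SNP single-chromosome matrix where SNP 3 is a fixed difference
# (AA in population A, GG in population B) and all other SNPs are
# monomorphic TT.
gm_fixed_difference <- function(n_per_pop = 10, chrom = "1") {
  pops <- balanced_labels(n_per_pop)
  n <- length(pops)
  mono <- function(pos) list(chrom = chrom, pos = pos, ref = "T", alt = "A",
                             classes = rep("TT", n))
  fixed <- list(chrom = chrom, pos = 300L, ref = "A", alt = "G",
                classes = ifelse(pops == "popA", "AA", "GG"))
  make_gm(list(mono(100L), mono(200L), fixed, mono(400L), mono(500L)), pops)
}

# Write a small VCF from record strings (header generated here).
write_test_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

write_sample_map <- function(samples, pops, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

# Random three-axis count table for chain-rule / oracle properties.
random_joint3 <- function(d1 = 2, d2 = 3, d3 = 3, lambda = 4) {
  tab <- array(stats::rpois(d1 * d2 * d3, lambda), dim = c(d1, d2, d3))
  if (sum(tab) == 0) tab[1, 1, 1] <- 1
  tab
}

# Literal triple-sum oracle for the extractor: I(y; (x1, x2)) summed
# cell by cell with explicit loops (independent of the package's
# vectorised path).
extractor_triple_sum <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  py <- apply(p, 1, sum)
  p12 <- apply(p, c(2, 3), sum)
  d <- dim(p)
  total <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        pc <- p[i, j, k]
        if (pc > 0) total <- total + pc * log(pc / (py[i] * p12[j, k]))
      }
    }
  }
  total
}

# HWE genotype class vector at a background locus (label-independent).
hwe_classes <- function(n, p, ref = "A", alt = "G") {
  g <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  hom_ref <- paste0(ref, ref)
  het <- encode_site(ref, alt, "0/1")
  hom_alt <- paste0(alt, alt)
  c(hom_ref, het, hom_alt)[g + 1]
}
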