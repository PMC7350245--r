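# Truth-tagged two-population genotype/haplotype simulator.  The
# background model is deliberately simple: independent loci with a
# shared allele-frequency distribution and Hardy-Weinberg genotypes in
# both populations, so background genotypes are label-independent by
# construction.  On top of that, planted structure exercises every
# statistic in the package:
#   * fixed-difference loci    - one homozygous class per population,
#   * breed-exclusive-het loci - one population mixes het/hom while the
#                                other is fixed homozygous,
#   * epistatic locus pairs    - two adjacent loci whose joint genotype
#                                (allele parity) determines the
#                                population while each locus alone is
#                                uninformative,
#   * an extended-haplotype sweep - a carrier fraction of one
#                                population shares one haplotype over a
#                                configured segment, for XP-EHH.
# Linkage disequilibrium is absent outside the injected sweep.

#' Simulator configuration
#'
#' Builds the configuration consumed by [simulate_breeds()].  Defaults
#' describe a balanced 10 + 10 two-breed design with two 1-Mb autosomes
#' carrying a handful of planted discriminative loci, a 200-kb sweep in
#' population A on chromosome 2, and a 33-SNP mitochondrial contig whose
#' discriminative loci are four epistatic pairs (8 SNPs).
#'
#' @param n_per_pop Samples per population.
#' @param pop_names Two population labels.
#' @param n_chromosomes,snps_per_chromosome,chrom_length_bp Autosome
#'   layout.
#' @param n_fixed_difference_loci Fixed-difference loci (perfectly
#'   discriminative homozygous classes).
#' @param n_breed_exclusive_het_loci Breed-exclusive heterozygosity
#'   loci; ownership alternates between the populations.
#' @param n_epistatic_pairs Adjacent locus pairs whose joint genotype
#'   determines the population while the marginals do not.
#' @param background_freq Range of the shared background allele
#'   frequency (uniform draw per locus).
#' @param sweep `NULL`, or a list `chrom, core_bp, carrier_fraction,
#'   length_bp` describing a haplotype sweep in population A.
#' @param mito `NULL`, or a list `contig, length_bp, n_snps,
#'   n_fixed_difference_loci, n_epistatic_pairs` for the mitochondrial
#'   contig (simulated as homozygous, haploid-like genotypes).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_pop = 10L,
                       pop_names = c("popA", "popB"),
                       n_chromosomes = 2L,
                       snps_per_chromosome = 200L,
                       chrom_length_bp = 1e6,
                       n_fixed_difference_loci = 5L,
                       n_breed_exclusive_het_loci = 4L,
                       n_epistatic_pairs = 0L,
                       background_freq = c(0.05, 0.95),
                       sweep = list(chrom = "2", core_bp = 5e5,
                                    carrier_fraction = 0.9, length_bp = 2e5),
                       mito = list(contig = "MT", length_bp = 16338L,
                                   n_snps = 33L, n_fixed_difference_loci = 0L,
                                   n_epistatic_pairs = 4L),
                       seed = 1L) {
  stopifnot(n_per_pop >= 2, length(pop_names) == 2L, pop_names[1] != pop_names[2],
            n_chromosomes >= 1, snps_per_chromosome >= 2,
            length(background_freq) == 2L, background_freq[1] > 0,
            background_freq[2] < 1)
  if (!is.null(sweep)) {
    stopifnot(sweep$carrier_fraction > 0, sweep$carrier_fraction <= 1,
              sweep$length_bp > 0, sweep$core_bp <= chrom_length_bp)
  }
  n_planted <- n_fixed_difference_loci + n_breed_exclusive_het_loci +
    2L * n_epistatic_pairs
  if (n_planted > n_chromosomes * snps_per_chromosome / 2) {
    .stopf("sim_config: too many planted loci for the configured SNP count")
  }
  structure(list(n_per_pop = as.integer(n_per_pop), pop_names = pop_names,
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 chrom_length_bp = chrom_length_bp,
                 n_fixed_difference_loci = as.integer(n_fixed_difference_loci),
                 n_breed_exclusive_het_loci = as.integer(n_breed_exclusive_het_loci),
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 background_freq = background_freq, sweep = sweep, mito = mito,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Reserve `len` adjacent unused slots on a chromosome, keeping one free
# slot of margin around every reservation so planted loci are never
# adjacent to each other.
.reserve_block <- function(used, len, eligible = NULL, max_tries = 1000L) {
  m <- length(used)
  for (t in seq_len(max_tries)) {
    start <- sample.int(m - len + 1L, 1L)
    block <- start:(start + len - 1L)
    margin <- max(1L, start - 1L):min(m, start + len)
    if (any(used[margin])) next
    if (!is.null(eligible) && !all(eligible[block])) next
    return(block)
  }
  .stopf("simulate_breeds: could not place planted loci without position collisions")
}

#' Simulate a truth-tagged two-population cohort
#'
#' Generates phased genotypes under the configuration from
#' [sim_config()], writes a plain-text VCF, a sample map TSV, a truth
#' TSV listing every planted locus with its role and expected genotype
#' structure, and a BED of synthetic genes tiling the planted loci (for
#' annotation tests), and returns the in-memory genotype matrix.
#'
#' @param config A [sim_config()] object.
#' @param out_prefix Path prefix for the output files
#'   (`<prefix>.vcf`, `<prefix>.samples.tsv`, `<prefix>.truth.tsv`,
#'   `<prefix>.genes.bed`).
#' @return Invisibly, a list with the output `paths`, the
#'   [genotype_matrix()] `gm`, the `truth` data frame and the `config`.
#' @export
simulate_breeds <- function(config, out_prefix) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_pop
  n_ind <- 2L * n
  pops <- rep(config$pop_names, each = n)
  samples <- sprintf("%s_%02d", pops, rep(seq_len(n), 2L))
  hap_pop <- rep(pops, each = 2L)
  bases <- names(.BASE_RANK)

  chrom_names <- as.character(seq_len(config$n_chromosomes))
  sweep <- config$sweep
  sweep_chrom <- if (is.null(sweep)) NA_character_ else as.character(sweep$chrom)

  all_sites <- list()
  all_haps <- list()
  truth <- list()

  plant_chroms <- setdiff(chrom_names, sweep_chrom)
  if (length(plant_chroms) == 0L) plant_chroms <- chrom_names

  # distribute planted roles round-robin over the eligible chromosomes
  roles <- c(rep("fixed_difference", config$n_fixed_difference_loci),
             rep("exclusive_het", config$n_breed_exclusive_het_loci),
             rep("epistatic_pair", config$n_epistatic_pairs))
  role_chrom <- if (length(roles) > 0) {
    rep_len(plant_chroms, length(roles))
  } else character(0)

  excl_owner_next <- 1L  # alternate exclusive-het ownership between pops

  for (chrom in chrom_names) {
    m <- config$snps_per_chromosome
    positions <- sort(sample.int(config$chrom_length_bp, m))
    in_sweep <- rep(FALSE, m)
    if (identical(chrom, sweep_chrom)) {
      core_i <- which.min(abs(positions - sweep$core_bp))
      positions[core_i] <- as.integer(sweep$core_bp)
      positions <- sort(positions)
      in_sweep <- abs(positions - sweep$core_bp) <= sweep$length_bp / 2
    }
    freq <- stats::runif(m, config$background_freq[1], config$background_freq[2])
    haps <- matrix(stats::rbinom(m * 2L * n_ind, 1L, rep(freq, 2L * n_ind)),
                   nrow = m)
    ref_alt <- t(replicate(m, sample(bases, 2L)))
    used <- rep(FALSE, m)

    chrom_roles <- which(role_chrom == chrom)
    for (r in chrom_roles) {
      role <- roles[r]
      len <- if (role == "epistatic_pair") 2L else 1L
      eligible <- if (identical(chrom, sweep_chrom)) !in_sweep else NULL
      block <- .reserve_block(used, len, eligible)
      used[block] <- TRUE
      a_cols <- which(hap_pop == config$pop_names[1])
      b_cols <- which(hap_pop == config$pop_names[2])
      if (role == "fixed_difference") {
        i <- block
        haps[i, a_cols] <- 0L
        haps[i, b_cols] <- 1L
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, pos = positions[i], role = role,
          ref = ref_alt[i, 1], alt = ref_alt[i, 2],
          class_a = .pair_class(ref_alt[i, 1], ref_alt[i, 1]),
          class_b = .pair_class(ref_alt[i, 2], ref_alt[i, 2]),
          het_a = 0L, het_b = 0L, partner_pos = NA_integer_,
          stringsAsFactors = FALSE)
      } else if (role == "exclusive_het") {
        i <- block
        owner <- excl_owner_next
        excl_owner_next <- 3L - excl_owner_next
        own_cols <- if (owner == 1L) a_cols else b_cols
        oth_cols <- if (owner == 1L) b_cols else a_cols
        k <- sample.int(n - 1L, 1L)  # heterozygous individuals in the owner
        het_ind <- sample.int(n, k)
        haps[i, own_cols] <- 0L
        for (h in het_ind) {
          pair <- own_cols[c(2L * h - 1L, 2L * h)]
          haps[i, pair] <- sample(c(0L, 1L))
        }
        haps[i, oth_cols] <- 1L
        hom <- .pair_class(ref_alt[i, 1], ref_alt[i, 1])
        het <- .pair_class(ref_alt[i, 1], ref_alt[i, 2])
        oth <- .pair_class(ref_alt[i, 2], ref_alt[i, 2])
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, pos = positions[i], role = role,
          ref = ref_alt[i, 1], alt = ref_alt[i, 2],
          class_a = if (owner == 1L) paste(hom, het, sep = "/") else oth,
          class_b = if (owner == 1L) oth else paste(hom, het, sep = "/"),
          het_a = if (owner == 1L) k else 0L,
          het_b = if (owner == 1L) 0L else k,
          partner_pos = NA_integer_, stringsAsFactors = FALSE)
      } else {  # epistatic_pair: allele parity encodes the population
        i1 <- block[1]; i2 <- block[2]
        for (s in seq_len(n_ind)) {
          cols <- c(2L * s - 1L, 2L * s)
          a <- stats::rbinom(1L, 1L, 0.5)
          b <- if (pops[s] == config$pop_names[1]) a else 1L - a
          haps[i1, cols] <- a
          haps[i2, cols] <- b
        }
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, pos = positions[c(i1, i2)], role = role,
          ref = ref_alt[c(i1, i2), 1], alt = ref_alt[c(i1, i2), 2],
          class_a = NA_character_, class_b = NA_character_,
          het_a = 0L, het_b = 0L,
          partner_pos = positions[c(i2, i1)], stringsAsFactors = FALSE)
      }
    }

    if (identical(chrom, sweep_chrom)) {
      a_cols <- which(hap_pop == config$pop_names[1])
      n_carrier <- round(sweep$carrier_fraction * length(a_cols))
      carriers <- sample(a_cols, n_carrier)
      template <- stats::rbinom(sum(in_sweep), 1L, freq[in_sweep])
      haps[in_sweep, carriers] <- template
      core_i <- which(positions == as.integer(sweep$core_bp))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, pos = positions[core_i], role = "sweep_core",
        ref = ref_alt[core_i, 1], alt = ref_alt[core_i, 2],
        class_a = NA_character_, class_b = NA_character_,
        het_a = NA_integer_, het_b = NA_integer_,
        partner_pos = NA_integer_, stringsAsFactors = FALSE)
    }

    all_sites[[chrom]] <- data.frame(chrom = chrom, pos = positions,
                                     ref = ref_alt[, 1], alt = ref_alt[, 2],
                                     stringsAsFactors = FALSE)
    all_haps[[chrom]] <- haps
  }

  # mitochondrial contig: haploid-like (every individual homozygous)
  mito <- config$mito
  if (!is.null(mito)) {
    m <- mito$n_snps
    positions <- sort(sample.int(mito$length_bp, m))
    freq <- stats::runif(m, config$background_freq[1], config$background_freq[2])
    ind_allele <- matrix(stats::rbinom(m * n_ind, 1L, rep(freq, n_ind)), nrow = m)
    ref_alt <- t(replicate(m, sample(bases, 2L)))
    used <- rep(FALSE, m)
    a_ind <- which(pops == config$pop_names[1])
    b_ind <- which(pops == config$pop_names[2])
    for (f in seq_len(mito$n_fixed_difference_loci %||% 0L)) {
      i <- .reserve_block(used, 1L)
      used[i] <- TRUE
      ind_allele[i, a_ind] <- 0L
      ind_allele[i, b_ind] <- 1L
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = mito$contig, pos = positions[i], role = "fixed_difference",
        ref = ref_alt[i, 1], alt = ref_alt[i, 2],
        class_a = .pair_class(ref_alt[i, 1], ref_alt[i, 1]),
        class_b = .pair_class(ref_alt[i, 2], ref_alt[i, 2]),
        het_a = 0L, het_b = 0L, partner_pos = NA_integer_,
        stringsAsFactors = FALSE)
    }
    for (e in seq_len(mito$n_epistatic_pairs %||% 0L)) {
      block <- .reserve_block(used, 2L)
      used[block] <- TRUE
      i1 <- block[1]; i2 <- block[2]
      for (s in seq_len(n_ind)) {
        a <- stats::rbinom(1L, 1L, 0.5)
        b <- if (pops[s] == config$pop_names[1]) a else 1L - a
        ind_allele[i1, s] <- a
        ind_allele[i2, s] <- b
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = mito$contig, pos = positions[c(i1, i2)], role = "epistatic_pair",
        ref = ref_alt[c(i1, i2), 1], alt = ref_alt[c(i1, i2), 2],
        class_a = NA_character_, class_b = NA_character_,
        het_a = 0L, het_b = 0L,
        partner_pos = positions[c(i2, i1)], stringsAsFactors = FALSE)
    }
    haps <- ind_allele[, rep(seq_len(n_ind), each = 2L), drop = FALSE]
    all_sites[[mito$contig]] <- data.frame(chrom = mito$contig, pos = positions,
                                           ref = ref_alt[, 1], alt = ref_alt[, 2],
                                           stringsAsFactors = FALSE)
    all_haps[[mito$contig]] <- haps
  }

  sites <- do.call(rbind, all_sites)
  haps <- do.call(rbind, all_haps)
  classes <- matrix(NA_character_, nrow = nrow(sites), ncol = n_ind)
  for (s in seq_len(n_ind)) {
    a <- haps[, 2L * s - 1L]
    b <- haps[, 2L * s]
    b1 <- ifelse(a == 0L, sites$ref, sites$alt)
    b2 <- ifelse(b == 0L, sites$ref, sites$alt)
    classes[, s] <- .pair_class(b1, b2)
  }
  gm <- genotype_matrix(sites, classes, samples, pops, haplotypes = haps)

  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(chrom = character(0), pos = integer(0), role = character(0),
               ref = character(0), alt = character(0), class_a = character(0),
               class_b = character(0), het_a = integer(0), het_b = integer(0),
               partner_pos = integer(0))
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  paths <- list(vcf = paste0(out_prefix, ".vcf"),
                samples = paste0(out_prefix, ".samples.tsv"),
                truth = paste0(out_prefix, ".truth.tsv"),
                genes = paste0(out_prefix, ".genes.bed"))
  write_genotype_vcf(gm, paths$vcf)
  utils::write.table(data.frame(samples, pops), paths$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = truth$chrom,
                    start = pmax(0L, truth$pos - 1L - 500L),
                    end = truth$pos + 500L,
                    name = sprintf("SYNGENE_%s_%d", truth$chrom, truth$pos))
  utils::write.table(bed, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  invisible(list(paths = paths, gm = gm, truth = truth, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
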