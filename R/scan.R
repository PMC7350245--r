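# Genome-wide adjacent-pair extractor scan plus the descriptive
# summaries built on it: per-chromosome genotype-class distributions,
# heterozygosity-pattern tables, per-gene genotype profiles, and the
# mitochondrial summary.

#' Genome-wide two-locus mutual information scan
#'
#' Scores every SNP by the mutual information extractor
#' \eqn{CI(y; x_1, x_2)} computed over consecutive same-chromosome SNP
#' pairs in coordinate order ("adjacent loci"), where \eqn{y} is the
#' two-population label.  Each SNP's score is the maximum over the (at
#' most two) pairs containing it, with the partner recorded.  Label
#' permutation p-values are computed lazily, only for SNPs whose score
#' reaches `theta` (sub-threshold SNPs are reported with p = 1 and can
#' never be flagged).  A SNP is flagged when its score is at least
#' `theta` (closed comparison: the maximal score \eqn{\ln 2} attains the
#' default threshold) and its permutation p-value is below
#' `p_threshold`.
#'
#' @param gm A [genotype_matrix()] object.
#' @param theta Score threshold in nats; the default 0.693 is
#'   \eqn{\ln 2}, the maximum achievable for a balanced two-population
#'   sample, so flagged SNP pairs fully determine the population.
#' @param p_threshold Permutation p-value cutoff (strict `<`).
#' @param n_perm Permutations per tested SNP pair.  With the add-one
#'   estimator the smallest attainable p is `1 / (n_perm + 1)`, so
#'   `n_perm` must exceed `1 / p_threshold` for any SNP to be flagged.
#' @param seed Integer seed governing the permutation stream.
#' @param genes Optional gene annotation from [read_gene_annotation()];
#'   when supplied each SNP is annotated via [assign_snps_to_genes()].
#' @param max_distance_bp Flanking distance for gene assignment.
#' @param bonferroni Divide `p_threshold` by the number of tested SNPs
#'   (off by default; the scan uses a strict raw threshold).
#' @return An object of class `cmi_scan`: a list with `scores` (data
#'   frame `chrom pos ref alt pair_partner_pos cmi_nats p_value flagged
#'   gene`), the parameters, and `n_singleton` (SNPs on single-SNP
#'   chromosomes, which cannot be scored).
#' @export
cmi_scan <- function(gm, theta = 0.693, p_threshold = 1e-3, n_perm = 10000L,
                     seed = 1L, genes = NULL, max_distance_bp = 0,
                     bonferroni = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sites <- gm$sites
  n_sites <- nrow(sites)
  y <- as.integer(gm$populations)
  if (n_sites < 2L) .stopf("cmi_scan: need at least 2 SNPs")

  # integer-coded class vector per site (levels fixed across sites)
  codes <- matrix(match(gm$classes, .GENOTYPE_CLASSES), nrow = n_sites)

  score <- rep(NA_real_, n_sites)
  partner <- rep(NA_integer_, n_sites)
  chrom_rle <- rle(sites$chrom)
  offsets <- cumsum(c(0L, chrom_rle$lengths))
  n_singleton <- 0L

  for (ci in seq_along(chrom_rle$values)) {
    idx <- (offsets[ci] + 1L):offsets[ci + 1L]
    if (length(idx) < 2L) {
      n_singleton <- n_singleton + 1L
      next
    }
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      xi <- .composite_codes(codes[i, ], codes[j, ])
      v <- .mi_codes(y, xi, 2L, max(xi))
      if (is.na(score[i]) || v > score[i]) { score[i] <- v; partner[i] <- j }
      if (is.na(score[j]) || v > score[j]) { score[j] <- v; partner[j] <- i }
    }
  }
  if (n_singleton > 0L) {
    warning(sprintf("cmi_scan: %d chromosome(s) with a single SNP left unscored", n_singleton))
  }

  # lazy permutation p-values: only SNPs at/above theta can be flagged
  pval <- ifelse(is.na(score), NA_real_, 1)
  need <- which(!is.na(score) & score >= theta)
  set.seed(seed)
  if (length(need) > 0L) {
    # one permutation run per distinct best pair
    pair_key <- paste(pmin(need, partner[need]), pmax(need, partner[need]))
    for (key in unique(pair_key)) {
      members <- need[pair_key == key]
      i <- members[1]; j <- partner[i]
      xi <- .composite_codes(codes[i, ], codes[j, ])
      nx <- max(xi)
      obs <- score[i]
      hits <- 0L
      for (b in seq_len(n_perm)) {
        yy <- sample(y)
        if (.mi_codes(yy, xi, 2L, nx) >= obs - 1e-12) hits <- hits + 1L
      }
      pval[members] <- (1 + hits) / (1 + n_perm)
    }
  }

  thr <- if (bonferroni) p_threshold / max(1L, sum(!is.na(score))) else p_threshold
  flagged <- !is.na(score) & score >= theta & pval < thr

  gene <- rep(NA_character_, n_sites)
  if (!is.null(genes)) gene <- assign_snps_to_genes(sites, genes, max_distance_bp)

  scores <- data.frame(chrom = sites$chrom, pos = sites$pos,
                       ref = sites$ref, alt = sites$alt,
                       pair_partner_pos = ifelse(is.na(partner), NA_integer_,
                                                 sites$pos[partner]),
                       cmi_nats = score, p_value = pval, flagged = flagged,
                       gene = gene, stringsAsFactors = FALSE)
  structure(list(scores = scores, theta = theta, p_threshold = thr,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 bonferroni = bonferroni, n_singleton = n_singleton,
                 drop_log = gm$drop_log,
                 populations = levels(gm$populations)),
            class = "cmi_scan")
}

#' @export
print.cmi_scan <- function(x, ...) {
  s <- x$scores
  cat("cmi_scan: ", nrow(s), " SNPs scored on ",
      length(unique(s$chrom)), " chromosome(s)\n", sep = "")
  cat(sprintf("  theta = %.4g nats, p < %.3g, %d permutations (seed %d)\n",
              x$theta, x$p_threshold, x$n_perm, x$seed))
  cat("  flagged:", sum(s$flagged), "SNPs\n")
  if (x$n_singleton > 0) cat("  unscored single-SNP chromosomes:", x$n_singleton, "\n")
  invisible(x)
}

#' @export
summary.cmi_scan <- function(object, ...) {
  s <- object$scores
  per_chrom <- stats::aggregate(cbind(n_snps = pos, n_flagged = flagged) ~ chrom,
                                data = transform(s, pos = 1L), FUN = sum)
  out <- list(per_chrom = per_chrom,
              score_quantiles = stats::quantile(s$cmi_nats, c(0, .5, .9, .99, 1),
                                                na.rm = TRUE),
              n_flagged = sum(s$flagged), theta = object$theta)
  class(out) <- "summary.cmi_scan"
  out
}

#' @export
print.summary.cmi_scan <- function(x, ...) {
  cat("Flagged SNPs per chromosome (theta =", format(x$theta), "):\n")
  print(x$per_chrom, row.names = FALSE)
  cat("Score quantiles (nats):\n")
  print(round(x$score_quantiles, 4))
  invisible(x)
}

#' @export
plot.cmi_scan <- function(x, ...) {
  s <- x$scores[!is.na(x$scores$cmi_nats), ]
  chroms <- unique(s$chrom)
  col <- (match(s$chrom, chroms) %% 2L) + 1L
  xpos <- seq_len(nrow(s))
  graphics::plot(xpos, s$cmi_nats, col = c("grey30", "steelblue")[col],
                 pch = 16, cex = 0.5, xlab = "SNP index (genome order)",
                 ylab = "extractor score (nats)", ...)
  graphics::abline(h = x$theta, lty = 2, col = "red")
  graphics::points(xpos[s$flagged], s$cmi_nats[s$flagged], col = "red", pch = 1)
  invisible(x)
}

#' Per-chromosome genotype-class distribution of flagged SNPs
#'
#' For every flagged SNP each population contributes its majority
#' genotype class at that SNP (ties broken by the canonical class
#' order); counts are tabulated per chromosome, population and class.
#'
#' @param scan A `cmi_scan` object.
#' @param gm The genotype matrix the scan was computed from.
#' @return Data frame `chrom, population, class, count` covering all ten
#'   classes for every chromosome/population (zero counts included).
#' @export
genotype_class_distribution <- function(scan, gm) {
  stopifnot(inherits(scan, "cmi_scan"), inherits(gm, "genotype_matrix"))
  s <- scan$scores
  chroms <- unique(s$chrom)
  pops <- levels(gm$populations)
  grid <- expand.grid(chrom = chroms, population = pops,
                      class = .GENOTYPE_CLASSES, stringsAsFactors = FALSE)
  grid$count <- 0L
  flag_idx <- which(s$flagged)
  for (i in flag_idx) {
    for (pop in pops) {
      cls <- gm$classes[i, gm$populations == pop]
      counts <- table(factor(cls, levels = .GENOTYPE_CLASSES))
      maj <- .GENOTYPE_CLASSES[which.max(counts)]  # ties -> canonical order
      row <- grid$chrom == s$chrom[i] & grid$population == pop & grid$class == maj
      grid$count[row] <- grid$count[row] + 1L
    }
  }
  grid
}

#' Heterozygosity-pattern table for flagged SNPs
#'
#' For each population, the mean per-locus heterozygosity count (number
#' of individuals carrying two different bases) over flagged SNPs,
#' together with the two conditional means obtained by partitioning loci
#' on whether the *other* population is all-homozygous or has at least
#' one heterozygote.  Empty partitions yield `NA` (undefined, distinct
#' from 0).
#'
#' @param scan A `cmi_scan` object.
#' @param gm The genotype matrix the scan was computed from.
#' @param genes Optional character vector of gene names; restricts the
#'   flagged SNPs to those annotated to these genes (requires the scan
#'   to have been run with gene annotation).
#' @return Data frame with one row per population and columns
#'   `total_mean_het`, `mean_het_other_all_hom`,
#'   `mean_het_other_any_het`, `n_loci`.
#' @export
heterozygosity_table <- function(scan, gm, genes = NULL) {
  stopifnot(inherits(scan, "cmi_scan"), inherits(gm, "genotype_matrix"))
  s <- scan$scores
  idx <- which(s$flagged)
  if (!is.null(genes)) idx <- idx[!is.na(s$gene[idx]) & s$gene[idx] %in% genes]
  pops <- levels(gm$populations)
  het <- .is_het_class(gm$classes)
  dim(het) <- dim(gm$classes)
  het_count <- sapply(pops, function(pop) {
    cols <- gm$populations == pop
    if (length(idx) == 0L) integer(0) else rowSums(het[idx, cols, drop = FALSE])
  })
  if (length(idx) == 1L) het_count <- matrix(het_count, nrow = 1,
                                             dimnames = list(NULL, pops))
  cond_mean <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  out <- data.frame(population = pops,
                    total_mean_het = NA_real_,
                    mean_het_other_all_hom = NA_real_,
                    mean_het_other_any_het = NA_real_,
                    n_loci = length(idx), stringsAsFactors = FALSE)
  for (pi in seq_along(pops)) {
    this <- het_count[, pops[pi]]
    other <- het_count[, pops[-pi][1]]
    out$total_mean_het[pi] <- cond_mean(this)
    out$mean_het_other_all_hom[pi] <- cond_mean(this[other == 0])
    out$mean_het_other_any_het[pi] <- cond_mean(this[other > 0])
  }
  out
}

#' Genotype profile of the SNPs inside a gene
#'
#' Per SNP in the gene interval, counts of individuals in each of the
#' ten genotype classes, for one or both populations — the tabular form
#' of a sequence-logo genotype profile.  Column sums equal the
#' population size at every site.
#'
#' @param gm A [genotype_matrix()] object.
#' @param gene One-row data frame or list with `chrom`, `start`, `end`
#'   (0-based half-open, as returned by [read_gene_annotation()]).
#' @param population Population label; `NULL` returns a named list with
#'   one profile per population.
#' @return Integer matrix (sites x 10 classes, rownames = positions), or
#'   a list of two such matrices.
#' @export
genotype_profile <- function(gm, gene, population = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p0 <- gm$sites$pos - 1L
  idx <- which(gm$sites$chrom == gene$chrom & p0 >= gene$start & p0 < gene$end)
  if (length(idx) == 0L) {
    warning("genotype_profile: no SNPs in interval ",
            sprintf("%s:%d-%d", gene$chrom, gene$start, gene$end))
  }
  one_pop <- function(pop) {
    cols <- gm$populations == pop
    m <- t(vapply(idx, function(i) {
      as.integer(table(factor(gm$classes[i, cols], levels = .GENOTYPE_CLASSES)))
    }, integer(length(.GENOTYPE_CLASSES))))
    if (length(idx) == 0L) m <- matrix(0L, 0, length(.GENOTYPE_CLASSES))
    dimnames(m) <- list(gm$sites$pos[idx], .GENOTYPE_CLASSES)
    m
  }
  if (!is.null(population)) return(one_pop(population))
  stats::setNames(lapply(levels(gm$populations), one_pop), levels(gm$populations))
}

#' Mitochondrial scan summary
#'
#' Counts flagged SNPs on the mitochondrial contig and the percentage
#' they represent of all mitochondrial SNPs (reported to one decimal).
#'
#' @param scan A `cmi_scan` object.
#' @param mito_name Mitochondrial contig name (default `"MT"`).
#' @return List with `n_total`, `n_flagged` and `percent_flagged`
#'   (percentage, one decimal); all zero/`NA` when the contig is absent.
#' @export
#' @examples
#' # 8 flagged of 33 mitochondrial SNPs -> 24.2%
mito_summary <- function(scan, mito_name = "MT") {
  stopifnot(inherits(scan, "cmi_scan"))
  s <- scan$scores[scan$scores$chrom == mito_name, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(list(n_total = 0L, n_flagged = 0L, percent_flagged = NA_real_))
  }
  list(n_total = nrow(s), n_flagged = sum(s$flagged),
       percent_flagged = round(100 * sum(s$flagged) / nrow(s), 1))
}
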