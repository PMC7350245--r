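# Cross-population extended haplotype homozygosity (XP-EHH), built from
# scratch on phased haplotype matrices: site-EHH decay curves, their
# trapezoidal integral (iHH) over physical distance, the normalised
# cross-population log-ratio, extreme-quantile candidate selection, and
# the gene-list overlap report used for method comparison.

# Extract the phased allele matrix of one chromosome for one population.
.pop_haps <- function(gm, chrom, population) {
  if (is.null(gm$haplotypes)) {
    .stopf("xpehh: genotype matrix has no phased haplotypes (all GT must use '|')")
  }
  rows <- which(gm$sites$chrom == chrom)
  cols <- which(rep(gm$populations, each = 2L) == population)
  list(alleles = gm$haplotypes[rows, cols, drop = FALSE],
       positions = gm$sites$pos[rows])
}

#' Extended haplotype homozygosity decay curve
#'
#' Site-EHH with both core alleles pooled (the XP-EHH formulation): at
#' each successive SNP outward from the core,
#' \deqn{EHH(d) = \sum_h \binom{c_h}{2} / \binom{n}{2}}
#' where \eqn{c_h} are the counts of distinct extended haplotypes
#' spanning the flanking SNPs from the core out to distance \eqn{d},
#' among all \eqn{n} haplotypes of the population.  The curve starts at
#' (0, 1) and is non-increasing; a core on the chromosome edge yields a
#' curve of length 1 in that direction.
#'
#' @param alleles Integer 0/1 matrix, sites x haplotypes, one
#'   chromosome, rows in coordinate order.
#' @param positions 1-based bp positions matching the rows.
#' @param core_index Row index of the core SNP.
#' @param direction `"downstream"` (increasing position) or
#'   `"upstream"`.
#' @param min_ehh Stop extending once EHH falls below this value (the
#'   sub-threshold point itself is still recorded); 0 returns the full
#'   curve.
#' @return Data frame `distance_bp, ehh`.
#' @export
ehh <- function(alleles, positions, core_index,
                direction = c("downstream", "upstream"), min_ehh = 0) {
  direction <- match.arg(direction)
  alleles <- as.matrix(alleles)
  n <- ncol(alleles)
  if (n < 2L) .stopf("ehh: need at least 2 haplotypes")
  steps <- if (direction == "downstream") {
    seq_len(nrow(alleles) - core_index) + core_index
  } else {
    rev(seq_len(core_index - 1L))
  }
  dist <- 0
  val <- 1
  g <- rep(1L, n)  # haplotype group ids over the extension window
  denom <- choose(n, 2)
  for (j in steps) {
    key <- g * 2L + alleles[j, ]
    g <- match(key, unique(key))
    cnt <- tabulate(g)
    e <- sum(choose(cnt, 2)) / denom
    dist <- c(dist, abs(positions[j] - positions[core_index]))
    val <- c(val, e)
    if (e < min_ehh || e == 0) break
  }
  data.frame(distance_bp = dist, ehh = val)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH decay curve over physical distance,
#' summed over both directions from the core.  Each direction is
#' truncated at the first sample point where EHH drops below
#' `truncation_ehh` (that point's trapezoid is included; no
#' interpolation of the crossing).  If EHH never falls below the
#' truncation before the chromosome end the direction is integrated to
#' its end and `edge_warning` is set.
#'
#' @param downstream,upstream EHH curves from [ehh()] (either may be a
#'   length-1 curve at a chromosome edge).
#' @param truncation_ehh Truncation level in (0, 1).
#' @return List with `area` (bp) and `edge_warning` (logical).
#' @export
#' @examples
#' down <- data.frame(distance_bp = c(0, 100, 200), ehh = c(1, 0.5, 0.04))
#' up <- data.frame(distance_bp = 0, ehh = 1)
#' ihh(down, up, truncation_ehh = 0.05)$area  # 102
ihh <- function(downstream, upstream, truncation_ehh = 0.05) {
  stopifnot(truncation_ehh > 0, truncation_ehh < 1)
  one <- function(curve) {
    m <- nrow(curve)
    if (m < 2L) return(list(area = 0, edge = TRUE))
    area <- 0
    for (k in 2:m) {
      area <- area + 0.5 * (curve$ehh[k - 1] + curve$ehh[k]) *
        (curve$distance_bp[k] - curve$distance_bp[k - 1])
      if (curve$ehh[k] < truncation_ehh) return(list(area = area, edge = FALSE))
    }
    list(area = area, edge = TRUE)
  }
  d <- one(downstream)
  u <- one(upstream)
  list(area = d$area + u$area, edge_warning = d$edge || u$edge)
}

#' Cross-population XP-EHH scan
#'
#' For every SNP, integrates the EHH decay curve in each population
#' (both directions, truncated at `truncation`), forms the raw score
#' \eqn{\ln(iHH_A / iHH_B)}, and standardises the retained raw scores
#' genome-wide to mean 0 and variance 1.  Positive standardised scores
#' indicate unusually long haplotype homozygosity in population A
#' (consistent with selection there); negative scores point to
#' population B.  Sites where either iHH falls below `min_ihh` are
#' dropped (log-ratios of near-zero areas are unstable).
#'
#' @param gm A phased [genotype_matrix()].
#' @param pop_a,pop_b Population labels; default the first and second
#'   level of the matrix populations.  The score sign follows this
#'   order.
#' @param truncation EHH truncation level for [ihh()].
#' @param min_ihh Minimum iHH (bp) for a site to be retained.
#' @return Object of class `xpehh_scan`: list with `scores` (data frame
#'   `chrom pos ihh_a ihh_b raw z`), `n_dropped`, the populations and
#'   parameters.
#' @export
xpehh_scan <- function(gm, pop_a = NULL, pop_b = NULL, truncation = 0.05,
                       min_ihh = 1e-8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- levels(gm$populations)
  if (is.null(pop_a)) pop_a <- pops[1]
  if (is.null(pop_b)) pop_b <- pops[2]
  if (!all(c(pop_a, pop_b) %in% pops) || pop_a == pop_b) {
    .stopf("xpehh_scan: pop_a/pop_b must be the two distinct population labels")
  }
  res <- list()
  for (chrom in unique(gm$sites$chrom)) {
    ha <- .pop_haps(gm, chrom, pop_a)
    hb <- .pop_haps(gm, chrom, pop_b)
    m <- length(ha$positions)
    ia <- ib <- rep(NA_real_, m)
    for (i in seq_len(m)) {
      ia[i] <- ihh(ehh(ha$alleles, ha$positions, i, "downstream", min_ehh = truncation),
                   ehh(ha$alleles, ha$positions, i, "upstream", min_ehh = truncation),
                   truncation)$area
      ib[i] <- ihh(ehh(hb$alleles, hb$positions, i, "downstream", min_ehh = truncation),
                   ehh(hb$alleles, hb$positions, i, "upstream", min_ehh = truncation),
                   truncation)$area
    }
    res[[chrom]] <- data.frame(chrom = chrom, pos = ha$positions,
                               ihh_a = ia, ihh_b = ib, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  keep <- df$ihh_a >= min_ihh & df$ihh_b >= min_ihh
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) .stopf("xpehh_scan: fewer than 2 retained sites; cannot normalize")
  df$raw <- log(df$ihh_a / df$ihh_b)
  s <- stats::sd(df$raw)
  if (s == 0) {
    warning("xpehh_scan: degenerate raw score distribution (zero variance); z set to 0")
    df$z <- 0
  } else {
    df$z <- (df$raw - mean(df$raw)) / s
  }
  structure(list(scores = df, n_dropped = n_dropped,
                 pop_a = pop_a, pop_b = pop_b,
                 truncation = truncation, min_ihh = min_ihh),
            class = "xpehh_scan")
}

#' @export
print.xpehh_scan <- function(x, ...) {
  cat("xpehh_scan:", nrow(x$scores), "sites (", x$n_dropped, "dropped, iHH <",
      format(x$min_ihh), ")\n")
  cat(sprintf("  populations: A = %s (positive z), B = %s (negative z)\n",
              x$pop_a, x$pop_b))
  cat(sprintf("  z range: [%.3f, %.3f]\n", min(x$scores$z), max(x$scores$z)))
  invisible(x)
}

#' @export
summary.xpehh_scan <- function(object, ...) {
  z <- object$scores$z
  out <- list(n = length(z),
              z_quantiles = stats::quantile(z, c(0, .01, .5, .99, 1)),
              top_site = object$scores[which.max(z), c("chrom", "pos", "z")],
              bottom_site = object$scores[which.min(z), c("chrom", "pos", "z")])
  class(out) <- "summary.xpehh_scan"
  out
}

#' @export
print.summary.xpehh_scan <- function(x, ...) {
  cat("XP-EHH standardised scores over", x$n, "sites\n")
  print(round(x$z_quantiles, 3))
  cat("max z:\n"); print(x$top_site, row.names = FALSE)
  cat("min z:\n"); print(x$bottom_site, row.names = FALSE)
  invisible(x)
}

#' @export
plot.xpehh_scan <- function(x, ...) {
  s <- x$scores
  chroms <- unique(s$chrom)
  col <- (match(s$chrom, chroms) %% 2L) + 1L
  graphics::plot(seq_len(nrow(s)), s$z, col = c("grey30", "steelblue")[col],
                 pch = 16, cex = 0.5, xlab = "SNP index (genome order)",
                 ylab = "XP-EHH z", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Extreme-quantile XP-EHH candidates
#'
#' Sites in the top `quantile` of the standardised score distribution
#' are candidates for selection in population A, sites in the bottom
#' `quantile` for population B (`floor(n * quantile)` sites each).  A
#' degenerate all-equal score distribution yields empty candidate sets.
#' When a gene annotation is supplied each candidate is annotated with
#' its closest gene.
#'
#' @param xp An `xpehh_scan` object.
#' @param quantile Tail fraction in (0, 0.5).
#' @param genes Optional gene annotation from [read_gene_annotation()].
#' @param max_distance_bp Flanking distance for gene assignment.
#' @return List with data frames `pop_a` and `pop_b` (columns of the
#'   scan scores plus `gene` when annotated).
#' @export
select_extremes <- function(xp, quantile = 0.01, genes = NULL,
                            max_distance_bp = 0) {
  stopifnot(inherits(xp, "xpehh_scan"), quantile > 0, quantile < 0.5)
  s <- xp$scores
  k <- floor(nrow(s) * quantile)
  if (k < 1L || stats::sd(s$z) == 0) {
    empty <- s[0, , drop = FALSE]
    return(list(pop_a = empty, pop_b = empty))
  }
  ord <- order(s$z, decreasing = TRUE)
  top <- s[ord[seq_len(k)], , drop = FALSE]
  bottom <- s[rev(ord)[seq_len(k)], , drop = FALSE]
  if (!is.null(genes)) {
    top$gene <- assign_snps_to_genes(top, genes, max_distance_bp)
    bottom$gene <- assign_snps_to_genes(bottom, genes, max_distance_bp)
  }
  list(pop_a = top, pop_b = bottom)
}

#' Overlap report between candidate gene lists
#'
#' Pairwise and three-way intersections between the CMI-flagged genes
#' and the per-population XP-EHH (and optionally XP-CLR) candidate gene
#' lists.  Structural-RNA gene names matching `exclude_pattern` are
#' removed from every list before counting.
#'
#' @param cmi_genes Character vector of genes flagged by the CMI scan.
#' @param xpehh_genes_a,xpehh_genes_b XP-EHH candidate genes for the
#'   two populations.
#' @param xpclr_genes_a,xpclr_genes_b Optional XP-CLR candidate lists
#'   (produced by the external XP-CLR tool).
#' @param exclude_pattern Regular expression for gene names to exclude
#'   (defaults to common structural/small RNA names such as 5S_rRNA,
#'   7SK, U6).
#' @return List of the filtered input sets, the pairwise intersections
#'   `cmi_xpehh_a`/`cmi_xpehh_b` (and `cmi_xpclr_*`, `three_way_*` when
#'   XP-CLR lists are given), and a named `counts` vector.
#' @export
overlap_sets <- function(cmi_genes, xpehh_genes_a, xpehh_genes_b,
                         xpclr_genes_a = NULL, xpclr_genes_b = NULL,
                         exclude_pattern = "^(5S_rRNA|5_8S_rRNA|7SK|U[0-9]+|SNOR[A-Za-z0-9]*|mir-[0-9A-Za-z-]+)$") {
  clean <- function(x) {
    if (is.null(x)) return(NULL)
    x <- unique(trimws(x))
    x[!grepl(exclude_pattern, x)]
  }
  cmi <- clean(cmi_genes)
  xa <- clean(xpehh_genes_a)
  xb <- clean(xpehh_genes_b)
  ca <- clean(xpclr_genes_a)
  cb <- clean(xpclr_genes_b)
  out <- list(cmi = cmi, xpehh_a = xa, xpehh_b = xb,
              cmi_xpehh_a = intersect(cmi, xa),
              cmi_xpehh_b = intersect(cmi, xb))
  if (!is.null(ca)) {
    out$cmi_xpclr_a <- intersect(cmi, ca)
    out$three_way_a <- Reduce(intersect, list(cmi, xa, ca))
  }
  if (!is.null(cb)) {
    out$cmi_xpclr_b <- intersect(cmi, cb)
    out$three_way_b <- Reduce(intersect, list(cmi, xb, cb))
  }
  out$counts <- vapply(out[setdiff(names(out), "counts")], length, integer(1))
  out
}
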