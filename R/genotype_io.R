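# VCF genotypes, sample->population maps, gene annotations, and the
# score-table writer.  Coordinate conventions owned here: SNP positions
# are 1-based (VCF); gene intervals are normalised to 0-based half-open
# on read (BED native; GFF3 converted).  Missing genotypes are a hard
# error: imputation is an upstream concern and entropy estimates on
# partial counts are ill-defined without an imputation model.

#' Read a sample-to-population map
#'
#' Reads a two-column TSV (`sample_id<TAB>population`, `#` comments
#' allowed, no header) assigning every sample to one of exactly two
#' populations.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `sample_id` and `population`.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", col.names = c("sample_id", "population"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    .stopf("sample map: duplicated sample id(s): %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  pops <- unique(df$population)
  if (length(pops) != 2L) {
    .stopf("sample map: expected exactly two populations, found %d (%s)",
           length(pops), paste(pops, collapse = ", "))
  }
  df
}

#' Construct a genotype matrix object
#'
#' Low-level constructor for the container used by the scan functions:
#' biallelic SNP sites with per-sample unordered base-pair genotype
#' classes and a two-population sample annotation.  Usually produced by
#' [read_vcf()] or [simulate_breeds()]; exposed so that matrices can
#' also be built programmatically.
#'
#' @param sites Data frame with columns `chrom` (character), `pos`
#'   (1-based integer), `ref`, `alt` (single bases A/C/G/T).
#' @param classes Character matrix (sites x samples) of canonical
#'   genotype classes (see [genotype_classes()]).
#' @param samples Character vector of sample ids (column order of
#'   `classes`).
#' @param populations Population label per sample (exactly two levels).
#' @param haplotypes Optional integer matrix (sites x 2*samples) of
#'   phased 0/1 allele codes; column pairs (2i-1, 2i) are the two
#'   chromosome copies of sample i.
#' @param drop_log Named integer vector of records dropped during
#'   loading.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, classes, samples, populations,
                            haplotypes = NULL,
                            drop_log = c(indel = 0L, multiallelic = 0L, other = 0L)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$pos <- as.integer(sites$pos)
  if (!all(sites$ref %in% names(.BASE_RANK)) || !all(sites$alt %in% names(.BASE_RANK))) {
    .stopf("genotype_matrix: REF/ALT bases must be single bases in {A,C,G,T}")
  }
  classes <- as.matrix(classes)
  if (nrow(classes) != nrow(sites) || ncol(classes) != length(samples)) {
    .stopf("genotype_matrix: classes must be sites x samples")
  }
  if (!all(classes %in% .GENOTYPE_CLASSES)) {
    .stopf("genotype_matrix: invalid genotype class(es): %s",
           paste(utils::head(setdiff(unique(as.vector(classes)), .GENOTYPE_CLASSES)), collapse = ", "))
  }
  populations <- factor(populations)
  if (nlevels(populations) != 2L || length(populations) != length(samples)) {
    .stopf("genotype_matrix: populations must give exactly two levels, one label per sample")
  }
  # enforce per-chromosome coordinate order and position uniqueness
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  classes <- classes[ord, , drop = FALSE]
  if (!is.null(haplotypes)) haplotypes <- haplotypes[ord, , drop = FALSE]
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) {
    .stopf("genotype_matrix: duplicated position %s:%d",
           sites$chrom[dup][1], sites$pos[dup][1])
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (ncol(haplotypes) != 2L * length(samples)) {
      .stopf("genotype_matrix: haplotypes must have 2 columns per sample")
    }
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, classes = classes,
                 samples = as.character(samples), populations = populations,
                 haplotypes = haplotypes, drop_log = drop_log),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "biallelic SNPs,",
      length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  populations:", paste(sprintf("%s (n=%d)", levels(x$populations),
                                      table(x$populations)), collapse = ", "), "\n")
  cat("  phased haplotypes:", if (is.null(x$haplotypes)) "no" else "yes", "\n")
  if (any(x$drop_log > 0)) {
    cat("  dropped on load:",
        paste(sprintf("%s=%d", names(x$drop_log), x$drop_log), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map one site's genotype calls to the ten unordered classes
#'
#' Each diploid call (`"0/1"`, `"1|0"`, ...) is mapped to one of the ten
#' unordered base-pair classes (see [genotype_classes()]); heterozygote
#' allele order does not matter (`0/1` and `1/0` give the same class).
#'
#' @param ref,alt Reference and alternate bases (single characters in
#'   A/C/G/T).
#' @param gt Character vector of GT strings with `/` or `|` separators
#'   and allele codes 0/1.
#' @return Character vector of canonical genotype classes.
#' @export
#' @examples
#' encode_site("A", "G", c("0/0", "1/0", "1|1"))  # "AA" "AG" "GG"
#' encode_site("C", "G", "0/1")                   # "GC": canonical order
encode_site <- function(ref, alt, gt) {
  if (!(ref %in% names(.BASE_RANK)) || !(alt %in% names(.BASE_RANK))) {
    .stopf("encode_site: REF/ALT must be single bases in {A,C,G,T} (got %s/%s)", ref, alt)
  }
  parts <- strsplit(gt, "[/|]")
  bad <- vapply(parts, function(p) length(p) != 2L || anyNA(suppressWarnings(as.integer(p))) ||
                  !all(p %in% c("0", "1")), logical(1))
  if (any(bad)) {
    .stopf("encode_site: malformed or missing GT '%s'", gt[bad][1])
  }
  a <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  b <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  bases <- c(ref, alt)
  .pair_class(bases[a + 1L], bases[b + 1L])
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Loads a VCF (optionally gzipped), keeps biallelic SNP records only
#' (indels and multiallelic records are dropped and counted), checks the
#' samples against a two-population sample map, and encodes every call
#' as one of the ten unordered genotype classes.  When every genotype in
#' the file is phased (`|` separators throughout) a phased haplotype
#' matrix is attached as well, enabling the XP-EHH scan.
#'
#' Missing genotypes (`./.`) are a hard error: this loader requires
#' complete matrices and treats imputation as an upstream step.
#'
#' @param path Path to a VCF or VCF.gz file with GT fields.
#' @param sample_map Data frame from [read_sample_map()] covering all
#'   VCF samples.
#' @return A [genotype_matrix()] object (with `haplotypes` non-NULL when
#'   fully phased).
#' @export
read_vcf <- function(path, sample_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) .stopf("read_vcf: no records in %s", path)

  gt_raw <- tryCatch(vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE),
                     error = function(e) .stopf("read_vcf: no GT field in %s", path))
  if (is.null(gt_raw)) .stopf("read_vcf: no GT field in %s", path)

  vcf_samples <- colnames(gt_raw)
  unmapped <- setdiff(vcf_samples, sample_map$sample_id)
  if (length(unmapped) > 0L) {
    .stopf("read_vcf: sample(s) not in sample map: %s", paste(unmapped, collapse = ", "))
  }
  extra <- setdiff(sample_map$sample_id, vcf_samples)
  if (length(extra) > 0L) {
    warning("read_vcf: sample map entries absent from VCF ignored: ",
            paste(extra, collapse = ", "))
  }

  ref <- fix$REF
  alt <- fix$ALT
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_snp <- !is_multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% names(.BASE_RANK) & alt %in% names(.BASE_RANK)
  is_indel <- !is_multi & !is_snp & (nchar(ref) != 1L | nchar(alt) != 1L)
  drop_log <- c(indel = sum(is_indel),
                multiallelic = sum(is_multi),
                other = sum(!is_snp & !is_indel & !is_multi))
  if (!any(is_snp)) .stopf("read_vcf: no biallelic SNP records in %s", path)

  keep <- which(is_snp)
  gt <- gt_raw[keep, , drop = FALSE]
  chrom <- fix$CHROM[keep]
  pos <- as.integer(fix$POS[keep])
  ref <- ref[keep]
  alt <- alt[keep]

  miss <- grepl("\\.", gt) | is.na(gt)
  if (any(miss)) {
    i <- which(miss, arr.ind = TRUE)[1, 1]
    .stopf("read_vcf: missing genotype at %s:%d (impute upstream; complete matrices required)",
           chrom[i], pos[i])
  }

  phased <- all(grepl("|", gt, fixed = TRUE))
  classes <- matrix(NA_character_, nrow = length(keep), ncol = ncol(gt))
  haps <- if (phased) matrix(NA_integer_, nrow = length(keep), ncol = 2L * ncol(gt)) else NULL
  for (i in seq_along(keep)) {
    row <- gt[i, ]
    cls <- tryCatch(encode_site(ref[i], alt[i], row),
                    error = function(e) .stopf("read_vcf: %s at %s:%d",
                                               conditionMessage(e), chrom[i], pos[i]))
    classes[i, ] <- cls
    if (phased) {
      parts <- strsplit(row, "|", fixed = TRUE)
      haps[i, ] <- as.integer(unlist(parts))
    }
  }

  gm <- genotype_matrix(
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    classes = classes, samples = vcf_samples,
    populations = sample_map$population[match(vcf_samples, sample_map$sample_id)],
    haplotypes = haps, drop_log = drop_log)
  gm
}

#' Write a genotype matrix back to VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT.  Phased separators are
#' used when the matrix carries haplotypes, so that a write/read
#' round-trip preserves sites, genotype classes, populations and
#' phasing.
#'
#' @param gm A [genotype_matrix()] object.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sites <- gm$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=cmiscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  phased <- !is.null(gm$haplotypes)
  sep <- if (phased) "|" else "/"
  n_s <- length(gm$samples)
  for (i in seq_len(nrow(sites))) {
    if (phased) {
      a <- gm$haplotypes[i, seq(1L, 2L * n_s, by = 2L)]
      b <- gm$haplotypes[i, seq(2L, 2L * n_s, by = 2L)]
    } else {
      cls <- gm$classes[i, ]
      hom_ref <- paste0(sites$ref[i], sites$ref[i])
      hom_alt <- paste0(sites$alt[i], sites$alt[i])
      a <- ifelse(cls == hom_alt, 1L, 0L)
      b <- ifelse(cls == hom_ref, 0L, 1L)
    }
    gt <- paste0(a, sep, b)
    writeLines(paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
                       sites$alt[i], ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene annotations from BED or GFF3
#'
#' Parses gene intervals and normalises all coordinates to 0-based
#' half-open (BED native; GFF3 1-based closed records converted).  For
#' GFF3 only `gene` features are kept and names are taken from the
#' `Name=` attribute, falling back to `gene_id=` then `ID=`.  Records
#' are de-duplicated by (name, chromosome).
#'
#' @param path Path to a BED4+ or GFF3 file.
#' @param format `"bed"` or `"gff3"`; guessed from the file extension
#'   when omitted.
#' @return Data frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
                 error = function(e) .stopf("read_gene_annotation: malformed %s file %s: %s",
                                            format, path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (format == "gff3") {
    keep <- !is.na(df$type) & df$type == "gene"
    df <- df[keep, , drop = FALSE]
    name <- df$Name
    if (is.null(name)) name <- rep(NA_character_, nrow(df))
    for (fallback in c("gene_id", "ID")) {
      if (!is.null(df[[fallback]])) {
        name <- ifelse(is.na(name) | name == "", df[[fallback]], name)
      }
    }
  } else {
    name <- df$name
  }
  if (is.null(name) || any(is.na(name) | name == "")) {
    .stopf("read_gene_annotation: gene name missing in %s", path)
  }
  out <- data.frame(name = as.character(name),
                    chrom = as.character(df$seqnames),
                    start = as.integer(df$start) - 1L,  # to 0-based half-open
                    end = as.integer(df$end),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "."
  bad <- out$start >= out$end
  if (any(bad)) {
    .stopf("read_gene_annotation: empty/negative interval for gene %s (%s:%d-%d)",
           out$name[bad][1], out$chrom[bad][1], out$start[bad][1], out$end[bad][1])
  }
  out <- out[!duplicated(out[, c("name", "chrom")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign SNPs to their closest gene
#'
#' A site inside a gene maps to that gene (distance 0); otherwise to the
#' nearest gene on the same chromosome within `max_distance_bp`, ties
#' broken by the smaller gene start.  Sites farther than
#' `max_distance_bp` from every gene remain unassigned (`NA`), which is
#' a valid outcome.
#'
#' @param sites Data frame with columns `chrom` and `pos` (1-based).
#' @param genes Gene interval data frame from [read_gene_annotation()]
#'   (0-based half-open coordinates).
#' @param max_distance_bp Maximum distance in bp for flanking
#'   assignment; 0 assigns inside-gene sites only.
#' @return Character vector of gene names, `NA` where unassigned.
#' @export
assign_snps_to_genes <- function(sites, genes, max_distance_bp = 0) {
  stopifnot(max_distance_bp >= 0)
  out <- rep(NA_character_, nrow(sites))
  if (nrow(genes) == 0L) return(out)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  for (chr in unique(sites$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) next
    idx <- which(sites$chrom == chr)
    p0 <- sites$pos[idx] - 1L  # 0-based position of the base
    for (j in seq_along(idx)) {
      d <- ifelse(p0[j] >= g$start & p0[j] < g$end, 0,
                  ifelse(p0[j] < g$start, g$start - p0[j], p0[j] - (g$end - 1L)))
      best <- which(d == min(d))[1]  # genes sorted by start: tie -> smaller start
      if (d[best] <= max_distance_bp) out[idx[j]] <- g$name[best]
    }
  }
  out
}

#' Write a per-SNP score table
#'
#' Writes the scan result as a TSV with header
#' `chrom pos ref alt pair_partner_pos cmi_nats p_value flagged gene`.
#'
#' @param scan A `cmi_scan` object (see [cmi_scan()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scan, path) {
  stopifnot(inherits(scan, "cmi_scan"))
  utils::write.table(scan$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
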