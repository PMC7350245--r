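# Shared low-level helpers: genotype-class canonicalisation and fast
# plug-in mutual information on integer-coded vectors.

# Canonical order of the ten unordered base-pair genotype classes.
# Heterozygote orientation is collapsed (e.g. GA -> AG); the base
# precedence A < T < G < C fixes the canonical spelling of each
# heterozygous class (AT, AG, AC, TG, TC, GC).
.GENOTYPE_CLASSES <- c("AA", "TT", "GG", "CC", "AT", "AG", "AC", "TG", "TC", "GC")
.BASE_RANK <- c(A = 1L, T = 2L, G = 3L, C = 4L)

#' Canonical genotype class order
#'
#' The ten unordered base-pair genotype classes in their canonical order:
#' the four homozygous classes first, then the six heterozygous classes
#' with orientation collapsed (`"GA"` and `"AG"` are the same class,
#' spelled `"AG"`).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' genotype_classes()
genotype_classes <- function() .GENOTYPE_CLASSES

# Map two base characters (each in A/C/G/T) to the canonical class string.
.pair_class <- function(b1, b2) {
  bad <- !(b1 %in% names(.BASE_RANK)) | !(b2 %in% names(.BASE_RANK))
  if (any(bad)) {
    stop("genotype base outside {A,C,G,T}: ",
         paste(unique(c(b1[bad], b2[bad])), collapse = ", "))
  }
  swap <- .BASE_RANK[b1] > .BASE_RANK[b2]
  lo <- ifelse(swap, b2, b1)
  hi <- ifelse(swap, b1, b2)
  paste0(lo, hi)
}

.is_het_class <- function(class) substr(class, 1L, 1L) != substr(class, 2L, 2L)

# Plug-in mutual information (nats) between two integer-coded vectors
# with known level counts.  Hot path of the permutation test: avoids
# factor/table overhead.
.mi_codes <- function(yi, xi, ny, nx) {
  n <- length(yi)
  joint <- tabulate(yi + ny * (xi - 1L), nbins = ny * nx)
  py <- tabulate(yi, nbins = ny) / n
  px <- tabulate(xi, nbins = nx) / n
  pj <- joint / n
  keep <- pj > 0
  pyx <- as.vector(outer(py, px))
  sum(pj[keep] * log(pj[keep] / pyx[keep]))
}

# Combine two integer-coded site vectors into a single composite code.
.composite_codes <- function(x1, x2) {
  key <- paste(x1, x2, sep = "\r")
  match(key, unique(key))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
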