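# Entropy, mutual information, conditional mutual information, the
# two-locus mutual information extractor, and its permutation null.
#
# All estimators are plug-in (maximum-likelihood) and use the natural
# logarithm, so values are in nats.  No bias correction is applied: the
# extractor threshold ln 2 = 0.693... is only interpretable for the raw
# definitional sums.  0 * log 0 is taken as 0 throughout.

#' Plug-in entropy of a discrete count vector
#'
#' Computes the maximum-likelihood (plug-in) estimate of the Shannon
#' entropy \eqn{H(x) = -\sum_x p(x) \log p(x)} in nats from a vector or
#' table of non-negative counts.  Cells with zero count contribute zero.
#'
#' @param counts Non-negative numeric vector, table or array of counts
#'   with positive total.
#' @return Entropy in nats (non-negative scalar).
#' @export
#' @examples
#' entropy(c(10, 10))   # ln 2 for a uniform binary variable
#' entropy(c(a = 20))   # 0 for a degenerate distribution
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    .stopf("entropy: counts must be non-negative and non-missing")
  }
  n <- sum(counts)
  if (n <= 0) .stopf("entropy: counts sum to zero")
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Plug-in mutual information between two discrete variables
#'
#' Computes \eqn{I(x;y) = \sum_{x,y} p(x,y) \log \frac{p(x,y)}{p(x)p(y)}}
#' in nats from a two-dimensional joint count table, using empirical
#' (plug-in) probabilities.  Equivalently \eqn{H(x) - H(x|y)}.
#'
#' @param joint Two-dimensional matrix or table of non-negative counts
#'   with positive total.
#' @return Mutual information in nats (clamped at 0 against floating
#'   point round-off).
#' @export
#' @examples
#' mutual_information(matrix(c(10, 0, 0, 10), 2))  # ln 2: perfect dependence
#' mutual_information(matrix(5, 2, 2))             # 0: independence
mutual_information <- function(joint) {
  joint <- as.array(joint)
  if (length(dim(joint)) != 2L) {
    .stopf("mutual_information: joint table must have exactly two axes")
  }
  if (any(joint < 0) || any(is.na(joint))) {
    .stopf("mutual_information: counts must be non-negative and non-missing")
  }
  n <- sum(joint)
  if (n <= 0) .stopf("mutual_information: counts sum to zero")
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  keep <- p > 0
  denom <- outer(px, py)
  val <- sum(p[keep] * log(p[keep] / denom[keep]))
  max(val, 0)
}

#' Conditional mutual information CI(y; x1 | x2)
#'
#' Information that the first site carries about the population label
#' beyond what the second site already carries:
#' \deqn{CI(y;x_1|x_2) = \sum_{y,s_1,s_2} p(y,s_1,s_2)
#'   \log \frac{p(s_2)\, p(y,s_1,s_2)}{p(y,s_2)\, p(s_1,s_2)}.}
#' Estimated by plug-in probabilities from a three-dimensional count
#' table with axes ordered (y, x1, x2).  Small negative round-off
#' (within 1e-12) is clamped to zero.
#'
#' @param joint Three-dimensional count array with axes (y, x1, x2).
#' @return Conditional mutual information in nats.
#' @seealso [mi_extractor()] for the joint two-locus score, related by
#'   the chain rule \eqn{CI(y;x_1,x_2) = CI(y;x_1|x_2) + I(y;x_2)}.
#' @export
conditional_mi <- function(joint) {
  joint <- as.array(joint)
  if (length(dim(joint)) != 3L) {
    .stopf("conditional_mi: joint table must have exactly three axes (y, x1, x2)")
  }
  if (any(joint < 0) || any(is.na(joint))) {
    .stopf("conditional_mi: counts must be non-negative and non-missing")
  }
  n <- sum(joint)
  if (n <= 0) .stopf("conditional_mi: counts sum to zero")
  p <- joint / n
  p_s2 <- apply(p, 3, sum)
  p_y_s2 <- apply(p, c(1, 3), sum)
  p_s1_s2 <- apply(p, c(2, 3), sum)
  d <- dim(p)
  val <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        pc <- p[i, j, k]
        if (pc > 0) {
          val <- val + pc * log(p_s2[k] * pc / (p_y_s2[i, k] * p_s1_s2[j, k]))
        }
      }
    }
  }
  if (val < 0 && val > -1e-12) val <- 0
  max(val, 0)
}

#' Two-locus mutual information extractor CI(y; x1, x2)
#'
#' The score used by the genome scan: the mutual information between a
#' binary population label and the composite genotype class of two
#' sites, \eqn{I(y; (x_1, x_2))}.  By the chain rule it equals
#' \eqn{CI(y;x_1|x_2) + I(y;x_2)}.  It is zero iff the label is
#' independent of the two-locus genotype, and bounded above by
#' \eqn{H(y) = \ln 2} for a balanced two-population sample — which is
#' why the default scan threshold is 0.693.
#'
#' @param joint Three-dimensional count array with axes (y, x1, x2);
#'   the first axis must have exactly two levels.
#' @return Extractor value in nats.
#' @export
#' @examples
#' # perfectly discriminative first locus, balanced 10 vs 10:
#' tab <- array(0, c(2, 2, 1))
#' tab[1, 1, 1] <- 10; tab[2, 2, 1] <- 10
#' mi_extractor(tab)  # = ln 2 = 0.6931...
mi_extractor <- function(joint) {
  joint <- as.array(joint)
  if (length(dim(joint)) != 3L) {
    .stopf("mi_extractor: joint table must have exactly three axes (y, x1, x2)")
  }
  if (dim(joint)[1] != 2L) {
    .stopf("mi_extractor: the population axis must have exactly 2 levels (two-population method)")
  }
  d <- dim(joint)
  m <- joint
  dim(m) <- c(d[1], d[2] * d[3])
  mutual_information(m)
}

#' Build a joint count table from observation vectors
#'
#' Convenience constructor for the count tables consumed by
#' [mutual_information()], [conditional_mi()] and [mi_extractor()].
#'
#' @param y Population labels (coerced to factor).
#' @param x1,x2 Genotype class vectors (coerced to factor); `x2` may be
#'   omitted for a two-axis table.
#' @return A contingency table with axes (y, x1) or (y, x1, x2).
#' @export
joint_counts <- function(y, x1, x2 = NULL) {
  y <- factor(y)
  x1 <- factor(x1)
  if (is.null(x2)) return(table(y = y, x1 = x1))
  x2 <- factor(x2)
  if (length(y) != length(x1) || length(y) != length(x2)) {
    .stopf("joint_counts: y, x1, x2 must have equal length")
  }
  table(y = y, x1 = x1, x2 = x2)
}

#' Permutation p-value for an extractor score
#'
#' Significance of an observed two-locus extractor value under the null
#' that population labels are exchangeable: labels are permuted while
#' the two genotype vectors stay fixed, and the extractor is recomputed
#' for each relabelling.
#'
#' In Monte-Carlo mode the add-one estimator
#' \eqn{p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (1 + n_{perm})}
#' is used, which is never zero and is a valid p-value.  In exact mode
#' all \eqn{\binom{n}{n_A}} distinct label assignments are enumerated
#' and the exact tail fraction is returned.
#'
#' @param observed_nats Observed extractor value in nats.
#' @param y Population labels for the samples (two levels).
#' @param x1,x2 Genotype class vectors for the two sites.
#' @param n_perm Number of Monte-Carlo permutations (ignored in exact
#'   mode).
#' @param seed Optional integer seed for the permutation stream; when
#'   `NULL` the caller's RNG state is used.
#' @param exact Enumerate all distinct label assignments instead of
#'   sampling.
#' @param max_exact Refuse exact enumeration beyond this many
#'   assignments (error instructs to use Monte-Carlo).
#' @return List with elements `p_value`, `exact_null` (logical) and
#'   `n_permutations` (number of relabellings evaluated).
#' @export
#' @examples
#' y <- rep(c("A", "B"), each = 2)
#' x1 <- c("AA", "AA", "GG", "GG")  # perfectly discriminating
#' x2 <- rep("TT", 4)
#' obs <- mi_extractor(joint_counts(y, x1, x2))
#' permutation_pvalue(obs, y, x1, x2, exact = TRUE)$p_value  # 2/6
permutation_pvalue <- function(observed_nats, y, x1, x2, n_perm = 999L,
                               seed = NULL, exact = FALSE, max_exact = 2e5) {
  y <- factor(y)
  if (nlevels(y) != 2L) .stopf("permutation_pvalue: y must have exactly two levels")
  n <- length(y)
  if (length(x1) != n || length(x2) != n) {
    .stopf("permutation_pvalue: x1 and x2 must match the length of y")
  }
  x1i <- as.integer(factor(x1))
  x2i <- as.integer(factor(x2))
  xi <- .composite_codes(x1i, x2i)
  nx <- max(xi)
  yi <- as.integer(y)
  tol <- 1e-12

  if (exact) {
    n_a <- sum(yi == 1L)
    total <- choose(n, n_a)
    if (total > max_exact) {
      .stopf(paste0("permutation_pvalue: %.0f balanced assignments exceed max_exact = %.0f; ",
                    "use Monte-Carlo mode (exact = FALSE)"), total, max_exact)
    }
    combos <- utils::combn(n, n_a)
    hits <- 0L
    for (col in seq_len(ncol(combos))) {
      yy <- rep(2L, n)
      yy[combos[, col]] <- 1L
      if (.mi_codes(yy, xi, 2L, nx) >= observed_nats - tol) hits <- hits + 1L
    }
    return(list(p_value = hits / total, exact_null = TRUE,
                n_permutations = as.integer(total)))
  }

  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) .stopf("permutation_pvalue: n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    yy <- sample(yi)
    if (.mi_codes(yy, xi, 2L, nx) >= observed_nats - tol) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (1 + n_perm), exact_null = FALSE,
       n_permutations = n_perm)
}
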