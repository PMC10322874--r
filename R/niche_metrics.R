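# Glycan niche width and overlap statistics.
#
# A taxon's glycan niche is its proportion vector p over degradative CAZyme
# families. Width is measured by the Levins index B = 1/sum(p_j^2) (inverse
# Simpson concentration), its (B-1)/(n-1) standardization B_A to [0,1] where
# n is the number of families predicted in the dataset, and the
# Shannon-Wiener evenness B_i = -sum(p_j log p_j). Overlap between two taxa
# is the Morisita-Horn index O = 2*sum(p*q) / (sum(p^2) + sum(q^2)).

NORM_TOL <- 1e-6

# Check |sum(p) - 1| <= tol, then renormalize exactly.
check_proportions <- function(p, what = "p") {
  if (any(p < 0)) stop(what, " has negative entries")
  s <- sum(p)
  if (abs(s - 1) > NORM_TOL)
    stop(what, " is not a proportion vector (sums to ", format(s), ")")
  p / s
}

#' Levins niche width
#'
#' B = 1 / sum(p_j^2), the inverse Simpson concentration of a proportion
#' vector: 1 for a single-family specialist, `length(p)` for a perfectly
#' even generalist.
#'
#' @param p proportion vector over CAZyme families (sums to 1 within 1e-6).
#' @return B in [1, length(p)].
#' @export
#' @examples
#' levins_B(c(0.6, 0.4))  # 1.9231
levins_B <- function(p) {
  p <- check_proportions(p)
  1 / sum(p^2)
}

#' Standardized Levins niche width
#'
#' B_A = (B - 1) / (n - 1), scaling the Levins width to [0, 1] against the
#' total number of families predicted in the dataset.
#'
#' @param p proportion vector.
#' @param n dataset-wide count of predicted degradative CAZyme families,
#'   >= 2 and >= the number of families in `p`.
#' @return B_A in [0, 1].
#' @export
levins_standardized <- function(p, n) {
  if (length(n) != 1 || is.na(n) || n < 2)
    stop("n (dataset-wide family count) must be >= 2")
  (levins_B(p) - 1) / (n - 1)
}

#' Shannon-Wiener evenness of a CAZyme profile
#'
#' B_i = -sum(p_j ln p_j) with 0*ln(0) = 0; natural logarithm.
#'
#' @param p proportion vector.
#' @return B_i in [0, ln(length(p))].
#' @export
shannon_evenness <- function(p) {
  p <- check_proportions(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Morisita-Horn niche overlap
#'
#' O = 2*sum(p_a*p_b) / (sum(p_a^2) + sum(p_b^2)) over a shared family
#' index: 1 iff the normalized profiles are identical, 0 iff their supports
#' are disjoint; symmetric in its arguments.
#'
#' @param p_a,p_b proportion vectors over the same family index (equal
#'   length; align on the union of families, zero-filled, before calling).
#' @return O in [0, 1].
#' @export
#' @examples
#' morisita_horn(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # 0.5
morisita_horn <- function(p_a, p_b) {
  if (length(p_a) != length(p_b))
    stop("profiles must be aligned on the same family index (lengths ",
         length(p_a), " vs ", length(p_b), ")")
  p_a <- check_proportions(p_a, "p_a")
  p_b <- check_proportions(p_b, "p_b")
  2 * sum(p_a * p_b) / (sum(p_a^2) + sum(p_b^2))
}

#' Per-taxon niche width table
#'
#' Computes B, B_A and B_i for every row of a taxon-by-family profile
#' matrix.
#'
#' @param m `profile_matrix` (taxa x families, RPKM).
#' @param n dataset-wide family count for the B_A standardization; defaults
#'   to `ncol(m)`. Pass the per-taxon family count instead to standardize
#'   each taxon against its own repertoire.
#' @param drop_empty drop taxa with zero total abundance (default) instead
#'   of erroring.
#' @return data.frame with columns taxon, n_families, B, B_A, B_i.
#' @export
niche_width_table <- function(m, n = ncol(m), drop_empty = TRUE) {
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    if (!drop_empty)
      stop("taxon '", rownames(m)[which(totals <= 0)[1]],
           "' has no degradative CAZyme abundance")
    m <- m[totals > 0, , drop = FALSE]
  }
  res <- lapply(rownames(m), function(tx) {
    p <- to_proportions(m[tx, ], taxon = tx)
    data.frame(taxon = tx, n_families = sum(p > 0),
               B = levins_B(p), B_A = levins_standardized(p, n),
               B_i = shannon_evenness(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise niche overlap matrix
#'
#' Morisita-Horn overlap between every pair of taxa in a profile matrix,
#' computed on proportion vectors aligned on the union of families
#' (zero-filled). The in-memory diagonal is the mathematical self-overlap 1;
#' use [write_matrix()] with `layout = "table1_style"` for the conventional
#' lower-triangular display with a 0.00 diagonal.
#'
#' @param m `profile_matrix` (>= 2 taxa) or a plain matrix of non-negative
#'   abundances with rownames.
#' @param drop_empty drop zero-abundance taxa before computing.
#' @return Symmetric matrix of class `overlap_matrix`, entries in [0, 1],
#'   diagonal 1.
#' @export
overlap_matrix <- function(m, drop_empty = TRUE) {
  totals <- rowSums(m)
  if (drop_empty) m <- m[totals > 0, , drop = FALSE]
  if (nrow(m) < 2)
    stop("overlap needs at least 2 taxa with non-zero profiles")
  p <- sweep(unclass(m), 1, rowSums(m), "/")
  k <- nrow(p)
  o <- matrix(1, k, k, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(k - 1))
    for (j in seq((i + 1), k)) {
      o[i, j] <- morisita_horn(p[i, ], p[j, ])
      o[j, i] <- o[i, j]
    }
  structure(o, sample_id = attr(m, "sample_id"),
            class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d taxa (Morisita-Horn, diagonal = 1)\n",
              nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}
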