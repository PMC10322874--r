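# Group comparisons: Wilcoxon rank-sum screens, Bray-Curtis dissimilarity,
# principal coordinates analysis, PERMANOVA.

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test with the small-sample convention: the exact
#' distribution (enumeration of rank assignments) when the combined sample
#' size is at most `exact_limit` and there are no ties, otherwise the normal
#' approximation with tie-corrected variance and continuity correction
#' (mid-ranks for ties).
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param exact_limit switch to the approximation above this combined size
#'   (default 12).
#' @return list with elements `U` (Mann-Whitney statistic for `x`) and
#'   `p_value`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= exact_limit
  res <- stats::wilcox.test(x, y, alternative = alternative,
                            exact = use_exact, correct = TRUE)
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Per-family differential screen with Benjamini-Hochberg control
#'
#' Runs a Wilcoxon rank-sum test per feature column between two groups of
#' samples and adjusts the raw p-values by the Benjamini-Hochberg procedure.
#'
#' @param m samples-by-features abundance matrix (rownames = sample ids).
#' @param groups factor/character of group labels per row (exactly 2 levels).
#' @param alpha BH significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame with columns family, p_value, p_adj, significant,
#'   ordered as the input columns.
#' @export
family_screen <- function(m, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(groups) != nrow(m))
    stop("one group label per sample row is required")
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups are required")
  p <- vapply(seq_len(ncol(m)), function(j) {
    wilcoxon_rank_sum(m[groups == lev[1], j], m[groups == lev[2], j])$p_value
  }, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(family = colnames(m), p_value = p, p_adj = p_adj,
             significant = p_adj <= alpha, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x - y| / sum(x + y) over feature columns, for every pair of
#' sample rows.
#'
#' @param m samples-by-features matrix of non-negative abundances, >= 2 rows.
#' @return A `dist` object.
#' @export
bray_curtis <- function(m) {
  if (nrow(m) < 2) stop("at least two samples are required")
  if (any(m < 0)) stop("abundances must be non-negative")
  if (sum(rowSums(m) == 0) >= 2)
    stop("dissimilarity is undefined between all-zero samples")
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it; axes
#' are ordered by decreasing eigenvalue and axes with negative eigenvalues
#' are dropped (their eigenvalues are still reported).
#'
#' @param d `dist` object or square symmetric zero-diagonal matrix.
#' @param k maximum number of axes to return (default all positive axes).
#' @return list with `points` (samples x axes), `eig` (all eigenvalues),
#'   `prop_explained` (positive eigenvalues over their sum).
#' @export
pcoa <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
      stop("distance input must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; negative and
  # null axes are handled explicitly below
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-9 * max(abs(eig)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  pts <- sc$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = eig,
       prop_explained = eig[pos] / sum(eig[pos]))
}

#' PERMANOVA (permutational multivariate ANOVA)
#'
#' One-factor PERMANOVA on a distance matrix, in Anderson's
#' sums-of-squared-distances formulation with freely permuted group labels;
#' p = (1 + #{permuted F >= observed F}) / (1 + n_permutations). Backed by
#' \code{vegan::adonis2}; the seed makes the permutation stream reproducible.
#'
#' @param d `dist` object or symmetric matrix.
#' @param groups group label per sample; every group needs >= 2 samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream (required).
#' @return list of class `permanova_result`: pseudo_F, R2, p_value,
#'   n_permutations, seed.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  groups <- as.character(groups)
  if (length(groups) != attr(d, "Size"))
    stop("one group label per sample is required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least two groups are required")
  if (any(sizes < 2))
    stop("every group needs >= 2 samples (singleton: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  dat <- data.frame(group = factor(groups))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ group, data = dat,
                        permutations = n_permutations)
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations, seed %d)\n",
    x$pseudo_F, x$R2, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
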