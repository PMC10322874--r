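# Lowest-common-ancestor taxonomy assignment from scored database hits.

#' Assign a consensus lineage by lowest common ancestor
#'
#' Given several database hits for one gene (each a ranked lineage with an
#' alignment score), keeps the hits whose score is within a top fraction of
#' the best score and returns the longest lineage prefix shared by all of
#' them. Ties at the threshold are retained (`>=`). The result is invariant
#' to the order of the hits.
#'
#' @param hits data.frame with columns `lineage` (rank-prefixed,
#'   semicolon-delimited string) and `score` (positive), or a list of
#'   `list(lineage=, score=)`.
#' @param top_fraction hits with score `>= (1 - top_fraction) * max(score)`
#'   enter the consensus; in (0, 1]. Default 0.1, the conventional
#'   top-10-percent window of DIAMOND-style LCA.
#' @return The consensus lineage string; `"unclassified"` when the retained
#'   hits share no rank at all.
#' @export
#' @examples
#' hits <- data.frame(
#'   lineage = c("d__Bacteria;p__Proteobacteria;g__Alteromonas",
#'               "d__Bacteria;p__Proteobacteria;g__Vibrio"),
#'   score = c(100, 98))
#' assign_lca(hits)  # truncates at the phylum
assign_lca <- function(hits, top_fraction = 0.1) {
  if (is.list(hits) && !is.data.frame(hits))
    hits <- data.frame(lineage = vapply(hits, `[[`, "", "lineage"),
                       score = vapply(hits, `[[`, 0, "score"),
                       stringsAsFactors = FALSE)
  if (!is.data.frame(hits) || nrow(hits) == 0)
    stop("at least one hit is required")
  if (!all(c("lineage", "score") %in% names(hits)))
    stop("hits need 'lineage' and 'score' columns")
  if (any(hits$score <= 0)) stop("hit scores must be positive")
  if (length(top_fraction) != 1 || is.na(top_fraction) ||
      top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  keep <- hits$score >= (1 - top_fraction) * max(hits$score)
  lineages <- lapply(hits$lineage[keep], parse_lineage)
  if (any(lengths(lineages) == 0)) stop("retained hit has an empty lineage")
  prefix <- lineages[[1]]
  for (ln in lineages[-1]) {
    k <- 0
    for (i in seq_len(min(length(prefix), length(ln)))) {
      if (identical(unname(prefix[i]), unname(ln[i]))) k <- i else break
    }
    prefix <- prefix[seq_len(k)]
    if (k == 0) break
  }
  if (length(prefix) == 0) return("unclassified")
  paste(prefix, collapse = ";")
}

#' Resolve per-gene hit tables to consensus lineages
#'
#' Convenience wrapper applying [assign_lca()] per gene over a long-format
#' hit table.
#'
#' @param hit_table data.frame with columns `gene_id`, `lineage`, `score`.
#' @param top_fraction see [assign_lca()].
#' @return data.frame with columns `gene_id`, `lineage`.
#' @export
assign_lca_table <- function(hit_table, top_fraction = 0.1) {
  if (!all(c("gene_id", "lineage", "score") %in% names(hit_table)))
    stop("hit table needs gene_id, lineage and score columns")
  ids <- unique(hit_table$gene_id)
  lin <- vapply(ids, function(g) {
    assign_lca(hit_table[hit_table$gene_id == g, , drop = FALSE],
               top_fraction = top_fraction)
  }, "")
  data.frame(gene_id = ids, lineage = unname(lin), stringsAsFactors = FALSE)
}
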