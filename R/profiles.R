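# RPKM normalization and per-taxon CAZyme-family profiles.

#' Reads per kilobase per million (RPKM)
#'
#' RPKM = 1e6 * (reads_mapped / gene length in kb) / library size. Invariant
#' to joint rescaling of `reads_mapped` and `total_reads`.
#'
#' @param reads_mapped non-negative read counts (vectorised).
#' @param length_bp gene lengths in base pairs, >= 1.
#' @param total_reads library size of the sample, >= 1.
#' @return RPKM values.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
rpkm <- function(reads_mapped, length_bp, total_reads) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  if (any(reads_mapped < 0)) stop("reads_mapped must be non-negative")
  1e6 * (reads_mapped / (length_bp / 1000)) / total_reads
}

# Contig length per gene: declared column, or summed gene length per contig
# as a lower bound when the table carries no contig lengths.
contig_lengths <- function(genes) {
  if ("contig_len_bp" %in% names(genes) && !all(genes$contig_len_bp == 0))
    return(genes$contig_len_bp)
  if (!"contig_id" %in% names(genes) || all(!nzchar(genes$contig_id)))
    return(genes$length_bp)
  as.integer(stats::ave(genes$length_bp, genes$contig_id, FUN = sum))
}

#' Build a taxon-by-family RPKM profile matrix for one sample
#'
#' Applies the analysis rules in one pass: genes on contigs of at most
#' `contig_min_bp` are excluded (the strict ">500 bp" convention, so 501 bp
#' passes); each multi-domain gene contributes its full RPKM to every CAZyme
#' family it carries (or an equal split with `multi_domain = "split"`);
#' glycosyltransferases (class GT) are excluded by default so the profile
#' covers degradative CAZymes only; taxa are aggregated at `rank`, with genes
#' that are unassigned at that rank pooled into an `unclassified_<rank>`
#' bucket so column totals conserve the sample-wide family totals.
#'
#' @param genes validated `glyco_genes` table.
#' @param meta validated metadata.
#' @param sample_id sample to profile (must appear in `meta`).
#' @param rank aggregation rank: "phylum", "class" or "genus".
#' @param exclude_classes CAZyme classes dropped from the profile
#'   (default `"GT"`; use `character(0)` to keep all).
#' @param contig_min_bp contigs must be strictly longer than this (default 500).
#' @param secreted_only restrict to genes flagged secreted.
#' @param multi_domain `"full"` (default) or `"split"` RPKM attribution for
#'   genes carrying several families.
#' @return A numeric matrix (taxa x families) of class `profile_matrix` with
#'   attributes `sample_id`, `rank`.
#' @export
build_profile_matrix <- function(genes, meta, sample_id,
                                 rank = c("phylum", "class", "genus"),
                                 exclude_classes = "GT",
                                 contig_min_bp = 500,
                                 secreted_only = FALSE,
                                 multi_domain = c("full", "split")) {
  rank <- match.arg(rank)
  multi_domain <- match.arg(multi_domain)
  if (!sample_id %in% meta$sample_id)
    stop("unknown sample_id '", sample_id, "'")
  total <- meta$total_reads[match(sample_id, meta$sample_id)]
  if (!sample_id %in% names(genes))
    stop("gene table has no count column for sample '", sample_id, "'")

  keep <- contig_lengths(genes) > contig_min_bp
  if (secreted_only) {
    sec <- genes$secreted
    keep <- keep & !is.na(sec) & sec %in% c("1", "TRUE", "true", "yes", 1, TRUE)
  }
  g <- genes[keep, , drop = FALSE]
  fams <- parse_families(g$cazyme_families)
  if (length(exclude_classes) > 0)
    fams <- lapply(fams, function(f) f[!family_class(f) %in% exclude_classes])
  nfam <- lengths(fams)
  has <- nfam > 0
  g <- g[has, , drop = FALSE]
  fams <- fams[has]
  nfam <- nfam[has]

  taxa <- vapply(g$lineage, lineage_at_rank, "", rank = rank,
                 USE.NAMES = FALSE)
  taxa[is.na(taxa) | !nzchar(taxa)] <- paste0("unclassified_", rank)
  abund <- rpkm(g[[sample_id]], g$length_bp, total)
  if (multi_domain == "split") abund <- abund / nfam

  fam_levels <- sort(unique(unlist(fams, use.names = FALSE)))
  tax_levels <- sort(unique(taxa))
  m <- matrix(0, length(tax_levels), length(fam_levels),
              dimnames = list(tax_levels, fam_levels))
  for (i in seq_along(fams))
    m[taxa[i], fams[[i]]] <- m[taxa[i], fams[[i]]] + abund[i]
  structure(m, sample_id = sample_id, rank = rank,
            class = c("profile_matrix", class(m)))
}

#' CAZyme gene frequency
#'
#' Fraction of predicted genes (ORFs) carrying at least one CAZyme family
#' from the given class set, as a percentage. Count-based, not
#' abundance-weighted. The conventional summary set is GH + CBM + CE + PL;
#' auxiliary activities (AA) can be added via `classes`.
#'
#' @param genes `glyco_genes` table (all predicted genes, not only CAZymes).
#' @param classes CAZyme classes that qualify (default GH, CBM, CE, PL).
#' @return Percentage in [0, 100].
#' @export
cazyme_gene_frequency <- function(genes, classes = c("GH", "CBM", "CE", "PL")) {
  if (nrow(genes) == 0) stop("empty gene set")
  fams <- parse_families(genes$cazyme_families)
  hit <- vapply(fams, function(f) any(family_class(f) %in% classes), NA)
  100 * sum(hit) / nrow(genes)
}

#' Convert a family-abundance vector to proportions
#'
#' @param abundance named non-negative numeric vector (RPKM per family) or a
#'   single row of a profile matrix.
#' @param taxon label used in error messages.
#' @return Proportion vector summing to 1.
#' @export
to_proportions <- function(abundance, taxon = "taxon") {
  if (any(abundance < 0)) stop("negative abundance")
  total <- sum(abundance)
  if (length(abundance) == 0 || total <= 0)
    stop("'", taxon, "' has no degradative CAZyme abundance; ",
         "its niche proportions are undefined")
  abundance / total
}

#' Aggregate a family profile matrix into substrate categories
#'
#' Each family column is added to every substrate category the map assigns it
#' to (a family mapped to two categories contributes fully to both). Families
#' absent from the map are pooled into an `"unmapped"` column rather than
#' dropped, so total abundance is conserved whenever no family is
#' multi-mapped.
#'
#' @param m `profile_matrix` (taxa x families).
#' @param map a `substrate_map`; default the bundled table.
#' @return A `profile_matrix` over substrate categories, with attribute
#'   `unmapped_families` listing families that fell through the map.
#' @export
substrate_aggregate <- function(m, map = default_substrate_map()) {
  fams <- colnames(m)
  cats <- lapply(fams, function(f) {
    v <- map[[f]]
    if (is.null(v) || length(v) == 0) "unmapped" else v
  })
  cat_levels <- sort(unique(unlist(cats)))
  out <- matrix(0, nrow(m), length(cat_levels),
                dimnames = list(rownames(m), cat_levels))
  for (j in seq_along(fams))
    for (cc in cats[[j]])
      out[, cc] <- out[, cc] + m[, j]
  structure(out,
            sample_id = attr(m, "sample_id"), rank = attr(m, "rank"),
            unmapped_families = fams[vapply(cats, identical, NA, "unmapped")],
            class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d taxa x %d features (sample %s, rank %s)\n",
              nrow(x), ncol(x),
              attr(x, "sample_id") %||% "?", attr(x, "rank") %||% "?"))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(8, ncol(x))),
                   drop = FALSE], digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
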