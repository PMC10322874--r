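# Carbohydrate-transporter profiling and uptake-strategy scoring.
#
# Transporter classes: ABC (broad-specificity uptake of mono/oligosaccharides),
# PTS and MFS (substrate-specific symporters/phosphotransferase), TonB
# (TonB-dependent receptors) and SusC (starch-utilization-system outer
# membrane transporter, the marker of "selfish" polysaccharide uptake).

#' Per-taxon transporter profiles
#'
#' Aggregates the RPKM of KO-annotated transporter genes by taxon at a rank,
#' per KEGG ortholog and per transporter class. Genes whose KO is absent
#' from the map are counted in the `unmapped` attribute, never silently
#' dropped into a class.
#'
#' @param genes validated `glyco_genes` table.
#' @param meta validated metadata.
#' @param sample_id sample to profile.
#' @param rank "phylum", "class" or "genus".
#' @param ko_map `transporter_map` (default the bundled table).
#' @return data.frame of class `transporter_profiles` with columns taxon,
#'   class columns (ABC, PTS, MFS, TonB, SusC); attributes `ko_abundance`
#'   (taxon x ko matrix) and `unmapped` (data.frame ko_id, n_genes).
#' @export
classify_transporters <- function(genes, meta, sample_id,
                                  rank = c("phylum", "class", "genus"),
                                  ko_map = default_transporter_map()) {
  rank <- match.arg(rank)
  if (!sample_id %in% meta$sample_id)
    stop("unknown sample_id '", sample_id, "'")
  total <- meta$total_reads[match(sample_id, meta$sample_id)]
  has_ko <- !is.na(genes$ko_id) & nzchar(genes$ko_id)
  g <- genes[has_ko, , drop = FALSE]
  mapped <- g$ko_id %in% ko_map$ko_id
  unmapped <- if (any(!mapped)) {
    stats::aggregate(list(n_genes = rep(1L, sum(!mapped))),
                     by = list(ko_id = g$ko_id[!mapped]), FUN = sum)
  } else data.frame(ko_id = character(0), n_genes = integer(0))
  g <- g[mapped, , drop = FALSE]

  taxa <- vapply(g$lineage, lineage_at_rank, "", rank = rank,
                 USE.NAMES = FALSE)
  taxa[is.na(taxa) | !nzchar(taxa)] <- paste0("unclassified_", rank)
  abund <- rpkm(g[[sample_id]], g$length_bp, total)
  kos <- sort(unique(g$ko_id))
  tax_levels <- sort(unique(taxa))
  ko_m <- matrix(0, length(tax_levels), length(kos),
                 dimnames = list(tax_levels, kos))
  for (i in seq_along(abund))
    ko_m[taxa[i], g$ko_id[i]] <- ko_m[taxa[i], g$ko_id[i]] + abund[i]

  cls <- ko_map$class[match(kos, ko_map$ko_id)]
  class_m <- matrix(0, length(tax_levels), length(TRANSPORTER_VOCAB),
                    dimnames = list(tax_levels, TRANSPORTER_VOCAB))
  for (j in seq_along(kos))
    class_m[, cls[j]] <- class_m[, cls[j]] + ko_m[, j]

  out <- data.frame(taxon = tax_levels, class_m, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ko_abundance") <- ko_m
  attr(out, "unmapped") <- unmapped
  attr(out, "sample_id") <- sample_id
  attr(out, "rank") <- rank
  class(out) <- c("transporter_profiles", "data.frame")
  out
}

#' Score a taxon's carbohydrate-uptake strategy
#'
#' Codifies the sharer/scavenger/selfish typology as a transparent rule on
#' transporter-class fractions: with f_ABC, f_specific = (PTS + MFS + TonB)
#' and f_SusC summing to 1, the label is "scavenger" when f_ABC is strictly
#' greatest (broad low-specificity uptake of dissolved hydrolysis products),
#' "selfish" when f_SusC is strictly greatest (periplasmic capture with
#' little diffusive loss), "sharer" when f_specific is strictly greatest and
#' the taxon also secretes a substantial CAZyme fraction
#' (`secreted_cazyme_fraction >= sharer_secretion_min`), and "mixed"
#' otherwise (including exact ties). This is an operationalization of a
#' qualitative typology, not a measured quantity; the rule and threshold are
#' echoed in the result.
#'
#' @param class_abundance named vector (or single-row slice of
#'   [classify_transporters()] output) with components ABC, PTS, MFS, TonB,
#'   SusC; total must be positive.
#' @param secreted_cazyme_fraction fraction of the taxon's CAZyme RPKM that
#'   is secreted, in [0, 1]; gates the "sharer" label.
#' @param sharer_secretion_min secretion threshold for "sharer"
#'   (default 0.25).
#' @return list of class `strategy_score`: fractions f_ABC, f_specific,
#'   f_SusC; label; rule description.
#' @export
strategy_score <- function(class_abundance, secreted_cazyme_fraction = 0,
                           sharer_secretion_min = 0.25) {
  v <- unlist(class_abundance)[TRANSPORTER_VOCAB]
  v[is.na(v)] <- 0
  total <- sum(v)
  if (total <= 0) stop("zero total transporter abundance; strategy undefined")
  if (secreted_cazyme_fraction < 0 || secreted_cazyme_fraction > 1)
    stop("secreted_cazyme_fraction must lie in [0, 1]")
  f <- c(ABC = unname(v["ABC"]),
         specific = unname(v["PTS"] + v["MFS"] + v["TonB"]),
         SusC = unname(v["SusC"])) / total
  top <- which(f == max(f))
  label <- if (length(top) > 1) "mixed"
  else switch(names(top),
              ABC = "scavenger",
              SusC = "selfish",
              specific = if (secreted_cazyme_fraction >= sharer_secretion_min)
                "sharer" else "mixed")
  structure(list(f_ABC = unname(f["ABC"]), f_specific = unname(f["specific"]),
                 f_SusC = unname(f["SusC"]), label = label,
                 secreted_cazyme_fraction = secreted_cazyme_fraction,
                 rule = sprintf(
                   "strict argmax over {ABC, PTS+MFS+TonB, SusC}; sharer requires secreted fraction >= %.2f; ties -> mixed",
                   sharer_secretion_min)),
            class = "strategy_score")
}

#' @export
print.strategy_score <- function(x, ...) {
  cat(sprintf("strategy: %s (f_ABC=%.2f, f_specific=%.2f, f_SusC=%.2f)\n",
              x$label, x$f_ABC, x$f_specific, x$f_SusC))
  cat("rule:", x$rule, "\n")
  invisible(x)
}
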