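# End-to-end pipeline: validated tables -> profiles -> niche metrics ->
# overlap -> substrate categories -> transporters -> group comparison,
# with a machine-readable run manifest.

#' Sample-by-family abundance matrix across samples
#'
#' Stacks the per-sample family totals (summed over taxa, unclassified
#' included) into a samples x families matrix aligned on the union of
#' families, the input to the ordination and screening steps.
#'
#' @param genes validated `glyco_genes`.
#' @param meta validated metadata.
#' @param ... passed to [build_profile_matrix()].
#' @return numeric matrix, samples x families.
#' @export
sample_family_matrix <- function(genes, meta, ...) {
  per_sample <- lapply(meta$sample_id, function(s)
    colSums(build_profile_matrix(genes, meta, s, ...)))
  fams <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, nrow(meta), length(fams),
              dimnames = list(meta$sample_id, fams))
  for (i in seq_along(per_sample))
    m[i, names(per_sample[[i]])] <- per_sample[[i]]
  m
}

#' Run the full glycan-niche pipeline
#'
#' Executes the stages in order on one gene table: validation, per-sample
#' taxon x family profiles, niche width tables, overlap matrices (full and
#' lower-triangular display layout), substrate-category matrices,
#' transporter profiles with strategy labels, and the group comparison
#' (per-family Wilcoxon screen with Benjamini-Hochberg control, Bray-Curtis,
#' PCoA, PERMANOVA). All outputs are TSV/JSON files under `out_dir`; a
#' manifest records the configuration, seed, package version and an MD5
#' checksum per file. Any stage failure aborts with the stage name.
#'
#' @param genes `glyco_genes` object or path to a gene table TSV.
#' @param meta `glyco_meta` object or path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param rank aggregation rank.
#' @param group_by metadata column (or per-sample label vector) defining the
#'   comparison groups; default `"fraction"`.
#' @param exclude_classes,contig_min_bp profile-building rules (see
#'   [build_profile_matrix()]).
#' @param substrate_map,ko_map mapping tables; defaults bundled.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed integer seed (mandatory; drives the permutation stream).
#' @param alpha BH level for the differential screen.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(genes, meta, out_dir,
                         rank = c("phylum", "class", "genus"),
                         group_by = "fraction",
                         exclude_classes = "GT", contig_min_bp = 500,
                         substrate_map = default_substrate_map(),
                         ko_map = default_transporter_map(),
                         n_permutations = 999, seed, alpha = 0.05) {
  rank <- match.arg(rank)
  if (missing(seed)) stop("stage [config]: a seed is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name, writer = utils::write.table) {
    path <- file.path(out_dir, name)
    if (identical(writer, utils::write.table))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else writer(obj, path)
    files <<- c(files, path)
    path
  }

  stage("validate", {
    if (is.character(meta)) meta <- read_sample_meta(meta)
    else meta <- validate_meta(as.data.frame(meta))
    if (is.character(genes)) genes <- read_gene_table(genes, meta)
    else genes <- validate_genes(as.data.frame(genes), meta)
  })
  groups <- if (length(group_by) == 1 && group_by %in% names(meta))
    meta[[group_by]] else group_by
  if (length(groups) != nrow(meta))
    stop("stage [config]: group_by must name a metadata column or give one label per sample")

  profiles <- stage("profile", {
    lapply(stats::setNames(meta$sample_id, meta$sample_id), function(s)
      build_profile_matrix(genes, meta, s, rank = rank,
                           exclude_classes = exclude_classes,
                           contig_min_bp = contig_min_bp))
  })
  dataset_n <- length(unique(unlist(lapply(profiles, colnames))))

  niche <- stage("niche", {
    do.call(rbind, lapply(names(profiles), function(s) {
      tab <- niche_width_table(profiles[[s]], n = dataset_n)
      cbind(sample_id = s, tab)
    }))
  })
  emit(niche, "niche_width.tsv")

  overlaps <- stage("overlap", {
    lapply(profiles, function(m)
      if (sum(rowSums(m) > 0) >= 2) overlap_matrix(m) else NULL)
  })
  for (s in names(overlaps)) {
    if (is.null(overlaps[[s]])) next
    emit(overlaps[[s]], paste0("overlap_", s, ".tsv"),
         function(o, p) write_matrix(o, p, layout = "full"))
    emit(overlaps[[s]], paste0("overlap_", s, "_display.tsv"),
         function(o, p) write_matrix(o, p, layout = "table1_style"))
  }

  substrates <- stage("substrate", {
    lapply(profiles, substrate_aggregate, map = substrate_map)
  })
  for (s in names(substrates))
    emit(substrates[[s]], paste0("substrate_", s, ".tsv"),
         function(o, p) write_matrix(unclass(o), p, layout = "full"))

  transporters <- stage("transporters", {
    lapply(stats::setNames(meta$sample_id, meta$sample_id), function(s) {
      prof <- classify_transporters(genes, meta, s, rank = rank,
                                    ko_map = ko_map)
      tot <- rowSums(prof[, TRANSPORTER_VOCAB, drop = FALSE])
      prof$strategy <- NA_character_
      ok <- tot > 0
      prof$strategy[ok] <- vapply(which(ok), function(i)
        strategy_score(prof[i, TRANSPORTER_VOCAB])$label, "")
      prof
    })
  })
  for (s in names(transporters))
    emit(as.data.frame(transporters[[s]]), paste0("transporters_", s, ".tsv"))

  compare <- stage("compare", {
    sf <- sample_family_matrix(genes, meta, rank = rank,
                               exclude_classes = exclude_classes,
                               contig_min_bp = contig_min_bp)
    screen <- if (length(unique(groups)) == 2)
      family_screen(sf, groups, alpha = alpha) else NULL
    d <- bray_curtis(sf)
    ord <- pcoa(d)
    perm <- permanova(d, groups, n_permutations = n_permutations,
                      seed = seed)
    list(matrix = sf, screen = screen, dist = d, pcoa = ord,
         permanova = perm)
  })
  if (!is.null(compare$screen)) emit(compare$screen, "wilcoxon_screen.tsv")
  emit(as.matrix(compare$dist), "bray_curtis.tsv",
       function(o, p) write_matrix(o, p, layout = "full"))
  emit(data.frame(sample_id = rownames(compare$pcoa$points),
                  compare$pcoa$points, check.names = FALSE),
       "pcoa_coordinates.tsv")
  emit(data.frame(statistic = c("pseudo_F", "R2", "p_value",
                                "n_permutations", "seed"),
                  value = c(compare$permanova$pseudo_F,
                            compare$permanova$R2,
                            compare$permanova$p_value,
                            n_permutations, seed)),
       "permanova.tsv")

  manifest <- list(
    package = "glyconiche",
    version = as.character(utils::packageVersion("glyconiche")),
    rank = rank, exclude_classes = as.list(exclude_classes),
    contig_min_bp = contig_min_bp, n_permutations = n_permutations,
    seed = seed, alpha = alpha,
    n_genes = nrow(genes), n_samples = nrow(meta),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(genes = genes, meta = meta, profiles = profiles,
                 niche = niche, overlaps = overlaps,
                 substrates = substrates, transporters = transporters,
                 compare = compare, manifest = manifest))
}
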