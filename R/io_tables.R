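# Gene-table, metadata and mapping-table IO.
#
# Gene table format (TSV, header row):
#   gene_id, contig_id, [contig_len_bp], length_bp, lineage, cazyme_families,
#   ko_id, secreted, then one non-negative integer read-count column per sample.
# Multi-valued cells (several CAZyme families on one gene) are ";"-separated.
# Lineages are semicolon-delimited rank-prefixed strings
# ("d__Bacteria;p__Proteobacteria;...;g__Alteromonas"); tails may be absent.
# contig_len_bp is optional; when missing, contig length is taken as the summed
# length of the genes on that contig (a lower bound on the true length).

CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")
DEGRADATIVE_CLASSES <- c("GH", "PL", "CE", "AA", "CBM")

SUBSTRATE_VOCAB <- c("alpha_glucan", "beta_glucan", "N_glycan",
                     "cellulose_hemicellulose", "beta_mannoside", "lignin",
                     "fucose_SP", "rhamnose_SP", "pectin", "alginate")

TRANSPORTER_VOCAB <- c("ABC", "PTS", "MFS", "TonB", "SusC")

RANK_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

#' CAZyme class of a family label
#'
#' Extracts the class prefix (GH, GT, PL, CE, AA or CBM) from family labels
#' such as "GH13" or "CBM48".
#'
#' @param family character vector of CAZyme family labels.
#' @return Character vector of class prefixes; `NA` where the label does not
#'   match `<class><digits>`.
#' @export
#' @examples
#' family_class(c("GH13", "CBM48", "GT2"))
family_class <- function(family) {
  m <- regmatches(family, regexpr("^(GH|GT|PL|CE|AA|CBM)(?=[0-9]+$)",
                                  family, perl = TRUE))
  out <- rep(NA_character_, length(family))
  ok <- grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$", family)
  out[ok] <- sub("[0-9]+$", "", family[ok])
  out
}

#' Read per-sample metadata
#'
#' @param path TSV with columns sample_id, fraction (FL/PA/sediment),
#'   layer (surface/bottom/sediment), station, total_reads.
#' @return A data.frame of class `glyco_meta`.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  validate_meta(meta)
}

#' Validate sample metadata
#'
#' Checks the metadata contract: known fraction and layer levels, positive
#' library sizes, and the sediment fraction/layer coupling.
#'
#' @param meta data.frame with columns sample_id, fraction, layer, station,
#'   total_reads.
#' @return The validated data.frame, classed `glyco_meta`.
#' @export
validate_meta <- function(meta) {
  required <- c("sample_id", "fraction", "layer", "station", "total_reads")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    stop("sample metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(meta$fraction, c("FL", "PA", "sediment"))
  if (length(bad) > 0)
    stop("unknown fraction level(s): ", paste(bad, collapse = ", "),
         " (allowed: FL, PA, sediment)")
  bad <- setdiff(meta$layer, c("surface", "bottom", "sediment"))
  if (length(bad) > 0)
    stop("unknown layer level(s): ", paste(bad, collapse = ", "),
         " (allowed: surface, bottom, sediment)")
  if (any(meta$total_reads < 1))
    stop("total_reads must be a positive library size")
  mismatch <- xor(meta$fraction == "sediment", meta$layer == "sediment")
  if (any(mismatch))
    stop("fraction 'sediment' must pair with layer 'sediment' (sample ",
         paste(meta$sample_id[mismatch], collapse = ", "), ")")
  class(meta) <- c("glyco_meta", "data.frame")
  meta
}

#' Read a gene annotation table
#'
#' Reads the flattened TSV produced by upstream annotation (one row per
#' predicted ORF) and validates every row; rows are never dropped silently.
#' A parse report (rows read, rows with CAZyme labels, rows with KO labels)
#' is attached as the `"report"` attribute and printed when `verbose = TRUE`.
#'
#' @param path gene table TSV.
#' @param meta validated sample metadata (see [read_sample_meta()]); the
#'   read-count columns of the table must match its sample ids.
#' @param verbose print the parse report.
#' @return A data.frame of class `glyco_genes` with attributes `samples`
#'   (sample ids) and `report`.
#' @export
read_gene_table <- function(path, meta, verbose = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  required <- c("gene_id", "length_bp")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("gene table is missing required column(s): ",
         paste(missing, collapse = ", "))
  annot_cols <- c("gene_id", "contig_id", "contig_len_bp", "length_bp",
                  "lineage", "cazyme_families", "ko_id", "secreted")
  count_cols <- setdiff(names(tab), annot_cols)
  unknown <- setdiff(count_cols, meta$sample_id)
  if (length(unknown) > 0)
    stop("unknown sample column(s) ", paste(unknown, collapse = ", "),
         "; declared samples: ", paste(meta$sample_id, collapse = ", "))
  if (length(count_cols) == 0)
    stop("gene table has no per-sample read-count column")
  for (col in c("length_bp", "contig_len_bp", count_cols)) {
    if (!col %in% names(tab)) next
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0)
      stop("column '", col, "' is not integer-valued at row ", bad[1])
    tab[[col]] <- as.integer(v)
  }
  for (opt in c("contig_id", "lineage", "cazyme_families", "ko_id", "secreted"))
    if (!opt %in% names(tab)) tab[[opt]] <- ""
  genes <- tab[, c(intersect(annot_cols, names(tab)), count_cols)]
  genes <- validate_genes(genes, meta, samples = count_cols)
  if (verbose) {
    rep <- attr(genes, "report")
    message(sprintf("parsed %d genes (%d with CAZyme labels, %d with KO labels)",
                    rep$n_rows, rep$n_cazyme, rep$n_ko))
  }
  genes
}

#' Validate a gene table
#'
#' Enforces the gene-record invariants: positive gene lengths, non-negative
#' integer counts bounded by each sample's library size, well-formed CAZyme
#' family labels, and count columns restricted to declared samples.
#'
#' @param genes data.frame in the gene-table layout.
#' @param meta validated sample metadata.
#' @param samples character vector of sample-count column names; defaults to
#'   the intersection of `names(genes)` with `meta$sample_id`.
#' @return The validated `glyco_genes` data.frame.
#' @export
validate_genes <- function(genes, meta,
                           samples = intersect(names(genes), meta$sample_id)) {
  if (length(samples) == 0) stop("no sample count columns present")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id at row ", which(duplicated(genes$gene_id))[1])
  bad <- which(genes$length_bp < 1)
  if (length(bad) > 0)
    stop("length_bp must be >= 1; violated at row ", bad[1])
  if ("contig_len_bp" %in% names(genes)) {
    bad <- which(genes$contig_len_bp < 1)
    if (length(bad) > 0)
      stop("contig_len_bp must be >= 1; violated at row ", bad[1])
  }
  for (s in samples) {
    bad <- which(genes[[s]] < 0)
    if (length(bad) > 0)
      stop("negative read count in sample '", s, "' at row ", bad[1])
    total <- meta$total_reads[match(s, meta$sample_id)]
    bad <- which(genes[[s]] > total)
    if (length(bad) > 0)
      stop("read count exceeds library size (", total, ") in sample '", s,
           "' at row ", bad[1])
  }
  fams <- parse_families(genes$cazyme_families)
  all_fams <- unlist(fams, use.names = FALSE)
  if (length(all_fams) > 0) {
    bad <- all_fams[is.na(family_class(all_fams))]
    if (length(bad) > 0)
      stop("malformed CAZyme family label(s): ",
           paste(unique(bad), collapse = ", "),
           " (expected class prefix in ",
           paste(CAZY_CLASSES, collapse = "/"), " followed by digits)")
  }
  attr(genes, "samples") <- samples
  attr(genes, "report") <- list(
    n_rows = nrow(genes),
    n_cazyme = sum(lengths(fams) > 0),
    n_ko = sum(!is.na(genes$ko_id) & genes$ko_id != ""))
  class(genes) <- c("glyco_genes", "data.frame")
  genes
}

#' @export
print.glyco_genes <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("<glyco_genes> %d genes, %d samples (%d CAZyme-annotated, %d with KO)\n",
              rep$n_rows, length(attr(x, "samples")), rep$n_cazyme, rep$n_ko))
  invisible(x)
}

# Split ";"-delimited multi-valued cells into label sets.
parse_families <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) unique(trimws(v[nzchar(trimws(v))])))
}

# Parse a rank-prefixed lineage string into a named rank->name vector.
parse_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) return(character(0))
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  ranks <- rep(NA_character_, length(parts))
  for (r in names(RANK_PREFIXES)) {
    hit <- startsWith(parts, RANK_PREFIXES[[r]])
    ranks[hit] <- r
  }
  names(parts) <- ranks
  parts
}

# Name at a rank, stripped of its prefix; NA when the lineage stops above it.
lineage_at_rank <- function(lineage, rank) {
  parts <- parse_lineage(lineage)
  if (!rank %in% names(parts)) return(NA_character_)
  sub(RANK_PREFIXES[[rank]], "", parts[[rank]], fixed = TRUE)
}

#' Read a curated mapping table
#'
#' @param path two-or-three column TSV (key, label, optional note). With
#'   `kind = "substrate"` duplicate keys are merged into label sets; with
#'   `kind = "transporter"` duplicate keys are rejected.
#' @param kind `"substrate"` (CAZyme family to substrate category) or
#'   `"transporter"` (KEGG KO to transporter class).
#' @return For substrates, a named list family -> character vector of
#'   categories; for transporters, a data.frame with columns ko_id, class,
#'   note.
#' @seealso [default_substrate_map()], [default_transporter_map()] for the
#'   bundled tables.
#' @export
read_mapping_table <- function(path, kind = c("substrate", "transporter")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("mapping table needs at least two columns")
  key <- as.character(tab[[1]])
  label <- as.character(tab[[2]])
  note <- if (ncol(tab) >= 3) as.character(tab[[3]]) else rep("", nrow(tab))
  if (kind == "substrate") {
    bad <- setdiff(label, SUBSTRATE_VOCAB)
    if (length(bad) > 0)
      stop("substrate label(s) outside controlled vocabulary: ",
           paste(unique(bad), collapse = ", "), "; allowed: ",
           paste(SUBSTRATE_VOCAB, collapse = ", "))
    map <- lapply(split(label, key), unique)
    structure(map, class = c("substrate_map", class(map)))
  } else {
    bad <- setdiff(label, TRANSPORTER_VOCAB)
    if (length(bad) > 0)
      stop("transporter class(es) outside controlled vocabulary: ",
           paste(unique(bad), collapse = ", "), "; allowed: ",
           paste(TRANSPORTER_VOCAB, collapse = ", "))
    if (anyDuplicated(key))
      stop("duplicate KO id(s) in transporter map: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    structure(data.frame(ko_id = key, class = label, note = note,
                         stringsAsFactors = FALSE),
              class = c("transporter_map", "data.frame"))
  }
}

#' Bundled family-to-substrate map
#'
#' The default map covers the substrate categories used throughout the
#' analyses (alpha/beta glucans, nitrogen-containing glycans, cellulose and
#' hemicellulose, beta-mannosides, lignin, sulfated fucose- and
#' rhamnose-containing polysaccharides, pectin, alginate). It is a curated
#' reconstruction from the families' documented activities, not an exhaustive
#' CAZy-wide table; supply your own TSV to [read_mapping_table()] to override.
#'
#' @return A `substrate_map` (named list family -> categories).
#' @export
default_substrate_map <- function() {
  read_mapping_table(system.file("extdata", "substrate_map.tsv",
                                 package = "glyconiche", mustWork = TRUE),
                     kind = "substrate")
}

#' Bundled KO-to-transporter-class map
#'
#' Carbohydrate-transporter KEGG orthologs classified into ABC, PTS, MFS,
#' TonB and SusC, covering the KO set used in the transporter-strategy
#' analysis (e.g. K03832 tonB, K21573 susC, K02429 fucP).
#'
#' @return A `transporter_map` data.frame (ko_id, class, note).
#' @export
default_transporter_map <- function() {
  read_mapping_table(system.file("extdata", "transporter_ko_map.tsv",
                                 package = "glyconiche", mustWork = TRUE),
                     kind = "transporter")
}

#' Write a labelled matrix
#'
#' `layout = "full"` writes a dense TSV (row labels in the first column) that
#' round-trips through [read_matrix()] at full double precision.
#' `layout = "table1_style"` writes a symmetric matrix in the conventional
#' lower-triangular display: upper triangle blank and the diagonal rendered
#' "0.00" (display only — the in-memory diagonal of an overlap matrix is 1).
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param layout `"full"` or `"table1_style"`.
#' @param digits decimal places for `table1_style` (default 2).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, layout = c("full", "table1_style"),
                         digits = 2) {
  layout <- match.arg(layout)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column labels")
  if (layout == "full") {
    df <- data.frame(label = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("table1_style layout requires a symmetric square matrix")
    out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
    fmt <- paste0("%.", digits, "f")
    for (i in seq_len(nrow(m))) {
      if (i > 1)
        out[i, seq_len(i - 1)] <- sprintf(fmt, m[i, seq_len(i - 1)])
      out[i, i] <- sprintf(fmt, 0)
    }
    df <- data.frame(label = rownames(m), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()] (full layout)
#'
#' @param path TSV written with `layout = "full"`.
#' @return The numeric matrix with dimnames restored.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a gene table
#'
#' Inverse of [read_gene_table()]; used by the simulator and the pipeline.
#'
#' @param genes a `glyco_genes` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sample metadata
#'
#' @param meta a `glyco_meta` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
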