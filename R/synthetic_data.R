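# Seeded community simulator with known niche structure.
#
# The generator emulates the statistical structure the niche metrics assume:
# each taxon's glycan niche is a proportion vector p over degradative CAZyme
# families drawn from a symmetric Dirichlet (small alpha -> specialist,
# large alpha -> generalist); pairwise overlap is planted by mixing a shared
# uniform component into both members of a pair (p = (1-s)*private +
# s*shared), and the exact Morisita-Horn value of the realized vectors is
# recorded as truth rather than the nominal s. Genes inherit family mass
# (split equally among a family's genes), lengths come from a bounded
# log-normal, and per-sample read counts are multinomial over all genes with
# expected counts proportional to mass x gene length, so RPKM recovers the
# planted proportions. Group structure (SF/SP/BF/BP/S or custom) multiplies
# selected family weights in selected groups.

GROUP_PRESETS <- data.frame(
  group = c("SF", "SP", "BF", "BP", "S"),
  fraction = c("FL", "PA", "FL", "PA", "sediment"),
  layer = c("surface", "surface", "bottom", "bottom", "sediment"),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Assembles and validates the generator parameters. Defaults describe a
#' small estuarine-like community: 5 taxa over 40 degradative families (plus
#' GT families carrying 30% of read mass, mirroring GTs being the most
#' abundant class), one planted overlap pair with 60% shared mass, the five
#' condition groups (surface/bottom x free-living/particle plus sediment)
#' with two samples each, and 1e5 reads per sample.
#'
#' @param n_taxa number of taxa.
#' @param n_families number of degradative CAZyme families (classes GH, PL,
#'   CE, AA, CBM in realistic proportion).
#' @param n_gt_families glycosyltransferase families added on top (excluded
#'   by the degradative analyses; exercise the GT filter).
#' @param alpha Dirichlet concentration for per-taxon niche evenness.
#' @param overlap_design list of `list(pair = c(i, k), s = shared fraction)`;
#'   a taxon may appear in at most one pair.
#' @param family_sets optional list (length `n_taxa`) of family-index
#'   vectors restricting each taxon's support (disjoint sets give overlap 0).
#' @param groups data.frame with columns group, fraction, layer, n_samples;
#'   default the five condition groups, 2 samples each.
#' @param effects optional data.frame (group, family index, multiplier)
#'   multiplying a family's expected abundance in that group's samples.
#' @param genes_per_taxon degradative genes per taxon (spread over the
#'   taxon's non-zero families, at least one gene per family).
#' @param total_reads library size per sample.
#' @param gt_mass,transporter_mass,background_mass within-taxon read-mass
#'   shares of GT genes, transporter genes and unannotated background genes.
#' @param background_genes unannotated ORFs per taxon (0 disables).
#' @param transporter_kos named list taxon index -> named KO weight vector;
#'   `NULL` uses a default three-strategy spectrum (ABC-dominant,
#'   SusC/TonB-dominant, mixed specific) on the first three taxa.
#' @param taxon_weights relative community abundance of the taxa.
#' @param length_meanlog,length_sdlog,length_bounds log-normal gene-length
#'   model, truncated to `length_bounds` (default [500, 5000] bp).
#' @param secreted_prob per-gene probability of the secreted flag.
#' @param short_contig_genes spike-in genes placed on 400 bp contigs
#'   (excluded by the contig filter downstream).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 = plain
#'   multinomial sampling.
#' @param seed integer seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 5, n_families = 40, n_gt_families = 10,
                       alpha = 1,
                       overlap_design = list(list(pair = c(1, 2), s = 0.6)),
                       family_sets = NULL,
                       groups = cbind(GROUP_PRESETS, n_samples = 2),
                       effects = NULL,
                       genes_per_taxon = n_families,
                       total_reads = 1e5,
                       gt_mass = 0.3, transporter_mass = 0.05,
                       background_mass = 0, background_genes = 0,
                       transporter_kos = NULL,
                       taxon_weights = NULL,
                       length_meanlog = log(1000), length_sdlog = 0.35,
                       length_bounds = c(500, 5000),
                       secreted_prob = 0.2,
                       short_contig_genes = 0,
                       overdispersion = 0,
                       seed) {
  if (missing(seed) || is.na(seed)) stop("a seed is mandatory")
  stopifnot(n_taxa >= 1, n_families >= 2, genes_per_taxon >= 1,
            total_reads >= 1, alpha > 0)
  if (n_gt_families == 0) gt_mass <- 0
  if (background_genes == 0) background_mass <- 0
  if (is.null(taxon_weights)) taxon_weights <- rep(1, n_taxa)
  if (length(taxon_weights) != n_taxa || any(taxon_weights <= 0))
    stop("taxon_weights must be ", n_taxa, " positive values")
  if (!is.null(family_sets)) {
    if (length(family_sets) != n_taxa)
      stop("family_sets must list one index set per taxon")
    if (any(vapply(family_sets, function(s)
      length(s) < 1 || any(s < 1 | s > n_families), NA)))
      stop("family_sets indices must lie in 1..n_families")
  }
  seen <- integer(0)
  for (od in overlap_design) {
    if (length(od$pair) != 2 || any(od$pair < 1 | od$pair > n_taxa))
      stop("overlap pair indices must lie in 1..n_taxa")
    if (is.null(od$s) || od$s < 0 || od$s > 1)
      stop("shared fraction s must lie in [0, 1]")
    if (any(od$pair %in% seen))
      stop("infeasible overlap design: taxon ",
           intersect(od$pair, seen)[1], " appears in more than one pair")
    seen <- c(seen, od$pair)
  }
  stopifnot(all(c("group", "fraction", "layer", "n_samples") %in%
                  names(groups)))
  if (!is.null(effects)) {
    stopifnot(all(c("group", "family", "multiplier") %in% names(effects)))
    if (any(!effects$group %in% groups$group))
      stop("effects reference unknown group(s)")
    if (any(effects$family < 1 | effects$family > n_families))
      stop("effects family index out of range")
    if (any(effects$multiplier <= 0)) stop("effect multipliers must be > 0")
  }
  if (is.null(transporter_kos) && transporter_mass > 0) {
    presets <- list(
      c(K02027 = 3, K02056 = 3, K02058 = 2),              # ABC scavenger
      c(K21573 = 4, K03832 = 2, K02429 = 1),              # SusC selfish
      c(K03832 = 2, K02429 = 2, K02777 = 1, K02027 = 1))  # mixed specific
    transporter_kos <- stats::setNames(
      presets[pmin(seq_len(min(3, n_taxa)), 3)],
      seq_len(min(3, n_taxa)))
  }
  structure(list(
    n_taxa = n_taxa, n_families = n_families, n_gt_families = n_gt_families,
    alpha = alpha, overlap_design = overlap_design,
    family_sets = family_sets, groups = groups, effects = effects,
    genes_per_taxon = genes_per_taxon, total_reads = total_reads,
    gt_mass = gt_mass, transporter_mass = transporter_mass,
    background_mass = background_mass, background_genes = background_genes,
    transporter_kos = transporter_kos, taxon_weights = taxon_weights,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_bounds = length_bounds, secreted_prob = secreted_prob,
    short_contig_genes = short_contig_genes,
    overdispersion = overdispersion, seed = as.integer(seed)),
    class = "sim_config")
}

# Family labels: degradative classes in roughly the observed class mix,
# then GT families.
sim_family_labels <- function(n_families, n_gt_families) {
  shares <- c(GH = 0.55, CBM = 0.17, PL = 0.11, CE = 0.09, AA = 0.08)
  counts <- round(shares * n_families)
  counts[counts < 1] <- 1
  while (sum(counts) > n_families) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1
  while (sum(counts) < n_families) counts[which.max(shares)] <-
      counts[which.max(shares)] + 1
  deg <- unlist(lapply(names(counts), function(cl)
    paste0(cl, seq_len(counts[[cl]]))), use.names = FALSE)
  gt <- if (n_gt_families > 0) paste0("GT", seq_len(n_gt_families))
  else character(0)
  list(degradative = deg, gt = gt)
}

rdirichlet1 <- function(alpha_vec) {
  repeat {
    g <- stats::rgamma(length(alpha_vec), shape = alpha_vec)
    if (sum(g) > 0) return(g / sum(g))
  }
}

rlnorm_bounded <- function(n, meanlog, sdlog, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 4, meanlog, sdlog)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Exact niche metrics from known proportions (independent oracle)
#'
#' Computes B, B_A, B_i and pairwise Morisita-Horn overlap from generating
#' proportion vectors by direct elementwise loops. Deliberately independent
#' of [levins_B()] and friends so it can serve as the ground-truth oracle in
#' recovery tests.
#'
#' @param p matrix (taxa x families) of generating proportions, rows
#'   summing to 1.
#' @param n family count used for the B_A standardization (default
#'   `ncol(p)`).
#' @return list with per-taxon data.frame `width` (taxon, B, B_A, B_i) and
#'   matrix `overlap`.
#' @export
truth_metrics <- function(p, n = ncol(p)) {
  p <- as.matrix(p)
  k <- nrow(p)
  B <- B_i <- numeric(k)
  for (t in seq_len(k)) {
    ss <- 0; h <- 0
    for (j in seq_len(ncol(p))) {
      ss <- ss + p[t, j]^2
      if (p[t, j] > 0) h <- h - p[t, j] * log(p[t, j])
    }
    B[t] <- 1 / ss
    B_i[t] <- h
  }
  ov <- matrix(1, k, k, dimnames = list(rownames(p), rownames(p)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    num <- 0; da <- 0; db <- 0
    for (j in seq_len(ncol(p))) {
      num <- num + p[a, j] * p[b, j]
      da <- da + p[a, j]^2
      db <- db + p[b, j]^2
    }
    ov[a, b] <- 2 * num / (da + db)
  }
  list(width = data.frame(taxon = rownames(p) %||% paste0("t", seq_len(k)),
                          B = B, B_A = (B - 1) / (n - 1), B_i = B_i,
                          stringsAsFactors = FALSE),
       overlap = ov)
}

#' Simulate a gene table with known niche structure
#'
#' Draws per-taxon niche proportions, plants overlap and group effects,
#' assigns genes with bounded log-normal lengths, and samples per-sample
#' read counts; returns tables in the package's IO formats together with
#' the exact truth metrics of the realized proportions. Identical seeds
#' give identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `genes` (validated `glyco_genes`), `meta`
#'   (`glyco_meta`), `truth` (proportions, width table, overlap matrix,
#'   planted effects) and `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  labs <- sim_family_labels(config$n_families, config$n_gt_families)
  fam <- labs$degradative
  taxa <- paste0("t", seq_len(config$n_taxa))
  lineages <- sprintf(
    "d__Bacteria;p__SimPhylum%02d;c__SimClass%02d;o__SimOrder%02d;f__SimFamily%02d;g__SimGenus%02d",
    seq_len(config$n_taxa), seq_len(config$n_taxa), seq_len(config$n_taxa),
    seq_len(config$n_taxa), seq_len(config$n_taxa))

  # niche proportions over degradative families
  p <- matrix(0, config$n_taxa, config$n_families,
              dimnames = list(taxa, fam))
  for (t in seq_len(config$n_taxa)) {
    idx <- if (is.null(config$family_sets)) seq_len(config$n_families)
    else config$family_sets[[t]]
    p[t, idx] <- rdirichlet1(rep(config$alpha, length(idx)))
  }
  for (od in config$overlap_design) {
    i <- od$pair[1]; k <- od$pair[2]
    common <- which(p[i, ] > 0 | p[k, ] > 0)
    shared <- numeric(config$n_families)
    shared[common] <- 1 / length(common)
    p[i, ] <- (1 - od$s) * p[i, ] + od$s * shared
    p[k, ] <- (1 - od$s) * p[k, ] + od$s * shared
  }

  truth <- truth_metrics(p, n = config$n_families)
  truth$p <- p
  truth$effects <- config$effects

  # sample sheet
  g <- config$groups
  meta <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(sample_id = paste0(g$group[i], "_", seq_len(g$n_samples[i])),
               fraction = g$fraction[i], layer = g$layer[i],
               station = paste0("ST", i), total_reads = config$total_reads,
               group = g$group[i], stringsAsFactors = FALSE)
  }))

  # gene roster: id, taxon, family (or ko/background), length, contig
  rows <- list()
  w <- config$taxon_weights / sum(config$taxon_weights)
  deg_share <- 1 - config$gt_mass - config$transporter_mass -
    config$background_mass
  if (deg_share <= 0) stop("component masses leave no degradative share")
  for (t in seq_len(config$n_taxa)) {
    nz <- which(p[t, ] > 0)
    fam_of_gene <- rep(fam[nz], length.out = max(config$genes_per_taxon,
                                                 length(nz)))
    ngf <- table(fam_of_gene)
    mass <- deg_share * p[t, match(fam_of_gene, fam)] /
      as.numeric(ngf[fam_of_gene])
    rows[[length(rows) + 1]] <- data.frame(
      taxon = t, family = fam_of_gene, ko = "", kind = "caz",
      mass = w[t] * mass, stringsAsFactors = FALSE)
    if (config$gt_mass > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon = t, family = labs$gt, ko = "", kind = "gt",
        mass = w[t] * config$gt_mass / length(labs$gt),
        stringsAsFactors = FALSE)
    }
    ko <- config$transporter_kos[[as.character(t)]]
    if (config$transporter_mass > 0 && !is.null(ko)) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon = t, family = "", ko = names(ko), kind = "tr",
        mass = w[t] * config$transporter_mass * ko / sum(ko),
        stringsAsFactors = FALSE)
    }
    if (config$background_genes > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon = t, family = "", ko = "", kind = "bg",
        mass = w[t] * config$background_mass / config$background_genes,
        stringsAsFactors = FALSE)[rep(1, config$background_genes), ]
    }
  }
  roster <- do.call(rbind, rows)
  rownames(roster) <- NULL
  if (config$short_contig_genes > 0) {
    spike <- data.frame(
      taxon = rep(seq_len(config$n_taxa),
                  length.out = config$short_contig_genes),
      family = fam[1], ko = "", kind = "short",
      mass = 0.01 / config$short_contig_genes, stringsAsFactors = FALSE)
    roster <- rbind(roster, spike)
  }
  n_genes <- nrow(roster)
  len <- rlnorm_bounded(n_genes, config$length_meanlog, config$length_sdlog,
                        config$length_bounds)
  len[roster$kind == "short"] <- 350L
  contig_len <- len + 150L
  contig_len[roster$kind == "short"] <- 400L
  secreted <- as.integer(stats::runif(n_genes) < config$secreted_prob)

  # per-sample multinomial reads; expected counts ~ mass x length,
  # with group effects multiplying planted degradative families
  counts <- matrix(0L, n_genes, nrow(meta),
                   dimnames = list(NULL, meta$sample_id))
  base_w <- roster$mass * len
  for (s in seq_len(nrow(meta))) {
    ws <- base_w
    if (!is.null(config$effects)) {
      eff <- config$effects[config$effects$group == meta$group[s], ,
                            drop = FALSE]
      for (e in seq_len(nrow(eff))) {
        hit <- roster$kind %in% c("caz", "short") &
          roster$family == fam[eff$family[e]]
        ws[hit] <- ws[hit] * eff$multiplier[e]
      }
    }
    q <- ws / sum(ws)
    if (config$overdispersion > 0) {
      q <- rdirichlet1(q / config$overdispersion)
    }
    counts[, s] <- stats::rmultinom(1, config$total_reads, q)[, 1]
  }

  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    contig_id = sprintf("contig_%05d", seq_len(n_genes)),
    contig_len_bp = contig_len,
    length_bp = len,
    lineage = lineages[roster$taxon],
    cazyme_families = roster$family,
    ko_id = roster$ko,
    secreted = as.character(secreted),
    counts, check.names = FALSE, stringsAsFactors = FALSE)
  meta_out <- validate_meta(meta[, c("sample_id", "fraction", "layer",
                                     "station", "total_reads")])
  attr(meta_out, "group") <- stats::setNames(meta$group, meta$sample_id)
  genes <- validate_genes(genes, meta_out, samples = meta$sample_id)
  list(genes = genes, meta = meta_out, truth = truth, config = config)
}
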