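# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive loops or full enumeration, never by calling the
# package's implementation paths.

oracle_levins <- function(p) {
  ss <- 0
  for (v in p) ss <- ss + v * v
  1 / ss
}

oracle_levins_std <- function(p, n) (oracle_levins(p) - 1) / (n - 1)

oracle_shannon <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h
}

oracle_morisita_horn <- function(a, b) {
  num <- 0; da <- 0; db <- 0
  for (j in seq_along(a)) {
    num <- num + a[j] * b[j]
    da <- da + a[j]^2
    db <- db + b[j]^2
  }
  2 * num / (da + db)
}

# Exact two-sided (or one-sided) Mann-Whitney p-value by full enumeration of
# all choose(n+m, n) assignments of the pooled ranks to the first sample.
# Assumes tie-free data.
oracle_wilcoxon_exact <- function(x, y,
                                  alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(idx) - n * (n + 1) / 2)
  total <- ncol(combos)
  p_le <- sum(us <= u_obs) / total
  p_ge <- sum(us >= u_obs) / total
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

random_proportions <- function(k, alpha = NULL) {
  if (is.null(alpha)) alpha <- stats::runif(1, 0.2, 5)
  g <- stats::rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Zero-fill a profile matrix onto a fixed family set (columns).
align_to_families <- function(m, fams) {
  out <- matrix(0, nrow(m), length(fams),
                dimnames = list(rownames(m), fams))
  common <- intersect(colnames(m), fams)
  out[, common] <- m[, common]
  out
}

# Small handwritten gene table fixture: 2 samples, 5 genes.
write_fixture_genes <- function(dir = tempdir()) {
  meta_path <- file.path(dir, "meta.tsv")
  genes_path <- file.path(dir, "genes.tsv")
  writeLines(c(
    "sample_id\tfraction\tlayer\tstation\ttotal_reads",
    "W1\tFL\tsurface\tST1\t1000000",
    "W2\tPA\tsurface\tST1\t2000000"), meta_path)
  writeLines(c(
    paste("gene_id", "contig_id", "contig_len_bp", "length_bp", "lineage",
          "cazyme_families", "ko_id", "secreted", "W1", "W2", sep = "\t"),
    paste("g1", "c1", "1200", "1000",
          "d__Bacteria;p__PhyA;c__ClsA;o__OrdA;f__FamA;g__GenA",
          "GH13;CBM48", "", "1", "100", "40", sep = "\t"),
    paste("g2", "c1", "1200", "500",
          "d__Bacteria;p__PhyA;c__ClsA;o__OrdA;f__FamA;g__GenA",
          "GH13", "", "0", "50", "10", sep = "\t"),
    paste("g3", "c2", "900", "800",
          "d__Bacteria;p__PhyA;c__ClsA;o__OrdA;f__FamA;g__GenA",
          "GT2", "", "0", "30", "5", sep = "\t"),
    paste("g4", "c3", "2000", "1500",
          "d__Bacteria;p__PhyB;c__ClsB;o__OrdB;f__FamB;g__GenB",
          "PL1", "K03832", "1", "60", "80", sep = "\t"),
    paste("g5", "c4", "400", "350",
          "d__Bacteria;p__PhyB;c__ClsB;o__OrdB;f__FamB;g__GenB",
          "GH16", "", "0", "20", "20", sep = "\t")),
    genes_path)
  list(genes = genes_path, meta = meta_path)
}
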