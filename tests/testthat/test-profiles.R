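test_that("rpkm matches the printed formula and its invariances", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 777, 123456), 0)
  expect_equal(rpkm(50, 2000, 1e7), 2.5)
  # joint rescaling of counts and library size cancels
  set.seed(5)
  for (i in 1:20) {
    r <- sample(0:500, 1); l <- sample(100:5000, 1); t <- sample(1e5:1e7, 1)
    k <- sample(2:9, 1)
    expect_equal(rpkm(k * r, l, k * t), rpkm(r, l, t))
  }
  expect_error(rpkm(10, 0, 1000), "length_bp")
  expect_error(rpkm(10, 100, 0), "total_reads")
})

make_profile_fixture <- function() {
  meta <- validate_meta(data.frame(
    sample_id = "W1", fraction = "FL", layer = "surface",
    station = "ST1", total_reads = 1e6))
  # equal RPKM 10 for each gene: 10 reads on 1000 bp in a 1e6-read library
  genes <- data.frame(
    gene_id = paste0("g", 1:4),
    contig_id = paste0("c", 1:4),
    contig_len_bp = c(1200, 1200, 1200, 1200),
    length_bp = 1000,
    lineage = c("d__Bacteria;p__A", "d__Bacteria;p__A",
                "d__Bacteria;p__A", "d__Bacteria;p__B"),
    cazyme_families = c("GH13", "GH13", "GT2", "PL1"),
    ko_id = "", secreted = "0",
    W1 = c(10L, 10L, 10L, 10L),
    stringsAsFactors = FALSE)
  list(genes = validate_genes(genes, meta), meta = meta)
}

test_that("profile matrices apply GT exclusion, aggregation and the contig filter", {
  fx <- make_profile_fixture()
  m <- build_profile_matrix(fx$genes, fx$meta, "W1", rank = "phylum")
  expect_equal(sort(colnames(m)), c("GH13", "PL1"))
  expect_equal(m["A", "GH13"], 20)
  expect_equal(m["B", "PL1"], 10)

  m2 <- build_profile_matrix(fx$genes, fx$meta, "W1", rank = "phylum",
                             exclude_classes = character(0))
  expect_equal(m2["A", "GT2"], 10)

  # a gene on a 400 bp contig contributes nothing; 501 bp passes (strict >)
  g <- as.data.frame(fx$genes)
  g$contig_len_bp[1] <- 400L
  g$contig_len_bp[2] <- 501L
  g <- validate_genes(g, fx$meta)
  m3 <- build_profile_matrix(g, fx$meta, "W1", rank = "phylum")
  expect_equal(m3["A", "GH13"], 10)

  expect_error(build_profile_matrix(fx$genes, fx$meta, "nope"), "sample_id")
})

test_that("multi-domain genes contribute fully to each family (split optional)", {
  fx <- make_profile_fixture()
  g <- as.data.frame(fx$genes)
  g$cazyme_families[1] <- "GH13;CBM48"
  g <- validate_genes(g, fx$meta)
  m <- build_profile_matrix(g, fx$meta, "W1", rank = "phylum")
  expect_equal(m["A", "GH13"], 20)
  expect_equal(m["A", "CBM48"], 10)
  ms <- build_profile_matrix(g, fx$meta, "W1", rank = "phylum",
                             multi_domain = "split")
  expect_equal(ms["A", "GH13"], 15)
  expect_equal(ms["A", "CBM48"], 5)
})

test_that("genes unresolved at the rank land in the unclassified bucket and totals conserve", {
  fx <- make_profile_fixture()
  g <- as.data.frame(fx$genes)
  g$lineage[4] <- "d__Bacteria"   # stops above phylum
  g <- validate_genes(g, fx$meta)
  m <- build_profile_matrix(g, fx$meta, "W1", rank = "phylum")
  expect_true("unclassified_phylum" %in% rownames(m))
  expect_equal(m["unclassified_phylum", "PL1"], 10)
  # conservation: taxon marginals equal sample-wide family totals
  expect_equal(colSums(m), c(GH13 = 20, PL1 = 10))
})

test_that("CAZyme gene frequency counts genes, not abundance", {
  meta <- validate_meta(data.frame(
    sample_id = "W1", fraction = "FL", layer = "surface",
    station = "ST1", total_reads = 1e6))
  genes <- data.frame(
    gene_id = paste0("g", 1:1000), contig_id = paste0("c", 1:1000),
    length_bp = 1000, lineage = "d__Bacteria;p__A",
    cazyme_families = c(rep("GH1", 2), rep("CE1", 1), rep("PL1", 1),
                        rep("GT2", 3), rep("", 993)),
    ko_id = "", secreted = "0", W1 = 1L, stringsAsFactors = FALSE)
  genes <- validate_genes(genes, meta)
  expect_equal(cazyme_gene_frequency(genes), 0.4)
  expect_equal(cazyme_gene_frequency(genes, classes = "AA"), 0)
  expect_equal(cazyme_gene_frequency(genes,
                                     classes = c("GH", "CE", "PL", "GT")),
               0.7)
  all_caz <- genes[1:4, ]
  expect_equal(cazyme_gene_frequency(validate_genes(as.data.frame(all_caz),
                                                    meta)), 100)
  expect_error(cazyme_gene_frequency(genes[0, ]), "empty")
})

test_that("proportion conversion normalizes and guards empties", {
  expect_equal(to_proportions(c(GH13 = 20, PL1 = 20)), c(GH13 = 0.5, PL1 = 0.5))
  expect_equal(to_proportions(c(GH13 = 30, PL1 = 10)),
               c(GH13 = 0.75, PL1 = 0.25))
  expect_equal(sum(to_proportions(runif(30))), 1, tolerance = 1e-12)
  expect_error(to_proportions(numeric(0), taxon = "ghost"), "ghost")
  expect_error(to_proportions(c(a = 0, b = 0)), "no degradative")
})

test_that("substrate aggregation follows the map and conserves abundance", {
  fx <- make_profile_fixture()
  g <- as.data.frame(fx$genes)
  g$cazyme_families <- c("GH16", "GH17", "GT2", "GH9999")
  g <- validate_genes(g, fx$meta)
  m <- build_profile_matrix(g, fx$meta, "W1", rank = "phylum")
  agg <- substrate_aggregate(m)
  expect_equal(sum(agg[, "beta_glucan"]), 20)  # GH16 + GH17
  expect_equal(sum(agg[, "unmapped"]), 10)     # GH9999 not silently dropped
  expect_equal(attr(agg, "unmapped_families"), "GH9999")
  expect_equal(sum(agg), sum(m))               # single-category map conserves

  # a family mapped to two categories contributes fully to both
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.tsv")
  writeLines(c("family\tcategory", "GH16\talpha_glucan",
               "GH16\tbeta_glucan"), path)
  map2 <- read_mapping_table(path, kind = "substrate")
  agg2 <- substrate_aggregate(m, map = map2)
  expect_equal(sum(agg2[, "alpha_glucan"]), 10)
  expect_equal(sum(agg2[, "beta_glucan"]), 10)
})
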