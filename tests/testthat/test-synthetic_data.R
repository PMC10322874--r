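test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_community(sim_config(seed = 5))
  b <- simulate_community(sim_config(seed = 5))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_identical(a$truth, b$truth)
  c <- simulate_community(sim_config(seed = 6))
  expect_false(identical(as.data.frame(a$genes), as.data.frame(c$genes)))
})

test_that("simulated tables satisfy the IO contracts", {
  sim <- simulate_community(sim_config(seed = 9, short_contig_genes = 3))
  expect_s3_class(sim$genes, "glyco_genes")
  expect_s3_class(sim$meta, "glyco_meta")
  expect_true(all(sim$genes$length_bp >= 350))
  long <- sim$genes$contig_len_bp > 500
  expect_true(all(sim$genes$length_bp[long] >= 500))
  expect_true(all(sim$genes$length_bp[long] <= 5000))
  expect_equal(sum(!long), 3)
  # every sample's counts sum to the library size
  for (s in attr(sim$genes, "samples"))
    expect_equal(sum(sim$genes[[s]]), sim$meta$total_reads[1])
})

test_that("planted overlap extremes give O = 1 and O = 0 in truth", {
  one <- simulate_community(sim_config(
    seed = 2, overlap_design = list(list(pair = c(1, 2), s = 1))))
  expect_equal(one$truth$overlap["t1", "t2"], 1)
  expect_equal(one$truth$p["t1", ], one$truth$p["t2", ])

  sets <- list(1:10, 11:20, 21:30, 31:40, 1:40)
  dis <- simulate_community(sim_config(
    seed = 2, family_sets = sets, overlap_design = list()))
  expect_equal(dis$truth$overlap["t1", "t2"], 0)
  expect_equal(dis$truth$overlap["t2", "t3"], 0)
})

test_that("large Dirichlet concentration approaches the generalist limit", {
  sim <- simulate_community(sim_config(seed = 4, alpha = 1e4,
                                       n_families = 20,
                                       overlap_design = list()))
  expect_true(all(abs(sim$truth$width$B_A - 1) < 0.02))
})

test_that("truth oracle obeys the niche-metric invariants", {
  set.seed(15)
  for (i in 1:10) {
    k <- sample(3:6, 1); f <- sample(5:30, 1)
    p <- t(vapply(seq_len(k), function(...) random_proportions(f),
                  numeric(f)))
    tr <- truth_metrics(p)
    expect_true(all(tr$width$B >= 1 - 1e-9 & tr$width$B <= f + 1e-9))
    expect_true(all(tr$width$B_A >= -1e-9 & tr$width$B_A <= 1 + 1e-9))
    expect_true(all(tr$width$B_i >= 0 & tr$width$B_i <= log(f) + 1e-9))
    expect_equal(tr$overlap, t(tr$overlap))
    expect_equal(unname(diag(tr$overlap)), rep(1, k))
    expect_true(all(tr$overlap >= 0 & tr$overlap <= 1 + 1e-9))
  }
  expect_equal(truth_metrics(rbind(c(0.5, 0.5, 0),
                                   c(0, 0.5, 0.5)))$overlap[1, 2], 0.5)
})

test_that("infeasible configurations error before sampling", {
  expect_error(sim_config(seed = 1, overlap_design = list(
    list(pair = c(1, 2), s = 0.5), list(pair = c(2, 3), s = 0.5))),
    "more than one pair")
  expect_error(sim_config(seed = 1, overlap_design = list(
    list(pair = c(1, 2), s = 1.5))), "s must lie")
  expect_error(sim_config(seed = 1, overlap_design = list(
    list(pair = c(1, 9), s = 0.5))), "indices")
  expect_error(sim_config(seed = 1, effects = data.frame(
    group = "XX", family = 1, multiplier = 4)), "unknown group")
  expect_error(simulate_community(sim_config(seed = 1)[-1]), "sim_config")
})

test_that("pipeline estimates recover planted metrics from read counts", {
  sim <- simulate_community(sim_config(
    seed = 21,
    groups = data.frame(group = "SF", fraction = "FL", layer = "surface",
                        n_samples = 1)))
  m <- build_profile_matrix(sim$genes, sim$meta, "SF_1", rank = "genus")
  taxa_map <- paste0("SimGenus", sprintf("%02d", 1:5))
  m <- align_to_families(m[taxa_map, , drop = FALSE], colnames(sim$truth$p))
  # estimated proportions track the generating ones family by family
  for (t in 1:5) {
    est <- to_proportions(m[taxa_map[t], ])
    expect_lt(max(abs(est - sim$truth$p[t, ])), 0.02)
  }
  nw <- niche_width_table(m, n = ncol(sim$truth$p))
  expect_lt(max(abs(nw$B_A - sim$truth$width$B_A)), 0.05)
  ov <- overlap_matrix(m)
  expect_lt(abs(ov[1, 2] - sim$truth$overlap["t1", "t2"]), 0.02)
})

test_that("overdispersed sampling still conserves library size", {
  sim <- simulate_community(sim_config(seed = 8, overdispersion = 0.005))
  for (s in attr(sim$genes, "samples"))
    expect_equal(sum(sim$genes[[s]]), sim$meta$total_reads[1])
})
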