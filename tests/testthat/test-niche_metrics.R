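test_that("niche width indices match hand-computed and closed-form values", {
  expect_equal(levins_B(c(1, 0, 0)), 1)
  expect_equal(levins_B(rep(0.2, 5)), 5)
  expect_equal(levins_B(c(0.6, 0.4)), 1 / 0.52)
  expect_equal(round(levins_B(c(0.6, 0.4)), 4), 1.9231)

  expect_equal(levins_standardized(c(1, 0), n = 2), 0)
  expect_equal(levins_standardized(rep(0.1, 10), n = 10), 1)
  expect_equal(round(levins_standardized(c(0.6, 0.4), n = 5), 4), 0.2308)
  expect_error(levins_standardized(c(0.5, 0.5), n = 1), "n")

  expect_equal(shannon_evenness(c(1, 0)), 0)
  expect_equal(shannon_evenness(rep(0.25, 4)), log(4))
  expect_equal(round(shannon_evenness(c(0.6, 0.4)), 4), 0.673)

  expect_error(levins_B(c(0.5, 0.2)), "proportion")
  expect_error(shannon_evenness(c(0.7, -0.1, 0.4)), "negative")
})

test_that("Morisita-Horn overlap has its identity, disjointness and symmetry", {
  p <- random_proportions(12)
  expect_equal(morisita_horn(p, p), 1)
  expect_equal(morisita_horn(c(0.5, 0.5, 0, 0), c(0, 0, 0.3, 0.7)), 0)
  expect_equal(morisita_horn(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  a <- random_proportions(8); b <- random_proportions(8)
  expect_equal(morisita_horn(a, b), morisita_horn(b, a))
  expect_error(morisita_horn(c(0.5, 0.5), c(1, 0, 0)), "aligned")
})

test_that("indices agree with brute-force oracles on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(2:60, 1)
    p <- random_proportions(k)
    q <- random_proportions(k)
    n <- k + sample(0:20, 1)
    expect_equal(levins_B(p), oracle_levins(p), tolerance = 1e-12)
    expect_equal(levins_standardized(p, n), oracle_levins_std(p, n),
                 tolerance = 1e-12)
    expect_equal(shannon_evenness(p), oracle_shannon(p), tolerance = 1e-12)
    expect_equal(morisita_horn(p, q), oracle_morisita_horn(p, q),
                 tolerance = 1e-12)
  }
})

test_that("width indices respect their bounds and Schur-concavity", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:30, 1)
    p <- random_proportions(k)
    B <- levins_B(p)
    expect_gte(B, 1); expect_lte(B, k + 1e-9)
    expect_gte(shannon_evenness(p), 0)
    expect_lte(shannon_evenness(p), log(k) + 1e-9)
    # transfer mass from a smaller to a larger component: both indices
    # must not increase
    o <- order(p)
    lo <- o[1]; hi <- o[k]
    if (p[lo] > 1e-6) {
      eps <- p[lo] * runif(1, 0.1, 0.9)
      q <- p; q[lo] <- q[lo] - eps; q[hi] <- q[hi] + eps
      expect_lte(levins_B(q), levins_B(p) + 1e-12)
      expect_lte(shannon_evenness(q), shannon_evenness(p) + 1e-12)
    }
  }
})

test_that("cross-check against vegan's inverse-Simpson diversity", {
  set.seed(13)
  p <- random_proportions(25)
  expect_equal(levins_B(p), vegan::diversity(p, index = "invsimpson"))
  expect_equal(shannon_evenness(p), vegan::diversity(p, index = "shannon"))
})

test_that("overlap matrices are symmetric with unit diagonal and scale-invariant", {
  set.seed(23)
  m <- matrix(rexp(4 * 10), 4, 10,
              dimnames = list(paste0("tax", 1:4), paste0("GH", 1:10)))
  o <- overlap_matrix(m)
  expect_equal(unclass(o), t(unclass(o)))
  expect_equal(unname(diag(o)), rep(1, 4))
  expect_true(all(o >= 0 & o <= 1 + 1e-12))

  # proportional profiles overlap fully; scaling a row changes nothing
  m2 <- rbind(a = c(1, 2, 3), b = 3 * c(1, 2, 3), c = c(5, 0, 0))
  colnames(m2) <- paste0("GH", 1:3)
  o2 <- overlap_matrix(m2)
  expect_equal(o2["a", "b"], 1)

  # pairwise-disjoint supports give zero off-diagonal
  m3 <- diag(c(4, 7, 9))
  dimnames(m3) <- list(paste0("t", 1:3), paste0("GH", 1:3))
  o3 <- overlap_matrix(m3)
  expect_equal(unname(o3[upper.tri(o3)]), c(0, 0, 0))

  expect_error(overlap_matrix(m2[1, , drop = FALSE]), "at least 2")
})

test_that("per-taxon width tables standardize against the dataset family count", {
  m <- rbind(gen = rep(2, 10), spec = c(20, rep(0, 9)))
  colnames(m) <- paste0("GH", 1:10)
  tab <- niche_width_table(m)            # n defaults to ncol = 10
  expect_equal(tab$B_A[tab$taxon == "gen"], 1)
  expect_equal(tab$B_A[tab$taxon == "spec"], 0)
  expect_equal(tab$B_i[tab$taxon == "gen"], log(10))
  tab2 <- niche_width_table(m, n = 21)   # wider dataset-wide count
  expect_equal(tab2$B_A[tab2$taxon == "gen"], 9 / 20)
})
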