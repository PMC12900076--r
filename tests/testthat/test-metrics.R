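test_that("weighted UniFrac matches hand-enumerated branch sums", {
  tr <- two_leaf_tree()
  d10 <- weighted_unifrac(branch_profile(tr, c(A = 1, B = 0)),
                          branch_profile(tr, c(A = 0, B = 1)))
  expect_equal(d10, 1)  # disjoint support is maximal

  # a=(2,0), b=(1,1): numerator 1+1, denominator 3+1 (+0 on the root edge)
  expect_equal(weighted_unifrac(branch_profile(tr, c(A = 2, B = 0)),
                                branch_profile(tr, c(A = 1, B = 1))), 0.5)

  p <- branch_profile(tr, c(A = 3, B = 4))
  expect_equal(weighted_unifrac(p, p), 0)
})

test_that("generalized UniFrac interpolates and recovers the weighted form", {
  tr <- two_leaf_tree()
  pa <- branch_profile(tr, c(A = 2, B = 0))
  pb <- branch_profile(tr, c(A = 1, B = 1))
  expect_equal(generalized_unifrac(pa, pb, 0), (1 / 3 + 1) / 2)
  expect_equal(generalized_unifrac(pa, pb, 0.5),
               (sqrt(3) * (1 / 3) + 1) / (sqrt(3) + 1))
  expect_equal(generalized_unifrac(pa, pb, 1), weighted_unifrac(pa, pb))
  expect_error(generalized_unifrac(pa, pb, 1.5), "alpha")
})

test_that("unweighted UniFrac sees incidence only", {
  tr <- two_leaf_tree()
  expect_equal(unweighted_unifrac(branch_profile(tr, c(A = 1, B = 0)),
                                  branch_profile(tr, c(A = 0, B = 7))), 1)
  expect_equal(unweighted_unifrac(branch_profile(tr, c(A = 1, B = 5)),
                                  branch_profile(tr, c(A = 90, B = 2))), 0)

  tr4 <- four_leaf_tree()
  ca <- c(A = 1, B = 1, C = 0, D = 0)
  cb <- c(A = 1, B = 0, C = 1, D = 0)
  got <- unweighted_unifrac(branch_profile(tr4, ca),
                            branch_profile(tr4, cb))
  expect_equal(got, oracle_uw(tr4, ca, cb))
  expect_equal(got, 2.5 / 4)  # unique {B, C, edge over {C,D}} / covered

  # invariant to positive rescaling of either sample
  expect_equal(unweighted_unifrac(branch_profile(tr4, ca * 13),
                                  branch_profile(tr4, cb)), got)
})

test_that("Bray-Curtis follows the direct formula", {
  expect_equal(bray_curtis(c(2, 0), c(1, 1)), 0.5)
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  k <- 7
  expect_equal(bray_curtis(k * c(2, 5), c(2, 5)), (k - 1) / (k + 1))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
})

test_that("degenerate profiles and mismatched inputs are rejected", {
  tr <- two_leaf_tree()
  z <- branch_profile(tr, c(A = 0, B = 0))
  p <- branch_profile(tr, c(A = 1, B = 0))
  expect_error(weighted_unifrac(z, z), "all-zero")
  expect_error(generalized_unifrac(z, z, 0.5), "all-zero")
  expect_error(unweighted_unifrac(z, z), "all-zero")
  rel <- branch_profile(tr, c(A = 1, B = 0), mode = "relative")
  expect_error(weighted_unifrac(p, rel), "mode")
  other <- branch_profile(four_leaf_tree(), c(A = 1, B = 0, C = 0, D = 0))
  expect_error(weighted_unifrac(p, other), "enumeration")
})

test_that("matrix builders agree with the pairwise kernels", {
  fx <- random_fixture(n_taxa = 12, n_samples = 6, seed = 5)
  abs_tab <- as_absolute(fx$table, fx$loads)
  al <- align_tree_table(fx$tree, abs_tab)
  profs <- lapply(rownames(abs_tab), function(s)
    branch_profile(al$tree, unclass(al$table)[s, ]))
  specs <- list(w = metric_spec("unifrac_weighted", "absolute"),
                g = metric_spec("unifrac_generalized", "absolute",
                                alpha = 0.3),
                u = metric_spec("unifrac_unweighted", "absolute"))
  mats <- lapply(specs, function(sp)
    pairwise_distances(abs_tab, fx$tree, sp))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(mats$w[i, j], weighted_unifrac(profs[[i]], profs[[j]]))
    expect_equal(mats$g[i, j],
                 generalized_unifrac(profs[[i]], profs[[j]], 0.3))
    expect_equal(mats$u[i, j], unweighted_unifrac(profs[[i]], profs[[j]]))
  }
  bc <- pairwise_distances(abs_tab, spec = metric_spec("bray_curtis",
                                                       "absolute"))
  expect_equal(bc[2, 5], bray_curtis(unclass(abs_tab)[2, ],
                                     unclass(abs_tab)[5, ]))
})

test_that("the mode pipeline behaves: loads, equal-load collapse, shapes", {
  fx <- random_fixture(n_taxa = 10, n_samples = 5, seed = 9)
  spec_abs <- metric_spec("unifrac_weighted", "absolute")
  spec_rel <- metric_spec("unifrac_weighted", "relative")
  expect_error(pairwise_distances(fx$table, fx$tree, spec_abs), "loads")
  expect_error(pairwise_distances(fx$table, spec = spec_abs,
                                  loads = fx$loads), "tree")

  # equal loads for all samples: absolute and relative matrices coincide
  eq_loads <- load_vector(stats::setNames(rep(3e7, 5), rownames(fx$table)))
  d_abs <- pairwise_distances(fx$table, fx$tree, spec_abs, eq_loads)
  d_rel <- pairwise_distances(fx$table, fx$tree, spec_rel)
  expect_lt(max(abs(d_abs - d_rel)), 1e-12)

  one <- count_table(unclass(fx$table)[1, , drop = FALSE], "raw_reads")
  d1 <- pairwise_distances(one, fx$tree, spec_rel)
  expect_equal(dim(d1), c(1L, 1L))
  expect_equal(as.numeric(d1), 0)

  gu <- pairwise_distances(fx$table, fx$tree,
                           metric_spec("unifrac_generalized", "absolute",
                                       alpha = c(0, 0.5, 1)), fx$loads)
  expect_named(gu, c("alpha_0", "alpha_0.5", "alpha_1"))
  expect_lt(max(abs(gu$alpha_1 -
                      pairwise_distances(fx$table, fx$tree, spec_abs,
                                         fx$loads))), 1e-14)
})

test_that("relative weighted UniFrac matches phyloseq's implementation", {
  skip_if_not_installed("phyloseq")
  fx <- random_fixture(n_taxa = 15, n_samples = 6, seed = 21)
  d_ours <- pairwise_distances(fx$table, fx$tree,
                               metric_spec("unifrac_weighted", "relative"))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(unclass(fx$table)), taxa_are_rows = TRUE),
    phyloseq::phy_tree(fx$tree))
  d_ps <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                      normalized = TRUE))
  d_ps <- d_ps[rownames(d_ours), rownames(d_ours)]
  expect_lt(max(abs(unclass(d_ours) - d_ps)), 1e-10)
})

test_that("Bray-Curtis matrices match vegan's vegdist", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(n_taxa = 15, n_samples = 6, seed = 22)
  abs_tab <- as_absolute(fx$table, fx$loads)
  d_ours <- pairwise_distances(abs_tab,
                               spec = metric_spec("bray_curtis",
                                                  "absolute"))
  d_veg <- as.matrix(vegan::vegdist(unclass(abs_tab), method = "bray"))
  expect_lt(max(abs(unclass(d_ours) - d_veg)), 1e-12)
})

test_that("metric matrices satisfy range, symmetry and zero diagonal", {
  fx <- random_fixture(n_taxa = 8, n_samples = 7, seed = 31)
  for (spec in list(metric_spec("unifrac_weighted", "absolute"),
                    metric_spec("unifrac_generalized", "relative",
                                alpha = 0.2),
                    metric_spec("unifrac_unweighted", "relative"),
                    metric_spec("bray_curtis", "absolute"))) {
    d <- pairwise_distances(fx$table, fx$tree, spec, fx$loads)
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
    expect_equal(unclass(d), t(unclass(d)))
    expect_true(all(diag(d) == 0))
  }
})
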