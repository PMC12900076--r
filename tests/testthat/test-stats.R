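test_that("load-difference matrices are plain absolute differences", {
  expect_true(all(load_difference_matrix(
    load_vector(c(a = 10, b = 10, c = 10))) == 0))
  expect_equal(load_difference_matrix(load_vector(c(a = 1, b = 3)))[1, 2],
               2)
  m <- load_difference_matrix(load_vector(c(a = 1, b = 10, c = 100)))
  expect_equal(m[upper.tri(m)], c(9, 99, 90))
  lg <- load_difference_matrix(load_vector(c(a = 1, b = 10, c = 100)),
                               log10 = TRUE)
  expect_equal(lg[upper.tri(lg)], c(1, 2, 1))
})

test_that("Mantel correlation: identity, affine invariance, alignment", {
  set.seed(12)
  m <- as.matrix(dist(matrix(rnorm(12), 6)))
  d1 <- distance_matrix(m)
  expect_equal(mantel_test(d1, d1, permutations = 49, seed = 1)$r, 1)
  d2 <- distance_matrix(0.3 + 2 * m - diag(diag(0.3 + 2 * m)))
  expect_equal(mantel_test(d1, d2, permutations = 49, seed = 1)$r, 1)

  # matrices are matched by label, not position
  perm <- c(3, 1, 2, 6, 5, 4)
  d1p <- distance_matrix(m[perm, perm])
  expect_equal(mantel_test(d1, d1p, permutations = 49, seed = 1)$r, 1)

  expect_error(mantel_test(d1, distance_matrix(m[1:5, 1:5])), "sample set")
  const <- distance_matrix(matrix(1, 4, 4,
                                  dimnames = list(letters[1:4],
                                                  letters[1:4])) -
                             diag(4))
  expect_error(mantel_test(const, const), "constant")
})

test_that("Mantel permutation p matches exhaustive enumeration on 5 samples", {
  set.seed(31)
  m1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  m2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(m2) <- dimnames(m1)
  d1 <- distance_matrix(m1)
  d2 <- distance_matrix(m2)
  oracle <- oracle_mantel_exhaustive(m1, m2)
  res <- mantel_test(d1, d2, permutations = 4000, seed = 7)
  expect_equal(res$r, oracle$r)
  # our sampled p estimates the exhaustive tail probability
  expect_lt(abs(res$p - oracle$p_exhaustive),
            3 * sqrt(oracle$p_exhaustive / 4000) + 1e-3)
  # fixed seed reproduces exactly
  expect_identical(res$p, mantel_test(d1, d2, permutations = 4000,
                                      seed = 7)$p)
})

test_that("PERMANOVA partitions variance and matches the brute-force oracle", {
  # perfect separation: all within-group distances 0
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  res <- permanova(distance_matrix(m),
                   stats::setNames(c("x", "x", "y", "y"), letters[1:4]),
                   permutations = 99, seed = 1)
  expect_equal(res$r2, 1)

  set.seed(55)
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- stats::setNames(c("a", "a", "b", "b", "b", "a"),
                            rownames(d))
  oracle <- oracle_permanova_exhaustive(d, unname(groups))
  res <- permanova(distance_matrix(d), groups, permutations = 3000,
                   seed = 2)
  expect_equal(res$f, oracle$f)
  expect_equal(res$r2, oracle$r2)
  expect_lt(abs(res$p - oracle$p_exhaustive),
            3 * sqrt(oracle$p_exhaustive / 3000) + 1e-3)
  # SS additivity: R^2 + SS_within / SS_total = 1
  expect_equal(res$r2 + res$ss[["within"]] / res$ss[["total"]], 1)
  expect_error(permanova(distance_matrix(d), rep("one", 6)), "two groups")
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(n_taxa = 10, n_samples = 9, seed = 61)
  dm <- pairwise_distances(fx$table, fx$tree,
                           metric_spec("unifrac_weighted", "absolute"),
                           fx$loads)
  groups <- stats::setNames(rep(c("u", "v", "w"), each = 3),
                            rownames(dm))
  res <- permanova(dm, groups, permutations = 99, seed = 1)
  adn <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ g,
                        data = data.frame(g = unname(groups)),
                        permutations = 99)
  expect_equal(res$f, adn$F[1], tolerance = 1e-10)
  expect_equal(res$r2, adn$R2[1], tolerance = 1e-10)
})

test_that("load-error injection: zero error is exact, deviation grows", {
  fx <- random_fixture(n_taxa = 10, n_samples = 6, seed = 71,
                       load_log10_range = c(6, 8))
  spec <- metric_spec("unifrac_generalized", "absolute", alpha = 1)
  sens <- error_sensitivity(fx$table, fx$tree, fx$loads, spec,
                            error_levels = c(0, 0.05, 0.25),
                            iterations = 8, seed = 5)
  expect_equal(sens$mean_dev[1], 0)
  expect_equal(sens$max_dev[1], 0)
  expect_true(all(diff(sens$mean_dev) > 0))
  expect_error(
    error_sensitivity(fx$table, fx$tree, fx$loads, spec, 1.2),
    "\\[0, 1\\)")
  expect_error(
    error_sensitivity(fx$table, fx$tree, fx$loads,
                      metric_spec("unifrac_weighted", "relative"),
                      0.1),
    "absolute")
})
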