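test_that("motion index arithmetic and antisymmetry", {
  expect_equal(motion_index(0.55, 0.50, 0.45, 0.50), 0.10)
  expect_equal(motion_index(0.5, 0.5, 0.5, 0.5), 0)
  expect_equal(motion_index(0.45, 0.50, 0.55, 0.50),
               -motion_index(0.55, 0.50, 0.45, 0.50))
  expect_error(motion_index(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("the r-to-t transform matches its closed form and is odd", {
  expect_identical(r_to_t(0, 14), 0)
  expect_equal(r_to_t(0.6, 14), 0.6 * sqrt(12) / sqrt(1 - 0.36))
  expect_equal(r_to_t(0.6, 14), 2.598, tolerance = 1e-3)
  expect_equal(r_to_t(-0.35, 10), -r_to_t(0.35, 10))
  expect_error(r_to_t(1, 14), "< 1")
  expect_error(r_to_t(0.5, 2), "n >= 3")
})

test_that("cluster t-test finds a seeded adjacent effect and reports members", {
  lay <- fix_layout()
  adj <- lay$adjacency
  set.seed(27)
  n <- 14; ne <- 31
  blk <- c(31, which(adj[31, ])[1:3])
  x <- matrix(rnorm(n * ne), n, ne); y <- matrix(rnorm(n * ne), n, ne)
  x[, blk] <- x[, blk] + 1.5
  cr <- cluster_perm_ttest(x, y, adj, seed = 2)
  tj <- tidy(cr)
  expect_gt(nrow(tj), 0)
  expect_true(any(tj$significant))
  found <- unlist(tj$members[tj$significant])
  expect_gte(length(intersect(found, blk)), 3)
  # permutation p respects its lower bound
  expect_gte(min(tj$p.value), 1 / 1001)
  g <- glance(cr)
  expect_identical(g$kind, "dependent-t")
  expect_identical(g$n_permutations, 1000)
})

test_that("cluster results are exactly reproducible for a fixed seed", {
  set.seed(28)
  n <- 10; ne <- 31
  adj <- fix_layout()$adjacency
  x <- matrix(rnorm(n * ne), n, ne); y <- matrix(rnorm(n * ne), n, ne)
  a <- cluster_perm_ttest(x, y, adj, n_perm = 300, seed = 5)
  b <- cluster_perm_ttest(x, y, adj, n_perm = 300, seed = 5)
  expect_identical(tidy(a), tidy(b))
})

test_that("identical conditions yield no significant clusters", {
  set.seed(29)
  adj <- fix_layout()$adjacency
  x <- matrix(rnorm(12 * 31), 12, 31)
  cr <- cluster_perm_ttest(x, x + matrix(rnorm(12 * 31, 0, 1), 12, 31),
                           adj, n_perm = 500, seed = 3)
  # pure noise: any cluster found must be non-significant almost always;
  # a single run is checked loosely, the rate is checked in acceptance
  expect_true(all(tidy(cr)$p.value > 1 / 501))
})

test_that("permuted correlation recovers a linked posterior block", {
  lay <- fix_layout()
  pa <- pair_adjacency(lay)
  set.seed(30)
  n <- 14
  mi <- rnorm(n, 0, 0.1)
  delta <- matrix(rnorm(n * 13, 0, 0.05), n, 13)
  blk <- c(13, which(pa[13, ])[1])
  for (p in blk) delta[, p] <- delta[, p] + 3 * mi
  cc <- cluster_perm_correlation(delta, mi, pa, seed = 4)
  tj <- tidy(cc)
  expect_true(any(tj$significant))
  expect_gte(length(intersect(unlist(tj$members[tj$significant]), blk)), 1)
})

test_that("single-element supra-threshold effects are never significant", {
  # min_cluster = 2: an isolated channel cannot be reported
  set.seed(31)
  n <- 12
  adj <- matrix(FALSE, 5, 5)  # no adjacency at all -> all clusters size 1
  mi <- rnorm(n)
  delta <- matrix(rnorm(n * 5, 0, 0.1), n, 5)
  delta[, 3] <- delta[, 3] + 2 * mi
  cc <- cluster_perm_correlation(delta, mi, adj, seed = 6)
  expect_false(any(tidy(cc)$significant))
})

test_that("the alternative subject-shuffle permutation scheme runs", {
  set.seed(32)
  n <- 10
  pa <- pair_adjacency(fix_layout())
  mi <- rnorm(n)
  delta <- matrix(rnorm(n * 13), n, 13)
  cc <- cluster_perm_correlation(delta, mi, pa, n_perm = 200, seed = 7,
                                 scheme = "shuffle_mi")
  expect_s3_class(cc, "cluster_result")
  expect_true(all(tidy(cc)$p.value >= 1 / 201))
})

test_that("results are invariant to relabeling of subjects", {
  set.seed(33)
  n <- 9; ne <- 31
  adj <- fix_layout()$adjacency
  x <- matrix(rnorm(n * ne), n, ne); y <- matrix(rnorm(n * ne), n, ne)
  x[, 1:4] <- x[, 1:4] + 1
  a <- cluster_perm_ttest(x, y, adj, n_perm = 400, seed = 8)
  perm <- sample(n)
  b <- cluster_perm_ttest(x[perm, ], y[perm, ], adj, n_perm = 400, seed = 8)
  # observed clusters identical; permutation p equal because the sign-flip
  # null is exchangeable over subjects
  expect_identical(tidy(a)$members, tidy(b)$members)
  expect_identical(tidy(a)$sum_t, tidy(b)$sum_t)
})

test_that("grid adjacency links sensors in space and neighboring frequencies", {
  sp_adj <- matrix(FALSE, 3, 3)
  sp_adj[1, 2] <- sp_adj[2, 1] <- TRUE
  g <- grid_adjacency(sp_adj, n_freq = 2)
  expect_identical(dim(g), c(6L, 6L))
  expect_true(g[1, 2])   # spatial neighbors at freq 1
  expect_true(g[4, 5])   # spatial neighbors at freq 2
  expect_true(g[1, 4])   # same sensor, adjacent freq
  expect_false(g[1, 5])  # no diagonal links
  expect_false(any(diag(g)))
  expect_true(all(g == t(g)))
})
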