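test_that("class aggregation sums counts and preserves totals", {
  counts <- matrix(c(30L, 70L, 100L,
                     10L, 10L, 180L), 2, 3, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  tax <- data.frame(domain = "d", phylum = c("pA", "pA", "pB"),
                    class = c("cA", "cA", "cB"),
                    order = "o", family = "f", genus = "g",
                    row.names = c("t1", "t2", "t3"))
  meta <- data.frame(depth_cm = 1:2, treatment = "bioturbated",
                     time_point = "T1", row.names = c("a", "b"))
  tm <- aggregate_to_class(zotu_table(counts, tax, meta))
  expect_equal(tm$abundance["a", "cA"], 0.5)
  expect_equal(unname(rowSums(tm$abundance)), c(1, 1))
  # unclassified class falls back to phylum
  tax2 <- tax; tax2$class[3] <- "unclassified"
  expect_message(tm2 <- aggregate_to_class(zotu_table(counts, tax2, meta)),
                 "phylum")
  expect_true("pB" %in% colnames(tm2$abundance))
})

test_that("spearman network matches the mid-rank Pearson oracle with ties", {
  set.seed(12)
  for (i in 1:100) {
    x <- sample(1:6, 15, replace = TRUE)   # heavy ties
    y <- sample(1:6, 15, replace = TRUE)
    m <- cbind(a = x, b = y, c = rnorm(15))
    net <- suppressMessages(spearman_network(m))
    expect_lt(abs(net$rho["a", "b"] - oracle_spearman(x, y)), 1e-12)
  }
  # monotone pairs are exactly +/- 1
  v <- sort(rexp(12)); m <- cbind(a = v, b = v^3, c = rev(v))
  net <- spearman_network(m)
  expect_equal(net$rho["a", "b"], 1)
  expect_equal(net$rho["a", "c"], -1)
})

test_that("small-sample p-values come from exact permutation enumeration", {
  set.seed(13)
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  m <- cbind(a = x, b = y)
  net <- spearman_network(m)
  # independent enumeration over all 6! permutations
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- as.matrix(perms[apply(perms, 1, function(r) length(unique(r)) == 6), ])
  rho_obs <- oracle_spearman(x, y)
  rho_null <- apply(perms, 1, function(p) oracle_spearman(x, y[p]))
  p_exact <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  expect_equal(net$p["a", "b"], p_exact, tolerance = 1e-12)
})

test_that("significance masks nest and the t-approximation is two-sided", {
  set.seed(14)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, paste0("c", 1:6)))
  n1 <- spearman_network(m, alpha = 0.01)
  n2 <- spearman_network(m, alpha = 0.10)
  expect_true(all(n2$significant[n1$significant]))
  expect_equal(n1$n_tests, 15)
})

test_that("planted two-block structure is recovered exactly", {
  set.seed(15)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- cbind(f1 + rnorm(n, 0, 0.05), f1 + rnorm(n, 0, 0.05),
                 f1 + rnorm(n, 0, 0.05), f2 + rnorm(n, 0, 0.05),
                 f2 + rnorm(n, 0, 0.05), f2 + rnorm(n, 0, 0.05))
  colnames(block) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  net <- spearman_network(block)
  cl <- extract_clusters(net)          # automatic k
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(cl[c("b1", "b2", "b3")])), 1)
  # k = number of classes gives singletons
  singles <- extract_clusters(net, k = 6)
  expect_equal(length(unique(singles)), 6)
  expect_error(extract_clusters(net, k = 7), "exceeds")
  # permuting class order permutes labels consistently
  perm <- c(4, 1, 6, 2, 5, 3)
  net_p <- spearman_network(block[, perm])
  cl_p <- extract_clusters(net_p, k = 2)
  same <- function(l) outer(l, l, "==")
  expect_equal(same(cl_p[colnames(block)]), same(cl[colnames(block)]))
})

test_that("distance correlation matches the brute-force oracle and its invariances", {
  set.seed(16)
  a <- matrix(rnorm(50 * 3), 50)
  b <- matrix(rnorm(50 * 2), 50)
  expect_lt(abs(distance_correlation(a, b) - oracle_dcor(a, b)), 1e-10)
  expect_equal(distance_correlation(a, a), 1)
  # invariance to orthogonal rotation and scaling of a block
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(distance_correlation(a %*% q * 3.7, b),
               distance_correlation(a, b), tolerance = 1e-12)
})

test_that("interdomain dcor test is seeded, bounded and validates input", {
  set.seed(17)
  a <- matrix(rnorm(30 * 3), 30, dimnames = list(paste0("s", 1:30), NULL))
  b_dep <- a[, 1:2] + matrix(rnorm(60, 0, 0.1), 30)
  rownames(b_dep) <- rownames(a)
  r <- interdomain_dcor(a, b_dep, n_resamples = 199, seed = 1)
  expect_true(r$dcor_R > 0.8 && r$dcor_R <= 1)
  expect_equal(r$p_value, 1 / 200)
  expect_true(r$significant)
  r2 <- interdomain_dcor(a, b_dep, n_resamples = 199, seed = 1)
  expect_identical(r$p_value, r2$p_value)
  expect_error(interdomain_dcor(a[1:7, ], b_dep[1:7, ]), "at least 8")
  bad <- b_dep; rownames(bad) <- rev(rownames(a))
  expect_error(interdomain_dcor(a, bad), "same samples")
})
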