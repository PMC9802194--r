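test_that("rarefaction subsamples exactly, deterministically, and only loses taxa", {
  tab <- make_table(n_samples = 6, n_taxa = 30, seed = 2)
  r <- rarefy(tab, depth = 100, seed = 7)
  expect_true(all(rowSums(r$counts) == 100))
  expect_true(all(richness(r) <= richness(tab)))
  r2 <- rarefy(tab, depth = 100, seed = 7)
  expect_identical(r$counts, r2$counts)
  # exhaustive draw leaves a sample unchanged
  tot <- rowSums(tab$counts)[1]
  expect_warning(r3 <- rarefy(tab, depth = tot, seed = 1), "dropped")
  expect_equal(unname(r3$counts[rownames(tab$counts)[1], ]),
               unname(tab$counts[1, ]))
  expect_error(rarefy(tab, depth = 0), "positive")
})

test_that("richness counts positive taxa and ignores zero columns", {
  tab <- make_table(n_samples = 4, n_taxa = 10, seed = 3)
  expect_equal(unname(richness(tab)), rep(10, 4))  # fixture has all counts > 0
  counts2 <- cbind(tab$counts, t999 = 0L)
  tax2 <- rbind(tab$taxonomy, t999 = tab$taxonomy[1, ])
  tab2 <- zotu_table(counts2, tax2, tab$metadata)
  expect_equal(unname(richness(tab2)), unname(richness(tab)))
})

test_that("unifrac closed forms hold on a two-tip star tree", {
  counts <- matrix(c(5L, 0L, 0L, 7L, 3L, 3L), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  tax <- data.frame(domain = c("d", "d"), phylum = "p", class = "c",
                    order = "o", family = "f", genus = "g",
                    row.names = c("t1", "t2"))
  meta <- data.frame(depth_cm = 1:3, treatment = "bioturbated",
                     time_point = "T1", row.names = c("a", "b", "c"))
  tab <- zotu_table(counts, tax, meta)
  star <- ape::read.tree(text = "(t1:0.3,t2:0.3);")
  dw <- unifrac(tab, star, weighted = TRUE)
  du <- unifrac(tab, star, weighted = FALSE)
  expect_equal(dw["a", "b"], 1)   # complete turnover
  expect_equal(du["a", "b"], 1)
  expect_equal(dw["c", "c"], 0)
  expect_equal(du["a", "c"], 0.5) # one of two equal branches unshared
  expect_equal(dw["a", "c"], 0.5) # hand evaluation of the branch sums
  expect_equal(du["b", "c"], 0.5)
})

test_that("unifrac agrees with phyloseq and is a valid distance", {
  tab <- make_table(n_samples = 8, n_taxa = 25, seed = 4)
  tree <- make_tree(colnames(tab$counts), seed = 5)
  dw <- unifrac(tab, tree, weighted = TRUE)
  du <- unifrac(tab, tree, weighted = FALSE)
  expect_true(all(abs(dw - t(dw)) == 0) && all(diag(dw) == 0))
  expect_true(all(dw >= 0 & dw <= 1))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(tab$counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree))
  expect_equal(dw, as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                               normalized = TRUE)),
               tolerance = 1e-10)
  expect_equal(du, as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)),
               tolerance = 1e-10)
  # a taxon absent from both samples does not change the distance
  counts2 <- cbind(tab$counts, textra = 0L)
  tax2 <- rbind(tab$taxonomy, textra = tab$taxonomy[1, ])
  tab2 <- zotu_table(counts2, tax2, tab$metadata)
  tree2 <- make_tree(colnames(counts2), seed = 5)
  # restrict comparison to the shared tree by pruning: distances on tab2 with
  # tree over 26 tips must match on the shared sample pairs up to the tree
  dw2 <- unifrac(tab2, tree2, weighted = TRUE)
  expect_equal(dim(dw2), dim(dw))
  expect_error(unifrac(tab2, tree, weighted = TRUE), "textra")
})

test_that("pcoa reproduces Euclidean configurations and flags negatives", {
  set.seed(6)
  pts <- cbind(rnorm(10), rnorm(10))
  rownames(pts) <- paste0("s", 1:10)
  d <- as.matrix(dist(pts))
  ord <- pcoa_ord(d)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(sum(ord$proportions), 1 + 1e-12)
  expect_equal(ord$negative$count, 0)
  # agreement with the classical implementation in ape
  ap <- ape::pcoa(as.dist(d))
  expect_equal(ord$eigenvalues[1:2], ap$values$Eigenvalues[1:2],
               tolerance = 1e-10)
  # all-zero distances: no positive axes, zero-dimensional embedding
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(ncol(pcoa_ord(z)$coordinates), 0)
  # lingoes correction removes negative eigenvalues
  tabn <- make_table(n_samples = 8, n_taxa = 25, seed = 4)
  dn <- unifrac(tabn, make_tree(colnames(tabn$counts), seed = 5))
  ordn <- pcoa_ord(dn)
  if (ordn$negative$count > 0) {
    ordc <- pcoa_ord(dn, correction = "lingoes")
    expect_equal(ordc$negative$count, 0)
  }
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permanova matches vegan and is invariant to joint relabeling", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(12, 0), 6), matrix(rnorm(12, 1.5), 6))
  rownames(pts) <- paste0("s", 1:12)
  d <- as.matrix(dist(pts))
  gr <- rep(c("x", "y"), each = 6)
  pm <- permanova(d, gr, n_permutations = 999, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ gr, permutations = 99)
  expect_equal(pm$f, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$r2, ad$R2[1], tolerance = 1e-10)
  # permuting samples together with labels leaves F unchanged
  perm <- sample(12)
  pm2 <- permanova(d[perm, perm], gr[perm], n_permutations = 99, seed = 1)
  expect_equal(pm2$f, pm$f, tolerance = 1e-10)
  # clearly separated clouds saturate the significance floor
  far <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 50, 0.1), 10))
  rownames(far) <- paste0("s", 1:20)
  pf <- permanova(as.matrix(dist(far)), rep(c("x", "y"), each = 10),
                  n_permutations = 999, seed = 2)
  expect_equal(pf$p, 0.001)
  expect_error(permanova(d, c(rep("x", 11), "y")), "at least 2 samples")
})

test_that("cap recovers spanned directions and is span-invariant", {
  tab <- make_table(n_samples = 12, n_taxa = 30, seed = 8)
  tree <- make_tree(colnames(tab$counts), seed = 9)
  d <- unifrac(tab, tree)
  ord <- pcoa_ord(d)
  # constraining on PCo1 itself reproduces PCo1 exactly
  res <- cap(d, data.frame(pc1 = ord$coordinates[, 1]), seed = 1)
  expect_gt(abs(cor(res$sample_scores[, 1], ord$coordinates[, 1])), 0.999)
  expect_lt(abs(res$explained_total - ord$proportions[1]), 1e-6)
  # duplicating a variable leaves the explained proportion unchanged
  set.seed(10)
  env <- data.frame(v1 = rnorm(12), v2 = rnorm(12))
  c1 <- cap(d, env, prefilter = FALSE, seed = 1)
  c2 <- cap(d, cbind(env, v1b = env$v1), prefilter = FALSE, seed = 1)
  expect_equal(c2$explained_total, c1$explained_total, tolerance = 1e-10)
  # dropping a variable cannot increase the explained proportion
  c3 <- cap(d, env["v1"], prefilter = FALSE, seed = 1)
  expect_lte(c3$explained_total, c1$explained_total + 1e-12)
  # full-axis CAP on a Euclidean distance agrees with vegan's capscale
  pts <- matrix(rnorm(12 * 5), 12, dimnames = list(rownames(tab$counts), NULL))
  de <- as.matrix(dist(pts))
  cfull <- cap(de, env, n_retained_axes = 100, prefilter = FALSE, seed = 1)
  cs <- vegan::capscale(as.dist(de) ~ v1 + v2, data = env)
  expect_equal(cfull$explained_total, cs$CCA$tot.chi / cs$tot.chi,
               tolerance = 1e-8)
  expect_error(cap(d, matrix(rnorm(12 * 12), 12)), "variables")
})
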