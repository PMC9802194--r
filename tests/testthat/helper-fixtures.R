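# Programmatic fixtures shared across test files.

make_counts <- function(n_samples = 10, n_taxa = 20, seed = 1, lambda = 20) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  counts <- withr_seed(matrix(rpois(n_samples * n_taxa, lambda) + 1L,
                              n_samples, n_taxa))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)),
                           sprintf("t%03d", seq_len(n_taxa)))
  counts
}

make_table <- function(n_samples = 10, n_taxa = 20, seed = 1,
                       n_classes = 4) {
  counts <- make_counts(n_samples, n_taxa, seed)
  cls <- rep(sprintf("c%d", seq_len(n_classes)), length.out = n_taxa)
  taxonomy <- data.frame(domain = "Bacteria",
                         phylum = rep("p1", n_taxa),
                         class = cls,
                         order = "unclassified", family = "unclassified",
                         genus = "unclassified",
                         row.names = colnames(counts))
  metadata <- data.frame(
    depth_cm = rep(seq_len(ceiling(n_samples / 2)) * 3,
                   length.out = n_samples),
    treatment = "bioturbated", time_point = "T1",
    row.names = rownames(counts))
  zotu_table(counts, taxonomy, metadata)
}

make_tree <- function(taxa, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ape::rcoal(length(taxa), tip.label = taxa)
}

# Independent brute-force oracles --------------------------------------------

# mid-rank Pearson Spearman
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# explicit double-centering distance correlation
oracle_dcor <- function(a, b) {
  n <- nrow(a)
  A <- as.matrix(dist(a)); B <- as.matrix(dist(b))
  Ah <- A; Bh <- B
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Ah[i, j] <- A[i, j] - mean(A[i, ]) - mean(A[, j]) + mean(A)
    Bh[i, j] <- B[i, j] - mean(B[i, ]) - mean(B[, j]) + mean(B)
  }
  sqrt(mean(Ah * Bh) / sqrt(mean(Ah^2) * mean(Bh^2)))
}

# textbook Welch statistic
oracle_welch <- function(a, b) {
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
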