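#' Aggregate a ZOTU table to class level
#'
#' Sums counts within each taxonomic class per sample and converts to
#' relative abundance (fraction of the sample's total reads).  Where the
#' class rank is missing or `"unclassified"` the phylum is used instead
#' (reported via a message).
#'
#' @param table a [zotu_table()] whose taxonomy has `class` and `phylum`
#'   columns.
#' @return An object of class `"taxon_matrix"`: `abundance` (samples x
#'   classes relative abundances), `metadata`, `domain`.
#' @export
aggregate_to_class <- function(table) {
  stopifnot(inherits(table, "zotu_table"))
  tax <- table$taxonomy
  if (!all(c("class", "phylum") %in% names(tax)))
    stop_invalid("taxonomy must contain `class` and `phylum` ranks")
  cls <- as.character(tax$class)
  fall_back <- is.na(cls) | cls == "" | cls == "unclassified"
  if (any(fall_back)) {
    cls[fall_back] <- as.character(tax$phylum)[fall_back]
    message(sum(fall_back), " taxa aggregated at phylum rank (class unclassified)")
  }
  if (all(is.na(cls) | cls == "")) stop_invalid("taxonomy is empty")
  rel <- table$counts / rowSums(table$counts)
  groups <- split(seq_along(cls), cls)
  ab <- vapply(groups, function(idx) rowSums(rel[, idx, drop = FALSE]),
               numeric(nrow(rel)))
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1,
                                     dimnames = list(rownames(rel), names(groups)))
  structure(list(abundance = ab, metadata = table$metadata,
                 domain = table$domain),
            class = "taxon_matrix")
}

# All permutations of 1..n (n <= 9), cached per session.
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  gen <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], gen(v[-i]))))
  }
  p <- gen(seq_len(n))
  perm_cache[[key]] <- p
  p
}

# Exact two-sided permutation p-value for Spearman's rho with mid-ranks.
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- all_permutations(n)
  a <- rx - mean(rx)
  ry_perm <- matrix(ry[perms], nrow(perms), n)
  num <- ry_perm %*% a
  den <- sqrt(sum(a^2) * sum((ry - mean(ry))^2))
  rho_perm <- num / den
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

#' Class-level Spearman co-occurrence network
#'
#' Pairwise Spearman correlations (Pearson on mid-ranks) between taxon
#' classes across all samples and time points, with two-sided p-values
#' (t approximation for `n >= 10` samples, exact rank-permutation
#' enumeration below that), a significance mask at `alpha` (no
#' multiple-testing correction; the number of tests is reported), and
#' average-linkage hierarchical clustering on `1 - rho` with cluster labels
#' from a dendrogram cut.
#'
#' @param matrix_ a [aggregate_to_class()] result or a plain samples x
#'   classes abundance matrix with at least 5 samples.
#' @param alpha significance threshold for the edge mask.
#' @param k number of clusters to cut, or `NULL` for the automatic rule
#'   (maximize mean within-cluster rho minus mean between-cluster rho over
#'   `k` in 2..8).
#' @return An object of class `"correlation_network"`: `rho`, `p`,
#'   `significant`, `clusters`, `linkage` (the `hclust` record), `alpha`,
#'   `n_samples`, `n_tests`, `dropped` (zero-variance classes).
#' @export
spearman_network <- function(matrix_, alpha = 0.05, k = NULL) {
  x <- if (inherits(matrix_, "taxon_matrix")) matrix_$abundance else
    as.matrix(matrix_)
  n <- nrow(x)
  if (n < 5) stop_invalid("need at least 5 samples")
  keep <- apply(x, 2, function(v) var(v) > 0)
  dropped <- colnames(x)[!keep]
  if (any(!keep)) {
    message(sum(!keep), " zero-variance class(es) excluded: ",
            paste(dropped, collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  p_cls <- ncol(x)
  if (p_cls < 2) stop_invalid("need at least 2 classes with variance")
  rho <- cor(x, method = "spearman")
  pmat <- matrix(NA_real_, p_cls, p_cls, dimnames = dimnames(rho))
  for (i in seq_len(p_cls - 1)) for (j in (i + 1):p_cls) {
    pv <- if (n >= 10) {
      r <- min(max(rho[i, j], -1), 1)
      if (abs(r) >= 1) 0 else {
        tv <- r * sqrt((n - 2) / (1 - r^2))
        2 * pt(-abs(tv), n - 2)
      }
    } else spearman_exact_p(x[, i], x[, j])
    pmat[i, j] <- pmat[j, i] <- pv
  }
  diag(pmat) <- 0
  sig <- pmat < alpha
  diag(sig) <- FALSE
  hc <- hclust(stats::as.dist(1 - rho), method = "average")
  net <- structure(list(rho = rho, p = pmat, significant = sig,
                        clusters = NULL, linkage = hc, alpha = alpha,
                        n_samples = n, n_tests = p_cls * (p_cls - 1) / 2,
                        dropped = dropped),
                   class = "correlation_network")
  net$clusters <- extract_clusters(net, k)
  net
}

#' Cut network clusters from the linkage record
#'
#' Cuts the average-linkage dendrogram of a correlation network into `k`
#' clusters.  The automatic rule chooses `k` in 2..8 to maximize the mean
#' within-cluster correlation minus the mean between-cluster correlation.
#'
#' @param network a [spearman_network()] result.
#' @param k number of clusters, or `NULL` for automatic selection.
#' @return Named integer vector of cluster labels, one per class.
#' @export
extract_clusters <- function(network, k = NULL) {
  stopifnot(inherits(network, "correlation_network"))
  rho <- network$rho
  p_cls <- ncol(rho)
  if (!is.null(k)) {
    if (k > p_cls) stop_invalid("k exceeds the number of classes")
    return(cutree(network$linkage, k = k))
  }
  score <- function(labels) {
    same <- outer(labels, labels, "==")
    ut <- upper.tri(rho)
    within <- rho[ut & same]
    between <- rho[ut & !same]
    (if (length(within)) mean(within) else 0) -
      (if (length(between)) mean(between) else 0)
  }
  ks <- seq(2, min(8, p_cls))
  scores <- vapply(ks, function(kk) score(cutree(network$linkage, k = kk)),
                   numeric(1))
  cutree(network$linkage, k = ks[which.max(scores)])
}

#' Sample distance correlation
#'
#' Szekely's distance correlation between two multivariate blocks observed
#' on the same samples, from doubly-centered Euclidean distance matrices;
#' lies in `[0, 1]` and is zero (at population level) iff the blocks are
#' independent.
#'
#' @param a,b numeric matrices (samples x variables) with matching rows.
#' @return A single number in `[0, 1]`.
#' @export
distance_correlation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop_invalid("blocks must have the same sample count")
  ah <- dcenter(as.matrix(dist(a)))
  bh <- dcenter(as.matrix(dist(b)))
  dcor_from_centered(ah, bh)
}

dcenter <- function(m) {
  rm_ <- rowMeans(m)
  sweep(sweep(m, 1, rm_), 2, rm_) + mean(m)
}

dcor_from_centered <- function(ah, bh) {
  dcov2 <- mean(ah * bh)
  dvar <- sqrt(mean(ah * ah) * mean(bh * bh))   # sqrt(dVar2_x * dVar2_y)
  if (dvar <= 0) return(0)
  sqrt(max(dcov2, 0) / dvar)
}

#' Interdomain cluster distance correlation
#'
#' Distance correlation between the member-class abundance blocks of two
#' network clusters (typically from different domains), with significance
#' from `n_resamples` permutations of the sample rows of the second block,
#' `p = (1 + #\{dcor* >= dcor\}) / (1 + n_resamples)`.  The sign of the
#' Pearson correlation between the clusters' aggregate abundances is
#' attached as `sign_hint` for "positively/negatively correlated" reporting
#' (distance correlation itself is unsigned).
#'
#' @param cluster_a,cluster_b samples x member-class abundance matrices with
#'   identical row names; at least 8 samples.
#' @param n_resamples permutations for the null (default 999).
#' @param seed integer seed.
#' @param alpha significance threshold.
#' @return An object of class `"cluster_correlation"`: `dcor_R`, `p_value`,
#'   `significant`, `sign_hint`, `n_resamples`, `seed`.
#' @export
interdomain_dcor <- function(cluster_a, cluster_b, n_resamples = 999,
                             seed = 1, alpha = 0.05) {
  a <- as.matrix(cluster_a); b <- as.matrix(cluster_b)
  if (nrow(a) != nrow(b) ||
      (!is.null(rownames(a)) && !is.null(rownames(b)) &&
       !identical(rownames(a), rownames(b))))
    stop_invalid("cluster blocks must share the same samples")
  n <- nrow(a)
  if (n < 8) stop_invalid("need at least 8 samples")
  ah <- dcenter(as.matrix(dist(a)))
  bh <- dcenter(as.matrix(dist(b)))
  obs <- dcor_from_centered(ah, bh)
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_resamples)) {
      p <- sample.int(n)
      if (dcor_from_centered(ah, bh[p, p]) >= obs - 1e-12) count <- count + 1L
    }
    count
  })
  p_val <- (1 + exceed) / (1 + n_resamples)
  structure(list(dcor_R = obs, p_value = p_val,
                 significant = p_val < alpha,
                 sign_hint = sign(cor(rowSums(a), rowSums(b))),
                 n_resamples = n_resamples, seed = seed),
            class = "cluster_correlation")
}

#' @export
print.cluster_correlation <- function(x, ...) {
  cat(sprintf("dcor R = %.3f, p = %.4g (%d permutations), sign %s\n",
              x$dcor_R, x$p_value, x$n_resamples,
              if (is.na(x$sign_hint)) "NA" else
                if (x$sign_hint >= 0) "+" else "-"))
  invisible(x)
}

#' Export a correlation network as an edge list
#'
#' @param network a [spearman_network()] result.
#' @return Data frame with `class_a`, `class_b`, `rho`, `p`, `significant`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  cls <- colnames(network$rho)
  idx <- which(upper.tri(network$rho), arr.ind = TRUE)
  data.frame(class_a = cls[idx[, 1]], class_b = cls[idx[, 2]],
             rho = network$rho[idx], p = network$p[idx],
             significant = network$significant[idx])
}
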