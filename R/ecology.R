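#' ZOTU count table
#'
#' Container for a samples x taxa count matrix with taxonomy and sample
#' metadata, the unit of all community analyses.  Taxa are zero-radius OTUs
#' (exact sequence variants).
#'
#' @param counts integer matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = taxon ids); non-negative, every sample with
#'   total count `> 0`.
#' @param taxonomy data frame with one row per taxon (rownames = taxon ids)
#'   and rank columns such as `domain`, `phylum`, `class`, ...; lower ranks
#'   may be `"unclassified"`.
#' @param metadata data frame with one row per sample (rownames = sample
#'   ids); typically `depth_cm`, `treatment`, `zone`, `time_point`.
#' @param domain which marker the table represents (`"bac16S"`, `"arc16S"`,
#'   `"euk18S"`).
#' @return An object of class `"zotu_table"`.
#' @export
zotu_table <- function(counts, taxonomy, metadata, domain = "bac16S") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_invalid("`counts` needs sample rownames and taxon colnames")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop_invalid("`counts` must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop_invalid("every sample must have total count > 0")
  if (!all(colnames(counts) %in% rownames(taxonomy)))
    stop_invalid("taxonomy missing for some taxa")
  if (!all(rownames(counts) %in% rownames(metadata)))
    stop_invalid("metadata missing for some samples")
  structure(list(counts = counts,
                 taxonomy = taxonomy[colnames(counts), , drop = FALSE],
                 metadata = metadata[rownames(counts), , drop = FALSE],
                 domain = domain),
            class = "zotu_table")
}

#' @export
print.zotu_table <- function(x, ...) {
  cat(sprintf("zotu_table (%s): %d samples x %d taxa, %d total reads\n",
              x$domain, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Rarefy a ZOTU table
#'
#' Subsamples every sample to exactly `depth` reads without replacement.
#' Samples whose total is below `depth` are dropped with a warning.  The
#' draw is deterministic given `seed`.
#'
#' @param table a [zotu_table()].
#' @param depth target reads per sample (`> 0`); defaults to 90% of the
#'   smallest sample total.
#' @param seed integer seed.
#' @return A rarefied [zotu_table()].
#' @export
rarefy <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "zotu_table"))
  totals <- rowSums(table$counts)
  if (is.null(depth)) depth <- floor(0.9 * min(totals))
  if (!is.numeric(depth) || depth <= 0)
    stop_invalid("`depth` must be a positive count")
  depth <- as.integer(depth)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below rarefaction depth dropped",
            call. = FALSE)
  counts <- table$counts[keep, , drop = FALSE]
  n_taxa <- ncol(counts)
  out <- with_seed(seed, t(apply(counts, 1, function(row) {
    total <- sum(row)
    if (total == depth) return(row)
    drawn <- sample.int(total, depth)
    tabulate(findInterval(drawn - 1, cumsum(row)) + 1L, nbins = n_taxa)
  })))
  dimnames(out) <- dimnames(counts)
  zotu_table(out, table$taxonomy, table$metadata[keep, , drop = FALSE],
             table$domain)
}

#' Observed ZOTU richness
#'
#' Number of taxa with count `> 0` in each sample.
#'
#' @param table a [zotu_table()].
#' @return Named integer vector, one entry per sample.
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "zotu_table"))
  rowSums(table$counts > 0)
}

# Per-edge descendant fractions: returns a list with `lengths` (edge branch
# lengths) and `frac` (edges x samples matrix of the per-sample proportion
# of signal descending from each edge).  `values` is samples x taxa.
edge_fractions <- function(tree, values) {
  n_tip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  node_tot <- matrix(0, n_tip + tree$Nnode, nrow(values))
  node_tot[seq_len(n_tip), ] <- t(values[, tre$tip.label, drop = FALSE])
  for (e in seq_len(nrow(tre$edge))) {
    p <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    node_tot[p, ] <- node_tot[p, ] + node_tot[ch, ]
  }
  list(lengths = tre$edge.length, frac = node_tot[tre$edge[, 2], , drop = FALSE])
}

#' UniFrac distances
#'
#' Phylogenetic beta diversity between all sample pairs.  The weighted
#' variant sums branch-length-weighted differences in the fraction of reads
#' descending from each branch, normalized (by default) by the
#' branch-weighted sum of the two profiles so distances lie in `[0, 1]`:
#' \deqn{d_W(A, B) = \sum_i b_i |A_i - B_i| \big/ \sum_i b_i (A_i + B_i).}
#' The unweighted variant scores presence turnover:
#' \deqn{d_U(A, B) = \sum_i b_i \,\mathrm{XOR}(A_i, B_i) \big/
#'   \sum_i b_i \,\mathrm{OR}(A_i, B_i).}
#'
#' @param table a [zotu_table()]; counts are converted to relative
#'   abundances for the weighted variant.
#' @param tree a rooted `ape::phylo` tree whose tips cover all taxa in the
#'   table (extra tips are pruned); branch lengths must be non-negative.
#' @param weighted logical.
#' @param normalized divide the weighted distance by its maximum attainable
#'   value (the `[0, 1]` variant); ignored for unweighted.
#' @return Symmetric distance matrix with sample labels.
#' @export
unifrac <- function(table, tree, weighted = TRUE, normalized = TRUE) {
  stopifnot(inherits(table, "zotu_table"), inherits(tree, "phylo"))
  taxa <- colnames(table$counts)
  absent <- setdiff(taxa, tree$tip.label)
  if (length(absent))
    stop_invalid("taxa missing from tree: ", paste(absent, collapse = ", "))
  if (any(tree$edge.length < 0))
    stop_invalid("tree has negative branch lengths")
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  rel <- table$counts / rowSums(table$counts)
  n <- nrow(rel)
  labels <- rownames(rel)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (weighted) {
    ef <- edge_fractions(tree, rel)
    b <- ef$lengths
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(b * abs(ef$frac[, i] - ef$frac[, j]))
      val <- if (normalized) {
        den <- sum(b * (ef$frac[, i] + ef$frac[, j]))
        if (den > 0) num / den else 0
      } else num
      d[i, j] <- d[j, i] <- val
    }
  } else {
    ef <- edge_fractions(tree, (table$counts > 0) * 1)
    b <- ef$lengths
    pres <- ef$frac > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ors <- sum(b[pres[, i] | pres[, j]])
      xors <- sum(b[xor(pres[, i], pres[, j])])
      d[i, j] <- d[j, i] <- if (ors > 0) xors / ors else 0
    }
  }
  d
}

as_distance_matrix <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) ||
      any(abs(diag(d)) > 1e-12) || any(!is.finite(d)) || any(d < -1e-12))
    stop_invalid("`distances` must be a symmetric non-negative matrix with zero diagonal")
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered Gower
#' matrix of squared distances.  Axes with negative eigenvalues (possible
#' for non-Euclidean distances such as UniFrac) are excluded from the
#' variance proportions and reported in `$negative`.
#'
#' @param distances symmetric distance matrix (or `dist`).
#' @param correction `"none"` (default) or `"lingoes"` (adds the smallest
#'   constant to squared off-diagonal distances that makes the matrix
#'   Euclidean).
#' @return An object of class `"pcoa_result"`: `coordinates` (samples x
#'   axes, positive-eigenvalue axes only), `eigenvalues` (all), `proportions`
#'   (per positive axis), `negative` (count and most negative value),
#'   `correction`.
#' @export
pcoa_ord <- function(distances, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_distance_matrix(distances)
  n <- nrow(d)
  gower <- function(d2) {
    j <- diag(n) - 1 / n
    -0.5 * j %*% d2 %*% j
  }
  d2 <- d^2
  eig <- eigen(gower(d2), symmetric = TRUE)
  note <- NULL
  tol <- max(1e-12, 1e-8 * max(abs(eig$values)))
  if (correction == "lingoes" && min(eig$values) < -tol) {
    c1 <- -min(eig$values)
    d2c <- d2 + 2 * c1
    diag(d2c) <- 0
    eig <- eigen(gower(d2c), symmetric = TRUE)
    note <- sprintf("Lingoes constant %.6g added to squared distances", c1)
    tol <- max(1e-12, 1e-8 * max(abs(eig$values)))
  }
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 proportions = eig$values[pos] / sum(eig$values[pos]),
                 negative = list(count = sum(eig$values < -tol),
                                 most_negative = min(eig$values, 0)),
                 correction = c(correction, note)),
            class = "pcoa_result")
}

permanova_f <- function(d2, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  list(f = (ssa / (a - 1)) / (ssw / (n - a)), r2 = ssa / sst)
}

#' PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from the among/within partition of squared inter-sample
#' distances, with a p-value from free permutation of the group labels,
#' `p = (1 + #\{F* >= F\}) / (1 + n_permutations)`.
#'
#' @param distances symmetric distance matrix (or `dist`).
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `"permanova_result"` with `f`, `r2`, `p`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(distances, groups, n_permutations = 999, seed = 1) {
  d <- as_distance_matrix(distances)
  groups <- as.character(groups)
  if (length(groups) != nrow(d))
    stop_invalid("`groups` length must match the distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop_invalid("need at least 2 groups")
  if (any(sizes < 2)) stop_invalid("every group needs at least 2 samples")
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_permutations)) {
      fp <- permanova_f(d2, sample(groups))$f
      if (fp >= obs$f - 1e-12) count <- count + 1L
    }
    count
  })
  structure(list(f = obs$f, r2 = obs$r2,
                 p = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$f, x$r2, x$p, x$n_permutations))
  invisible(x)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Constrained ordination of a distance matrix against environmental
#' variables: PCoA axes covering at least 95% of the positive-eigenvalue
#' variance (or a user-set number) are regressed on the standardized
#' environment matrix, and the fitted values are rotated to canonical axes.
#' Variables are pre-filtered by a marginal permutation test (each variable
#' alone, distance-based pseudo-F, `n_permutations` row permutations) at
#' `alpha`, so only variables significantly associated with community
#' composition constrain the ordination.
#'
#' @param distances symmetric distance matrix (or `dist`).
#' @param environment data frame or matrix of environmental variables
#'   (samples x variables); standardized internally; rows with missing
#'   values are removed listwise together with the matching samples.
#' @param n_retained_axes number of PCoA axes to retain, or `NULL` for the
#'   95% positive-variance rule.
#' @param n_permutations permutations for the marginal tests.
#' @param alpha retention threshold for the marginal permutation p-value.
#' @param prefilter set `FALSE` to keep all variables.
#' @param seed integer seed.
#' @return An object of class `"cap_result"`: `sample_scores` (constrained
#'   axes CAP1, CAP2, ...), `eigenvalues`, `explained_total` (proportion of
#'   total positive-eigenvalue variance explained by the retained
#'   variables), `explained_per_variable` (marginal proportions),
#'   `variable_scores` (correlations of variables with the axes),
#'   `marginal_p`, `retained_variables`, `n_retained_axes`.
#' @export
cap <- function(distances, environment, n_retained_axes = NULL,
                n_permutations = 999, alpha = 0.05, prefilter = TRUE,
                seed = 1) {
  d <- as_distance_matrix(distances)
  env <- as.matrix(environment)
  if (is.null(colnames(env)))
    colnames(env) <- paste0("V", seq_len(ncol(env)))
  if (nrow(env) != nrow(d))
    stop_invalid("`environment` rows must match the distance matrix")
  ok <- stats::complete.cases(env)
  if (!all(ok)) {
    env <- env[ok, , drop = FALSE]
    d <- d[ok, ok, drop = FALSE]
  }
  n <- nrow(d)
  if (ncol(env) > n - 1)
    stop_invalid("more environmental variables than samples - 1")
  env <- scale(env)
  if (any(!is.finite(env)))
    stop_invalid("environmental variables must have positive variance")

  ord <- pcoa_ord(d)
  lambda <- ord$eigenvalues[ord$eigenvalues > 1e-8 * max(ord$eigenvalues)]
  total_inertia <- sum(lambda)
  m <- if (is.null(n_retained_axes)) {
    which(cumsum(lambda) / total_inertia >= 0.95 - 1e-12)[1]
  } else min(n_retained_axes, length(lambda))
  q <- ord$coordinates[, seq_len(m), drop = FALSE]

  # marginal permutation test per variable (distance-based pseudo-F on the
  # retained coordinate space)
  marginal_f <- function(v) {
    fit <- drop(crossprod(q, v)) / sum(v^2)   # projection coefficients
    ss_fit <- sum((v %o% fit)^2)
    ss_tot <- sum(q^2)
    (ss_fit / 1) / ((ss_tot - ss_fit) / (n - 2))
  }
  p_marg <- setNames(rep(NA_real_, ncol(env)), colnames(env))
  expl_marg <- setNames(numeric(ncol(env)), colnames(env))
  for (j in seq_len(ncol(env))) {
    v <- env[, j]
    f_obs <- marginal_f(v)
    expl_marg[j] <- sum((v %o% (drop(crossprod(q, v)) / sum(v^2)))^2) /
      total_inertia
    exceed <- with_seed(child_seed(seed, j), {
      count <- 0L
      for (i in seq_len(n_permutations))
        if (marginal_f(v[sample.int(n)]) >= f_obs - 1e-12) count <- count + 1L
      count
    })
    p_marg[j] <- (1 + exceed) / (1 + n_permutations)
  }
  retained <- if (prefilter) colnames(env)[p_marg < alpha] else colnames(env)
  if (!length(retained)) {
    warning("no environmental variable passed the marginal test", call. = FALSE)
    return(structure(list(sample_scores = NULL, eigenvalues = numeric(0),
                          explained_total = 0,
                          explained_per_variable = expl_marg,
                          variable_scores = NULL, marginal_p = p_marg,
                          retained_variables = character(0),
                          n_retained_axes = m),
                     class = "cap_result"))
  }
  x <- env[, retained, drop = FALSE]
  qr_x <- qr(x)
  fitted <- qr.fitted(qr_x, q)
  sv <- svd(fitted)
  r <- sum(sv$d > 1e-9 * max(sv$d, 1e-300))
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("CAP", seq_len(r))
  var_scores <- cor(x, scores)
  structure(list(sample_scores = scores, eigenvalues = sv$d[seq_len(r)]^2,
                 explained_total = sum(sv$d^2) / total_inertia,
                 explained_per_variable = expl_marg,
                 variable_scores = var_scores, marginal_p = p_marg,
                 retained_variables = retained, n_retained_axes = m),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: %d constrained axes, %.1f%% of community variation explained\n",
              length(x$eigenvalues), 100 * x$explained_total))
  cat("  retained variables:",
      if (length(x$retained_variables))
        paste(x$retained_variables, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
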