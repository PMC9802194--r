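profile_columns <- c("depth_cm", "value", "analyte", "units", "treatment",
                     "time_point", "replicate")

#' Read and write depth-profile tables
#'
#' The profile dialect is a UTF-8 tab-separated table with one header line
#' and columns `depth_cm`, `value`, `analyte`, `units`, `treatment`,
#' `time_point`, `replicate`.  Missing optional columns (`units`,
#' `replicate`) are filled with `NA` on read.
#'
#' @param path file path.
#' @param profiles data frame with at least `depth_cm`, `value`, `analyte`,
#'   `treatment`, `time_point`.
#' @return `read_profiles()` returns a data frame; `write_profiles()`
#'   returns `path` invisibly.
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("depth_cm", "value", "analyte", "treatment", "time_point")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_invalid("profile file lacks columns: ", paste(missing, collapse = ", "))
  for (col in setdiff(profile_columns, names(df))) df[[col]] <- NA
  if (any(!is.finite(df$value)))
    stop_invalid("profile values must be finite")
  df[profile_columns]
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  need <- c("depth_cm", "value", "analyte", "treatment", "time_point")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop_invalid("profiles lack columns: ", paste(missing, collapse = ", "))
  for (col in setdiff(profile_columns, names(profiles))) profiles[[col]] <- NA
  write.table(profiles[profile_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write ZOTU tables
#'
#' `write_zotu_table()` writes three tab-separated files under `dir`: a
#' QIIME-classic taxa x samples count table whose first column is
#' `#OTU ID` and whose last column `taxonomy` holds the semicolon-joined
#' lineage, a sample metadata table keyed by `sample_id`, and (optionally)
#' a Newick tree.  `read_zotu_table()` reads them back losslessly.
#'
#' @param table a [zotu_table()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the table's domain.
#' @param tree optional `ape::phylo` to write alongside.
#' @return `write_zotu_table()` returns the file paths invisibly;
#'   `read_zotu_table()` returns a [zotu_table()] (and attaches the tree as
#'   attribute `"tree"` when present).
#' @export
write_zotu_table <- function(table, dir, prefix = table$domain, tree = NULL) {
  stopifnot(inherits(table, "zotu_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  tax <- apply(table$taxonomy[, ranks, drop = FALSE], 1, paste,
               collapse = "; ")
  counts_path <- file.path(dir, paste0(prefix, "_counts.tsv"))
  df <- data.frame(`#OTU ID` = colnames(table$counts),
                   t(table$counts), taxonomy = tax,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  meta_path <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  meta <- cbind(sample_id = rownames(table$metadata), table$metadata)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  paths <- c(counts = counts_path, metadata = meta_path)
  if (!is.null(tree)) {
    tree_path <- file.path(dir, paste0(prefix, "_tree.nwk"))
    ape::write.tree(tree, tree_path)
    paths <- c(paths, tree = tree_path)
  }
  invisible(paths)
}

#' @rdname write_zotu_table
#' @param counts_path,metadata_path,tree_path file paths as written by
#'   `write_zotu_table()`.
#' @param domain marker label for the returned table.
#' @export
read_zotu_table <- function(counts_path, metadata_path, domain = "bac16S",
                            tree_path = NULL) {
  raw <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (!"taxonomy" %in% names(raw) || names(raw)[1] != "#OTU ID")
    stop_invalid("not a QIIME-classic count table (need `#OTU ID` and `taxonomy`)")
  taxa <- raw[["#OTU ID"]]
  lineage <- strsplit(raw$taxonomy, ";\\s*")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  taxonomy <- as.data.frame(do.call(rbind, lapply(lineage, function(l)
    c(l, rep("unclassified", max(0, length(ranks) - length(l))))[seq_along(ranks)])),
    stringsAsFactors = FALSE)
  names(taxonomy) <- ranks
  rownames(taxonomy) <- taxa
  counts <- t(as.matrix(raw[, setdiff(names(raw), c("#OTU ID", "taxonomy")),
                            drop = FALSE]))
  colnames(counts) <- taxa
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  meta$sample_id <- NULL
  tab <- zotu_table(counts, taxonomy, meta, domain)
  if (!is.null(tree_path)) attr(tab, "tree") <- ape::read.tree(tree_path)
  tab
}
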