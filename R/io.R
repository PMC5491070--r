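#' Read an OTU count table from TSV
#'
#' On disk the table follows the common amplicon convention: OTUs as rows,
#' samples as columns, first column the OTU ID. A leading `#OTU ID` header
#' (BIOM-TSV dialect) is tolerated. In memory the table is transposed to
#' samples x OTUs.
#'
#' @param path file path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (startsWith(first, "#OTU ID")) names(df)[1] <- "otu_id"
  otus <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- otus
  count_table(m)
}

#' Write an OTU count table to TSV (OTUs as rows)
#' @param table count table (samples x OTUs).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  m <- as_count_matrix(table)
  df <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE)
  write_tsv(df, path)
}

#' @noRd
write_tsv <- function(df, path) {
  con <- file(path, open = "wb") # wb => LF line endings on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write a taxonomy table (OTU ID + six rank columns)
#' @param path file path.
#' @return data frame with columns otu_id, kingdom..genus.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = NULL)
  names(df)[1] <- "otu_id"
  names(df) <- tolower(names(df))
  taxonomy_table(df)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data frame.
#' @export
write_taxonomy <- function(tax, path) write_tsv(taxonomy_table(tax), path)

#' Read/write sample metadata TSV
#' @param path file path.
#' @return validated metadata data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta metadata data frame.
#' @export
write_sample_metadata <- function(meta, path) write_tsv(sample_metadata(meta), path)

#' Read a rooted OTU tree from a newick file
#'
#' Unrooted trees are midpoint-rooted with a message (UniFrac requires a
#' root). Branch lengths are required.
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_otu_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stopf("tree has no branch lengths")
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stopf("tree has missing or non-finite branch lengths")
  if (anyDuplicated(tr$tip.label)) stopf("duplicate tip labels in tree")
  if (!ape::is.rooted(tr)) {
    message("input tree is unrooted; applying midpoint rooting")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' @rdname read_otu_tree
#' @param tree a `phylo` object.
#' @export
write_otu_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as a square TSV with header row and column
#' @param d distance matrix (see [distance_matrix()]).
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m)
}
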