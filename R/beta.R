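#' Pairwise community dissimilarities
#'
#' `bray_curtis()` is the abundance-based Bray-Curtis dissimilarity
#' \eqn{\sum |x_i - y_i| / \sum (x_i + y_i)}; `jaccard_binary()` is the
#' presence/absence Jaccard dissimilarity
#' \eqn{1 - |shared| / |union|}.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return a dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))   # 1/3
#' jaccard_binary(c(1, 1, 0), c(0, 1, 1)) # 2/3
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' @rdname bray_curtis
#' @export
jaccard_binary <- function(x, y) {
  check_pair(x, y)
  a <- x > 0
  b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

#' @noRd
check_pair <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stopf("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0) stopf("both vectors are all-zero")
  invisible(TRUE)
}

# Branch structure of a rooted tree: for each edge, which OTU columns
# descend from it. Returned as edge lengths plus a (edges x otus) logical
# incidence matrix restricted to the requested otu_ids.
#' @noRd
tree_branch_incidence <- function(tree, otu_ids) {
  if (!ape::is.rooted(tree)) {
    message("tree is unrooted; applying midpoint rooting for UniFrac")
    tree <- phangorn::midpoint(tree)
  }
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing))
    stopf("OTU(s) absent from the tree: %s", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  # accumulate tip sets up the tree in postorder
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, nrow = ntip + tree$Nnode, ncol = length(otu_ids))
  tipcol <- match(tree$tip.label, otu_ids)
  for (i in seq_len(ntip)) if (!is.na(tipcol[i])) desc[i, tipcol[i]] <- TRUE
  for (e in seq_len(nedge)) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    desc[par, ] <- desc[par, ] | desc[chi, ]
  }
  inc <- desc[tree$edge[, 2], , drop = FALSE]
  list(lengths = tree$edge.length, incidence = inc)
}

#' UniFrac dissimilarities between two communities
#'
#' UniFrac measures how much of a phylogeny's branch length separates two
#' communities. The unweighted form uses presence/absence: the total length
#' of branches leading exclusively to one community's OTUs, divided by the
#' total length of branches leading to either community's OTUs. The weighted
#' form weights each branch by the difference in the fraction of reads
#' descending from it, `sum_b l_b |p_b(x) - p_b(y)|`; with
#' `normalized = TRUE` (the default) it is divided by
#' `sum_j d_j (p_j(x) + p_j(y))` over leaves `j` at root-to-tip distance
#' `d_j`, bounding it by 1.
#'
#' @param tree rooted `phylo` with branch lengths (unrooted input is
#'   midpoint-rooted with a message).
#' @param x,y abundance vectors named by OTU ID (or aligned to
#'   `tree$tip.label` when unnamed and of matching length).
#' @param normalized divide weighted UniFrac by its maximum (default TRUE).
#' @return a dissimilarity (in `[0, 1]` for unweighted and normalized
#'   weighted).
#' @export
unweighted_unifrac <- function(tree, x, y) {
  ab <- unifrac_align(tree, x, y)
  st <- tree_branch_incidence(tree, ab$ids)
  px <- as.vector(st$incidence %*% (ab$x > 0)) > 0
  py <- as.vector(st$incidence %*% (ab$y > 0)) > 0
  either <- sum(st$lengths[px | py])
  if (either == 0) stopf("no branch length covered by either community")
  sum(st$lengths[xor(px, py)]) / either
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(tree, x, y, normalized = TRUE) {
  ab <- unifrac_align(tree, x, y)
  st <- tree_branch_incidence(tree, ab$ids)
  px <- as.vector(st$incidence %*% ab$x) / sum(ab$x)
  py <- as.vector(st$incidence %*% ab$y) / sum(ab$y)
  raw <- sum(st$lengths * abs(px - py))
  if (!normalized) return(raw)
  d_leaf <- as.vector(t(st$incidence) %*% st$lengths) # root-to-leaf distances
  denom <- sum(d_leaf * (ab$x / sum(ab$x) + ab$y / sum(ab$y)))
  if (denom == 0) stopf("zero normalising branch length")
  raw / denom
}

#' @noRd
unifrac_align <- function(tree, x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (is.null(names(x)) && length(x) == length(tree$tip.label)) {
    names(x) <- tree$tip.label
    names(y) <- tree$tip.label
  }
  if (is.null(names(x)) || is.null(names(y)))
    stopf("abundance vectors must be named by OTU ID")
  if (sum(x) == 0 || sum(y) == 0) stopf("each community needs reads")
  present <- names(x)[x > 0 | y > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stopf("OTU(s) absent from the tree: %s", paste(missing, collapse = ", "))
  list(ids = names(x), x = as.numeric(x), y = as.numeric(y))
}

#' Distance matrix over all samples of a count table
#'
#' @param table a [count_table()] (use the rarefied table so depth does not
#'   masquerade as composition).
#' @param metric one of `"bray"`, `"jaccard"`, `"unifrac_unweighted"`,
#'   `"unifrac_weighted"`.
#' @param tree rooted `phylo`; required for the UniFrac metrics.
#' @param normalized passed to [weighted_unifrac()].
#' @return a symmetric matrix of class `dist_matrix` with sample IDs.
#' @export
distance_matrix <- function(table,
                            metric = c("bray", "jaccard",
                                       "unifrac_unweighted", "unifrac_weighted"),
                            tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  m <- as_count_matrix(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (startsWith(metric, "unifrac")) {
    if (is.null(tree)) stopf("a tree is required for UniFrac metrics")
    st <- tree_branch_incidence(tree, colnames(m))
    if (metric == "unifrac_unweighted") {
      pres <- (m > 0) %*% t(st$incidence) > 0 # samples x edges
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        a <- pres[i, ]; b <- pres[j, ]
        d[i, j] <- d[j, i] <-
          sum(st$lengths[xor(a, b)]) / sum(st$lengths[a | b])
      }
    } else {
      rel <- m / rowSums(m)
      pb <- rel %*% t(st$incidence) # samples x edges, fraction under branch
      d_leaf <- as.vector(t(st$incidence) %*% st$lengths)
      leafsum <- as.vector(rel %*% d_leaf)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        raw <- sum(st$lengths * abs(pb[i, ] - pb[j, ]))
        d[i, j] <- d[j, i] <-
          if (normalized) raw / (leafsum[i] + leafsum[j]) else raw
      }
    }
  } else {
    fun <- if (metric == "bray") bray_curtis else jaccard_binary
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- fun(m[i, ], m[j, ])
  }
  dist_matrix(d)
}

#' Validate/construct a symmetric dissimilarity matrix
#' @param m symmetric numeric matrix with zero diagonal and dimnames.
#' @return matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10)
    stopf("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stopf("distance matrix must have a zero diagonal")
  if (any(m < 0)) stopf("dissimilarities must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  m <- (m + t(m)) / 2
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers `-d^2/2` (Gower centering) and eigendecomposes. Negative
#' eigenvalues, which arise for non-Euclidean dissimilarities such as
#' Bray-Curtis, are reported as-is; no Cailliez/Lingoes correction is
#' applied. Coordinates are returned for axes with positive eigenvalues,
#' scaled so Euclidean distances among them reproduce the input distances
#' when the matrix is Euclidean-embeddable.
#'
#' @param d a `dist_matrix` (or symmetric matrix / `dist`).
#' @return object of class `pcoa_result`: `eigenvalues` (descending),
#'   `points` (samples x positive axes), `proportion` (variance share of
#'   each positive axis, relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (max(abs(m - t(m))) > 1e-10) stopf("distance matrix must be symmetric")
  n <- nrow(m)
  if (n < 3L) stopf("need at least 3 samples")
  a <- -0.5 * m^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 nrow = sum(pos))
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(eigenvalues = e$values,
                 points = pts,
                 proportion = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(4L, ncol(x$points))
  cat(sprintf("PCoA: %d samples, %d positive axes\n", nrow(x$points),
              ncol(x$points)))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$proportion[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, axes = c(1, 2), groups = NULL, ...) {
  pts <- x$points[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(pts, col = col, pch = 19,
       xlab = sprintf("Axis %d (%.1f%%)", axes[1], 100 * x$proportion[axes[1]]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2], 100 * x$proportion[axes[2]]),
       ...)
  invisible(x)
}

#' Write ordination results (eigenvalues and coordinates TSVs)
#' @param ord a `pcoa_result`.
#' @param eig_path,coords_path output paths.
#' @export
write_ordination <- function(ord, eig_path, coords_path) {
  write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues), eig_path)
  write_tsv(data.frame(sample_id = rownames(ord$points), ord$points,
                       check.names = FALSE), coords_path)
}
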