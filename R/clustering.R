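#' Distance between coprolite pollen assemblages
#'
#' Pairwise distances between coprolite percentage profiles.  The default
#' metric is 1 minus the uncentred Pearson correlation (the historical
#' default of early gene-expression clustering programs): for profiles x, y
#' the similarity is `sum(x*y) / (||x|| * ||y||)`, so identical profiles are
#' at distance 0 and profiles on disjoint taxa at distance 1; the range is
#' `[0, 2]`.
#'
#' @param pct percentage matrix, coprolites in rows (needs >= 2 rows).
#' @param metric `"uncentered"` (default), `"pearson"` (centred
#'   correlation distance) or `"euclidean"`.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
assemblage_distance <- function(pct,
                                metric = c("uncentered", "pearson",
                                           "euclidean")) {
  metric <- match.arg(metric)
  pct <- as.matrix(pct)
  if (nrow(pct) < 2) stop("need at least 2 coprolites")
  if (metric == "euclidean")
    return(as.matrix(stats::dist(pct)))
  if (metric == "pearson") {
    v <- apply(pct, 1, stats::sd)
    if (any(v == 0))
      stop("zero-variance assemblage(s) under centred correlation: ",
           paste(rownames(pct)[v == 0], collapse = ", "))
    d <- 1 - stats::cor(t(pct))
  } else {
    nrm <- sqrt(rowSums(pct^2))
    if (any(nrm == 0))
      stop("all-zero assemblage(s): ",
           paste(rownames(pct)[nrm == 0], collapse = ", "))
    d <- 1 - (pct %*% t(pct)) / outer(nrm, nrm)
  }
  d[d < 0] <- 0 # numerical noise
  diag(d) <- 0
  dimnames(d) <- list(rownames(pct), rownames(pct))
  d
}

#' Agglomerative clustering of assemblages
#'
#' Hierarchical agglomeration over a precomputed distance matrix with a
#' deterministic tie-break: at every step the closest active pair is merged
#' and, among exact ties, the pair with the lowest cluster indices (in
#' order of creation) wins.  Average linkage (UPGMA) is the default.
#' The result is `hclust`-compatible (`$merge`, `$height`, `$order`,
#' `$labels`), so [stats::cutree()] and `plot()` work on it directly.
#'
#' @param d square symmetric distance matrix with dimnames, e.g. from
#'   [assemblage_distance()].
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return an object of class `c("assemblage_tree", "hclust")`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (n < 2) stop("need at least 2 leaves")
  labels <- rownames(d) %||% as.character(seq_len(n))

  # active clusters indexed 1..(2n-1): 1..n leaves, n+k the k-th merge
  size <- c(rep(1L, n), rep(NA_integer_, n - 1L))
  code <- c(-seq_len(n), rep(NA_integer_, n - 1L)) # hclust merge coding
  D <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
  D[1:n, 1:n] <- d
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (k in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < best_d) { # strict: ties keep lowest-index pair
          best_d <- D[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    new <- n + k
    merge[k, ] <- order_merge_pair(code[i], code[j])
    height[k] <- best_d
    size[new] <- size[i] + size[j]
    code[new] <- k
    others <- setdiff(active, c(i, j))
    for (o in others) {
      D[new, o] <- D[o, new] <- switch(linkage,
        average = (size[i] * D[i, o] + size[j] * D[j, o]) / size[new],
        single = min(D[i, o], D[j, o]),
        complete = max(D[i, o], D[j, o]))
    }
    active <- c(others, new)
  }

  tree <- structure(list(merge = merge, height = height,
                         order = tree_leaf_order(merge),
                         labels = labels, method = linkage,
                         dist.method = "assemblage",
                         call = match.call()),
                    class = c("assemblage_tree", "hclust"))
  tree
}

# hclust's merge-row convention: singletons (negative) before clusters,
# each kind in ascending absolute order
order_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(max(a, b), min(a, b))
  else if (a < 0 || b < 0) c(min(a, b), max(a, b))
  else c(min(a, b), max(a, b))
}

# depth-first leaf order for plotting / diagram layout
tree_leaf_order <- function(merge) {
  walk <- function(row) {
    unlist(lapply(merge[row, ], function(x)
      if (x < 0) -x else walk(x)))
  }
  walk(nrow(merge))
}

#' Cluster membership at a distance threshold
#'
#' Cuts the tree at `threshold` and returns the group id of every leaf
#' (singletons included).
#'
#' @param tree an [hierarchical_cluster()] result.
#' @param threshold cut height in metric units.
#' @return named integer vector of group ids.
#' @export
assemblage_membership <- function(tree, threshold) {
  stats::cutree(tree, h = threshold)
}

#' Highly similar assemblage groups
#'
#' Groups of two or more coprolites whose assemblages merge below the
#' distance threshold — the "nearly identical assemblages" read off a
#' coloured dendrogram.  With the uncentred-correlation metric the default
#' threshold 0.1 corresponds to correlation >= 0.9.
#'
#' @param tree an [hierarchical_cluster()] result.
#' @param threshold cut height (default 0.1).
#' @return named list of character vectors (group members), possibly empty.
#' @export
similar_groups <- function(tree, threshold = 0.1) {
  mem <- assemblage_membership(tree, threshold)
  grp <- split(names(mem), mem)
  grp <- grp[lengths(grp) >= 2]
  if (length(grp)) names(grp) <- paste0("G", seq_along(grp))
  grp
}

#' Write a cluster tree as Newick
#'
#' Exports the dendrogram with branch lengths derived from merge heights.
#'
#' @param tree an [hierarchical_cluster()] result.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}
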