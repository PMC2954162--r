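# Correlation-distance complete-linkage clustering with deterministic
# tie-breaking, tree cutting, 2D (gene x sample) ordering and
# Newick / Cluster-3.0 (CDT/GTR/ATR) export.

#' Correlation distance between two profiles
#'
#' `1 - r`, with `r` the centered Pearson correlation (default) or the
#' uncentered cosine correlation. Range 0 to 2.
#'
#' @param x,y Numeric profiles of equal length, at least 3.
#' @param centered Use centered correlation (`FALSE` = uncentered).
#' @return Distance in `[0, 2]`.
#' @export
correlation_distance <- function(x, y, centered = TRUE) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("profiles must have equal length >= 3")
  }
  if (centered) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero-variance profile: correlation distance undefined")
    }
    1 - stats::cor(x, y)
  } else {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) stop("zero profile: uncentered correlation undefined")
    1 - sum(x * y) / (nx * ny)
  }
}

#' Correlation distance matrix between matrix rows
#'
#' @param m Numeric matrix; rows are the items being clustered.
#' @param centered See [correlation_distance()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_dist_matrix <- function(m, centered = TRUE) {
  if (ncol(m) < 3L) stop("profiles must have length >= 3")
  if (centered) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance profile(s): ",
           paste(utils::head(rownames(m)[sds == 0], 5L), collapse = ", "))
    }
    d <- 1 - stats::cor(t(m))
  } else {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("zero profile(s)")
    d <- 1 - (m %*% t(m)) / tcrossprod(nrm)
  }
  d[d < 0] <- 0  # guard tiny negative rounding at r ~ 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Agglomerative complete-linkage clustering
#'
#' Standard agglomerative clustering with complete (maximum) linkage and
#' deterministic tie-breaking: among pairs at the minimal distance, the
#' pair containing the smallest leaf label is merged (then the smallest
#' partner label; unlabeled input falls back to leaf indices). Breaking
#' ties on labels rather than positions makes the result invariant, up
#' to relabeling, under input permutations. Merge heights are
#' non-decreasing. Leaves are ordered recursively with the tighter
#' (lower-height) subtree first, ties by smallest contained label.
#'
#' @param dist Symmetric distance matrix with zero diagonal (or a `dist`
#'   object).
#' @return An object of class `hclust` (method `"complete"`); a
#'   single-leaf input yields a degenerate tree with no merges.
#' @export
complete_linkage <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 1L) stop("empty distance matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0L, 2L),
                          height = numeric(0), order = 1L,
                          labels = labels, method = "complete",
                          call = match.call(), dist.method = "user"),
                     class = "hclust"))
  }
  code <- -seq_len(n)               # hclust merge coding: -leaf or step no.
  min_key <- labels                 # smallest leaf label in each cluster
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(code)
    Dm <- D
    Dm[!upper.tri(Dm)] <- Inf
    mmin <- min(Dm)
    cand <- which(Dm == mmin, arr.ind = TRUE)
    # tie-break: pair containing the smallest leaf label, then smallest
    # partner label
    pl <- pmin(min_key[cand[, 1L]], min_key[cand[, 2L]])
    ph <- pmax(min_key[cand[, 1L]], min_key[cand[, 2L]])
    pick <- order(pl, ph)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- D[i, j]
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    code[i] <- step
    min_key[i] <- min(min_key[i], min_key[j])
    keep <- setdiff(seq_len(k), j)
    D <- D[keep, keep, drop = FALSE]
    code <- code[keep]; min_key <- min_key[keep]
  }
  h <- structure(list(merge = merge, height = height,
                      order = integer(n), labels = labels,
                      method = "complete", call = match.call(),
                      dist.method = "user"),
                 class = "hclust")
  h$order <- .leaf_order(h)
  h
}

# recursive leaf ordering: tighter (lower merge height) subtree first.
# Height ties are broken by the smallest contained leaf label (so the
# ordering is invariant under input permutations), falling back to the
# leaf index when labels are absent.
.leaf_order <- function(h) {
  n <- nrow(h$merge) + 1L
  keys <- if (is.null(h$labels)) as.character(seq_len(n)) else h$labels
  node_height <- function(code) if (code < 0L) 0 else h$height[code]
  node_minkey <- function(code) {
    if (code < 0L) return(keys[-code])
    min(node_minkey(h$merge[code, 1L]), node_minkey(h$merge[code, 2L]))
  }
  walk <- function(code) {
    if (code < 0L) return(-code)
    a <- h$merge[code, 1L]; b <- h$merge[code, 2L]
    ha <- node_height(a); hb <- node_height(b)
    first_a <- ha < hb || (ha == hb && node_minkey(a) < node_minkey(b))
    if (first_a) c(walk(a), walk(b)) else c(walk(b), walk(a))
  }
  walk(n - 1L)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges.
#'
#' @param h An `hclust` tree (e.g. from [complete_linkage()]).
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer cluster labels.
#' @export
cut_tree <- function(h, k) {
  n <- nrow(h$merge) + 1L
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves")
  if (n == 1L) return(stats::setNames(1L, h$labels))
  stats::cutree(h, k = k)
}

#' Two-dimensional correlation clustering of an expression matrix
#'
#' Clusters rows and columns independently with correlation distance and
#' complete linkage, and returns the reordered matrix together with both
#' dendrograms. Results are invariant (up to relabeling) under input
#' row/column permutations.
#'
#' @param values Numeric matrix (e.g. log2 ratios: probes x samples).
#' @param centered See [correlation_distance()].
#' @return List of class `two_d_clust`: `ordered` (reordered matrix),
#'   `row_tree`, `col_tree`.
#' @export
two_d_cluster <- function(values, centered = TRUE) {
  if (!is.matrix(values) || !all(is.finite(values))) {
    stop("values must be a finite numeric matrix")
  }
  row_tree <- complete_linkage(correlation_dist_matrix(values, centered))
  col_tree <- complete_linkage(correlation_dist_matrix(t(values), centered))
  structure(list(ordered = values[row_tree$order, col_tree$order,
                                  drop = FALSE],
                 row_tree = row_tree, col_tree = col_tree),
            class = "two_d_clust")
}

#' @export
print.two_d_clust <- function(x, ...) {
  cat(sprintf("2D clustering: %d rows x %d columns (complete-link correlation)\n",
              nrow(x$ordered), ncol(x$ordered)))
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' Branch lengths follow merge heights (ultrametric).
#'
#' @param h An `hclust` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Export a 2D clustering in Cluster 3.0 format (CDT/GTR/ATR)
#'
#' Writes `<basename>.cdt` (reordered matrix), `<basename>.gtr` (row
#' tree) and `<basename>.atr` (column tree) readable by heat-map viewers
#' of the TreeView family. Node scores are `1 - height/2` so perfectly
#' correlated merges score 1.
#'
#' @param x A `two_d_clust` object.
#' @param basename Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_cdt <- function(x, basename) {
  stopifnot(inherits(x, "two_d_clust"))
  gtr <- paste0(basename, ".gtr"); atr <- paste0(basename, ".atr")
  cdt <- paste0(basename, ".cdt")
  .write_tree_file <- function(h, path, prefix) {
    n <- nrow(h$merge) + 1L
    code_name <- function(code, step) {
      if (code < 0L) sprintf("%s%dX", prefix, -code)
      else sprintf("NODE%dX", code)
    }
    lines <- vapply(seq_len(nrow(h$merge)), function(s) {
      paste(sprintf("NODE%dX", s),
            code_name(h$merge[s, 1L]), code_name(h$merge[s, 2L]),
            format(1 - h$height[s] / 2, digits = 6), sep = "\t")
    }, "")
    writeLines(lines, path)
  }
  .write_tree_file(x$row_tree, gtr, "GENE")
  .write_tree_file(x$col_tree, atr, "ARRY")
  m <- x$ordered
  rid <- sprintf("GENE%dX", x$row_tree$order)
  aid <- sprintf("ARRY%dX", x$col_tree$order)
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)),
                  collapse = "\t")
  aidline <- paste(c("AID", "", "", "", aid), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                   collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rid[i], rownames(m)[i], rownames(m)[i], "1",
            format(m[i, ], digits = 6)), collapse = "\t")
  }, "")
  writeLines(c(header, aidline, eweight, body), cdt)
  invisible(c(cdt, gtr, atr))
}
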