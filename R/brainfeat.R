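#' Fisher z-transform of correlations
#'
#' @param r correlations with |r| < 1.
#' @return `atanh(r)`, elementwise.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1")
  atanh(r)
}

#' Binarize a connectivity matrix at a proportional cost
#'
#' Retains the `round(cost * n(n-1)/2)` strongest strictly positive
#' upper-triangle entries (all positives if fewer are available); negative
#' and zero weights are never retained. Rounding is half-away-from-zero.
#' Ties at the retention boundary are broken deterministically: higher
#' weight first, then smaller node-pair index in the column-major
#' upper-triangle enumeration.
#'
#' @param M symmetric matrix with finite off-diagonal entries.
#' @param cost fraction of possible edges to retain, in (0, 1].
#' @return a symmetric 0/1 adjacency matrix of class `"binary_graph"` with
#'   attribute `n_edges`. Warns and returns an empty graph when the matrix
#'   has no positive off-diagonal entries.
#' @export
proportional_threshold <- function(M, cost) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
    stop("`M` must be symmetric")
  if (cost <= 0 || cost > 1) stop("`cost` must be in (0, 1]")
  n <- nrow(M)
  ut <- which(upper.tri(M))
  w <- M[ut]
  if (any(!is.finite(w))) stop("off-diagonal entries must be finite")
  k <- floor(cost * n * (n - 1) / 2 + 0.5)
  pos <- which(w > 0)
  if (length(pos) == 0) {
    warning("no positive connections: returning an empty graph")
    keep <- integer(0)
  } else {
    ord <- pos[order(-w[pos], pos)]
    keep <- ord[seq_len(min(k, length(ord)))]
  }
  A <- matrix(0L, n, n, dimnames = dimnames(M))
  A[ut[keep]] <- 1L
  A <- A + t(A)
  structure(A, n_edges = length(keep), class = c("binary_graph", class(A)))
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(unclass(A) > 0, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal global efficiency
#'
#' For each node, the mean over all other nodes of the inverse unweighted
#' shortest-path distance (unreachable pairs contribute 0). Always in
#' \[0, 1\]; 1 on a complete graph, 0 for an isolated node.
#'
#' @param A binary adjacency matrix (e.g. from [proportional_threshold()]).
#' @param v optional node index/indices; default all nodes.
#' @return numeric vector of efficiencies.
#' @export
nodal_global_efficiency <- function(A, v = NULL) {
  n <- nrow(A)
  v <- v %||% seq_len(n)
  if (n < 2) return(rep(0, length(v)))
  g <- as_igraph(A)
  d <- igraph::distances(g, v = v, algorithm = "unweighted")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0 # unreachable and self
  rowSums(inv) / (n - 1)
}

#' Nodal local efficiency
#'
#' The global efficiency of the subgraph induced by a node's neighbors
#' (distances measured inside that subgraph, not through the full graph);
#' 0 for nodes with fewer than two neighbors.
#'
#' @inheritParams nodal_global_efficiency
#' @return numeric vector of local efficiencies in \[0, 1\].
#' @export
nodal_local_efficiency <- function(A, v = NULL) {
  n <- nrow(A)
  v <- v %||% seq_len(n)
  vapply(v, function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- unclass(A)[nb, nb, drop = FALSE]
    mean(nodal_global_efficiency(sub))
  }, numeric(1))
}

#' Average nodal values within atlas regions
#'
#' @param values numeric vector, one value per node.
#' @param map region label per node (every node must be mapped).
#' @return named vector of per-region arithmetic means, one per region in
#'   first-appearance order.
#' @export
aggregate_nodal <- function(values, map) {
  if (length(values) != length(map)) stop("`values` and `map` lengths differ")
  if (anyNA(map)) stop("every node must be mapped to a region")
  f <- factor(map, levels = unique(map))
  v <- tapply(values, f, mean)
  stats::setNames(as.vector(v), names(v))
}

#' Within- and between-network connectivity features
#'
#' Fisher z-transforms the parcel correlation matrix and averages its
#' entries within each network's diagonal block (upper triangle) and within
#' each off-diagonal network pair, giving K within + K(K-1)/2 between
#' features (78 for K = 12). A network with a single parcel has no within
#' pairs; its within feature is `NA` with a warning.
#'
#' @param M symmetric parcel correlation matrix (|off-diagonal| < 1).
#' @param map network label per parcel.
#' @param fisher apply the Fisher z-transform first (default TRUE).
#' @return named vector of `within_<k>` and `between_<k>_<l>` features.
#' @export
network_block_features <- function(M, map, fisher = TRUE) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), length(map) == nrow(M))
  if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
    stop("`M` must be symmetric")
  nets <- unique(map)
  K <- length(nets)
  Z <- M
  off <- row(M) != col(M)
  if (fisher) Z[off] <- fisher_z(M[off])
  out <- numeric(0)
  for (a in seq_len(K)) {
    ia <- which(map == nets[a])
    blk <- Z[ia, ia, drop = FALSE]
    if (length(ia) < 2) {
      warning("network `", nets[a], "` has a single parcel; within value NA")
      val <- NA_real_
    } else val <- mean(blk[upper.tri(blk)])
    out[paste0("within_", nets[a])] <- val
  }
  if (K > 1) for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ia <- which(map == nets[a])
    ib <- which(map == nets[b])
    out[paste0("between_", nets[a], "_", nets[b])] <- mean(Z[ia, ib])
  }
  out
}

#' Per-site Cohen's d of an activation field
#'
#' One-sample effect size against zero at every site: across-subject mean
#' divided by across-subject SD (n - 1 denominator). Sites with zero SD are
#' undefined (`NA`) and excluded from clustering.
#'
#' @param fields subjects x sites matrix of activation values.
#' @return numeric vector of per-site d values.
#' @examples
#' cohen_d_field(rbind(c(2, 1), c(4, 1))) # 2.1213, NA
#' @export
cohen_d_field <- function(fields) {
  stopifnot(is.matrix(fields), nrow(fields) >= 2)
  m <- colMeans(fields)
  s <- apply(fields, 2, sd)
  d <- m / s
  d[s == 0] <- NA_real_
  d
}

#' 4-connected lattice adjacency
#'
#' @param nr,nc grid dimensions (sites enumerated column-major).
#' @return symmetric 0/1 adjacency matrix over the `nr * nc` sites.
#' @export
grid_adjacency <- function(nr, nc) {
  n <- nr * nc
  A <- matrix(0L, n, n)
  idx <- function(r, c) (c - 1) * nr + r
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (r < nr) A[idx(r, c), idx(r + 1, c)] <- 1L
    if (c < nc) A[idx(r, c), idx(r, c + 1)] <- 1L
  }
  A + t(A)
}

#' Clusters of large effect sizes and per-subject cluster means
#'
#' Thresholds the per-site effect-size map at `threshold` (strictly
#' greater), finds connected components of the suprathreshold sites under
#' the given adjacency, and, when subject fields are supplied, extracts each
#' subject's mean value over every cluster. Zero suprathreshold sites give a
#' valid empty result.
#'
#' @param d per-site effect sizes (NA sites are excluded).
#' @param adjacency symmetric site adjacency matrix.
#' @param threshold effect-size cutoff, default 0.8.
#' @param fields optional subjects x sites matrix to extract cluster means
#'   from.
#' @return list with `clusters` (list of site-index vectors, ordered by
#'   smallest member) and `features` (subjects x clusters matrix, or NULL).
#' @export
find_clusters <- function(d, adjacency, threshold = 0.8, fields = NULL) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency),
            length(d) == nrow(adjacency))
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("`adjacency` must be symmetric")
  supra <- which(!is.na(d) & d > threshold)
  if (length(supra) == 0)
    return(list(clusters = list(), features = NULL))
  sub <- adjacency[supra, supra, drop = FALSE]
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    sub > 0, mode = "undirected", diag = FALSE))
  clusters <- split(supra, comp$membership)
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  names(clusters) <- paste0("cluster_", seq_along(clusters))
  features <- NULL
  if (!is.null(fields)) {
    stopifnot(ncol(fields) == length(d))
    features <- vapply(clusters, function(cl)
      rowMeans(fields[, cl, drop = FALSE]), numeric(nrow(fields)))
    features <- matrix(features, nrow = nrow(fields),
                       dimnames = list(NULL, names(clusters)))
  }
  list(clusters = clusters, features = features)
}

#' Nodal efficiency features aggregated to atlas regions
#'
#' The resting-state efficiency feature set: each subject's connectivity
#' matrix is Fisher z-transformed, binarized at a proportional cost, nodal
#' global and local efficiency are computed for every node, and both
#' measures are averaged within atlas regions. By default each measure
#' contributes one feature per region (`geff_<region>`, `leff_<region>`);
#' `combine = TRUE` instead averages the two measures into a single
#' per-region feature (`eff_<region>`).
#'
#' @param stack a [generate_connectomes()] stack (or list of symmetric
#'   matrices).
#' @param node_region_map region label per node; default one region per
#'   node.
#' @param cost proportional threshold, default 0.15.
#' @param combine average global and local efficiency into one feature per
#'   region.
#' @return subjects x features numeric matrix.
#' @export
efficiency_features <- function(stack, node_region_map = NULL, cost = 0.15,
                                combine = FALSE) {
  mats <- if (inherits(stack, "connectome_stack")) stack$matrices else stack
  n_nodes <- nrow(mats[[1]])
  node_region_map <- node_region_map %||% seq_len(n_nodes)
  rows <- lapply(mats, function(M) {
    off <- row(M) != col(M)
    Z <- M
    Z[off] <- fisher_z(pmin(pmax(M[off], -0.999999), 0.999999))
    A <- proportional_threshold(Z, cost)
    ge <- aggregate_nodal(nodal_global_efficiency(A), node_region_map)
    le <- aggregate_nodal(nodal_local_efficiency(A), node_region_map)
    if (combine) {
      stats::setNames((ge + le) / 2, paste0("eff_", names(ge)))
    } else {
      c(stats::setNames(ge, paste0("geff_", names(ge))),
        stats::setNames(le, paste0("leff_", names(le))))
    }
  })
  do.call(rbind, rows)
}
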