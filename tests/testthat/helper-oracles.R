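# Independent oracles, written against the documented contracts only (no
# reuse of package internals), used to cross-check the fast implementations.

# --- tree / ensemble oracles -----------------------------------------------

# Conditional expectation of one tree given known-feature set S (1-based ids),
# re-implemented from scratch with explicit stack-free recursion.
oracle_tree_value <- function(tree, x, S) {
  walk <- function(node) {
    f <- tree$feature[node] + 1L
    if (f <= 0L) return(tree$value[node])
    l <- tree$left[node] + 1L
    r <- tree$right[node] + 1L
    if (f %in% S) {
      xv <- x[f]
      go_left <- if (is.na(xv)) tree$default_left[node] == 1L
                 else xv < tree$threshold[node]
      if (go_left) walk(l) else walk(r)
    } else {
      (tree$cover[l] * walk(l) + tree$cover[r] * walk(r)) /
        (tree$cover[l] + tree$cover[r])
    }
  }
  walk(1L)
}

oracle_margin <- function(model, x) {
  model$base_score + sum(vapply(model$trees, function(tr)
    oracle_tree_value(tr, x, seq_along(model$feature_names)), numeric(1)))
}

# Shapley values by enumerating coalitions over the UNION of all features
# used anywhere in the ensemble (not per tree).
oracle_shapley_union <- function(model, x) {
  p <- length(model$feature_names)
  used <- sort(unique(unlist(lapply(model$trees, function(tr)
    tr$feature[tr$feature >= 0] + 1L))))
  m <- length(used)
  stopifnot(m <= 12)
  v_of <- function(S) sum(vapply(model$trees, function(tr)
    oracle_tree_value(tr, x, S), numeric(1)))
  v <- vapply(0:(2^m - 1), function(mask)
    v_of(used[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]), numeric(1))
  phi <- numeric(p)
  for (ji in seq_along(used)) {
    bit <- 2^(ji - 1)
    for (mask in 0:(2^m - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      w <- factorial(s) * factorial(m - s - 1) / factorial(m)
      phi[used[ji]] <- phi[used[ji]] + w * (v[mask + bit + 1] - v[mask + 1])
    }
  }
  names(phi) <- model$feature_names
  phi
}

# Random tree with consistent covers, for attribution tests that should not
# depend on the fitting path.
random_tree <- function(p, depth, rng_cover = c(0.5, 4)) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = -1L, threshold = 0,
                                         default_left = 1L, left = -1L,
                                         right = -1L, cover = 0, value = 0)
    length(nodes)
  }
  grow <- function(node, d, cover) {
    nodes[[node]]$cover <<- cover
    if (d == 0 || runif(1) < 0.25) {
      nodes[[node]]$value <<- rnorm(1)
      return(invisible())
    }
    nodes[[node]]$feature <<- sample.int(p, 1) - 1L
    nodes[[node]]$threshold <<- rnorm(1)
    nodes[[node]]$default_left <<- sample(0:1, 1)
    frac <- runif(1, 0.2, 0.8)
    l <- new_node()
    r <- new_node()
    nodes[[node]]$left <<- l - 1L
    nodes[[node]]$right <<- r - 1L
    grow(l, d - 1, cover * frac)
    grow(r, d - 1, cover * (1 - frac))
  }
  root <- new_node()
  grow(root, depth, runif(1, rng_cover[1], rng_cover[2]) * 2^depth)
  list(feature = vapply(nodes, `[[`, integer(1), "feature"),
       threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
       default_left = vapply(nodes, `[[`, integer(1), "default_left"),
       left = vapply(nodes, `[[`, integer(1), "left"),
       right = vapply(nodes, `[[`, integer(1), "right"),
       cover = vapply(nodes, `[[`, numeric(1), "cover"),
       value = vapply(nodes, `[[`, numeric(1), "value"))
}

random_ensemble <- function(p = 5, n_trees = 4, depth = 3, base = NULL) {
  structure(list(
    trees = replicate(n_trees, random_tree(p, depth), simplify = FALSE),
    base_score = if (is.null(base)) rnorm(1) else base,
    feature_names = paste0("f", seq_len(p)),
    params = list(), best_iteration = n_trees, n_rounds_run = n_trees,
    evaluation_log = data.frame(), y = NULL), class = "gbt")
}

random_instances <- function(n, p, na_frac = 0.15) {
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  x[runif(n * p) < na_frac] <- NA
  x
}

# The depth-2 AND tree: output 1 iff x1 > 0 and x2 > 0, equal quarter covers.
and_tree_model <- function() {
  tr <- list(feature = c(0L, -1L, 1L, -1L, -1L),
             threshold = c(0, 0, 0, 0, 0),
             default_left = c(1L, 1L, 1L, 1L, 1L),
             left = c(1L, -1L, 3L, -1L, -1L),
             right = c(2L, -1L, 4L, -1L, -1L),
             cover = c(4, 2, 2, 1, 1),
             value = c(0, 0, 0, 0, 1))
  structure(list(trees = list(tr), base_score = 0,
                 feature_names = c("x1", "x2"), params = list(),
                 best_iteration = 1L, n_rounds_run = 1L,
                 evaluation_log = data.frame(), y = NULL), class = "gbt")
}

# --- graph oracles ----------------------------------------------------------

# All-pairs shortest paths by Floyd-Warshall, then nodal global efficiency.
oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  if (n < 2) return(rep(0, n))
  rowSums(inv) / (n - 1)
}

random_graph <- function(n, p_edge = 0.4) {
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.integer(runif(sum(ut)) < p_edge)
  A + t(A)
}

# --- statistics oracle ------------------------------------------------------

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
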