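#' Path-dependent conditional expectation of a single tree
#'
#' Evaluates the tree's expected output when only the features in `S` are
#' known: at a node splitting on a known feature the instance's routing is
#' followed (missing values take the node's default direction); at a node
#' splitting on an unknown feature the cover-weighted average of the two
#' children is returned. This is the coalition value underlying all Shapley
#' computations in the package.
#'
#' @param tree a single tree (an element of a [gbt()] model's `trees` list).
#' @param x named numeric vector (or single-row matrix) with the instance's
#'   feature values, indexed like the model's feature registry.
#' @param S integer vector of 1-based feature indices treated as known.
#' @return the conditional expectation of the tree's output.
#' @export
tree_conditional_expectation <- function(tree, x, S) {
  x <- as.numeric(x)
  rec <- function(node) {
    f <- tree$feature[node] + 1L
    if (f <= 0L) return(tree$value[node])
    l <- tree$left[node] + 1L
    r <- tree$right[node] + 1L
    if (f %in% S) {
      v <- x[f]
      if (is.na(v)) {
        if (tree$default_left[node] == 1L) rec(l) else rec(r)
      } else if (v < tree$threshold[node]) rec(l) else rec(r)
    } else {
      cl <- tree$cover[l]
      cr <- tree$cover[r]
      if (cl + cr <= 0) stop("zero cover at an internal node: invalid model")
      (cl * rec(l) + cr * rec(r)) / (cl + cr)
    }
  }
  rec(1L)
}

tree_used_features <- function(tree) sort(unique(tree$feature[tree$feature >= 0] + 1L))

tree_mean_value <- function(tree) tree_conditional_expectation(tree, numeric(0), integer(0))

#' Base value of a tree ensemble
#'
#' The expected margin with no feature known: the base score plus each
#' tree's cover-weighted mean leaf value.
#' @param model a [gbt()] model.
#' @return scalar base value on the margin scale.
#' @export
shapley_base_value <- function(model) {
  model$base_score + sum(vapply(model$trees, tree_mean_value, numeric(1)))
}

#' Exact Shapley attributions by subset enumeration
#'
#' Computes, per tree, the Shapley value of every feature the tree splits on
#' via the exact weighted sum over feature subsets
#' \eqn{\sum_S |S|!(m-|S|-1)!/m!\,[v(S\cup\{j\}) - v(S)]}, then sums over
#' trees (features unused by a tree receive zero from it). Intended as the
#' reference implementation: the enumeration is limited to trees using at
#' most `guard` distinct features; use [shapley_fast()] beyond that.
#'
#' @param model a [gbt()] model.
#' @param x a single instance (named vector or one-row matrix).
#' @param guard maximum number of distinct features per tree.
#' @return list with `phi` (named attribution vector) and `phi0` (base
#'   value); `phi0 + sum(phi)` equals the model margin at `x`.
#' @export
shapley_exact <- function(model, x, guard = 20L) {
  x <- instance_vector(model, x)
  p <- length(model$feature_names)
  phi <- stats::setNames(numeric(p), model$feature_names)
  for (tree in model$trees) {
    used <- tree_used_features(tree)
    m <- length(used)
    if (m == 0L) next
    if (m > guard)
      stop("tree uses more than `guard` distinct features; use shapley_fast()")
    v <- vapply(0:(2^m - 1), function(mask)
      tree_conditional_expectation(tree, x, used[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]),
      numeric(1))
    for (ji in seq_len(m)) {
      j <- used[ji]
      bit <- 2^(ji - 1)
      for (mask in 0:(2^m - 1)) {
        if (bitwAnd(mask, bit) > 0) next
        s <- sum(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
        w <- factorial(s) * factorial(m - s - 1) / factorial(m)
        phi[j] <- phi[j] + w * (v[mask + bit + 1] - v[mask + 1])
      }
    }
  }
  list(phi = phi, phi0 = shapley_base_value(model))
}

#' Fast Shapley attributions for tree ensembles
#'
#' Polynomial-time path-dependent Shapley attribution (the tree-traversal
#' algorithm keeping a weighted path of the features encountered), agreeing
#' with [shapley_exact()] to numerical precision but with cost linear in
#' the number of leaves rather than exponential in the number of features.
#'
#' @param model a [gbt()] model.
#' @param newdata feature matrix of instances to explain.
#' @return object of class `"gbt_shap"`: list with `phi` (n x p matrix of
#'   margin-scale attributions), `phi0` (base value), and `feature_names`.
#'   For every row, `phi0 + sum(phi[i, ])` equals the model margin.
#' @export
shapley_fast <- function(model, newdata) {
  x <- as_feature_matrix(newdata, template = model$feature_names)
  phi <- cpp_tree_shap(model$trees, x, length(model$feature_names), 0L, -1L)
  colnames(phi) <- model$feature_names
  structure(list(phi = phi, phi0 = shapley_base_value(model),
                 feature_names = model$feature_names),
            class = "gbt_shap")
}

#' @export
print.gbt_shap <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d instances x %d features (base value %.4f)\n",
              nrow(x$phi), ncol(x$phi), x$phi0))
  imp <- sort(colMeans(abs(x$phi)), decreasing = TRUE)
  cat("  top mean |phi|:\n")
  for (nm in names(utils::head(imp, 5)))
    cat(sprintf("    %-24s %.4f\n", nm, imp[[nm]]))
  invisible(x)
}

#' Pairwise Shapley interaction values
#'
#' Decomposes each instance's attribution vector into main and pairwise
#' interaction terms. The off-diagonal entry for features \eqn{(i, j)} is
#' the Shapley interaction index
#' \eqn{\Phi_{ij} = \sum_{S \subseteq M\setminus\{i,j\}}
#' \frac{|S|!\,(m-|S|-2)!}{(m-1)!}\,\Delta_{ij}(S)} with
#' \eqn{\Delta_{ij}(S) = v(S\cup\{i,j\}) - v(S\cup\{i\}) - v(S\cup\{j\}) +
#' v(S)}; it is stored symmetrically at `(i, j)` and `(j, i)`, so the pair's
#' total interaction attribution reported to users is the sum of the two
#' entries. The diagonal holds the main effect
#' \eqn{\Phi_{ii} = \phi_i - \sum_{j \ne i} \Phi_{ij}}, so every row sums to
#' the feature's Shapley value.
#'
#' The fast path computes \eqn{\Phi_{ij}} as the difference between feature
#' j's attributions in the games where feature i is always known and always
#' unknown, needing only two conditioned traversals per requested partner.
#'
#' @param model a [gbt()] model.
#' @param newdata feature matrix of instances.
#' @param partner a single feature (name or index) for which all pairs
#'   `(partner, j)` are computed, or `"all"` for the full interaction
#'   tensor.
#' @param method `"fast"` (conditioned traversals) or `"exact"` (subset
#'   enumeration, small trees only).
#' @return object of class `"gbt_interactions"`: for `partner = "all"` an
#'   n x p x p array `Phi`; otherwise a list with the n x p matrix
#'   `partner_row` of entries \eqn{\Phi_{sj}} (the stored symmetric half;
#'   multiply by 2 for the pair total), the partner's diagonal main effect,
#'   and the attribution set used.
#' @export
shapley_interactions <- function(model, newdata, partner = "all",
                                 method = c("fast", "exact")) {
  method <- match.arg(method)
  x <- as_feature_matrix(newdata, template = model$feature_names)
  p <- length(model$feature_names)
  attr_set <- shapley_fast(model, x)
  if (identical(partner, "all")) {
    Phi <- array(0, dim = c(nrow(x), p, p),
                 dimnames = list(NULL, model$feature_names, model$feature_names))
    for (i in seq_len(p)) {
      row_i <- interaction_row(model, x, i, method)
      Phi[, i, ] <- row_i
    }
    # symmetrize (exact arithmetic already symmetric; guard rounding)
    if (p > 1) for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      s <- (Phi[, i, j] + Phi[, j, i]) / 2
      Phi[, i, j] <- s
      Phi[, j, i] <- s
    }
    for (i in seq_len(p)) {
      off <- matrix(Phi[, i, ], nrow = nrow(x), ncol = p)
      Phi[, i, i] <- attr_set$phi[, i] - (rowSums(off) - off[, i])
    }
    return(structure(list(Phi = Phi, attributions = attr_set,
                          feature_names = model$feature_names),
                     class = "gbt_interactions"))
  }
  s <- feature_index(model, partner)
  row_s <- interaction_row(model, x, s, method)
  row_s[, s] <- 0
  diag_s <- attr_set$phi[, s] - rowSums(row_s)
  structure(list(partner = model$feature_names[s],
                 partner_row = row_s, partner_main = diag_s,
                 attributions = attr_set,
                 feature_names = model$feature_names),
            class = "gbt_interactions")
}

feature_index <- function(model, f) {
  if (is.character(f)) {
    i <- match(f, model$feature_names)
    if (is.na(i)) stop("feature `", f, "` not in the model's registry")
    return(i)
  }
  i <- as.integer(f)
  stopifnot(i >= 1, i <= length(model$feature_names))
  i
}

# Phi(i, j) for all j != i (stored symmetric-half convention), one matrix row
# per instance.
interaction_row <- function(model, x, i, method) {
  p <- length(model$feature_names)
  if (method == "fast") {
    phi_in <- cpp_tree_shap(model$trees, x, p, 1L, i - 1L)
    phi_out <- cpp_tree_shap(model$trees, x, p, -1L, i - 1L)
    out <- phi_in - phi_out
    out[, i] <- 0
    colnames(out) <- model$feature_names
    return(out)
  }
  out <- matrix(0, nrow(x), p, dimnames = list(NULL, model$feature_names))
  for (r in seq_len(nrow(x)))
    out[r, ] <- exact_interaction_row(model, x[r, ], i)
  out
}

# Exact interaction row by per-tree subset enumeration.
exact_interaction_row <- function(model, x, i, guard = 20L) {
  p <- length(model$feature_names)
  out <- numeric(p)
  for (tree in model$trees) {
    used <- tree_used_features(tree)
    m <- length(used)
    if (m < 2L || !(i %in% used)) next
    if (m > guard) stop("tree too large for exact interactions")
    v <- vapply(0:(2^m - 1), function(mask)
      tree_conditional_expectation(tree, x, used[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]),
      numeric(1))
    ii <- match(i, used)
    for (jj in seq_len(m)) {
      if (jj == ii) next
      j <- used[jj]
      bi <- 2^(ii - 1)
      bj <- 2^(jj - 1)
      acc <- 0
      for (mask in 0:(2^m - 1)) {
        if (bitwAnd(mask, bi) > 0 || bitwAnd(mask, bj) > 0) next
        s <- sum(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
        w <- factorial(s) * factorial(m - s - 2) / factorial(m - 1)
        acc <- acc + w * (v[mask + bi + bj + 1] - v[mask + bi + 1] -
                            v[mask + bj + 1] + v[mask + 1])
      }
      out[j] <- out[j] + acc
    }
  }
  out
}

instance_vector <- function(model, x) {
  if (is.matrix(x) || is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as_feature_matrix(as.matrix(x), template = model$feature_names)[1, ]
  } else if (!is.null(names(x))) {
    x <- x[model$feature_names]
  }
  if (length(x) != length(model$feature_names))
    stop("instance length does not match the model's feature registry")
  as.numeric(x)
}

#' Dependence-plot data for a feature, optionally with main effects removed
#'
#' Extracts per-instance `(x_j, value)` pairs for plotting a feature's
#' attribution against its observed value, grouped by a partner feature
#' (typically sex). In `"full"` mode the value is the feature's Shapley
#' attribution; in `"interaction_only"` mode it is the pair's total
#' interaction attribution \eqn{\Phi_{js} + \Phi_{sj}}, i.e. the dependence
#' pattern with main effects removed.
#'
#' @param interactions a `"gbt_interactions"` object computed with the
#'   partner of interest.
#' @param newdata the feature matrix the interactions were computed on.
#' @param feature feature to plot (name or index).
#' @param mode `"full"` or `"interaction_only"`.
#' @return data frame with columns `x` (the feature's observed value),
#'   `value`, and `group` (the partner feature's observed value).
#' @export
dependence_data <- function(interactions, newdata, feature,
                            mode = c("full", "interaction_only")) {
  mode <- match.arg(mode)
  if (is.null(interactions$partner))
    stop("interactions must be computed for a single partner feature")
  fn <- interactions$feature_names
  j <- if (is.character(feature)) match(feature, fn) else as.integer(feature)
  if (is.na(j)) stop("feature `", feature, "` not in the registry")
  x <- as_feature_matrix(newdata)[, fn, drop = FALSE]
  s <- match(interactions$partner, fn)
  value <- if (mode == "full") interactions$attributions$phi[, j]
           else 2 * interactions$partner_row[, j]
  data.frame(x = x[, j], value = value, group = x[, s])
}
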