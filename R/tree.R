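# CART-style binary classification tree (the bagging base learner).
#
# Greedy recursive partitioning on axis-aligned thresholds, Gini impurity,
# no depth limit by default, minimum leaf size 2. Entirely deterministic
# given (X, y, params): ties between equally good splits go to the
# lowest-index feature, then the smallest threshold.

#' Decision-tree hyperparameters
#'
#' @param min_leaf Minimum samples in each child of a split (default 2).
#' @param max_depth Maximum tree depth (default unlimited).
#' @return A `tree_params` list.
#' @export
tree_params <- function(min_leaf = 2L, max_depth = Inf) {
  stopifnot(min_leaf >= 1)
  structure(list(min_leaf = as.integer(min_leaf), max_depth = max_depth),
            class = "tree_params")
}

# Best Gini split of rows `idx`; NULL when no impurity-reducing split exists.
best_split <- function(X, y, idx, min_leaf) {
  n <- length(idx)
  if (n < 2 * min_leaf) return(NULL)
  tot1 <- sum(y[idx])
  parent_gini <- 1 - (tot1 / n)^2 - ((n - tot1) / n)^2
  if (parent_gini <= 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]
    ys <- y[idx][o]
    k <- seq_len(n - 1)
    valid <- (xs[k] < xs[k + 1]) & (k >= min_leaf) & ((n - k) >= min_leaf)
    if (!any(valid)) next
    l1 <- cumsum(ys)[k]
    r1 <- tot1 - l1
    gl <- 1 - (l1 / k)^2 - ((k - l1) / k)^2
    gr <- 1 - (r1 / (n - k))^2 - ((n - k - r1) / (n - k))^2
    wg <- (k * gl + (n - k) * gr) / n
    wg[!valid] <- Inf
    kbest <- which.min(wg)
    if (wg[kbest] < parent_gini - 1e-12 &&
        (is.null(best) || wg[kbest] < best$score - 1e-12)) {
      best <- list(feature = j,
                   threshold = (xs[kbest] + xs[kbest + 1]) / 2,
                   score = wg[kbest],
                   left_rows = idx[o[seq_len(kbest)]],
                   right_rows = idx[o[(kbest + 1):n]])
    }
  }
  best
}

#' Fit a CART classification tree
#'
#' @param X Numeric feature matrix.
#' @param y Integer 0/1 labels. Single-class input yields a constant
#'   predictor.
#' @param params A [tree_params()] list.
#' @return A `cart_tree` object.
#' @export
fit_tree <- function(X, y, params = tree_params()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  nodes <- list()
  new_node <- function(idx, depth) {
    n1 <- sum(y[idx])
    n <- length(idx)
    node <- list(n = n, prob1 = n1 / n,
                 pred = if (n1 * 2 > n) 1L else 0L,
                 is_leaf = TRUE, feature = NA_integer_,
                 threshold = NA_real_, left = NA_integer_,
                 right = NA_integer_)
    id <- length(nodes) + 1L
    nodes[[id]] <<- node
    if (depth < params$max_depth) {
      sp <- best_split(X, y, idx, params$min_leaf)
      if (!is.null(sp)) {
        lid <- new_node(sp$left_rows, depth + 1L)
        rid <- new_node(sp$right_rows, depth + 1L)
        nodes[[id]]$is_leaf <<- FALSE
        nodes[[id]]$feature <<- sp$feature
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$left <<- lid
        nodes[[id]]$right <<- rid
      }
    }
    id
  }
  new_node(seq_along(y), 0L)
  structure(list(nodes = nodes, p = ncol(X), params = params),
            class = "cart_tree")
}

#' Predict with a CART tree
#'
#' @param object A `cart_tree`.
#' @param newdata Numeric matrix with the training feature width.
#' @param type `"class"` for 0/1 labels, `"prob"` for leaf class-1
#'   frequencies.
#' @param ... Unused.
#' @return Numeric/integer vector, one value per row.
#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("feature-width mismatch: model expects ", object$p,
         " columns, got ", ncol(newdata))
  }
  out <- numeric(nrow(newdata))
  recurse <- function(id, rows) {
    node <- object$nodes[[id]]
    if (node$is_leaf) {
      out[rows] <<- if (type == "class") node$pred else node$prob1
      return(invisible())
    }
    go_left <- newdata[rows, node$feature] <= node$threshold
    if (any(go_left)) recurse(node$left, rows[go_left])
    if (any(!go_left)) recurse(node$right, rows[!go_left])
  }
  if (nrow(newdata) > 0) recurse(1L, seq_len(nrow(newdata)))
  if (type == "class") as.integer(out) else out
}

# training depth-first node count (used in tests)
tree_size <- function(tree) length(tree$nodes)
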