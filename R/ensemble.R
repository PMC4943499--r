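# Bagging (bootstrap aggregating) over CART base learners.
#
# m bootstrap samples of size n' (default n) are drawn uniformly with
# replacement; one tree is fitted per sample; prediction is by majority
# vote, with the vote fraction for the positive class as the score. A tied
# vote (score exactly 0.5) is called negative (non-interface), the
# conservative choice for site calling.

#' Bagging configuration
#'
#' @param m Number of base learners (default 10).
#' @param n_prime Bootstrap sample size; `NULL` means the training-set size.
#' @param min_leaf,max_depth Base-learner parameters, see [tree_params()].
#' @param seed Integer seed controlling all bootstrap draws.
#' @return A `bagging_config` list.
#' @export
bagging_config <- function(m = 10L, n_prime = NULL, min_leaf = 2L,
                           max_depth = Inf, seed = 1L) {
  stopifnot(m >= 1, is.null(n_prime) || n_prime >= 1)
  structure(list(m = as.integer(m), n_prime = n_prime,
                 tree = tree_params(min_leaf, max_depth),
                 seed = as.integer(seed)),
            class = "bagging_config")
}

#' Draw one bootstrap sample of indices
#'
#' @param n Dataset size.
#' @param n_prime Sample size (default `n`).
#' @return Integer vector of `n_prime` indices in `1..n`, drawn i.i.d.
#'   uniformly with replacement from the current RNG state.
#' @export
bootstrap_sample <- function(n, n_prime = n) {
  stopifnot(n >= 1, n_prime >= 1)
  sample.int(n, n_prime, replace = TRUE)
}

#' Train a bagging ensemble
#'
#' @param X Numeric feature matrix.
#' @param y Integer 0/1 labels.
#' @param config A [bagging_config()].
#' @param .sample_fun Test hook: replacement for [bootstrap_sample()]
#'   (called as `f(n, n_prime)`).
#' @return A `bagging_model` with `config$m` fitted trees.
#' @export
train_bagging <- function(X, y, config = bagging_config(),
                          .sample_fun = bootstrap_sample) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) >= 1, nrow(X) == length(y))
  n <- nrow(X)
  n_prime <- if (is.null(config$n_prime)) n else config$n_prime
  learners <- vector("list", config$m)
  set.seed(config$seed)
  for (i in seq_len(config$m)) {
    idx <- .sample_fun(n, n_prime)
    learners[[i]] <- fit_tree(X[idx, , drop = FALSE], y[idx], config$tree)
  }
  structure(list(learners = learners, config = config, p = ncol(X)),
            class = "bagging_model")
}

#' Majority-vote prediction with vote-fraction scores
#'
#' @param model A `bagging_model`.
#' @param X Feature matrix with the training width.
#' @return List: `score` (fraction of learners voting class 1) and `label`
#'   (1 iff score > 0.5; a 0.5 tie is class 0).
#' @export
predict_vote <- function(model, X) {
  stopifnot(inherits(model, "bagging_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop("feature-width mismatch: model expects ", model$p,
         " columns, got ", ncol(X))
  }
  votes <- vapply(model$learners, function(t) predict(t, X, type = "class"),
                  integer(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  score <- rowMeans(votes)
  list(score = score, label = as.integer(score > 0.5))
}

#' @export
predict.bagging_model <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  pv <- predict_vote(object, newdata)
  if (type == "class") pv$label else pv$score
}

# Stratified fold assignment: samples are shuffled within class, classes
# concatenated, and folds dealt round-robin across the whole sequence, so
# total fold sizes differ by at most one (k = n gives leave-one-out) while
# each class stays near-evenly spread.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  ordered <- unlist(lapply(sort(unique(y)), function(cls) {
    idx <- which(y == cls)
    idx[sample.int(length(idx))]
  }))
  folds[ordered] <- rep_len(seq_len(k), length(y))
  folds
}

# Group-aware assignment: whole groups (e.g. chains) stay in one fold.
group_folds <- function(groups, k) {
  ug <- unique(groups)
  ug <- ug[sample.int(length(ug))]
  gf <- stats::setNames(rep_len(seq_len(k), length(ug)), ug)
  unname(gf[as.character(groups)])
}

#' k-fold cross-validation of the bagging ensemble
#'
#' Stratified folds by default; when `groups` is given (e.g. chain ids),
#' whole groups are kept in a single fold so windowed features cannot leak
#' across the split. Each sample is tested exactly once.
#'
#' @param X,y Dataset.
#' @param k Number of folds (default 5).
#' @param config A [bagging_config()].
#' @param seed Seed for the fold assignment.
#' @param groups Optional grouping vector aligned to rows.
#' @return List: `folds` (per-fold confusion, metrics, test indices, and a
#'   `single_class` flag), `pooled` (confusion + metrics over all samples),
#'   `scores` (out-of-fold vote fractions), `fold_id`.
#' @export
cross_validate <- function(X, y, k = 5L, config = bagging_config(),
                           seed = 1L, groups = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(n >= k)
  set.seed(seed)
  fold_id <- if (is.null(groups)) stratified_folds(y, k) else group_folds(groups, k)
  scores <- rep(NA_real_, n)
  preds <- rep(NA_integer_, n)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    if (length(test) == 0) next
    single_class <- length(unique(y[train])) < 2 || length(unique(y[test])) < 2
    model <- train_bagging(X[train, , drop = FALSE], y[train], config)
    pv <- predict_vote(model, X[test, , drop = FALSE])
    scores[test] <- pv$score
    preds[test] <- pv$label
    cc <- confusion(y[test], pv$label)
    folds[[f]] <- list(confusion = cc, metrics = classification_metrics(cc),
                       test = test, single_class = single_class)
  }
  pooled_cc <- confusion(y[!is.na(preds)], preds[!is.na(preds)])
  list(folds = folds, pooled = list(confusion = pooled_cc,
                                    metrics = classification_metrics(pooled_cc)),
       scores = scores, fold_id = fold_id)
}
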