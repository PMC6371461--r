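#' Fit the plant-count Random Forest
#'
#' Trains a Random Forest classifier that predicts the number of plants
#' (1-8) contained in a connected plant object from its six morphological
#' features. The labelled set is split into a training fraction and a
#' holdout fraction (stratified by class so rare counts appear in both);
#' the forest's own out-of-bag error is reported alongside holdout
#' accuracy. All randomness (split and forest) derives from `seed`.
#'
#' @param features data.frame of numeric feature columns, one row per
#'   labelled object (normally the six columns of [compute_features()]).
#' @param counts integer labels in 1..8, parallel to `features`.
#' @param n_trees number of trees (default 100; the out-of-bag error is
#'   essentially flat beyond ~75 trees on typical training sets).
#' @param train_fraction fraction used for training, in (0, 1)
#'   (default 0.8).
#' @param seed integer seed controlling the split and the forest.
#' @param mtry features tried per split (default 2, approximately the
#'   square root of the six features).
#' @return an object of class `count_model` with components `forest`,
#'   `feature_order`, `holdout_accuracy`, `oob_error`, `n_trees`,
#'   `train_fraction`, `seed`, `classes`, `n_train`, `n_holdout`.
#' @seealso [predict.count_model()], [variable_importance()],
#'   [confusion_matrix()]
#' @references Breiman, L. (2001) Random forests. Machine Learning 45,
#'   5-32.
#' @export
fit_count_model <- function(features, counts, n_trees = 100L,
                            train_fraction = 0.8, seed = 1L, mtry = 2L) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  counts <- as.integer(counts)
  if (nrow(features) != length(counts))
    stop("'features' and 'counts' lengths differ")
  if (nrow(features) < 10L)
    stop("need at least 10 labelled objects to fit a count model")
  if (any(counts < 1L | counts > 8L))
    stop("plant counts outside 1..8 are not supported; objects holding ",
         "more than 8 plants must be excluded or re-labelled upstream")
  if (length(unique(counts)) < 2L)
    stop("training data contain a single class; at least 2 distinct ",
         "counts are required")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("'train_fraction' must lie strictly between 0 and 1")
  if (n_trees < 1L) stop("'n_trees' must be at least 1")

  y <- factor(counts, levels = sort(unique(counts)))
  res <- with_seed(as.integer(seed), {
    # stratified split: sample train_fraction within each class
    idx_train <- unlist(lapply(split(seq_along(y), y), function(ix) {
      n_tr <- max(1L, round(length(ix) * train_fraction))
      if (n_tr >= length(ix)) n_tr <- length(ix) - 1L
      if (n_tr < 1L) n_tr <- 1L
      sample(ix, n_tr)
    }), use.names = FALSE)
    idx_hold <- setdiff(seq_along(y), idx_train)
    forest <- randomForest::randomForest(
      x = features[idx_train, , drop = FALSE], y = y[idx_train],
      ntree = n_trees, mtry = min(mtry, ncol(features)),
      importance = TRUE, keep.forest = TRUE)
    list(forest = forest, idx_train = idx_train, idx_hold = idx_hold)
  })
  model <- structure(list(
    forest = res$forest,
    feature_order = colnames(features),
    n_trees = as.integer(n_trees),
    train_fraction = train_fraction,
    seed = as.integer(seed),
    classes = as.integer(levels(y)),
    n_train = length(res$idx_train),
    n_holdout = length(res$idx_hold),
    holdout_accuracy = NA_real_,
    oob_error = unname(res$forest$err.rate[n_trees, "OOB"])
  ), class = "count_model")
  hold_pred <- predict(model, features[res$idx_hold, , drop = FALSE])
  model$holdout_accuracy <-
    mean(hold_pred == counts[res$idx_hold])
  model
}

#' Predict plant counts for new objects
#'
#' Majority vote over the forest's trees; a tied vote is resolved in
#' favour of the smaller count (conservative against the tendency to
#' overestimate mid-sized objects).
#'
#' @param object a fitted `count_model`.
#' @param newdata data.frame with the model's feature columns (extra
#'   columns are ignored; order is fixed by the model).
#' @param ... unused.
#' @return integer vector of predicted plant counts in 1..8.
#' @export
predict.count_model <- function(object, newdata, ...) {
  stopifnot(inherits(object, "count_model"))
  if (is.null(object$forest)) stop("count model has no trained forest")
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_order, colnames(newdata))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  newdata <- newdata[, object$feature_order, drop = FALSE]
  if (nrow(newdata) == 0L) return(integer())
  votes <- predict(object$forest, newdata, type = "vote", norm.votes = FALSE)
  vote_decision(votes, object$classes)
}

# classes are sorted ascending, so the first maximal column is the
# smallest tied count
vote_decision <- function(votes, classes) {
  stopifnot(ncol(votes) == length(classes), !is.unsorted(classes))
  classes[max.col(votes, ties.method = "first")]
}

#' @rdname predict.count_model
#' @param model a fitted `count_model`.
#' @param features data.frame of feature rows.
#' @export
predict_count <- function(model, features) predict(model, features)

#' Permutation variable importance
#'
#' Importance of each morphological feature as the mean increase in
#' out-of-bag classification error when that feature's values are
#' permuted, averaged over trees (raw, unscaled scores; larger means more
#' important). Scores are floored at zero.
#'
#' @param model a fitted `count_model`.
#' @return named numeric vector in the model's feature order.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "count_model"))
  if (is.null(model$forest)) stop("count model has no trained forest")
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  pmax(stats::setNames(imp[, 1], rownames(imp)), 0)
}

#' Confusion matrix of actual versus predicted counts
#'
#' @param model a fitted `count_model`.
#' @param features data.frame of feature rows for labelled objects.
#' @param counts their true plant counts (1..8).
#' @return list with `table` (square actual x predicted integer matrix
#'   over the union of observed classes) and `correct_rate`
#'   (trace / total).
#' @export
confusion_matrix <- function(model, features, counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("no labelled objects supplied")
  if (any(counts < 1L | counts > 8L))
    stop("plant counts outside 1..8 are not supported")
  pred <- predict(model, features)
  lev <- sort(union(counts, pred))
  tab <- table(actual = factor(counts, levels = lev),
               predicted = factor(pred, levels = lev))
  tab <- unclass(tab)
  storage.mode(tab) <- "integer"
  list(table = tab, correct_rate = sum(diag(tab)) / sum(tab))
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf(
    paste0("<count_model> Random Forest, %d trees, classes %s\n",
           "  trained on %d objects (holdout %d): ",
           "holdout accuracy %.3f, OOB error %.3f\n"),
    x$n_trees, paste(range(x$classes), collapse = "-"),
    x$n_train, x$n_holdout, x$holdout_accuracy, x$oob_error))
  invisible(x)
}

#' @export
summary.count_model <- function(object, ...) {
  print(object)
  imp <- variable_importance(object)
  cat("  permutation importance (raw OOB-error increase):\n")
  ord <- order(imp, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("    %-20s %.5f\n", names(imp)[i], imp[i]))
  invisible(object)
}

#' @export
plot.count_model <- function(x, ...) {
  imp <- sort(variable_importance(x))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "permutation importance (OOB-error increase)",
                    main = "Plant-count feature importance", ...)
  invisible(x)
}

#' Save / load a count model
#'
#' The model is serialised as RDS with a JSON sidecar (`<path>.json`)
#' recording the forest size, seed, feature order and an MD5 checksum of
#' the artifact for provenance.
#'
#' @param model a `count_model`.
#' @param path output file path.
#' @return `path`, invisibly (`read_count_model` returns the model).
#' @export
save_count_model <- function(model, path) {
  stopifnot(inherits(model, "count_model"))
  saveRDS(model, path)
  sidecar <- list(format = "emergekit-count-model", version = 1L,
                  n_trees = model$n_trees, seed = model$seed,
                  train_fraction = model$train_fraction,
                  feature_order = model$feature_order,
                  classes = model$classes,
                  md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_count_model
#' @export
read_count_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "count_model"))
    stop("'", path, "' does not contain a count_model")
  model
}

#' Read a labelled training CSV
#'
#' Expects columns `length_cm`, `length_width_ratio`, `area_cm2`,
#' `perimeter_cm`, `convex_area_cm2`, `solidity`, `count`.
#'
#' @param path CSV path.
#' @return data.frame with the six feature columns and integer `count`.
#' @export
read_training_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c(feature_names(), "count")
  missing_cols <- setdiff(need, colnames(d))
  if (length(missing_cols))
    stop("training CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  d$count <- as.integer(d$count)
  d[, need]
}

#' The six morphological feature names, in canonical order
#' @return character vector of length 6.
#' @export
feature_names <- function() {
  c("length_cm", "length_width_ratio", "area_cm2", "perimeter_cm",
    "convex_area_cm2", "solidity")
}
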