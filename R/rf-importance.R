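#' Random-forest Gini importance for a compound table
#'
#' Mean decrease in Gini impurity per compound from a classification
#' forest on the replicate-level content matrix, via the randomForest
#' package.  The raw importances (whose scale depends on tree count and
#' sample size) are reported together with a sum-to-1 normalized column.
#' Fixing `seed` makes the forest, and hence the importances, fully
#' reproducible.
#'
#' @param X samples x compounds matrix (relative contents).
#' @param y two-class group labels.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed (default 1).
#' @param mtry variables tried at each split (default `floor(sqrt(p))`).
#' @return data.frame of class `importance_table` with `compound`,
#'   `gini_raw`, `gini_normalized`, `rank` (stable tie-break by name) and
#'   attributes `n_trees`, `seed`.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1, mtry = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.factor(as.character(y))
  if (nlevels(y) < 2) stop("y must contain at least 2 classes")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                    ntree = n_trees, mtry = mtry,
                                    importance = FALSE)
  gini <- randomForest::importance(fit, type = 2)[, 1]
  stopifnot(all(is.finite(gini)), all(gini >= 0))
  ord <- order(-gini, colnames(X))
  out <- data.frame(compound = colnames(X),
                    gini_raw = unname(gini),
                    gini_normalized = unname(gini) / sum(gini),
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(ncol(X)), ord)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_trees = n_trees, seed = seed,
            class = c("importance_table", "data.frame"))
}
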