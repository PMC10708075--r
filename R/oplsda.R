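#' Center and scale a two-group compound matrix
#'
#' Prepares a samples x compounds matrix for latent-variable modelling:
#' drops zero-variance columns (recorded in the result), mean-centers, and
#' scales per column.  `"uv"` divides by the column SD (unit variance,
#' SIMCA's default for discriminant models), `"pareto"` by its square
#' root, `"none"` only centers.
#'
#' @param X numeric matrix, samples x variables.
#' @param y group labels: a factor/character with exactly two levels, or a
#'   numeric +/-1 vector.
#' @param scaling one of `"uv"`, `"pareto"`, `"none"`.
#' @return list of class `scaled_matrix`: `X` (processed), `y` (+/-1
#'   codes), `levels` (group -> code mapping), `scaling`, `center`,
#'   `scale`, `dropped` (zero-variance column names).
#' @export
opls_scale <- function(X, y, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  enc <- encode_y(y)
  if (nrow(X) != length(enc$y)) stop("X rows and y length differ")

  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(colnames(X), dropped)
  if (length(keep) < 1) stop("no variable with non-zero variance")
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X)
  scl <- switch(scaling,
                uv = apply(X, 2, stats::sd),
                pareto = sqrt(apply(X, 2, stats::sd)),
                none = rep(1, ncol(X)))
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  structure(list(X = Xs, y = enc$y, levels = enc$levels, scaling = scaling,
                 center = ctr, scale = scl, dropped = dropped),
            class = "scaled_matrix")
}

encode_y <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (length(u) != 2) stop("y must have exactly 2 classes")
    codes <- c(-1, 1)
    return(list(y = ifelse(y == u[1], -1, 1),
                levels = stats::setNames(codes, as.character(u))))
  }
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  list(y = ifelse(y == levels(y)[1], -1, 1),
       levels = stats::setNames(c(-1, 1), levels(y)))
}

#' Fit a two-class OPLS-DA model
#'
#' Single-response orthogonal projection to latent structures: `n_ortho`
#' orthogonal (y-unrelated) components are extracted and removed from X
#' before one predictive component is fitted.  With one response the
#' NIPALS weight vector is available in closed form (w proportional to
#' X'y), so the fit is fully deterministic.  An orthogonal component whose
#' weight norm falls below `tol` is not extracted (the model records the
#' number actually fitted).
#'
#' @param X samples x compounds matrix, or a `scaled_matrix` (then `y` and
#'   `scaling` are ignored).
#' @param y two-class labels (see [opls_scale()]).
#' @param n_ortho number of orthogonal components (default 1).
#' @param scaling scaling mode passed to [opls_scale()].
#' @param tol numerical tolerance for degenerate weight vectors.
#' @return object of class `opls_model`: predictive part (`w`, `t`, `p`,
#'   `q`), orthogonal part (`W_o`, `T_o`, `P_o`), `r2x`, `r2y`, `n_ortho`,
#'   the preprocessing record, and per-component SSY bookkeeping used by
#'   [compute_vip()].
#' @export
fit_oplsda <- function(X, y = NULL, n_ortho = 1, scaling = "uv",
                       tol = 1e-12) {
  sm <- if (inherits(X, "scaled_matrix")) X else opls_scale(X, y, scaling)
  if (min(table(sm$y)) < 3)
    warning("fewer than 3 samples in a class; model will be unstable")
  E <- sm$X
  yc <- sm$y - mean(sm$y)
  ssy_tot <- sum(yc^2)
  ssx_tot <- sum(E^2)
  if (ssy_tot <= tol) stop("constant y: cannot fit a discriminant model")

  p_vars <- ncol(E)
  W_o <- T_o <- P_o <- NULL
  ssy_ortho <- numeric(0)
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(E, yc))
    if (sqrt(sum(w^2)) <= tol) break
    w <- w / sqrt(sum(w^2))
    t_p <- drop(E %*% w)
    p <- drop(crossprod(E, t_p)) / sum(t_p^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw <= tol) break                      # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(E %*% w_o)
    p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    q_o <- sum(yc * t_o) / sum(t_o^2)
    ssy_ortho <- c(ssy_ortho, q_o^2 * sum(t_o^2))
  }
  n_ortho_fit <- if (is.null(T_o)) 0L else ncol(T_o)

  w <- drop(crossprod(E, yc))
  if (sqrt(sum(w^2)) <= tol)
    stop("y is orthogonal to every column of X after deflation")
  w <- w / sqrt(sum(w^2))
  t_p <- drop(E %*% w)
  p <- drop(crossprod(E, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)

  ssy_pred <- q^2 * sum(t_p^2)
  r2y <- ssy_pred / ssy_tot
  modelled_x <- sum(tcrossprod(t_p, p)^2)
  if (n_ortho_fit > 0)
    modelled_x <- modelled_x +
      sum(vapply(seq_len(n_ortho_fit),
                 function(k) sum(tcrossprod(T_o[, k], P_o[, k])^2), 0))
  structure(list(w = w, t = t_p, p = p, q = q,
                 W_o = W_o, T_o = T_o, P_o = P_o,
                 n_ortho = n_ortho_fit,
                 r2x = modelled_x / ssx_tot, r2y = r2y,
                 ssy_pred = ssy_pred, ssy_ortho = ssy_ortho,
                 y_mean = mean(sm$y), levels = sm$levels,
                 variables = colnames(sm$X),
                 preprocess = sm[c("scaling", "center", "scale", "dropped")]),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: 1 predictive + %d orthogonal component(s), %d variables\n",
    x$n_ortho, length(x$w)))
  cat(sprintf("R2X = %.3f  R2Y = %.3f\n", x$r2x, x$r2y))
  invisible(x)
}

#' Predict scores and class values for new samples
#'
#' Applies the training preprocessing, strips the orthogonal components,
#' and projects on the predictive weight vector.
#'
#' @param object an `opls_model`.
#' @param newdata samples x compounds matrix on the raw scale of the
#'   training data (columns matched by name when present).
#' @param ... unused.
#' @return list with `t_pred` (predictive scores), `y_hat` (continuous
#'   prediction on the +/-1 scale) and `class` (decoded labels).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$variables %in% colnames(X)))
    X <- X[, object$variables, drop = FALSE]
  if (ncol(X) != length(object$w))
    stop("newdata must carry the model's ", length(object$w), " variables")
  Xs <- sweep(sweep(X, 2, object$preprocess$center, "-"), 2,
              object$preprocess$scale, "/")
  if (object$n_ortho > 0)
    for (k in seq_len(object$n_ortho)) {
      t_o <- drop(Xs %*% object$W_o[, k])
      Xs <- Xs - tcrossprod(t_o, object$P_o[, k])
    }
  t_pred <- drop(Xs %*% object$w)
  y_hat <- t_pred * object$q + object$y_mean
  lev <- names(object$levels)
  list(t_pred = t_pred, y_hat = y_hat,
       class = ifelse(y_hat < 0, lev[1], lev[2]))
}

#' Variable importance in the projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ) over
#' the model components, so that the mean squared VIP over the p retained
#' variables is exactly 1.  By default all components (predictive plus
#' orthogonal) enter, weighted by the Y-variance each explains; since
#' orthogonal components explain essentially no Y-variance this is
#' numerically dominated by the predictive component.  `type =
#' "predictive"` restricts to the predictive component.
#'
#' @param model an `opls_model`.
#' @param type `"total"` (default) or `"predictive"`.
#' @return data.frame of class `vip_table` with `compound`, `vip`, `rank`
#'   (stable tie-break by decreasing VIP then compound name).
#' @export
compute_vip <- function(model, type = c("total", "predictive")) {
  type <- match.arg(type)
  p_vars <- length(model$w)
  W <- matrix(model$w, ncol = 1)
  ssy <- model$ssy_pred
  if (type == "total" && model$n_ortho > 0) {
    W <- cbind(W, model$W_o)
    ssy <- c(ssy, model$ssy_ortho)
  }
  # weight vectors are unit norm by construction
  vip <- sqrt(p_vars * drop(W^2 %*% ssy) / sum(ssy))
  ord <- order(-vip, model$variables)
  out <- data.frame(compound = model$variables, vip = vip,
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(p_vars), ord)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("vip_table", "data.frame"))
}

venetian_folds <- function(y, n_folds) {
  n <- length(y)
  if (n_folds >= n) return(seq_len(n))           # leave-one-out
  fold <- integer(n)
  for (cls in unique(y)) {                       # stratified venetian blind
    idx <- which(y == cls)
    fold[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
  }
  fold
}

#' Cross-validated predictive ability (Q2)
#'
#' Q2 = 1 - PRESS/TSS with PRESS accumulated over held-out samples under
#' stratified venetian-blind folds assigned in sample order (deterministic;
#' no shuffling).  Each training split refits preprocessing and the full
#' orthogonal + predictive decomposition.  `n_folds >=` the number of
#' samples gives leave-one-out.  A split that would lose an entire class is
#' repaired by falling back to leave-one-out with a warning.
#'
#' @param X samples x compounds matrix (raw scale).
#' @param y two-class labels.
#' @param n_ortho orthogonal components (default 1).
#' @param n_folds folds (default 7, SIMCA-style).
#' @param scaling scaling mode.
#' @return Q2 (scalar).
#' @export
cross_validate <- function(X, y, n_ortho = 1, n_folds = 7, scaling = "uv") {
  stopifnot(n_folds >= 2)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  enc <- encode_y(y)
  yn <- enc$y
  fold <- venetian_folds(yn, n_folds)
  for (f in unique(fold)) {
    if (length(unique(yn[fold != f])) < 2) {
      warning("a training split lost an entire class; using leave-one-out")
      fold <- seq_along(yn)
      break
    }
  }
  press <- 0
  for (f in unique(fold)) {
    tr <- fold != f
    fit <- fit_oplsda(X[tr, , drop = FALSE], yn[tr], n_ortho = n_ortho,
                      scaling = scaling)
    pred <- predict(fit, X[!tr, fit$variables, drop = FALSE])
    press <- press + sum((yn[!tr] - pred$y_hat)^2)
  }
  tss <- sum((yn - mean(yn))^2)
  1 - press / tss
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits and cross-validates the model on `n_permutations` random
#' permutations of the class labels, then regresses the permuted R2Y and
#' Q2 values (plus the observed model at correlation 1) on the absolute
#' correlation between permuted and original labels.  Intercepts near or
#' below zero for Q2 indicate the observed model is not an overfitting
#' artefact.
#'
#' @param X samples x compounds matrix.
#' @param y two-class labels.
#' @param n_permutations number of permutations (>= 20 recommended for a
#'   stable intercept; smaller values are allowed).
#' @param seed RNG seed (the only source of randomness).
#' @param n_ortho,n_folds,scaling model settings as in [cross_validate()].
#' @return object of class `perm_result`: `observed` (r2y, q2),
#'   `permuted` data.frame (`correlation`, `r2y`, `q2`), `r2_intercept`,
#'   `q2_intercept`, `p_value` (empirical, observed Q2 vs permuted),
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(X, y, n_permutations = 200, seed = 1,
                             n_ortho = 1, n_folds = 7, scaling = "uv") {
  stopifnot(n_permutations >= 1)
  X <- as.matrix(X)
  enc <- encode_y(y)
  yn <- enc$y
  obs_fit <- fit_oplsda(X, yn, n_ortho = n_ortho, scaling = scaling)
  obs_q2 <- cross_validate(X, yn, n_ortho = n_ortho, n_folds = n_folds,
                           scaling = scaling)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    yp <- sample(yn)
    r2y <- tryCatch(fit_oplsda(X, yp, n_ortho = n_ortho,
                               scaling = scaling)$r2y,
                    error = function(e) NA_real_)
    q2 <- tryCatch(cross_validate(X, yp, n_ortho = n_ortho,
                                  n_folds = n_folds, scaling = scaling),
                   error = function(e) NA_real_)
    c(abs(stats::cor(yp, yn)), r2y, q2)
  }, numeric(3))
  permuted <- data.frame(correlation = perm[1, ], r2y = perm[2, ],
                         q2 = perm[3, ])
  xs <- c(permuted$correlation, 1)
  fit_r2 <- stats::lm(c(permuted$r2y, obs_fit$r2y) ~ xs)
  fit_q2 <- stats::lm(c(permuted$q2, obs_q2) ~ xs)
  structure(list(observed = c(r2y = obs_fit$r2y, q2 = obs_q2),
                 permuted = permuted,
                 r2_intercept = unname(stats::coef(fit_r2)[1]),
                 q2_intercept = unname(stats::coef(fit_q2)[1]),
                 p_value = (sum(permuted$q2 >= obs_q2, na.rm = TRUE) + 1) /
                   (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%d permutations): observed R2Y = %.3f, Q2 = %.3f\n",
    x$n_permutations, x$observed["r2y"], x$observed["q2"]))
  cat(sprintf("intercepts: R2 = %.3f, Q2 = %.3f; empirical p = %.4f\n",
              x$r2_intercept, x$q2_intercept, x$p_value))
  invisible(x)
}

#' Principal component analysis of a content matrix
#'
#' Thin wrapper around [stats::prcomp()] returning scores, loadings and
#' explained-variance fractions, with zero-variance columns dropped before
#' optional unit-variance scaling.
#'
#' @param X samples x compounds matrix.
#' @param n_components number of components to keep (truncated with a
#'   warning if above the matrix rank bound).
#' @param scale. scale columns to unit variance (default TRUE).
#' @return list with `scores`, `loadings`, `explained` (fractions, ordered
#'   decreasing), `dropped`.
#' @export
fit_pca <- function(X, n_components = 2, scale. = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  X <- X[, sds > 0, drop = FALSE]
  max_k <- min(nrow(X) - 1, ncol(X))
  if (n_components > max_k) {
    warning("truncating to ", max_k, " components")
    n_components <- max_k
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained = expl, dropped = dropped)
}
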