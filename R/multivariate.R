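#' Unit-variance-scaled principal component analysis
#'
#' PCA of samples (observations) over genes (variables) after UV
#' (autoscaling): each variable centered and scaled to unit variance.
#' Per-component `R2X` is the fraction of total scaled variance explained;
#' over the full rank the `R2X` values sum to 1. Zero-variance variables
#' (UV undefined) are dropped with a warning. Loadings are signed so each
#' component's largest-magnitude loading is positive.
#'
#' @param expr An `expr_tbl` (samples are the columns) or a numeric matrix
#'   with observations in rows.
#' @param n_components Number of components to keep (default: full rank).
#' @return A `latent_model` (kind `"pca"`): `scores` tibble (`sample`, `PC1`
#'   ...), `loadings` matrix (variables x components), `r2x` per component,
#'   `r2x_cum`, `scaling = "UV"`.
#' @export
pca_uv <- function(expr, n_components = NULL) {
  x <- if (is.matrix(expr)) expr else t(expr_matrix(expr))
  if (nrow(x) < 2) abort("Need >= 2 observations.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance variable(s) before UV scaling.",
                 sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  full_rank <- min(nrow(x) - 1, ncol(x))
  if (is.null(n_components)) n_components <- full_rank
  if (n_components > full_rank) {
    abort(sprintf("n_components must be <= min(obs - 1, variables) = %d.", full_rank))
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  r2x <- ev / sum(ev)
  keep <- seq_len(n_components)
  loadings <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  for (j in keep) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    kind = "pca", scaling = "UV",
    scores = bind_cols(tibble(sample = rownames(x) %||% as.character(seq_len(nrow(x)))),
                       as_tibble(scores)),
    loadings = loadings,
    r2x = r2x[keep], r2x_cum = cumsum(r2x)[n_components],
    n_components = n_components
  ), class = "latent_model")
}

uv_scale <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, sd)
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`), center = center, scale = scale)
}

# One NIPALS PLS2 round on (X, Y); returns weight w, scores t, loadings p, q.
nipals_pls_component <- function(X, Y, tol = 1e-10, max_iter = 500) {
  u <- Y[, which.max(apply(Y, 2, var)), drop = TRUE]
  t_old <- rep(Inf, nrow(X))
  for (i in seq_len(max_iter)) {
    w <- crossprod(X, u) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t <- X %*% w
    q <- crossprod(Y, t) / sum(t^2)
    u <- Y %*% q / sum(q^2)
    if (sum((t - t_old)^2) < tol * sum(t^2)) break
    t_old <- t
  }
  list(w = as.vector(w), t = as.vector(t), p = as.vector(crossprod(X, t) / sum(t^2)),
       q = as.vector(q))
}

# Core OPLS fit on pre-scaled X (n x p) and centered indicator Y (n x g).
opls_fit_core <- function(X, Y, n_predictive, n_orthogonal) {
  ss_x0 <- sum(X^2)
  W_o <- P_o <- NULL
  T_o <- NULL
  Xf <- X
  for (a in seq_len(n_orthogonal)) {
    comp <- nipals_pls_component(Xf, Y)
    w_o <- comp$p - sum(comp$w * comp$p) * comp$w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break
    w_o <- w_o / nrm
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, as.vector(p_o))
    T_o <- cbind(T_o, as.vector(t_o))
  }
  W <- P <- Q <- NULL
  T_p <- NULL
  Xd <- Xf; Yd <- Y
  for (a in seq_len(n_predictive)) {
    comp <- nipals_pls_component(Xd, Yd)
    Xd <- Xd - comp$t %*% t(comp$p)
    Yd <- Yd - comp$t %*% t(comp$q)
    W <- cbind(W, comp$w); P <- cbind(P, comp$p); Q <- cbind(Q, comp$q)
    T_p <- cbind(T_p, comp$t)
  }
  r2x_pred <- sum((T_p %*% t(P))^2) / ss_x0
  r2x_orth <- if (is.null(T_o)) 0 else sum((T_o %*% t(P_o))^2) / ss_x0
  r2y <- 1 - sum(Yd^2) / sum(Y^2)
  # regression coefficients on the orthogonal-filtered X
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(W = W, P = P, Q = Q, T_p = T_p, W_o = W_o, P_o = P_o, T_o = T_o,
       B = B, r2x_pred = r2x_pred, r2x_orth = r2x_orth, r2y = r2y)
}

opls_filter_orth <- function(Xnew, fit) {
  if (is.null(fit$W_o)) return(Xnew)
  for (a in seq_len(ncol(fit$W_o))) {
    t_o <- Xnew %*% fit$W_o[, a]
    Xnew <- Xnew - t_o %*% t(fit$P_o[, a])
  }
  Xnew
}

class_indicator <- function(classes) {
  classes <- as.factor(classes)
  Y <- stats::model.matrix(~ 0 + classes)
  colnames(Y) <- levels(classes)
  Y
}

stratified_folds <- function(classes, n_folds, seed) {
  set.seed(seed)
  classes <- as.factor(classes)
  fold <- integer(length(classes))
  for (l in levels(classes)) {
    idx <- sample(which(classes == l))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' NIPALS OPLS on UV-scaled predictors against a centered class-indicator
#' response: `n_orthogonal` components of class-uncorrelated predictor
#' variation are removed, then `n_predictive` PLS components are fitted on
#' the filtered predictors. The model reports `R2X` split into predictive
#' and orthogonal parts, `R2Y`, and `Q2` from class-stratified k-fold
#' cross-validation with per-fold re-estimation of the UV scaling and the
#' model. Component notation follows the `(predictive+orthogonal+0)`
#' convention.
#'
#' @param expr An `expr_tbl` (samples = observations, genes = variables) or
#'   a numeric matrix with observations in rows.
#' @param classes Class label per observation (>= 2 classes, each >= 2
#'   observations).
#' @param n_predictive,n_orthogonal Component counts;
#'   `n_predictive + n_orthogonal` must be below the predictor rank.
#' @param cv_folds Cross-validation folds (default 7), capped at the
#'   smallest class size.
#' @param seed Seed for fold assignment.
#' @return A `latent_model` (kind `"oplsda"`) with `scores` (predictive and
#'   orthogonal score tibbles), `loadings`, `weights`, `r2x_pred`,
#'   `r2x_orth`, `r2y`, `q2`, `notation`, `classes`.
#' @export
opls_da <- function(expr, classes, n_predictive = 2, n_orthogonal = 1,
                    cv_folds = 7, seed = 1) {
  x <- if (is.matrix(expr)) expr else t(expr_matrix(expr))
  classes <- as.factor(classes)
  if (length(classes) != nrow(x)) abort("classes must match the number of observations.")
  if (nlevels(classes) < 2) abort("Need >= 2 classes.")
  if (any(table(classes) < 2)) abort("Every class needs >= 2 observations.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance variable(s) before UV scaling.", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  rank_x <- qr(scale(x))$rank
  if (n_predictive + n_orthogonal >= rank_x) {
    abort(sprintf("n_predictive + n_orthogonal must be < rank(X) = %d.", rank_x))
  }
  sc <- uv_scale(x)
  Y <- scale(class_indicator(classes), scale = FALSE)
  fit <- opls_fit_core(sc$x, Y, n_predictive, n_orthogonal)

  # sign convention: largest-magnitude predictive loading positive
  for (a in seq_len(ncol(fit$P))) {
    s <- sign(fit$P[which.max(abs(fit$P[, a])), a])
    if (s < 0) {
      fit$P[, a] <- -fit$P[, a]; fit$W[, a] <- -fit$W[, a]
      fit$T_p[, a] <- -fit$T_p[, a]; fit$Q[, a] <- -fit$Q[, a]
    }
  }

  q2 <- opls_q2(x, classes, n_predictive, n_orthogonal, cv_folds, seed)
  sample_names <- rownames(x) %||% as.character(seq_len(nrow(x)))
  scores <- bind_cols(
    tibble(sample = sample_names, class = as.character(classes)),
    as_tibble(structure(fit$T_p,
                        dimnames = list(NULL, paste0("p", seq_len(n_predictive))))),
    if (!is.null(fit$T_o)) {
      as_tibble(structure(fit$T_o,
                          dimnames = list(NULL, paste0("o", seq_len(ncol(fit$T_o))))))
    }
  )
  structure(list(
    kind = "oplsda", scaling = "UV",
    n_predictive = n_predictive, n_orthogonal = n_orthogonal,
    notation = sprintf("(%d+%d+0, UV)", n_predictive, n_orthogonal),
    scores = scores, loadings = fit$P, weights = fit$W,
    orthogonal_weights = fit$W_o,
    r2x_pred = fit$r2x_pred, r2x_orth = fit$r2x_orth,
    r2x_cum = fit$r2x_pred + fit$r2x_orth,
    r2y = fit$r2y, q2 = q2, classes = as.character(classes),
    fit = fit, center = sc$center, scale = sc$scale, seed = seed
  ), class = "latent_model")
}

# Class-stratified k-fold cross-validated Q2 (per-fold UV refit).
opls_q2 <- function(x, classes, n_predictive, n_orthogonal, cv_folds, seed) {
  cv_folds <- min(cv_folds, min(table(classes)))
  if (cv_folds < 2) return(NA_real_)
  fold <- stratified_folds(classes, cv_folds, seed)
  Y_full <- class_indicator(classes)
  press <- 0; tss <- 0
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- !tr
    x_tr <- x[tr, , drop = FALSE]
    keep <- apply(x_tr, 2, sd) > 0
    sc <- uv_scale(x_tr[, keep, drop = FALSE])
    y_mean <- colMeans(Y_full[tr, , drop = FALSE])
    Y_tr <- sweep(Y_full[tr, , drop = FALSE], 2, y_mean)
    fit <- opls_fit_core(sc$x, Y_tr, n_predictive, n_orthogonal)
    x_te <- sweep(sweep(x[te, keep, drop = FALSE], 2, sc$center), 2, sc$scale, `/`)
    x_te <- opls_filter_orth(x_te, fit)
    y_hat <- x_te %*% fit$B
    y_obs <- sweep(Y_full[te, , drop = FALSE], 2, y_mean)
    press <- press + sum((y_obs - y_hat)^2)
    tss <- tss + sum(y_obs^2)
  }
  1 - press / tss
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model under random permutations of the class labels and
#' reports empirical p-values for the observed `R2Y` and `Q2`:
#' `p = (1 + #\{perm >= observed\}) / (n_perms + 1)`.
#'
#' @inheritParams opls_da
#' @param n_perms Number of label permutations (the study convention is 100).
#' @param seed Seed for permutations and fold assignment.
#' @return A `permutation_validation`: tibble `perms` (`r2y`, `q2` per
#'   permutation), observed values, `p_r2y`, `p_q2`, `n_perms`, `seed`.
#' @export
permutation_validation <- function(expr, classes, n_predictive = 2,
                                   n_orthogonal = 0, n_perms = 100,
                                   cv_folds = 7, seed = 1) {
  if (n_perms < 1) abort("n_perms must be >= 1.")
  x <- if (is.matrix(expr)) expr else t(expr_matrix(expr))
  observed <- opls_da(x, classes, n_predictive, n_orthogonal,
                      cv_folds = cv_folds, seed = seed)
  set.seed(seed)
  perm_stats <- purrr::map_dfr(seq_len(n_perms), function(i) {
    cl_p <- sample(classes)
    fit_p <- opls_da(x, cl_p, n_predictive, n_orthogonal,
                     cv_folds = cv_folds, seed = seed + i)
    tibble(perm = i, r2y = fit_p$r2y, q2 = fit_p$q2)
  })
  structure(list(
    perms = perm_stats,
    observed_r2y = observed$r2y, observed_q2 = observed$q2,
    p_r2y = (1 + sum(perm_stats$r2y >= observed$r2y)) / (n_perms + 1),
    p_q2 = (1 + sum(perm_stats$q2 >= observed$q2)) / (n_perms + 1),
    n_perms = n_perms, seed = seed
  ), class = "permutation_validation")
}

#' @export
print.latent_model <- function(x, ...) {
  if (x$kind == "pca") {
    cat(sprintf("UV-scaled PCA: %d components, cumulative R2X = %.3f\n",
                x$n_components, x$r2x_cum))
  } else {
    cat(sprintf("OPLS-DA %s: R2X = %.3f (pred %.3f + orth %.3f), R2Y = %.3f, Q2 = %.3f\n",
                x$notation, x$r2x_cum, x$r2x_pred, x$r2x_orth, x$r2y, x$q2))
  }
  invisible(x)
}

#' @export
print.permutation_validation <- function(x, ...) {
  cat(sprintf("Permutation validation (%d permutations): observed R2Y = %.3f (p = %.4g), Q2 = %.3f (p = %.4g)\n",
              x$n_perms, x$observed_r2y, x$p_r2y, x$observed_q2, x$p_q2))
  invisible(x)
}

#' @rdname pca_uv
#' @param x A `latent_model`.
#' @param matrix `"scores"` or `"loadings"`.
#' @param ... Unused.
#' @export
tidy.latent_model <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  as_tibble(x$loadings, rownames = "variable")
}

#' @rdname pca_uv
#' @export
glance.latent_model <- function(x, ...) {
  if (x$kind == "pca") {
    tibble(kind = "pca", n_components = x$n_components, r2x_cum = x$r2x_cum)
  } else {
    tibble(kind = "oplsda", notation = x$notation, r2x_pred = x$r2x_pred,
           r2x_orth = x$r2x_orth, r2x_cum = x$r2x_cum, r2y = x$r2y, q2 = x$q2)
  }
}

#' @rdname permutation_validation
#' @param x A `permutation_validation`.
#' @param ... Unused.
#' @export
tidy.permutation_validation <- function(x, ...) x$perms

#' @rdname permutation_validation
#' @export
glance.permutation_validation <- function(x, ...) {
  tibble(observed_r2y = x$observed_r2y, observed_q2 = x$observed_q2,
         p_r2y = x$p_r2y, p_q2 = x$p_q2, n_perms = x$n_perms)
}
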