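# Multivariate engine: autoscaling, SVD PCA with Wold element-wise
# cross-validated Q2, agglomerative HCA, single-response OPLS-DA
# (Trygg-Wold) with predictive-component VIP, and the 200x permutation test.

#' Autoscale a data matrix
#'
#' Column-wise centering and scaling. `unit_variance` (the chemometric
#' default) divides each centered column by its SD; `pareto` by sqrt(SD);
#' `none` leaves values untouched. Constant columns are centered but scaled
#' by 1, and flagged.
#'
#' @param X numeric matrix (>= 2 rows).
#' @param mode one of `"unit_variance"`, `"pareto"`, `"none"`.
#' @return an object of class `scaled_matrix` with elements `values`,
#'   `column_means`, `column_sds`, `scaling_mode`, `constant_columns`.
#' @export
autoscale <- function(X, mode = c("unit_variance", "pareto", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2) .fail("autoscale needs at least 2 rows")
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  if (mode == "none") {
    vals <- X; mu <- rep(0, ncol(X)); sc <- rep(1, ncol(X))
  } else {
    sc <- switch(mode, unit_variance = sds, pareto = sqrt(sds))
    sc[const] <- 1
    vals <- sweep(sweep(X, 2, mu), 2, sc, "/")
  }
  structure(list(values = vals, column_means = mu, column_sds = sc,
                 scaling_mode = mode, constant_columns = const),
            class = "scaled_matrix")
}

.as_values <- function(X) if (inherits(X, "scaled_matrix")) X$values else as.matrix(X)

#' Principal component analysis by SVD
#'
#' Scores are `U S`; loadings are the orthonormal right singular vectors;
#' the k-th explained-variance fraction is \eqn{s_k^2 / \sum_i s_i^2}.
#' The input is used as-is (apply [autoscale()] first for the usual
#' chemometric preprocessing). The matrix is centered only if not already
#' column-centered.
#'
#' @param X matrix or [autoscale()] output.
#' @param n_components number of components to retain.
#' @return list of class `pca_model`: `scores`, `loadings`,
#'   `explained_variance_fraction`, `r2x_cum`, `singular_values`, `center`.
#' @export
fit_pca <- function(X, n_components) {
  V <- .as_values(X)
  if (n_components > min(nrow(V) - 1, ncol(V)))
    .fail("n_components = %d exceeds min(n-1, p) = %d", n_components,
          min(nrow(V) - 1, ncol(V)))
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  sv <- svd(Vc)
  k <- seq_len(n_components)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components),
                 loadings = sv$v[, k, drop = FALSE],
                 explained_variance_fraction = ev[k],
                 r2x_cum = sum(ev[k]),
                 singular_values = sv$d,
                 center = ctr),
            class = "pca_model")
}

#' Cross-validated Q2 for PCA (Wold element-wise deletion)
#'
#' Matrix elements are assigned to `n_folds` folds by a seeded permutation.
#' For each fold the held-out elements are treated as missing and predicted
#' by an EM-style iterative SVD imputation with k components; PRESS is
#' accumulated over folds and \eqn{Q^2_k = 1 - PRESS_k / SS}, with SS the
#' total sum of squares of the (centered) matrix.
#'
#' @param X matrix or [autoscale()] output.
#' @param n_components components to evaluate (Q2 returned per component).
#' @param n_folds number of element folds (default 7).
#' @param seed seed for the fold assignment.
#' @param max_iter,tol EM iteration controls.
#' @return numeric vector of Q2 values, one per component count.
#' @export
pca_q2 <- function(X, n_components, n_folds = 7, seed = 1L,
                   max_iter = 100, tol = 1e-6) {
  V <- .as_values(X)
  n <- nrow(V); p <- ncol(V)
  if (n < n_folds) .fail("need at least n_folds = %d rows, got %d", n_folds, n)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  ss <- sum(Vc^2)
  fold <- matrix(.with_seed(derive_seed(seed, 5L),
                            sample(rep(seq_len(n_folds), length.out = n * p))),
                 n, p)
  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    miss <- fold == f
    for (k in seq_len(n_components)) {
      W <- Vc
      W[miss] <- 0                       # start missing at the column center
      prev <- W[miss]
      for (it in seq_len(max_iter)) {
        sv <- svd(W, nu = k, nv = k)
        hat <- sv$u %*% diag(sv$d[seq_len(k)], k) %*% t(sv$v)
        W[miss] <- hat[miss]
        if (sqrt(mean((W[miss] - prev)^2)) < tol * (1 + stats::sd(Vc))) break
        prev <- W[miss]
      }
      press[k] <- press[k] + sum((W[miss] - Vc[miss])^2)
    }
  }
  1 - press / ss
}

#' Agglomerative hierarchical clustering of batches
#'
#' Agglomerative clustering with Lance-Williams distance updates (Ward,
#' average, or complete linkage) on Euclidean or correlation
#' (`1 - Pearson r`) dissimilarity, cut at `k` clusters. Ward linkage uses
#' the squared-Euclidean Ward criterion on Euclidean input (ward.D2).
#'
#' @param X numeric matrix (rows clustered) or [autoscale()] output.
#' @param linkage `"ward"`, `"average"`, or `"complete"`.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param k number of clusters.
#' @return list with `labels` (integer cluster per row) and `tree`
#'   (the `hclust` merge tree).
#' @export
hca <- function(X, linkage = c("ward", "average", "complete"),
                metric = c("euclidean", "correlation"), k) {
  linkage <- match.arg(linkage); metric <- match.arg(metric)
  V <- .as_values(X)
  if (k > nrow(V)) .fail("k = %d exceeds number of rows %d", k, nrow(V))
  if (nrow(V) == 1) return(list(labels = 1L, tree = NULL))
  d <- switch(metric,
              euclidean = stats::dist(V),
              correlation = stats::as.dist(1 - stats::cor(t(V))))
  tree <- stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                           average = "average",
                                           complete = "complete"))
  list(labels = stats::cutree(tree, k = k), tree = tree)
}

# Core single-response O-PLS decomposition (Trygg-Wold). X rows x p, y in
# {-1,+1} (centered internally). Removes n_orthogonal Y-orthogonal
# components from X, then fits one predictive PLS component.
.opls_core <- function(X, y, n_orthogonal) {
  yc <- y - mean(y)
  Xr <- X
  W_o <- P_o <- NULL
  T_o <- NULL
  w <- drop(crossprod(Xr, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  if (n_orthogonal > 0) {
    for (j in seq_len(n_orthogonal)) {
      t_ <- drop(Xr %*% w)
      p_ <- drop(crossprod(Xr, t_)) / sum(t_^2)
      w_o <- p_ - drop(crossprod(w, p_)) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) break                 # no orthogonal variation left
      w_o <- w_o / nw
      t_o <- drop(Xr %*% w_o)
      p_o <- drop(crossprod(Xr, t_o)) / sum(t_o^2)
      Xr <- Xr - tcrossprod(t_o, p_o)
      W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
      w <- drop(crossprod(Xr, yc)) / sum(yc^2)
      w <- w / sqrt(sum(w^2))
    }
  }
  t_p <- drop(Xr %*% w)
  p_p <- drop(crossprod(Xr, t_p)) / sum(t_p^2)
  c_p <- sum(yc * t_p) / sum(t_p^2)
  list(w = w, t_p = t_p, p_p = p_p, c_p = c_p,
       W_o = W_o, P_o = P_o, T_o = T_o, y_mean = mean(y))
}

# Predict class scores for new rows given a fitted .opls_core
.opls_predict <- function(core, Xnew) {
  Xr <- Xnew
  if (!is.null(core$W_o)) {
    for (j in seq_len(ncol(core$W_o))) {
      t_o <- drop(Xr %*% core$W_o[, j])
      Xr <- Xr - tcrossprod(t_o, core$P_o[, j])
    }
  }
  t_p <- drop(Xr %*% core$w)
  core$y_mean + core$c_p * t_p
}

#' Two-class OPLS-DA with VIP
#'
#' Single-response orthogonal projections to latent structures discriminant
#' analysis: `n_orthogonal` Y-orthogonal components are stripped from X, then
#' one predictive PLS component is fitted against the class vector encoded
#' -1/+1. Reports R2X (variance captured by predictive + orthogonal
#' components), R2Y, row-wise 7-fold cross-validated Q2, and VIP computed on
#' the predictive component only (so `mean(VIP^2) = 1` exactly).
#' `n_orthogonal = "auto"` adds orthogonal components while the Q2 gain
#' exceeds 0.01.
#'
#' @param X matrix or [autoscale()] output (apply autoscaling first, as in
#'   standard chemometric practice).
#' @param y two-class vector (factor, character, or -1/+1 numeric).
#' @param n_orthogonal count of orthogonal components (default 1) or
#'   `"auto"`.
#' @param n_folds folds for the Q2 row CV (default 7).
#' @param seed seed for the CV fold assignment.
#' @return list of class `oplsda_model` with scores, loadings, weights,
#'   `r2x`, `r2y`, `q2`, `vip`, `classes`, and the encoded `y`.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1, n_folds = 7, seed = 1L) {
  V <- .as_values(X)
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2) .fail("y must contain exactly 2 classes, got %d", length(cls))
  yy <- ifelse(as.character(y) == cls[2], 1, -1)
  if (identical(n_orthogonal, "auto")) {
    q_prev <- .opls_q2(V, yy, 0, n_folds, seed)
    n_orthogonal <- 0
    repeat {
      q_next <- .opls_q2(V, yy, n_orthogonal + 1, n_folds, seed)
      if (!is.finite(q_next) || q_next - q_prev < 0.01 ||
          n_orthogonal + 1 >= min(nrow(V) - 2, ncol(V) - 1)) break
      n_orthogonal <- n_orthogonal + 1
      q_prev <- q_next
    }
  }
  if (n_orthogonal < 0) .fail("n_orthogonal must be >= 0")
  core <- .opls_core(V, yy, n_orthogonal)
  ssx <- sum(V^2)
  ssx_pred <- sum(core$t_p^2) * sum(core$p_p^2)
  ssx_orth <- if (is.null(core$T_o)) 0 else
    sum(vapply(seq_len(ncol(core$T_o)), function(j)
      sum(core$T_o[, j]^2) * sum(core$P_o[, j]^2), numeric(1)))
  yc <- yy - mean(yy)
  r2y <- 1 - sum((yc - core$c_p * core$t_p)^2) / sum(yc^2)
  vip <- sqrt(length(core$w)) * abs(core$w)   # w is unit norm
  structure(list(predictive_scores = core$t_p,
                 predictive_loadings = core$p_p,
                 orthogonal_scores = core$T_o,
                 orthogonal_loadings = core$P_o,
                 weights = core$w,
                 n_orthogonal = if (is.null(core$T_o)) 0 else ncol(core$T_o),
                 r2x = (ssx_pred + ssx_orth) / ssx,
                 r2y = r2y,
                 q2 = .opls_q2(V, yy, n_orthogonal, n_folds, seed),
                 vip = stats::setNames(vip, colnames(V)),
                 classes = cls, y = yy, core = core),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("OPLS-DA (%s vs %s): %d orthogonal comp; R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
              x$classes[1], x$classes[2], x$n_orthogonal, x$r2x, x$r2y, x$q2))
  invisible(x)
}

# Row-wise k-fold cross-validated Q2 for the OPLS-DA model
.opls_q2 <- function(V, yy, n_orthogonal, n_folds, seed) {
  n <- nrow(V)
  if (n < n_folds) n_folds <- n
  fold <- .with_seed(derive_seed(seed, 6L),
                     sample(rep(seq_len(n_folds), length.out = n)))
  press <- 0
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(yy[tr])) < 2) return(NA_real_)
    core <- .opls_core(V[tr, , drop = FALSE], yy[tr], n_orthogonal)
    pred <- .opls_predict(core, V[!tr, , drop = FALSE])
    press <- press + sum((yy[!tr] - pred)^2)
  }
  1 - press / sum((yy - mean(yy))^2)
}

#' Permutation test for an OPLS-DA model
#'
#' Refits the model `n_permutations` times with the class vector randomly
#' permuted, recording R2Y and Q2 each time. The Q2 intercept is the value at
#' zero correlation of the least-squares line through the points
#' (|cor(y, y_perm)|, Q2), including the original model at correlation 1.
#' The model is `valid` when every permuted Q2 falls below the original Q2
#' and the intercept is negative.
#'
#' @param X matrix or [autoscale()] output.
#' @param y two-class vector.
#' @param n_orthogonal orthogonal component count.
#' @param n_permutations default 200.
#' @param seed seed controlling the permutations.
#' @return list of class `permutation_report`: `permuted_r2y`, `permuted_q2`,
#'   `original_r2y`, `original_q2`, `q2_intercept`, `valid`.
#' @export
permutation_test <- function(X, y, n_orthogonal = 1, n_permutations = 200,
                             seed = 1L) {
  V <- .as_values(X)
  orig <- fit_oplsda(V, y, n_orthogonal = n_orthogonal, seed = seed)
  yy <- orig$y
  perms <- .with_seed(derive_seed(seed, 7L),
                      replicate(n_permutations, sample(yy)))
  r2y <- q2 <- cors <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- perms[, b]
    m <- fit_oplsda(V, yp, n_orthogonal = n_orthogonal, seed = seed)
    r2y[b] <- m$r2y; q2[b] <- m$q2
    cors[b] <- abs(stats::cor(yy, yp))
  }
  fitln <- stats::lm(q ~ r, data = data.frame(q = c(q2, orig$q2), r = c(cors, 1)))
  icpt <- unname(stats::coef(fitln)[1])
  structure(list(n_permutations = n_permutations,
                 permuted_r2y = r2y, permuted_q2 = q2,
                 original_r2y = orig$r2y, original_q2 = orig$q2,
                 q2_intercept = icpt,
                 valid = all(q2 < orig$q2) && icpt < 0),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("Permutation test (%dx): original Q2 = %.3f, max permuted Q2 = %.3f, Q2 intercept = %.3f -> %s\n",
              x$n_permutations, x$original_q2, max(x$permuted_q2),
              x$q2_intercept, if (x$valid) "valid" else "NOT valid"))
  invisible(x)
}
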