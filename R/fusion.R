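#' Assemble a feature matrix with block provenance
#'
#' Feature-level fusion operates on named column blocks (one per backbone).
#' This constructor binds blocks column-wise, records each block's column
#' span, and aligns the label vector.
#'
#' @param blocks Named list of numeric matrices with equal row counts.
#' @param labels Vector of class labels, one per row.
#' @return A `feature_matrix`: tibble with a `label` column followed by all
#'   feature columns, plus attribute `block_spans` (named list of column
#'   index vectors into the feature columns).
#' @export
feature_matrix <- function(blocks, labels) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  nr <- unique(map_int(blocks, nrow))
  if (length(nr) != 1L) abort("all blocks must have the same number of rows")
  if (length(labels) != nr) abort("labels must align with block rows")
  mats <- imap(blocks, function(m, nm) {
    colnames(m) <- paste0(nm, "_f", seq_len(ncol(m)))
    m
  })
  wide <- do.call(cbind, unname(mats))
  spans <- list()
  at <- 0L
  for (nm in names(blocks)) {
    spans[[nm]] <- at + seq_len(ncol(blocks[[nm]]))
    at <- at + ncol(blocks[[nm]])
  }
  out <- bind_cols(tibble(label = labels), as_tibble(wide))
  attr(out, "block_spans") <- spans
  class(out) <- c("feature_matrix", class(out))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  spans <- attr(x, "block_spans")
  cat("<feature_matrix>", nrow(x), "samples x", ncol(x) - 1L, "features |",
      length(spans), "block(s):",
      paste(sprintf("%s[%d]", names(spans), lengths(spans)), collapse = ", "),
      "\n")
  NextMethod()
}

fm_values <- function(x) {
  as.matrix(x[, setdiff(names(x), "label"), drop = FALSE])
}

# Ridge-stabilized covariance: ridge is relative to the mean diagonal entry.
reg_cov <- function(m, ridge) {
  S <- cov(m)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), ncol(S))
  S
}

# Symmetric inverse square root restricted to eigenvalues above tolerance;
# also reports the numerical rank.
inv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  r <- sum(keep)
  V <- e$vectors[, keep, drop = FALSE]
  list(m = V %*% (t(V) / sqrt(e$values[keep])), rank = r)
}

#' Fit canonical correlation analysis on two views
#'
#' Finds `d` pairs of projection vectors maximizing the correlation between
#' the projected views, by singular value decomposition of the whitened
#' cross-covariance \eqn{\Sigma_{xx}^{-1/2}\Sigma_{xy}\Sigma_{yy}^{-1/2}}.
#' Covariances can be ridge-stabilized (relative ridge, a multiple of the
#' mean diagonal variance) for `n` at or below the view dimension.
#'
#' @param x,y Row-aligned numeric matrices (samples x features).
#' @param d Number of canonical pairs to retain.
#' @param ridge Relative ridge on both view covariances (default 0).
#' @return A `cca_model`: projection matrices `Wx`, `Wy` (unit training
#'   variance per component), descending canonical correlations `rho`,
#'   training column means, and `d`.
#' @export
fit_cca <- function(x, y, d, ridge = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must be row-aligned")
  n <- nrow(x)
  if (n <= d) abort("need more rows than retained components")
  if (ridge < 0) abort("`ridge` must be non-negative")
  if (ridge == 0 && n <= max(ncol(x), ncol(y))) {
    abort(paste0("n = ", n, " rows with view dimensions ", ncol(x), "/",
                 ncol(y), ": covariances are singular; supply a small ridge"))
  }
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  Sxx <- reg_cov(xc, ridge); Syy <- reg_cov(yc, ridge)
  Sxy <- crossprod(xc, yc) / (n - 1)
  wx <- inv_sqrt(Sxx); wy <- inv_sqrt(Syy)
  if (d > min(wx$rank, wy$rank)) {
    abort(paste0("d = ", d, " exceeds min view rank ", min(wx$rank, wy$rank)))
  }
  K <- wx$m %*% Sxy %*% wy$m
  sv <- svd(K, nu = d, nv = d)
  structure(list(Wx = wx$m %*% sv$u, Wy = wy$m %*% sv$v,
                 rho = pmin(pmax(sv$d[seq_len(d)], 0), 1),
                 mean_x = mx, mean_y = my, d = d, ridge = ridge),
            class = "cca_model")
}

#' Project and fuse two views through a fitted CCA model
#'
#' @param model A `cca_model`.
#' @param x,y Matrices with the training dimensionalities.
#' @param fuse_mode `"sum"` (default; fused row = `x Wx + y Wy`, width `d`),
#'   `"concat"` (width `2d`), or `"concat-truncate"` (first `d` columns of the
#'   concatenation), or `"none"` to return both projected views.
#' @return Fused numeric matrix, or a list `(zx, zy)` for `"none"`.
#' @export
transform_cca <- function(model, x, y,
                          fuse_mode = c("sum", "concat", "concat-truncate", "none")) {
  fuse_mode <- match.arg(fuse_mode)
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != length(model$mean_x) || ncol(y) != length(model$mean_y)) {
    abort("input dimensions do not match the fitted views")
  }
  zx <- sweep(x, 2, model$mean_x) %*% model$Wx
  zy <- sweep(y, 2, model$mean_y) %*% model$Wy
  switch(fuse_mode,
    sum = zx + zy,
    concat = cbind(zx, zy),
    `concat-truncate` = cbind(zx, zy)[, seq_len(model$d), drop = FALSE],
    none = list(zx = zx, zy = zy)
  )
}

#' @export
tidy.cca_model <- function(x, ...) {
  tibble(component = seq_len(x$d), correlation = x$rho)
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model> d =", x$d, "| rho:",
      paste(sprintf("%.3f", x$rho), collapse = " "), "\n")
  invisible(x)
}

# Between-class scatter factor Phi (p x c) with Sb = Phi %*% t(Phi).
between_factor <- function(xc, y) {
  cls <- levels(y)
  Phi <- vapply(cls, function(cl) {
    rows <- y == cl
    sqrt(sum(rows)) * colMeans(xc[rows, , drop = FALSE])
  }, numeric(ncol(xc)))
  matrix(Phi, ncol = length(cls))
}

# Between-class whitening basis: W' Sb W = I on the retained subspace.
# Requested components beyond rank(Sb) (at most classes - 1) are filled later
# from residual cross-covariance directions.
between_whiten <- function(xc, y, tol = 1e-10) {
  Phi <- between_factor(xc, y)
  small <- crossprod(Phi)                     # c x c
  e <- eigen(small, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  lam <- e$values[keep]
  Q <- Phi %*% e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(lam),
                                                        length(lam))
  # columns of Q are orthonormal eigenvectors of Sb; scale for whitening
  W <- Q %*% diag(1 / sqrt(lam), length(lam))
  list(W = W, basis = Q, rank = sum(keep))
}

#' Fit discriminant correlation analysis on two row-aligned views
#'
#' Class-aware feature-level fusion: each view is whitened against its
#' between-class scatter (restricted to the scatter's rank, at most
#' `classes - 1`), then both views are rotated by the orthonormal singular
#' vectors of the transformed cross-covariance so that, on training data, the
#' between-class scatter of each transformed view is the identity and the
#' cross-view covariance is diagonal — correlations across classes are
#' removed while within-class correlations are kept. When `r` exceeds the
#' between-class rank the remaining components are taken from the leading
#' cross-covariance directions in each view's residual (complement) subspace
#' and flagged via the model's `n_residual` field and a message.
#'
#' @param xa,xb Row-aligned numeric matrices.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @param r Retained components per view.
#' @return A `dca_model` with projections `Wa`, `Wb`, training means, the
#'   diagonal cross-covariance `cross_diag`, `rank_b` (between-class rank
#'   used) and `n_residual`.
#' @export
fit_dca <- function(xa, xb, labels, r) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  y <- factor(labels)
  if (nlevels(y) < 2) abort("need at least 2 classes")
  if (any(table(y) < 2)) abort("every class needs at least 2 samples")
  n <- nrow(xa)
  if (nrow(xb) != n || length(y) != n) abort("views and labels must be row-aligned")
  cmax <- nlevels(y) - 1L
  pmin_dim <- min(ncol(xa), ncol(xb))
  if (r > pmin_dim) {
    abort(paste0("r = ", r, " exceeds the view dimension ", pmin_dim))
  }

  ma <- colMeans(xa); mb <- colMeans(xb)
  ac <- sweep(xa, 2, ma); bc <- sweep(xb, 2, mb)
  wa <- between_whiten(ac, y)
  wb <- between_whiten(bc, y)
  rb <- min(wa$rank, wb$rank, r)
  if (r > cmax && r > rb) {
    inform(paste0("DCA: requested r = ", r, " exceeds the between-class rank ",
                  "ceiling (classes - 1 = ", cmax, "); ", r - rb,
                  " component(s) filled from residual cross-covariance"))
  } else if (r > min(wa$rank, wb$rank)) {
    abort(paste0("r = ", r, " exceeds the between-class scatter rank ",
                 min(wa$rank, wb$rank), " (ceiling is classes - 1 = ",
                 cmax, ")"))
  }

  Wa <- wa$W[, seq_len(rb), drop = FALSE]
  Wb <- wb$W[, seq_len(rb), drop = FALSE]
  ta <- ac %*% Wa
  tb <- bc %*% Wb
  Sab <- crossprod(ta, tb) / (n - 1)
  sv <- svd(Sab)
  Wa <- Wa %*% sv$u
  Wb <- Wb %*% sv$v
  cross_diag <- sv$d

  n_res <- r - rb
  if (n_res > 0) {
    # residual subspaces: orthogonal complements of the between-class bases
    Pa <- diag(ncol(ac)) - wa$basis %*% t(wa$basis)
    Pb <- diag(ncol(bc)) - wb$basis %*% t(wb$basis)
    ra <- ac %*% Pa
    rbm <- bc %*% Pb
    Sres <- crossprod(ra, rbm) / (n - 1)
    sres <- svd(Sres)
    for (k in seq_len(n_res)) {
      u <- sres$u[, k]; v <- sres$v[, k]
      sdu <- sd(ra %*% u); sdv <- sd(rbm %*% v)
      Wa <- cbind(Wa, Pa %*% u / max(sdu, 1e-12))
      Wb <- cbind(Wb, Pb %*% v / max(sdv, 1e-12))
      cross_diag <- c(cross_diag, cor(ra %*% u, rbm %*% v)[1])
    }
  }
  structure(list(Wa = Wa, Wb = Wb, mean_a = ma, mean_b = mb, r = r,
                 rank_b = rb, n_residual = n_res, cross_diag = cross_diag,
                 class_order = levels(y)),
            class = "dca_model")
}

#' Project and fuse two views through a fitted DCA model
#'
#' @param model A `dca_model`.
#' @param xa,xb Matrices with the training dimensionalities.
#' @param fuse_mode `"sum"` (default) or `"concat"`.
#' @return Fused numeric matrix of width `r` (sum) or `2r` (concat).
#' @export
transform_dca <- function(model, xa, xb, fuse_mode = c("sum", "concat")) {
  fuse_mode <- match.arg(fuse_mode)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (ncol(xa) != length(model$mean_a) || ncol(xb) != length(model$mean_b)) {
    abort("input dimensions do not match the fitted views")
  }
  za <- sweep(xa, 2, model$mean_a) %*% model$Wa
  zb <- sweep(xb, 2, model$mean_b) %*% model$Wb
  if (fuse_mode == "sum") za + zb else cbind(za, zb)
}

#' @export
tidy.dca_model <- function(x, ...) {
  tibble(component = seq_len(ncol(x$Wa)),
         cross_covariance = x$cross_diag,
         residual_fill = seq_len(ncol(x$Wa)) > x$rank_b)
}

#' @export
print.dca_model <- function(x, ...) {
  cat("<dca_model> r =", x$r, "| between-class rank used:", x$rank_b,
      if (x$n_residual > 0) paste0("| ", x$n_residual, " residual fill"), "\n")
  invisible(x)
}

#' Full CCA + DCA fusion of a multi-block feature matrix
#'
#' Splits the provenance blocks into two views (first half of the blocks vs
#' the rest, in registry order, unless `view_split` names the blocks of view
#' X), fits CCA on the training rows, fuses the projected views by summation
#' into `d` CCA features, then fits DCA on the pair of CCA-projected training
#' views and fuses them into `d` DCA features. Transforms are frozen on
#' training rows and applied to all rows. With the 5-backbone, 16-class
#' configuration (5 x 16 = 80 input columns) the output is 16 + 16 = 32
#' columns.
#'
#' @param features A [feature_matrix()] with at least two blocks.
#' @param d Fused width per method (default: number of classes).
#' @param train Integer row indices used for fitting (default: all rows).
#' @param view_split Optional character vector naming the blocks of view X.
#' @param ridge Relative ridge for the CCA covariances (default `1e-6`).
#' @return A [feature_matrix()] with blocks `cca` and `dca` (width `2d`) and
#'   attribute `fusion_models` (the fitted `cca_model` and `dca_model`).
#' @export
fuse_pipeline <- function(features, d = NULL, train = NULL, view_split = NULL,
                          ridge = 1e-6) {
  spans <- attr(features, "block_spans")
  if (length(spans) < 2L) {
    abort("feature matrix has a single block: fusion needs two views")
  }
  labels <- features$label
  d <- d %||% length(unique(labels))
  train <- train %||% seq_len(nrow(features))
  vx_names <- view_split %||% names(spans)[seq_len(length(spans) %/% 2)]
  if (!all(vx_names %in% names(spans)) || length(vx_names) == 0 ||
      length(vx_names) == length(spans)) {
    abort("`view_split` must name a non-empty strict subset of the blocks")
  }
  vals <- fm_values(features)
  cx <- unlist(spans[vx_names], use.names = FALSE)
  cy <- unlist(spans[setdiff(names(spans), vx_names)], use.names = FALSE)
  X <- vals[, cx, drop = FALSE]
  Y <- vals[, cy, drop = FALSE]

  cca <- fit_cca(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                 d = d, ridge = ridge)
  proj <- transform_cca(cca, X, Y, fuse_mode = "none")
  cca_block <- proj$zx + proj$zy

  dca <- fit_dca(proj$zx[train, , drop = FALSE], proj$zy[train, , drop = FALSE],
                 labels[train], r = d)
  dca_block <- transform_dca(dca, proj$zx, proj$zy, fuse_mode = "sum")

  out <- feature_matrix(list(cca = cca_block, dca = dca_block), labels)
  attr(out, "fusion_models") <- list(cca = cca, dca = dca,
                                     view_split = vx_names, train = train)
  out
}
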