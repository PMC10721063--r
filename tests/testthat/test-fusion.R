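test_that("feature matrices track block provenance", {
  b1 <- matrix(rnorm(40), 10, 4)
  b2 <- matrix(rnorm(60), 10, 6)
  fm <- feature_matrix(list(one = b1, two = b2), labels = rep(c("a", "b"), 5))
  spans <- attr(fm, "block_spans")
  expect_equal(spans$one, 1:4)
  expect_equal(spans$two, 5:10)
  expect_equal(ncol(fm), 11)  # label + 10 features
  expect_error(feature_matrix(list(one = b1, two = b2[1:5, ]), rep("a", 10)),
               "same number of rows")
})

test_that("CCA recovers perfect correlation on identical views", {
  withr::with_seed(1, x <- matrix(rnorm(50 * 3), 50, 3))
  m <- fit_cca(x, x, d = 3)
  expect_equal(m$rho, c(1, 1, 1), tolerance = 1e-8)
  expect_true(all(diff(m$rho) <= 1e-8))
  z <- transform_cca(m, x, x, fuse_mode = "none")
  expect_equal(z$zx + z$zy, 2 * z$zx, tolerance = 1e-10)
  # unit training variance per component
  expect_equal(unname(apply(z$zx, 2, var)), rep(1, 3), tolerance = 1e-6)
})

test_that("independent views have near-zero canonical correlations", {
  withr::with_seed(2, {
    x <- matrix(rnorm(2000 * 5), 2000, 5)
    y <- matrix(rnorm(2000 * 5), 2000, 5)
  })
  m <- fit_cca(x, y, d = 5)
  expect_true(all(m$rho < 0.15))
})

test_that("CCA matches a random-restart brute-force oracle on small views", {
  withr::with_seed(3, {
    z <- matrix(rnorm(80 * 2), 80, 2)
    x <- cbind(z %*% matrix(c(1, .5, -.3, .8), 2), rnorm(80)) # 3-dim
    y <- cbind(z %*% matrix(c(.7, -.2, .4, 1), 2), rnorm(80))
  })
  m <- fit_cca(x, y, d = 1)
  # brute-force maximization of cor(x a, y b) over random restarts
  obj <- function(p) {
    a <- p[1:3]; b <- p[4:6]
    -abs(cor(x %*% a, y %*% b))
  }
  best <- withr::with_seed(4, {
    min(vapply(1:40, function(i) {
      optim(rnorm(6), obj, method = "BFGS")$value
    }, 0))
  })
  expect_equal(m$rho[1], -best, tolerance = 1e-4)
})

test_that("canonical correlations are affine invariant", {
  withr::with_seed(5, {
    x <- matrix(rnorm(120 * 4), 120, 4)
    y <- x %*% matrix(rnorm(16), 4) + 0.5 * matrix(rnorm(120 * 4), 120, 4)
    m0 <- fit_cca(x, y, d = 3)
    for (i in 1:5) {
      A <- matrix(rnorm(16), 4); while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
      B <- matrix(rnorm(16), 4); while (abs(det(B)) < 0.1) B <- matrix(rnorm(16), 4)
      m1 <- fit_cca(sweep(x %*% A, 2, rnorm(4), "+"), y %*% B, d = 3)
      expect_equal(m1$rho, m0$rho, tolerance = 1e-6)
    }
  })
})

test_that("CCA validates dimensions, rank and conditioning", {
  withr::with_seed(6, {
    x <- matrix(rnorm(10 * 4), 10, 4)
    y <- matrix(rnorm(10 * 20), 10, 20)
  })
  expect_error(fit_cca(x, y, d = 2), "ridge")
  expect_silent(m <- fit_cca(x, y, d = 2, ridge = 1e-4))
  expect_error(fit_cca(x, x[, 1:2], d = 3), "rank")
  expect_error(fit_cca(x[1:5, ], x, d = 2), "row-aligned")
  # on centered views the zero matrix maps to the zero fused block
  withr::with_seed(7, {
    xc <- scale(matrix(rnorm(24), 12, 2), scale = FALSE)
    yc <- scale(matrix(rnorm(24), 12, 2), scale = FALSE)
  })
  mz <- fit_cca(xc, yc, d = 1)
  expect_equal(transform_cca(mz, matrix(0, 12, 2), matrix(0, 12, 2)),
               matrix(0, 12, 1), tolerance = 1e-12, ignore_attr = TRUE)
})

dca_fixture <- function(seed = 7, n_per = 30, sep = 4) {
  withr::with_seed(seed, {
    xa <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
                matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
    list(xa = xa, xb = xa + 0.1 * matrix(rnorm(2 * n_per * 2), 2 * n_per, 2),
         y = rep(c("c1", "c2"), each = n_per))
  })
}

fisher_ratio <- function(v, y) {
  classes <- unique(y)
  m <- mean(v)
  between <- sum(vapply(classes, function(cl) {
    sum(y == cl) * (mean(v[y == cl]) - m)^2
  }, 0))
  within <- sum(vapply(classes, function(cl) {
    sum((v[y == cl] - mean(v[y == cl]))^2)
  }, 0))
  between / within
}

test_that("DCA fused features are at least as discriminant as raw ones", {
  d <- dca_fixture()
  m <- fit_dca(d$xa, d$xb, d$y, r = 1)
  fused <- transform_dca(m, d$xa, d$xb)
  fr_fused <- fisher_ratio(fused[, 1], d$y)
  fr_raw <- max(vapply(1:2, function(j) fisher_ratio(d$xa[, j], d$y), 0))
  expect_gte(fr_fused, fr_raw)
})

test_that("DCA on shuffled labels collapses to the permutation null", {
  d <- dca_fixture(seed = 8)
  y_shuf <- withr::with_seed(9, sample(d$y))
  m <- fit_dca(d$xa, d$xb, y_shuf, r = 1)
  fr <- fisher_ratio(transform_dca(m, d$xa, d$xb)[, 1], y_shuf)
  null_fr <- withr::with_seed(10, vapply(1:200, function(i) {
    yp <- sample(d$y)
    mp <- fit_dca(d$xa, d$xb, yp, r = 1)
    fisher_ratio(transform_dca(mp, d$xa, d$xb)[, 1], yp)
  }, 0))
  expect_lte(fr, quantile(null_fr, 0.975))
  expect_gte(fr, quantile(null_fr, 0.025))
})

test_that("DCA whitens between-class scatter and diagonalizes cross-covariance", {
  withr::with_seed(11, {
    n_per <- 25
    centers <- matrix(rnorm(4 * 5, sd = 3), 4, 5)
    xa <- do.call(rbind, lapply(1:4, function(k) {
      matrix(rnorm(n_per * 5, mean = rep(centers[k, ], each = n_per)), n_per, 5)
    }))
    xb <- xa %*% matrix(rnorm(25), 5) + 0.2 * matrix(rnorm(nrow(xa) * 5), nrow(xa), 5)
    y <- rep(paste0("k", 1:4), each = n_per)
  })
  m <- fit_dca(xa, xb, y, r = 3)
  za <- sweep(xa, 2, m$mean_a) %*% m$Wa
  zb <- sweep(xb, 2, m$mean_b) %*% m$Wb
  # between-class scatter of each transformed view is the identity
  sb_of <- function(z, y) {
    mu <- colMeans(z)
    Reduce(`+`, lapply(unique(y), function(cl) {
      d <- colMeans(z[y == cl, , drop = FALSE]) - mu
      sum(y == cl) * tcrossprod(d)
    }))
  }
  expect_equal(sb_of(za, y), diag(3), tolerance = 1e-6)
  expect_equal(sb_of(zb, y), diag(3), tolerance = 1e-6)
  # cross-covariance is diagonal
  cc <- crossprod(scale(za, scale = FALSE), scale(zb, scale = FALSE)) /
    (nrow(za) - 1)
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-6)

  expect_error(fit_dca(xa, xb, y, r = 6), "view dimension")
  # requests beyond the classes - 1 rank ceiling are filled from residual
  # cross-covariance directions and flagged
  expect_message(m2 <- fit_dca(xa[, 1:2], xb[, 1:2],
                               rep(c("a", "b"), length.out = nrow(xa)),
                               r = 2),
                 "classes - 1")
  expect_equal(m2$rank_b, 1L)
  expect_equal(m2$n_residual, 1L)
})

test_that("the 80-column, 16-class configuration fuses to exactly 32 features", {
  withr::with_seed(12, {
    n_per <- 20
    y <- rep(sprintf("f%02d", 1:16), each = n_per)
    centers <- matrix(rnorm(16 * 16, sd = 2), 16, 16)
    blocks <- lapply(1:5, function(b) {
      noise <- matrix(rnorm(16 * n_per * 16), 16 * n_per, 16)
      centers[rep(1:16, each = n_per), ] %*% matrix(rnorm(256, sd = 0.3), 16) + noise
    })
    names(blocks) <- paste0("net", 1:5)
  })
  fm <- feature_matrix(blocks, y)
  expect_equal(length(attr(fm, "block_spans")), 5)
  expect_equal(ncol(fm) - 1, 80)
  fused <- suppressMessages(fuse_pipeline(fm, d = 16))
  expect_equal(ncol(fused) - 1, 32)
  spans <- attr(fused, "block_spans")
  expect_equal(spans$cca, 1:16)
  expect_equal(spans$dca, 17:32)
  # deterministic refit
  fused2 <- suppressMessages(fuse_pipeline(fm, d = 16))
  expect_equal(as.data.frame(fused), as.data.frame(fused2), tolerance = 1e-12)

  expect_error(fuse_pipeline(feature_matrix(blocks[1], y)), "single block")
})

test_that("fusion fitted on training rows transfers frozen to held-out rows", {
  withr::with_seed(13, {
    y <- rep(c("a", "b", "c"), each = 30)
    sig <- model.matrix(~ 0 + factor(y))
    b1 <- sig %*% matrix(rnorm(9), 3) + 0.5 * matrix(rnorm(90 * 3), 90, 3)
    b2 <- sig %*% matrix(rnorm(9), 3) + 0.5 * matrix(rnorm(90 * 3), 90, 3)
  })
  fm <- feature_matrix(list(u = b1, v = b2), y)
  train <- withr::with_seed(14, sort(sample(90, 60)))
  fused <- suppressMessages(fuse_pipeline(fm, d = 3, train = train))
  models <- attr(fused, "fusion_models")
  # applying the frozen CCA to held-out rows reproduces the stored columns
  test_rows <- setdiff(1:90, train)
  proj <- transform_cca(models$cca, b1[test_rows, ], b2[test_rows, ],
                        fuse_mode = "none")
  vals <- as.matrix(fused[test_rows, paste0("cca_f", 1:3)])
  expect_equal(unname(vals), unname(proj$zx + proj$zy), tolerance = 1e-10)
})
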