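test_that("confusion counts follow the one-vs-rest bookkeeping", {
  cc <- confusion_counts(c("1", "1", "2"), c("1", "2", "2"),
                         class_order = c("1", "2"))
  r1 <- cc[cc$class == "1", ]
  expect_equal(c(r1$tp, r1$fn, r1$fp, r1$tn), c(1L, 1L, 0L, 1L))
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 3L))
  expect_equal(sum(cc$tp) + sum(cc$fn), 3L)

  perfect <- confusion_counts(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))

  allone <- confusion_counts(rep(c("a", "b"), c(3, 7)), rep("a", 10))
  expect_equal(allone$fp[allone$class == "a"], 7L)

  expect_error(confusion_counts("a", "z", class_order = "a"), "outside")
})

test_that("per-class metrics reproduce printed whole-percent table rows", {
  counts <- tibble::tibble(class = c("Family01", "Family05"),
                           tp = c(114L, 112L), fp = c(4L, 0L),
                           fn = c(2L, 4L), tn = c(1736L, 1740L))
  m <- per_class_metrics(counts, rounding = "integer")
  expect_equal(m$precision, c(97, 100))
  expect_equal(m$sensitivity, c(98, 97))
  expect_equal(m$specificity, c(100, 100))
  expect_equal(m$f1, c(97, 98))

  und <- per_class_metrics(tibble::tibble(class = "empty", tp = 0L, fp = 0L,
                                          fn = 5L, tn = 10L))
  expect_true(is.na(und$precision))
  expect_equal(attr(und, "undefined"), "empty")
})

test_that("rounding is half-up, not banker's", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(99.77), 100)
  expect_equal(round_half_up(91.093, 1), 91.1)
  expect_equal(round_half_up(-0.5), -1)
})

test_that("overall accuracy works from vectors and from count tables", {
  expect_equal(overall_accuracy(c("a", "b"), c("a", "b")), 100)
  t1 <- reference_counts("test_70_30")
  expect_equal(overall_accuracy(counts = t1, total = attr(t1, "stated_total"),
                                rounding = "integer"), 93)
  t2 <- reference_counts("validation")
  expect_equal(overall_accuracy(counts = t2, rounding = "one_decimal"), 91.1)
  expect_error(overall_accuracy(character(0), character(0)), "one sample")
})

test_that("one-vs-rest AUC matches the rank-statistic oracle", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(30:80, 1)
      truth <- sample(c("p", "n"), n, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(truth)) < 2) next
      sc <- round(runif(n), sample(1:3, 1))  # force ties sometimes
      probs <- cbind(n = 1 - sc, p = sc)
      auc <- roc_auc_ovr(truth, probs, class_order = c("n", "p"))
      pos <- truth == "p"
      u <- sum(rank(sc)[pos]) - sum(pos) * (sum(pos) + 1) / 2
      oracle <- u / (sum(pos) * sum(!pos))
      expect_equal(auc$auc[auc$class == "p"], oracle, tolerance = 1e-10)
    }
  })
})

test_that("AUC hits the perfect, null, and degenerate cases", {
  truth <- rep(c("a", "b"), each = 5)
  probs <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
                 b = c(rep(0.1, 5), rep(0.9, 5)))
  auc <- roc_auc_ovr(truth, probs)
  expect_equal(auc$auc, c(1, 1))

  withr::with_seed(31, {
    n <- 2000
    truth2 <- rep(c("a", "b"), each = n / 2)
    p <- runif(n)
    null_auc <- roc_auc_ovr(truth2, cbind(a = p, b = 1 - p))
    expect_true(all(null_auc$auc > 0.45 & null_auc$auc < 0.55))
  })

  # monotone transform invariance
  withr::with_seed(32, {
    sc <- runif(40)
    truth3 <- sample(c("a", "b"), 40, replace = TRUE)
    a1 <- roc_auc_ovr(truth3, cbind(a = sc, b = 1 - sc))$auc[1]
    sc2 <- plogis(5 * sc - 1)  # strictly monotone; renormalized pair
    a2 <- roc_auc_ovr(truth3, cbind(a = sc2, b = 1 - sc2))$auc[1]
    expect_equal(a1, a2, tolerance = 1e-12)
  })

  miss <- roc_auc_ovr(rep("a", 4), cbind(a = rep(1, 4), b = rep(0, 4)),
                      class_order = c("a", "b"))
  expect_true(is.na(miss$auc[miss$class == "b"]))
  expect_error(roc_auc_ovr(rep("a", 2), cbind(a = c(1, 1), b = c(0.5, 0))),
               "sum to 1")
})

test_that("evaluation reports aggregate counts, metrics and accuracy", {
  truth <- rep(c("a", "b", "c"), each = 4)
  est <- c("a", "a", "a", "b", "b", "b", "b", "b", "c", "c", "c", "a")
  rep_ <- evaluation_report(truth, est)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$accuracy, 100 * 10 / 12)
  td <- tidy(rep_)
  expect_true(all(c("tp", "precision", "f1") %in% names(td)))
  gl <- glance(rep_)
  expect_equal(gl$n, 12)
  expect_equal(sum(diag(rep_$confusion)), 10)
})
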