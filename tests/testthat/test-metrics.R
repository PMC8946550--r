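# SNR improvement, confusion counts, derived metrics, ROC/AUC, count report.

test_that("SNR improvement matches direct evaluation on a hand-computed case", {
  rep <- snr_improvement(c(1, 2), c(1, 3), c(1, 2.5))
  # signal power 5; input residual 1; output residual 0.25
  expect_equal(rep$snr_in, 10 * log10(5), tolerance = 1e-12)
  expect_equal(rep$snr_out, 10 * log10(20), tolerance = 1e-12)
  expect_equal(rep$snr_imp, 10 * log10(4), tolerance = 1e-12)
  expect_equal(rep$snr_imp, rep$snr_out - rep$snr_in)
  expect_equal(rep$n_points, 2L)
})

test_that("identity denoiser gives exactly zero improvement for any pair", {
  set.seed(31)
  for (i in 1:10) {
    x <- matrix(runif(64, 1, 255), 8)
    xt <- x + matrix(rnorm(64, 0, 10), 8)
    expect_identical(snr_improvement(x, xt, xt)$snr_imp, 0)
  }
})

test_that("perfect reconstruction reports the infinite-SNR sentinel", {
  x <- matrix(1:9, 3)
  xt <- x + 1
  rep <- snr_improvement(x, xt, x)
  expect_identical(rep$snr_out, Inf)
  expect_identical(rep$snr_imp, Inf)
  expect_true(is.finite(rep$snr_in))
})

test_that("SNR of an all-zero clean crop is an error, and shapes must agree", {
  expect_error(snr_improvement(matrix(0, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2)),
               "all-zero")
  expect_error(snr_improvement(1:4, 1:3, 1:4), "same shape")
})

test_that("one-vs-rest confusion counts agree with brute-force enumeration", {
  # all 3^4 labelings of 4 samples over 3 classes, against a naive counter
  classes <- c("a", "b", "c")
  grid <- expand.grid(rep(list(classes), 4), stringsAsFactors = FALSE)
  truth <- c("a", "b", "c", "a")
  brute <- function(truth, pred, pos) {
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(truth)) {
      if (truth[i] == pos && pred[i] == pos) tp <- tp + 1L
      else if (truth[i] != pos && pred[i] != pos) tn <- tn + 1L
      else if (truth[i] != pos && pred[i] == pos) fp <- fp + 1L
      else fn <- fn + 1L
    }
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  for (r in seq_len(nrow(grid))) {
    pred <- as.character(grid[r, ])
    for (pos in classes) {
      got <- confusion_counts(truth, pred, pos)
      expect_identical(got, brute(truth, pred, pos))
      expect_identical(sum(got), 4L)
    }
  }
})

test_that("a perfect 6-class prediction yields the all-correct count row", {
  truth <- rep(c("RBC", "WBC", "MCF7", "HepG2", "BEAD10", "BEAD20"), each = 324)
  got <- confusion_counts(truth, truth, "RBC")
  expect_identical(got, c(tp = 324L, tn = 1620L, fp = 0L, fn = 0L))
  allneg <- confusion_counts(truth, rep("WBC", length(truth)), "RBC")
  expect_identical(allneg[["tp"]], 0L)
  expect_identical(allneg[["fn"]], 324L)
})

published_rows <- list(
  # printed per-class performance rows of the classifier study:
  # counts, then accuracy, precision, recall, specificity, sensitivity,
  # f1, ppv, npv
  bead10 = list(counts = c(322, 1614, 2, 6),
                metrics = c(0.9959, 0.9938, 0.9817, 0.9988, 0.9817, 0.9877, 0.9938, 0.9963)),
  bead20 = list(counts = c(324, 1611, 0, 9),
                metrics = c(0.9954, 1.0000, 0.9730, 1.0000, 0.9730, 0.9863, 1.0000, 0.9944)),
  mcf7 = list(counts = c(184, 1571, 140, 49),
              metrics = c(0.9028, 0.5679, 0.7897, 0.9182, 0.7897, 0.6607, 0.5679, 0.9698)),
  hepg2 = list(counts = c(276, 1494, 48, 126),
               metrics = c(0.9105, 0.8519, 0.6866, 0.9689, 0.6866, 0.7603, 0.8519, 0.9222)),
  rbc = list(counts = c(324, 1620, 0, 0),
             metrics = c(1, 1, 1, 1, 1, 1, 1, 1)),
  wbc = list(counts = c(324, 1620, 0, 0),
             metrics = c(1, 1, 1, 1, 1, 1, 1, 1))
)

test_that("derived metrics reproduce every published table row to 4 decimals", {
  for (nm in names(published_rows)) {
    row <- published_rows[[nm]]
    m <- class_metrics(row$counts)
    got <- round(unlist(m[c("accuracy", "precision", "recall", "specificity",
                            "sensitivity", "f1", "ppv", "npv")]), 4)
    expect_equal(unname(got), row$metrics, tolerance = 1e-12, label = nm)
  }
})

test_that("undefined metrics stay NA instead of being coerced to zero", {
  m <- class_metrics(c(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_identical(m$specificity, 1)
  expect_identical(m$accuracy, 1)
  expect_error(class_metrics(c(1, 2, 3)), "four")
})

test_that("metrics_table satisfies the balanced multi-class tp identity", {
  set.seed(5)
  classes <- letters[1:4]
  truth <- sample(classes, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(classes, 200, replace = TRUE))
  tab <- metrics_table(truth, pred, classes, digits = NULL)
  expect_identical(sum(tab$tp), sum(truth == pred))
  expect_true(all(tab$tp + tab$tn + tab$fp + tab$fn == 200))
})

test_that("relabeling classes permutes confusion rows and columns identically", {
  set.seed(8)
  classes <- c("RBC", "WBC", "MCF7")
  truth <- sample(classes, 120, replace = TRUE)
  pred <- sample(classes, 120, replace = TRUE)
  cm <- table(factor(truth, classes), factor(pred, classes))
  perm <- c("MCF7", "RBC", "WBC")
  cm_perm <- table(factor(truth, perm), factor(pred, perm))
  expect_identical(unclass(cm_perm), unclass(cm[perm, perm]))
})

test_that("ROC/AUC matches hand cases and the concordance definition", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$auc, 1)
  r2 <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.75, tolerance = 1e-12)
  expect_true(all(diff(r$points$fpr) >= 0), info = "fpr monotone")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rnorm(300)
  truth <- runif(300) < plogis(scores)
  a1 <- roc_auc(scores, truth)$auc
  a2 <- roc_auc(exp(scores), truth)$auc
  a3 <- roc_auc(qlogis(plogis(scores) * 0.98 + 0.01), truth)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-10)
})

test_that("AUC agrees with an independent implementation and the null is ~0.5", {
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- runif(1000)
  truth <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  mine <- roc_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
  expect_lt(abs(mine - 0.5), 0.05)
  expect_error(roc_auc(scores, rep(TRUE, 1000)), "single class")
})

test_that("count report arithmetic and class-universe checks", {
  rep <- count_report(c(a = 50, b = 50), c(a = 45, b = 55))
  expect_identical(rep$diff, c(-5, 5))
  expect_identical(rep$pct_diff, c(-10, 10))
  same <- count_report(c(a = 10), c(a = 10))
  expect_identical(same$diff, 0)
  expect_error(count_report(c(a = 1), c(b = 1)), "class universe")
})
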