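test_that("confusion counts partition the examples", {
  cc <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 1, fp = 0, fn = 0))
  inv <- confusion(c(0, 1, 0), c(1, 0, 1))
  expect_equal(inv$tp + inv$tn, 0)
  set.seed(41)
  calls <- rbinom(50, 1, 0.3); truth <- rbinom(50, 1, 0.1)
  cc2 <- confusion(calls, truth)
  expect_equal(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 50)
  expect_equal(cc2$tp + cc2$fn, sum(truth))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("point metrics match direct formula evaluation", {
  perfect <- structure(list(tp = 10, tn = 90, fp = 0, fn = 0),
                       class = "confusion_counts")
  expect_equal(c(ppv(perfect), tpr(perfect), f1(perfect), mcc(perfect)),
               c(1, 1, 1, 1))

  balanced <- structure(list(tp = 1, tn = 1, fp = 1, fn = 1),
                        class = "confusion_counts")
  expect_equal(mcc(balanced), 0)

  c3 <- structure(list(tp = 3, tn = 88, fp = 7, fn = 2),
                  class = "confusion_counts")
  expect_equal(ppv(c3), 0.3)
  expect_equal(tpr(c3), 0.6)
  expect_equal(f1(c3), 0.4)
  expect_equal(mcc(c3), 250 / sqrt(10 * 5 * 95 * 90))
})

test_that("metrics agree with independent oracles over small enumerated tables", {
  # MCC equals the Pearson correlation of the expanded binary vectors
  for (tp in 0:4) for (tn in 0:4) for (fp in 0:4) for (fn in 0:4) {
    n <- tp + tn + fp + fn
    if (n == 0) next
    cc <- structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
                    class = "confusion_counts")
    calls <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
    truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
    expect_equal(ppv(cc), if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(tpr(cc), if (tp + fn == 0) 0 else tp / (tp + fn))
    p <- ppv(cc); r <- tpr(cc)
    expect_equal(f1(cc), if (p + r == 0) 0 else 2 * p * r / (p + r))
    if (isTRUE(stats::sd(calls) > 0) && isTRUE(stats::sd(truth) > 0)) {
      expect_equal(mcc(cc), suppressWarnings(stats::cor(calls, truth)),
                   tolerance = 1e-12)
    } else {
      expect_equal(mcc(cc), 0)  # zero-marginal convention
    }
  }
})

test_that("MCC is invariant under the class-swap symmetry", {
  set.seed(42)
  for (rep in 1:20) {
    v <- sample(0:20, 4, replace = TRUE)
    a <- structure(list(tp = v[1], tn = v[2], fp = v[3], fn = v[4]),
                   class = "confusion_counts")
    b <- structure(list(tp = v[2], tn = v[1], fp = v[4], fn = v[3]),
                   class = "confusion_counts")
    expect_equal(mcc(a), mcc(b))
  }
})

test_that("f1 is the harmonic mean of precision and recall", {
  set.seed(43)
  for (rep in 1:20) {
    v <- sample(1:30, 4, replace = TRUE)
    cc <- structure(list(tp = v[1], tn = v[2], fp = v[3], fn = v[4]),
                    class = "confusion_counts")
    p <- ppv(cc); r <- tpr(cc)
    if (p > 0 && r > 0)
      expect_equal(f1(cc), 2 / (1 / p + 1 / r))
  }
})

test_that("recall-precision curves match per-threshold brute force", {
  set.seed(44)
  scores <- round(runif(400), 2)
  truth <- rbinom(400, 1, 0.15)
  pr <- pr_curve(scores, truth)
  for (i in seq(1, nrow(pr), by = 7)) {
    t <- pr$threshold[i]
    cc <- confusion(as.integer(scores >= t), truth)
    expect_equal(pr$precision[i], ppv(cc))
    expect_equal(pr$recall[i], tpr(cc))
  }
  expect_true(all(diff(pr$recall) <= 1e-12))  # recall non-increasing in threshold
  expect_equal(attr(pr, "baseline"), mean(truth))
  # threshold 0 calls everything positive
  expect_equal(pr$recall[pr$threshold == 0], 1)
  expect_equal(pr$precision[pr$threshold == 0], mean(truth))
})

test_that("degenerate score vectors give the documented curve shapes", {
  truth <- c(1, 0, 0, 1, 0)
  exact <- pr_curve(as.numeric(truth), truth)
  expect_true(all(exact$precision[exact$threshold > 0 &
                                  exact$recall > 0] == 1))
  expect_equal(attr(exact, "auc"), 1)

  const <- pr_curve(rep(0.4, 5), truth)
  nz <- const[const$recall > 0, ]
  expect_true(all(nz$precision == mean(truth)))
})

test_that("score plots report the F1-maximizing cutoff on the grid", {
  set.seed(45)
  truth <- rbinom(300, 1, 0.2)
  scores <- pmin(1, pmax(0, truth * 0.7 + runif(300, 0, 0.5)))
  sp <- score_plot(scores, truth, bins = 51)
  expect_equal(nrow(sp), 51)
  best <- attr(sp, "best_cutoff")
  expect_equal(max(sp$f1), sp$f1[sp$cutoff == best])
  expect_true(all(sp$f1 <= max(sp$f1)))

  sep <- score_plot(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1), bins = 21)
  expect_equal(max(sep$f1), 1)
})
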