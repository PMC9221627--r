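worked_instance <- function() {
  gt <- ground_truth_set(c("p1", "p1"),
                         boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30)))
  pred <- detection_records(rep("p1", 3),
                            boxes(c(0, 50, 20), c(0, 50, 20),
                                  c(10, 60, 30), c(10, 60, 30)),
                            c(0.99, 0.95, 0.91), "m1")
  list(gt = gt, pred = pred)
}

test_that("greedy IoU matching labels the worked instances correctly", {
  w <- worked_instance()
  m <- match_detections(w$pred, w$gt, 0.5)
  expect_equal(m$detections$label, c("TP", "FP", "TP"))
  expect_equal(m$fn, 0)

  # one GT, one perfect prediction
  gt1 <- ground_truth_set("a", boxes(0, 0, 10, 10))
  p1 <- detection_records("a", boxes(0, 0, 10, 10), 0.9, "m1")
  m1 <- match_detections(p1, gt1, 0.5)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1, 0, 0))

  # two overlapping predictions on one GT: only the higher score matches
  p2 <- detection_records(c("a", "a"),
                          boxes(c(0, 1), c(0, 1), c(10, 11), c(10, 11)),
                          c(0.7, 0.9), "m1")
  m2 <- match_detections(p2, gt1, 0.5)
  expect_equal(m2$detections$label, c("FP", "TP"))  # 0.9 wins despite order
  expect_equal(m2$fn, 0)

  # unknown image in predictions is an error naming the image
  bad <- detection_records("ghost", boxes(0, 0, 5, 5), 0.5, "m1")
  expect_error(match_detections(bad, gt1), "ghost")
})

test_that("TP + FN equals the ground-truth count on random instances", {
  set.seed(71)
  for (k in 1:50) {
    inst <- random_match_instance()
    m <- match_detections(inst$pred, inst$gt, 0.5)
    expect_equal(m$tp + m$fn, m$n_gt)
    expect_equal(m$tp + m$fp, nrow(inst$pred))
    # each GT matched at most once: TP can never exceed GT count
    expect_lte(m$tp, m$n_gt)
  }
})

test_that("average precision integrates the worked envelope to 5/6", {
  w <- worked_instance()
  m <- match_detections(w$pred, w$gt, 0.5)
  expect_equal(average_precision(m), 0.5 * 1 + 0.5 * (2 / 3))
  pr <- pr_curve(m)
  expect_equal(pr$recall, c(0.5, 0.5, 1))
  expect_equal(pr$precision, c(1, 0.5, 2 / 3))
  expect_true(all(diff(pr$recall) >= 0))

  # perfect predictions give AP 1
  gt <- ground_truth_set("a", boxes(0, 0, 10, 10))
  perfect <- detection_records("a", boxes(0, 0, 10, 10), 1, "m1")
  expect_equal(average_precision(match_detections(perfect, gt)), 1)

  # zero GT boxes leaves AP undefined
  empty_gt <- ground_truth_set(images = "a")
  expect_error(average_precision(match_detections(perfect, empty_gt)),
               "undefined")
})

test_that("average precision equals the brute-force envelope oracle", {
  set.seed(81)
  for (k in 1:200) {
    inst <- random_match_instance()
    m <- match_detections(inst$pred, inst$gt, 0.5)
    expect_equal(average_precision(m),
                 ap_oracle(m$detections$label, m$detections$score, m$n_gt))
  }
})

test_that("appending zero-score false positives does not change AP", {
  w <- worked_instance()
  padded <- rbind(w$pred,
                  detection_records("p1", boxes(70, 70, 80, 80), 0, "m1"))
  m0 <- match_detections(w$pred, w$gt)
  m1 <- match_detections(validate_detections(padded), w$gt)
  expect_equal(average_precision(m1), average_precision(m0))
})

test_that("classification metrics match direct arithmetic", {
  m <- classification_metrics(tp = 50, tn = 40, fp = 10, fn = 20)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$sensitivity, 50 / 70)
  expect_equal(m$f_score, 2 * (50 / 60) * (50 / 70) / (50 / 60 + 50 / 70))
  expect_equal(m$f_score, 0.7692, tolerance = 1e-4)
  expect_equal(m$mcc, (50 * 40 - 10 * 20) / sqrt(60 * 70 * 50 * 60))
  expect_equal(m$mcc, 0.50709, tolerance = 1e-5)
  expect_equal(m$kappa, 0.5)
  expect_false(m$mcc_undefined)

  perfect <- classification_metrics(tp = 30, tn = 70, fp = 0, fn = 0)
  for (v in c("accuracy", "sensitivity", "precision", "f_score", "mcc",
              "kappa")) {
    expect_equal(perfect[[v]], 1)
  }

  # all-one-class degenerate: MCC denominator vanishes, flagged zero
  deg <- classification_metrics(tp = 0, tn = 10, fp = 0, fn = 5)
  expect_true(deg$mcc_undefined)
  expect_equal(deg$mcc, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("Clopper-Pearson and normal binomial intervals behave as documented", {
  # k = 0: lower bound 0, upper = 1 - 0.025^(1/10)
  ci <- binomial_ci(k = 0, n = 10)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 10))
  expect_equal(ci[["upper"]], 0.30850, tolerance = 1e-5)
  # k = n: upper bound 1
  expect_equal(binomial_ci(k = 10, n = 10)[["upper"]], 1)

  # exact interval always contains k/n; normal is symmetric before clipping
  set.seed(91)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    cp <- binomial_ci(k = k, n = n)
    expect_lte(cp[["lower"]], k / n + 1e-12)
    expect_gte(cp[["upper"]], k / n - 1e-12)
    p <- runif(1, 0.1, 0.9)
    no <- binomial_ci(p = p, n = n, method = "normal")
    expect_equal(no[["upper"]] - p, p - no[["lower"]], tolerance = 1e-12)
  }
  expect_error(binomial_ci(k = 1, n = 0), "n must be")
})

test_that("evaluate_detections runs the filter-match-AP-CI pipeline", {
  w <- worked_instance()
  ev <- evaluate_detections(w$pred, w$gt, confidence_threshold = 0,
                            n_for_ci = 1200, ci_method = "normal")
  expect_s3_class(ev, "detection_eval")
  expect_equal(ev$map, 5 / 6)
  expect_equal(ev$map, ev$ap)  # single class: mAP = AP
  half <- 1.96 * sqrt((5 / 6) * (1 / 6) / 1200)
  expect_equal(as.numeric(ev$ci), c(5 / 6 - half, 5 / 6 + half),
               tolerance = 1e-5)

  # the strict 0.9 filter keeps 0.91 but drops a score of exactly 0.9
  boundary <- detection_records(
    rep("p1", 2), boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30)),
    c(0.90, 0.91), "m1")
  ev2 <- evaluate_detections(boundary, w$gt, confidence_threshold = 0.9)
  expect_equal(nrow(ev2$pr), 1)
  expect_equal(ev2$match$tp, 1)
  expect_equal(ev2$match$fn, 1)  # the GT box whose prediction was filtered
})
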