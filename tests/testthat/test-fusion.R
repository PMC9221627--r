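mk_preds <- function(x1, y1, x2, y2, score, model_id, image_id = "p1") {
  detection_records(rep(image_id, length(x1)), boxes(x1, y1, x2, y2),
                    score, model_id)
}

test_that("confidence filtering is strict and idempotent", {
  d <- mk_preds(c(0, 20, 40), c(0, 20, 40), c(10, 30, 50), c(10, 30, 50),
                c(0.95, 0.90, 0.85), "m1")
  kept <- filter_by_confidence(d, 0.9)
  expect_equal(kept$score, 0.95)  # exactly 0.9 is dropped
  expect_equal(filter_by_confidence(kept, 0.9), kept)
  expect_equal(nrow(filter_by_confidence(d, 0)), 3)
  empty <- filter_by_confidence(d, 1)
  expect_equal(nrow(filter_by_confidence(empty, 0.5)), 0)
})

test_that("greedy NMS suppresses the hand-computed overlap and is idempotent", {
  # IoU(b1, b2) = 81 / 119 = 0.68 >= 0.5 -> b2 suppressed; b3 disjoint
  d <- mk_preds(c(0, 1, 20), c(0, 1, 20), c(10, 11, 30), c(10, 11, 30),
                c(0.95, 0.90, 0.85), "m1")
  out <- nms(d, 0.5)
  expect_equal(out$score, c(0.95, 0.85))
  expect_equal(nms(out, 0.5), out)

  single <- mk_preds(0, 0, 10, 10, 0.5, "m1")
  expect_equal(nms(single, 0.5), single)

  disjoint <- mk_preds(c(0, 50, 100), c(0, 0, 0), c(10, 60, 110),
                       c(10, 10, 10), c(0.9, 0.8, 0.7), "m1")
  expect_equal(nrow(nms(disjoint, 0.5)), 3)

  mixed <- rbind(d, mk_preds(0, 0, 10, 10, 0.5, "m1", image_id = "p2"))
  expect_error(nms(validate_detections(mixed), 0.5), "single image")
})

test_that("NMS idempotence holds on random instances", {
  set.seed(51)
  for (k in 1:20) {
    inst <- random_match_instance(n_pred_max = 6)
    if (nrow(inst$pred) == 0) next
    once <- nms(inst$pred, 0.5)
    expect_equal(nms(once, 0.5), once)
  }
})

test_that("weighted-average fusion reproduces the worked three-member example", {
  members <- mk_preds(c(0, 1, 1), c(0, 1, 0), c(10, 11, 11), c(10, 11, 10),
                      c(0.95, 0.92, 0.91), c("m1", "m2", "m3"))
  cfg <- ensemble_config(c("m1", "m2", "m3"))
  expect_equal(cfg$member_weights, c(1, 0.9, 0.8))
  fused <- fuse(members, cfg)
  expect_equal(nrow(fused), 1)
  # weighted means over weight-sum 2.7
  expect_equal(as.numeric(fused[1, c("x1", "y1", "x2", "y2")]),
               c(1.7, 0.9, 28.7, 27.9) / 2.7)
  expect_equal(as.numeric(fused[1, c("x1", "y1", "x2", "y2")]),
               c(0.6296, 0.3333, 10.6296, 10.3333), tolerance = 1e-4)
  expect_equal(fused$score, 2.506 / 2.7)
  expect_equal(fused$score, 0.92815, tolerance = 1e-5)
  expect_equal(fused$n_votes, 3L)
})

test_that("fusion is the identity on unanimous members and respects min_votes", {
  cfg <- ensemble_config(c("m1", "m2", "m3"))
  ident <- mk_preds(rep(0, 3), rep(0, 3), rep(10, 3), rep(10, 3),
                    rep(0.95, 3), c("m1", "m2", "m3"))
  fused <- fuse(ident, cfg)
  expect_equal(as.numeric(fused[1, c("x1", "y1", "x2", "y2")]), c(0, 0, 10, 10))
  expect_equal(fused$score, 0.95)

  # a single-member box disappears once min_votes = 2
  lone <- mk_preds(c(0, 100), c(0, 100), c(10, 110), c(10, 110),
                   c(0.95, 0.94), c("m1", "m2"))
  cfg2 <- ensemble_config(c("m1", "m2", "m3"), min_votes = 2)
  expect_equal(nrow(fuse(lone, cfg2)), 0)
  cfg1 <- ensemble_config(c("m1", "m2", "m3"), min_votes = 1)
  expect_equal(nrow(fuse(lone, cfg1)), 2)

  expect_error(fuse(mk_preds(0, 0, 1, 1, 0.95, "mx"), cfg), "mx")
})

test_that("fused boxes stay inside the contributors' coordinate envelope", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(2:3, 1)
    x1 <- runif(n, 0, 50); y1 <- runif(n, 0, 50)
    d <- mk_preds(x1, y1, x1 + runif(n, 30, 60), y1 + runif(n, 30, 60),
                  runif(n, 0.91, 0.99), paste0("m", 1:n))
    cfg <- ensemble_config(paste0("m", 1:3))
    fused <- fuse(d, cfg)
    contribs <- attr(fused, "contributors")
    for (i in seq_len(nrow(fused))) {
      cb <- contribs[[i]]
      for (col in c("x1", "y1", "x2", "y2")) {
        expect_gte(fused[[col]][i], min(cb[[col]]) - 1e-9)
        expect_lte(fused[[col]][i], max(cb[[col]]) + 1e-9)
      }
      expect_false(anyDuplicated(cb$model_id) > 0)
    }
  }
})

test_that("fusion is equivariant under renaming and member reordering", {
  members <- mk_preds(c(0, 1, 1), c(0, 1, 0), c(10, 11, 11), c(10, 11, 10),
                      c(0.95, 0.92, 0.91), c("m1", "m2", "m3"))
  cfg <- ensemble_config(c("m1", "m2", "m3"))
  base <- fuse(members, cfg)

  renamed <- members
  renamed$model_id <- c("alpha", "beta", "gamma")[match(renamed$model_id,
                                                        c("m1", "m2", "m3"))]
  cfg_r <- ensemble_config(c("alpha", "beta", "gamma"))
  expect_equal(fuse(validate_detections(renamed), cfg_r)[, 1:6], base[, 1:6])

  # permuting members together with their weights changes nothing
  cfg_p <- ensemble_config(c("m3", "m1", "m2"), c(0.8, 1, 0.9))
  expect_equal(fuse(members, cfg_p)[, 1:6], base[, 1:6])
})

test_that("rank_and_weight ranks validation scores with documented tie-break", {
  cfg <- rank_and_weight(c(A = 0.2865, B = 0.2859, C = 0.2763, D = 0.25))
  expect_equal(cfg$member_ids, c("A", "B", "C"))
  expect_equal(cfg$member_weights, c(1, 0.9, 0.8))
  expect_equal(rank_and_weight(c(solo = 0.5))$member_weights, 1)
  # ties resolved by model id, stably
  tie <- rank_and_weight(c(z = 0.3, a = 0.3, m = 0.3))
  expect_equal(tie$member_ids, c("a", "m", "z"))
  expect_error(rank_and_weight(numeric()), "no validation scores")
})
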