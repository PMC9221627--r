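test_that("RSNA CSV rows map to records and the negative-image convention holds", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patientId,x,y,width,height,score",
               "p1,100,100,50,80,0.95",
               "p2,,,,,"), tmp)
  gt_tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patientId,x,y,width,height",
               "p1,100,100,50,80",
               "p2,,,,"), gt_tmp)

  pred <- read_rsna_csv(tmp, "prediction", model_id = "m1")
  expect_equal(nrow(pred), 1)
  expect_equal(as.numeric(pred[1, c("x1", "y1", "x2", "y2")]),
               c(100, 100, 150, 180))
  expect_equal(pred$score, 0.95)
  expect_equal(pred$model_id, "m1")

  gt <- read_rsna_csv(gt_tmp, "ground_truth")
  expect_setequal(gt_images(gt), c("p1", "p2"))
  expect_equal(nrow(gt_boxes(gt, "p2")), 0)
  expect_equal(nrow(gt_boxes(gt, "p1")), 1)
})

test_that("format errors name the offending column or row", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patientId,x,y,width", "p1,1,1,5"), tmp)
  expect_error(read_rsna_csv(tmp, "ground_truth"), "height")
  writeLines(c("patientId,x,y,width,height", "p1,1,1,5,5", "p2,1,1,-3,5"), tmp)
  expect_error(read_rsna_csv(tmp, "ground_truth"), "row\\(s\\) 2")
  # prediction files need a score column (alias: confidence)
  writeLines(c("patientId,x,y,width,height", "p1,1,1,5,5"), tmp)
  expect_error(read_rsna_csv(tmp, "prediction"), "score")
  writeLines(c("patientId,x,y,width,height,confidence", "p1,1,1,5,5,0.7"), tmp)
  expect_equal(read_rsna_csv(tmp, "prediction")$score, 0.7)
})

test_that("write-then-read round trip preserves records exactly", {
  set.seed(11)
  n <- 15
  x1 <- sample(0:400, n, replace = TRUE)
  y1 <- sample(0:400, n, replace = TRUE)
  d <- detection_records(sample(paste0("p", 1:4), n, replace = TRUE),
                         boxes(x1, y1, x1 + sample(5:100, n, TRUE),
                               y1 + sample(5:100, n, TRUE)),
                         round(runif(n), 4),
                         sample(c("m1", "m2"), n, replace = TRUE))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rsna_csv(d, tmp)
  back <- read_rsna_csv(tmp, "prediction")
  expect_equal(back, d, ignore_attr = TRUE)

  gt <- ground_truth_set(d$image_id, boxes(d$x1, d$y1, d$x2, d$y2),
                         images = c(paste0("p", 1:4), "empty1"))
  write_rsna_csv(gt, tmp)
  gt_back <- read_rsna_csv(tmp, "ground_truth")
  expect_setequal(gt_images(gt_back), gt_images(gt))
  expect_equal(as.data.frame(gt_back), as.data.frame(gt), ignore_attr = TRUE)
})

test_that("duplicate rows are kept, not deduplicated", {
  d <- detection_records(c("p1", "p1"), boxes(c(0, 0), c(0, 0), c(5, 5),
                                              c(5, 5)), c(0.5, 0.5), "m1")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rsna_csv(d, tmp)
  expect_equal(nrow(read_rsna_csv(tmp, "prediction")), 2)
})

test_that("COCO JSON reads, filters categories and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  gt <- ground_truth_set(c("a", "a", "b"),
                         boxes(c(0, 20, 5), c(0, 20, 5), c(10, 30, 9),
                               c(10, 30, 9)),
                         images = c("a", "b", "c"))
  pred <- detection_records(c("a", "c"), boxes(c(1, 2), c(1, 2), c(9, 8),
                                               c(9, 8)),
                            c(0.9, 0.4), c("m1", "m2"))
  write_coco_json(gt, pred, tmp)
  back <- read_coco_json(tmp)
  expect_setequal(gt_images(back$ground_truth), c("a", "b", "c"))
  expect_equal(as.data.frame(back$ground_truth), as.data.frame(gt),
               ignore_attr = TRUE)
  expect_equal(back$predictions, pred, ignore_attr = TRUE)

  # single annotation bbox [x, y, w, h] becomes a corner-form box
  one <- list(images = list(list(id = "i1")),
              categories = list(list(id = 1, name = "opacity")),
              annotations = list(list(id = 1, image_id = "i1",
                                      category_id = 1, bbox = c(0, 0, 10, 10))))
  jsonlite::write_json(one, tmp, auto_unbox = TRUE)
  r <- read_coco_json(tmp)
  expect_equal(as.numeric(r$ground_truth[1, c("x1", "y1", "x2", "y2")]),
               c(0, 0, 10, 10))

  # empty annotations array: image universe survives with zero boxes
  none <- list(images = list(list(id = "i1")),
               categories = list(list(id = 1, name = "opacity")),
               annotations = list())
  jsonlite::write_json(none, tmp, auto_unbox = TRUE)
  r2 <- read_coco_json(tmp)
  expect_equal(gt_images(r2$ground_truth), "i1")
  expect_equal(nrow(r2$ground_truth), 0)

  # unknown category id lists the known ones
  expect_error(read_coco_json(tmp, category_id = 99), "known ids: 1")
})

test_that("the RSNA submission dialect packs score x y w h per image", {
  d <- detection_records(c("p1", "p1"), boxes(c(0, 20), c(0, 20), c(10, 30),
                                              c(10, 30)),
                         c(0.9, 0.8), "m1")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rsna_submission(d, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "patientId,PredictionString")
  expect_equal(lines[2], "p1,0.9 0 0 10 10 0.8 20 20 10 10")
})
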