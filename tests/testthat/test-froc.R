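gt_row <- function(id, x, y, z, d) data.frame(seriesuid = id, coordX = x,
                                              coordY = y, coordZ = z,
                                              diameter_mm = d)
det_row <- function(id, x, y, z, p) data.frame(seriesuid = id, coordX = x,
                                               coordY = y, coordZ = z,
                                               probability = p)

test_that("the centre-within-radius hit rule credits each nodule once", {
  gts <- gt_row("s", 0, 0, 0, 10)                       # radius 5
  d1 <- det_row("s", 2, 0, 0, 0.9)                      # 0.4 R -> TP
  d2 <- det_row("s", 5.5, 0, 0, 0.8)                    # 1.1 R -> FP
  m <- match_detections(rbind(d1, d2), gts)
  expect_identical(m$dets$match, c("TP", "FP"))
  expect_equal(m$gt_hit_prob, 0.9)

  # two hits on one nodule: highest probability credited, other ignored
  d3 <- det_row("s", -2, 0, 0, 0.8)
  m2 <- match_detections(rbind(d1, d3), gts)
  expect_identical(m2$dets$match, c("TP", "ignored"))
  m3 <- match_detections(rbind(d1, d3), gts, extra_hits_are_fp = TRUE)
  expect_identical(m3$dets$match, c("TP", "FP"))
})

test_that("FROC curves reach the limit cases and match exhaustive enumeration", {
  gts <- rbind(gt_row("a", 0, 0, 0, 8), gt_row("a", 30, 0, 0, 8),
               gt_row("b", 0, 0, 0, 8))
  # perfect detector: every gt hit at p = 1, no FPs
  perfect <- rbind(det_row("a", 0, 0, 0, 1), det_row("a", 30, 0, 0, 1),
                   det_row("b", 0, 0, 0, 1))
  cv <- froc_curve(perfect, gts, n_scans = 2)
  expect_equal(cv$sensitivity[1], 1)
  expect_equal(cv$fp_per_scan[1], 0)

  # empty detector: zero sensitivity everywhere
  none <- det_row("a", 0, 0, 0, 1)[0, ]
  expect_equal(unname(sensitivity_at(froc_curve(rbind(det_row("a", 99, 99, 99, 0.1)),
                                                gts, 2))),
               rep(0, 7))

  expect_error(froc_curve(perfect, gts[0, ], 2), "zero nodules")

  # randomized instances against the per-threshold re-matching oracle
  set.seed(14)
  for (rep in 1:20) {
    ids <- sample(letters[1:4], 1)
    n_scans <- 4
    gts_r <- do.call(rbind, lapply(1:sample(2:6, 1), function(i)
      gt_row(sample(letters[1:4], 1), runif(1, 0, 50), runif(1, 0, 50),
             runif(1, 0, 50), runif(1, 5, 15))))
    dets_r <- do.call(rbind, lapply(1:sample(3:20, 1), function(i) {
      if (runif(1) < 0.5 && i <= nrow(gts_r)) {
        g <- gts_r[i, ]
        det_row(g$seriesuid, g$coordX + runif(1, -2, 2), g$coordY, g$coordZ,
                round(runif(1), 3))
      } else det_row(sample(letters[1:4], 1), runif(1, 60, 90), runif(1, 0, 50),
                     runif(1, 0, 50), round(runif(1), 3))
    }))
    dets_r <- dets_r[!duplicated(dets_r$probability), , drop = FALSE]
    got <- froc_curve(dets_r, gts_r, n_scans)
    want <- oracle_froc(dets_r, gts_r, n_scans)
    expect_equal(got$fp_per_scan, want$fp_per_scan)
    expect_equal(got$sensitivity, want$sensitivity)
  }
})

test_that("sensitivity read-off interpolates linearly and handles the ends", {
  curve <- structure(data.frame(threshold = c(0.9, 0.5),
                                fp_per_scan = c(1, 4),
                                sensitivity = c(0.6, 0.9)),
                     class = c("froc_curve", "data.frame"))
  s <- sensitivity_at(curve, c(0.5, 1, 2, 4, 8))
  expect_equal(unname(s[2]), 0.6)              # exact hit
  expect_equal(unname(s[3]), 0.7)              # interpolated between 1 and 4
  expect_equal(unname(s[4]), 0.9)              # exact hit
  expect_equal(unname(s[5]), 0.9)              # beyond the largest rate
  expect_equal(unname(s[1]), 0.3)              # interpolated towards (0, 0)

  flat <- structure(data.frame(threshold = 0.5, fp_per_scan = 0.125,
                               sensitivity = 0.8),
                    class = c("froc_curve", "data.frame"))
  expect_equal(unname(sensitivity_at(flat)), c(0.8, rep(0.8, 6)))
})

test_that("CPM is the exact mean of the seven printed sensitivities", {
  expect_equal(round(cpm(c(77.0, 84.3, 89.4, 92.5, 94.6, 96.0, 96.6)), 1), 90.1)
  expect_equal(round(cpm(c(45.9, 58.3, 67.4, 76.9, 84.8, 91.0, 94.6)), 1), 74.1)
  expect_equal(cpm(rep(1, 7)), 1)
  expect_error(cpm(c(0.5, 0.6)), "exactly 7")
})

test_that("adding detections moves the metrics in the right direction", {
  gts <- rbind(gt_row("a", 0, 0, 0, 10), gt_row("a", 40, 0, 0, 10))
  base <- rbind(det_row("a", 0, 0, 0, 0.9), det_row("a", 70, 0, 0, 0.5))
  s0 <- sensitivity_at(froc_curve(base, gts, 1))
  # an extra FP never increases any read-off sensitivity
  worse <- rbind(base, det_row("a", 90, 0, 0, 0.7))
  s1 <- sensitivity_at(froc_curve(worse, gts, 1))
  expect_true(all(s1 <= s0 + 1e-12))
  # an extra TP never decreases CPM
  better <- rbind(base, det_row("a", 40, 0, 0, 0.8))
  s2 <- sensitivity_at(froc_curve(better, gts, 1))
  expect_gte(cpm(s2), cpm(s0))
})

test_that("cross-validation aggregation gives fold means and sample SDs", {
  mk <- function(v) structure(list(curve = NULL,
                                   sensitivities = setNames(rep(v, 7),
                                                            as.character(1:7)),
                                   cpm = v), class = "cpm_result")
  same <- crossval_aggregate(list(mk(0.8), mk(0.8), mk(0.8)))
  expect_equal(unname(same$sd["cpm"]), 0)
  two <- crossval_aggregate(list(mk(0.7), mk(0.9)))
  expect_equal(unname(two$mean["cpm"]), 0.8)
  expect_equal(unname(two$sd["cpm"]), sqrt(0.02), tolerance = 1e-9)
  expect_equal(unname(two$sd["cpm"]), 0.1414, tolerance = 1e-3)
  set.seed(15)
  vals <- runif(10, 0.5, 0.9)
  ten <- crossval_aggregate(lapply(vals, mk))
  expect_equal(unname(ten$mean["cpm"]), mean(vals))
  expect_equal(unname(ten$sd["cpm"]), sd(vals))
  one <- crossval_aggregate(list(mk(0.6)))
  expect_true(is.na(one$sd[length(one$sd)]))

  folds <- assign_folds(sprintf("s%02d", 1:10), 10, seed = 2)
  expect_identical(sort(unname(folds)), 1:10)   # 10 scans, 10 folds: 1 each
})
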