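# Image primitives and per-field feature extraction.

disc_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(y, x) (y - c0)^2 + (x - c0)^2 <= r^2)
}

test_that("illumination correction flattens ramps, passes degenerates", {
  flat <- matrix(500, 64, 64)
  expect_equal(correct_illumination(flat), flat, tolerance = 1e-6)
  # x2 linear ramp across the field
  ramp <- matrix(rep(seq(1, 2, length.out = 96), each = 96), 96, 96) * 400
  corr <- correct_illumination(ramp)
  q <- ncol(corr) %/% 4
  left <- mean(corr[, 1:q])
  right <- mean(corr[, (3 * q):ncol(corr)])
  raw_ratio <- mean(ramp[, (3 * q):ncol(ramp)]) / mean(ramp[, 1:q])
  expect_gt(raw_ratio, 1.5)
  expect_lt(abs(right / left - 1), 0.1)
  zeros <- matrix(0, 32, 32)
  expect_warning(out <- correct_illumination(zeros), "constant-zero")
  expect_identical(out, zeros)
})

test_that("segment_channel: blank fields, vacuous thresholds, recovery", {
  blank <- matrix(100, 64, 64)
  expect_equal(max(segment_channel(blank)), 0)
  img <- matrix(100, 64, 64)
  img[20:30, 20:30] <- 1000
  expect_equal(max(segment_channel(img, threshold = 2000)), 0)
  expect_equal(max(segment_channel(img, "otsu")), 1)
  # nuclei count recovery on a rendered field
  ft <- field_truth("panelA", n_nuclei = 50)
  fr <- render_field(ft, optics_params(), seed = 11)
  lab <- segment_channel(correct_illumination(fr$images$Hoechst), "otsu",
                         min_size = 10)
  expect_lt(abs(max(lab) / 50 - 1), 0.05)
})

test_that("otsu threshold splits a clear bimodal mixture", {
  x <- c(rnorm(600, 100, 10), rnorm(200, 900, 50))
  th <- otsu_threshold(x)
  expect_gt(th, 200)
  expect_lt(th, 800)
  expect_equal(otsu_threshold(rep(5, 10)), 5)  # degenerate
})

test_that("mitochondrial segmentation: gradients removed, puncta kept", {
  expect_error(segment_mitochondria(matrix(0, 8, 8), ball_radius = -1),
               "positive")
  expect_error(segment_mitochondria(matrix(0, 8, 8), ball_radius = 3,
                                    tophat_radius = 5), "exceed")
  # blank field with smooth gradient only
  ftb <- field_truth("panelMito", n_nuclei = 0, n_mito = 0)
  frb <- render_field(ftb, optics_params(), seed = 2)
  expect_equal(max(segment_mitochondria(frb$images$TMRM)), 0)
  # 30 puncta on the gradient
  ft <- field_truth("panelMito", n_nuclei = 0, n_mito = 30)
  fr <- render_field(ft, optics_params(), seed = 3)
  lab <- segment_mitochondria(fr$images$TMRM)
  expect_lte(abs(max(lab) - 30) / 30, 0.10)
})

test_that("morphometry: discs are round, lines are not", {
  rp <- region_props(disc_mask(10) * 1L)
  expect_gte(rp$form_factor, 0.85)
  expect_gt(rp$compactness, 0.8)
  expect_lt(rp$eccentricity, 0.3)
  line <- matrix(FALSE, 40, 40)
  line[20, 5:36] <- TRUE
  rl <- region_props(line * 1L)
  expect_lte(rl$form_factor, 0.2)
  expect_gt(rl$eccentricity, 0.95)
  expect_lt(rl$compactness, 0.2)
})

test_that("skeletonization topology: line, Y, empty", {
  line <- matrix(FALSE, 110, 21)
  line[6:105, 11] <- TRUE
  r <- skeletonize_neurites(line)
  expect_equal(r$n_branch_points, 0L)
  expect_equal(r$n_end_points, 2L)
  y <- matrix(FALSE, 60, 60)
  y[cbind(10:30, 30)] <- TRUE
  y[cbind(31:50, 30 + (1:20))] <- TRUE
  y[cbind(31:50, 30 - (1:20))] <- TRUE
  ry <- skeletonize_neurites(y)
  expect_equal(ry$n_branch_points, 1L)
  expect_equal(ry$n_end_points, 3L)
  re <- skeletonize_neurites(matrix(FALSE, 10, 10))
  expect_equal(re$total_length, 0L)
  expect_equal(re$n_branch_points, 0L)
})

test_that("rendered neurite trees recover branch counts within +/-1", {
  op <- optics_params(margin = 60)  # keep whole trees in frame
  ok <- 0L
  for (s in 1:8) {
    ft <- field_truth("panelA", n_nuclei = 1, map2_fraction = 1,
                      th_fraction = 1, branches_per_cell = 2)
    fr <- render_field(ft, op, seed = 100 + s)
    seg <- segment_field(fr$images, "panelA")
    ok <- ok + (abs(seg$neurites$n_branch_points -
                    fr$truth$n_branch_points) <= 1L)
  }
  expect_gte(ok, 7L)
})

test_that("marker positivity calls recover planted fractions", {
  expect_equal(mean(classify_cells(rep(0, 40))), 0)
  expect_true(mean(classify_cells(5)) %in% c(0, 1))
  set.seed(42)
  truth <- rep(c(TRUE, FALSE), c(40, 60))
  ints <- ifelse(truth, rnorm(100, 900, 80), rnorm(100, 80, 30))
  expect_lt(abs(mean(classify_cells(ints)) - 0.40), 0.05)
})

test_that("well feature vectors follow the catalogue contract", {
  ft <- field_truth("panelA", n_nuclei = 25)
  fr <- render_field(ft, optics_params(), seed = 9)
  seg <- segment_field(fr$images, "panelA")
  v <- compute_well_features(seg, feature_catalogue("panelA"))
  expect_length(v, 126)
  expect_named(v, feature_catalogue("panelA")$name)
  # mean idempotence: two identical fields = one field
  v2 <- compute_well_features(list(seg, seg), feature_catalogue("panelA"))
  expect_equal(v, v2, tolerance = 1e-12)
  # panel/catalogue mismatch
  expect_error(field_features(seg, feature_catalogue("panelMito")),
               "catalogue error")
  ftm <- field_truth("panelMito", n_nuclei = 20, n_mito = 80)
  frm <- render_field(ftm, optics_params(), seed = 10)
  vm <- compute_well_features(segment_field(frm$images, "panelMito"),
                              feature_catalogue("panelMito"))
  expect_length(vm, 96)
})

test_that("rotating a field by 90 degrees preserves counts and morphology", {
  ft <- field_truth("panelA", n_nuclei = 30)
  fr <- render_field(ft, optics_params(), seed = 21)
  seg1 <- segment_field(fr$images, "panelA")
  rot <- lapply(fr$images, function(m) t(m)[ncol(m):1, , drop = FALSE])
  seg2 <- segment_field(rot, "panelA")
  expect_equal(nrow(seg2$nuclei_props), nrow(seg1$nuclei_props))
  expect_equal(sum(seg2$th_pos), sum(seg1$th_pos))
  for (col in c("area", "form_factor", "eccentricity"))
    expect_lt(abs(mean(seg2$nuclei_props[[col]]) /
                  mean(seg1$nuclei_props[[col]]) - 1), 0.02)
})

test_that("granularity responds to punctate structure", {
  smooth <- matrix(500, 48, 48)
  expect_lt(granularity(smooth, 3), 1e-9)
  dots <- smooth
  dots[cbind(seq(6, 42, by = 6), seq(6, 42, by = 6))] <- 5000
  expect_gt(granularity(dots, 3), granularity(smooth, 3))
})
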