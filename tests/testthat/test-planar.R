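make_image <- function(counts, spacing = 2) planar_image(counts, spacing)

test_that("roi_mean matches a per-pixel summation oracle", {
  img <- make_image(matrix(7, 10, 10))
  r <- roi(cbind(c(2, 3, 4), c(5, 5, 6)))
  expect_equal(roi_mean(img, r), 7)
  img2 <- make_image(matrix(0, 5, 5)); img2$counts[2, 3] <- 4; img2$counts[4, 3] <- 6
  expect_equal(roi_mean(img2, roi(cbind(c(2, 4), c(3, 3)))), 5)
  # irregular ROI on a random image vs explicit loop
  set.seed(9)
  img3 <- make_image(matrix(rpois(400, 30), 20, 20))
  px <- unique(cbind(sample(3:18, 15, TRUE), sample(3:18, 15, TRUE)))
  r3 <- roi(px)
  s <- 0
  for (i in seq_len(nrow(px))) s <- s + img3$counts[px[i, 1], px[i, 2]]
  expect_equal(roi_mean(img3, r3), s / nrow(px), tolerance = 1e-15)
  # errors: out-of-bounds mask
  expect_error(roi_mean(img, roi(cbind(11, 2))), "bounds")
  expect_error(roi(matrix(integer(0), ncol = 2)), "empty")
})

test_that("mirror_roi is a congruent involution about the midline", {
  img <- make_image(matrix(1, 20, 21))
  mid <- 11
  # asymmetric L-shaped mask vs a per-pixel reflection oracle
  px <- rbind(c(5, 3), c(6, 3), c(7, 3), c(7, 4), c(7, 5))
  r <- roi(px)
  m <- mirror_roi(r, img, mid)
  oracle <- cbind(px[, 1], 2 * mid - px[, 2])
  expect_setequal(paste(m$pixels[, 1], m$pixels[, 2]),
                  paste(oracle[, 1], oracle[, 2]))
  expect_identical(nrow(m$pixels), nrow(r$pixels)) # mask congruence
  # involution: mirroring twice returns the original mask
  mm <- mirror_roi(m, img, mid, label = "thyroid_ref")
  expect_setequal(paste(mm$pixels[, 1], mm$pixels[, 2]), paste(px[, 1], px[, 2]))
  # ROI touching the midline reflects to touch it from the other side
  rt <- roi(cbind(4:6, rep(mid, 3)))
  expect_true(all(mirror_roi(rt, img, mid)$pixels[, 2] == mid))
  rt2 <- roi(cbind(4:6, rep(mid - 1, 3)))
  expect_true(all(mirror_roi(rt2, img, mid)$pixels[, 2] == mid + 1))
  # reflection exiting the bounds suggests a translation
  r_edge <- roi(cbind(5, 19))
  expect_error(mirror_roi(r_edge, img, midline_col = 3), "offset_rows")
})

test_that("uptake ratios and the retention index follow their definitions", {
  expect_equal(compute_lbr(100, 50), 2.0)
  expect_equal(compute_lbr(80, 80), 1.0)
  expect_error(compute_lbr(100, 0), "background")
  expect_equal(compute_ltr(120, 100), 1.2)
  expect_equal(compute_ltr(95, 95), 1.0)
  expect_error(compute_ltr(120, -1), "thyroid")
  expect_equal(compute_ri(2, 2), 0)
  expect_equal(compute_ri(2.0, 1.0), 0.5)
  # delayed accumulation gives a negative retention index
  expect_equal(compute_ri(1.0, 1.9), -0.9)
  expect_error(compute_ri(0, 1), "eLTR")
})

test_that("quantify_patient_planar matches an independent formula-by-formula oracle", {
  spec <- phantom_spec()
  dp <- simulate_dual_phase(spec, noise = FALSE, blur = FALSE)
  lesion <- phantom_lesion_roi(spec, dp$early)
  pp <- quantify_patient_planar(dp$early, dp$delayed, lesion)
  # oracle: mirror coordinates by arithmetic, ray-sum means from the 3-D
  # truth, each ratio applied independently
  mid <- (ncol(dp$early$counts) + 1) / 2
  thy <- roi(cbind(lesion$pixels[, 1], round(2 * mid - lesion$pixels[, 2])))
  h <- diff(range(lesion$pixels[, 1])) + 1
  bkg <- roi(cbind(lesion$pixels[, 1] - h, round(2 * mid - lesion$pixels[, 2])))
  e3 <- build_activity_volume(spec, "early")$counts
  d3 <- build_activity_volume(spec, "delayed")$counts
  expect_equal(pp$elbr, ray_sum_ratio_oracle(e3, lesion, bkg), tolerance = 1e-12)
  expect_equal(pp$dlbr, ray_sum_ratio_oracle(d3, lesion, bkg), tolerance = 1e-12)
  expect_equal(pp$eltr, ray_sum_ratio_oracle(e3, lesion, thy), tolerance = 1e-12)
  expect_equal(pp$dltr, ray_sum_ratio_oracle(d3, lesion, thy), tolerance = 1e-12)
  expect_equal(pp$ri, (pp$eltr - pp$dltr) / pp$eltr, tolerance = 1e-15)
})

test_that("ratios are invariant under global intensity scaling", {
  spec <- phantom_spec()
  dp <- simulate_dual_phase(spec, noise = TRUE, seed = 2)
  lesion <- phantom_lesion_roi(spec, dp$early)
  pp <- quantify_patient_planar(dp$early, dp$delayed, lesion)
  scale_img <- function(img, k) planar_image(img$counts * k, img$pixel_spacing, img$time_point)
  pp2 <- quantify_patient_planar(scale_img(dp$early, 7.3), scale_img(dp$delayed, 7.3), lesion)
  for (f in c("elbr", "dlbr", "eltr", "dltr", "ri")) {
    expect_equal(pp2[[f]], pp[[f]], tolerance = 1e-12)
  }
})

test_that("a washout-free phantom has equal-phase ratios and zero RI", {
  spec <- phantom_spec(half_life = c(adenoma = Inf, thyroid = Inf, background = Inf))
  dp <- simulate_dual_phase(spec, noise = FALSE, blur = FALSE)
  pp <- quantify_patient_planar(dp$early, dp$delayed, phantom_lesion_roi(spec, dp$early))
  expect_equal(pp$elbr, pp$dlbr, tolerance = 1e-12)
  expect_equal(pp$ri, 0, tolerance = 1e-12)
})

test_that("thyroid-only washout drives RI negative", {
  # only thyroid washes out: the delayed lesion/thyroid ratio rises
  spec <- phantom_spec(half_life = c(adenoma = Inf, thyroid = 40, background = Inf))
  dp <- simulate_dual_phase(spec, noise = FALSE, blur = FALSE)
  pp <- quantify_patient_planar(dp$early, dp$delayed, phantom_lesion_roi(spec, dp$early))
  expect_gt(pp$dltr, pp$eltr)
  expect_lt(pp$ri, 0)
})

test_that("mean eLBR over 200 noisy replicates stays within 3 SE of noise-free", {
  spec <- phantom_spec(count_scale = 3)
  lesion <- phantom_lesion_roi(spec, project_planar(build_activity_volume(spec, "early")))
  noise_free <- {
    dp0 <- simulate_dual_phase(spec, noise = FALSE, blur = TRUE)
    quantify_patient_planar(dp0$early, dp0$delayed, lesion)$elbr
  }
  elbrs <- vapply(1:200, function(s) {
    dp <- simulate_dual_phase(spec, noise = TRUE, seed = 1000 + s)
    quantify_patient_planar(dp$early, dp$delayed, lesion)$elbr
  }, numeric(1))
  se <- sd(elbrs) / sqrt(length(elbrs))
  expect_lt(abs(mean(elbrs) - noise_free), 3 * se)
})
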