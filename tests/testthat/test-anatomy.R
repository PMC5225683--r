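test_that("dome rule fires after two consecutive >= 10 percent decreases", {
  # 14.1 % then 17.6 % drops -> dome two slices after the start of the fall
  expect_identical(detect_liver_dome(c(2000, 1980, 1700, 1400, 1300)), 4L)
  # boundary case: exactly 10 % decreases qualify (<= comparison)
  expect_identical(detect_liver_dome(c(1000, 900, 810, 805, 800)), 3L)
  # a single large drop flanked by plateaus does not qualify
  expect_warning(d <- detect_liver_dome(c(1000, 1000, 800, 795, 790)),
                 "not found")
  expect_true(is.na(d))
})

test_that("dome rule signals when areas never decrease", {
  expect_warning(d <- detect_liver_dome(c(100, 200, 300, 400, 500)),
                 "not found")
  expect_true(is.na(d))
  expect_error(detect_liver_dome(c(100, 200)), "3 slices")
})

test_that("dome detection is translation-invariant in slice index", {
  base <- c(2000, 1980, 1700, 1400, 1300)
  d0 <- detect_liver_dome(base)
  for (k in c(1, 3, 7))
    expect_identical(detect_liver_dome(c(rep(2100, k), base)), d0 + as.integer(k))
})

test_that("middle/last rule follows counts and the 100-pixel threshold", {
  ext <- liver_extent_from_counts(c(500, 900, 700, 300, 120, 90), dome = 10)
  expect_identical(ext$middle, 11L)     # argmax
  expect_identical(ext$last, 15L)       # first post-middle count < 100
  # all counts >= 100: last slice falls back to the final slice
  ext2 <- liver_extent_from_counts(c(500, 900, 700, 300), dome = 10)
  expect_identical(ext2$last, 13L)
  # tie in the argmax resolves to the most superior slice
  ext3 <- liver_extent_from_counts(c(500, 900, 900, 50), dome = 1)
  expect_identical(ext3$middle, 2L)
})

test_that("right lung is the low-attenuation component on patient-right", {
  sl <- matrix(40, 96, 96)
  # patient-right lung (image-left) bigger than needed, left lung smaller
  rl <- (row(sl) - 40)^2 / 18^2 + (col(sl) - 30)^2 / 12^2 <= 1
  ll <- (row(sl) - 40)^2 / 15^2 + (col(sl) - 70)^2 / 11^2 <= 1
  sl[rl] <- -700; sl[ll] <- -700
  below <- matrix(40, 96, 96)           # slice with no lung at all
  vol <- ct_volume(array(c(sl, sl, below), c(96, 96, 3)) |>
                     aperm(c(3, 1, 2)))
  body <- matrix(TRUE, 96, 96)
  lungs <- detect_lungs(vol, list(body, body, body))
  expect_equal(lungs$area[1], sum(rl))  # right lobe selected, exact area
  expect_equal(lungs$area[3], 0)        # below the lungs
  expect_true(lungs$midpoint[1, 2] < 48)  # centroid in the image-left half
  expect_true(all(lungs$masks[[1]] == rl))
})

test_that("lung detection fails loudly when no slice contains lung", {
  vol <- ct_volume(array(40, c(3, 32, 32)))
  body <- matrix(TRUE, 32, 32)
  expect_error(detect_lungs(vol, list(body, body, body)), "no lung")
})

test_that("phantom lung areas match the generator within tolerance", {
  ph <- test_phantom("healthy")
  cfg <- pipeline_config()
  nz <- dim(ph$volume)[1]
  body <- lapply(seq_len(nz), function(z) ph$masks$body[z, , ])
  lungs <- detect_lungs(ph$volume, body, lung_hu = cfg$lung_hu_threshold,
                        min_area = cfg$lung_min_area)
  gen <- ph$areas$lung_right_pixels
  pre_dome <- which(gen > 500 & seq_len(nz) < ph$spec$dome_slice)
  expect_true(all(abs(lungs$area[pre_dome] - gen[pre_dome]) /
                    gen[pre_dome] < 0.03))
  # and the analytic ellipse areas agree with the rasterized masks
  ana <- ph$areas$lung_right_analytic[pre_dome]
  expect_true(all(abs(gen[pre_dome] - ana) / ana < 0.03))
})

test_that("dome, middle and last are recovered on the phantom", {
  ph <- test_phantom("healthy")
  seg <- test_segmentation("healthy")
  expect_identical(seg$extent$dome, ph$spec$dome_slice)
  expect_lte(abs(seg$extent$middle - ph$spec$middle_slice), 1)
  expect_lte(abs(seg$extent$last - ph$spec$last_slice), 1)
  expect_true(seg$extent$dome <= seg$extent$middle)
  expect_true(seg$extent$middle <= seg$extent$last)
  expect_lte(seg$extent$last, dim(ph$volume)[1])
})
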