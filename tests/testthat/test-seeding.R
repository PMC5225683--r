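test_that("sub-grid sampling is capped, deterministic, and within the mask", {
  withr::local_seed(81)
  for (i in 1:4) {
    mask <- matrix(runif(96 * 96) < 0.6, 96, 96)
    s1 <- subgrid_sample(mask, cap = 600)
    s2 <- subgrid_sample(mask, cap = 600)
    expect_identical(s1, s2)                 # no randomness
    expect_lte(sum(s1), 600)
    expect_true(all(mask[s1]))               # subset of the candidates
  }
  small <- matrix(FALSE, 10, 10); small[3:5, 3:5] <- TRUE
  expect_identical(subgrid_sample(small, 600), small)  # under the cap: all
  expect_identical(sum(subgrid_sample(small, 0)), 0L)
})

test_that("propagated liver seeds stay in the eroded previous core", {
  prev <- matrix(FALSE, 80, 80); prev[16:65, 16:65] <- TRUE   # 50x50 square
  slice <- matrix(100, 80, 80)                                # liver HU
  body <- matrix(TRUE, 80, 80)
  cfg <- pipeline_config()
  sm <- propagate_seeds(prev, slice, body, stats = list(mean = 100, deviation = 10),
                        config = cfg)
  liver_px <- which(sm$seeds == 1L, arr.ind = TRUE)
  expect_gt(nrow(liver_px), 0)
  # erosion radius 3: all liver seeds inside the 44x44 core
  expect_true(all(liver_px[, 1] >= 19 & liver_px[, 1] <= 62))
  expect_true(all(liver_px[, 2] >= 19 & liver_px[, 2] <= 62))
  # background seeds keep their distance from the previous liver (margin
  # one pixel inside the nominal radius, tolerant of the disc kernel shape)
  m <- cfg$seed_dilation_radius - 1
  other_px <- which(sm$seeds == 2L, arr.ind = TRUE)
  expect_false(any(other_px[, 1] >= 16 - m & other_px[, 1] <= 65 + m &
                     other_px[, 2] >= 16 - m & other_px[, 2] <= 65 + m))
})

test_that("an empty previous liver signals the initial-seed fallback", {
  prev <- matrix(FALSE, 40, 40)
  slice <- matrix(40, 40, 40)
  sm <- propagate_seeds(prev, slice, matrix(TRUE, 40, 40),
                        stats = list(mean = 100, deviation = 10),
                        config = pipeline_config())
  expect_true(isTRUE(attr(sm, "empty_liver")))
  expect_identical(sum(sm$seeds), 0L)
})

test_that("initial seeds respect the template, the band, and the caps", {
  ph <- test_phantom("healthy")
  seg <- test_segmentation("healthy")
  z <- ph$spec$dome_slice + 2L
  cfg <- pipeline_config()
  pp <- preprocess_slice(ph$volume$voxels[z, , ], cfg)
  sm <- place_initial_seeds(pp$slice, seg$extent$template, pp$mask,
                            stats = list(mean = seg$extent$mean,
                                         deviation = seg$extent$deviation),
                            config = cfg)
  expect_lte(sum(sm$seeds == 1L), 600)
  expect_lte(sum(sm$seeds == 2L), 600)
  expect_lte(sum(sm$seeds > 0L), 1200)
  # every liver seed falls inside the phantom liver ground truth
  expect_true(all(ph$masks$liver[z, , ][sm$seeds == 1L]))
  # no seed outside the body
  expect_false(any(sm$seeds > 0L & !pp$mask))
})

test_that("lesion outliers are seeded as their own enclosed label", {
  withr::local_seed(91)
  slice <- matrix(rnorm(96 * 96, 100, 5), 96, 96)     # liver parenchyma
  les <- (row(slice) - 48)^2 + (col(slice) - 40)^2 <= 8^2
  slice[les] <- rnorm(sum(les), 40, 5)                # low-attenuation lesion
  region <- (row(slice) - 48)^2 / 40^2 + (col(slice) - 48)^2 / 44^2 <= 1
  base <- liverseg:::new_seed_map(matrix(0L, 96, 96))
  cfg <- pipeline_config()
  sm <- seed_lesions(base, slice, region, stats = list(mean = 100, deviation = 5),
                     config = cfg)
  lpx <- which(sm$seeds == 3L, arr.ind = TRUE)
  expect_gt(nrow(lpx), 0)
  # one cluster, centered within 3 px of the lesion center
  expect_lt(sqrt((mean(lpx[, 1]) - 48)^2 + (mean(lpx[, 2]) - 40)^2), 3)
  expect_true(all(les[sm$seeds == 3L]))
  # homogeneous liver: no lesion seeds at all
  clean <- matrix(rnorm(96 * 96, 100, 5), 96, 96)
  sm0 <- seed_lesions(base, clean, region, stats = list(mean = 100, deviation = 5),
                      config = cfg)
  expect_identical(sum(sm0$seeds == 3L), 0L)
})

test_that("every slice of every phantom run respects the seed budget", {
  for (preset in c("healthy", "multi-lesion")) {
    d <- test_segmentation(preset)$diagnostics
    expect_true(all(d$seeds_liver + d$seeds_other + d$seeds_lesion <= 1200))
    expect_true(all(d$seeds_liver + d$seeds_lesion <= 600))
    expect_true(all(d$seeds_other <= 600))
    expect_true(all(d$seeds_outside_body == 0))
  }
})
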