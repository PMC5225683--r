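test_that("De Boor evaluation equals the Cox-de Boor basis expansion", {
  withr::local_seed(21)
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(60 + 25 * sin(theta), 60 + 35 * cos(theta))
  cv <- fit_ribcage_spline(pts)
  us <- runif(20, cv$degree, nrow(pts) + cv$degree)
  for (u in us) {
    db <- deboor_point(u, cv$degree, cv$knots, cv$control)
    bs <- basis_spline_point(u, cv$degree, cv$knots, cv$control)
    expect_lt(max(abs(db - bs)), 1e-9)
  }
  # and for a couple of other degrees
  for (p in c(2, 4)) {
    n <- 7
    ctrl <- matrix(rnorm(2 * (n + p)), ncol = 2)
    knots <- 0:(nrow(ctrl) + p)
    for (u in runif(10, p, nrow(ctrl))) {
      expect_lt(max(abs(deboor_point(u, p, knots, ctrl) -
                          basis_spline_point(u, p, knots, ctrl))), 1e-9)
    }
  }
})

test_that("spline through circular centroids stays in their convex hull", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  r <- 30
  pts <- cbind(50 + r * sin(theta), 50 + r * cos(theta))
  cv <- fit_ribcage_spline(pts, dim = c(100, 100))
  d <- sqrt((cv$curve[, 1] - 50)^2 + (cv$curve[, 2] - 50)^2)
  expect_true(all(d <= r + 1e-9))       # convex-hull property
  expect_true(all(d > 0.5 * r))         # and it does not collapse inward
  # closed curve: first and last sample coincide
  expect_equal(cv$curve[1, ], cv$curve[nrow(cv$curve), ])
})

test_that("four-point square yields a positive interior below its bbox", {
  pts <- rbind(c(20, 20), c(20, 60), c(60, 60), c(60, 20))
  # order angularly around the centroid
  ctr <- colMeans(pts)
  pts <- pts[order(atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])), ]
  cv <- fit_ribcage_spline(pts, dim = c(80, 80))
  a <- sum(cv$interior)
  expect_gt(a, 0)
  expect_lt(a, 41 * 41)                 # bounding-box area
})

test_that("degenerate centroid sets are rejected", {
  line <- cbind(10:16, 2 * (10:16))     # collinear
  expect_error(fit_ribcage_spline(line), "collinear")
  expect_error(fit_ribcage_spline(rbind(c(1, 2), c(3, 4), c(5, 8))),
               "insufficient")
})

test_that("rib centroids are found to pixel accuracy and ordered by angle", {
  sb <- synthetic_body_slice(ribs = 8)
  cents <- detect_rib_centroids(sb$slice, sb$body)
  expect_true(cents$sufficient)
  expect_identical(nrow(cents$points), 8L)
  # each detected centroid within 1 px of a generated rib center
  for (i in seq_len(8)) {
    d <- sqrt(rowSums((sb$rib_centers -
                         matrix(cents$points[i, ], 8, 2, byrow = TRUE))^2))
    expect_lt(min(d), 1)
  }
  ang <- atan2(cents$points[, 1] - cents$center[1],
               cents$points[, 2] - cents$center[2])
  expect_true(all(diff(ang) > 0))       # strictly increasing polar order
})

test_that("no bone means an insufficient-centroid signal, not an error", {
  sb <- synthetic_body_slice(ribs = 0)
  cents <- detect_rib_centroids(sb$slice, sb$body)
  expect_false(cents$sufficient)
  expect_identical(nrow(cents$points), 0L)
})

test_that("touching ribs merge into a single centroid", {
  sl <- matrix(40, 64, 64)
  sl[30:34, 20:24] <- 700
  sl[33:37, 24:28] <- 700               # overlaps the first blob
  sl[10:14, 40:44] <- 700
  sl[50:54, 40:44] <- 700
  sl[30:34, 50:54] <- 700
  cents <- detect_rib_centroids(sl, matrix(TRUE, 64, 64))
  expect_identical(nrow(cents$points), 4L)   # merged pair counts once
})

test_that("masking keeps the interior and fills the exterior with air", {
  sb <- synthetic_body_slice(ribs = 8)
  cents <- detect_rib_centroids(sb$slice, sb$body)
  cv <- fit_ribcage_spline(cents, dim = dim(sb$slice))
  masked <- mask_inside_ribcage(sb$slice, cv)
  ctr <- round(sb$center)
  expect_equal(masked[ctr[1], ctr[2]], sb$slice[ctr[1], ctr[2]])  # body centroid
  expect_equal(masked[1, 1], -1000)                               # corner
  expect_true(all(masked[cv$interior] == sb$slice[cv$interior]))
  expect_true(all(masked[!cv$interior] == -1000))
  # unchanged pixel count equals the interior mask area (no -1000 inside)
  expect_identical(sum(masked != -1000), sum(cv$interior & sb$slice != -1000))
})

test_that("neighbor-centroid pooling rescues rib-poor slices", {
  sb8 <- synthetic_body_slice(ribs = 8)
  sb2 <- synthetic_body_slice(ribs = 2)
  c8 <- detect_rib_centroids(sb8$slice, sb8$body)
  c2 <- detect_rib_centroids(sb2$slice, sb2$body)
  expect_false(c2$sufficient)
  pooled <- fallback_centroids(list(c8, c8, c2))
  expect_gte(nrow(pooled$points), 8)
  expect_true(pooled$sufficient)

  slices <- list(sb8$slice, sb2$slice, sb8$slice)
  bodies <- list(sb8$body, sb2$body, sb8$body)
  out <- ribcage_interiors(slices, bodies, pipeline_config())
  expect_true(out$fallback_used[2])
  # fallback restores a comparable interior area
  expect_gte(out$areas[2], 0.8 * mean(out$areas[c(1, 3)]))
})

test_that("all slices rib-poor passes through unmasked with a warning", {
  sb2 <- synthetic_body_slice(ribs = 2)
  w <- capture_warnings(
    out <- ribcage_interiors(list(sb2$slice, sb2$slice),
                             list(sb2$body, sb2$body), pipeline_config()))
  expect_true(all(grepl("unmasked", w)))   # one warning per affected slice
  expect_length(w, 2)
  expect_identical(out$interiors[[1]], sb2$body)
})
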