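test_that("edge weights follow the Gaussian intensity and spatial forms", {
  p0 <- rw_params(beta = 1, omega = 0, use_spatial = FALSE)
  expect_equal(edge_weight(0.4, 0.4, c(1, 1), c(1, 2), p0), 1)    # equal g
  expect_equal(edge_weight(0, 1, c(1, 1), c(1, 2), p0), exp(-1))
  pb0 <- rw_params(beta = 0, omega = 0, use_spatial = FALSE)
  expect_equal(edge_weight(0.1, 0.9, c(1, 1), c(1, 2), pb0), 1)   # beta = 0
  ps <- rw_params(beta = 0, omega = 0, use_spatial = TRUE, lambda_s = 2)
  expect_equal(edge_weight(0, 0, c(1, 1), c(2, 2), ps), exp(-2 / 2))
  pw <- rw_params(beta = 1, omega = 0.5, use_spatial = FALSE)
  expect_equal(edge_weight(0, 1, c(1, 1), c(1, 2), pw), exp(-1) + 0.5)
  expect_error(rw_params(lambda_s = 0), "lambda_s")
  expect_error(rw_params(beta = -1))
})

test_that("grid graphs have the expected edge counts and corner degrees", {
  img <- matrix(0.5, 3, 3)
  seeds <- matrix(0L, 3, 3); seeds[1, 1] <- 1L
  g4 <- build_pixel_graph(img, seeds, rw_params(connectivity = 4))
  expect_identical(nrow(g4$edges), 12L)       # 2mn - m - n
  g8 <- build_pixel_graph(img, seeds, rw_params(connectivity = 8))
  expect_identical(nrow(g8$edges), 20L)       # + 2(m-1)(n-1) diagonals
  # corner node (node id of pixel (1,1)) has 2 incident edges under 4-conn
  corner <- g4$node_index[1, 1]
  expect_identical(sum(g4$edges == corner), 2L)
  # weights symmetric positive, degrees are incident-weight sums
  expect_true(all(g8$weights > 0))
  i <- 5L
  expect_equal(g8$degrees[i],
               sum(g8$weights[g8$edges[, 1] == i | g8$edges[, 2] == i]))
  # Laplacian rows sum to zero
  expect_lt(max(abs(Matrix::rowSums(graph_laplacian(g8)))), 1e-12)
})

test_that("missing seeds are rejected; label without seeds is dropped", {
  img <- matrix(0.5, 3, 3)
  expect_error(build_pixel_graph(img, matrix(0L, 3, 3)), "seeds")
  seeds <- matrix(0L, 3, 3); seeds[1, 1] <- 1L; seeds[3, 3] <- 2L
  g <- build_pixel_graph(img, seeds)
  expect_warning(p <- solve_probabilities(g, labels = c(1, 2, 9)), "no seeds")
  expect_identical(p$labels, c(1L, 2L))
})

test_that("uniform chain with end seeds gives the exact linear solution", {
  img <- matrix(0.5, 5, 1)
  seeds <- matrix(0L, 5, 1); seeds[1, 1] <- 1L; seeds[5, 1] <- 2L
  res <- random_walker(img, seeds,
                       rw_params(beta = 0, omega = 0, use_spatial = FALSE,
                                 connectivity = 4))
  expect_equal(res$probs$probs[, 1], c(1, 0.75, 0.5, 0.25, 0),
               tolerance = 1e-10)
  # argmax labelling: the middle node ties at 0.5 and goes to label 1
  expect_identical(as.integer(res$labels), c(1L, 1L, 1L, 2L, 2L))
})

test_that("fully seeded and single-label cases degenerate correctly", {
  img <- matrix(runif(9), 3, 3)
  seeds <- matrix(rep(c(1L, 2L, 1L), 3), 3, 3)
  p <- solve_probabilities(build_pixel_graph(img, seeds))
  expect_true(all(p$probs %in% c(0, 1)))      # one-hot everywhere
  expect_identical(assign_labels(p), seeds)
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  p1 <- solve_probabilities(build_pixel_graph(img, one))
  expect_true(all(p1$probs == 1))             # complement rule, single label
})

test_that("sparse block solve matches the dense constrained oracle", {
  withr::local_seed(31)
  for (i in 1:8) {
    cs <- random_rw_case(maxdim = 9)
    res <- random_walker(cs$image, cs$seeds, cs$params)
    orc <- dense_rw_oracle(cs$image, cs$seeds, beta = cs$params$beta,
                           omega = cs$params$omega,
                           lambda_s = cs$params$lambda_s,
                           connectivity = cs$params$connectivity,
                           use_spatial = cs$params$use_spatial)
    expect_lt(max(abs(res$probs$probs - orc$probs)), 1e-7)
  }
})

test_that("solutions are normalized and harmonic (neighbor-hull bound)", {
  withr::local_seed(41)
  for (i in 1:6) {
    cs <- random_rw_case(maxdim = 8)
    g <- build_pixel_graph(cs$image, cs$seeds, cs$params)
    p <- solve_probabilities(g)
    expect_lt(max(abs(rowSums(p$probs) - 1)), 1e-8)
    expect_true(all(p$probs >= -1e-10 & p$probs <= 1 + 1e-10))
    nb <- lapply(seq_along(g$pixel_index), function(j) integer(0))
    for (e in seq_len(nrow(g$edges))) {
      a <- g$edges[e, 1]; b <- g$edges[e, 2]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
    for (v in which(g$seeds == 0L)) {
      for (li in seq_along(p$labels)) {
        vals <- p$probs[nb[[v]], li]
        expect_gte(p$probs[v, li], min(vals) - 1e-9)
        expect_lte(p$probs[v, li], max(vals) + 1e-9)
      }
    }
  }
})

test_that("an unseeded component cut off by zero weights gets uniform P", {
  img <- matrix(0.5, 1, 5)
  seeds <- matrix(0L, 1, 5); seeds[1, 1] <- 1L; seeds[1, 2] <- 2L
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 1, 5)
  g <- build_pixel_graph(img, seeds, rw_params(omega = 0, connectivity = 4),
                         mask = mask)
  expect_warning(p <- solve_probabilities(g), "disconnected")
  # the isolated pair (nodes 3 and 4) carries uniform probabilities
  un <- p$probs[3:4, ]
  expect_true(all(abs(un - 0.5) < 1e-12))
  # the seeded component stays one-hot
  expect_equal(p$probs[1, ], c(`1` = 1, `2` = 0))
})

test_that("increasing beta hardens a step edge against crossing", {
  img <- matrix(0.8, 16, 16); img[, 1:8] <- 0.2
  seeds <- matrix(0L, 16, 16)
  seeds[8, 2] <- 1L                     # deep on the dark side
  seeds[8, 9] <- 2L                     # just over the step
  truth <- matrix(2L, 16, 16); truth[, 1:8] <- 1L
  cons <- vapply(c(0, 0.1, 1, 10, 100), function(b) {
    res <- random_walker(img, seeds,
                         rw_params(beta = b, omega = 0, use_spatial = FALSE,
                                   connectivity = 4))
    mean(res$labels == truth)
  }, numeric(1))
  expect_true(all(diff(cons) >= 0))
  expect_lt(cons[1], 1)                 # beta = 0: distance-driven labels
  expect_equal(cons[5], 1)              # strong contrast term wins
})

test_that("probability images rebuild image geometry with masked NAs", {
  img <- matrix(runif(20), 4, 5)
  seeds <- matrix(0L, 4, 5); seeds[1, 1] <- 1L; seeds[4, 5] <- 2L
  mask <- matrix(TRUE, 4, 5); mask[2, 2] <- FALSE
  res <- random_walker(img, seeds, rw_params(), mask = mask)
  pim <- probability_images(res$probs)
  expect_identical(names(pim), c("1", "2"))
  expect_true(is.na(pim[["1"]][2, 2]))
  expect_equal(pim[["1"]][1, 1], 1)
  ok <- !is.na(pim[["1"]])
  expect_equal(pim[["1"]][ok] + pim[["2"]][ok], rep(1, sum(ok)),
               tolerance = 1e-8)
})
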