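# Shared phantom fixtures and cached end-to-end runs. The reduced
# 40 x 256 x 256 shape keeps full-pipeline tests fast while preserving all
# anatomy the pipeline's rules key on.

.phantom_cache <- new.env(parent = emptyenv())

test_phantom <- function(preset = "healthy", shape = c(40, 256, 256),
                         seed = 7) {
  key <- paste("ph", preset, paste(shape, collapse = "x"), seed, sep = "_")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(
      phantom_preset(preset, shape = shape, seed = seed))
  .phantom_cache[[key]]
}

# memoized end-to-end segmentation of a preset phantom
test_segmentation <- function(preset = "healthy", shape = c(40, 256, 256),
                              seed = 7) {
  key <- paste("seg", preset, paste(shape, collapse = "x"), seed, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    ph <- test_phantom(preset, shape, seed)
    .phantom_cache[[key]] <- segment_series(ph$volume)
  }
  .phantom_cache[[key]]
}

# memoized run that also retains the per-label probability images
segment_series_cached_probs <- function(ph, cfg = pipeline_config()) {
  key <- paste("segprob", ph$spec$seed, paste(ph$spec$shape, collapse = "x"),
               sep = "_")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- segment_series(ph$volume, cfg,
                                            keep_probabilities = TRUE)
  .phantom_cache[[key]]
}

# interior of a mask, for assertions tolerant of 1-2 px boundary effects
shrink_test_mask <- function(mask, radius = 2) liverseg:::disc_erode(mask, radius)

# tiny phantom for I/O tests (geometry compressed into 16 slices)
small_phantom <- function(seed = 3, noise = TRUE) {
  key <- paste("small", seed, noise, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    sp <- phantom_spec(shape = c(16, 64, 64), dome_slice = 5,
                       middle_slice = 8, last_slice = 13, seed = seed)
    if (!noise) sp$noise_sd <- lapply(sp$noise_sd, function(x) 0)
    .phantom_cache[[key]] <- generate_phantom(sp)
  }
  .phantom_cache[[key]]
}

# small synthetic body slice used by preprocess/ribcage unit tests
synthetic_body_slice <- function(dim = c(128, 128), ribs = 8,
                                 with_table = FALSE, lung = FALSE) {
  sl <- matrix(-1000, dim[1], dim[2])
  ctr <- dim / 2
  semi <- c(0.58, 0.78) * dim / 2
  body <- ((row(sl) - ctr[1]) / semi[1])^2 + ((col(sl) - ctr[2]) / semi[2])^2 <= 1
  sl[body] <- 40
  if (with_table) {
    # thin detached arc below the body, like an imaging table
    tr <- round(dim[1] * 0.93)
    sl[tr:(tr + 1), round(dim[2] * 0.2):round(dim[2] * 0.8)] <- 200
  }
  rib_pts <- NULL
  if (ribs > 0) {
    ang <- seq(0, 2 * pi, length.out = ribs + 1)[-(ribs + 1)]
    ring <- 0.88 * semi
    for (a in ang) {
      rc <- ctr + c(ring[1] * sin(a), ring[2] * cos(a))
      rib <- ((row(sl) - rc[1]) / 3)^2 + ((col(sl) - rc[2]) / 2.2)^2 <= 1
      sl[rib & body] <- 700
      rib_pts <- rbind(rib_pts, rc)
    }
  }
  if (lung) {
    lm <- ((row(sl) - ctr[1] * 0.8) / (0.22 * dim[1]))^2 +
      ((col(sl) - ctr[2] * 0.6) / (0.16 * dim[2]))^2 <= 1
    sl[lm & body] <- -700
  }
  list(slice = sl, body = body, center = ctr, body_semi = semi,
       rib_centers = rib_pts)
}
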