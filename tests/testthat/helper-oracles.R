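# Independent oracles used across the suite. These re-derive expected
# values from first principles (dense linear algebra, exhaustive loops,
# textbook basis functions) and never call the code paths they check.

# Dense constrained Dirichlet solve: builds the weight matrix with its own
# neighbor loops and solves the full Laplacian system with seed rows
# replaced by identity rows.
dense_rw_oracle <- function(image, seeds, beta, omega = 1e-6, lambda_s = 2,
                            connectivity = 8, use_spatial = TRUE) {
  m <- nrow(image); n <- ncol(image)
  N <- m * n
  id <- function(r, c) (c - 1L) * m + r
  W <- matrix(0, N, N)
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  for (r in 1:m) for (c in 1:n) for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    if (r2 < 1 || r2 > m || c2 < 1 || c2 > n) next
    w <- exp(-beta * (image[r, c] - image[r2, c2])^2)
    if (use_spatial) w <- w * exp(-(o[1]^2 + o[2]^2) / lambda_s)
    w <- w + omega
    W[id(r, c), id(r2, c2)] <- w
    W[id(r2, c2), id(r, c)] <- w
  }
  L <- diag(rowSums(W)) - W
  svec <- as.integer(seeds)
  labs <- sort(unique(svec[svec > 0]))
  P <- matrix(0, N, length(labs))
  sidx <- which(svec > 0)
  for (li in seq_along(labs)) {
    A <- L; b <- rep(0, N)
    for (s in sidx) {
      A[s, ] <- 0; A[s, s] <- 1
      b[s] <- as.numeric(svec[s] == labs[li])
    }
    P[, li] <- solve(A, b)
  }
  list(probs = P, labels = labs,
       labels_img = matrix(labs[max.col(P, ties.method = "first")], m, n))
}

# random seeded test image for the solver checks
random_rw_case <- function(maxdim = 12, max_labels = 4) {
  m <- sample(2:maxdim, 1); n <- sample(2:maxdim, 1)
  image <- matrix(runif(m * n), m, n)
  k <- sample(2:max_labels, 1)
  seeds <- matrix(0L, m, n)
  pos <- sample(m * n, min(m * n, k + sample(0:4, 1)))
  seeds[pos] <- c(seq_len(k), sample(seq_len(k), length(pos) - k, replace = TRUE))
  params <- rw_params(beta = runif(1, 0, 50), omega = 10^runif(1, -8, -2),
                      lambda_s = runif(1, 0.5, 5),
                      connectivity = sample(c(4, 8), 1),
                      use_spatial = sample(c(TRUE, FALSE), 1))
  list(image = image, seeds = seeds, params = params)
}

# brute-force 3x3 median with in-bounds border handling
brute_median3 <- function(x) {
  m <- nrow(x); n <- ncol(x)
  out <- x
  for (r in 1:m) for (c in 1:n) {
    rr <- max(1, r - 1):min(m, r + 1)
    cc <- max(1, c - 1):min(n, c + 1)
    out[r, c] <- median(x[rr, cc])
  }
  out
}

# brute-force grayscale erosion/dilation under a disc, for the top-hat oracle
brute_hat_enhance <- function(x, radius) {
  m <- nrow(x); n <- ncol(x)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  # EBImage disc brush of size 2r+1: points with distance < r + 0.5
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) < radius + 0.5, ]
  filt <- function(f) {
    out <- x
    for (r in 1:m) for (c in 1:n) {
      vals <- c()
      for (i in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[i]; c2 <- c + offs$dc[i]
        if (r2 >= 1 && r2 <= m && c2 >= 1 && c2 <= n) vals <- c(vals, x[r2, c2])
      }
      out[r, c] <- f(vals)
    }
    out
  }
  ero <- filt(min); dil <- filt(max)
  # opening = dilate(erode), closing = erode(dilate), each with the same disc
  redil <- ero; reero <- dil
  for (r in 1:m) for (c in 1:n) {
    vals_o <- c(); vals_c <- c()
    for (i in seq_len(nrow(offs))) {
      r2 <- r + offs$dr[i]; c2 <- c + offs$dc[i]
      if (r2 >= 1 && r2 <= m && c2 >= 1 && c2 <= n) {
        vals_o <- c(vals_o, ero[r2, c2]); vals_c <- c(vals_c, dil[r2, c2])
      }
    }
    redil[r, c] <- max(vals_o); reero[r, c] <- min(vals_c)
  }
  tophat <- x - redil
  bottomhat <- reero - x
  x + tophat - bottomhat
}

# brute-force confusion tally
brute_confusion <- function(a, b) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(a)) {
    if (a[i] != 0 && b[i] != 0) tp <- tp + 1L
    else if (a[i] != 0) fp <- fp + 1L
    else if (b[i] != 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Cox-de Boor basis expansion via splines::splineDesign (independent of the
# package's De Boor recursion)
basis_spline_point <- function(u, degree, knots, ctrl) {
  B <- splines::splineDesign(knots, u, ord = degree + 1, outer.ok = TRUE)
  as.numeric(B %*% ctrl)
}
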