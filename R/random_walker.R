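# Seeded multi-label random-walker segmentation: weighted pixel graph,
# combinatorial Laplacian, and the Dirichlet solve for label probabilities.

#' Random-walker parameters
#'
#' @param beta contrast scaling of the intensity weight
#'   `exp(-beta * (g_i - g_j)^2)`; larger beta makes intensity edges harder
#'   to cross. Intensities are expected in \[0, 1\].
#' @param omega regularization added to every edge weight so all edges stay
#'   crossable (an additive floor penalizing the gradient norm); 0 disables.
#' @param lambda_s scale of the spatial proximity term
#'   `exp(-dist^2 / lambda_s)`; must be > 0 when `use_spatial`.
#' @param connectivity pixel neighborhood, 4 or 8.
#' @param use_spatial multiply the intensity weight by the spatial term.
#' @param tol relative residual tolerance for iterative fallback solves.
#' @return object of class `rw_params`.
#' @export
rw_params <- function(beta = 600, omega = 1e-6, lambda_s = 2,
                      connectivity = 8, use_spatial = TRUE, tol = 1e-8) {
  stopifnot(beta >= 0, omega >= 0, connectivity %in% c(4, 8))
  if (use_spatial && lambda_s <= 0) stop("lambda_s must be > 0 when use_spatial")
  structure(list(beta = beta, omega = omega, lambda_s = lambda_s,
                 connectivity = as.integer(connectivity),
                 use_spatial = isTRUE(use_spatial), tol = tol),
            class = "rw_params")
}

#' Edge weight between two pixels
#'
#' Intensity term `w = exp(-beta (g_i - g_j)^2)` (the Grady weighting),
#' optionally multiplied by the spatial proximity term
#' `w_s = exp(-((x_i-x_j)^2 + (y_i-y_j)^2) / lambda_s)`, plus the additive
#' regularization floor `omega`.
#'
#' @param g_i,g_j pixel intensities (vectors allowed).
#' @param p_i,p_j two-column matrices (or length-2 vectors) of pixel
#'   coordinates.
#' @param params [rw_params()].
#' @return numeric weights, elementwise over the inputs.
#' @export
edge_weight <- function(g_i, g_j, p_i, p_j, params = rw_params()) {
  stopifnot(inherits(params, "rw_params"))
  w <- exp(-params$beta * (g_i - g_j)^2)
  if (params$use_spatial) {
    p_i <- matrix(p_i, ncol = 2); p_j <- matrix(p_j, ncol = 2)
    d2 <- (p_i[, 1] - p_j[, 1])^2 + (p_i[, 2] - p_j[, 2])^2
    w <- w * exp(-d2 / params$lambda_s)
  }
  w + params$omega
}

#' Build the weighted pixel graph for a seeded image
#'
#' One node per pixel (optionally restricted to a mask); undirected edges
#' between 4- or 8-neighbors with weights from [edge_weight()]. Records the
#' seeded/unseeded node partition used by the Dirichlet solve.
#'
#' @param image 2D numeric matrix, intensities in \[0, 1\].
#' @param seeds integer matrix, same shape: 0 = unseeded, >0 = label id.
#' @param params [rw_params()].
#' @param mask optional logical matrix restricting the graph to a pixel
#'   subset (e.g. the ribcage interior); seeds outside the mask are ignored.
#' @return object of class `pixel_graph`: node bookkeeping, edge list with
#'   weights, node degrees, per-node seed labels.
#' @export
build_pixel_graph <- function(image, seeds, params = rw_params(), mask = NULL) {
  stopifnot(is.matrix(image), is.matrix(seeds),
            all(dim(image) == dim(seeds)), inherits(params, "rw_params"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(all(dim(mask) == dim(image)))
  mask <- mask != 0
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) stop("empty graph: mask excludes every pixel")
  nid <- matrix(0L, nrow(image), ncol(image))
  nid[idx] <- seq_len(n)
  seed_vec <- as.integer(seeds[idx])
  labs <- sort(unique(seed_vec[seed_vec > 0L]))
  if (length(labs) == 0L) stop("missing seeds: at least one labeled pixel required")

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (params$connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rc <- arrayInd(idx, dim(image))
  ei <- ej <- integer(0); gi <- gj <- numeric(0); d2 <- numeric(0)
  for (off in offsets) {
    nb <- shift_mat(nid, off[1], off[2], fill = 0L)
    keep <- which(nid > 0L & nb > 0L)
    if (!length(keep)) next
    a <- nid[keep]; b <- nb[keep]
    ei <- c(ei, a); ej <- c(ej, b)
    gi <- c(gi, image[idx[a]]); gj <- c(gj, image[idx[b]])
    d2 <- c(d2, rep(sum(off^2), length(a)))
  }
  w <- exp(-params$beta * (gi - gj)^2)
  if (params$use_spatial) w <- w * exp(-d2 / params$lambda_s)
  w <- w + params$omega

  deg <- numeric(n)
  if (length(ei)) {
    t1 <- tapply(w, ei, sum); t2 <- tapply(w, ej, sum)
    deg[as.integer(names(t1))] <- deg[as.integer(names(t1))] + t1
    deg[as.integer(names(t2))] <- deg[as.integer(names(t2))] + t2
  }
  structure(
    list(dim = dim(image), mask = mask, node_index = nid, pixel_index = idx,
         coords = rc, edges = cbind(i = ei, j = ej), weights = w,
         degrees = deg, seeds = seed_vec, labels = labs, params = params),
    class = "pixel_graph"
  )
}

#' @export
print.pixel_graph <- function(x, ...) {
  cat(sprintf("<pixel_graph> %d nodes, %d edges, labels {%s}, %d seeded\n",
              length(x$pixel_index), nrow(x$edges),
              paste(x$labels, collapse = ","), sum(x$seeds > 0)))
  invisible(x)
}

#' Sparse combinatorial Laplacian of a pixel graph
#'
#' `L = D - W` with node degrees `d_v` on the diagonal and the negated edge
#' weights off-diagonal; rows sum to zero.
#'
#' @param graph a [build_pixel_graph()] result.
#' @return sparse symmetric `Matrix`.
#' @export
graph_laplacian <- function(graph) {
  n <- length(graph$pixel_index)
  e <- graph$edges; w <- graph$weights
  W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(w, w), dims = c(n, n))
  Matrix::Diagonal(x = graph$degrees) - W
}

#' Solve the combinatorial Dirichlet problem for label probabilities
#'
#' For each label the harmonic extension of the one-hot seed indicator is
#' obtained from the seeded/unseeded block decomposition of the Laplacian:
#' `L_U x_U = -B^T m`, a sparse symmetric positive-definite system solved by
#' Cholesky factorization (factorized once, reused across labels). Only
#' `L - 1` systems are solved; the last label's probabilities follow from
#' the unit-sum complement. Unseeded components with no path of positive
#' weight to any seed (possible only when `omega = 0`) receive uniform
#' probabilities and a warning.
#'
#' @param graph a [build_pixel_graph()] result.
#' @param labels optional integer label set; defaults to the labels present
#'   in the graph's seeds. Labels without seeds are dropped with a warning.
#' @return object of class `label_probabilities`: matrix `probs`
#'   (nodes x labels, rows summing to 1), the label set, graph geometry, and
#'   the maximum relative solver residual.
#' @export
solve_probabilities <- function(graph, labels = NULL) {
  stopifnot(inherits(graph, "pixel_graph"))
  if (is.null(labels)) labels <- graph$labels
  labels <- sort(unique(as.integer(labels)))
  present <- labels %in% graph$seeds
  if (any(!present)) {
    warning("dropping labels with no seeds: ",
            paste(labels[!present], collapse = ", "))
    labels <- labels[present]
  }
  if (length(labels) == 0L) stop("no seeded labels to solve for")
  n <- length(graph$pixel_index)
  k <- length(labels)
  probs <- matrix(0, n, k, dimnames = list(NULL, labels))
  seeded <- which(graph$seeds > 0L)
  unseeded <- which(graph$seeds == 0L)
  for (li in seq_len(k)) probs[graph$seeds == labels[li], li] <- 1
  residual <- 0

  if (length(unseeded) > 0L) {
    if (k == 1L) {
      probs[unseeded, 1] <- 1   # single label: complement rule gives 1
    } else {
      # unseeded nodes unreachable through positive-weight edges (isolated
      # mask blobs, or zero weights when omega = 0) get uniform P; they must
      # also leave the linear system, which would otherwise be singular
      pos <- graph$weights > 0
      g <- igraph::make_empty_graph(n = n, directed = FALSE)
      if (any(pos)) g <- igraph::add_edges(g, t(graph$edges[pos, , drop = FALSE]))
      memb <- igraph::components(g)$membership
      seeded_comps <- unique(memb[seeded])
      iso <- unseeded[!(memb[unseeded] %in% seeded_comps)]
      if (length(iso)) {
        warning(length(iso), " unseeded node(s) disconnected from all seeds; ",
                "assigned uniform probabilities")
        probs[iso, ] <- 1 / k
      }
      u <- setdiff(unseeded, iso)
      if (length(u) > 0L) {
        L <- graph_laplacian(graph)
        LU <- L[u, u, drop = FALSE]
        B <- L[seeded, u, drop = FALSE]     # seeded-unseeded coupling block
        M <- matrix(0, length(seeded), k - 1L)
        for (li in seq_len(k - 1L))
          M[, li] <- as.numeric(graph$seeds[seeded] == labels[li])
        rhs <- -Matrix::crossprod(B, M)     # -B^T m, one column per label
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(LU), LDL = FALSE)
        X <- as.matrix(Matrix::solve(ch, rhs))
        rn <- sqrt(Matrix::colSums((LU %*% X - rhs)^2))
        bn <- sqrt(Matrix::colSums(rhs^2))
        residual <- max(ifelse(bn > 0, rn / bn, 0))
        X <- pmin(pmax(X, 0), 1)
        probs[u, seq_len(k - 1L)] <- X
        probs[u, k] <- pmax(0, 1 - rowSums(X))
      }
    }
  }
  structure(
    list(probs = probs, labels = labels, dim = graph$dim,
         mask = graph$mask, pixel_index = graph$pixel_index,
         seeds = graph$seeds, residual = residual),
    class = "label_probabilities"
  )
}

#' @export
print.label_probabilities <- function(x, ...) {
  cat(sprintf("<label_probabilities> %d nodes x %d labels, max residual %.3g\n",
              nrow(x$probs), length(x$labels), x$residual))
  invisible(x)
}

#' Per-label probability images
#'
#' Expands the per-node probabilities back to image geometry, one matrix per
#' label (the grayscale probability maps); pixels outside the graph mask
#' are `NA`.
#'
#' @param probs a [solve_probabilities()] result.
#' @return named list of matrices, one per label.
#' @export
probability_images <- function(probs) {
  stopifnot(inherits(probs, "label_probabilities"))
  out <- lapply(seq_along(probs$labels), function(li) {
    m <- matrix(NA_real_, probs$dim[1], probs$dim[2])
    m[probs$pixel_index] <- probs$probs[, li]
    m
  })
  names(out) <- probs$labels
  out
}

#' Assign each pixel the maximum-probability label
#'
#' Argmax over labels per node; ties break to the lowest label id; seeded
#' pixels keep their seed label. Pixels outside the graph mask get 0.
#'
#' @param probs a [solve_probabilities()] result.
#' @return integer label matrix in image geometry.
#' @export
assign_labels <- function(probs) {
  stopifnot(inherits(probs, "label_probabilities"))
  # probabilities within ~1e-12 count as ties and go to the lowest label
  # (an exact 0.5/0.5 split must not flip on rounding noise)
  k <- ncol(probs$probs)
  biased <- sweep(probs$probs, 2, (seq_len(k) - 1) * 1e-12, `-`)
  win <- max.col(biased, ties.method = "first")
  lab <- probs$labels[win]
  lab[probs$seeds > 0L] <- probs$seeds[probs$seeds > 0L]
  out <- matrix(0L, probs$dim[1], probs$dim[2])
  out[probs$pixel_index] <- as.integer(lab)
  out
}

#' Segment one seeded image with the random walker
#'
#' Convenience wrapper: graph construction, Dirichlet solve, argmax
#' labelling.
#'
#' @inheritParams build_pixel_graph
#' @return list `labels` (integer matrix), `probs`
#'   ([solve_probabilities()] result), `residual`.
#' @export
random_walker <- function(image, seeds, params = rw_params(), mask = NULL) {
  g <- build_pixel_graph(image, seeds, params, mask)
  p <- solve_probabilities(g)
  list(labels = assign_labels(p), probs = p, residual = p$residual)
}
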