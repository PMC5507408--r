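# Independent oracles used across the test files. These deliberately use
# different algorithms from the package internals.

# Brute-force BFS flood fill returning the largest 6-connected component
# of a 0/1 array as a 0/1 array.
flood_fill_largest <- function(arr) {
  d <- dim(arr)
  visited <- array(FALSE, d)
  best <- NULL
  best_size <- 0
  idx_of <- function(z, y, x) cbind(z, y, x)
  for (start in which(arr == 1 & !visited)) {
    z0 <- (start - 1) %% d[1] + 1
    y0 <- ((start - 1) %/% d[1]) %% d[2] + 1
    x0 <- (start - 1) %/% (d[1] * d[2]) + 1
    if (visited[z0, y0, x0]) next
    comp <- list()
    queue <- list(c(z0, y0, x0))
    visited[z0, y0, x0] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      comp[[length(comp) + 1]] <- v
      for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        w <- v + s
        if (any(w < 1) || any(w > d)) next
        if (arr[w[1], w[2], w[3]] == 1 && !visited[w[1], w[2], w[3]]) {
          visited[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    if (length(comp) > best_size) {
      best_size <- length(comp)
      best <- comp
    }
  }
  out <- array(0L, d)
  for (v in best) out[v[1], v[2], v[3]] <- 1L
  out
}

# Dense direct FE solve: assemble the full stiffness from the shared
# element matrix, apply Dirichlet conditions by elimination, solve with
# base R's dense solver.
dense_fe_solve <- function(mesh, params, bc) {
  Ke <- element_stiffness(params, mesh$voxel_size)
  ndof <- 3 * mesh$n_node
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(mesh$n_elem)) {
    dofs <- as.vector(t(cbind(3 * (mesh$elem_nodes[e, ] - 1) + 1,
                              3 * (mesh$elem_nodes[e, ] - 1) + 2,
                              3 * (mesh$elem_nodes[e, ] - 1) + 3)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  u <- numeric(ndof)
  cdof <- as.vector(t(cbind(3 * (bc$nodes - 1) + 1, 3 * (bc$nodes - 1) + 2,
                            3 * (bc$nodes - 1) + 3)))
  u[3 * (bc$nodes - 1) + 1] <- bc$u[, 1]
  u[3 * (bc$nodes - 1) + 2] <- bc$u[, 2]
  u[3 * (bc$nodes - 1) + 3] <- bc$u[, 3]
  free <- setdiff(seq_len(ndof), cdof)
  u[free] <- solve(K[free, free], -K[free, cdof] %*% u[cdof])
  matrix(u, mesh$n_node, 3, byrow = TRUE)
}

# Leave-one-out Cook's distance for simple linear regression:
# D_i = sum_j (yhat_j - yhat_j(-i))^2 / (p * s^2), p = 2.
cooks_loo <- function(x, y) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  yhat <- stats::fitted(fit)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    f2 <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- stats::coef(f2)[1] + stats::coef(f2)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, 1)
}

# Random face-connected voxel blob (largest component of thresholded
# smoothed noise), guaranteed nonempty.
random_connected_blob <- function(dims, fill = 0.3, seed = 1) {
  arr <- vertfe:::with_seed(seed, {
    noise <- array(stats::runif(prod(dims)), dims)
    array(as.integer(noise < fill), dims)
  })
  flood_fill_largest(arr)
}

# Standard small phantom used by several DVC tests (built once per run).
dvc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(dims = c(40, 40, 40), noise_sigma = 0,
                           blur_sigma = 1.0, seed = 7)
      p <- generate_phantom(spec)
      mask <- trim_mask_border(
        build_mask(p$grey, vertfe:::default_low_threshold(p$grey), 2), 4)
      grid <- dvc_grid(p$grey, ns = 8)
      supp <- dvc_node_support(grid, mask)
      cache <<- list(spec = spec, phantom = p, mask = mask, grid = grid,
                     well = supp >= 0.25 * 8^3,
                     nodes = vertfe:::grid_node_coords(grid))
    }
    cache
  }
})
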