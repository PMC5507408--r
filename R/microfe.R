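#' Elastic material parameters for bone tissue
#'
#' Homogeneous isotropic linear elasticity assigned to every bone element.
#' The defaults are the literature tissue modulus for vertebral bone from
#' wet microindentation (12.0 GPa) and Poisson's ratio 0.3; a back-calculated
#' modulus (see [back_calculate_modulus()]) is typically around 4.6 GPa for
#' this kind of model.
#'
#' @param e_t Tissue elastic modulus, GPa (> 0).
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @return An `elastic_params` list.
#' @export
elastic_params <- function(e_t = 12.0, nu = 0.3) {
  if (e_t <= 0) stop("`e_t` must be > 0 (GPa)", call. = FALSE)
  if (nu < 0 || nu >= 0.5)
    stop("`nu` must be in [0, 0.5); the incompressible limit is not supported",
         call. = FALSE)
  structure(list(e_t = e_t, nu = nu), class = "elastic_params")
}

#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' Standard 8-node hexahedral stiffness for an isotropic material,
#' integrated with 2x2x2 Gauss quadrature. All elements of a voxel mesh are
#' identical cubes with identical material, so a single 24 x 24 matrix is
#' shared by the whole model. Degree-of-freedom order is node-major with
#' components (x, y, z); the local node order is the voxel-corner circuit
#' (0,0,0), (1,0,0), (1,1,0), (0,1,0), (0,0,1), (1,0,1), (1,1,1), (0,1,1)
#' in (x, y, z) offsets. Units: displacements um, forces N (E in GPa is
#' converted to N/um^2 internally).
#'
#' @param params [elastic_params()].
#' @param voxel_size Element edge length, um.
#' @return A symmetric 24 x 24 matrix (N/um).
#' @export
element_stiffness <- function(params, voxel_size) {
  stopifnot(inherits(params, "elastic_params"))
  E <- params$e_t * 1e-3  # GPa -> N/um^2
  nu <- params$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  h <- voxel_size
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 24, 24)
  offs <- hex_local_offsets()
  for (gx in gp) for (gy in gp) for (gz in gp) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      sx <- 2 * offs[a, 1] - 1; sy <- 2 * offs[a, 2] - 1
      sz <- 2 * offs[a, 3] - 1
      # dN/dx_i at (gx, gy, gz); dxi/dx = 2/h
      dNx <- sx * (1 + gy * sy) * (1 + gz * sz) / 8 * 2 / h
      dNy <- sy * (1 + gx * sx) * (1 + gz * sz) / 8 * 2 / h
      dNz <- sz * (1 + gx * sx) * (1 + gy * sy) / 8 * 2 / h
      col <- 3 * (a - 1)
      B[1, col + 1] <- dNx
      B[2, col + 2] <- dNy
      B[3, col + 3] <- dNz
      B[4, col + 1] <- dNy; B[4, col + 2] <- dNx
      B[5, col + 2] <- dNz; B[5, col + 3] <- dNy
      B[6, col + 1] <- dNz; B[6, col + 3] <- dNx
    }
    K <- K + t(B) %*% D %*% B * (h / 2)^3
  }
  (K + t(K)) / 2
}

# local node offsets in (x, y, z), rows = local nodes 1..8
hex_local_offsets <- function() {
  matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
           0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
         ncol = 3, byrow = TRUE)
}

#' Build the voxel hexahedral mesh
#'
#' Converts every bone voxel of a (connectivity-filtered) binary volume into
#' one 8-node hexahedral element. Nodes live on the voxel-corner lattice and
#' are numbered deterministically (z fastest, then y, then x, by corner
#' index); coincident corners of face-adjacent voxels share one node.
#'
#' @param bin A [binary_volume()], nonempty, ideally connectivity-filtered.
#' @return A `hex_mesh`: `elem_nodes` (n_elem x 8, 1-based node ids in the
#'   local order of [element_stiffness()]), `node_coords` (n_node x 3, um,
#'   (x, y, z)), `elem_voxel` (n_elem x 3 voxel indices (z, y, x), 1-based),
#'   `voxel_size`, `dims`.
#' @export
build_mesh <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  d <- dim(bin$data)
  vox <- which(bin$data == 1L)
  if (length(vox) == 0) stop("cannot mesh an empty volume", call. = FALSE)
  vz <- (vox - 1L) %% d[1]                    # 0-based voxel indices
  vy <- ((vox - 1L) %/% d[1]) %% d[2]
  vx <- (vox - 1L) %/% (d[1] * d[2])
  nzc <- d[1] + 1L; nyc <- d[2] + 1L          # corner-lattice dims
  offs <- hex_local_offsets()
  corner_id <- matrix(0, length(vox), 8)      # z-fastest lattice linear id
  for (a in 1:8) {
    cz <- vz + offs[a, 3]; cy <- vy + offs[a, 2]; cx <- vx + offs[a, 1]
    corner_id[, a] <- 1 + cz + nzc * (cy + nyc * cx)
  }
  used <- sort(unique(as.vector(corner_id)))
  elem_nodes <- matrix(match(corner_id, used), ncol = 8)
  storage.mode(elem_nodes) <- "integer"
  u0 <- used - 1
  ccz <- u0 %% nzc
  ccy <- (u0 %/% nzc) %% nyc
  ccx <- u0 %/% (nzc * nyc)
  node_coords <- cbind(x = ccx, y = ccy, z = ccz) * bin$voxel_size
  structure(list(elem_nodes = elem_nodes, node_coords = node_coords,
                 elem_voxel = cbind(z = vz + 1L, y = vy + 1L, x = vx + 1L),
                 voxel_size = bin$voxel_size, dims = d,
                 n_elem = nrow(elem_nodes), n_node = length(used)),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d elements, %d nodes (%d DOF), voxel %.4g um\n",
              x$n_elem, x$n_node, 3 * x$n_node, x$voxel_size))
  invisible(x)
}

#' Boundary conditions from a DVC displacement field
#'
#' Constrains all three displacement components of every node lying on the
#' mesh's extreme axial node planes (the single top and bottom voxel-corner
#' layers), with values trilinearly interpolated from the DVC grid field.
#' Interior nodes stay free. Errors if the grid does not cover a boundary
#' node.
#'
#' @param mesh A `hex_mesh`.
#' @param disp A `displacement_grid`.
#' @return A `bc_set`: `nodes` (ids), `u` (n x 3, um), `plane` ("bottom" or
#'   "top" per node).
#' @export
apply_boundary_conditions <- function(mesh, disp) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(disp, "displacement_grid"))
  z <- mesh$node_coords[, 3]
  zmin <- min(z); zmax <- max(z)
  sel <- which(z == zmin | z == zmax)
  u <- interpolate_displacement(disp, mesh$node_coords[sel, , drop = FALSE])
  new_bc_set(sel, u, ifelse(z[sel] == zmin, "bottom", "top"))
}

#' Boundary conditions from a displacement function
#'
#' Builds a `bc_set` by evaluating `fun` at selected mesh nodes: either the
#' extreme axial node planes (`nodes = "axial"`, mirroring the experimental
#' platen constraint) or all surface nodes (`nodes = "surface"`, used e.g.
#' for patch tests).
#'
#' @param mesh A `hex_mesh`.
#' @param fun Function mapping an n x 3 (x, y, z) um coordinate matrix to
#'   n x 3 displacements, um.
#' @param nodes `"axial"` or `"surface"`.
#' @return A `bc_set`.
#' @export
bc_from_function <- function(mesh, fun, nodes = c("axial", "surface")) {
  nodes <- match.arg(nodes)
  z <- mesh$node_coords[, 3]
  zmin <- min(z); zmax <- max(z)
  if (nodes == "axial") {
    sel <- which(z == zmin | z == zmax)
  } else {
    # a corner node is interior iff all 8 adjacent voxels are bone,
    # i.e. it is shared by 8 elements
    cnt <- tabulate(as.vector(mesh$elem_nodes), nbins = mesh$n_node)
    sel <- which(cnt < 8L)
  }
  u <- fun(mesh$node_coords[sel, , drop = FALSE])
  new_bc_set(sel, u, ifelse(z[sel] == zmin, "bottom",
                            ifelse(z[sel] == zmax, "top", "lateral")))
}

new_bc_set <- function(nodes, u, plane) {
  stopifnot(length(nodes) > 0, nrow(u) == length(nodes))
  if (!all(is.finite(u))) stop("non-finite imposed displacement", call. = FALSE)
  structure(list(nodes = as.integer(nodes), u = u, plane = plane),
            class = "bc_set")
}

#' Solve the microFE model
#'
#' Solves `K u = f` for the voxel mesh with Dirichlet conditions eliminated
#' by constraint reduction. Small models (at most `sparse_threshold`
#' elements) are assembled into a sparse matrix and solved directly; larger
#' models use Jacobi-preconditioned conjugate gradients with a matrix-free
#' element-by-element operator (the assembled matrix is never formed).
#'
#' @param mesh A `hex_mesh`.
#' @param params [elastic_params()].
#' @param bc A `bc_set` (all boundary-plane nodes fully constrained).
#' @param tolerance Relative residual, in (0, 1e-3].
#' @param max_iterations CG iteration cap.
#' @param sparse_threshold Element count below which the assembled sparse
#'   direct path is used.
#' @return An `fe_solution`: `u` (n_node x 3, um), `iterations`,
#'   `relative_residual`, `method`.
#' @export
solve_microfe <- function(mesh, params, bc, tolerance = 1e-8,
                          max_iterations = 20000L,
                          sparse_threshold = 2000L) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(bc, "bc_set"))
  if (tolerance <= 0 || tolerance > 1e-3)
    stop("`tolerance` must be in (0, 1e-3]", call. = FALSE)
  Ke <- element_stiffness(params, mesh$voxel_size)
  ndof <- 3L * mesh$n_node
  u <- numeric(ndof)
  cdof <- as.vector(t(cbind(3 * (bc$nodes - 1) + 1, 3 * (bc$nodes - 1) + 2,
                            3 * (bc$nodes - 1) + 3)))
  u[3 * (bc$nodes - 1) + 1] <- bc$u[, 1]
  u[3 * (bc$nodes - 1) + 2] <- bc$u[, 2]
  u[3 * (bc$nodes - 1) + 3] <- bc$u[, 3]
  free <- setdiff(seq_len(ndof), cdof)
  if (length(free) == 0) {
    return(new_fe_solution(mesh, u, 0L, 0, "all-constrained"))
  }
  f <- -.fe_matvec(mesh$elem_nodes, Ke, u)[free]
  if (mesh$n_elem <= sparse_threshold) {
    tri <- .fe_triplets(mesh$elem_nodes, Ke)
    K <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                              dims = c(ndof, ndof))
    KFF <- Matrix::forceSymmetric(K[free, free])
    uf <- as.vector(Matrix::solve(KFF, f))
    u[free] <- uf
    rr <- sqrt(sum((as.vector(KFF %*% uf) - f)^2)) /
      max(sqrt(sum(f^2)), 1e-300)
    return(new_fe_solution(mesh, u, 1L, rr, "sparse-direct"))
  }
  # matrix-free Jacobi-PCG on the free dofs
  diagK <- .fe_diag(mesh$elem_nodes, Ke, mesh$n_node)[free]
  diagK[diagK <= 0] <- 1
  Av <- function(v) {
    w <- numeric(ndof)
    w[free] <- v
    .fe_matvec(mesh$elem_nodes, Ke, w)[free]
  }
  bnorm <- sqrt(sum(f^2))
  if (bnorm == 0) {
    return(new_fe_solution(mesh, u, 0L, 0, "pcg"))
  }
  x <- numeric(length(free))
  r <- f
  z <- r / diagK
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Ap <- Av(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2)) / bnorm
    if (rn <= tolerance) break
    if (it >= max_iterations)
      stop(sprintf("PCG did not converge in %d iterations (relative residual %.3g)",
                   it, rn), call. = FALSE)
    z <- r / diagK
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  u[free] <- x
  new_fe_solution(mesh, u, it, sqrt(sum(r^2)) / bnorm, "pcg")
}

new_fe_solution <- function(mesh, u, iterations, rr, method) {
  structure(list(u = matrix(u, mesh$n_node, 3, byrow = TRUE,
                            dimnames = list(NULL, c("x", "y", "z"))),
                 iterations = iterations, relative_residual = rr,
                 method = method),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %d nodes, %s, %d iterations, rel. residual %.2e\n",
              nrow(x$u), x$method, x$iterations, x$relative_residual))
  invisible(x)
}

#' Reaction forces of a solved microFE model
#'
#' Computes per-node reactions `(K u)` at the constrained nodes and the
#' total axial force AF as the axial resultant over the top-plane nodes
#' (those closest to the loading platen). AF is reported as a positive
#' magnitude under compression; the raw signed resultant is retained.
#'
#' @param mesh A `hex_mesh`.
#' @param params The [elastic_params()] used in the solve.
#' @param bc The `bc_set` used in the solve.
#' @param sol The `fe_solution`.
#' @return A `force_result`: `af` (N, magnitude), `af_signed` (N),
#'   `reactions` tibble (node, plane, rx, ry, rz), `equilibrium` (norm of
#'   the summed reaction vector over all constrained nodes, N).
#' @export
reaction_forces <- function(mesh, params, bc, sol) {
  stopifnot(inherits(sol, "fe_solution"))
  Ke <- element_stiffness(params, mesh$voxel_size)
  r <- .fe_matvec(mesh$elem_nodes, Ke, as.vector(t(sol$u)))
  rx <- r[3 * (bc$nodes - 1) + 1]
  ry <- r[3 * (bc$nodes - 1) + 2]
  rz <- r[3 * (bc$nodes - 1) + 3]
  top <- bc$plane == "top"
  af_signed <- sum(rz[top])
  structure(list(
    af = abs(af_signed), af_signed = af_signed,
    reactions = tibble::tibble(node = bc$nodes, plane = bc$plane,
                               rx = rx, ry = ry, rz = rz),
    equilibrium = sqrt(sum(c(sum(rx), sum(ry), sum(rz))^2))),
    class = "force_result")
}

#' Element centroid strains
#'
#' Small-strain tensor at each element centroid from the trilinear
#' shape-function derivatives, with sorted principal strains and optional
#' compartment labels copied from a [label_volume()].
#'
#' @param mesh A `hex_mesh`.
#' @param sol An `fe_solution`.
#' @param labels Optional [label_volume()] matching the meshed volume.
#' @return A `strain_field` tibble: element id, voxel indices, six strain
#'   components (dimensionless, tensor shears), principal strains
#'   `p1 >= p2 >= p3` and `compartment` (factor, if labels given).
#' @export
element_strains <- function(mesh, sol, labels = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(sol, "fe_solution"))
  h <- mesh$voxel_size
  offs <- hex_local_offsets()
  # local node index for given (oz, oy, ox) offsets
  local_of <- function(oz, oy, ox)
    which(offs[, 1] == ox & offs[, 2] == oy & offs[, 3] == oz)
  eps <- strain_from_corners(
    corner_u = function(oz, oy, ox) {
      a <- local_of(oz, oy, ox)
      sol$u[mesh$elem_nodes[, a], , drop = FALSE]
    }, hx = h, hy = h, hz = h)
  pv <- principal_values_sym3(eps)
  out <- tibble::tibble(
    element = seq_len(mesh$n_elem),
    vz = mesh$elem_voxel[, 1], vy = mesh$elem_voxel[, 2],
    vx = mesh$elem_voxel[, 3],
    exx = eps[, 1], eyy = eps[, 2], ezz = eps[, 3],
    exy = eps[, 4], eyz = eps[, 5], exz = eps[, 6],
    p1 = pv[, 1], p2 = pv[, 2], p3 = pv[, 3])
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_volume"))
    lin <- mesh$elem_voxel[, 1] +
      dim(labels$data)[1] * (mesh$elem_voxel[, 2] - 1L +
                               dim(labels$data)[2] * (mesh$elem_voxel[, 3] - 1L))
    lab <- labels$data[lin]
    out$compartment <- factor(ifelse(lab == 2L, "cortical", "trabecular"),
                              levels = c("trabecular", "cortical"))
  }
  class(out) <- c("strain_field", class(out))
  attr(out, "voxel_size") <- h
  out
}

#' Yield strain criteria
#'
#' Tensile and compressive principal-strain yield limits for vertebral
#' trabecular bone tissue; elements strained beyond them indicate where a
#' linear-elastic model stops being trustworthy.
#'
#' @param eps_p1y Tensile yield strain, microstrain (> 0; default +7200).
#' @param eps_p3y Compressive yield strain, microstrain (< 0; default -8000).
#' @return A `yield_criteria` list.
#' @export
yield_criteria <- function(eps_p1y = 7200, eps_p3y = -8000) {
  if (!(eps_p1y > 0 && eps_p3y < 0))
    stop("need eps_p1y > 0 > eps_p3y (microstrain)", call. = FALSE)
  structure(list(eps_p1y = eps_p1y, eps_p3y = eps_p3y),
            class = "yield_criteria")
}

#' Fractions of elements strained beyond yield
#'
#' Share of elements whose third principal strain is below the compressive
#' yield limit, whose first principal strain is above the tensile limit, or
#' either; when compartment labels are present, also the share of the
#' yielded elements belonging to each compartment.
#'
#' @param strains A `strain_field` from [element_strains()].
#' @param crit A [yield_criteria()].
#' @return A one-row tibble with `n_elements`, `tensile_fraction`,
#'   `compressive_fraction`, `yielded_fraction`, and (when labels exist)
#'   `cortical_share_tensile` / `cortical_share_compressive`: the
#'   proportion of cortical elements among those beyond each limit
#'   (NA when none yields).
#' @export
yield_fractions <- function(strains, crit = yield_criteria()) {
  stopifnot(inherits(strains, "strain_field"),
            inherits(crit, "yield_criteria"))
  tens <- strains$p1 * 1e6 > crit$eps_p1y
  comp <- strains$p3 * 1e6 < crit$eps_p3y
  out <- tibble::tibble(
    n_elements = nrow(strains),
    tensile_fraction = mean(tens),
    compressive_fraction = mean(comp),
    yielded_fraction = mean(tens | comp))
  if ("compartment" %in% names(strains)) {
    cort <- strains$compartment == "cortical"
    out$cortical_share_tensile <-
      if (any(tens)) mean(cort[tens]) else NA_real_
    out$cortical_share_compressive <-
      if (any(comp)) mean(cort[comp]) else NA_real_
  }
  out
}
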