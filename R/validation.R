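#' Extract measured/predicted displacement pairs at DVC grid nodes
#'
#' Keeps the DVC grid nodes that fall inside a bone element of the mesh and
#' within the centred axial slab spanning `height_fraction` of the mesh
#' height (comparisons are restricted to the middle of the model to reduce
#' the influence of the imposed boundary conditions; 0.7 is the
#' conventional choice). The predicted displacement at each kept node is the
#' trilinear interpolation of the 8 nodal solution values of its containing
#' element; the measured displacement is the DVC nodal value. A node lying
#' exactly on an element face is assigned to the element whose low corner is
#' `floor(position / voxel_size)`.
#'
#' @param disp A `displacement_grid` (the DVC measurement).
#' @param mesh The `hex_mesh` of the model.
#' @param sol The `fe_solution`.
#' @param labels Optional [label_volume()] for compartment labels.
#' @param height_fraction Axial fraction of the mesh height to keep,
#'   in (0, 1].
#' @return A `comparison_table` tibble: node id, position (um), compartment,
#'   and paired columns `u_dvc_x` ... `u_fe_z` (um).
#' @export
select_comparison_points <- function(disp, mesh, sol, labels = NULL,
                                     height_fraction = 0.7) {
  stopifnot(inherits(disp, "displacement_grid"), inherits(mesh, "hex_mesh"),
            inherits(sol, "fe_solution"))
  if (height_fraction <= 0 || height_fraction > 1)
    stop("`height_fraction` must be in (0, 1]", call. = FALSE)
  h <- mesh$voxel_size
  d <- mesh$dims
  pts <- grid_node_coords(disp$grid)
  z <- mesh$node_coords[, 3]
  zmin <- min(z); zmax <- max(z)
  margin <- (1 - height_fraction) / 2 * (zmax - zmin)
  in_slab <- pts[, 3] >= zmin + margin & pts[, 3] <= zmax - margin

  # containing voxel: low corner floor(p / h), 1-based array indices (z,y,x)
  vz <- floor(pts[, 3] / h) + 1
  vy <- floor(pts[, 2] / h) + 1
  vx <- floor(pts[, 1] / h) + 1
  ok <- in_slab & vz >= 1 & vz <= d[1] & vy >= 1 & vy <= d[2] &
    vx >= 1 & vx <= d[3]
  elem_lookup <- array(0L, d)
  elem_lookup[mesh$elem_voxel] <- seq_len(mesh$n_elem)
  eid <- integer(length(ok))
  eid[ok] <- elem_lookup[cbind(vz[ok], vy[ok], vx[ok])]
  keep <- which(ok & eid > 0L)
  if (length(keep) == 0)
    stop("no DVC grid node lies inside a bone element in the comparison slab",
         call. = FALSE)

  # trilinear interpolation inside the containing element
  el <- eid[keep]
  tz <- pts[keep, 3] / h - (vz[keep] - 1)
  ty <- pts[keep, 2] / h - (vy[keep] - 1)
  tx <- pts[keep, 1] / h - (vx[keep] - 1)
  offs <- hex_local_offsets()
  u_fe <- matrix(0, length(keep), 3)
  for (a in 1:8) {
    w <- (if (offs[a, 1] == 1) tx else 1 - tx) *
      (if (offs[a, 2] == 1) ty else 1 - ty) *
      (if (offs[a, 3] == 1) tz else 1 - tz)
    u_fe <- u_fe + w * sol$u[mesh$elem_nodes[el, a], , drop = FALSE]
  }
  out <- tibble::tibble(
    node = keep,
    x_um = pts[keep, 1], y_um = pts[keep, 2], z_um = pts[keep, 3],
    u_dvc_x = disp$u[keep, 1], u_dvc_y = disp$u[keep, 2],
    u_dvc_z = disp$u[keep, 3],
    u_fe_x = u_fe[, 1], u_fe_y = u_fe[, 2], u_fe_z = u_fe[, 3])
  if (!is.null(labels)) {
    lin <- vz[keep] + d[1] * (vy[keep] - 1 + d[2] * (vx[keep] - 1))
    lab <- labels$data[lin]
    out$compartment <- factor(ifelse(lab == 2L, "cortical", "trabecular"),
                              levels = c("trabecular", "cortical"))
  }
  class(out) <- c("comparison_table", class(out))
  attr(out, "height_fraction") <- height_fraction
  out
}

#' Cook's-distance outlier screen
#'
#' Flags influential points of the simple linear regression of `y` on `x`
#' whose Cook's distance is at least `k` times the mean Cook's distance
#' (default k = 5), applied once (not iterated). Perfect fits, where the
#' distances degenerate, remove nothing.
#'
#' @param x,y Numeric vectors of equal length >= 4 (experimental on `x`).
#' @param k Multiplier of the mean Cook's distance (> 0).
#' @return A list with integer index vectors `kept` and `removed`.
#' @export
cooks_filter <- function(x, y, k = 5) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- stats::sigma(fit)
  # a numerically perfect fit makes the distances meaningless
  if (!is.finite(s) || s <= 1e-10 * (max(abs(y)) + 1))
    return(list(kept = seq_along(x), removed = integer(0)))
  d <- stats::cooks.distance(fit)
  d[!is.finite(d)] <- 0
  md <- mean(d)
  if (md == 0) return(list(kept = seq_along(x), removed = integer(0)))
  removed <- which(d >= k * md)
  list(kept = setdiff(seq_along(x), removed), removed = as.integer(removed))
}

#' Agreement statistics between measured and predicted displacements
#'
#' Ordinary least-squares regression of predicted (`y`) on experimental
#' (`x`) values, plus accuracy metrics against the 1:1 line: RMSE is the
#' root-mean-square of `y - x` (prediction error, not the regression
#' residual), RMSE% divides it by the absolute maximum experimental value,
#' MaxError is the largest absolute prediction error, and CC is Lin's
#' concordance correlation coefficient computed with population (1/n)
#' moments.
#'
#' @param x Experimental (measured) values.
#' @param y Predicted values.
#' @param n_removed Number of points removed upstream (recorded only).
#' @return A `regression_stats` object; see [tidy.regression_stats()].
#' @export
regression_stats <- function(x, y, n_removed = 0L) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in experimental values", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    r2 = suppressWarnings(summary(fit)$r.squared),
    rmse = sqrt(mean((y - x)^2)),
    rmse_pct = 100 * sqrt(mean((y - x)^2)) / max(abs(x)),
    max_error = max(abs(y - x)),
    cc = lins_ccc(x, y),
    n_points = length(x), n_removed = as.integer(n_removed)),
    class = "regression_stats")
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line: `2 s_xy / (s_x^2 + s_y^2 +
#' (mean(x) - mean(y))^2)` with population (1/n) moments. Equals 1 only for
#' perfect agreement (`y = x`) and never exceeds the Pearson correlation in
#' magnitude.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
lins_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' @export
print.regression_stats <- function(x, ...) {
  cat(sprintf(
    "<regression_stats> n=%d (removed %d)\n  slope %.4f  intercept %.4g um  R2 %.4f\n  RMSE %.4g um (%.3g%% of max |exp|)  MaxError %.4g um  CC %.4f\n",
    x$n_points, x$n_removed, x$slope, x$intercept, x$r2, x$rmse, x$rmse_pct,
    x$max_error, x$cc))
  invisible(x)
}

#' Per-direction validation statistics for a comparison table
#'
#' For each displacement direction (x, y, z), optionally within each
#' compartment and pooled, applies the Cook's-distance screen once and then
#' computes [regression_stats()] on the surviving points. Groups with fewer
#' than 4 points are dropped with a warning.
#'
#' @param comparison A `comparison_table` from [select_comparison_points()].
#' @param k Cook's-distance multiplier (see [cooks_filter()]).
#' @param by_compartment Also compute per-compartment rows (requires
#'   labels in the comparison table).
#' @return A tibble with one row per direction (and compartment), the
#'   regression/agreement statistics and point counts.
#' @export
validate_displacements <- function(comparison, k = 5, by_compartment = FALSE) {
  stopifnot(inherits(comparison, "comparison_table"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(comparison),
    cols = dplyr::starts_with("u_"),
    names_to = c("source", "direction"), names_pattern = "u_(dvc|fe)_(.)",
    values_to = "u")
  wide <- tidyr::pivot_wider(long, names_from = "source", values_from = "u")
  groups <- list(all = wide)
  if (by_compartment && "compartment" %in% names(wide)) {
    for (cp in levels(wide$compartment))
      groups[[cp]] <- wide[wide$compartment == cp, ]
  }
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (dir in c("x", "y", "z")) {
      gd <- g[g$direction == dir, ]
      if (nrow(gd) < 4) {
        warning(sprintf("group %s/%s has < 4 points; skipped", gname, dir))
        next
      }
      flt <- cooks_filter(gd$dvc, gd$fe, k = k)
      st <- regression_stats(gd$dvc[flt$kept], gd$fe[flt$kept],
                             n_removed = length(flt$removed))
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = gname, direction = dir, tidy(st))
    }
  }
  dplyr::bind_rows(rows)
}

#' Axial force comparison
#'
#' Absolute percentage difference between predicted and experimental axial
#' forces, `%diff_AF = 100 |AF_pred - AF_exp| / AF_exp`, for one or more
#' specimens (vectorised). The raw value is retained alongside the
#' integer-rounded value conventionally reported.
#'
#' @param af_exp Experimental axial forces, N (> 0).
#' @param af_pred Predicted axial forces, N.
#' @param specimen_id Optional labels.
#' @return A tibble with `af_exp`, `af_pred`, `pct_diff` and
#'   `pct_diff_rounded`.
#' @export
force_diff <- function(af_exp, af_pred, specimen_id = NULL) {
  if (any(!is.finite(af_exp)) || any(af_exp <= 0))
    stop("`af_exp` must be positive and finite", call. = FALSE)
  if (length(af_exp) != length(af_pred))
    stop("force vectors have different lengths", call. = FALSE)
  pct <- 100 * abs(af_pred - af_exp) / af_exp
  out <- tibble::tibble(af_exp = af_exp, af_pred = af_pred,
                        pct_diff = pct, pct_diff_rounded = round(pct))
  if (!is.null(specimen_id))
    out <- dplyr::bind_cols(tibble::tibble(specimen_id = specimen_id), out)
  out
}

#' Back-calculate the tissue elastic modulus
#'
#' Because the model is linear elastic with Dirichlet boundary conditions,
#' predicted forces are exactly proportional to the tissue modulus. The
#' modulus best matching the experimental forces in the least-squares sense
#' therefore has the closed form `s = sum(af_pred * af_exp) / sum(af_pred^2)`
#' applied to predictions made at a reference modulus `e_ref`:
#' `e_backcalc = s * e_ref`.
#'
#' @param af_pred_ref Predicted axial forces at `e_ref`, N.
#' @param af_exp Experimental axial forces, N (same length).
#' @param e_ref Reference tissue modulus, GPa (> 0).
#' @return A `back_calc` object: `e_backcalc` (GPa), `scale`,
#'   `residual_norm` (N), `n`.
#' @export
back_calculate_modulus <- function(af_pred_ref, af_exp, e_ref = 12.0) {
  if (length(af_pred_ref) != length(af_exp) || length(af_exp) == 0)
    stop("force vectors must be nonempty and of equal length", call. = FALSE)
  if (e_ref <= 0) stop("`e_ref` must be > 0", call. = FALSE)
  if (all(af_pred_ref == 0))
    stop("all predicted forces are zero; scale is undefined", call. = FALSE)
  s <- sum(af_pred_ref * af_exp) / sum(af_pred_ref^2)
  structure(list(e_backcalc = s * e_ref, scale = s, e_ref = e_ref,
                 residual_norm = sqrt(sum((s * af_pred_ref - af_exp)^2)),
                 n = length(af_exp)),
            class = "back_calc")
}

#' @export
print.back_calc <- function(x, ...) {
  cat(sprintf(
    "<back_calc> E_t = %.4g GPa (scale %.4f of %.3g GPa, n = %d, residual %.4g N)\n",
    x$e_backcalc, x$scale, x$e_ref, x$n, x$residual_norm))
  invisible(x)
}

#' Reference axial-force measurements for four porcine vertebral bodies
#'
#' Experimental axial forces from stepwise in situ compression of four
#' porcine thoracic vertebral bodies (nominal 5% apparent strain, ~39 um
#' voxel micro-CT), together with the axial forces predicted by the
#' corresponding voxel microFE models at a literature tissue modulus of
#' 12.0 GPa and at the back-calculated 4.6 GPa, and specimen properties
#' (free height, total bone volume fraction). Shipped as a plain CSV in
#' `inst/extdata/porcine_vertebra_forces.csv`.
#'
#' @return A tibble with columns `specimen_id`, `free_height_mm`,
#'   `af_exp_N`, `af_fe_12gpa_N`, `af_fe_4p6gpa_N`, `tot_bvtv_pct`,
#'   `voxel_size_um`.
#' @export
vertebra_forces <- function() {
  read_force_records(system.file("extdata", "porcine_vertebra_forces.csv",
                                 package = "vertfe", mustWork = TRUE))
}
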