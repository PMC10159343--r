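#' Refine a centerline by arc-length interpolation
#'
#' Linearly interpolates points and radii onto a uniform arc-length grid
#' with spacing at most `max_spacing`. Used before the pseudo-CFD closure so
#' that nearest-station assignment does not jump across coarse stations with
#' strong radius gradients (e.g. through a coarctation), and so that the
#' 99-station gradient slabs are well populated.
#'
#' @param cl a [centerline()].
#' @param max_spacing target maximum station spacing (mm).
#' @return The refined [centerline()].
#' @export
refine_centerline <- function(cl, max_spacing = 2.5) {
  s <- cl$arc_length
  n_new <- max(nrow(cl$points),
               as.integer(ceiling(max(s) / max_spacing)) + 1L)
  s_new <- seq(0, max(s), length.out = n_new)
  pts <- vapply(1:3, function(k) {
    stats::approx(s, cl$points[, k], xout = s_new)$y
  }, numeric(n_new))
  centerline(pts, stats::approx(s, cl$radius, xout = s_new)$y)
}

#' Steady laminar flow boundary conditions
#'
#' Defaults follow the cohort's simulation set-up: uniform inlet velocity
#' 1.3 m/s (average ascending aortic peak-systolic value), 0 Pa outlet gauge
#' pressure, Newtonian blood with density 1060 kg/m^3 and dynamic viscosity
#' 0.004 Pa.s.
#'
#' @param inlet_velocity m/s, > 0.
#' @param outlet_pressure Pa (gauge), >= 0.
#' @param density kg/m^3, > 0.
#' @param viscosity Pa.s, > 0.
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(inlet_velocity = 1.3, outlet_pressure = 0,
                            density = 1060, viscosity = 0.004) {
  if (inlet_velocity <= 0 || density <= 0 || viscosity <= 0) {
    stop("inlet velocity, density and viscosity must be positive")
  }
  if (outlet_pressure < 0) stop("outlet gauge pressure must be >= 0")
  structure(list(inlet_velocity = inlet_velocity,
                 outlet_pressure = outlet_pressure,
                 density = density, viscosity = viscosity),
            class = "flow_conditions")
}

#' Per-node flow field on a correspondence mesh
#'
#' @param pressure per-node static pressure (Pa).
#' @param velocity per-node velocity magnitude (m/s), >= 0.
#' @param lineage_id lineage tag matching the mesh the field lives on.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(pressure, velocity, lineage_id = "") {
  if (length(pressure) != length(velocity)) {
    stop("pressure and velocity must have equal length")
  }
  if (any(velocity < 0)) stop("velocity magnitude must be >= 0")
  structure(list(pressure = as.numeric(pressure),
                 velocity = as.numeric(velocity),
                 lineage_id = lineage_id),
            class = "flow_field")
}

# Poiseuille-closure field evaluation at arbitrary points (mm).
# Returns pressure (Pa) and velocity magnitude (m/s) per point, plus the
# per-station pressure profile. Geometry converts mm -> m before physics.
poiseuille_eval <- function(points, cl, cond) {
  pts <- to_points(points)
  nn <- nn_ref(pts, cl$points)
  s_idx <- nn$index
  d_mm <- nn$dist
  r_mm <- cl$radius
  r_m <- r_mm / 1000
  s_m <- cl$arc_length / 1000
  Q <- cond$inlet_velocity * pi * r_m[1L]^2      # conserved volumetric flow
  vbar <- Q / (pi * r_m^2)                       # mean axial velocity per station
  # pressure profile integrated upstream from the outlet: dP/ds = 8 mu Q/(pi r^4)
  gp <- 8 * cond$viscosity * Q / (pi * r_m^4)
  n <- length(s_m)
  seg <- diff(s_m)
  drop_seg <- (gp[-n] + gp[-1L]) / 2 * seg       # trapezoid per segment
  p_sta <- cond$outlet_pressure + rev(c(0, cumsum(rev(drop_seg))))
  ratio <- d_mm / r_mm[s_idx]
  vel <- 2 * vbar[s_idx] * pmax(0, 1 - ratio^2)
  list(pressure = p_sta[s_idx], velocity = vel,
       station_index = s_idx, dist_mm = d_mm,
       station_pressure = p_sta, station_vbar = vbar)
}

#' Solve the pseudo-CFD closure on a volume mesh
#'
#' Deterministic ground-truth generator standing in for a steady laminar
#' Navier-Stokes solver. Volumetric flow `Q = inlet_velocity * pi * r(0)^2`
#' is conserved along the vessel; each node takes the parabolic Poiseuille
#' velocity profile `2 * vbar(s) * max(0, 1 - (d/r(s))^2)` of its nearest
#' centerline station, and pressure is integrated upstream from the outlet
#' with `dP/ds = 8 mu Q / (pi r(s)^4)`, constant across each cross-section.
#'
#' @param volume a [volume_mesh()].
#' @param cl the matching [centerline()] (radius > 0 at all stations).
#' @param cond [flow_conditions()].
#' @return A [flow_field()] with attribute `station_pressure` (the
#'   per-station plane pressure profile).
#' @export
solve_pseudo_cfd <- function(volume, cl, cond = flow_conditions()) {
  stopifnot(inherits(volume, "volume_mesh"), inherits(cl, "centerline"))
  ev <- poiseuille_eval(volume$nodes, cl, cond)
  too_far <- ev$dist_mm > 1.5 * cl$radius[ev$station_index]
  if (any(too_far)) {
    stop(sprintf(
      "mesh/centerline mismatch: %d nodes farther than 1.5 x local radius",
      sum(too_far)))
  }
  out <- flow_field(ev$pressure, ev$velocity, lineage_id = volume$lineage_id)
  attr(out, "station_pressure") <- ev$station_pressure
  attr(out, "station_index") <- ev$station_index
  out
}

#' Voronoi-kernel resampling onto correspondence nodes
#'
#' Nearest-neighbour (Voronoi-cell) assignment of source values onto target
#' nodes, the limit of the voxelised Voronoi kernel used to restore point
#' correspondence. Targets whose nearest source lies beyond the padding
#' distance still receive the nearest value but are counted in the
#' `n_beyond_padding` attribute.
#'
#' @param source_points m x 3 matrix of source point positions (mm).
#' @param source_values length-m vector (or m x p matrix) of values.
#' @param target_nodes n x 3 matrix of target node positions (mm).
#' @param padding_mm padding distance (default 5 mm).
#' @return Values on the targets, with attribute `n_beyond_padding`.
#' @export
resample_voronoi <- function(source_points, source_values, target_nodes,
                             padding_mm = 5) {
  source_points <- to_points(source_points)
  if (!nrow(source_points)) stop("empty source point set")
  target_nodes <- to_points(target_nodes)
  nn <- nn_ref(target_nodes, source_points)
  vals <- if (is.null(dim(source_values))) {
    as.numeric(source_values)[nn$index]
  } else {
    as.matrix(source_values)[nn$index, , drop = FALSE]
  }
  attr(vals, "n_beyond_padding") <- sum(nn$dist > padding_mm)
  vals
}

#' Build the cohort field matrices
#'
#' Runs the pseudo-CFD closure on every subject and stacks the per-node
#' pressure and velocity fields into `n x N` matrices (one row per subject,
#' one column per correspondence node). With `jitter_resample = TRUE` each
#' field is first evaluated on an independent jittered point cloud and then
#' Voronoi-resampled back onto the correspondence nodes, mirroring the
#' CFD-mesh-to-SSM-mesh interpolation stage; the induced loss of accuracy is
#' reported as the cohort-mean percentage error of the centerline gradient
#' curves.
#'
#' @param volumes list of [volume_mesh()] objects sharing one lineage.
#' @param centerlines list of matching [centerline()] objects.
#' @param cond [flow_conditions()].
#' @param jitter_resample emulate the interpolation stage (default off).
#' @param jitter_mm uniform jitter amplitude (mm).
#' @param seed RNG seed for the jitter cloud.
#' @param n_stations stations used for the interpolation-error gradient
#'   curves.
#' @return An object of class `cohort_fields`: list with matrices `pressure`
#'   and `velocity` and (when jittering) `interp_error`, the mean gradient
#'   percentage error per quantity.
#' @export
build_cohort_fields <- function(volumes, centerlines,
                                cond = flow_conditions(),
                                jitter_resample = FALSE, jitter_mm = 1,
                                seed = 1L, n_stations = 99L) {
  stopifnot(length(volumes) == length(centerlines), length(volumes) >= 1L)
  lin <- vapply(volumes, function(v) v$lineage_id, character(1))
  if (length(unique(lin)) != 1L || !nzchar(lin[1L])) {
    stop("all volumes must share one non-empty lineage_id")
  }
  n <- length(volumes)
  N <- nrow(volumes[[1L]]$nodes)
  P <- matrix(0, n, N)
  V <- matrix(0, n, N)
  err_p <- err_v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vol <- volumes[[i]]
    cl <- centerlines[[i]]
    fld <- solve_pseudo_cfd(vol, cl, cond)
    p <- fld$pressure
    v <- fld$velocity
    if (jitter_resample) {
      cloud <- with_seed(derive_seed(seed, paste0("jitter-", i)), {
        vol$nodes + matrix(stats::runif(3L * N, -jitter_mm, jitter_mm), N, 3L)
      })
      ev <- poiseuille_eval(cloud, cl, cond)
      res <- resample_voronoi(cloud, cbind(ev$pressure, ev$velocity),
                              vol$nodes)
      gp0 <- extract_gradient(p, vol$nodes, cl, n_stations = n_stations)
      gv0 <- extract_gradient(v, vol$nodes, cl, n_stations = n_stations)
      p <- res[, 1L]
      v <- res[, 2L]
      gp1 <- extract_gradient(p, vol$nodes, cl, n_stations = n_stations)
      gv1 <- extract_gradient(v, vol$nodes, cl, n_stations = n_stations)
      err_p[i] <- gradient_pct_error(gp0, gp1)
      err_v[i] <- gradient_pct_error(gv0, gv1)
    }
    P[i, ] <- p
    V[i, ] <- v
  }
  out <- list(pressure = P, velocity = V, lineage_id = lin[1L],
              conditions = cond)
  if (jitter_resample) {
    out$interp_error <- c(pressure = mean(err_p), velocity = mean(err_v))
  }
  structure(out, class = "cohort_fields")
}

# mean |curve difference| as a percentage of the reference curve's range
gradient_pct_error <- function(ref, other) {
  rng <- max(ref$values) - min(ref$values)
  if (rng <= 0) return(0)
  100 * mean(abs(other$values - ref$values)) / rng
}

#' Recompute a centerline from a deformed correspondence mesh
#'
#' After shooting a volume mesh through a deformation, the template's radius
#' law no longer holds and the advected axis points drift off-centre in
#' sheared cross-sections. The wall (outermost radial layer) nodes of each
#' axial station are in known correspondence, so each centerline point is
#' re-centred at its station's wall-node centroid and the local lumen
#' radius re-estimated as the mean centroid-to-wall distance.
#'
#' @param cl the deformed [centerline()] (points moved, radii stale).
#' @param volume the deformed [volume_mesh()] with `stations`/`layers` tags.
#' @return The re-centred [centerline()] with updated radii.
#' @export
update_centerline_radius <- function(cl, volume) {
  if (is.null(volume$stations) || is.null(volume$layers)) {
    stop("volume mesh lacks station/layer tags")
  }
  wall <- volume$layers == max(volume$layers)
  st <- volume$stations[wall]
  wn <- volume$nodes[wall, , drop = FALSE]
  if (max(st) != nrow(cl$points)) {
    stop("station count does not match the centerline")
  }
  centres <- rowsum(wn, st) / as.vector(table(st))
  d2 <- rowSums((wn - centres[st, , drop = FALSE])^2)
  # RMS wall distance: equals the radius for circular sections and stays
  # robust when a deformed ring cuts the lumen obliquely (elongated section)
  centerline(centres, sqrt(as.numeric(tapply(d2, st, mean))))
}
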