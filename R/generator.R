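#' Cohort specification for the parametric aorta generator
#'
#' The generator stands in for a segmented patient population: it draws
#' candy-cane tubes (a circular arch joined to a straight descending segment)
#' whose arch radius, lumen radius, arch angle, taper and mid-descending
#' narrowing (emulating residual coarctation) vary subject-to-subject.
#' Each distribution is given as `c(mean, sd)`. Units are millimetres and
#' degrees.
#'
#' Defaults emulate a young adult post-repair coarctation cohort: arch radius
#' of curvature 35 mm, lumen radius 10 mm (mean diameter close to 20 mm),
#' full 180-degree arch, descending length 150 mm (total centerline length
#' around 260 mm), 30% root-to-outlet taper, and a mild-to-moderate residual
#' narrowing (severity 0.25 of local radius, SD 0.12).
#'
#' @param n_subjects number of subjects to draw.
#' @param arch_radius,tube_radius,arch_angle,taper,coarctation,desc_length
#'   `c(mean, sd)` pairs; `coarctation` severity is the fractional radius
#'   reduction at the narrowing (0 = none), `taper` the fractional radius
#'   reduction from root to outlet.
#' @param coarct_width Gaussian half-width of the narrowed band (mm).
#' @param rng_seed integer seed making the cohort reproducible.
#' @param n_axial,n_circ surface discretisation (axial stations x ring
#'   vertices).
#' @param vol_n_axial,vol_n_radial,vol_n_circ volume discretisation (axial
#'   stations x radial layers x ring nodes).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L,
                        arch_radius = c(35, 3),
                        tube_radius = c(10, 1),
                        arch_angle = c(180, 10),
                        taper = c(0.3, 0.08),
                        coarctation = c(0.25, 0.12),
                        desc_length = c(150, 12),
                        coarct_width = 12,
                        rng_seed = 1L,
                        n_axial = 84L, n_circ = 30L,
                        vol_n_axial = 120L, vol_n_radial = 3L,
                        vol_n_circ = 26L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               arch_radius = as.numeric(arch_radius),
               tube_radius = as.numeric(tube_radius),
               arch_angle = as.numeric(arch_angle),
               taper = as.numeric(taper),
               coarctation = as.numeric(coarctation),
               desc_length = as.numeric(desc_length),
               coarct_width = as.numeric(coarct_width),
               rng_seed = as.integer(rng_seed),
               n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
               vol_n_axial = as.integer(vol_n_axial),
               vol_n_radial = as.integer(vol_n_radial),
               vol_n_circ = as.integer(vol_n_circ))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1")
  for (nm in c("arch_radius", "tube_radius", "arch_angle", "taper",
               "coarctation", "desc_length")) {
    p <- spec[[nm]]
    if (length(p) != 2L || anyNA(p)) stop(nm, " must be c(mean, sd)")
    if (p[2L] < 0) stop(nm, " SD must be >= 0")
  }
  if (spec$arch_radius[1L] <= 0) stop("arch radius mean must be positive")
  if (spec$tube_radius[1L] <= 0) stop("tube radius mean must be positive")
  if (spec$desc_length[1L] <= 0) stop("descending length must be positive")
  if (spec$arch_angle[1L] < 0) stop("arch angle must be >= 0")
  invisible(spec)
}

# deterministic per-subject parameter draw (subject 0 = template/means)
draw_params <- function(spec, subject) {
  if (subject == 0L) {
    return(list(R = spec$arch_radius[1L], r0 = spec$tube_radius[1L],
                alpha = spec$arch_angle[1L] * pi / 180,
                taper = spec$taper[1L], sev = spec$coarctation[1L],
                Ld = spec$desc_length[1L], w = spec$coarct_width))
  }
  with_seed(derive_seed(spec$rng_seed, paste0("subject-", subject)), {
    cl <- function(x, lo, hi) min(max(x, lo), hi)
    list(
      R = cl(stats::rnorm(1, spec$arch_radius[1L], spec$arch_radius[2L]),
             0.3 * spec$arch_radius[1L], 3 * spec$arch_radius[1L]),
      r0 = cl(stats::rnorm(1, spec$tube_radius[1L], spec$tube_radius[2L]),
              0.3 * spec$tube_radius[1L], 3 * spec$tube_radius[1L]),
      alpha = cl(stats::rnorm(1, spec$arch_angle[1L], spec$arch_angle[2L]),
                 0, 270) * pi / 180,
      taper = cl(stats::rnorm(1, spec$taper[1L], spec$taper[2L]), 0, 0.6),
      sev = cl(stats::rnorm(1, spec$coarctation[1L], spec$coarctation[2L]),
               0, 0.8),
      Ld = cl(stats::rnorm(1, spec$desc_length[1L], spec$desc_length[2L]),
              0.3 * spec$desc_length[1L], 3 * spec$desc_length[1L]),
      w = spec$coarct_width)
  })
}

# centerline curve of the candy cane: circular arch (radius R, angle alpha)
# in the xz-plane followed by a straight descending segment of length Ld.
# Returns point/tangent/normal at arc lengths s (binormal is +y).
cane_frame <- function(s, R, alpha, Ld) {
  arch_len <- R * alpha
  p <- matrix(0, length(s), 3L)
  tg <- matrix(0, length(s), 3L)
  on_arch <- s <= arch_len & alpha > 0
  th <- ifelse(rep(alpha > 0, length(s)), pmin(s / max(R, 1e-12), alpha), 0)
  p[on_arch, ] <- cbind(R * cos(th[on_arch]), 0, R * sin(th[on_arch]))
  tg[on_arch, ] <- cbind(-sin(th[on_arch]), 0, cos(th[on_arch]))
  if (any(!on_arch)) {
    u <- s[!on_arch] - arch_len
    p_end <- c(R * cos(alpha), 0, R * sin(alpha))
    t_end <- c(-sin(alpha), 0, cos(alpha))
    if (alpha == 0) { # degenerate straight tube rising from the root
      p_end <- c(R, 0, 0); t_end <- c(0, 0, 1)
    }
    p[!on_arch, ] <- rep(p_end, each = sum(!on_arch)) + outer(u, t_end)
    tg[!on_arch, ] <- rep(t_end, each = sum(!on_arch))
  }
  nr <- cbind(tg[, 3L], 0, -tg[, 1L]) # (0,1,0) x t for a planar curve
  list(points = p, tangent = tg, normal = nr)
}

# lumen radius law: linear taper plus a Gaussian mid-descending narrowing
radius_law <- function(s, params) {
  L <- params$R * params$alpha + params$Ld
  sc <- params$R * params$alpha + 0.4 * params$Ld
  r <- params$r0 * (1 - params$taper * s / L)
  r * (1 - params$sev * exp(-(s - sc)^2 / (2 * params$w^2)))
}

build_aorta_geometry <- function(spec, params, lineage_id = "",
                                 with_volume = TRUE) {
  L <- params$R * params$alpha + params$Ld
  s_axial <- seq(0, L, length.out = spec$n_axial)
  fr <- cane_frame(s_axial, params$R, params$alpha, params$Ld)
  r_axial <- radius_law(s_axial, params)

  n_circ <- spec$n_circ
  phi <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  nv <- spec$n_axial * n_circ
  verts <- matrix(0, nv + 2L, 3L)
  stations <- integer(nv + 2L)
  for (i in seq_len(spec$n_axial)) {
    ring <- fr$points[rep(i, n_circ), ] +
      r_axial[i] * (outer(cos(phi), fr$normal[i, ]) +
                      outer(sin(phi), c(0, 1, 0)))
    rows <- ((i - 1L) * n_circ + 1L):(i * n_circ)
    verts[rows, ] <- ring
    stations[rows] <- i
  }
  # cap centres (inlet = root station, outlet = last station)
  verts[nv + 1L, ] <- fr$points[1L, ]
  verts[nv + 2L, ] <- fr$points[spec$n_axial, ]
  stations[nv + 1L] <- 1L
  stations[nv + 2L] <- spec$n_axial

  tris <- vector("list", spec$n_axial - 1L + 2L)
  for (i in seq_len(spec$n_axial - 1L)) {
    a <- (i - 1L) * n_circ + seq_len(n_circ)
    b <- i * n_circ + seq_len(n_circ)
    an <- a[c(2:n_circ, 1L)]
    bn <- b[c(2:n_circ, 1L)]
    tris[[i]] <- rbind(cbind(a, b, an), cbind(an, b, bn))
  }
  inlet_ring <- seq_len(n_circ)
  outlet_ring <- (spec$n_axial - 1L) * n_circ + seq_len(n_circ)
  tris[[spec$n_axial]] <- cbind(inlet_ring[c(2:n_circ, 1L)], inlet_ring,
                                nv + 1L)
  tris[[spec$n_axial + 1L]] <- cbind(outlet_ring, outlet_ring[c(2:n_circ, 1L)],
                                     nv + 2L)
  surface <- surface_mesh(verts, do.call(rbind, tris),
                          inlet_ring = inlet_ring, outlet_ring = outlet_ring,
                          stations = stations, lineage_id = lineage_id)

  # the centerline shares the volume mesh's axial stations so that radii can
  # be re-estimated from wall nodes after shooting
  s_cl <- seq(0, L, length.out = spec$vol_n_axial)
  fr_cl <- cane_frame(s_cl, params$R, params$alpha, params$Ld)
  cl <- centerline(fr_cl$points, radius_law(s_cl, params))

  volume <- NULL
  if (with_volume) {
    volume <- build_tube_volume(spec, params, lineage_id)
  }
  list(surface = surface, volume = volume, centerline = cl)
}

build_tube_volume <- function(spec, params, lineage_id = "") {
  L <- params$R * params$alpha + params$Ld
  na <- spec$vol_n_axial
  nr <- spec$vol_n_radial
  nc <- spec$vol_n_circ
  s_axial <- seq(0, L, length.out = na)
  fr <- cane_frame(s_axial, params$R, params$alpha, params$Ld)
  r_axial <- radius_law(s_axial, params)
  phi <- 2 * pi * (seq_len(nc) - 1L) / nc
  per_station <- 1L + nr * nc
  nodes <- matrix(0, na * per_station, 3L)
  stations <- integer(na * per_station)
  layers <- integer(na * per_station)
  for (i in seq_len(na)) {
    base <- (i - 1L) * per_station
    nodes[base + 1L, ] <- fr$points[i, ]
    stations[base + 1L] <- i
    layers[base + 1L] <- 0L
    for (l in seq_len(nr)) {
      rho <- l / nr
      rows <- base + 1L + (l - 1L) * nc + seq_len(nc)
      nodes[rows, ] <- fr$points[rep(i, nc), ] +
        rho * r_axial[i] * (outer(cos(phi), fr$normal[i, ]) +
                              outer(sin(phi), c(0, 1, 0)))
      stations[rows] <- i
      layers[rows] <- l
    }
  }
  node_id <- function(i, l, j) { # station i, layer l (0=axis), ring pos j
    j <- ((j - 1L) %% nc) + 1L
    if (l == 0L) (i - 1L) * per_station + 1L
    else (i - 1L) * per_station + 1L + (l - 1L) * nc + j
  }
  tets <- vector("list", (na - 1L) * nr * nc)
  k <- 0L
  for (i in seq_len(na - 1L)) {
    for (j in seq_len(nc)) {
      # innermost wedge: axis segment + first ring sector -> 3 tets
      p0 <- node_id(i, 0L, 1L); p1 <- node_id(i, 1L, j)
      p2 <- node_id(i, 1L, j + 1L)
      q0 <- node_id(i + 1L, 0L, 1L); q1 <- node_id(i + 1L, 1L, j)
      q2 <- node_id(i + 1L, 1L, j + 1L)
      k <- k + 1L
      tets[[k]] <- rbind(c(p0, p1, p2, q0), c(p1, p2, q0, q1),
                         c(p2, q0, q1, q2))
      for (l in seq_len(nr - 1L)) {
        # hexahedral cell between layers l, l+1 -> 6 tets on diagonal a-c2
        a <- node_id(i, l, j); b <- node_id(i, l, j + 1L)
        cc <- node_id(i, l + 1L, j + 1L); d <- node_id(i, l + 1L, j)
        a2 <- node_id(i + 1L, l, j); b2 <- node_id(i + 1L, l, j + 1L)
        c2 <- node_id(i + 1L, l + 1L, j + 1L); d2 <- node_id(i + 1L, l + 1L, j)
        k <- k + 1L
        tets[[k]] <- rbind(c(a, b, cc, c2), c(a, cc, d, c2), c(a, d, d2, c2),
                           c(a, d2, a2, c2), c(a, a2, b2, c2), c(a, b2, b, c2))
      }
    }
  }
  volume_mesh(nodes, do.call(rbind, tets[seq_len(k)]),
              lineage_id = lineage_id, stations = stations, layers = layers)
}

#' Generate the template aorta
#'
#' Builds the mean-parameter candy-cane aorta: a closed triangulated surface,
#' a tetrahedral volume mesh with interior nodes, and the generating
#' centerline with its radius law. The template is the shape every synthetic
#' subject is shot from, so its meshes carry a lineage tag.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `surface`, `volume`, `centerline`.
#' @export
generate_template_aorta <- function(spec) {
  validate_cohort_spec(spec)
  params <- draw_params(spec, 0L)
  lineage <- sprintf("tpl-%s",
                     substr(digest_config(spec[c("n_axial", "n_circ",
                                                 "vol_n_axial", "vol_n_radial",
                                                 "vol_n_circ", "rng_seed")]),
                            1L, 8L))
  build_aorta_geometry(spec, params, lineage_id = lineage)
}

#' Generate the target population
#'
#' Draws `n_subjects` analytically perturbed aortic surfaces (arch angle,
#' radii, taper, optional mid-descending narrowing) that stand in for the
#' segmented patient cohort. The targets are generated from perturbed
#' generating curves, not by deforming the template, so downstream shape-model
#' registration is tested against shapes it did not produce. All subjects are
#' built in the template's canonical frame (rigidly pre-aligned).
#'
#' @param template result of [generate_template_aorta()] (used for frame and
#'   resolution consistency).
#' @param spec a [cohort_spec()].
#' @return A list of `n_subjects` [surface_mesh()] objects.
#' @export
generate_target_population <- function(template, spec) {
  validate_cohort_spec(spec)
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1")
  lapply(seq_len(spec$n_subjects), function(k) {
    params <- draw_params(spec, k)
    build_aorta_geometry(spec, params, with_volume = FALSE)$surface
  })
}

#' Add a straight flow extension at the inlet
#'
#' Prolongs the tagged inlet ring by a straight prismatic extension normal to
#' the inlet plane, producing the flat circular inlet face needed for a
#' uniform velocity boundary condition. Extension vertices are recorded so
#' they can be excluded from field matrices.
#'
#' @param surface a [surface_mesh()] with a tagged inlet ring.
#' @param length_mm extension length (default 40 mm at the inlet).
#' @param end which boundary to extend; only `"inlet"` is supported.
#' @param seg_length target axial segment length of the extension (mm).
#' @return The extended [surface_mesh()]; attribute `extension_vertices`
#'   holds the indices of the newly added vertices.
#' @export
add_flow_extension <- function(surface, length_mm = 40, end = "inlet",
                               seg_length = 5) {
  stopifnot(inherits(surface, "surface_mesh"))
  if (!identical(end, "inlet")) stop("only the inlet end can be extended")
  if (length_mm < 0) stop("extension length must be >= 0")
  if (length_mm == 0) return(surface)
  ring <- surface$inlet_ring
  if (!length(ring)) stop("no tagged inlet ring found on this surface")

  v <- surface$vertices
  rv <- v[ring, , drop = FALSE]
  centroid <- colMeans(rv)
  # ring plane normal via SVD; orient away from the mesh body
  sv <- svd(sweep(rv, 2L, centroid))
  normal <- sv$v[, 3L]
  body_dir <- colMeans(v) - centroid
  if (sum(normal * body_dir) > 0) normal <- -normal

  n_seg <- max(1L, round(length_mm / seg_length))
  step <- length_mm / n_seg
  n_ring <- length(ring)
  new_verts <- do.call(rbind, lapply(seq_len(n_seg), function(k) {
    sweep(rv, 2L, k * step * normal, `+`)
  }))
  nv0 <- nrow(v)

  # drop the old inlet cap fan (triangles touching the cap centre vertex,
  # identified as a vertex used only by triangles that all touch the ring)
  tri <- surface$triangles
  cap_vertex <- find_cap_vertex(surface, ring)
  if (!is.na(cap_vertex)) {
    tri <- tri[rowSums(matrix(tri %in% cap_vertex, nrow(tri))) == 0L, ,
               drop = FALSE]
  }

  ring_ids <- function(k) {
    if (k == 0L) ring else nv0 + (k - 1L) * n_ring + seq_len(n_ring)
  }
  wall <- do.call(rbind, lapply(seq_len(n_seg), function(k) {
    a <- ring_ids(k - 1L); b <- ring_ids(k)
    an <- a[c(2:n_ring, 1L)]; bn <- b[c(2:n_ring, 1L)]
    rbind(cbind(a, an, b), cbind(an, bn, b))
  }))
  new_ring <- ring_ids(n_seg)
  all_verts <- rbind(v, new_verts)
  cap_tris <- NULL
  if (!is.na(cap_vertex)) {
    all_verts[cap_vertex, ] <- centroid + length_mm * normal
    cap_tris <- cbind(new_ring[c(2:n_ring, 1L)], new_ring, cap_vertex)
  }
  stations <- surface$stations
  if (!is.null(stations)) stations <- c(stations, rep(NA_integer_,
                                                      nrow(new_verts)))
  out <- surface_mesh(all_verts, rbind(tri, wall, cap_tris),
                      inlet_ring = new_ring,
                      outlet_ring = surface$outlet_ring,
                      stations = stations, lineage_id = surface$lineage_id)
  ext_prev <- attr(surface, "extension_vertices")
  attr(out, "extension_vertices") <- c(ext_prev,
                                       nv0 + seq_len(nrow(new_verts)))
  out
}

find_cap_vertex <- function(surface, ring) {
  tri <- surface$triangles
  touches_ring <- matrix(tri %in% ring, nrow(tri))
  cand <- tri[rowSums(touches_ring) == 2L, , drop = FALSE]
  cand <- setdiff(as.vector(cand), ring)
  if (!length(cand)) return(NA_integer_)
  # the cap centre appears in as many triangles as the ring has vertices
  tab <- table(factor(as.vector(tri), levels = cand))
  best <- as.integer(names(tab)[which.max(tab)])
  if (tab[as.character(best)] >= length(ring)) best else NA_integer_
}
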