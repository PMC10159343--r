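# small deterministic fixtures shared across test files; built once per run

fixture_env <- new.env()

small_spec <- function(...) {
  defaults <- list(n_subjects = 6L, n_axial = 36L, n_circ = 14L,
                   vol_n_axial = 36L, vol_n_radial = 2L, vol_n_circ = 10L,
                   rng_seed = 7L)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

small_template <- function() {
  if (is.null(fixture_env$template)) {
    fixture_env$template <- generate_template_aorta(small_spec())
  }
  fixture_env$template
}

# a unit tetrahedron surface (4 vertices, 4 faces)
tetra_surface <- function() {
  surface_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                     c(1, 1, 1)),
    triangles = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# brute-force discrete Frechet distance by enumerating monotone couplings
frechet_brute <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, worst) {
    worst <- max(worst, abs(a[i] - b[j]))
    if (worst >= best) return()
    if (i == n && j == m) { best <<- min(best, worst); return() }
    if (i < n) rec(i + 1L, j, worst)
    if (j < m) rec(i, j + 1L, worst)
    if (i < n && j < m) rec(i + 1L, j + 1L, worst)
  }
  rec(1L, 1L, 0)
  best
}
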