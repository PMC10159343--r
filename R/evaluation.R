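#' Node-wise normalised absolute error
#'
#' `NAE_i = |true_i - pred_i| / (max(true) - min(true)) * 100`: the absolute
#' nodal error as a percentage of the subject's ground-truth field range,
#' making subjects (and pressure vs velocity) directly comparable.
#'
#' @param true_field,pred_field length-N numeric vectors.
#' @return Length-N vector of percentages.
#' @export
nae <- function(true_field, pred_field) {
  if (length(true_field) != length(pred_field)) {
    stop("true and predicted fields must have equal length")
  }
  rng <- max(true_field) - min(true_field)
  if (rng <= 0) stop("zero-range ground-truth field: NAE undefined")
  abs(true_field - pred_field) / rng * 100
}

# signed counterpart used for Bland-Altman agreement
signed_nae <- function(true_field, pred_field) {
  rng <- max(true_field) - min(true_field)
  if (rng <= 0) stop("zero-range ground-truth field: NAE undefined")
  (pred_field - true_field) / rng * 100
}

#' Aggregate nodal errors into an error report
#'
#' Computes the paper's summaries from an `n_subjects x N` NAE matrix and the
#' matching signed-error matrix: `MNAE_N` (column means: per-node average
#' across the population), `MNAE_S` (row means: per-subject average across
#' nodes), the population error (mean +/- SD of `MNAE_S`), and Bland-Altman
#' bias and 1.96-SD limits of agreement of the signed errors.
#'
#' @param nae_matrix n x N matrix of NAE percentages.
#' @param signed_matrix n x N matrix of signed normalised errors (%).
#' @return An object of class `error_report`.
#' @export
aggregate_errors <- function(nae_matrix, signed_matrix) {
  nae_matrix <- as.matrix(nae_matrix)
  signed_matrix <- as.matrix(signed_matrix)
  if (!length(nae_matrix)) stop("empty error matrix")
  if (!all(dim(nae_matrix) == dim(signed_matrix))) {
    stop("NAE and signed matrices must have the same shape")
  }
  mnae_node <- colMeans(nae_matrix)
  mnae_subject <- rowMeans(nae_matrix)
  se <- as.numeric(signed_matrix)
  bias <- mean(se)
  sd_se <- stats::sd(se)
  if (is.na(sd_se)) sd_se <- 0
  structure(list(
    nae = nae_matrix,
    mnae_node = mnae_node,
    mnae_subject = mnae_subject,
    population_mean = mean(mnae_subject),
    population_sd = if (length(mnae_subject) > 1L) stats::sd(mnae_subject)
                    else 0,
    bias = bias,
    loa_low = bias - 1.96 * sd_se,
    loa_high = bias + 1.96 * sd_se
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    paste0("error_report: population MNAE_S %.2f%% +/- %.2f SD ",
           "(bias %.2f%%, LoA [%.2f, %.2f])\n"),
    x$population_mean, x$population_sd, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' One-row tibble summary of an error report
#'
#' @param report an [aggregate_errors()] report.
#' @return A tibble with population mean/SD, min/max/max-node errors, bias
#'   and limits of agreement.
#' @export
summarise_errors <- function(report) {
  stopifnot(inherits(report, "error_report"))
  tibble::tibble(
    population_mean = report$population_mean,
    population_sd = report$population_sd,
    mnae_s_min = min(report$mnae_subject),
    mnae_s_max = max(report$mnae_subject),
    mnae_n_max = max(report$mnae_node),
    bias = report$bias,
    loa_low = report$loa_low,
    loa_high = report$loa_high)
}

#' Label nodes by aortic region
#'
#' Assigns each node to the ascending aorta, transverse arch or descending
#' aorta by thirds of centerline arc length (the anatomical definition of
#' the source cohort is not reproducible, so equal arc-length thirds are
#' used). Enables regional Bland-Altman analyses by subsetting error-matrix
#' columns.
#'
#' @param points N x 3 node positions (or a mesh).
#' @param cl the [centerline()].
#' @return A factor of length N with levels `ascending`, `arch`,
#'   `descending`.
#' @export
node_regions <- function(points, cl) {
  points <- mesh_points(points)
  s <- cl$arc_length[nn_ref(points, cl$points)$index]
  L <- max(cl$arc_length)
  cut(s, breaks = c(-Inf, L / 3, 2 * L / 3, Inf),
      labels = c("ascending", "arch", "descending"))
}

#' Export an error report as plain-text tables
#'
#' Writes the per-subject errors (`mnae_subject.tsv`), the per-node errors
#' (`mnae_node.tsv`) and the structured summary (`summary.json`) into a
#' directory.
#'
#' @param report an [aggregate_errors()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_error_report <- function(report, dir) {
  stopifnot(inherits(report, "error_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(subject = seq_along(report$mnae_subject),
               mnae_s_pct = report$mnae_subject),
    file.path(dir, "mnae_subject.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(node = seq_along(report$mnae_node),
               mnae_n_pct = report$mnae_node),
    file.path(dir, "mnae_node.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(as.list(summarise_errors(report)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Correlation between shape mode scores and subject errors
#'
#' Pearson R per shape mode against the per-subject error, with a two-sided
#' p-value from the t distribution with n - 2 degrees of freedom. Modes with
#' zero variance are reported as missing, not as zero.
#'
#' @param shape_scores n x k score matrix.
#' @param mnae_subject length-n vector of subject errors (%).
#' @return A tibble with columns `mode`, `r`, `p`.
#' @export
mode_error_correlation <- function(shape_scores, mnae_subject) {
  shape_scores <- as.matrix(shape_scores)
  n <- nrow(shape_scores)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(mnae_subject) != n) stop("subject error length mismatch")
  res <- lapply(seq_len(ncol(shape_scores)), function(j) {
    x <- shape_scores[, j]
    if (stats::sd(x) == 0 || stats::sd(mnae_subject) == 0) {
      return(c(NA_real_, NA_real_))
    }
    r <- stats::cor(x, mnae_subject)
    df <- n - 2L
    if (abs(r) >= 1) return(c(r, 0))
    t_ <- r * sqrt(df / (1 - r^2))
    c(r, 2 * stats::pt(-abs(t_), df))
  })
  tibble::tibble(mode = seq_len(ncol(shape_scores)),
                 r = vapply(res, `[`, numeric(1), 1L),
                 p = vapply(res, `[`, numeric(1), 2L))
}

#' Extract a plane-averaged centerline gradient curve
#'
#' Splits the vessel into `n_stations` equally spaced arc-length slabs from
#' the root (s = 0, flow extension excluded) to the outlet and averages the
#' field over the nodes whose nearest-centerline arc length falls in each
#' slab. Empty slabs inherit the nearest non-empty station's value and are
#' counted in the `n_empty` attribute.
#'
#' @param values length-N field values (or a [flow_field()], with `what`
#'   picking the quantity).
#' @param points N x 3 node positions (or the [volume_mesh()] the field
#'   lives on).
#' @param cl the [centerline()].
#' @param n_stations number of stations (default 99).
#' @param what `"pressure"` or `"velocity"` when `values` is a
#'   [flow_field()].
#' @return An object of class `gradient_curve`: `stations` (arc length, mm)
#'   and `values`.
#' @export
extract_gradient <- function(values, points, cl, n_stations = 99L,
                             what = c("pressure", "velocity")) {
  if (inherits(values, "flow_field")) {
    what <- match.arg(what)
    values <- values[[what]]
  }
  points <- mesh_points(points)
  if (length(values) != nrow(points)) {
    stop("values and points must have equal length")
  }
  if (n_stations < 2L) stop("need at least 2 stations")
  s_node <- cl$arc_length[nn_ref(points, cl$points)$index]
  L <- max(cl$arc_length)
  stations <- seq(0, L, length.out = n_stations)
  h <- stations[2L] - stations[1L]
  slab <- pmin(pmax(floor(s_node / h + 0.5), 0), n_stations - 1L) + 1L
  sums <- tapply(values, slab, mean)
  vals <- rep(NA_real_, n_stations)
  vals[as.integer(names(sums))] <- sums
  n_empty <- sum(is.na(vals))
  if (n_empty == n_stations) stop("all gradient slabs are empty")
  if (n_empty > 0L) {
    warning(sprintf("%d empty gradient slabs filled from neighbours",
                    n_empty))
    filled <- which(!is.na(vals))
    for (i in which(is.na(vals))) {
      vals[i] <- vals[filled[which.min(abs(filled - i))]]
    }
  }
  structure(list(stations = stations, values = vals),
            class = "gradient_curve", n_empty = n_empty)
}

#' @export
print.gradient_curve <- function(x, ...) {
  cat(sprintf("gradient_curve: %d stations over %.1f mm, values %.3g..%.3g\n",
              length(x$stations), max(x$stations), min(x$values),
              max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.gradient_curve <- function(x, ...) {
  data.frame(arc_length_mm = x$stations, value = x$values)
}

#' Discrete Frechet distance between two curves
#'
#' The standard dynamic program
#' `c(i,j) = max(d(a_i, b_j), min(c(i-1,j), c(i-1,j-1), c(i,j-1)))`
#' over all monotone couplings of the two sequences. By default the ground
#' metric is the absolute difference of the values only, keeping the result
#' in the field's units (Pa or m/s); `use_positions = TRUE` couples
#' (station, value) pairs with the Euclidean metric instead.
#'
#' @param a,b numeric value sequences (non-empty).
#' @param positions_a,positions_b optional station coordinates, used when
#'   `use_positions = TRUE`.
#' @param use_positions couple 2D (position, value) points instead of bare
#'   values.
#' @return The discrete Frechet distance (units of the values).
#' @export
frechet_distance <- function(a, b, positions_a = NULL, positions_b = NULL,
                             use_positions = FALSE) {
  if (!length(a) || !length(b)) stop("empty sequence")
  n <- length(a)
  m <- length(b)
  if (use_positions) {
    if (is.null(positions_a) || is.null(positions_b)) {
      stop("positions required when use_positions = TRUE")
    }
    d <- sqrt(outer(positions_a, positions_b, `-`)^2 + outer(a, b, `-`)^2)
  } else {
    d <- abs(outer(a, b, `-`))
  }
  cmat <- matrix(0, n, m)
  cmat[1L, 1L] <- d[1L, 1L]
  for (i in seq_len(n)[-1L]) cmat[i, 1L] <- max(cmat[i - 1L, 1L], d[i, 1L])
  for (j in seq_len(m)[-1L]) cmat[1L, j] <- max(cmat[1L, j - 1L], d[1L, j])
  if (n > 1L && m > 1L) {
    for (i in 2:n) {
      for (j in 2:m) {
        cmat[i, j] <- max(d[i, j], min(cmat[i - 1L, j], cmat[i - 1L, j - 1L],
                                       cmat[i, j - 1L]))
      }
    }
  }
  cmat[n, m]
}

#' Centerline geometry statistics
#'
#' Length, mean diameter, tortuosity (arc length over the endpoint chord)
#' and mean torsion (arc-length-weighted mean of the discrete Frenet torsion
#' from centred finite differences; zero where the curve is locally straight
#' or planar).
#'
#' @param cl a [centerline()] with at least 5 points (third derivatives).
#' @return A one-row tibble: `length_mm`, `mean_diameter_mm`, `tortuosity`,
#'   `mean_torsion`.
#' @export
geometry_stats <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  n <- nrow(p)
  if (n < 5L) stop("need at least 5 centerline points for torsion")
  len <- max(cl$arc_length)
  chord <- sqrt(sum((p[n, ] - p[1L, ])^2))
  if (chord == 0) stop("coincident centerline endpoints")
  tau <- discrete_torsion(p, cl$arc_length)
  w <- tau$weights
  tibble::tibble(
    length_mm = len,
    mean_diameter_mm = mean(2 * cl$radius),
    tortuosity = len / chord,
    mean_torsion = sum(tau$torsion * w) / sum(w))
}

# centred finite-difference Frenet torsion tau = ((r' x r'') . r''') /
# |r' x r''|^2 at interior points 3..n-2, with arc-length weights
discrete_torsion <- function(p, s) {
  n <- nrow(p)
  idx <- 3:(n - 2L)
  h <- mean(diff(s))
  d1 <- (p[idx + 1L, , drop = FALSE] - p[idx - 1L, , drop = FALSE]) / (2 * h)
  d2 <- (p[idx + 1L, , drop = FALSE] - 2 * p[idx, , drop = FALSE] +
           p[idx - 1L, , drop = FALSE]) / h^2
  d3 <- (p[idx + 2L, , drop = FALSE] - 2 * p[idx + 1L, , drop = FALSE] +
           2 * p[idx - 1L, , drop = FALSE] - p[idx - 2L, , drop = FALSE]) /
    (2 * h^3)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  denom <- rowSums(cr^2)
  num <- rowSums(cr * d3)
  tau <- ifelse(denom > 1e-12 * max(1, max(denom)), num / denom, 0)
  list(torsion = tau, weights = rep(h, length(idx)))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p. When both samples have zero variance: p = 1 if the means
#' agree (by convention), p = 0 otherwise.
#'
#' @param sample_a,sample_b numeric vectors of size >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("both samples must have size >= 2")
  }
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    return(list(t = if (same) 0 else Inf,
                df = length(sample_a) + length(sample_b) - 2L,
                p = if (same) 1 else 0))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
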