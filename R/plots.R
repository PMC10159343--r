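#' Plot a centerline gradient curve
#'
#' Line plot of the plane-averaged profile against arc length; overlay a
#' second curve (e.g. the surrogate prediction against the ground truth) via
#' `compare`.
#'
#' @param object a [extract_gradient()] curve.
#' @param compare optional second `gradient_curve`.
#' @param ylab y-axis label (e.g. `"Pressure (Pa)"`).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gradient_curve <- function(object, compare = NULL,
                                    ylab = "Value", ...) {
  df <- data.frame(arc = object$stations, value = object$values,
                   curve = "ground truth")
  if (!is.null(compare)) {
    df <- rbind(df, data.frame(arc = compare$stations,
                               value = compare$values,
                               curve = "prediction"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = arc, y = value,
                                   colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Arc length from root (mm)", y = ylab,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of signed normalised errors
#'
#' Scatter of signed node errors against the node mean of truth and
#' prediction (both in % of the subject range), with the bias and 1.96-SD
#' limits of agreement as horizontal lines. Points are subsampled for
#' readability.
#'
#' @param report an [aggregate_errors()] error report.
#' @param signed_matrix the signed error matrix the report was built from.
#' @param max_points subsample cap (default 1000, as in the source figures).
#' @param seed subsample seed.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report, signed_matrix, max_points = 1000L,
                              seed = 1L) {
  stopifnot(inherits(report, "error_report"))
  se <- as.numeric(signed_matrix)
  keep <- if (length(se) > max_points) {
    with_seed(seed, sample.int(length(se), max_points))
  } else seq_along(se)
  df <- data.frame(index = seq_along(keep), error = se[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = index, y = error)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_hline(yintercept = report$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Node sample", y = "Signed normalised error (%)") +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA basis
#'
#' Per-mode and cumulative variance fractions of a fitted basis.
#'
#' @param basis a [fit_pca()] basis.
#' @return A ggplot object.
#' @export
plot_variance <- function(basis) {
  stopifnot(inherits(basis, "pca_basis"))
  df <- data.frame(mode = seq_along(basis$variance_fraction),
                   variance = basis$variance_fraction,
                   cumulative = cumsum(basis$variance_fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = mode)) +
    ggplot2::geom_col(ggplot2::aes(y = variance), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = cumulative),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = cumulative),
                        colour = "steelblue", size = 1) +
    ggplot2::labs(x = "PCA mode", y = "Variance fraction") +
    ggplot2::theme_minimal()
}
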