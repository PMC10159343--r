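#' Gaussian kernel of the deformation model
#'
#' `K(x, q) = exp(-||x - q||^2 / sigma^2)` with the kernel width `sigma` in
#' millimetres (default 10 mm). Accepts single points or matrices of points
#' (row-wise) and returns the kernel matrix.
#'
#' @param x query point(s): length-3 vector or n x 3 matrix.
#' @param q kernel centre(s): length-3 vector or m x 3 matrix.
#' @param sigma kernel width (mm), > 0.
#' @return An n x m matrix of kernel values in (0, 1] (scalar when both
#'   inputs are single points).
#' @export
gaussian_kernel <- function(x, q, sigma = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  x <- to_points(x)
  q <- to_points(q)
  K <- exp(-cross_dist2(x, q) / sigma^2)
  if (nrow(x) == 1L && nrow(q) == 1L) K[1L, 1L] else K
}

to_points <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3L) else {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  }
}

# squared Euclidean cross-distance matrix, clamped at zero
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Kernel deformation parameterisation
#'
#' A deformation of ambient space parameterised by `n_cp` control points and
#' a Gaussian kernel of width `sigma`; paired momenta drive a kernel-weighted
#' velocity field integrated over `n_steps` Euler steps. Momenta are
#' interpreted as the total displacement at a kernel centre over unit flow
#' time. Control points are advected with the flow; momenta are held fixed
#' along it (simplified kernel flow, not full geodesic shooting).
#'
#' @param control_points n_cp x 3 matrix of control point positions (mm).
#' @param sigma kernel width (mm), default 10.
#' @param n_steps number of Euler integration steps, >= 1.
#' @return An object of class `kernel_deformation`.
#' @export
kernel_deformation <- function(control_points, sigma = 10, n_steps = 10L) {
  control_points <- to_points(control_points)
  if (sigma <= 0) stop("sigma must be positive")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (nrow(control_points) < 1L) stop("need at least one control point")
  structure(list(control_points = control_points, sigma = sigma,
                 n_steps = as.integer(n_steps)),
            class = "kernel_deformation")
}

#' Apply a kernel deformation to ambient points
#'
#' Integrates the kernel flow: at each of `n_steps` Euler steps every point
#' (and every control point) moves by `sum_i K(x, q_i) mu_i / n_steps`.
#' Applying the deformation to a mesh preserves connectivity and node
#' ordering, which is the point-correspondence property the pipeline relies
#' on.
#'
#' @param points n x 3 matrix of points to deform (mm).
#' @param deformation a [kernel_deformation()].
#' @param momenta n_cp x 3 matrix of momenta vectors (mm).
#' @param return_weights also return the accumulated kernel weight matrix
#'   `W` (n x n_cp) with `x_final = x_0 + W %*% momenta`; used by the
#'   registration gradient.
#' @return The deformed points (or a list `points`/`weights`/`control_points`
#'   when `return_weights = TRUE`).
#' @export
deform_points <- function(points, deformation, momenta,
                          return_weights = FALSE) {
  stopifnot(inherits(deformation, "kernel_deformation"))
  pts <- to_points(points)
  mu <- to_points(momenta)
  q <- deformation$control_points
  if (nrow(mu) != nrow(q)) stop("momenta must pair with control points")
  if (anyNA(pts) || anyNA(mu) || any(!is.finite(pts)) || any(!is.finite(mu))) {
    stop("non-finite values in points or momenta")
  }
  n_steps <- deformation$n_steps
  W <- if (return_weights) matrix(0, nrow(pts), nrow(q)) else NULL
  for (s in seq_len(n_steps)) {
    Kp <- exp(-cross_dist2(pts, q) / deformation$sigma^2)
    Kq <- exp(-cross_dist2(q, q) / deformation$sigma^2)
    pts <- pts + (Kp %*% mu) / n_steps
    q <- q + (Kq %*% mu) / n_steps
    if (return_weights) W <- W + Kp / n_steps
  }
  if (return_weights) list(points = pts, weights = W, control_points = q)
  else pts
}

#' Shoot a mesh (or centerline) through a kernel deformation
#'
#' @param mesh a [surface_mesh()], [volume_mesh()] or [centerline()].
#' @param deformation a [kernel_deformation()].
#' @param momenta n_cp x 3 momenta matrix.
#' @return The deformed object; connectivity, ordering, tags and lineage are
#'   preserved.
#' @export
deform_mesh <- function(mesh, deformation, momenta) {
  if (inherits(mesh, "surface_mesh")) {
    out <- mesh
    out$vertices <- deform_points(mesh$vertices, deformation, momenta)
    out
  } else if (inherits(mesh, "volume_mesh")) {
    out <- mesh
    out$nodes <- deform_points(mesh$nodes, deformation, momenta)
    out
  } else if (inherits(mesh, "centerline")) {
    centerline(deform_points(mesh$points, deformation, momenta), mesh$radius)
  } else stop("unsupported object for deform_mesh")
}

#' Rigid registration by iterative closest point
#'
#' Alternates nearest-neighbour correspondence with the Kabsch least-squares
#' rigid fit until the mean squared closest-point distance stops improving.
#'
#' @param source,target [surface_mesh()] objects or point matrices.
#' @param max_iter iteration cap.
#' @param tol relative improvement threshold.
#' @return A `rigid_transform` (list with `rotation` 3x3, `translation`
#'   length-3, `mse` trajectory); apply with [apply_rigid()].
#' @export
rigid_icp <- function(source, target, max_iter = 50L, tol = 1e-10) {
  src <- mesh_points(source)
  tgt <- mesh_points(target)
  if (!nrow(src) || !nrow(tgt)) stop("empty mesh in rigid_icp")
  if (collinear_points(src)) {
    warning("degenerate (collinear) source; returning best-effort transform")
  }
  R <- diag(3)
  tvec <- c(0, 0, 0)
  cur <- src
  mse <- rep(NA_real_, max_iter)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    nn <- nn_ref(cur, tgt)
    corr <- tgt[nn$index, , drop = FALSE]
    mse[it] <- mean(nn$dist^2)
    fit <- kabsch(src, corr)
    R <- fit$rotation
    tvec <- fit$translation
    cur <- sweep(src %*% t(R), 2L, tvec, `+`)
    if (is.finite(prev) && (prev - mse[it]) < tol * max(prev, 1e-30)) break
    prev <- mse[it]
  }
  structure(list(rotation = R, translation = tvec,
                 mse = mse[!is.na(mse)]),
            class = "rigid_transform")
}

kabsch <- function(from, to) {
  cf <- colMeans(from)
  ct <- colMeans(to)
  H <- crossprod(sweep(from, 2L, cf), sweep(to, 2L, ct))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(rotation = R, translation = as.numeric(ct - R %*% cf))
}

collinear_points <- function(p, tol = 1e-9) {
  if (nrow(p) < 3L) return(TRUE)
  sv <- svd(sweep(p, 2L, colMeans(p)), nu = 0, nv = 0)
  sv$d[2L] <= tol * max(sv$d[1L], 1e-30)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a `rigid_transform` from [rigid_icp()].
#' @param x point matrix, [surface_mesh()], [volume_mesh()] or
#'   [centerline()].
#' @return `x` transformed.
#' @export
apply_rigid <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  f <- function(p) sweep(p %*% t(transform$rotation), 2L,
                         transform$translation, `+`)
  if (inherits(x, "surface_mesh")) { x$vertices <- f(x$vertices); x }
  else if (inherits(x, "volume_mesh")) { x$nodes <- f(x$nodes); x }
  else if (inherits(x, "centerline")) centerline(f(x$points), x$radius)
  else f(to_points(x))
}

#' Initialise a high-resolution control point grid
#'
#' Lays a regular axis-aligned lattice over the template bounding box (padded
#' by `sigma`) and keeps lattice points within `sigma` of the surface; the
#' lattice spacing is searched so the count comes as close to `n_target` as
#' granularity allows (the model is later truncated to the most influential
#' points).
#'
#' @param template a [surface_mesh()].
#' @param n_target desired number of control points (paper-scale default
#'   500).
#' @param sigma kernel width used for padding and pruning (mm).
#' @return A matrix of control point positions.
#' @export
init_control_grid <- function(template, n_target = 500L, sigma = 10) {
  if (n_target < 1L) stop("n_target must be >= 1")
  v <- mesh_points(template)
  lo <- apply(v, 2L, min) - sigma
  hi <- apply(v, 2L, max) + sigma
  diag_len <- sqrt(sum((hi - lo)^2))
  spacings <- exp(seq(log(diag_len / 2), log(diag_len / 60),
                      length.out = 50L))
  best <- NULL
  best_gap <- Inf
  for (h in spacings) {
    grid <- lattice_points(lo, hi, h)
    keep <- nn_ref(grid, v)$dist <= sigma
    cnt <- sum(keep)
    gap <- abs(cnt - n_target)
    if (cnt >= 1L && gap < best_gap) {
      best <- grid[keep, , drop = FALSE]
      best_gap <- gap
      if (gap == 0L) break
    }
    if (cnt > 4L * n_target) break # lattice already far too fine
  }
  best
}

lattice_points <- function(lo, hi, h) {
  ax <- lapply(1:3, function(k) {
    n <- max(2L, ceiling((hi[k] - lo[k]) / h) + 1L)
    seq(lo[k], hi[k], length.out = n)
  })
  as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
}

#' Estimate momenta registering the template to a target surface
#'
#' Minimises
#' `L(mu) = d_sym(phi_mu(template), target) + lambda_reg * sum_ij K(q_i, q_j)
#' mu_i . mu_j`, where `d_sym` is the symmetric mean squared
#' nearest-neighbour vertex distance and the second term is the kernel norm
#' of the deformation. Optimisation runs in three stages, all sharing a
#' damped Gauss-Newton (Levenberg-Marquardt) step built on the frozen-weight
#' Jacobian of the flow (`x_final = x_0 + W mu` with `W` the kernel weights
#' accumulated along the current trajectory):
#'
#' 1. an optional soft-correspondence annealing phase (EM-ICP style): hard
#'    nearest neighbours are replaced by Gaussian-weighted soft targets whose
#'    temperature is cooled geometrically, which avoids the correspondence
#'    locking that traps plain iterative-closest-point schemes;
#' 2. a graduated-regularisation phase stepping the kernel-norm weight down
#'    to `lambda_reg` (coarse-to-fine smoothness);
#' 3. a final exact-nearest-neighbour phase at `lambda_reg`, whose accepted
#'    loss sequence is non-increasing by construction (the damping is raised
#'    until a step decreases the loss) and is returned as `loss_trace`.
#'
#' @param template,target [surface_mesh()] objects (rigidly pre-aligned).
#' @param deformation a [kernel_deformation()].
#' @param lambda_reg kernel-norm regularisation weight.
#' @param max_iter iteration cap for the final phase.
#' @param tol relative-improvement stopping threshold (final phase).
#' @param init optional initial momenta (defaults to zero).
#' @param anneal run the soft-correspondence initialisation (default TRUE).
#' @param anneal_factor,anneal_min,anneal_steps cooling schedule: temperature
#'   multiplier per stage, final temperature (mm), LM iterations per stage.
#' @return A list with `momenta`, `loss`, `data_loss`, `loss_trace` (final
#'   phase) and a `converged` flag; the best iterate is returned even
#'   without convergence.
#' @export
fit_momenta <- function(template, target, deformation, lambda_reg = 1e-3,
                        max_iter = 150L, tol = 1e-8, init = NULL,
                        anneal = TRUE, anneal_factor = 0.85,
                        anneal_min = 0.2, anneal_steps = 5L) {
  Tv <- mesh_points(template)
  Yv <- mesh_points(target)
  q0 <- deformation$control_points
  n_cp <- nrow(q0)
  K0 <- exp(-cross_dist2(q0, q0) / deformation$sigma^2)
  mu <- if (is.null(init)) matrix(0, n_cp, 3L) else to_points(init)
  if (nrow(mu) != n_cp) stop("init momenta must pair with control points")

  # exact symmetric-NN objective with frozen-weight LM ingredients
  eval_hard <- function(mu, lambda) {
    dd <- deform_points(Tv, deformation, mu, return_weights = TRUE)
    X <- dd$points
    fwd <- nn_ref(X, Yv)
    bwd <- nn_ref(Yv, X)
    data_loss <- mean(fwd$dist^2) + mean(bwd$dist^2)
    G <- 2 * (X - Yv[fwd$index, , drop = FALSE]) / nrow(X)
    delta <- 2 * (X[bwd$index, , drop = FALSE] - Yv) / nrow(Yv)
    agg <- rowsum(delta, group = bwd$index)
    G[as.integer(rownames(agg)), ] <-
      G[as.integer(rownames(agg)), , drop = FALSE] + agg
    cnt <- tabulate(bwd$index, nbins = nrow(X))
    wt <- 2 / nrow(X) + 2 * cnt / nrow(Yv)
    list(loss = data_loss + lambda * sum(mu * (K0 %*% mu)),
         data_loss = data_loss,
         grad = crossprod(dd$weights, G) + 2 * lambda * (K0 %*% mu),
         normal = crossprod(dd$weights * sqrt(wt)) + 2 * lambda * K0)
  }

  # soft-correspondence objective: Gaussian-weighted k-NN targets
  eval_soft <- function(mu, lambda, temp, kk = 10L) {
    dd <- deform_points(Tv, deformation, mu, return_weights = TRUE)
    X <- dd$points
    kk <- min(kk, nrow(Yv))
    kn <- FNN::get.knnx(Yv, X, k = kk)
    w <- exp(-(kn$nn.dist^2 - kn$nn.dist[, 1L]^2) / temp^2)
    w <- w / rowSums(w)
    Ybar <- matrix(0, nrow(X), 3L)
    for (j in seq_len(kk)) {
      Ybar <- Ybar + w[, j] * Yv[kn$nn.index[, j], , drop = FALSE]
    }
    data_loss <- mean(rowSums((X - Ybar)^2))
    list(loss = data_loss + lambda * sum(mu * (K0 %*% mu)),
         data_loss = data_loss,
         grad = crossprod(dd$weights, 2 * (X - Ybar) / nrow(X)) +
           2 * lambda * (K0 %*% mu),
         normal = crossprod(dd$weights * sqrt(2 / nrow(X))) + 2 * lambda * K0)
  }

  # damped Gauss-Newton loop; accepted losses are non-increasing
  lm_run <- function(mu, objective, iter_cap, tol_phase = 0) {
    cur <- objective(mu)
    trace <- numeric(iter_cap + 1L)
    trace[1L] <- cur$loss
    damp <- 1e-3
    converged <- FALSE
    it <- 0L
    while (it < iter_cap) {
      it <- it + 1L
      accepted <- FALSE
      for (half in 1:30) {
        step <- tryCatch(
          solve(cur$normal + damp * diag(n_cp), cur$grad),
          error = function(e) NULL)
        if (!is.null(step)) {
          cand <- objective(mu - step)
          if (is.finite(cand$loss) && cand$loss < cur$loss) {
            accepted <- TRUE
            break
          }
        }
        damp <- damp * 10
      }
      if (!accepted) { it <- it - 1L; converged <- TRUE; break }
      improve <- (cur$loss - cand$loss) / max(cur$loss, 1e-30)
      mu <- mu - step
      cur <- cand
      trace[it + 1L] <- cur$loss
      damp <- max(damp / 3, 1e-9)
      if (improve < tol_phase) { converged <- TRUE; break }
    }
    list(mu = mu, loss = cur$loss, data_loss = cur$data_loss,
         trace = trace[seq_len(it + 1L)], converged = converged,
         iterations = it)
  }

  lambda_coarse <- max(lambda_reg, 1e-3)
  if (anneal) {
    temp <- 2 * max(stats::median(nn_ref(Tv, Yv)$dist), anneal_min)
    while (temp > anneal_min) {
      mu <- lm_run(mu, function(m) eval_soft(m, lambda_coarse, temp),
                   anneal_steps)$mu
      temp <- temp * anneal_factor
    }
  }
  # graduated regularisation down to lambda_reg
  lams <- lambda_coarse
  while (utils::tail(lams, 1L) > max(lambda_reg, 1e-6) * 9.99) {
    lams <- c(lams, utils::tail(lams, 1L) / 10)
  }
  for (lam in lams[-length(lams)]) {
    mu <- lm_run(mu, function(m) eval_hard(m, lam), 30L, tol_phase = 1e-10)$mu
  }
  final <- lm_run(mu, function(m) eval_hard(m, lambda_reg), max_iter,
                  tol_phase = tol)
  list(momenta = final$mu, loss = final$loss, data_loss = final$data_loss,
       loss_trace = final$trace, converged = final$converged,
       iterations = final$iterations)
}

#' Rank and truncate control points by momenta variance
#'
#' Ranks control points by the total variance of their three momenta
#' components across subjects and keeps the `keep_n` highest-variance points
#' (the paper reduces a 500-point grid to 172 this way).
#'
#' @param momenta_stack n_subjects x (3 * n_cp) matrix of flattened momenta
#'   (rows as produced by [flatten_momenta()]), or a list of momenta
#'   matrices.
#' @param keep_n number of control points to keep.
#' @return Integer vector of kept control point indices, in decreasing
#'   variance order.
#' @export
truncate_control_points <- function(momenta_stack, keep_n) {
  if (is.list(momenta_stack)) {
    momenta_stack <- do.call(rbind, lapply(momenta_stack, flatten_momenta))
  }
  if (nrow(momenta_stack) < 2L) stop("need at least 2 subjects to rank")
  n_cp <- ncol(momenta_stack) / 3L
  if (n_cp != round(n_cp)) stop("momenta stack width must be 3 * n_cp")
  if (keep_n > n_cp) stop("keep_n exceeds the number of control points")
  v <- apply(momenta_stack, 2L, stats::var)
  per_cp <- rowSums(matrix(v, ncol = 3L, byrow = TRUE))
  order(per_cp, decreasing = TRUE)[seq_len(keep_n)]
}

#' Flatten momenta to a coefficient vector
#'
#' Row-major flattening `(x1, y1, z1, x2, ...)`: with the paper's 172 control
#' points this yields the 516-coefficient deformation vector.
#'
#' @param momenta n_cp x 3 momenta matrix.
#' @return Numeric vector of length `3 * n_cp`.
#' @seealso [reshape_momenta()] for the exact inverse.
#' @export
flatten_momenta <- function(momenta) {
  as.vector(t(to_points(momenta)))
}

#' Reshape a flattened deformation vector back to momenta
#'
#' @param v numeric vector of length `3 * n_cp`.
#' @return n_cp x 3 momenta matrix; exact inverse of [flatten_momenta()].
#' @export
reshape_momenta <- function(v) {
  if (length(v) %% 3L != 0L) stop("length must be a multiple of 3")
  matrix(v, ncol = 3L, byrow = TRUE)
}
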