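test_that("gaussian kernel matches its closed form", {
  q <- c(1, 2, 3)
  expect_equal(gaussian_kernel(q, q, 10), 1)
  x <- q + c(10, 0, 0) # distance = sigma
  expect_equal(gaussian_kernel(x, q, 10), exp(-1))
  far <- q + c(100, 0, 0) # 10 sigma
  expect_lt(gaussian_kernel(far, q, 10), 1e-40)
  expect_error(gaussian_kernel(x, q, 0), "positive")
  # symmetry and PSD of the kernel matrix on random control sets
  for (seed in 1:5) {
    pts <- with_seed(seed, matrix(stats::rnorm(60, sd = 20), ncol = 3L))
    K <- gaussian_kernel(pts, pts, 10)
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
  }
})

test_that("kernel flow deforms points as specified", {
  pts <- matrix(stats::rnorm(30, sd = 5), ncol = 3L)
  def <- kernel_deformation(pts[1:4, ], sigma = 10, n_steps = 1L)
  mu0 <- matrix(0, 4L, 3L)
  expect_equal(deform_points(pts, def, mu0), pts)

  # single control point, coincident point, one step: displacement is mu
  q <- matrix(c(0, 0, 0), 1L)
  def1 <- kernel_deformation(q, sigma = 10, n_steps = 1L)
  mu <- matrix(c(3, -2, 1), 1L)
  expect_equal(deform_points(q, def1, mu), q + mu)

  expect_error(deform_points(matrix(NA_real_, 1L, 3L), def1, mu),
               "non-finite")
  expect_error(deform_points(pts, def1, matrix(0, 2L, 3L)), "pair")
})

test_that("the Euler flow self-converges as steps refine", {
  set.seed(3)
  pts <- matrix(stats::rnorm(150, sd = 15), ncol = 3L)
  q <- matrix(stats::rnorm(24, sd = 15), ncol = 3L)
  mu <- matrix(stats::rnorm(24, sd = 3), ncol = 3L)
  ref <- deform_points(pts, kernel_deformation(q, 10, n_steps = 800L), mu)
  err <- vapply(c(25L, 100L, 200L), function(ns) {
    max(abs(deform_points(pts, kernel_deformation(q, 10, n_steps = ns), mu) -
              ref))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("rigid ICP recovers identity, translation and rotation", {
  surf <- small_template()$surface
  tr <- rigid_icp(surf, surf)
  expect_lt(sqrt(sum(tr$translation^2)), 1e-9)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_lt(max(tr$rotation %*% t(tr$rotation) - diag(3)), 1e-9)

  shifted <- surf
  shifted$vertices <- sweep(surf$vertices, 2L, c(5, 0, 0), `+`)
  tr2 <- rigid_icp(surf, shifted)
  expect_equal(tr2$translation, c(5, 0, 0), tolerance = 1e-6)

  th <- 10 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- surf
  rot$vertices <- surf$vertices %*% t(Rz)
  tr3 <- rigid_icp(surf, rot)
  ang_err <- acos(pmin(1, (sum(diag(t(tr3$rotation) %*% Rz)) - 1) / 2))
  expect_lt(ang_err, 1e-4)
  # mean squared distance decreases monotonically over iterations
  expect_true(all(diff(tr3$mse) <= 1e-12))

  line <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), ncol = 3L, byrow = TRUE)
  expect_warning(rigid_icp(line, surf), "degenerate")
})

test_that("control grid initialisation hits the target count and stays near
          the surface", {
  surf <- small_template()$surface
  grid <- init_control_grid(surf, n_target = 120L, sigma = 10)
  expect_gt(nrow(grid), 0.75 * 120)
  expect_lt(nrow(grid), 1.25 * 120)
  expect_lt(max(FNN::get.knnx(surf$vertices, grid, k = 1)$nn.dist), 10)
  expect_error(init_control_grid(surf, n_target = 0L), ">= 1")
})

test_that("momenta fitting recovers the identity and known deformations", {
  tpl <- small_template()
  grid <- init_control_grid(tpl$surface, n_target = 60L, sigma = 10)
  def <- kernel_deformation(grid, sigma = 10, n_steps = 5L)

  # identity target: fitted momenta vanish, loss near the zero-deformation
  # loss of zero
  fit0 <- fit_momenta(tpl$surface, tpl$surface, def, lambda_reg = 1e-3,
                      max_iter = 30L, anneal = FALSE)
  expect_lt(fit0$loss, 1e-6)
  expect_lt(max(abs(fit0$momenta)), 1e-3)

  # known-momenta target: forward model is the oracle
  mu_true <- with_seed(11, matrix(stats::rnorm(nrow(grid) * 3, 0, 1),
                                  ncol = 3L))
  tgt <- deform_mesh(tpl$surface, def, mu_true)
  fit <- fit_momenta(tpl$surface, tgt, def, lambda_reg = 1e-4,
                     max_iter = 60L)
  moved <- deform_points(tpl$surface$vertices, def, fit$momenta)
  d <- mean(FNN::get.knnx(tgt$vertices, moved, k = 1)$nn.dist)
  expect_lt(d, 0.1)
  expect_true(all(diff(fit$loss_trace) <= 0))
})

test_that("stronger regularisation shrinks fitted momenta monotonically", {
  tpl <- small_template()
  grid <- init_control_grid(tpl$surface, n_target = 40L, sigma = 10)
  def <- kernel_deformation(grid, sigma = 10, n_steps = 3L)
  mu_true <- with_seed(5, matrix(stats::rnorm(nrow(grid) * 3, 0, 0.8),
                                 ncol = 3L))
  tgt <- deform_mesh(tpl$surface, def, mu_true)
  norms <- vapply(c(1e-3, 1e-1, 10), function(lam) {
    f <- fit_momenta(tpl$surface, tgt, def, lambda_reg = lam,
                     max_iter = 25L, anneal = FALSE)
    sqrt(sum(f$momenta^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("fitted momenta are equivariant under joint translation", {
  tpl <- small_template()
  grid <- init_control_grid(tpl$surface, n_target = 40L, sigma = 10)
  mu_true <- with_seed(9, matrix(stats::rnorm(nrow(grid) * 3, 0, 0.6),
                                 ncol = 3L))
  def <- kernel_deformation(grid, sigma = 10, n_steps = 3L)
  tgt <- deform_mesh(tpl$surface, def, mu_true)
  fit_a <- fit_momenta(tpl$surface, tgt, def, max_iter = 15L,
                       anneal = FALSE)

  shift <- c(12, -7, 30)
  tpl_s <- tpl$surface
  tpl_s$vertices <- sweep(tpl_s$vertices, 2L, shift, `+`)
  tgt_s <- tgt
  tgt_s$vertices <- sweep(tgt_s$vertices, 2L, shift, `+`)
  def_s <- kernel_deformation(sweep(grid, 2L, shift, `+`), sigma = 10,
                              n_steps = 3L)
  fit_b <- fit_momenta(tpl_s, tgt_s, def_s, max_iter = 15L, anneal = FALSE)
  expect_equal(fit_a$momenta, fit_b$momenta, tolerance = 1e-6)
})

test_that("momenta flattening, reshaping and truncation behave as specified", {
  mu <- matrix(seq_len(12), ncol = 3L, byrow = TRUE)
  v <- flatten_momenta(mu)
  expect_identical(v, as.numeric(1:12))
  expect_identical(reshape_momenta(v), matrix(as.numeric(1:12), ncol = 3L,
                                              byrow = TRUE))
  expect_length(flatten_momenta(matrix(0, 172L, 3L)), 516L)
  expect_length(flatten_momenta(matrix(0, 1L, 3L)), 3L)

  # variance ranking: A's variance 10x B's puts A first; dead point last
  set.seed(2)
  stack <- cbind(matrix(stats::rnorm(40, sd = sqrt(10)), 20L), # cp 1 (x,y)
                 matrix(stats::rnorm(20, sd = 1), 20L, 1L),
                 matrix(stats::rnorm(60, sd = 1), 20L, 3L),    # cp 2
                 matrix(0, 20L, 3L))                           # cp 3 dead
  sel <- truncate_control_points(stack, 3L)
  expect_identical(sel[1L], 1L)
  expect_identical(sel[3L], 3L)
  expect_identical(sort(truncate_control_points(stack, 3L)), 1:3)
  expect_error(truncate_control_points(stack, 4L), "exceeds")
})
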