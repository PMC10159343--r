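test_that("normalised absolute error follows its definition", {
  true <- c(0, 50, 100)
  expect_equal(nae(true, true), c(0, 0, 0))
  pred <- c(0, 60, 100)
  expect_equal(nae(true, pred), c(0, 10, 0))
  expect_error(nae(c(1, 1, 1), c(1, 2, 1)), "zero-range")
  expect_error(nae(1:3, 1:4), "equal length")

  # range normalisation is affine-invariant: a*x+b on both leaves NAE fixed
  t0 <- stats::rnorm(50)
  p0 <- t0 + stats::rnorm(50, sd = 0.1)
  expect_equal(nae(3 * t0 - 7, 3 * p0 - 7), nae(t0, p0), tolerance = 1e-10)
})

test_that("error aggregation produces the stated summaries", {
  # perfect prediction: all summaries zero
  z <- matrix(0, 4L, 6L)
  rep0 <- aggregate_errors(z, z)
  expect_equal(rep0$population_mean, 0)
  expect_equal(rep0$population_sd, 0)
  expect_equal(rep0$bias, 0)
  expect_equal(rep0$loa_high - rep0$loa_low, 0)

  # constant signed offset c: bias c, zero-width limits of agreement
  c_ <- 3.5
  repc <- aggregate_errors(abs(matrix(c_, 4L, 6L)), matrix(c_, 4L, 6L))
  expect_equal(repc$bias, c_)
  expect_equal(repc$loa_low, c_)
  expect_equal(repc$loa_high, c_)

  # row/column means are MNAE_S / MNAE_N
  m <- matrix(1:6, 2L, 3L)
  repm <- aggregate_errors(m, m * 0)
  expect_equal(repm$mnae_subject, rowMeans(m))
  expect_equal(repm$mnae_node, colMeans(m))
  expect_true(repm$bias >= repm$loa_low && repm$bias <= repm$loa_high)

  # antisymmetric signed errors have exactly zero bias
  a <- with_seed(4, matrix(stats::rnorm(100), 10L))
  rep_a <- aggregate_errors(abs(rbind(a, -a)), rbind(a, -a))
  expect_equal(rep_a$bias, 0)

  expect_error(aggregate_errors(matrix(0, 0L, 0L), matrix(0, 0L, 0L)),
               "empty")
  expect_s3_class(summarise_errors(rep0), "tbl_df")
})

test_that("limits of agreement match the normal 1.96 quantile at n = 1e5", {
  se <- with_seed(12, matrix(stats::rnorm(1e5), 100L))
  rep_n <- aggregate_errors(abs(se), se)
  expect_equal(rep_n$loa_high, 1.96, tolerance = 0.02)
  expect_equal(rep_n$loa_low, -1.96, tolerance = 0.02)
})

test_that("mode-error correlations report Pearson R with t-distribution p", {
  X <- with_seed(5, matrix(stats::rnorm(300), 100L, 3L))
  err <- 2 * X[, 1L] + 5
  res <- mode_error_correlation(X, err)
  expect_equal(res$r[1L], 1, tolerance = 1e-10)
  expect_lt(res$p[1L], 1e-12)
  # cross-check a non-degenerate mode against stats::cor.test
  ct <- stats::cor.test(X[, 2L], err)
  expect_equal(res$r[2L], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p[2L], ct$p.value, tolerance = 1e-10)

  # zero-variance mode is missing, not zero
  Xz <- cbind(X[, 1:2], 1)
  expect_true(is.na(mode_error_correlation(Xz, err)$r[3L]))

  # n = 3 collinear: |R| = 1 with 1 df
  res3 <- mode_error_correlation(matrix(c(1, 2, 3), 3L, 1L), c(2, 4, 6))
  expect_equal(abs(res3$r), 1)

  # independence null: |R| < 0.1 in ~99% of trials at n = 1000
  hits <- vapply(1:200, function(s) {
    with_seed(1000 + s, {
      x <- stats::rnorm(1000)
      y <- stats::rnorm(1000)
      abs(stats::cor(x, y)) < 0.1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("gradient extraction averages plane slabs over 99 stations", {
  tpl <- small_template()
  fld <- solve_pseudo_cfd(tpl$volume, tpl$centerline)
  g <- suppressWarnings(
    extract_gradient(fld, tpl$volume, tpl$centerline))
  expect_length(g$stations, 99L)
  expect_length(g$values, 99L)
  expect_true(all(diff(g$stations) > 0))

  # constant field: every station value equals the constant
  gc <- suppressWarnings(
    extract_gradient(rep(7, nrow(tpl$volume$nodes)), tpl$volume$nodes,
                     tpl$centerline))
  expect_true(all(gc$values == 7))

  # a field equal to the arc length of the nearest station reproduces the
  # station positions to within half a slab
  s_node <- tpl$centerline$arc_length[
    FNN::get.knnx(tpl$centerline$points, tpl$volume$nodes, k = 1)$nn.index]
  gs <- suppressWarnings(
    extract_gradient(s_node, tpl$volume$nodes, tpl$centerline))
  h <- diff(gs$stations[1:2])
  # node arc lengths are discrete at the mesh's ring spacing, and empty
  # slabs inherit a neighbour, so the bound is half a ring plus half a slab
  ring_h <- max(tpl$centerline$arc_length) /
    (nrow(tpl$centerline$points) - 1L)
  expect_lt(max(abs(gs$values - gs$stations)), (ring_h + h) / 2 + 1e-9)

  expect_error(extract_gradient(1:5, matrix(0, 4L, 3L), tpl$centerline),
               "equal length")
})

test_that("discrete Frechet distance equals brute-force coupling search", {
  expect_equal(frechet_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(frechet_distance(c(1, 2, 3), c(1, 2, 3) + 4), 4)
  expect_equal(frechet_distance(c(0, 1, 0), c(0, 0, 0)), 1)
  expect_error(frechet_distance(numeric(0), 1), "empty")

  for (case in 1:100) {
    ab <- with_seed(case, {
      list(a = stats::rnorm(sample(2:7, 1L)),
           b = stats::rnorm(sample(2:7, 1L)))
    })
    expect_equal(frechet_distance(ab$a, ab$b), frechet_brute(ab$a, ab$b))
  }
})

test_that("Frechet distance respects its elementary bounds", {
  for (case in 1:25) {
    ab <- with_seed(200 + case, {
      n <- sample(3:9, 1L)
      list(a = stats::rnorm(n), b = stats::rnorm(n))
    })
    fd <- frechet_distance(ab$a, ab$b)
    expect_equal(fd, frechet_distance(ab$b, ab$a))
    expect_gte(fd + 1e-12, max(abs(ab$a[1L] - ab$b[1L]),
                               abs(ab$a[length(ab$a)] - ab$b[length(ab$b)])))
    expect_lte(fd, max(abs(ab$a - ab$b)) + 1e-12)
  }
})

test_that("centerline geometry matches closed forms", {
  # semicircular arc: tortuosity = pi/2
  th <- seq(0, pi, length.out = 200L)
  arc <- centerline(cbind(cos(th), sin(th), 0), rep(0.2, 200L))
  gs <- geometry_stats(arc)
  expect_equal(gs$tortuosity, pi / 2, tolerance = 1e-4)
  expect_equal(gs$mean_torsion, 0)
  expect_equal(gs$mean_diameter_mm, 0.4)

  # circular helix: torsion converges to b / (a^2 + b^2)
  a <- 3
  b <- 0.8
  tau_true <- b / (a^2 + b^2)
  err <- vapply(c(100L, 200L, 400L), function(n) {
    t_ <- seq(0, 6 * pi, length.out = n)
    hel <- centerline(cbind(a * cos(t_), a * sin(t_), b * t_), rep(1, n))
    abs(geometry_stats(hel)$mean_torsion - tau_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3L], 0.01 * tau_true)

  expect_error(geometry_stats(centerline(matrix(stats::rnorm(12), 4L),
                                         rep(1, 4L))),
               "at least 5")
})

test_that("Welch's t-test handles conventions and has power", {
  same <- c(1, 2, 3, 4)
  res <- welch_ttest(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # zero-variance conventions
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_ttest(c(2, 2), c(3, 3))$p, 0)

  # strong separation: p below 1e-6
  x <- with_seed(3, stats::rnorm(30, 0, 1))
  y <- with_seed(4, stats::rnorm(30, 10, 1))
  expect_lt(welch_ttest(x, y)$p, 1e-6)

  # null calibration: p values uniform over seeded repetitions
  ps <- vapply(1:200, function(s) {
    with_seed(5000 + s, welch_ttest(stats::rnorm(25), stats::rnorm(25))$p)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("regional labels and report export support regional analyses", {
  tpl <- small_template()
  reg <- node_regions(tpl$volume$nodes, tpl$centerline)
  expect_identical(levels(reg), c("ascending", "arch", "descending"))
  expect_true(all(table(reg) > 0))
  # labels follow arc length: the inlet station is ascending, the outlet
  # station descending
  first_station <- tpl$volume$stations == 1L
  expect_true(all(reg[first_station] == "ascending"))
  last_station <- tpl$volume$stations == max(tpl$volume$stations)
  expect_true(all(reg[last_station] == "descending"))

  # regional Bland-Altman via column subsetting keeps the identities
  se <- with_seed(77, matrix(stats::rnorm(5 * nrow(tpl$volume$nodes)), 5L))
  rep_all <- aggregate_errors(abs(se), se)
  rep_asc <- aggregate_errors(abs(se[, reg == "ascending"]),
                              se[, reg == "ascending"])
  expect_true(rep_asc$bias >= rep_asc$loa_low &&
                rep_asc$bias <= rep_asc$loa_high)
  expect_false(identical(rep_all$bias, rep_asc$bias))

  dir <- withr::local_tempdir()
  write_error_report(rep_all, dir)
  tab <- utils::read.delim(file.path(dir, "mnae_subject.tsv"))
  expect_equal(tab$mnae_s_pct, rep_all$mnae_subject)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$bias, rep_all$bias, tolerance = 1e-12)
})
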