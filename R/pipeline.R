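#' End-to-end experiment configuration
#'
#' Aggregates every stage setting of the experiment: cohort generation,
#' shape-model fitting (kernel width 10 mm, 500-point initial grid truncated
#' to 172), synthetic sampling within 2 SD, flow conditions (1.3 m/s, 0 Pa,
#' 1060 kg/m^3, 0.004 Pa.s), basis rules (99% variance for shape and
#' pressure, fixed 55 modes for velocity), the train/test split and the
#' network settings. Defaults are desk-scaled (40 targets, 350 synthetic
#' subjects) but every knob is exposed.
#'
#' @param cohort a [cohort_spec()].
#' @param ssm list: `sigma`, `grid_n`, `keep_n`, `n_steps`, `lambda_reg`,
#'   `max_iter`, `tol`.
#' @param sampling list: `n_synthetic`, `truncation_sd`.
#' @param flow a [flow_conditions()].
#' @param basis list: `shape_var`, `pressure_var`, `velocity_k`.
#' @param split list: `n_train`, `n_test` (must sum to at most
#'   `n_synthetic`).
#' @param net a [net_config()] used for both field networks (the final
#'   training epochs come from `epochs_final`).
#' @param epochs_final epochs for the final training runs.
#' @param tune list: `enabled`, `n_trials`, `strategy` (hyperparameter
#'   search before final training).
#' @param seed global integer seed; stage seeds derive from it via
#'   [derive_seed()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       ssm = list(),
                       sampling = list(),
                       flow = flow_conditions(),
                       basis = list(),
                       split = list(),
                       net = net_config(),
                       epochs_final = 200L,
                       tune = list(),
                       seed = 1L) {
  ssm <- utils::modifyList(list(sigma = 10, grid_n = 500L, keep_n = 172L,
                                n_steps = 10L, lambda_reg = 1e-3,
                                max_iter = 150L, tol = 1e-8,
                                anneal = TRUE, anneal_factor = 0.85,
                                anneal_steps = 5L), ssm)
  sampling <- utils::modifyList(list(n_synthetic = 350L, truncation_sd = 2),
                                sampling)
  basis <- utils::modifyList(list(shape_var = 0.99, pressure_var = 0.99,
                                  velocity_k = 55L), basis)
  split <- utils::modifyList(list(n_train = 300L, n_test = 50L), split)
  tune <- utils::modifyList(list(enabled = FALSE, n_trials = 10L,
                                 strategy = "random"), tune)
  if (split$n_train + split$n_test > sampling$n_synthetic) {
    stop("train + test split exceeds the synthetic cohort size")
  }
  structure(list(cohort = cohort, ssm = ssm, sampling = sampling,
                 flow = flow, basis = basis, split = split, net = net,
                 epochs_final = as.integer(epochs_final), tune = tune,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Scalar fields override the [run_config()] defaults; unknown fields are
#' rejected.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  known <- c("cohort", "ssm", "sampling", "flow", "basis", "split", "net",
             "epochs_final", "tune", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_spec, raw$cohort)
  if (!is.null(raw$flow)) args$flow <- do.call(flow_conditions, raw$flow)
  if (!is.null(raw$net)) args$net <- do.call(net_config, raw$net)
  for (nm in c("ssm", "sampling", "basis", "split", "tune")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$epochs_final)) args$epochs_final <- raw$epochs_final
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(run_config, args)
}

stage_artifact <- function(out_dir, stage) {
  file.path(out_dir, paste0(stage, ".rds"))
}

run_stage <- function(stage, out_dir, resume, manifest_env, fn) {
  path <- stage_artifact(out_dir, stage)
  if (resume && file.exists(path)) {
    message(sprintf("[%s] reusing %s", stage, basename(path)))
    return(readRDS(path))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fn(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  saveRDS(res, path)
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf("[%s] done in %.1f s", stage, dt))
  manifest_env$stages[[stage]] <- list(
    artifact = basename(path), seconds = round(dt, 2),
    md5 = unname(tools::md5sum(path)))
  res
}

#' Run the full shape-to-flow experiment
#'
#' Executes every stage in order — generate template and targets, fit the
#' kernel shape model, build the shape basis, sample the synthetic cohort,
#' shoot meshes, run the pseudo-CFD closure, fit the field bases, train the
#' pressure and velocity surrogates and evaluate them — persisting every
#' intermediate artifact in `out_dir` together with a manifest (config hash,
#' stage seeds, artifact checksums, durations). With `resume = TRUE` any
#' stage whose artifact already exists is reloaded instead of recomputed.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param resume reuse existing stage artifacts.
#' @return Invisibly, a list with the evaluation results, the metric
#'   summary, and the manifest path.
#' @export
run_all <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_env <- new.env()
  manifest_env$stages <- list()
  seed <- config$seed
  cohort <- config$cohort

  template <- run_stage("template", out_dir, resume, manifest_env, function() {
    generate_template_aorta(cohort)
  })
  targets <- run_stage("targets", out_dir, resume, manifest_env, function() {
    generate_target_population(template, cohort)
  })

  ssm <- run_stage("ssm", out_dir, resume, manifest_env, function() {
    fit_ssm(template, targets, config$ssm)
  })

  shape_basis <- run_stage("shape_basis", out_dir, resume, manifest_env,
                           function() {
    basis <- fit_pca(ssm$momenta_matrix, var_target = config$basis$shape_var)
    list(basis = basis, scores = pca_project(basis, ssm$momenta_matrix))
  })

  cohort_sample <- run_stage("sample", out_dir, resume, manifest_env,
                             function() {
    sample_cohort(template, ssm, shape_basis, config)
  })

  fields <- run_stage("fields", out_dir, resume, manifest_env, function() {
    build_cohort_fields(cohort_sample$volumes, cohort_sample$centerlines,
                        config$flow)
  })

  models <- run_stage("models", out_dir, resume, manifest_env, function() {
    train_models(cohort_sample, fields, config)
  })

  evaluation <- run_stage("evaluation", out_dir, resume, manifest_env,
                          function() {
    evaluate_run(template, targets, cohort_sample, fields, models, config)
  })

  summary <- evaluation$summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("shapeflow")),
    config_hash = digest_config(unclass_deep(config)),
    global_seed = seed,
    stage_seeds = list(sample = derive_seed(seed, "sample"),
                       split = derive_seed(seed, "split"),
                       train = derive_seed(seed, "train")),
    stages = manifest_env$stages)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(evaluation = evaluation, summary = summary,
                 manifest = manifest_path, out_dir = out_dir))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Fit the kernel shape model to a target population
#'
#' Initialises the control grid on the template, registers every target
#' (rigid ICP refinement, then momenta estimation), truncates the grid to
#' the highest-variance control points and returns the truncated momenta
#' stack.
#'
#' @param template result of [generate_template_aorta()].
#' @param targets list of target [surface_mesh()] objects.
#' @param ssm_cfg the `ssm` sub-list of a [run_config()].
#' @return A list: `deformation` (truncated [kernel_deformation()]),
#'   `momenta_matrix` (n x 3*keep_n), `kept` indices, per-target fit
#'   diagnostics.
#' @export
fit_ssm <- function(template, targets, ssm_cfg = list()) {
  ssm_cfg <- utils::modifyList(
    list(sigma = 10, grid_n = 500L, keep_n = 172L, n_steps = 10L,
         lambda_reg = 1e-3, max_iter = 150L, tol = 1e-8, anneal = TRUE,
         anneal_factor = 0.85, anneal_steps = 5L), ssm_cfg)
  grid <- init_control_grid(template$surface, n_target = ssm_cfg$grid_n,
                            sigma = ssm_cfg$sigma)
  deformation <- kernel_deformation(grid, sigma = ssm_cfg$sigma,
                                    n_steps = ssm_cfg$n_steps)
  fits <- lapply(targets, function(tgt) {
    tr <- rigid_icp(tgt, template$surface)
    aligned <- apply_rigid(tr, tgt)
    fit_momenta(template$surface, aligned, deformation,
                lambda_reg = ssm_cfg$lambda_reg,
                max_iter = ssm_cfg$max_iter, tol = ssm_cfg$tol,
                anneal = ssm_cfg$anneal,
                anneal_factor = ssm_cfg$anneal_factor,
                anneal_steps = ssm_cfg$anneal_steps)
  })
  stack <- do.call(rbind, lapply(fits, function(f) flatten_momenta(f$momenta)))
  keep_n <- min(ssm_cfg$keep_n, nrow(grid))
  kept <- sort(truncate_control_points(stack, keep_n))
  cols <- as.vector(t(outer(kept, 1:3, function(i, k) 3L * (i - 1L) + k)))
  trunc_def <- kernel_deformation(grid[kept, , drop = FALSE],
                                  sigma = ssm_cfg$sigma,
                                  n_steps = ssm_cfg$n_steps)
  list(deformation = trunc_def,
       momenta_matrix = stack[, cols, drop = FALSE],
       kept = kept,
       final_loss = vapply(fits, function(f) f$loss, numeric(1)),
       data_loss = vapply(fits, function(f) f$data_loss, numeric(1)),
       converged = vapply(fits, function(f) f$converged, logical(1)))
}

# sample synthetic score vectors, reconstruct momenta and shoot the
# template. Rare extreme score combinations produce meshes that violate the
# solver's mesh/centerline validity bound (nodes beyond 1.5 x local radius,
# e.g. self-approaching sharply angulated arches); those are rejected and
# replaced from an oversampled pool so the cohort is, by construction, a
# cohort of solvable subjects.
sample_cohort <- function(template, ssm, shape_basis, config) {
  n <- config$sampling$n_synthetic
  pool <- sample_synthetic(shape_basis$basis, shape_basis$scores, 2L * n,
                           truncation_sd = config$sampling$truncation_sd,
                           seed = derive_seed(config$seed, "sample"))
  momenta_rows <- pca_reconstruct(shape_basis$basis, pool)
  volumes <- vector("list", n)
  centerlines <- vector("list", n)
  keep <- integer(n)
  got <- 0L
  rejected <- 0L
  for (i in seq_len(nrow(pool))) {
    mu <- reshape_momenta(momenta_rows[i, ])
    vol <- deform_mesh(template$volume, ssm$deformation, mu)
    cl <- refine_centerline(update_centerline_radius(
      deform_mesh(template$centerline, ssm$deformation, mu), vol))
    nn <- nn_ref(vol$nodes, cl$points)
    if (max(nn$dist / cl$radius[nn$index]) > 1.5) {
      rejected <- rejected + 1L
      next
    }
    got <- got + 1L
    keep[got] <- i
    volumes[[got]] <- vol
    centerlines[[got]] <- cl
    if (got == n) break
  }
  if (got < n) {
    stop(sprintf("only %d of %d synthetic subjects were solvable", got, n))
  }
  if (rejected > 0L) {
    warning(sprintf("rejected %d unsolvable synthetic subjects", rejected))
  }
  list(scores = pool[keep, , drop = FALSE], volumes = volumes,
       centerlines = centerlines, n_rejected = rejected)
}

# split, fit field bases on training rows only, train both networks
train_models <- function(cohort_sample, fields, config) {
  n <- nrow(fields$pressure)
  split_seed <- derive_seed(config$seed, "split")
  idx <- with_seed(split_seed, sample.int(n))
  train_idx <- idx[seq_len(config$split$n_train)]
  test_idx <- idx[config$split$n_train + seq_len(config$split$n_test)]
  X <- cohort_sample$scores
  cfg <- config$net
  cfg$epochs <- config$epochs_final
  cfg$rng_seed <- derive_seed(config$seed, "train")
  fit_one <- function(F_all, var_target, fixed_k) {
    basis <- fit_pca(F_all[train_idx, , drop = FALSE],
                     var_target = var_target, fixed_k = fixed_k)
    if (isTRUE(config$tune$enabled)) {
      tuned <- tune_hyperparameters(
        X[train_idx, , drop = FALSE], F_all[train_idx, , drop = FALSE],
        n_trials = config$tune$n_trials, strategy = config$tune$strategy,
        seed = derive_seed(config$seed, "tune"),
        var_target = var_target, fixed_k = fixed_k,
        batch_size = cfg$batch_size, epochs = config$net$epochs)
      cfg$n_hidden_layers <- tuned$n_hidden_layers
      cfg$neurons_per_layer <- tuned$neurons_per_layer
      cfg$learning_rate <- tuned$learning_rate
    }
    train_surrogate(X[train_idx, , drop = FALSE],
                    F_all[train_idx, , drop = FALSE], basis, cfg,
                    validation = list(scores = X[test_idx, , drop = FALSE],
                                      fields = F_all[test_idx, , drop = FALSE]))
  }
  vel_k <- min(config$basis$velocity_k, config$split$n_train - 1L)
  list(pressure = fit_one(fields$pressure, config$basis$pressure_var, NULL),
       velocity = fit_one(fields$velocity, NULL, vel_k),
       train_idx = train_idx, test_idx = test_idx)
}

# test-set error reports, mode correlations, geometry comparison, Frechet
evaluate_run <- function(template, targets, cohort_sample, fields, models,
                         config) {
  test_idx <- models$test_idx
  X_test <- cohort_sample$scores[test_idx, , drop = FALSE]
  report_one <- function(model, F_all) {
    truth <- F_all[test_idx, , drop = FALSE]
    pred <- predict(model, X_test)
    nae_m <- t(vapply(seq_len(nrow(truth)),
                      function(i) nae(truth[i, ], pred[i, ]),
                      numeric(ncol(truth))))
    sgn_m <- t(vapply(seq_len(nrow(truth)),
                      function(i) signed_nae(truth[i, ], pred[i, ]),
                      numeric(ncol(truth))))
    aggregate_errors(nae_m, sgn_m)
  }
  rep_p <- report_one(models$pressure, fields$pressure)
  rep_v <- report_one(models$velocity, fields$velocity)

  corr_p <- mode_error_correlation(X_test, rep_p$mnae_subject)
  corr_v <- mode_error_correlation(X_test, rep_v$mnae_subject)

  geo_syn <- do.call(rbind, lapply(cohort_sample$centerlines, geometry_stats))
  geo_tgt <- do.call(rbind, lapply(targets, function(s) {
    geometry_stats(surface_centerline_proxy(s))
  }))
  geo_tests <- lapply(names(geo_syn), function(nm) {
    welch_ttest(geo_syn[[nm]], geo_tgt[[nm]])$p
  })
  names(geo_tests) <- names(geo_syn)

  # gradient curves + Frechet for the best/median/worst pressure subjects
  ord <- order(rep_p$mnae_subject)
  pick <- unique(c(ord[1L], ord[ceiling(length(ord) / 2)],
                   ord[length(ord)]))
  frechet <- lapply(pick, function(k) {
    i <- test_idx[k]
    vol <- cohort_sample$volumes[[i]]
    cl <- cohort_sample$centerlines[[i]]
    pred_p <- predict(models$pressure, cohort_sample$scores[i, ])
    pred_v <- predict(models$velocity, cohort_sample$scores[i, ])
    gp_t <- extract_gradient(fields$pressure[i, ], vol$nodes, cl)
    gp_p <- extract_gradient(pred_p, vol$nodes, cl)
    gv_t <- extract_gradient(fields$velocity[i, ], vol$nodes, cl)
    gv_p <- extract_gradient(pred_v, vol$nodes, cl)
    list(subject = i,
         fd_pressure = frechet_distance(gp_t$values, gp_p$values),
         fd_velocity = frechet_distance(gv_t$values, gv_p$values))
  })

  summary <- list(
    pressure = as.list(summarise_errors(rep_p)),
    velocity = as.list(summarise_errors(rep_v)),
    geometry_welch_p = geo_tests,
    frechet = list(
      pressure_pa = vapply(frechet, `[[`, numeric(1), "fd_pressure"),
      velocity_ms = vapply(frechet, `[[`, numeric(1), "fd_velocity")),
    n_test = length(test_idx))
  list(pressure_report = rep_p, velocity_report = rep_v,
       mode_correlation = list(pressure = corr_p, velocity = corr_v),
       geometry = list(synthetic = geo_syn, targets = geo_tgt,
                       welch_p = geo_tests),
       frechet = frechet, summary = summary)
}

# approximate a generated target's centerline from its tagged ring structure
surface_centerline_proxy <- function(surface) {
  if (is.null(surface$stations)) stop("surface lacks station tags")
  st <- surface$stations
  ok <- !is.na(st)
  centres <- rowsum(surface$vertices[ok, , drop = FALSE], st[ok]) /
    as.vector(table(st[ok]))
  # drop cap-centre contamination: stations 1 and max contain the cap vertex
  radii <- vapply(sort(unique(st[ok])), function(i) {
    ring <- surface$vertices[ok, , drop = FALSE][st[ok] == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(ring, 2L,
                            centres[as.character(i), ])^2)))
  }, numeric(1))
  keep <- radii > 0
  centerline(centres[keep, , drop = FALSE], pmax(radii[keep], 1e-6))
}
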