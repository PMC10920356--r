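# End-to-end orchestration: train -> autonomous generation -> raster ->
# VP distance matrix -> rank-ordered matrix -> top-k restriction ->
# persistence barcode -> Betti curves, with a manifest of all artifacts.

#' Pipeline configuration
#'
#' @param target a [target_spec()].
#' @param network list with `N`, `M`, `p`, `g` (NULL = calibrate), `q_fb`,
#'   `params` ([neuron_params()]), and optionally `rate_target` (Hz) for the
#'   gain calibration (default: 78 for the circle, 50 for the roses --- the
#'   mid-points of the observed firing-rate bands).
#' @param training a [train_config()].
#' @param analysis list with `q` (VP shift cost, 1/s), `top_k` (most active
#'   neurons kept for the topology stage), `rank_convention`
#'   (see [rank_order()]), `betti_grid` (number of grid points on [0, 1]),
#'   `rate_window` (s, population-rate window), `settle` (s of autonomous
#'   simulation discarded before the 1 s collection window).
#' @param seeds list with `connectivity`, `training`, `simulation`.
#' @param output_dir directory for all artifacts.
#' @export
pipeline_config <- function(target = target_spec("circle"),
                            network = list(),
                            training = train_config(),
                            analysis = list(),
                            seeds = list(connectivity = 1, training = 2,
                                         simulation = 3),
                            output_dir = tempfile("spiketopo_run_")) {
  net <- modifyList(list(N = 1000L, M = 2L, p = 0.1, g = NULL, q_fb = 40,
                         params = neuron_params(), rate_target = NULL),
                    network)
  if (is.null(net$rate_target))
    net$rate_target <- if (target$shape == "circle") 78 else 50
  ana <- modifyList(list(q = 1, top_k = 100L, rank_convention = "descending",
                         betti_grid = 512L, rate_window = 0.02, settle = 0),
                    analysis)
  stopifnot(ana$top_k <= net$N, inherits(target, "target_spec"),
            inherits(training, "train_config"))
  structure(list(target = target, network = net, training = training,
                 analysis = ana, seeds = seeds, output_dir = output_dir),
            class = "pipeline_config")
}

new_manifest <- function(config, output_dir) {
  list(config = config_snapshot(config), files = list(), checksums = list(),
       wall_clock_s = list(), output_dir = output_dir)
}

config_snapshot <- function(config) {
  if (is.list(config)) return(lapply(unclass(config), config_snapshot))
  config
}

manifest_add <- function(manifest, stage, files, elapsed) {
  manifest$files[[stage]] <- files
  fv <- unlist(files)
  manifest$checksums[[stage]] <-
    if (length(fv)) as.list(tools::md5sum(fv)) else list()
  manifest$wall_clock_s[[stage]] <- round(elapsed, 3)
  manifest
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

run_stage <- function(manifest, dir, stage, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    write_manifest(manifest, file.path(dir, "manifest_partial.json"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res$elapsed <- proc.time()[["elapsed"]] - t0
  res
}

# Analysis core shared by run_full and run_analysis_only: from raster to
# rates, D, M, top-k restriction, barcode and Betti curves, writing CSVs.
analyze_raster <- function(raster, ana, dir) {
  if (raster$n_neurons < 2) stop("need at least 2 spike trains")
  if (sum(lengths(raster$times)) == 0) stop("empty raster")
  rates <- firing_rates(raster)
  D <- vp_distance_matrix(raster, q = ana$q)
  Mr <- rank_order(D, rates, convention = ana$rank_convention)
  k <- min(ana$top_k, raster$n_neurons)
  Msub <- Mr$M[seq_len(k), seq_len(k)]  # rows already in descending rate
  bars <- rips_persistence(Msub, max_dim = 1)
  grid <- seq(0, 1, length.out = ana$betti_grid)
  bc <- betti_curves(bars, grid)
  files <- list(
    distance_matrix = file.path(dir, "vp_distance_matrix.csv"),
    rank_matrix = file.path(dir, "rank_matrix.csv"),
    barcode = file.path(dir, "barcode.csv"),
    betti = file.path(dir, "betti_curves.csv"))
  write_matrix_csv(D, files$distance_matrix)
  write_matrix_csv(Mr$M, files$rank_matrix,
                   ids = paste0("n", Mr$neuron_order))
  write_barcode_csv(bars, files$barcode)
  write_betti_csv(bc, files$betti)
  list(rates = rates, D = D, M = Mr, bars = bars, betti = bc, files = files)
}

#' Run the full study pipeline
#'
#' Calibrates the gain (when `g` is NULL), FORCE-trains the readout on the
#' target, freezes `W`, simulates 1 s (one closed traversal) autonomously,
#' and pushes the collected raster through the metric and topology stages.
#' All artifacts are written under `config$output_dir` together with a JSON
#' manifest (config snapshot, file paths, md5 checksums, wall clock per
#' stage).
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (also written as `manifest.json`), plus the
#'   in-memory results: `conn`, `train`, `generation` (raster/output),
#'   `analysis`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- config$network
  ana <- config$analysis
  manifest <- new_manifest(config, dir)

  # -- target ---------------------------------------------------------
  st <- run_stage(manifest, dir, "target", function() {
    traj <- generate_target(config$target)
    f <- file.path(dir, "target_trajectory.csv")
    write_trajectory_csv(traj, f)
    list(traj = traj, files = list(trajectory = f))
  })
  manifest <- manifest_add(manifest, "target", st$files, st$elapsed)

  # -- connectivity (+ gain calibration) ------------------------------
  sc <- run_stage(manifest, dir, "connectivity", function() {
    conn <- init_connectivity(net$N, net$M, p = net$p,
                              g = if (is.null(net$g)) 1 else net$g,
                              q_fb = net$q_fb,
                              seed = config$seeds$connectivity)
    calib <- NULL
    if (is.null(net$g)) {
      calib <- calibrate_gain(conn, net$params, config$target,
                              rate_target = net$rate_target,
                              seed = config$seeds$simulation)
      conn <- set_gain(conn, calib$g)
    }
    list(conn = conn, calib = calib, files = list())
  })
  manifest <- manifest_add(manifest, "connectivity", sc$files, sc$elapsed)

  # -- training -------------------------------------------------------
  tr_cfg <- config$training
  tr_cfg$seed <- config$seeds$training
  tr <- run_stage(manifest, dir, "training", function() {
    fit <- train_force(sc$conn, net$params, config$target, tr_cfg)
    f_err <- file.path(dir, "training_errors.csv")
    write.csv(fit$errors, f_err, row.names = FALSE, quote = FALSE)
    f_conn <- file.path(dir, "trained_connectivity.rds")
    write_connectivity(fit$conn, net$params, f_conn)
    c(fit, list(files = list(errors = f_err, connectivity = f_conn)))
  })
  manifest <- manifest_add(manifest, "training", tr$files, tr$elapsed)

  # -- autonomous generation (1 s collection window) ------------------
  gen <- run_stage(manifest, dir, "generation", function() {
    state <- tr$state
    if (ana$settle > 0) {
      pre <- run_network(tr$conn, net$params, ana$settle,
                         dt = config$target$dt, state = state,
                         record_every = 0L)
      state <- pre$state
    }
    run <- run_network(tr$conn, net$params, config$target$duration,
                       dt = config$target$dt, state = state)
    f_r <- file.path(dir, "raster.csv")
    write_raster_csv(run$raster, f_r)
    f_z <- file.path(dir, "output_trace.csv")
    write.csv(run$output, f_z, row.names = FALSE, quote = FALSE)
    rt <- mean_rate_trace(run$raster, window = ana$rate_window)
    f_rt <- file.path(dir, "rate_trace.csv")
    write.csv(rt, f_rt, row.names = FALSE, quote = FALSE)
    c(run, list(rate_trace = rt,
                files = list(raster = f_r, output = f_z, rate_trace = f_rt)))
  })
  manifest <- manifest_add(manifest, "generation", gen$files, gen$elapsed)

  # -- metric + topology ----------------------------------------------
  an <- run_stage(manifest, dir, "analysis", function() {
    analyze_raster(gen$raster, ana, dir)
  })
  manifest <- manifest_add(manifest, "analysis", an$files, an$elapsed)

  stopifnot(all(file.exists(unlist(manifest$files))))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  list(manifest = manifest, conn = tr$conn, calib = sc$calib, train = tr,
       generation = gen, analysis = an)
}

#' Metric/topology analysis of a stored or in-memory raster
#'
#' Entry point for user-supplied rasters and synthetic data: computes the
#' VP distance matrix, the rank-ordered matrix, the top-k restriction, the
#' persistence barcode and the Betti curves, writing all CSVs and a
#' manifest.
#'
#' @param raster a [spike_raster()] or a path to a raster CSV
#'   (see [read_raster_csv()]).
#' @param analysis analysis options as in [pipeline_config()].
#' @param output_dir output directory.
#' @param duration trial duration override when reading from CSV.
#' @return list with `manifest` and the analysis results (see
#'   [pipeline_config()] for the fields).
#' @export
run_analysis_only <- function(raster, analysis = list(),
                              output_dir = tempfile("spiketopo_an_"),
                              duration = NULL) {
  ana <- modifyList(list(q = 1, top_k = 100L, rank_convention = "descending",
                         betti_grid = 512L, rate_window = 0.02, settle = 0),
                    analysis)
  if (is.character(raster))
    raster <- read_raster_csv(raster, duration = duration)
  stopifnot(inherits(raster, "spike_raster"))
  dir <- output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- new_manifest(list(analysis = ana), dir)
  an <- run_stage(manifest, dir, "analysis", function() {
    analyze_raster(raster, ana, dir)
  })
  manifest <- manifest_add(manifest, "analysis", an$files, an$elapsed)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  c(an, list(manifest = manifest))
}

#' Evaluate a trained network against its target
#'
#' Simulates the trained network autonomously over one target period and
#' reports the RMSE between the readout and the target, normalized by the
#' target amplitude R.  An untrained readout (`W = 0`, `zhat = 0`) gives
#' the RMS of the target itself (`~0.707` for the circle).
#'
#' @param conn trained connectivity, or a path to a
#'   [write_connectivity()] archive.
#' @param target [target_spec()].
#' @param params [neuron_params()] (taken from the archive when `conn` is a
#'   path).
#' @param state optional starting [network_state()]; when absent a fresh
#'   seeded state is used after a settle period of one period.
#' @param seed seed for the fresh state.
#' @return list with `rmse_norm`, `rmse`, `output` (readout trace), and
#'   `target_values`.
#' @export
run_trajectory_eval <- function(conn, target, params = neuron_params(),
                                state = NULL, seed = NULL) {
  if (is.character(conn)) {
    arc <- read_connectivity(conn)
    conn <- arc$conn
    params <- arc$params
  }
  dt <- target$dt
  if (is.null(state)) {
    pre <- run_network(conn, params, target$duration, dt = dt, seed = seed,
                       record_every = 0L)
    state <- pre$state
  }
  run <- run_network(conn, params, target$duration, dt = dt, state = state,
                     record_every = 1L)
  n_steps <- as.integer(round(target$duration / dt))
  z_tgt <- target_teacher(target, n_steps, dt)
  zhat <- as.matrix(run$output[, -1, drop = FALSE])
  m <- min(nrow(zhat), nrow(z_tgt))
  rmse <- sqrt(mean((zhat[seq_len(m), ] - z_tgt[seq_len(m), ])^2))
  list(rmse_norm = rmse / target$amplitude, rmse = rmse,
       output = run$output, target_values = z_tgt, raster = run$raster,
       state = run$state)
}
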