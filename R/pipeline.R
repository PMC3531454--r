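#' Write result tables with a manifest
#'
#' Writes each table as CSV (column names carry units: `_s`, `_per_s`,
#' `_uM`), plus a JSON manifest with the configuration hash, seed, package
#' version and file list, and a plain-text log with stage timings.
#'
#' @param tables Named list of data.frames (possibly empty).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` (hashed into the manifest).
#' @param timings Optional named numeric vector of stage timings, s.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, dir, config = NULL, timings = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    ok <- tryCatch({ utils::write.csv(tables[[nm]], f, row.names = FALSE); TRUE },
                   error = function(e)
                     stop("failed writing ", f, ": ", conditionMessage(e),
                          call. = FALSE))
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "caspike",
    version = as.character(utils::packageVersion("caspike")),
    config_hash = if (is.null(config)) NA else config_hash(config),
    seed = if (is.null(config)) NA else config$run$seed,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log <- c(sprintf("caspike %s", manifest$version),
           sprintf("tables: %s", paste(files, collapse = ", ")))
  if (!is.null(timings))
    log <- c(log, sprintf("stage %s: %.2f s", names(timings), timings))
  writeLines(log, file.path(dir, "run.log"))
  invisible(manifest)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages of the hierarchic stochastic workflow: (optional)
#' De Young-Keizer map fitting, chain construction, analytic first-passage
#' and occupancy statistics, a sweep of the stimulation parameter, stochastic
#' simulation, and the generic-model comparison. Stages fail fast with
#' stage-tagged errors; individual stages can be skipped. All randomness
#' derives from `config$run$seed` and reruns are deterministic.
#'
#' @param config A [load_config()] result.
#' @param output_dir Output directory; default from the config.
#' @param skip Character vector of stages to skip, from
#'   `c("sweep", "simulate", "generic")`.
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config = load_config(), output_dir = NULL,
                         skip = character(0)) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(output_dir)) output_dir <- config$run$output_dir
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  set.seed(config$run$seed)
  tables <- list()

  map <- stage("map", {
    if (isTRUE(config$run$fit_dyk))
      fit_parameter_maps(config$cell, n_samples = config$run$n_samples,
                         seed = config$run$seed)
    else default_param_map()
  })
  chain <- stage("chain",
    spike_chain_from_map(config$cell, map,
                         n_clusters = config$chain$n_clusters,
                         puff_scope = config$chain$puff_scope))
  analytic <- stage("analytic", {
    cwt <- build_conditioned_waiting_times(chain)
    pi <- stationary_occupancy(cwt)
    fpt <- fpt_moments(cwt, 1L, chain$target_state)
    xi <- coupling_from_mechanistic(cwt)
    tables$occupancy <- data.frame(state = names(pi), probability = pi,
                                    row.names = NULL)
    tables$isi_analytic <- data.frame(
      t_av_s = fpt$mean, sigma_s = fpt$sd, cv = fpt$cv,
      skewness = fpt$skewness, excess_kurtosis = fpt$excess_kurtosis,
      xi = xi)
    list(cwt = cwt, occupancy = pi, fpt = fpt, xi = xi)
  })

  sweep <- if ("sweep" %in% skip) NULL else stage("sweep", {
    rows <- lapply(config$sweep$grid, function(v) {
      cp <- config$cell
      cp[[config$sweep$parameter]] <- if (config$sweep$parameter == "n_ch")
        as.integer(v) else v
      cp <- do.call(cell_params, unclass(cp))
      ch <- spike_chain_from_map(cp, map,
                                 n_clusters = config$chain$n_clusters,
                                 puff_scope = config$chain$puff_scope)
      f <- fpt_moments(ch, 1L, ch$target_state, n_max = 2)
      xi <- coupling_from_mechanistic(ch)
      data.frame(value = v, t_av_s = f$mean, sigma_s = f$sd, xi = xi)
    })
    sw <- do.call(rbind, rows)
    names(sw)[1] <- paste0(config$sweep$parameter,
                           if (config$sweep$parameter == "ip3") "_uM" else "")
    tables$sweep <- sw
    sw
  })

  sim <- if ("simulate" %in% skip) NULL else stage("simulate", {
    traj <- simulate_trajectory(chain, t_max = config$run$t_max,
                                seed = config$run$seed)
    train <- extract_spikes(traj, chain$target_state)
    tables$trajectory <- traj$events
    tables$spikes <- data.frame(spike_epoch_s = train$spike_epochs)
    st <- if (length(train$isis) >= 2)
      isi_statistics(train, seed = config$run$seed) else NULL
    comparison <- data.frame(
      quantity = c("t_av_s", "occupancy_0"),
      analytic = c(analytic$fpt$mean, unname(analytic$occupancy[1])),
      simulated = c(if (is.null(st)) NA else st$mean,
                    unname(occupancy_fraction(traj)[1])))
    tables$comparison <- comparison
    list(trajectory = traj, train = train, stats = st)
  })

  gen <- if ("generic" %in% skip) NULL else stage("generic", {
    xi <- config$generic$xi %||% analytic$xi
    lam0 <- chain$trans[[1]][[1]]$dist$rate
    gp <- generic_params(lam0, xi, rho = config$generic$rho, n_clusters = 1)
    gm <- generic_moments(gp)
    tables$generic <- data.frame(
      lambda_inf_per_s = gp$lambda_inf, rho_per_s = config$generic$rho,
      t_av_s = gm$mean, sigma_s = gm$sd, cv = gm$cv,
      t_av_exact_s = analytic$fpt$mean,
      rel_error = abs(analytic$fpt$mean - gm$mean) / analytic$fpt$mean)
    gm
  })

  manifest <- stage("write", write_results(tables, output_dir, config,
                                           timings = unlist(timings)))
  invisible(list(map = map, chain = chain, analytic = analytic,
                 sweep = sweep, simulation = sim, generic = gen,
                 manifest = manifest, output_dir = output_dir))
}
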