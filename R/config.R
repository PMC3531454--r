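#' Load and validate a run configuration
#'
#' Reads a flat YAML document with sections `cell` (cellular parameters),
#' `chain` (`n_clusters`, `target_state`, `puff_scope`), `generic` (`rho`,
#' optional `xi` override), `sweep` (`parameter`, `grid`) and `run` (`seed`,
#' `t_max`, `n_samples`, `output_dir`, `fit_dyk`). Missing fields take the
#' standard defaults (N_ch = 5, \[IP3\] = 1 uM, Ca base/open = 0.01/0.6 uM);
#' unknown keys are rejected with field-level messages. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  validate_config(raw)
}

config_schema <- function() {
  list(
    cell = list(ip3 = 1, ca_base = 0.01, ca_open = 0.6, n_ch = 5L,
                lambda_cl = 50),
    chain = list(n_clusters = 4L, target_state = 4L,
                 puff_scope = "cluster"),
    generic = list(rho = Inf, xi = NULL),
    sweep = list(parameter = "ip3", grid = c(0.05, 0.1, 0.3, 1, 3, 8)),
    run = list(seed = 1L, t_max = 2000, n_samples = 1e4,
               output_dir = "caspike-results", fit_dyk = FALSE))
}

validate_config <- function(raw) {
  schema <- config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- schema
  for (sec in names(raw)) {
    if (!is.list(raw[[sec]]))
      stop(sprintf("config section '%s' must be a mapping", sec), call. = FALSE)
    badk <- setdiff(names(raw[[sec]]), names(schema[[sec]]))
    if (length(badk))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(badk, collapse = ", ")), call. = FALSE)
    for (k in names(raw[[sec]])) {
      if (is.null(raw[[sec]][[k]])) next  # YAML null: keep the default
      cfg[[sec]][[k]] <- raw[[sec]][[k]]
    }
  }
  # field-level validation; cell_params() enforces its own invariants
  cfg$cell <- tryCatch(do.call(cell_params, cfg$cell), error = function(e)
    stop("config field 'cell': ", conditionMessage(e), call. = FALSE))
  ch <- cfg$chain
  if (!(ch$n_clusters >= 2 && ch$n_clusters == round(ch$n_clusters)))
    stop("config field 'chain.n_clusters': integer >= 2 required", call. = FALSE)
  if (!(ch$target_state >= 1 && ch$target_state <= ch$n_clusters))
    stop("config field 'chain.target_state': must lie in 1..n_clusters",
         call. = FALSE)
  if (!ch$puff_scope %in% c("cluster", "cell"))
    stop("config field 'chain.puff_scope': 'cluster' or 'cell'", call. = FALSE)
  if (!is.null(cfg$generic$xi) && (cfg$generic$xi <= 0 || cfg$generic$xi > 1))
    stop("config field 'generic.xi': must lie in (0, 1]", call. = FALSE)
  if (cfg$generic$rho <= 0)
    stop("config field 'generic.rho': rate > 0 (or .inf) required", call. = FALSE)
  if (!cfg$sweep$parameter %in% c("ip3", "n_ch"))
    stop("config field 'sweep.parameter': 'ip3' or 'n_ch'", call. = FALSE)
  if (length(cfg$sweep$grid) < 2 || any(cfg$sweep$grid <= 0))
    stop("config field 'sweep.grid': >= 2 positive values", call. = FALSE)
  rn <- cfg$run
  if (!(rn$t_max > 0) || !(rn$n_samples >= 1) ||
      rn$seed != round(rn$seed))
    stop("config field 'run': t_max > 0, n_samples >= 1, integer seed",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML
#'
#' Round-trip companion of [load_config()]: `load_config(write_config(x))`
#' reproduces the normalised configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$cell <- unclass(out$cell)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$cell)
  cat(sprintf("  chain: N = %d, target = %d, puff scope '%s'\n",
              x$chain$n_clusters, x$chain$target_state, x$chain$puff_scope))
  cat(sprintf("  generic: rho = %g s^-1%s\n", x$generic$rho,
              if (is.null(x$generic$xi)) "" else
                sprintf(", xi override %g", x$generic$xi)))
  cat(sprintf("  sweep: %s over %s\n", x$sweep$parameter,
              paste(x$sweep$grid, collapse = ", ")))
  cat(sprintf("  run: seed %d, t_max %g s, n_samples %g, output '%s'\n",
              x$run$seed, x$run$t_max, x$run$n_samples, x$run$output_dir))
  invisible(x)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  out <- unclass(cfg)
  out$cell <- unclass(out$cell)
  out$generic$rho <- format(out$generic$rho)
  jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
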