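#' Evaluate a Hill function
#'
#' `offset + vmax * x^h / (K^h + x^h)`: the functional form used for the
#' dependence of the puff rate and the GE parameters on cellular parameters.
#' The offset is 0 for rate-type maps and 1 for the GE shape map (a GE
#' distribution changes character at shape 1, so the shape never drops
#' below it).
#'
#' @param x Abscissa (>= 0); concentration in uM or a channel count.
#' @param p List with `vmax`, `K` (> 0), `h` (> 0), `offset`.
#' @return Hill-curve values.
#' @export
hill_eval <- function(x, p) {
  stopifnot(is.list(p), all(c("vmax", "K", "h") %in% names(p)))
  if (p$K <= 0 || p$h <= 0)
    stop("Hill parameters require K > 0 and h > 0", call. = FALSE)
  off <- p$offset %||% 0
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  off + p$vmax * x^p$h / (p$K^p$h + x^p$h)
}

fit_hill <- function(x, y, offset = 0) {
  dat <- data.frame(x = x, y = y - offset)
  v0 <- max(dat$y) * 1.1
  K1 <- x[which.min(abs(dat$y - v0 / 2))]
  # multi-start: half-saturation may lie below the grid when the curve is
  # already saturated over the sampled range
  starts <- expand.grid(vmax = v0, K = unique(c(K1, min(x) / 4, min(x),
                                                stats::median(x), max(x))),
                        h = c(0.5, 1, 2))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ vmax * x^h / (K^h + x^h), data = dat,
                        start = as.list(starts[r, ]),
                        lower = c(1e-12, 1e-9, 0.05),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed for all starts", call. = FALSE)
  cf <- as.list(stats::coef(best$fit))
  list(vmax = cf$vmax, K = cf$K, h = cf$h, offset = offset, rss = best$rss)
}

fit_linear <- function(x, y) {
  fit <- stats::lm(y ~ x)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       rss = sum(stats::residuals(fit)^2))
}

eval_component <- function(comp, x) {
  switch(comp$form,
    hill = hill_eval(x, comp$fit),
    linear = comp$fit$intercept + comp$fit$slope * x,
    stop("unknown component form", call. = FALSE))
}

#' Fit the cellular parameter maps from the De Young-Keizer model
#'
#' Reproduces the map-building procedure of the hierarchic model: cluster
#' first-opening times are sampled from the De Young-Keizer channel chain on
#' a grid of cellular parameters, fitted per grid point (exponential rate at
#' basal Ca2+, GE at the puff-elevated Ca2+), and the parameter dependencies
#' are then condensed into analytical forms: Hill curves in \[IP3\] for the
#' puff rate and the GE scale, a Hill curve with offset 1 for the GE shape,
#' and linear forms in `n_ch` (whose dependencies are close to linear).
#' `n_ch` is a discrete variable, so its maps are only meant to be evaluated
#' at integers. The 1-D dependencies are combined multiplicatively after
#' normalisation at the reference parameter point (each grid varies one
#' parameter with the others held at the reference).
#'
#' @param params Reference [cell_params()] (defines `ca_base`, `ca_open`,
#'   `lambda_cl` and the reference `ip3`, `n_ch`).
#' @param ip3_grid Grid of IP3 concentrations, uM (>= 4 points).
#' @param nch_grid Grid of channels-per-cluster values (>= 4 integer points).
#' @param n_samples First-opening samples per grid point (default 10^4).
#' @param seed Integer seed; map construction is seed-reproducible.
#' @return An object of class `param_map` with components `puff_rate`
#'   (s^-1), `open_shape`, `open_rate` (s^-1), each holding `ip3` and `nch`
#'   1-D fits, reference values, fitted ranges and per-panel status.
#' @export
fit_parameter_maps <- function(params = cell_params(),
                               ip3_grid = c(0.05, 0.1, 0.3, 1, 3, 8),
                               nch_grid = c(2, 3, 5, 7, 10),
                               n_samples = 1e4, seed = 1L) {
  stopifnot(inherits(params, "cell_params"),
            length(ip3_grid) >= 4, length(nch_grid) >= 4)
  if (!is.null(seed)) set.seed(seed)
  ref <- params
  # the channel-level first-passage law depends on (Ca, IP3) only, so sweeps
  # over n_ch (and both Ca contexts of one IP3 value) share cached objects
  gen_cache <- new.env(parent = emptyenv())
  get_gen <- function(ca, ip3) {
    key <- paste(ca, ip3)
    if (is.null(gen_cache[[key]]))
      gen_cache[[key]] <- build_dyk_generator(
        cell_params(ip3 = ip3, ca_base = ref$ca_base, ca_open = ref$ca_open,
                    n_ch = ref$n_ch, lambda_cl = ref$lambda_cl), ca = ca)
    gen_cache[[key]]
  }
  fpt_cache <- new.env(parent = emptyenv())
  get_fpt <- function(ca, ip3) {
    key <- paste(ca, ip3)
    if (is.null(fpt_cache[[key]])) {
      gen <- get_gen(ca, ip3)
      fpt_cache[[key]] <- if (isTRUE(all.equal(ca, ref$ca_base)))
        dyk_first_opening(gen)
      else
        dyk_first_opening(gen,
                          init = dyk_stationary(get_gen(ref$ca_base,
                                                        ip3))$pi[!gen$open])
    }
    fpt_cache[[key]]
  }
  sample_point <- function(ip3, n_ch, ca) {
    p <- cell_params(ip3 = ip3, ca_base = ref$ca_base, ca_open = ref$ca_open,
                     n_ch = n_ch, lambda_cl = ref$lambda_cl)
    sample_first_opening_times(p, n_samples, fpt = get_fpt(ca, ip3))
  }
  # puff context: basal Ca, exponential rate = 1/mean
  puff_ip3 <- vapply(ip3_grid, function(v)
    1 / mean(sample_point(v, ref$n_ch, ref$ca_base)), numeric(1))
  puff_nch <- vapply(nch_grid, function(v)
    1 / mean(sample_point(ref$ip3, v, ref$ca_base)), numeric(1))
  # puff (CICR) context: elevated Ca, GE fits
  ge_ip3 <- lapply(ip3_grid, function(v)
    fit_waiting_time(sample_point(v, ref$n_ch, ref$ca_open), "ge")$params)
  ge_nch <- lapply(nch_grid, function(v)
    fit_waiting_time(sample_point(ref$ip3, v, ref$ca_open), "ge")$params)
  shape_ip3 <- vapply(ge_ip3, `[[`, numeric(1), "shape")
  rate_ip3 <- vapply(ge_ip3, `[[`, numeric(1), "rate")
  shape_nch <- vapply(ge_nch, `[[`, numeric(1), "shape")
  rate_nch <- vapply(ge_nch, `[[`, numeric(1), "rate")

  panel <- function(form, x, y, offset = 0) {
    res <- tryCatch({
      fit <- if (form == "hill") fit_hill(x, y, offset) else fit_linear(x, y)
      list(form = form, fit = fit, x = x, y = y, status = "ok")
    }, error = function(e)
      list(form = form, fit = NULL, x = x, y = y, status = "failed",
           message = conditionMessage(e)))
    res
  }
  comps <- list(
    puff_rate = list(ip3 = panel("hill", ip3_grid, puff_ip3),
                     nch = panel("linear", nch_grid, puff_nch)),
    open_shape = list(ip3 = panel("hill", ip3_grid, shape_ip3, offset = 1),
                      nch = panel("hill", nch_grid, shape_nch, offset = 1)),
    open_rate = list(ip3 = panel("hill", ip3_grid, rate_ip3),
                     nch = panel("linear", nch_grid, rate_nch)))
  failed <- unlist(lapply(comps, function(cc)
    vapply(cc, function(pn) pn$status != "ok", logical(1))))
  refvals <- list(
    puff_rate = unname(puff_ip3[which.min(abs(ip3_grid - ref$ip3))]),
    open_shape = unname(shape_ip3[which.min(abs(ip3_grid - ref$ip3))]),
    open_rate = unname(rate_ip3[which.min(abs(ip3_grid - ref$ip3))]))
  structure(list(components = comps, reference = ref, ref_values = refvals,
                 ranges = list(ip3 = range(ip3_grid), nch = range(nch_grid)),
                 n_samples = n_samples, seed = seed,
                 partial = any(failed)),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf(paste0("DYK parameter map (reference [IP3] = %g uM, N_ch = %d; ",
                     "%g samples/point, seed %s%s)\n"),
              x$reference$ip3, x$reference$n_ch, x$n_samples,
              format(x$seed), if (x$partial) "; PARTIAL" else ""))
  for (nm in names(x$components)) {
    for (ax in names(x$components[[nm]])) {
      pn <- x$components[[nm]][[ax]]
      if (pn$status != "ok") { cat(sprintf("  %s vs %s: FAILED\n", nm, ax)); next }
      if (pn$form == "hill")
        cat(sprintf("  %s vs %s: Hill vmax %.4g, K %.4g, h %.3g, offset %g\n",
                    nm, ax, pn$fit$vmax, pn$fit$K, pn$fit$h, pn$fit$offset))
      else
        cat(sprintf("  %s vs %s: linear %.4g + %.4g x\n",
                    nm, ax, pn$fit$intercept, pn$fit$slope))
    }
  }
  invisible(x)
}

map_eval_component <- function(map, quantity, params, warn_extrapolation = TRUE) {
  comp <- map$components[[quantity]]
  ref <- map$reference
  check_range <- function(x, rng, nm) {
    if (warn_extrapolation && (x < rng[1] / 2 || x > rng[2] * 2))
      warning(sprintf("%s = %g is beyond 2x the fitted %s range [%g, %g]",
                      nm, x, nm, rng[1], rng[2]))
  }
  check_range(params$ip3, map$ranges$ip3, "ip3")
  check_range(params$n_ch, map$ranges$nch, "n_ch")
  if (params$n_ch != round(params$n_ch))
    stop("n_ch maps are only defined at integer values", call. = FALSE)
  f_ip3 <- eval_component(comp$ip3, params$ip3)
  f_ip3_ref <- eval_component(comp$ip3, ref$ip3)
  f_nch <- eval_component(comp$nch, params$n_ch)
  f_nch_ref <- eval_component(comp$nch, ref$n_ch)
  base <- if (quantity == "open_shape") 1 else 0
  val <- base + (f_ip3 - base) * (f_nch - base) / (f_nch_ref - base)
  # the ip3 panel is fitted at the reference n_ch, so no further rescaling
  unname(val)
}

#' Evaluate the parameter map
#'
#' Deterministic lookup of the waiting-time density parameters at a cellular
#' parameter set: the puff rate (exponential rate of the first cluster
#' opening at basal Ca2+) and the GE shape/rate of subsequent openings at
#' the elevated Ca2+ level.
#'
#' @param map A [fit_parameter_maps()] result.
#' @param params A [cell_params()].
#' @return List with `puff_rate` (s^-1, per cluster), `open_shape` (>= 1),
#'   `open_rate` (s^-1). Warns when evaluated beyond 2x the fitted range.
#' @export
map_eval <- function(map, params) {
  stopifnot(inherits(map, "param_map"), inherits(params, "cell_params"))
  out <- list(puff_rate = map_eval_component(map, "puff_rate", params),
              open_shape = max(1, map_eval_component(map, "open_shape", params)),
              open_rate = map_eval_component(map, "open_rate", params))
  if (out$puff_rate <= 0 || out$open_rate <= 0)
    stop("parameter map produced a non-positive rate", call. = FALSE)
  out
}

#' Puff rate at a cellular parameter set
#'
#' Evaluates the Hill/linear puff-rate map: the exponential rate of the
#' 0 -> 1 cluster transition.
#'
#' @inheritParams map_eval
#' @return Rate, s^-1 (per cluster).
#' @export
puff_rate <- function(params, map) map_eval_component(map, "puff_rate", params)

#' Build a cluster chain from the fitted parameter maps
#'
#' Assembles the `0..N` open-cluster chain at a cellular parameter set:
#' exponential puff transition out of the ground state, the map's GE opening
#' density for subsequent openings, and the GE closing density
#' (`n_ch` exponential channel closings). The fitted puff rate is a
#' per-cluster rate by default, so the total 0 -> 1 rate is
#' `n_clusters * puff_rate`; `puff_scope = "cell"` instead takes the map
#' value as the total rate.
#'
#' @param params A [cell_params()].
#' @param map A [fit_parameter_maps()] result (default: the bundled map,
#'   [default_param_map()]).
#' @param n_clusters Number of clusters (default 4, the tetrahedron).
#' @param puff_scope `"cluster"` (default) or `"cell"`.
#' @return An [sm_chain()].
#' @export
spike_chain_from_map <- function(params, map = default_param_map(),
                                 n_clusters = 4,
                                 puff_scope = c("cluster", "cell")) {
  puff_scope <- match.arg(puff_scope)
  v <- map_eval(map, params)
  lam <- if (puff_scope == "cluster") n_clusters * v$puff_rate else v$puff_rate
  spike_chain(n_clusters, puff_rate = lam,
              open_dist = ge_dist(v$open_shape, v$open_rate),
              close_dist = make_closing_density(params))
}

#' Serialize / load a parameter map
#'
#' Key-value JSON round trip for [fit_parameter_maps()] results.
#'
#' @param map A `param_map`.
#' @param path File path.
#' @return `param_map_read` returns a `param_map`; `param_map_write` its
#'   path, invisibly.
#' @export
param_map_write <- function(map, path) {
  stopifnot(inherits(map, "param_map"))
  obj <- unclass(map)
  obj$reference <- unclass(obj$reference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname param_map_write
#' @export
param_map_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$reference <- do.call(cell_params, obj$reference[c("ip3", "ca_base",
                                                        "ca_open", "n_ch",
                                                        "lambda_cl")])
  obj$ranges <- lapply(obj$ranges, as.numeric)
  structure(obj, class = "param_map")
}

#' The bundled default parameter map
#'
#' A map fitted by [fit_parameter_maps()] at the standard cell parameters
#' (seeded; generation script in `tools/make_default_map.R`) and shipped as
#' JSON. It is a synthetic, package-generated calibration, not a measured
#' table.
#'
#' @return A `param_map`.
#' @export
default_param_map <- function() {
  path <- system.file("extdata", "param_map_default.json", package = "caspike")
  if (path == "") stop("bundled default parameter map not found", call. = FALSE)
  param_map_read(path)
}
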