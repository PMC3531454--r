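#' Cellular parameter set
#'
#' The biological knobs of the model: IP3 concentration (stimulus strength),
#' basal and puff-elevated local Ca2+ levels, channels per cluster and the
#' channel closing rate. Local Ca2+ is a two-level step map: `ca_base` when no
#' cluster is open, `ca_open` as soon as at least one cluster is open (the
#' CICR coupling).
#'
#' @param ip3 IP3 concentration, uM (> 0). Default 1.
#' @param ca_base Basal cytosolic Ca2+, uM. Default 0.01, calibrated so that
#'   the bundled De Young-Keizer rate set reproduces a measured interpuff
#'   interval of roughly 10 s per cluster (the basal level is experimentally
#'   undetermined and is always calibrated against the observed puff rate for
#'   whichever single-channel rate set is in use).
#' @param ca_open Local Ca2+ when >= 1 cluster is open, uM (>= `ca_base`).
#'   Default 0.6.
#' @param n_ch Channels per cluster, integer >= 1. Default 5.
#' @param lambda_cl Channel closing rate, s^-1. Default 50 (20 ms mean open
#'   time).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(ip3 = 1, ca_base = 0.01, ca_open = 0.6,
                        n_ch = 5, lambda_cl = 50) {
  chk <- function(v, nm, min = 0) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= min)
      stop(sprintf("'%s' must be a single finite number > %g", nm, min),
           call. = FALSE)
  }
  chk(ip3, "ip3"); chk(ca_base, "ca_base"); chk(ca_open, "ca_open")
  chk(lambda_cl, "lambda_cl")
  if (!is.numeric(n_ch) || length(n_ch) != 1L || n_ch < 1 || n_ch != round(n_ch))
    stop("'n_ch' must be an integer >= 1", call. = FALSE)
  if (ca_open < ca_base)
    stop("'ca_open' must be >= 'ca_base'", call. = FALSE)
  structure(list(ip3 = ip3, ca_base = ca_base, ca_open = ca_open,
                 n_ch = as.integer(n_ch), lambda_cl = lambda_cl),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(paste0("Cell parameters: [IP3] = %g uM, Ca base/open = %g/%g uM, ",
                     "N_ch = %d, lambda_cl = %g s^-1\n"),
              x$ip3, x$ca_base, x$ca_open, x$n_ch, x$lambda_cl))
  invisible(x)
}
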