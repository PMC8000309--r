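#' Chromatographic peak shapes and the elution index
#'
#' Every analyte elutes over a finite retention-time window centred on its
#' apex; within that window its signal follows a peak-shape function
#' normalized to 1 at its mode, so that the apex intensity equals the
#' molecule's `scale_intensity`. The default shape is the exponentially
#' modified Gaussian (EMG), the standard model for chromatographic elution;
#' plain Gaussian and gamma profiles are available as alternatives.
#'
#' @name elution
NULL

#' Construct a peak-shape function
#'
#' When explicit parameters are not supplied they are derived from the
#' elution-window `width` so that essentially all of the profile's mass
#' falls inside the window: Gaussian `sigma = width/6`; EMG
#' `sigma = tau = width/8`; gamma `k = 4`, `theta = width/12`. The gamma
#' profile is shifted so its mode sits at `mu` (requires `k > 1`); the EMG
#' mode is located numerically (tolerance 1e-9 s) and cached in the object.
#'
#' @param kind `"gaussian"`, `"emg"` or `"gamma"`.
#' @param mu apex location in seconds.
#' @param width elution-window length in seconds, used to derive defaults.
#' @param params optional named list overriding `sigma`, `tau` (EMG) or
#'   `k`, `theta` (gamma).
#' @return a `peak_shape` object usable with [shape_value()].
#' @export
peak_shape <- function(kind = c("emg", "gaussian", "gamma"), mu, width = 30,
                       params = NULL) {
  kind <- match.arg(kind)
  p <- function(name, default) {
    if (!is.null(params) && !is.null(params[[name]])) params[[name]]
    else default
  }
  s <- switch(kind,
    gaussian = list(kind = kind, mu = mu, sigma = p("sigma", width / 6)),
    emg = list(kind = kind, mu = mu, sigma = p("sigma", width / 8),
               tau = p("tau", width / 8)),
    gamma = list(kind = kind, mu = mu, k = p("k", 4),
                 theta = p("theta", width / 12)))
  if (s$sigma %||% 1 <= 0 && kind != "gamma") {
    stop("sigma must be > 0", call. = FALSE)
  }
  if (kind == "emg" && s$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (kind == "gamma") {
    if (s$k <= 1) stop("gamma shape k must be > 1 (mode undefined otherwise)",
                       call. = FALSE)
    if (s$theta <= 0) stop("gamma scale theta must be > 0", call. = FALSE)
  }
  if (kind == "emg") {
    opt <- optimize(function(t) .emg_logdens(t, s$mu, s$sigma, s$tau),
                    interval = c(mu - 6 * s$sigma,
                                 mu + 6 * s$sigma + 10 * s$tau),
                    maximum = TRUE, tol = 1e-9)
    s$mode <- opt$maximum
    s$log_peak <- opt$objective
  }
  structure(s, class = "peak_shape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# EMG log-density, stable form via the normal log-CDF
.emg_logdens <- function(t, mu, sigma, tau) {
  -log(tau) + (mu - t) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
}

#' Evaluate a peak shape, normalized to 1 at its mode
#'
#' @param s a `peak_shape`.
#' @param t retention time(s) in seconds.
#' @return relative intensity in \[0, 1\]; underflows to 0 far from the
#'   peak.
#' @export
shape_value <- function(s, t) {
  switch(s$kind,
    gaussian = exp(-(t - s$mu)^2 / (2 * s$sigma^2)),
    emg = exp(.emg_logdens(t, s$mu, s$sigma, s$tau) - s$log_peak),
    gamma = {
      # shifted so the mode (k-1)*theta lands at mu
      x <- t - (s$mu - (s$k - 1) * s$theta)
      peak <- dgamma((s$k - 1) * s$theta, shape = s$k, scale = s$theta)
      ifelse(x > 0, dgamma(x, shape = s$k, scale = s$theta) / peak, 0)
    })
}

#' Build a retention-time index over molecules
#'
#' Each molecule is indexed on the half-open interval
#' `[rt_apex - peak_width/2, rt_apex + peak_width/2)`. Queries return
#' exactly the molecules whose interval contains the query time, ordered by
#' `(rt_apex, id)`. The index is a flat column store over pre-sorted start
#' and end vectors; membership is evaluated with vectorized comparisons,
#' which is exact and, at the molecule counts the simulator handles, as
#' fast as a tree.
#'
#' @param molecules list of `molecule` objects.
#' @return an `elution_index`.
#' @export
build_index <- function(molecules) {
  if (length(molecules) == 0L) {
    return(structure(list(start = numeric(0), end = numeric(0),
                          molecules = list()), class = "elution_index"))
  }
  apex <- vapply(molecules, `[[`, numeric(1), "rt_apex")
  id <- vapply(molecules, `[[`, character(1), "id")
  o <- order(apex, id)
  molecules <- molecules[o]
  apex <- apex[o]
  w <- vapply(molecules, `[[`, numeric(1), "peak_width")
  structure(list(start = apex - w / 2, end = apex + w / 2,
                 molecules = molecules),
            class = "elution_index")
}

#' Molecules eluting at a given time
#'
#' @param idx an `elution_index` from [build_index()].
#' @param t retention time in seconds.
#' @return list of molecules whose `[start, end)` interval contains `t`,
#'   ordered by `(rt_apex, id)`.
#' @export
eluting_at <- function(idx, t) {
  stopifnot(t >= 0)
  idx$molecules[idx$start <= t & t < idx$end]
}
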