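#' Intensity-dependent noise model
#'
#' Two-component noise on every simulated peak, in the model family
#' established by earlier MS run simulators. Intensity noise is normal
#' with a saturating standard
#' deviation, `sigma_I = m * (1 - exp(-c * i)) + d`: `d` is the minimum
#' sigma, `m + d` the maximum, and `c` controls how fast sigma grows with
#' intensity. m/z noise is normal with a power-law standard deviation
#' `sigma_mz = m_mz * i^(-y)`: high-intensity peaks are located more
#' precisely. On top of the per-peak model, a fixed white-noise intensity
#' budget is distributed over a random number of peaks at random m/z per
#' spectrum, and fragment ions can be randomly omitted from MS2 scans.
#'
#' All draws come from R's global RNG; [simulate_run()] seeds it once from
#' the run configuration, making whole runs reproducible.
#'
#' @name noise
NULL

#' Noise parameters for one MS level
#'
#' Defaults follow the package's nucleoside simulation protocol: no
#' intensity noise (`m_int = 0`, `d_int = 0`), m/z noise with
#' `m_mz = 0.001701` Th and exponent `y_mz = 0.2`, a white-noise budget of
#' 1000 intensity units spread over 1 to 100 peaks between 50 and 1500 Th,
#' and 10% random fragment omission (MS2 only).
#'
#' @param m_int,c_int,d_int intensity-noise constants: sigma ranges from
#'   `d_int` (at zero intensity) to `m_int + d_int`; `c_int` sets the
#'   growth rate.
#' @param m_mz m/z-noise sigma at unit intensity, Th (the maximum sigma).
#' @param y_mz m/z-noise power-law exponent, >= 0.
#' @param white_total summed white-noise intensity per spectrum (0 disables).
#' @param white_peaks_min,white_peaks_max bounds on the white-noise peak
#'   count per spectrum.
#' @param mz_min,mz_max m/z range of white-noise peaks, Th.
#' @param fragment_omission_p probability in \[0, 1) that a fragment ion is
#'   dropped from an MS2 scan.
#' @param kind `"normal"` for the intensity-dependent model above, or
#'   `"uniform"` for `mz' ~ U(mz +/- uniform_mz_a)` and
#'   `i' ~ U(i * (1 +/- uniform_int_b))`.
#' @param uniform_mz_a,uniform_int_b half-widths of the uniform alternative.
#' @return a `noise_params` object.
#' @export
noise_params <- function(m_int = 0, c_int = 1, d_int = 0,
                         m_mz = 0.001701, y_mz = 0.2,
                         white_total = 1000,
                         white_peaks_min = 1L, white_peaks_max = 100L,
                         mz_min = 50, mz_max = 1500,
                         fragment_omission_p = 0.1,
                         kind = c("normal", "uniform"),
                         uniform_mz_a = 0.001, uniform_int_b = 0.05) {
  kind <- match.arg(kind)
  stopifnot(m_int >= 0, c_int > 0, d_int >= 0, m_mz >= 0, y_mz >= 0,
            white_total >= 0, white_peaks_min >= 1L,
            white_peaks_max >= white_peaks_min, mz_min < mz_max,
            fragment_omission_p >= 0, fragment_omission_p < 1)
  structure(list(m_int = m_int, c_int = c_int, d_int = d_int,
                 m_mz = m_mz, y_mz = y_mz, white_total = white_total,
                 white_peaks_min = as.integer(white_peaks_min),
                 white_peaks_max = as.integer(white_peaks_max),
                 mz_min = mz_min, mz_max = mz_max,
                 fragment_omission_p = fragment_omission_p,
                 kind = kind, uniform_mz_a = uniform_mz_a,
                 uniform_int_b = uniform_int_b),
            class = "noise_params")
}

#' Intensity-noise standard deviation
#' @param i intensity value(s), >= 0.
#' @param p a `noise_params`.
#' @return sigma in intensity units: `m_int * (1 - exp(-c_int * i)) + d_int`.
#' @export
intensity_sigma <- function(i, p) {
  stopifnot(all(i >= 0))
  p$m_int * (1 - exp(-p$c_int * i)) + p$d_int
}

#' m/z-noise standard deviation
#' @param i intensity value(s), > 0.
#' @param p a `noise_params`.
#' @return sigma in Th: `m_mz * i^(-y_mz)`.
#' @export
mz_sigma <- function(i, p) {
  if (any(i <= 0)) stop("mz_sigma requires intensities > 0", call. = FALSE)
  p$m_mz * i^(-p$y_mz)
}

#' Perturb a peak list with the configured noise model
#'
#' Each peak is perturbed independently: m/z gets normal noise with
#' [mz_sigma()] of its (pre-noise) intensity, intensity gets normal noise
#' with [intensity_sigma()] truncated at zero. Zero-intensity peaks keep
#' their m/z untouched (the m/z sigma is undefined at zero intensity); they
#' are removed later by the assembly's positivity filter. The returned list
#' is re-sorted by m/z.
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param p a `noise_params`.
#' @return data frame of the same shape, sorted by `mz`.
#' @export
inject_noise <- function(peaks, p) {
  n <- nrow(peaks)
  if (n == 0L) return(peaks)
  mz <- peaks$mz
  i <- peaks$intensity
  if (p$kind == "uniform") {
    pos <- i > 0
    mz2 <- mz
    mz2[pos] <- runif(sum(pos), mz[pos] - p$uniform_mz_a,
                      mz[pos] + p$uniform_mz_a)
    i2 <- pmax(0, runif(n, i * (1 - p$uniform_int_b),
                        i * (1 + p$uniform_int_b)))
  } else {
    pos <- i > 0
    mz2 <- mz
    if (any(pos)) {
      mz2[pos] <- rnorm(sum(pos), mz[pos], mz_sigma(i[pos], p))
    }
    i2 <- pmax(0, rnorm(n, i, intensity_sigma(i, p)))
  }
  o <- order(mz2)
  data.frame(mz = mz2[o], intensity = i2[o])
}

#' Spectrum-level white noise
#'
#' Draws the peak count uniformly from
#' `white_peaks_min..white_peaks_max`, places the peaks uniformly in
#' `[mz_min, mz_max]`, and splits `white_total` into positive shares by
#' uniform stick-breaking (flat Dirichlet). The shares sum to `white_total`
#' exactly: the last share absorbs the floating-point remainder.
#'
#' @param p a `noise_params`.
#' @return data frame with columns `mz`, `intensity` (empty when
#'   `white_total` is 0).
#' @export
white_noise_peaks <- function(p) {
  if (p$white_total == 0) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  n <- if (p$white_peaks_min == p$white_peaks_max) p$white_peaks_min
       else sample(p$white_peaks_min:p$white_peaks_max, 1L)
  mz <- runif(n, p$mz_min, p$mz_max)
  w <- diff(sort(c(0, runif(n - 1L), 1)))
  ints <- w * p$white_total
  # force exact conservation: the last share absorbs the floating-point
  # remainder (one correction pass closes any residual rounding ulp)
  for (pass in 1:3) {
    resid <- p$white_total - sum(ints)
    if (resid == 0) break
    ints[n] <- ints[n] + resid
  }
  data.frame(mz = mz, intensity = ints)
}

#' Randomly omit fragment ions
#'
#' Each fragment is dropped independently with probability `p_omit`,
#' emulating fragment ions that fall below detectability in a real scan.
#'
#' @param frags data frame of fragments (any columns).
#' @param p_omit omission probability in \[0, 1).
#' @return the surviving rows of `frags`.
#' @export
omit_fragments <- function(frags, p_omit) {
  if (p_omit < 0 || p_omit >= 1) {
    stop("p_omit must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(frags)
  if (n == 0L || p_omit == 0) return(frags)
  frags[runif(n) >= p_omit, , drop = FALSE]
}
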