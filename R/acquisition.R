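#' Data-dependent acquisition simulation
#'
#' The simulator advances a scan clock in fixed steps of `scan_diff`
#' seconds. At each MS1 tick, the isotope envelopes of all molecules
#' eluting at that retention time are scaled by their peak-shape value and
#' apex intensity, noise is injected, and the composite spectrum is
#' emitted. The top-N most intense precursor candidates (envelope base
#' peaks above the minimum intensity and not on the dynamic-exclusion
#' list) then each trigger one MS2 scan containing the fragments of every
#' molecule whose base peak falls inside the isolation window (chimeric
#' spectra arise naturally). Every scan, MS1 or MS2, consumes one clock
#' step, so a cycle of one MS1 plus 19 MS2 scans at the default 50 ms
#' spacing takes exactly 1 s. The run terminates when the clock reaches
#' the gradient length.
#'
#' @name acquisition
NULL

#' Run configuration
#'
#' @param gradient_length total run length in seconds; scans are emitted at
#'   retention times strictly below it.
#' @param scan_diff clock step between consecutive scans, seconds
#'   (default 0.05, i.e. 50 ms).
#' @param top_n maximum number of MS2 scans triggered per MS1 scan.
#' @param isolation_width full width of the precursor isolation window, Th,
#'   centred on the selected m/z.
#' @param exclusion_time dynamic-exclusion duration, seconds: a selected
#'   precursor m/z (within 10 ppm) is not selected again until this much
#'   time has passed.
#' @param min_intensity precursor candidates below this intensity are never
#'   selected.
#' @param ppm_offset fixed machine m/z miscalibration in ppm, applied to
#'   every theoretical m/z (see [apply_ppm_offset()]).
#' @param max_fragment_charge highest fragment charge for peptide MS2.
#' @param seed integer seed for the run's random-number stream.
#' @param ms1_noise,ms2_noise [noise_params()] for the two MS levels.
#' @return a `run_config` object.
#' @export
run_config <- function(gradient_length = 600, scan_diff = 0.05,
                       top_n = 20L, isolation_width = 2,
                       exclusion_time = 30, min_intensity = 500,
                       ppm_offset = 0, max_fragment_charge = 1L,
                       seed = 1L,
                       ms1_noise = noise_params(fragment_omission_p = 0),
                       ms2_noise = noise_params()) {
  if (!is.numeric(gradient_length) || gradient_length <= 0) {
    stop("gradient_length must be > 0", call. = FALSE)
  }
  if (!is.numeric(scan_diff) || scan_diff <= 0) {
    stop("scan_diff must be > 0", call. = FALSE)
  }
  if (top_n < 0) stop("top_n must be >= 0", call. = FALSE)
  if (isolation_width <= 0) stop("isolation_width must be > 0", call. = FALSE)
  if (exclusion_time < 0) stop("exclusion_time must be >= 0", call. = FALSE)
  if (min_intensity < 0) stop("min_intensity must be >= 0", call. = FALSE)
  if (max_fragment_charge < 1L) {
    stop("max_fragment_charge must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(ms1_noise, "noise_params"),
            inherits(ms2_noise, "noise_params"))
  structure(list(gradient_length = gradient_length, scan_diff = scan_diff,
                 top_n = as.integer(top_n), isolation_width = isolation_width,
                 exclusion_time = exclusion_time,
                 min_intensity = min_intensity, ppm_offset = ppm_offset,
                 max_fragment_charge = as.integer(max_fragment_charge),
                 seed = as.integer(seed),
                 ms1_noise = ms1_noise, ms2_noise = ms2_noise),
            class = "run_config")
}

# exclusion tolerance for matching a candidate against the exclusion list
.EXCLUSION_PPM <- 10
# peaks closer than this are centroided into one (co-eluting isomers share
# exact theoretical m/z)
.MERGE_TOL <- 1e-4

# precompute one row per molecule x charge ("species"), sorted by
# (rt_apex, id, charge); isotope patterns and fragments carry the machine
# ppm offset already
.build_species <- function(molecules, cfg, fragment_library = NULL) {
  apex <- vapply(molecules, `[[`, numeric(1), "rt_apex")
  ids <- vapply(molecules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids", call. = FALSE)
  molecules <- molecules[order(apex, ids)]

  frag_of <- function(m) {
    src <- m$fragment_source
    fr <- if (identical(src, "peptide")) {
      peptide_fragments(m$sequence, m$mods, cfg$max_fragment_charge)
    } else if (startsWith(src, "library:")) {
      key <- sub("^library:", "", src)
      if (is.null(fragment_library) || is.null(fragment_library[[key]])) {
        stop("molecule '", m$id, "': fragment library key '", key,
             "' not found", call. = FALSE)
      }
      fragment_library[[key]]
    } else if (identical(src, "nucleoside")) {
      nucleoside_default_fragments(m)
    } else {
      data.frame(mz = numeric(0), relative_intensity = numeric(0))
    }
    list(mz = if (nrow(fr) > 0L) apply_ppm_offset(fr$mz, cfg$ppm_offset)
              else numeric(0),
         ri = fr$relative_intensity)
  }

  rows <- list()
  for (mi in seq_along(molecules)) {
    m <- molecules[[mi]]
    fr <- frag_of(m)
    for (z in m$charges) {
      pat <- isotope_pattern(m$formula, charge = z)
      rows[[length(rows) + 1L]] <- list(
        mol = mi, id = m$id, z = z,
        start = m$rt_apex - m$peak_width / 2,
        end = m$rt_apex + m$peak_width / 2,
        apex = m$rt_apex, scale = m$scale_intensity,
        eff = m$fragmentation_efficiency, shape = m$shape,
        pat_mz = apply_ppm_offset(pat$peaks$mz, cfg$ppm_offset),
        pat_ab = pat$peaks$abundance,
        base_mz = apply_ppm_offset(
          pat$peaks$mz[which.max(pat$peaks$abundance)], cfg$ppm_offset),
        frag_mz = fr$mz, frag_ri = fr$ri)
    }
  }
  n <- length(rows)
  pull_n <- function(f) vapply(rows, `[[`, numeric(1), f)
  list(molecules = molecules, n = n,
       mol = vapply(rows, `[[`, numeric(1), "mol"),
       id = vapply(rows, `[[`, character(1), "id"),
       z = vapply(rows, function(r) as.integer(r$z), integer(1)),
       start = pull_n("start"), end = pull_n("end"), apex = pull_n("apex"),
       scale = pull_n("scale"), eff = pull_n("eff"),
       base_mz = pull_n("base_mz"),
       shape = lapply(rows, `[[`, "shape"),
       pat_mz = lapply(rows, `[[`, "pat_mz"),
       pat_ab = lapply(rows, `[[`, "pat_ab"),
       frag_mz = lapply(rows, `[[`, "frag_mz"),
       frag_ri = lapply(rows, `[[`, "frag_ri"))
}

# noise on parallel (mz, intensity) vectors; same model as inject_noise()
.noise_vec <- function(mz, i, p) {
  n <- length(mz)
  if (n == 0L) return(list(mz = mz, intensity = i))
  if (p$kind == "uniform") {
    pos <- i > 0
    mz[pos] <- runif(sum(pos), mz[pos] - p$uniform_mz_a,
                     mz[pos] + p$uniform_mz_a)
    i <- pmax(0, runif(n, i * (1 - p$uniform_int_b),
                       i * (1 + p$uniform_int_b)))
  } else {
    pos <- i > 0
    if (any(pos)) mz[pos] <- rnorm(sum(pos), mz[pos], mz_sigma(i[pos], p))
    i <- pmax(0, rnorm(n, i, intensity_sigma(i, p)))
  }
  list(mz = mz, intensity = i)
}

# sort, centroid peaks closer than .MERGE_TOL, drop non-positive intensities
.finalize_peaks <- function(mz, i) {
  keep <- i > 0
  mz <- mz[keep]; i <- i[keep]
  if (length(mz) > 1L) {
    o <- order(mz)
    mz <- mz[o]; i <- i[o]
    grp <- cumsum(c(TRUE, diff(mz) >= .MERGE_TOL))
    if (grp[length(grp)] < length(mz)) {
      tot <- rowsum(i, grp)[, 1L]
      mz <- rowsum(i * mz, grp)[, 1L] / tot
      i <- tot
    }
  }
  list(mz = unname(mz), intensity = unname(i))
}

.assemble_ms1_peaks <- function(rt, sp, cfg, eluting) {
  mzs <- vector("list", length(eluting))
  ints <- vector("list", length(eluting))
  for (k in seq_along(eluting)) {
    j <- eluting[k]
    sc <- shape_value(sp$shape[[j]], rt) * sp$scale[j]
    mzs[[k]] <- sp$pat_mz[[j]]
    ints[[k]] <- sp$pat_ab[[j]] * sc
  }
  mz <- unlist(mzs, use.names = FALSE) %||% numeric(0)
  i <- unlist(ints, use.names = FALSE) %||% numeric(0)
  pk <- .noise_vec(mz, i, cfg$ms1_noise)
  keep <- pk$intensity > 0
  mz <- pk$mz[keep]; i <- pk$intensity[keep]
  if (cfg$ms1_noise$white_total > 0) {
    wn <- white_noise_peaks(cfg$ms1_noise)
    mz <- c(mz, wn$mz); i <- c(i, wn$intensity)
  }
  .finalize_peaks(mz, i)
}

# top-N selection with dynamic exclusion; excl is an environment holding
# numeric vectors `mz` and `release`
.select_precursors_idx <- function(rt, sp, cfg, eluting, excl) {
  if (cfg$top_n == 0L || length(eluting) == 0L) return(list())
  active <- excl$release >= rt
  excl$mz <- excl$mz[active]
  excl$release <- excl$release[active]

  cand_int <- numeric(length(eluting))
  for (k in seq_along(eluting)) {
    j <- eluting[k]
    cand_int[k] <- shape_value(sp$shape[[j]], rt) * sp$scale[j]
  }
  cand_mz <- sp$base_mz[eluting]
  ord <- order(-cand_int, cand_mz)

  sels <- list()
  for (k in ord) {
    if (length(sels) >= cfg$top_n) break
    if (cand_int[k] < cfg$min_intensity) next
    if (length(excl$mz) > 0L &&
        any(abs(cand_mz[k] - excl$mz) / cand_mz[k] * 1e6 <= .EXCLUSION_PPM)) {
      next
    }
    co <- eluting[abs(sp$base_mz[eluting] - cand_mz[k]) <=
                    cfg$isolation_width / 2]
    sels[[length(sels) + 1L]] <- list(
      mz = cand_mz[k], species = eluting[k], co = co)
    excl$mz <- c(excl$mz, cand_mz[k])
    excl$release <- c(excl$release, rt + cfg$exclusion_time)
  }
  sels
}

.assemble_ms2_peaks <- function(rt, sp, cfg, sel) {
  mzs <- vector("list", length(sel$co))
  ints <- vector("list", length(sel$co))
  for (k in seq_along(sel$co)) {
    j <- sel$co[k]
    sc <- shape_value(sp$shape[[j]], rt) * sp$scale[j] * sp$eff[j]
    mzs[[k]] <- sp$frag_mz[[j]]
    ints[[k]] <- sp$frag_ri[[j]] * sc
  }
  mz <- unlist(mzs, use.names = FALSE) %||% numeric(0)
  i <- unlist(ints, use.names = FALSE) %||% numeric(0)
  n_gen <- length(mz)
  p_omit <- cfg$ms2_noise$fragment_omission_p
  if (p_omit > 0 && n_gen > 0L) {
    keep <- runif(n_gen) >= p_omit
    mz <- mz[keep]; i <- i[keep]
  }
  n_kept <- length(mz)
  pk <- .noise_vec(mz, i, cfg$ms2_noise)
  keep <- pk$intensity > 0
  mz <- pk$mz[keep]; i <- pk$intensity[keep]
  if (cfg$ms2_noise$white_total > 0) {
    wn <- white_noise_peaks(cfg$ms2_noise)
    mz <- c(mz, wn$mz); i <- c(i, wn$intensity)
  }
  out <- .finalize_peaks(mz, i)
  out$n_frag_generated <- n_gen
  out$n_frag_kept <- n_kept
  out
}

#' Simulate a complete LC-MS/MS run
#'
#' Runs the full acquisition loop (see the package overview) over a
#' validated molecule list and configuration. The RNG is seeded from
#' `cfg$seed`, so identical inputs give bit-identical runs.
#'
#' @param molecules list of [molecule()] objects.
#' @param cfg a [run_config()].
#' @param fragment_library optional library from [load_fragment_library()]
#'   for molecules with `fragment_source = "library:<key>"`.
#' @return a `sim_run` list with elements
#'   \describe{
#'     \item{scans}{list of scan objects: `scan_id`, `ms_level`, `rt`
#'       (seconds), ascending `mz` and `intensity` vectors, and for MS2
#'       scans `precursor` metadata (selected m/z, charge, isolation-window
#'       offsets, parent MS1 `scan_id`, contributing molecule ids) plus the
#'       ground-truth fragment counts `n_frag_generated` / `n_frag_kept`.}
#'     \item{features}{ground-truth feature table, one row per molecule x
#'       charge: elution window, apex, apex intensity, number of covering
#'       MS1 scans and the MS2 scans that sampled it.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_run <- function(molecules, cfg, fragment_library = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  sp <- .build_species(molecules, cfg, fragment_library)

  n_ticks <- ceiling(cfg$gradient_length / cfg$scan_diff) + 1L
  scans <- vector("list", n_ticks)
  n_scans <- 0L
  emit <- function(scan) {
    force(scan)   # scan_id fields reference n_scans pre-increment
    n_scans <<- n_scans + 1L
    scans[[n_scans]] <<- scan
  }
  excl <- new.env(parent = emptyenv())
  excl$mz <- numeric(0)
  excl$release <- numeric(0)

  ms1_count <- integer(sp$n)
  ms2_ids <- vector("list", sp$n)

  tick <- 0L
  repeat {
    rt <- tick * cfg$scan_diff
    if (rt >= cfg$gradient_length) break
    eluting <- which(sp$start <= rt & rt < sp$end)
    pk <- .assemble_ms1_peaks(rt, sp, cfg, eluting)
    emit(list(scan_id = n_scans + 1L, ms_level = 1L, rt = rt,
              mz = pk$mz, intensity = pk$intensity, precursor = NULL))
    parent_id <- n_scans
    ms1_count[eluting] <- ms1_count[eluting] + 1L
    tick <- tick + 1L

    sels <- .select_precursors_idx(rt, sp, cfg, eluting, excl)
    for (sel in sels) {
      rt2 <- tick * cfg$scan_diff
      if (rt2 >= cfg$gradient_length) break
      pk2 <- .assemble_ms2_peaks(rt2, sp, cfg, sel)
      emit(list(
        scan_id = n_scans + 1L, ms_level = 2L, rt = rt2,
        mz = pk2$mz, intensity = pk2$intensity,
        precursor = list(
          mz = sel$mz, charge = sp$z[sel$species],
          isolation_lower = cfg$isolation_width / 2,
          isolation_upper = cfg$isolation_width / 2,
          parent_scan_id = parent_id,
          molecule_ids = sp$id[sel$co]),
        n_frag_generated = pk2$n_frag_generated,
        n_frag_kept = pk2$n_frag_kept))
      for (j in sel$co) ms2_ids[[j]] <- c(ms2_ids[[j]], n_scans)
      tick <- tick + 1L
    }
  }

  features <- data.frame(
    id = sp$id, formula = vapply(seq_len(sp$n), function(k) {
      format(sp$molecules[[sp$mol[k]]]$formula)
    }, character(1)),
    charge = sp$z, rt_start = sp$start, rt_apex = sp$apex, rt_end = sp$end,
    apex_intensity = sp$scale, ms1_scans = ms1_count,
    ms2_scan_ids = vapply(ms2_ids, function(v) {
      paste(v, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)

  structure(list(scans = scans[seq_len(n_scans)], features = features,
                 config = cfg),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  lv <- vapply(x$scans, `[[`, integer(1), "ms_level")
  cat("<sim_run> ", length(x$scans), " scans (", sum(lv == 1L), " MS1, ",
      sum(lv == 2L), " MS2), ", nrow(x$features), " features, gradient ",
      x$config$gradient_length, " s\n", sep = "")
  invisible(x)
}

#' Extracted ion chromatogram from a simulated run
#'
#' Sums, per MS1 scan, the intensities of all peaks within `tol_ppm` of
#' `mz`. Used for the quantification checks: the trapezoid-integrated XIC
#' area of a molecule's base isotopologue is proportional to its
#' `scale_intensity`.
#'
#' @param run a `sim_run`.
#' @param mz target m/z, Th.
#' @param tol_ppm matching half-window in ppm.
#' @return data frame with columns `rt`, `intensity` (one row per MS1 scan).
#' @export
xic <- function(run, mz, tol_ppm = 10) {
  ms1 <- Filter(function(s) s$ms_level == 1L, run$scans)
  rt <- vapply(ms1, `[[`, numeric(1), "rt")
  int <- vapply(ms1, function(s) {
    hit <- abs(s$mz - mz) / mz * 1e6 <= tol_ppm
    if (any(hit)) sum(s$intensity[hit]) else 0
  }, numeric(1))
  data.frame(rt = rt, intensity = int)
}
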