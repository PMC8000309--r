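#' Run-parameter JSON, mzML output and the ground-truth feature CSV
#'
#' The run configuration lives in a JSON file with the flat keys of
#' [run_config()] plus a `noise` object holding `ms1` and `ms2` blocks with
#' the keys of [noise_params()]. Missing keys take the documented defaults;
#' unknown keys warn. The simulated run is written as indexed mzML 1.1
#' (64-bit m/z, 32-bit intensity, zlib-compressed binary arrays) and the
#' ground truth as a plain CSV, one row per molecule x charge.
#'
#' @name io
NULL

#' Read a run configuration from JSON
#'
#' @param path path to the JSON file.
#' @return a validated [run_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  top_keys <- c("gradient_length", "scan_diff", "top_n", "isolation_width",
                "exclusion_time", "min_intensity", "ppm_offset",
                "max_fragment_charge", "seed", "noise")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown) > 0L) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  noise_keys <- names(formals(noise_params))
  parse_noise <- function(block, level) {
    if (is.null(block)) block <- list()
    unknown <- setdiff(names(block), noise_keys)
    if (length(unknown) > 0L) {
      warning("ignoring unknown ", level, " noise key(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    block <- block[intersect(names(block), noise_keys)]
    if (level == "ms1" && is.null(block$fragment_omission_p)) {
      block$fragment_omission_p <- 0
    }
    tryCatch(do.call(noise_params, block), error = function(e) {
      stop("invalid ", level, " noise parameters: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  args <- raw[intersect(names(raw), setdiff(top_keys, "noise"))]
  args$ms1_noise <- parse_noise(raw$noise$ms1, "ms1")
  args$ms2_noise <- parse_noise(raw$noise$ms2, "ms2")
  tryCatch(do.call(run_config, args), error = function(e) {
    stop("invalid run config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write a run configuration to JSON
#'
#' Inverse of [read_config()]: the written file reads back to an equal
#' configuration.
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  strip <- function(np) unclass(np)
  out <- unclass(cfg)
  out$ms1_noise <- NULL
  out$ms2_noise <- NULL
  out$noise <- list(ms1 = strip(cfg$ms1_noise), ms2 = strip(cfg$ms2_noise))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run metadata embedded in the mzML output
#'
#' @param cfg the [run_config()] of the run.
#' @param software,version identify the generating software in the mzML
#'   software list.
#' @return a `run_metadata` list.
#' @export
run_metadata <- function(cfg, software = "mzsim",
                         version = as.character(packageVersion("mzsim"))) {
  structure(list(software = software, version = version,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 seed = cfg$seed, config = cfg),
            class = "run_metadata")
}

#' Write a scan stream as indexed mzML
#'
#' Produces standards-compliant indexed mzML 1.1 with centroid spectra,
#' per-scan ms level and retention time, and full precursor metadata
#' (selected-ion m/z and charge, isolation-window target and offsets) for
#' MS2 scans. Binary arrays are zlib-compressed 64-bit floats. A run with
#' zero scans is written as a minimal valid indexed mzML.
#'
#' @param scans scan list from [simulate_run()] (`run$scans`), ordered by
#'   retention time.
#' @param path output path (conventionally `.mzML`).
#' @param meta optional [run_metadata()]; identifies the software entry.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path, meta = NULL) {
  n <- length(scans)
  if (n == 0L) {
    .write_empty_mzml(path)
    return(invisible(path))
  }
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  if (is.unsorted(rt)) {
    stop("scan stream must be ordered by retention time", call. = FALSE)
  }
  get_or <- function(s, field, default) {
    v <- s$precursor[[field]]
    if (is.null(v)) default else v
  }
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = vapply(scans, `[[`, integer(1), "scan_id"),
    msLevel = vapply(scans, `[[`, integer(1), "ms_level"),
    polarity = 1L,
    peaksCount = vapply(scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = rt,
    basePeakMZ = vapply(scans, function(s) {
      if (length(s$mz) == 0L) 0 else s$mz[which.max(s$intensity)]
    }, numeric(1)),
    basePeakIntensity = vapply(scans, function(s) {
      if (length(s$intensity) == 0L) 0 else max(s$intensity)
    }, numeric(1)),
    collisionEnergy = vapply(scans, function(s) {
      if (s$ms_level == 2L) 25 else 0
    }, numeric(1)),
    ionisationEnergy = 0,
    lowMZ = vapply(scans, function(s) {
      if (length(s$mz) == 0L) 0 else min(s$mz)
    }, numeric(1)),
    highMZ = vapply(scans, function(s) {
      if (length(s$mz) == 0L) 0 else max(s$mz)
    }, numeric(1)),
    precursorScanNum = vapply(scans, function(s) {
      as.integer(get_or(s, "parent_scan_id", 0L))
    }, integer(1)),
    precursorMZ = vapply(scans, function(s) get_or(s, "mz", 0), numeric(1)),
    precursorCharge = vapply(scans, function(s) {
      as.integer(get_or(s, "charge", 0L))
    }, integer(1)),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", vapply(scans, `[[`, integer(1), "scan_id")),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(scans, function(s) {
      get_or(s, "mz", NA_real_)
    }, numeric(1)),
    isolationWindowLowerOffset = vapply(scans, function(s) {
      get_or(s, "isolation_lower", NA_real_)
    }, numeric(1)),
    isolationWindowUpperOffset = vapply(scans, function(s) {
      get_or(s, "isolation_upper", NA_real_)
    }, numeric(1)),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  peaks <- lapply(scans, function(s) {
    cbind(mz = s$mz, intensity = s$intensity)
  })
  software <- if (is.null(meta)) {
    c("mzsim", "mzsim", as.character(packageVersion("mzsim")))
  } else {
    c(meta$software, meta$software, meta$version)
  }
  mzR::writeMSData(peaks, file = path, header = hdr, outformat = "mzml",
                   rtime_seconds = TRUE,
                   software_processing = list(software))
  invisible(path)
}

# minimal valid indexedmzML for a zero-scan run, with a correct index
.write_empty_mzml <- function(path) {
  body_head <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml" ',
    'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
    'xsi:schemaLocation="http://psi.hupo.org/ms/mzml ',
    'http://psidev.info/files/ms/mzML/xsd/mzML1.1.2_idx.xsd">\n',
    '  <mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="mzsim">\n',
    '    <cvList count="1">\n',
    '      <cv id="MS" fullName="Proteomics Standards Initiative Mass ',
    'Spectrometry Ontology" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    </cvList>\n',
    '    <fileDescription>\n',
    '      <fileContent>\n',
    '        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" ',
    'value=""/>\n',
    '      </fileContent>\n',
    '    </fileDescription>\n',
    '    <run id="run">\n',
    '      <spectrumList count="0" defaultDataProcessingRef="dp">\n',
    '      </spectrumList>\n',
    '    </run>\n',
    '  </mzML>\n')
  index_offset <- nchar(body_head, type = "bytes")
  tail_xml <- paste0(
    '  <indexList count="1">\n',
    '    <index name="spectrum">\n',
    '    </index>\n',
    '  </indexList>\n',
    '  <indexListOffset>', index_offset, '</indexListOffset>\n',
    '  <fileChecksum>0</fileChecksum>\n',
    '</indexedmzML>\n')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(body_head, tail_xml), con, eos = NULL)
  invisible(path)
}

.FEATURE_COLS <- c("id", "formula", "charge", "rt_start", "rt_apex",
                   "rt_end", "apex_intensity", "ms1_scans", "ms2_scan_ids")

#' Write the ground-truth feature table
#'
#' One row per molecule x charge with the fixed header
#' `id,formula,charge,rt_start,rt_apex,rt_end,apex_intensity,ms1_scans,`
#' `ms2_scan_ids`; the last column holds semicolon-joined MS2 scan ids
#' (empty when the feature was never sampled).
#'
#' @param features feature data frame from [simulate_run()]
#'   (`run$features`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(identical(names(features), .FEATURE_COLS))
  write.csv(features, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a ground-truth feature table
#'
#' Inverse of [write_feature_csv()].
#'
#' @param path path to the feature CSV.
#' @return feature data frame.
#' @export
read_feature_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ms2_scan_ids = "character"))
  miss <- setdiff(.FEATURE_COLS, names(tab))
  if (length(miss) > 0L) {
    stop("feature CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$ms2_scan_ids[is.na(tab$ms2_scan_ids)] <- ""
  tab[.FEATURE_COLS]
}
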