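#' Analyte descriptions
#'
#' A molecule is one analyte of the simulated run: a chemical formula (given
#' directly or derived from a peptide sequence), the charge states it is
#' observed in, its elution parameters (retention-time apex, peak width,
#' peak-shape choice, apex intensity) and its MS2 behaviour (fragment source
#' and fragmentation efficiency).
#'
#' @name molecules
NULL

# residue formulas of the 20 standard amino acids (residue = AA - H2O)
.RESIDUES <- list(
  G = "C2H3NO",    A = "C3H5NO",    S = "C3H5NO2",   P = "C5H7NO",
  V = "C5H9NO",    T = "C4H7NO2",   C = "C3H5NOS",   L = "C6H11NO",
  I = "C6H11NO",   N = "C4H6N2O2",  D = "C4H5NO3",   Q = "C5H8N2O2",
  K = "C6H12N2O",  E = "C5H7NO3",   M = "C5H9NOS",   H = "C6H7N3O",
  F = "C9H9NO",    R = "C6H12N4O",  Y = "C9H9NO2",   W = "C11H10N2O")

# supported modification composition deltas
.MODS <- list(
  carbamidomethyl = "C2H3NO",  # on C
  oxidation       = "O",       # on M
  acetyl          = "C2H2O")   # protein/peptide N-terminus

.parse_mods <- function(mods) {
  # accepted forms: character vector "name@pos" (pos integer or "nterm"),
  # or a list of list(name=, pos=)
  if (is.null(mods) || length(mods) == 0L) return(list())
  if (is.character(mods)) {
    mods <- lapply(mods, function(m) {
      parts <- strsplit(m, "@", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop("modification must be written 'name@position': '", m, "'",
             call. = FALSE)
      }
      list(name = parts[1], pos = parts[2])
    })
  }
  for (m in mods) {
    if (!(m$name %in% names(.MODS))) {
      stop("unknown modification '", m$name, "'; supported: ",
           paste(names(.MODS), collapse = ", "), call. = FALSE)
    }
  }
  mods
}

.residue_formulas <- function(sequence, mods = NULL) {
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, names(.RESIDUES))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         "; valid residues: ", paste(names(.RESIDUES), collapse = ""),
         call. = FALSE)
  }
  fl <- lapply(letters, function(a) parse_formula(.RESIDUES[[a]]))
  for (m in .parse_mods(mods)) {
    delta <- parse_formula(.MODS[[m$name]])
    pos <- if (identical(m$pos, "nterm")) 1L else as.integer(m$pos)
    if (is.na(pos) || pos < 1L || pos > length(fl)) {
      stop("modification position out of range: ", m$pos, call. = FALSE)
    }
    fl[[pos]] <- formula_add(fl[[pos]], delta)
  }
  fl
}

#' Chemical formula of a (modified) peptide
#'
#' Sums the residue formulas of the sequence plus one water (peptide-bond
#' condensation bookkeeping) plus the composition deltas of any
#' modifications. Supported modifications: `carbamidomethyl` (+C2H3NO,
#' cysteine), `oxidation` (+O, methionine), `acetyl` (+C2H2O, N-terminus).
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param mods modifications as `"name@position"` strings (position is a
#'   1-based residue index, or `"nterm"` for acetylation), or a list of
#'   `list(name=, pos=)`.
#' @return a `chem_formula`.
#' @examples
#' peptide_to_formula("G")                       # C2H5NO2, glycine
#' peptide_to_formula("ACDEK", "carbamidomethyl@2")
#' @export
peptide_to_formula <- function(sequence, mods = NULL) {
  fl <- .residue_formulas(sequence, mods)
  out <- parse_formula("H2O")
  for (f in fl) out <- formula_add(out, f)
  out
}

#' b/y fragment ions of a peptide
#'
#' Returns the full b series (prefix residue masses plus proton) and y
#' series (suffix residue masses plus water plus proton) for fragment
#' indices 1..n-1, at every fragment charge 1..`max_fragment_charge`.
#' Modification deltas travel with the residues they sit on. Relative
#' intensities default to 1 for every fragment (scaled later by elution
#' profile and fragmentation efficiency).
#'
#' @inheritParams peptide_to_formula
#' @param max_fragment_charge highest fragment charge state generated.
#' @return a data frame with columns `label`, `mz`, `charge`,
#'   `relative_intensity`; zero rows for single-residue sequences.
#' @examples
#' peptide_fragments("AG") # b1 and y1
#' @export
peptide_fragments <- function(sequence, mods = NULL, max_fragment_charge = 1L) {
  fl <- .residue_formulas(sequence, mods)
  n <- length(fl)
  if (n < 2L) {
    return(data.frame(label = character(0), mz = numeric(0),
                      charge = integer(0), relative_intensity = numeric(0)))
  }
  masses <- vapply(fl, monoisotopic_mass, numeric(1))
  water <- monoisotopic_mass("H2O")
  b_neutral <- cumsum(masses)[seq_len(n - 1L)]
  suffix <- rev(cumsum(rev(masses)))   # suffix[i] = sum(masses[i:n])
  y_neutral <- suffix[seq(n, 2L)] + water   # y_k spans the last k residues
  out <- list()
  for (z in seq_len(max_fragment_charge)) {
    out[[length(out) + 1L]] <- data.frame(
      label = paste0("b", seq_len(n - 1L), if (z > 1L) paste0("^", z) else ""),
      mz = (b_neutral + z * .PROTON) / z,
      charge = z, relative_intensity = 1)
    out[[length(out) + 1L]] <- data.frame(
      label = paste0("y", seq_len(n - 1L), if (z > 1L) paste0("^", z) else ""),
      mz = (y_neutral + z * .PROTON) / z,
      charge = z, relative_intensity = 1)
  }
  do.call(rbind, out)
}

#' Load a fragment library from CSV
#'
#' For molecules that are not peptides (e.g. modified ribonucleosides), MS2
#' fragments can be supplied as a library. Columns: `key`, `fragment_label`,
#' exactly one of `fragment_formula` / `fragment_mz`, `charge`,
#' `relative_intensity`. Formulas are resolved to protonated m/z at load
#' time; rows are grouped by `key`.
#'
#' @param path path to the library CSV.
#' @return named list: library key -> fragment data frame (columns `label`,
#'   `mz`, `charge`, `relative_intensity`).
#' @export
load_fragment_library <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "fragment_label", "charge", "relative_intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("fragment library is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("fragment_formula" %in% names(tab))) tab$fragment_formula <- ""
  if (!("fragment_mz" %in% names(tab))) tab$fragment_mz <- NA_real_
  if (nrow(tab) == 0L) return(setNames(list(), character(0)))

  has_f <- !is.na(tab$fragment_formula) & nzchar(tab$fragment_formula)
  has_m <- !is.na(tab$fragment_mz)
  bad <- which(has_f == has_m)  # both or neither
  if (length(bad) > 0L) {
    stop("fragment library row ", bad[1] + 1L,
         ": give exactly one of fragment_formula / fragment_mz",
         call. = FALSE)
  }
  dup <- duplicated(tab[c("key", "fragment_label")])
  if (any(dup)) {
    stop("duplicate (key, fragment_label) pair: ",
         tab$key[dup][1], " / ", tab$fragment_label[dup][1], call. = FALSE)
  }
  z <- as.integer(tab$charge)
  mz <- ifelse(has_f, NA_real_, as.numeric(tab$fragment_mz))
  for (i in which(has_f)) {
    # formulas are neutral; library m/z is the protonated species
    fstr <- sub("\\+$", "", tab$fragment_formula[i])
    mz[i] <- (monoisotopic_mass(parse_formula(fstr)) + z[i] * .PROTON) / z[i]
  }
  frames <- split(
    data.frame(label = tab$fragment_label, mz = mz, charge = z,
               relative_intensity = as.numeric(tab$relative_intensity)),
    tab$key)
  lapply(frames, function(d) { rownames(d) <- NULL; d })
}

#' Default nucleoside fragment (ribose neutral loss)
#'
#' Ribonucleosides fragment predominantly by loss of the ribose moiety
#' (C5H8O4, 132.04226 Da), leaving the protonated nucleobase. For molecules
#' without an explicit fragment source this single fragment is used.
#'
#' @param m a `molecule` (see [molecule()]).
#' @return one-row fragment data frame.
#' @export
nucleoside_default_fragments <- function(m) {
  mh <- monoisotopic_mass(m$formula) + .PROTON
  loss <- monoisotopic_mass("C5H8O4")
  if (mh - loss <= 0) {
    stop("molecule '", m$id, "' is too small for the ribose loss (",
         "[M+H]+ = ", round(mh, 4), " Th)", call. = FALSE)
  }
  data.frame(label = "base", mz = mh - loss, charge = 1L,
             relative_intensity = 1)
}

#' Construct and validate one analyte
#'
#' @param id unique identifier string.
#' @param formula chemical formula (string or `chem_formula`); omit when
#'   `sequence` is given.
#' @param sequence peptide sequence; converted via [peptide_to_formula()].
#' @param mods peptide modifications (see [peptide_to_formula()]).
#' @param charges integer vector of precursor charge states (all >= 1).
#' @param rt_apex retention time of the peak apex, seconds, >= 0.
#' @param peak_width full elution-window length in seconds (the molecule
#'   contributes signal over `rt_apex +/- peak_width / 2`).
#' @param scale_intensity apex intensity in arbitrary units, > 0.
#' @param shape elution profile: `"emg"` (default), `"gaussian"` or
#'   `"gamma"`; see [peak_shape()].
#' @param shape_params optional named list overriding the shape parameters
#'   derived from `peak_width` (`sigma`, `tau`, `k`, `theta`).
#' @param fragmentation_efficiency fraction of the scaled precursor
#'   intensity transferred to each fragment, in (0, 1].
#' @param fragment_source one of `"peptide"`, `"library:<key>"`,
#'   `"nucleoside"`, `"none"`, or `NULL` to pick a default (peptide when a
#'   sequence was given, otherwise the nucleoside ribose-loss fragment).
#' @return a `molecule` object.
#' @export
molecule <- function(id, formula = NULL, sequence = NULL, mods = NULL,
                     charges = 1L, rt_apex, peak_width = 30,
                     scale_intensity = 1e5, shape = "emg",
                     shape_params = NULL, fragmentation_efficiency = 1,
                     fragment_source = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(formula) && is.null(sequence)) {
    stop("molecule '", id, "': give a formula or a sequence", call. = FALSE)
  }
  if (!is.null(sequence) && is.null(formula)) {
    formula <- peptide_to_formula(sequence, mods)
  } else {
    formula <- as_formula(formula)
  }
  charges <- as.integer(charges)
  if (length(charges) == 0L || any(charges < 1L)) {
    stop("molecule '", id, "': charges must be integers >= 1", call. = FALSE)
  }
  if (!is.numeric(rt_apex) || rt_apex < 0) {
    stop("molecule '", id, "': rt_apex must be >= 0", call. = FALSE)
  }
  if (!is.numeric(peak_width) || peak_width <= 0) {
    stop("molecule '", id, "': peak_width must be > 0", call. = FALSE)
  }
  if (!is.numeric(scale_intensity) || scale_intensity <= 0) {
    stop("molecule '", id, "': scale_intensity must be > 0", call. = FALSE)
  }
  if (!is.numeric(fragmentation_efficiency) ||
      fragmentation_efficiency <= 0 || fragmentation_efficiency > 1) {
    stop("molecule '", id, "': fragmentation_efficiency must be in (0, 1]",
         call. = FALSE)
  }
  if (is.null(fragment_source)) {
    fragment_source <- if (!is.null(sequence)) "peptide" else "nucleoside"
  }
  if (fragment_source == "peptide" && is.null(sequence)) {
    stop("molecule '", id, "': fragment_source 'peptide' needs a sequence",
         call. = FALSE)
  }
  ps <- peak_shape(shape, mu = rt_apex, width = peak_width,
                   params = shape_params)
  structure(
    list(id = id, formula = formula, sequence = sequence,
         mods = if (is.null(mods)) character(0) else mods,
         charges = charges, rt_apex = rt_apex, peak_width = peak_width,
         scale_intensity = scale_intensity, shape = ps,
         fragmentation_efficiency = fragmentation_efficiency,
         fragment_source = fragment_source),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, " [", format(x$formula), "] z=",
      paste(x$charges, collapse = ","), " apex=", x$rt_apex, "s\n", sep = "")
  invisible(x)
}

.MOLECULE_CSV_COLS <- c("id", "formula", "sequence", "mods", "charges",
                        "rt_apex", "peak_width", "scale_intensity", "shape",
                        "fragmentation_efficiency", "fragment_source")

#' Read a molecule table from CSV
#'
#' Required columns: `id`, `rt_apex`, `charges` (semicolon-separated charge
#' states) and one of `formula` / `sequence`. Optional columns `mods`
#' (semicolon-separated `name@pos`), `peak_width`, `scale_intensity`,
#' `shape`, `fragmentation_efficiency`, `fragment_source` take the
#' [molecule()] defaults when absent or empty. Unknown columns are ignored
#' with a warning.
#'
#' @param path path to the CSV file.
#' @return list of validated `molecule` objects.
#' @export
read_molecule_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "rt_apex", "charges")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("molecule CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!any(c("formula", "sequence") %in% names(tab))) {
    stop("molecule CSV needs a 'formula' or 'sequence' column",
         call. = FALSE)
  }
  extra <- setdiff(names(tab), .MOLECULE_CSV_COLS)
  if (length(extra) > 0L) {
    warning("ignoring unknown molecule CSV column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  get <- function(row, col, default = NULL) {
    if (!(col %in% names(tab))) return(default)
    v <- tab[[col]][row]
    if (is.na(v) || (is.character(v) && !nzchar(v))) default else v
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mods <- get(i, "mods")
    out[[i]] <- tryCatch(
      molecule(
        id = as.character(tab$id[i]),
        formula = get(i, "formula"),
        sequence = get(i, "sequence"),
        mods = if (is.null(mods)) NULL else strsplit(mods, ";")[[1]],
        charges = as.integer(strsplit(as.character(tab$charges[i]), ";")[[1]]),
        rt_apex = as.numeric(tab$rt_apex[i]),
        peak_width = as.numeric(get(i, "peak_width", 30)),
        scale_intensity = as.numeric(get(i, "scale_intensity", 1e5)),
        shape = get(i, "shape", "emg"),
        fragmentation_efficiency =
          as.numeric(get(i, "fragmentation_efficiency", 1)),
        fragment_source = get(i, "fragment_source")),
      error = function(e) {
        stop("molecule CSV row ", i + 1L, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a molecule list back to CSV
#'
#' Inverse of [read_molecule_csv()]: re-reading the written file yields
#' molecules equal to the input.
#'
#' @param molecules list of `molecule` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecule_csv <- function(molecules, path) {
  rows <- lapply(molecules, function(m) {
    data.frame(
      id = m$id,
      formula = if (is.null(m$sequence)) format(m$formula) else "",
      sequence = if (is.null(m$sequence)) "" else m$sequence,
      mods = paste(m$mods, collapse = ";"),
      charges = paste(m$charges, collapse = ";"),
      rt_apex = m$rt_apex,
      peak_width = m$peak_width,
      scale_intensity = m$scale_intensity,
      shape = m$shape$kind,
      fragmentation_efficiency = m$fragmentation_efficiency,
      fragment_source = m$fragment_source,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
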