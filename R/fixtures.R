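#' Synthetic inputs for tests and demos
#'
#' Everything the simulator needs can be generated in code: an in-silico
#' tryptic digest of a protein FASTA, a randomized molecule table with
#' realistic parameter distributions, and a small bundled mix of
#' ribonucleoside standards (including three isomeric methylcytidines that
#' share one formula and can only be told apart by retention time and MS2).
#'
#' @name fixtures
NULL

#' In-silico tryptic digest of a FASTA file
#'
#' Cleaves after K or R except when the next residue is P, allowing up to
#' `missed_cleavages` missed sites. Peptides outside `length_range` are
#' dropped; duplicates are removed keeping first-appearance order. Proteins
#' containing non-standard residues are dropped with a warning.
#'
#' @param fasta path to a protein FASTA file.
#' @param missed_cleavages maximum number of missed cleavage sites.
#' @param length_range integer vector `c(min, max)` of retained peptide
#'   lengths.
#' @return character vector of peptide sequences.
#' @export
digest_fasta <- function(fasta, missed_cleavages = 0L,
                         length_range = c(6L, 30L)) {
  if (!file.exists(fasta)) {
    stop("cannot read FASTA file: ", fasta, call. = FALSE)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- as.character(Biostrings::readAAStringSet(fasta))
  } else {
    lines <- readLines(fasta)
    idx <- cumsum(startsWith(lines, ">"))
    body <- !startsWith(lines, ">")
    seqs <- vapply(split(lines[body], idx[body]), paste, character(1),
                   collapse = "")
  }
  out <- character(0)
  for (s in seqs) {
    if (grepl(sprintf("[^%s]", paste(names(.RESIDUES), collapse = "")), s)) {
      warning("dropping sequence with non-standard residues", call. = FALSE)
      next
    }
    out <- c(out, .digest_one(s, missed_cleavages))
  }
  out <- unique(out)
  lens <- nchar(out)
  out[lens >= length_range[1] & lens <= length_range[2]]
}

.digest_one <- function(sequence, missed) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage after position i when chars[i] is K/R and chars[i+1] is not P
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n & chars[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  peptides <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    for (m in 0:missed) {
      j <- i + 1L + m
      if (j > length(bounds)) break
      peptides <- c(peptides,
                    substr(sequence, bounds[i] + 1L, bounds[j]))
    }
  }
  peptides
}

#' Randomized molecule table from a peptide pool
#'
#' Samples `n_sample` peptides without replacement and assigns run
#' parameters from the distributions used for benchmark simulations:
#' retention-time apex uniform over the gradient (a stand-in for predicted
#' RTs; pass `rt_apex` to use externally predicted values), peak width
#' uniform between 30 and 120 s, apex intensity uniform between 1e5 and
#' 1e6, and the charge state drawn from a multinomial over 2+/3+/4+ with
#' default probabilities 0.6/0.3/0.1.
#'
#' @param peptides character vector of peptide sequences.
#' @param n_sample number of peptides to sample (at most
#'   `length(peptides)`).
#' @param gradient_length gradient length in seconds for the default
#'   uniform RT assignment.
#' @param rt_apex optional numeric vector of length `n_sample` of
#'   externally supplied retention times (seconds), bypassing the uniform
#'   draw.
#' @param width_range,intensity_range uniform-draw bounds for peak width
#'   (s) and apex intensity (a.u.).
#' @param charge_probs named numeric vector of charge-state probabilities.
#' @param path optional path; when given the table is also written as a
#'   molecule CSV.
#' @return data frame in the [read_molecule_csv()] dialect.
#' @export
randomize_run <- function(peptides, n_sample,
                          gradient_length = 600,
                          rt_apex = NULL,
                          width_range = c(30, 120),
                          intensity_range = c(1e5, 1e6),
                          charge_probs = c("2" = 0.6, "3" = 0.3, "4" = 0.1),
                          path = NULL) {
  if (n_sample > length(peptides)) {
    stop("n_sample (", n_sample, ") exceeds the peptide pool (",
         length(peptides), ")", call. = FALSE)
  }
  picked <- sample(peptides, n_sample)
  if (is.null(rt_apex)) {
    rt_apex <- runif(n_sample, 0, gradient_length)
  } else {
    stopifnot(length(rt_apex) == n_sample)
  }
  tab <- data.frame(
    id = paste0("pep", seq_len(n_sample), "_", picked),
    formula = "",
    sequence = picked,
    mods = "",
    charges = sample(names(charge_probs), n_sample, replace = TRUE,
                     prob = charge_probs),
    rt_apex = rt_apex,
    peak_width = runif(n_sample, width_range[1], width_range[2]),
    scale_intensity = runif(n_sample, intensity_range[1], intensity_range[2]),
    shape = "emg",
    fragmentation_efficiency = 1,
    fragment_source = "peptide",
    stringsAsFactors = FALSE)
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE, quote = TRUE)
  tab
}

#' Bundled ribonucleoside standard mix
#'
#' A small set of common (modified) ribonucleosides with distinct
#' retention-time apexes, including the three isomeric methylcytidines
#' (2'-O-methylcytidine, 3-methylcytidine, 5-methylcytidine) that share
#' the formula C10H15N3O5 and therefore identical isotope envelopes. All
#' use the default ribose-neutral-loss MS2 fragment.
#'
#' @param scale_intensity apex intensity given to every molecule.
#' @return list of [molecule()] objects.
#' @export
nucleoside_mix <- function(scale_intensity = 5e5) {
  defs <- list(
    list(id = "pseudouridine",     formula = "C9H12N2O6",  rt = 150),
    list(id = "cytidine",          formula = "C9H13N3O5",  rt = 240),
    list(id = "uridine",           formula = "C9H12N2O6",  rt = 360),
    list(id = "5-methylcytidine",  formula = "C10H15N3O5", rt = 600),
    list(id = "3-methylcytidine",  formula = "C10H15N3O5", rt = 680),
    list(id = "2-O-methylcytidine", formula = "C10H15N3O5", rt = 780),
    list(id = "inosine",           formula = "C10H12N4O5", rt = 900),
    list(id = "guanosine",         formula = "C10H13N5O5", rt = 1000),
    list(id = "7-methylguanosine", formula = "C11H15N5O5", rt = 1100),
    list(id = "adenosine",         formula = "C10H13N5O4", rt = 1300))
  lapply(defs, function(d) {
    molecule(id = d$id, formula = d$formula, charges = 1L,
             rt_apex = d$rt, peak_width = 50,
             scale_intensity = scale_intensity,
             fragment_source = "nucleoside")
  })
}
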