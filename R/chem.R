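#' Chemical-formula arithmetic and isotope patterns
#'
#' All mass calculations in the simulator run off chemical formulas: a
#' formula is a named integer vector mapping element symbols to atom counts
#' (class `chem_formula`). Isotope masses and natural abundances come from a
#' bundled plain-text table derived from the NIST reference values.
#'
#' @name chem
NULL

.isotope_table <- function() {
  tab <- .mzsim_env$isotopes
  if (is.null(tab)) {
    path <- system.file("extdata", "isotopes.tsv", package = "mzsim",
                        mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    # most abundant isotope first within each element
    tab <- tab[order(tab$element, -tab$abundance), ]
    .mzsim_env$isotopes <- tab
  }
  tab
}

.element_isotopes <- function(symbol) {
  tab <- .isotope_table()
  rows <- tab[tab$element == symbol, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  rows
}

.known_elements <- function() unique(.isotope_table()$element)

.new_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative atom count", call. = FALSE)
  # Hill order: C, H, then alphabetical
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  counts <- counts[ord]
  storage.mode(counts) <- "integer"
  structure(counts, class = "chem_formula")
}

#' Parse a chemical formula string
#'
#' Accepts element symbols (capital letter plus optional lowercase letter)
#' with optional positive integer counts and parenthesized groups with a
#' multiplier, e.g. `"C6H12O6"` or `"CH3(CH2)2OH"`. Repeated elements are
#' summed. Unknown element symbols are rejected against the bundled isotope
#' table.
#'
#' @param text formula string.
#' @return a `chem_formula`: named integer vector of atom counts in Hill
#'   order (C, H, then alphabetical), zero counts dropped.
#' @examples
#' parse_formula("H2O")
#' parse_formula("CH3(CH2)2OH")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  pos <- 1L

  read_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) return(NA_integer_)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  parse_group <- function() {
    counts <- integer(0)
    add <- function(sym, k) {
      counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    }
    while (pos <= n) {
      ch <- chars[pos]
      if (ch == ")") break
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parse_group()
        if (pos > n || chars[pos] != ")") {
          stop("unbalanced '(' in formula at position ", pos, call. = FALSE)
        }
        pos <<- pos + 1L
        mult <- read_int()
        if (is.na(mult)) mult <- 1L
        for (sym in names(inner)) add(sym, inner[[sym]] * mult)
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (pos <= n && grepl("[a-z]", chars[pos])) {
          sym <- paste0(sym, chars[pos])
          pos <<- pos + 1L
        }
        if (!(sym %in% .known_elements())) {
          stop("unknown element symbol: '", sym, "'", call. = FALSE)
        }
        k <- read_int()
        if (is.na(k)) k <- 1L
        if (k <= 0L) stop("zero count for element '", sym, "'", call. = FALSE)
        add(sym, k)
      } else {
        stop("malformed formula '", text, "' at position ", pos,
             " (character '", ch, "')", call. = FALSE)
      }
    }
    counts
  }

  counts <- parse_group()
  if (pos <= n) {
    stop("malformed formula '", text, "' at position ", pos,
         " (unmatched ')')", call. = FALSE)
  }
  .new_formula(counts)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add chemical formulas
#'
#' Element-wise sum of atom counts; `k` scales the second operand (negative
#' `k` subtracts, e.g. for neutral losses).
#'
#' @param f,g `chem_formula` objects (or formula strings).
#' @param k integer multiplier applied to `g`.
#' @return a `chem_formula`.
#' @export
formula_add <- function(f, g, k = 1L) {
  f <- as_formula(f); g <- as_formula(g)
  counts <- setNames(as.integer(f), names(f))
  for (sym in names(g)) {
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) +
      k * g[[sym]]
  }
  .new_formula(counts)
}

#' Coerce to a chemical formula
#' @param x a `chem_formula` or a formula string.
#' @return a `chem_formula`.
#' @export
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  parse_formula(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of atom count times the mass of the element's most
#' abundant isotope. The empty formula has mass 0.
#'
#' @param f a `chem_formula` or formula string.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O")) # 18.0105646
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  masses <- vapply(names(f), function(sym) .element_isotopes(sym)$mass[1L],
                   numeric(1))
  sum(masses * as.numeric(f))
}

# convolve two (mass, abundance) distributions, merging peaks whose masses
# coincide within `tol` Da and dropping abundances below `floor` (relative)
.convolve_dist <- function(a, b, tol = 1e-8, floor = 1e-12) {
  mass <- outer(a$mass, b$mass, "+")
  ab <- outer(a$ab, b$ab)
  d <- list(mass = as.vector(mass), ab = as.vector(ab))
  .merge_dist(d, tol, floor)
}

.merge_dist <- function(d, tol, floor) {
  o <- order(d$mass)
  mass <- d$mass[o]; ab <- d$ab[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(TRUE, diff(mass) > tol))
    tot <- rowsum(ab, grp)[, 1L]
    ctr <- rowsum(ab * mass, grp)[, 1L] / tot
    mass <- ctr; ab <- tot
  }
  keep <- ab > floor * max(ab)
  list(mass = mass[keep], ab = ab[keep])
}

# distribution of `count` atoms of one element, by binary exponentiation
.element_power <- function(symbol, count) {
  iso <- .element_isotopes(symbol)
  base <- list(mass = iso$mass, ab = iso$abundance)
  if (count == 1L) return(base)
  res <- NULL
  p <- base
  k <- count
  while (k > 0L) {
    if (k %% 2L == 1L) {
      res <- if (is.null(res)) p else .convolve_dist(res, p)
    }
    k <- k %/% 2L
    if (k > 0L) p <- .convolve_dist(p, p)
  }
  res
}

#' Isotope pattern of a formula at a charge state
#'
#' Computes the centroided isotope envelope by iterated convolution of the
#' per-element isotope distributions (each element's distribution raised to
#' its atom-count power, elements combined by convolution). Abundances are
#' normalized so the base peak is exactly 1; peaks below `prune` (relative)
#' are dropped; neighbouring isotopologues closer than 1e-5 Th are merged
#' into an abundance-weighted centroid. m/z values assume protonation:
#' `(neutral mass + charge * 1.00727646688) / charge`.
#'
#' Patterns are cached per (formula, charge, prune) for reuse across scans.
#'
#' @param f a `chem_formula` or formula string.
#' @param charge positive integer charge state.
#' @param prune relative abundance threshold in (0, 1); default 1e-4.
#' @return an `isotope_pattern`: list with `charge` and a data frame
#'   `peaks` with columns `mz` (Th, strictly ascending) and `abundance`
#'   (relative, max exactly 1).
#' @examples
#' isotope_pattern("C6H12O6", charge = 1)
#' @export
isotope_pattern <- function(f, charge = 1L, prune = 1e-4) {
  f <- as_formula(f)
  if (length(f) == 0L) stop("empty formula has no isotope pattern",
                            call. = FALSE)
  stopifnot(charge >= 1L, prune > 0, prune < 1)
  key <- paste0(format(f), "/z", charge, "/p", prune)
  hit <- .mzsim_env$patterns[[key]]
  if (!is.null(hit)) return(hit)

  d <- NULL
  for (sym in names(f)) {
    e <- .element_power(sym, f[[sym]])
    d <- if (is.null(d)) e else .convolve_dist(d, e)
  }
  # final merge at the m/z-level tolerance, then prune after normalization
  d <- .merge_dist(d, tol = 1e-5 / charge, floor = 0)
  ab <- d$ab / max(d$ab)
  keep <- ab > prune
  mz <- (d$mass[keep] + charge * .PROTON) / charge
  pat <- structure(
    list(charge = as.integer(charge),
         peaks = data.frame(mz = mz, abundance = ab[keep])),
    class = "isotope_pattern")
  if (is.null(.mzsim_env$patterns)) .mzsim_env$patterns <- list()
  .mzsim_env$patterns[[key]] <- pat
  pat
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> z=", x$charge, ", ", nrow(x$peaks), " peaks, base ",
      sprintf("%.5f", x$peaks$mz[which.max(x$peaks$abundance)]), " Th\n",
      sep = "")
  invisible(x)
}

#' Apply a fixed machine m/z offset in ppm
#'
#' Models a miscalibrated instrument: every m/z value is shifted by a
#' constant relative offset, `mz * (1 + offset_ppm * 1e-6)`.
#'
#' @param mz m/z value(s) in Th, positive.
#' @param offset_ppm signed offset in parts per million.
#' @return shifted m/z value(s).
#' @export
apply_ppm_offset <- function(mz, offset_ppm) {
  stopifnot(all(mz > 0))
  mz * (1 + offset_ppm * 1e-6)
}
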