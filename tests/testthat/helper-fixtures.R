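# shared builders and independent oracles for the test suite

# noise parameters that switch every stochastic mechanism off
np_zero <- function(...) {
  noise_params(m_int = 0, c_int = 1, d_int = 0, m_mz = 0, y_mz = 0,
               white_total = 0, fragment_omission_p = 0, ...)
}

# a run configuration with all noise disabled
cfg_quiet <- function(...) {
  run_config(..., ms1_noise = np_zero(), ms2_noise = np_zero())
}

# brute-force isotopologue enumeration: every per-atom isotope choice,
# aggregated by (rounded) total mass; independent of the convolution code
brute_pattern <- function(counts, charge = 1, prune = 1e-4) {
  iso <- read.delim(system.file("extdata", "isotopes.tsv", package = "mzsim"))
  masses <- list(list(mass = 0, p = 1))
  dists <- list()
  for (el in names(counts)) {
    rows <- iso[iso$element == el, ]
    for (k in seq_len(counts[[el]])) {
      dists[[length(dists) + 1L]] <- rows
    }
  }
  grid <- expand.grid(lapply(dists, function(d) seq_len(nrow(d))))
  mass <- rep(0, nrow(grid))
  prob <- rep(1, nrow(grid))
  for (j in seq_along(dists)) {
    mass <- mass + dists[[j]]$mass[grid[[j]]]
    prob <- prob * dists[[j]]$abundance[grid[[j]]]
  }
  grp <- as.factor(round(mass, 6))
  p_tot <- tapply(prob, grp, sum)
  m_ctr <- tapply(prob * mass, grp, sum) / p_tot   # weighted centroid
  o <- order(m_ctr)
  p_tot <- p_tot[o]; m_ctr <- m_ctr[o]
  ab <- unname(p_tot / max(p_tot))
  keep <- ab > prune
  data.frame(mz = (unname(m_ctr)[keep] + charge * 1.00727646688) / charge,
             abundance = ab[keep])
}

# brute-force tryptic digestion: every substring that is a valid tryptic
# peptide with at most `missed` internal cleavage sites
brute_digest <- function(sequence, missed = 0) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_site <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") && chars[i + 1] != "P"
  }
  out <- character(0)
  for (a in 1:n) {
    for (b in a:n) {
      if (a > 1 && !is_site(a - 1)) next
      if (b < n && !is_site(b)) next
      internal <- if (b > a) sum(vapply(a:(b - 1), is_site, logical(1))) else 0
      if (internal > missed) next
      out <- c(out, substr(sequence, a, b))
    }
  }
  unique(out)
}

# trapezoid integration of an XIC
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# a small deterministic peptide pool for acquisition tests
test_peptides <- function(n = 20, len = 12, seed = 424) {
  withr::with_seed(seed, {
    replicate(n, paste(sample(c("A", "G", "L", "S", "E", "K", "V", "T",
                                "D", "F", "N", "Q"), len, replace = TRUE),
                       collapse = ""))
  })
}
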