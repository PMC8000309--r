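test_that("peptide formulas sum residues, water and modification deltas", {
  g <- peptide_to_formula("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O")],
               c(C = 2L, H = 5L, N = 1L, O = 2L))
  expect_equal(monoisotopic_mass(g), 75.03203, tolerance = 1e-5)
  expect_equal(monoisotopic_mass(peptide_to_formula("AG")), 146.06914,
               tolerance = 1e-5)
  expect_equal(monoisotopic_mass(peptide_to_formula("C", "carbamidomethyl@1")),
               178.04121, tolerance = 1e-5)
  # oxidation and N-terminal acetylation deltas
  expect_equal(monoisotopic_mass(peptide_to_formula("M", "oxidation@1")) -
                 monoisotopic_mass(peptide_to_formula("M")),
               15.9949146, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(peptide_to_formula("AG", "acetyl@nterm")) -
                 monoisotopic_mass(peptide_to_formula("AG")),
               42.0105646, tolerance = 1e-6)
})

test_that("unknown residues and modifications are rejected with options", {
  expect_error(peptide_to_formula("AXZ"), "unknown residue")
  expect_error(peptide_to_formula("AG", "phospho@1"), "supported")
  expect_error(peptide_to_formula("AG", "oxidation@5"), "out of range")
})

test_that("b/y fragments cover both series at every charge", {
  fr <- peptide_fragments("AG")
  expect_equal(fr$mz[fr$label == "b1"], 72.04439, tolerance = 1e-5)
  expect_equal(fr$mz[fr$label == "y1"], 76.03930, tolerance = 1e-5)
  expect_equal(nrow(peptide_fragments("G")), 0L)
  expect_equal(nrow(peptide_fragments("AAG")), 4L)
  # count law 2 * (len - 1) * z for unmodified peptides
  for (pep in c("ACDEK", "LLGNVLVCVLAHHFGK")) {
    for (z in 1:2) {
      expect_equal(nrow(peptide_fragments(pep, max_fragment_charge = z)),
                   2L * (nchar(pep) - 1L) * z)
    }
  }
})

test_that("terminal fragments complement the precursor mass", {
  proton <- 1.00727646688
  for (pep in c("AG", "ELVISLIVESK", "PEPTIDE", "MCDEFGHIK")) {
    fr <- peptide_fragments(pep)
    n <- nchar(pep)
    b_last <- fr$mz[fr$label == paste0("b", n - 1)]
    y_first <- fr$mz[fr$label == "y1"]
    mh <- monoisotopic_mass(peptide_to_formula(pep)) + proton
    expect_equal(b_last + y_first, mh + proton, tolerance = 1e-6)
  }
})

test_that("fragment libraries parse, resolve formulas, and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("key,fragment_label,fragment_formula,fragment_mz,charge,relative_intensity",
               "m5C,base,C5H8N3O+,,1,1.0",
               "m5C,other,,126.0662,1,0.5"), path)
  lib <- load_fragment_library(path)
  expect_named(lib, "m5C")
  expect_equal(nrow(lib$m5C), 2L)
  expect_equal(lib$m5C$mz[lib$m5C$label == "base"],
               monoisotopic_mass("C5H8N3O") + 1.00727646688, tolerance = 1e-9)
  expect_equal(lib$m5C$mz[lib$m5C$label == "other"], 126.0662)

  writeLines("key,fragment_label,fragment_formula,fragment_mz,charge,relative_intensity",
             path)
  expect_length(load_fragment_library(path), 0L)

  writeLines(c("key,fragment_label,fragment_formula,fragment_mz,charge,relative_intensity",
               "k,a,C5H8N3O,126.0662,1,1.0"), path)
  expect_error(load_fragment_library(path), "exactly one")
  writeLines(c("key,fragment_label,fragment_formula,fragment_mz,charge,relative_intensity",
               "k,a,,126.0662,1,1.0", "k,a,,127.0,1,1.0"), path)
  expect_error(load_fragment_library(path), "duplicate")
})

test_that("the default nucleoside fragment is the ribose neutral loss", {
  cyt <- molecule("cytidine", formula = "C9H13N3O5", rt_apex = 100)
  fr <- nucleoside_default_fragments(cyt)
  expect_equal(fr$mz, 112.0505, tolerance = 1e-4)
  m5c <- molecule("m5C", formula = "C10H15N3O5", rt_apex = 100)
  expect_equal(nucleoside_default_fragments(m5c)$mz, 126.0662,
               tolerance = 1e-4)
  tiny <- molecule("tiny", formula = "CH4O", rt_apex = 1,
                   fragment_source = "none")
  expect_error(nucleoside_default_fragments(tiny), "too small")
})

test_that("molecule validation enforces the documented invariants", {
  expect_error(molecule("m", formula = "C2H6O", rt_apex = -5), "rt_apex")
  expect_error(molecule("m", formula = "C2H6O", rt_apex = 5, peak_width = 0),
               "peak_width")
  expect_error(molecule("m", formula = "C2H6O", rt_apex = 5,
                        scale_intensity = 0), "scale_intensity")
  expect_error(molecule("m", formula = "C2H6O", rt_apex = 5,
                        fragmentation_efficiency = 1.5), "efficiency")
  expect_error(molecule("m", formula = "C2H6O", rt_apex = 5, charges = 0),
               "charges")
  expect_error(molecule("m", rt_apex = 5), "formula or a sequence")
})

test_that("the molecule CSV round-trips and validates rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,formula,charges,rt_apex,peak_width",
               "Cm,C10H15N3O5,1,780,50",
               "m3C,C10H15N3O5,1,680,50",
               "m5C,C10H15N3O5,1,600,50"), path)
  mols <- read_molecule_csv(path)
  expect_length(mols, 3L)
  masses <- vapply(mols, function(m) monoisotopic_mass(m$formula), numeric(1))
  expect_equal(masses, rep(masses[1], 3))
  # identical formulas hit one shared isotope-pattern cache entry
  pats <- lapply(mols, function(m) isotope_pattern(m$formula, 1L))
  expect_identical(pats[[1]], pats[[2]])

  out <- withr::local_tempfile(fileext = ".csv")
  write_molecule_csv(mols, out)
  back <- read_molecule_csv(out)
  expect_equal(back, mols)

  writeLines(c("id,formula,charges,rt_apex", "bad,C2H6O,1,-5"), path)
  expect_error(read_molecule_csv(path), "row 2")
  writeLines("id,formula,charges,rt_apex", path)
  expect_length(read_molecule_csv(path), 0L)
  writeLines(c("id,formula,charges,rt_apex,colour", "a,C2H6O,1,5,red"), path)
  expect_warning(read_molecule_csv(path), "colour")
  writeLines(c("id,charges,rt_apex", "a,1,5"), path)
  expect_error(read_molecule_csv(path), "formula.*sequence")
})
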