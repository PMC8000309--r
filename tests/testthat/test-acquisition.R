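# small helpers used across acquisition tests ------------------------------

two_peptide_run <- function(cfg, eff_a = 1) {
  mols <- list(
    molecule("pepA", sequence = "ELVISLIVESK", charges = 2, rt_apex = 10,
             peak_width = 12, scale_intensity = 2e5,
             fragmentation_efficiency = eff_a),
    molecule("pepB", sequence = "PEPTIDEK", charges = 2, rt_apex = 14,
             peak_width = 12, scale_intensity = 4e5))
  simulate_run(mols, cfg)
}

ms_levels <- function(run) vapply(run$scans, `[[`, integer(1), "ms_level")
scan_rts <- function(run) vapply(run$scans, `[[`, numeric(1), "rt")

test_that("an empty gradient yields exactly gradient/scan_diff MS1 scans", {
  cfg <- cfg_quiet(gradient_length = 10, scan_diff = 0.05, top_n = 0)
  run <- simulate_run(list(), cfg)
  expect_length(run$scans, 200L)
  expect_true(all(ms_levels(run) == 1L))
  expect_true(all(vapply(run$scans, function(s) length(s$mz), integer(1)) ==
                    0L))
  expect_equal(nrow(run$features), 0L)
})

test_that("the scan clock advances by exactly scan_diff and stops at the gradient", {
  cfg <- cfg_quiet(gradient_length = 20, top_n = 3, exclusion_time = 2,
                   min_intensity = 100)
  run <- two_peptide_run(cfg)
  rts <- scan_rts(run)
  expect_true(all(abs(diff(rts) - cfg$scan_diff) < 1e-9))
  expect_lt(max(rts), cfg$gradient_length)
  ids <- vapply(run$scans, `[[`, integer(1), "scan_id")
  expect_identical(ids, seq_along(run$scans))
})

test_that("a noise-free molecule at its apex reproduces the scaled envelope", {
  m <- molecule("apex", formula = "C10H15N3O5", charges = 1, rt_apex = 5,
                peak_width = 10, scale_intensity = 1e5, shape = "gaussian",
                fragment_source = "none")
  cfg <- cfg_quiet(gradient_length = 5.05, scan_diff = 5, top_n = 0)
  run <- simulate_run(list(m), cfg)
  sc <- run$scans[[2]]   # the scan at rt = 5, the apex
  pat <- isotope_pattern("C10H15N3O5", 1)
  expect_equal(sc$mz, pat$peaks$mz, tolerance = 1e-9)
  expect_equal(sc$intensity, pat$peaks$abundance * 1e5, tolerance = 1e-9)
})

test_that("at most top_n MS2 scans are triggered per MS1 scan", {
  cfg <- cfg_quiet(gradient_length = 30, top_n = 2, exclusion_time = 0,
                   min_intensity = 10)
  run <- two_peptide_run(cfg)
  lv <- ms_levels(run)
  runs2 <- rle(lv)
  expect_true(all(runs2$lengths[runs2$values == 2L] <= 2L))
  expect_gt(sum(lv == 2L), 0L)
})

test_that("dynamic exclusion blocks re-selection for the configured time", {
  cfg <- cfg_quiet(gradient_length = 60, top_n = 2, exclusion_time = 30,
                   min_intensity = 10)
  mols <- list(molecule("wide", sequence = "ELVISLIVESK", charges = 2,
                        rt_apex = 30, peak_width = 200,
                        scale_intensity = 1e6))
  run <- simulate_run(mols, cfg)
  lv <- ms_levels(run)
  sel_rt <- scan_rts(run)[lv == 2L]
  # the molecule elutes over the whole run: selections must be spaced by
  # at least the exclusion time
  expect_gt(length(sel_rt), 1L)
  expect_true(all(diff(sel_rt) >= cfg$exclusion_time))
})

test_that("no precursor m/z is ever selected twice within the exclusion time", {
  cfg <- run_config(gradient_length = 40, top_n = 3, exclusion_time = 10,
                    min_intensity = 100, seed = 5)
  run <- two_peptide_run(cfg)
  lv <- ms_levels(run)
  # selection happens at the parent MS1 scan's clock time
  prec <- do.call(rbind, lapply(run$scans[lv == 2L], function(s) {
    data.frame(rt = run$scans[[s$precursor$parent_scan_id]]$rt,
               mz = s$precursor$mz)
  }))
  if (!is.null(prec)) {
    for (i in seq_len(nrow(prec))) {
      same <- abs(prec$mz - prec$mz[i]) / prec$mz[i] * 1e6 <= 10
      close_rt <- abs(prec$rt - prec$rt[i]) < cfg$exclusion_time
      expect_equal(sum(same & close_rt), 1L)   # only the event itself
    }
  }
})

test_that("MS2 fragment intensities scale with fragmentation efficiency", {
  cfg <- cfg_quiet(gradient_length = 20, top_n = 1, exclusion_time = 0,
                   min_intensity = 10, seed = 5)
  full <- two_peptide_run(cfg, eff_a = 1)
  quarter <- two_peptide_run(cfg, eff_a = 0.25)
  lv <- ms_levels(full)
  pick <- function(run) Filter(function(s) {
    s$ms_level == 2L && identical(s$precursor$molecule_ids, "pepA")
  }, run$scans)
  f1 <- pick(full); f2 <- pick(quarter)
  expect_gt(length(f1), 0L)
  expect_equal(length(f1), length(f2))
  expect_equal(f2[[1]]$intensity, f1[[1]]$intensity * 0.25, tolerance = 1e-9)
  expect_equal(f2[[1]]$mz, f1[[1]]$mz, tolerance = 1e-12)
})

test_that("chimeric MS2 spectra are the union of the single-molecule spectra", {
  # two co-eluting peptides whose precursors sit inside one isolation window
  a <- molecule("isoA", sequence = "AAGLSEK", charges = 1, rt_apex = 10,
                peak_width = 20, scale_intensity = 3e5)
  b <- molecule("isoB", sequence = "GALSEAK", charges = 1, rt_apex = 11,
                peak_width = 20, scale_intensity = 2e5)
  expect_lt(abs(monoisotopic_mass(peptide_to_formula("AAGLSEK")) -
                  monoisotopic_mass(peptide_to_formula("GALSEAK"))), 1e-9)
  cfg <- cfg_quiet(gradient_length = 12, top_n = 1, exclusion_time = 0,
                   min_intensity = 10, isolation_width = 2)
  both <- simulate_run(list(a, b), cfg)
  only_a <- simulate_run(list(a), cfg)
  only_b <- simulate_run(list(b), cfg)
  pick_ms2 <- function(run, rt) {
    Filter(function(s) s$ms_level == 2L && abs(s$rt - rt) < 1e-9, run$scans)
  }
  # compare at a mid-elution MS2 (near the apexes) where all three runs are
  # above the minimum intensity and therefore on the same MS1/MS2 cadence
  lv <- ms_levels(both)
  rt2s <- scan_rts(both)[lv == 2L]
  rt2 <- rt2s[which.min(abs(rt2s - 10.5))]
  chim <- pick_ms2(both, rt2)[[1]]
  expect_setequal(chim$precursor$molecule_ids, c("isoA", "isoB"))
  sa <- pick_ms2(only_a, rt2)
  sb <- pick_ms2(only_b, rt2)
  expect_length(sa, 1L)
  expect_length(sb, 1L)
  want <- rbind(data.frame(mz = sa[[1]]$mz, intensity = sa[[1]]$intensity),
                data.frame(mz = sb[[1]]$mz, intensity = sb[[1]]$intensity))
  want <- want[order(want$mz), ]
  # merge shared m/z values the way scan assembly does
  grp <- cumsum(c(TRUE, diff(want$mz) >= 1e-4))
  tot <- rowsum(want$intensity, grp)[, 1]
  ctr <- rowsum(want$intensity * want$mz, grp)[, 1] / tot
  expect_equal(chim$mz, unname(ctr), tolerance = 1e-9)
  expect_equal(chim$intensity, unname(tot), tolerance = 1e-9)
})

test_that("every MS2 scan maps back to a feature covering its retention time", {
  cfg <- run_config(gradient_length = 40, top_n = 3, exclusion_time = 5,
                    min_intensity = 100, seed = 6)
  run <- two_peptide_run(cfg)
  feats <- run$features
  for (s in run$scans) {
    if (s$ms_level != 2L) next
    parent_rt <- run$scans[[s$precursor$parent_scan_id]]$rt
    for (mid in s$precursor$molecule_ids) {
      row <- feats[feats$id == mid, ]
      expect_true(any(row$rt_start <= parent_rt & parent_rt < row$rt_end))
      expect_true(any(vapply(strsplit(row$ms2_scan_ids, ";"), function(v) {
        as.character(s$scan_id) %in% v
      }, logical(1))))
    }
  }
})

test_that("XIC areas are proportional to the configured apex intensities", {
  set.seed(202)
  scales <- seq(1e5, 1e6, length.out = 10)
  mols <- lapply(seq_along(scales), function(i) {
    molecule(sprintf("mol%02d", i),
             formula = sprintf("C%dH%dN2O3", 9 + i, 13 + i),
             charges = 1, rt_apex = 15 + i * 7, peak_width = 30,
             scale_intensity = scales[i])
  })
  cfg <- run_config(
    gradient_length = 120, top_n = 0, seed = 13,
    ms1_noise = noise_params(m_int = 2000, c_int = 1e-5, d_int = 100,
                             m_mz = 0.001701, y_mz = 0.2,
                             white_total = 1000, fragment_omission_p = 0))
  run <- simulate_run(mols, cfg)
  areas <- vapply(mols, function(m) {
    base <- isotope_pattern(m$formula, 1)
    bmz <- base$peaks$mz[which.max(base$peaks$abundance)]
    x <- xic(run, bmz, tol_ppm = 20)
    trapz(x$rt, x$intensity)
  }, numeric(1))
  expect_gt(cor(areas, scales), 0.99)
})

test_that("a configured machine offset is recovered from the written m/z values", {
  m <- molecule("off", formula = "C20H30N5O10", charges = 1, rt_apex = 10,
                peak_width = 20, scale_intensity = 1e6,
                fragment_source = "none")
  cfg <- cfg_quiet(gradient_length = 20, top_n = 0, ppm_offset = 4)
  run <- simulate_run(list(m), cfg)
  # noise-free scans contain the full envelope, so peaks match by index
  theo <- isotope_pattern("C20H30N5O10", 1)$peaks$mz
  devs <- unlist(lapply(run$scans, function(s) {
    if (length(s$mz) != length(theo)) return(NULL)
    (s$mz / theo - 1) * 1e6
  }))
  expect_gt(length(devs), 0L)
  expect_equal(median(devs), 4, tolerance = 0.01 / 4)
})

test_that("identical seeds give bit-identical runs; different seeds differ", {
  cfg <- run_config(gradient_length = 15, top_n = 2, min_intensity = 100,
                    seed = 99)
  r1 <- two_peptide_run(cfg)
  r2 <- two_peptide_run(cfg)
  expect_identical(r1$scans, r2$scans)
  expect_identical(r1$features, r2$features)
  cfg2 <- run_config(gradient_length = 15, top_n = 2, min_intensity = 100,
                     seed = 100)
  r3 <- two_peptide_run(cfg2)
  expect_false(identical(r1$scans, r3$scans))
})

test_that("scan arrays are strictly ascending with non-negative intensities", {
  cfg <- run_config(gradient_length = 20, top_n = 3, min_intensity = 100,
                    seed = 14)
  run <- two_peptide_run(cfg)
  for (s in run$scans) {
    expect_true(all(diff(s$mz) > 0))
    expect_true(all(s$intensity >= 0))
    expect_equal(length(s$mz), length(s$intensity))
    if (s$ms_level == 2L) {
      expect_false(is.null(s$precursor$mz))
      expect_gt(s$precursor$charge, 0L)
    }
  }
})
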