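test_that("generators are deterministic per seed", {
  e1 <- gen_conformers("APLpSFRGSLPKSYVK", 3, seed = 13)
  e2 <- gen_conformers("APLpSFRGSLPKSYVK", 3, seed = 13)
  for (i in 1:3) expect_identical(e1[[i]], e2[[i]])
  e3 <- gen_conformers("APLpSFRGSLPKSYVK", 3, seed = 14)
  expect_false(identical(e1[[1]]$atoms, e3[[1]]$atoms))
  # byte-identical PDB output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_ensemble(e1, d1); write_ensemble(e2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  c1 <- gen_calibrants(400, 0.55, 1.4, n = 10, noise_frac = 0.01, seed = 8)
  c2 <- gen_calibrants(400, 0.55, 1.4, n = 10, noise_frac = 0.01, seed = 8)
  expect_identical(c1, c2)
  a1 <- gen_atd(data.frame(ccs = 350, width = 4, height = 1),
                noise_sd = 0.01, seed = 2)
  a2 <- gen_atd(data.frame(ccs = 350, width = 4, height = 1),
                noise_sd = 0.01, seed = 2)
  expect_identical(a1, a2)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_conformers("ApSK", 1, seed = 1))
  invisible(gen_calibrants(400, 0.5, 1.4, n = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("contact specs validate their margins", {
  expect_error(contact_spec(4, 11, 4.5, present = TRUE), "below 4")
  expect_error(contact_spec(4, 11, 5, present = FALSE), "6 A or more")
  expect_silent(contact_spec(4, 11, 3.5))
  expect_error(gen_conformers("APLpSFRGSLPKSYVK", 1,
                              contacts = contact_spec(2, 11, 3.5)),
               "phosphosite")
})

test_that("planted distances are hit to within 0.1 A, others kept far", {
  contacts <- contact_spec(4, 11, 3.4)
  ens <- gen_conformers("APLpSFRGSLPKSYVK", 10, contacts = contacts,
                        seed = 17)
  pat <- pattern_salt_bridge()
  for (s in ens) {
    g <- charged_atoms(s, pat)
    expect_equal(min_group_distance(g$phosphate, g$K11), 3.4,
                 tolerance = 0.1)
    expect_gte(min_group_distance(g$phosphate, g$R6), 6)
    expect_gte(min_group_distance(g$phosphate, g$K15), 6)
  }
})

test_that("size spread produces a CCS distribution bracketing the base", {
  ens <- gen_conformers("APLpSFRGSLPKSYVK", 12, seed = 19,
                        size_spread = 0.15)
  res <- batch_ccs(ens, n_orientations = 60, n_darts = 256, seed = 1)
  expect_gt(stats::sd(res$ccs) / mean(res$ccs), 0.01)
  # spread preserves planted contact distances (backbone-only scaling)
  ens2 <- gen_conformers("APLpSFRGSLPKSYVK", 5,
                         contacts = contact_spec(4, 11, 3.5),
                         seed = 20, size_spread = 0.15)
  pat <- pattern_salt_bridge()
  for (s in ens2)
    expect_equal(min_group_distance(charged_atoms(s, pat)$phosphate,
                                    charged_atoms(s, pat)$K11),
                 3.5, tolerance = 0.1)
})

test_that("calibrant generation inverts the power law exactly at zero noise", {
  cal <- gen_calibrants(520, 0.42, 1.2, n = 8, noise_frac = 0, seed = 25)
  red <- reduced_ccs(cal$ccs_A2, cal$charge, cal$mass)
  tdp <- correct_drift_time(cal$drift_time_ms,
                            cal$mass / cal$charge + 1.0072765, 1.2)
  expect_equal(red, 520 * tdp^0.42, tolerance = 1e-9)
  expect_error(gen_calibrants(400, 0.55, 1.4, n = 2), "at least 3")
})

test_that("peak lists realise requested abundances and reject bad ones", {
  pep <- build_peptide("APLpSFRGSLPKSYVK")
  ab <- data.frame(ion_type = c("c", "charge_reduced"),
                   frag_index = c(12, NA), neutral_loss = 0,
                   abundance = c(50, 50))
  pl <- gen_peaklist(pep, ab)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$intensity[1] / sum(pl$intensity), 0.5)
  # abundance for an impossible ion (fragment 20 of a 15-mer)
  bad <- data.frame(ion_type = "c", frag_index = 20, neutral_loss = 0,
                    abundance = 10)
  expect_error(gen_peaklist(pep, bad), "not generatable")
  over <- data.frame(ion_type = "c", frag_index = 12, neutral_loss = 0,
                     abundance = 120)
  expect_error(gen_peaklist(pep, over), "above 100")
})

test_that("decoys stay clear of theoretical ions and of assignments", {
  pep <- build_peptide("APLpSFRGSLPKSYVK")
  ab <- data.frame(ion_type = c("c", "z_radical"), frag_index = c(12, 11),
                   neutral_loss = 0, abundance = c(40, 20))
  clean <- gen_peaklist(pep, ab, n_decoys = 0, seed = 33)
  noisy <- gen_peaklist(pep, ab, n_decoys = 40, decoy_min_ppm = 5,
                        seed = 33)
  ions <- theoretical_ions(pep, types = c("c", "z_radical",
                                          "charge_reduced"))
  a_clean <- assign_peaks(clean, ions, tol_ppm = 3)
  a_noisy <- assign_peaks(noisy, ions, tol_ppm = 3)
  expect_equal(nrow(a_noisy), nrow(a_clean))
  expect_setequal(a_noisy$label, a_clean$label)
})

test_that("arrival-time profiles sum their Gaussians on the grid", {
  atd <- gen_atd(data.frame(ccs = c(337, 351), width = c(4, 4),
                            height = c(1, 2)))
  i337 <- which.min(abs(atd$ccs - 337))
  expect_equal(atd$intensity[i337],
               1 + 2 * exp(-(337 - 351)^2 / 32), tolerance = 1e-9)
  expect_error(gen_atd(data.frame(ccs = numeric(0), width = numeric(0),
                                  height = numeric(0))))
  # detection success improves with signal-to-noise (seeded sweep)
  hits <- vapply(c(0.02, 0.4), function(h) {
    found <- vapply(1:10, function(k) {
      atd <- gen_atd(data.frame(ccs = 360, width = 4, height = h),
                     noise_sd = 0.02, seed = k)
      p <- detect_conformers(atd, min_frac = 0.5)
      any(abs(p$ccs - 360) <= 1)
    }, TRUE)
    mean(found)
  }, 0)
  expect_gte(hits[2], hits[1])
})
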