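test_that("charged atoms resolve to the expected heavy atoms", {
  ens <- gen_conformers("APLpSFRGSLPKSYVK", n = 1, seed = 14)
  s <- ens[[1]]
  groups <- charged_atoms(s, pattern_salt_bridge())
  expect_setequal(names(groups), c("R6", "K11", "K15", "phosphate"))
  expect_equal(nrow(groups$R6), 3L)       # guanidinium N triad
  expect_equal(nrow(groups$K11), 1L)      # ammonium NZ
  expect_equal(nrow(groups$phosphate), 3L)  # terminal phosphate oxygens
  # no N-terminus entry unless the pattern charges it
  expect_false("NT" %in% names(groups))
  nt_pat <- protonation_pattern(
    "NT+,K11+,K15+,POx-",
    data.frame(index = c(1L, 11L, 15L),
               kind = c("n_terminus", "lys_ammonium", "lys_ammonium")),
    phosphate_state = -1L, phosphosite = 4L)
  expect_true("NT" %in% names(charged_atoms(s, nt_pat)))
  # missing atoms raise a clear error
  bad <- protonation_pattern(
    "K2+", data.frame(index = 2L, kind = "lys_ammonium"),
    phosphate_state = -1L, phosphosite = 4L)
  expect_error(charged_atoms(s, bad), "lacks expected")
})

test_that("minimum group distance equals the brute-force double loop", {
  expect_equal(min_group_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(min_group_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(19)
  a <- matrix(rnorm(15), ncol = 3)
  b <- matrix(rnorm(21), ncol = 3)
  brute <- min(vapply(seq_len(5), function(i)
    min(vapply(seq_len(7), function(j)
      sqrt(sum((a[i, ] - b[j, ])^2)), 0)), 0))
  expect_equal(min_group_distance(a, b), brute, tolerance = 1e-12)
  # invariant to atom order within groups
  expect_equal(min_group_distance(a[sample(5), ], b[sample(7), ]), brute,
               tolerance = 1e-12)
})

test_that("the 4 A rule classifies strictly", {
  expect_equal(classify_contact(3.99, -1L, TRUE), "salt_bridge")
  expect_equal(classify_contact(4.00, -1L, TRUE), "none")
  expect_equal(classify_contact(3.5, 0L, TRUE), "ionic_hydrogen_bond")
  expect_equal(classify_contact(3.5, 0L, FALSE), "hydrogen_bond")
  expect_equal(classify_contact(10, 0L, TRUE), "none")
  # monotone: shrinking d never turns a contact off
  d <- seq(5, 0.5, by = -0.5)
  cls <- vapply(d, classify_contact, "", phosphate_state = -1L,
                partner_charged = TRUE)
  first_y <- which(cls != "none")[1]
  expect_true(all(cls[first_y:length(cls)] != "none"))
  expect_error(classify_contact(3, -1L, TRUE, threshold = -1),
               "negative")
})

test_that("planted contacts reproduce the intended Y/N row exactly", {
  # emulates a 337 A^2-conformer row: pS4-K11 in contact, others far
  contacts <- contact_spec(4, 11, 3.5, present = TRUE)
  ens <- gen_conformers("APLpSFRGSLPKSYVK", n = 5, contacts = contacts,
                        seed = 23)
  tab <- interaction_table(ens, pattern_salt_bridge())
  grid <- contact_grid(tab)
  expect_equal(unname(grid[, "K11"]), rep("Y", 5))
  expect_equal(unname(grid[, "R6"]), rep("N", 5))
  expect_equal(unname(grid[, "K15"]), rep("N", 5))
  expect_equal(tab$classification[tab$site == "K11"], rep("salt_bridge", 5))
  d <- tab$min_distance[tab$site == "K11"]
  expect_equal(d, rep(3.5, 5), tolerance = 0.1)
  # same geometry under the neutral-phosphate hypothesis: ionic H-bond
  tab0 <- interaction_table(ens, pattern_neutral_phosphate())
  expect_true(all(tab0$classification[tab0$site == "K15"] == "none"))
})

test_that("two planted contacts give a Y,N,Y row; none give all-N", {
  contacts <- rbind(contact_spec(4, 6, 3.2), contact_spec(4, 15, 3.8))
  ens <- gen_conformers("APLpSFRGSLPKSYVK", n = 3, contacts = contacts,
                        seed = 31)
  grid <- contact_grid(interaction_table(ens, pattern_salt_bridge()))
  expect_equal(unname(grid[, "R6"]), rep("Y", 3))
  expect_equal(unname(grid[, "K11"]), rep("N", 3))
  expect_equal(unname(grid[, "K15"]), rep("Y", 3))
  none <- gen_conformers("APLpSFRGSLPKSYVK", n = 3, seed = 32)
  grid0 <- contact_grid(interaction_table(none, pattern_salt_bridge()))
  expect_true(all(grid0 == "N"))
})

test_that("cells do not depend on atom order within the structure", {
  ens <- gen_conformers("APLpSFRGSLPKSYVK", n = 1,
                        contacts = contact_spec(4, 11, 3.7), seed = 40)
  s <- ens[[1]]
  perm <- s
  ord <- sample(nrow(s$atoms))
  perm$atoms <- s$atoms[ord, ]
  t1 <- interaction_table(list(s), pattern_salt_bridge())
  t2 <- interaction_table(list(perm), pattern_salt_bridge())
  expect_equal(t1$min_distance, t2$min_distance, tolerance = 1e-12)
  expect_equal(t1$contact, t2$contact)
})

test_that("boundary distances honour strict inequality end to end", {
  # minimal structure with exact coordinates: phosphate oxygens at the
  # origin region, K11 NZ placed at exactly d on the x axis
  make_exact <- function(d) {
    structure_from_atoms(
      element = c("O", "O", "O", "N", "N", "N", "N", "N"),
      xyz = rbind(c(0, 0, 0), c(-1, 1, 0), c(-1, -1, 0),
                  c(d, 0, 0),                        # K11 NZ
                  c(0, 20, 0), c(1, 20, 0), c(0.5, 20.8, 0),  # R6 triad
                  c(0, -20, 0)),                     # K15 NZ
      resno = c(4L, 4L, 4L, 11L, 6L, 6L, 6L, 15L),
      resid = c("SEP", "SEP", "SEP", "LYS", "ARG", "ARG", "ARG", "LYS"),
      elety = c("O1P", "O2P", "O3P", "NZ", "NE", "NH1", "NH2", "NZ"),
      label = "exact")
  }
  for (d in c(3.99, 4.00)) {
    grid <- contact_grid(interaction_table(list(make_exact(d)),
                                           pattern_salt_bridge()))
    expect_equal(unname(grid[, "K11"]), if (d < 4) "Y" else "N")
  }
})
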