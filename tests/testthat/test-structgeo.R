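test_that("PDB round trip preserves coordinates to format precision", {
  s <- gen_structure("ideal_helix", list(length = 8))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  back <- parse_pdb(f)
  expect_equal(nrow(back$atoms), nrow(s$atoms))
  expect_equal(coords(back), coords(s), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("multi-model files load as separate coordinate models", {
  ref <- gen_structure("ideal_helix", list(length = 6))
  tr <- gen_trajectory(ref, "stable", 3, noise_sigma = 0.2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  s <- parse_pdb(f)
  expect_length(s$models, 3)
  expect_false(isTRUE(all.equal(s$models[[1]], s$models[[3]])))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.400   0.400   0.000  1.00  0.00           C",
    "END"), f)
  s <- parse_pdb(f)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(parse_pdb(f2), class = "vuscope_format_error")
})

test_that("planted hydrogen bond is reported at its exact distance", {
  s <- gen_structure("planted_interactions",
                     list(probes = "hbond", hbond_distance = 2.7))
  hb <- find_hbonds(s)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.7, tolerance = 1e-9)
  expect_equal(hb$atom_a, "OG")
  # beyond the cutoff: nothing
  far <- gen_structure("planted_interactions",
                       list(probes = "hbond", hbond_distance = 3.8))
  expect_equal(nrow(find_hbonds(far)), 0)
})

test_that("planted salt bridge is detected across chains and only within cutoff", {
  s <- gen_structure("planted_interactions",
                     list(probes = "salt_bridge", salt_distance = 3.5))
  sb <- find_salt_bridges(s)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)
  expect_true(sb$interchain)
  far <- gen_structure("planted_interactions",
                       list(probes = "salt_bridge", salt_distance = 5.0))
  expect_equal(nrow(find_salt_bridges(far)), 0)
})

test_that("cation-pi detection respects distance and ring-face geometry", {
  s <- gen_structure("planted_interactions",
                     list(probes = "cation_pi", catpi_distance = 4,
                          catpi_angle = 0))
  cp <- find_cation_pi(s)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$distance, 4, tolerance = 1e-9)
  expect_equal(cp$angle, 0, tolerance = 1e-6)
  # in-plane cation (angle 90 degrees) is not cation-pi
  flat <- gen_structure("planted_interactions",
                        list(probes = "cation_pi", catpi_distance = 4,
                             catpi_angle = 90))
  expect_equal(nrow(find_cation_pi(flat)), 0)
})

test_that("detectors agree with brute-force oracles on random fixtures", {
  for (seed in c(3, 14)) {
    s <- random_geometry_fixture(n_res = 50, seed = seed)
    hb <- find_hbonds(s)
    expect_equal(sort(paste(hb$chain_a, hb$resno_a, hb$atom_a, "->",
                            hb$chain_b, hb$resno_b, hb$atom_b)),
                 oracle_hbonds(s))
    sb <- find_salt_bridges(s)
    expect_equal(record_keys(sb), oracle_salt_bridges(s))
    cp <- find_cation_pi(s)
    expect_equal(record_keys(cp), oracle_cation_pi(s))
    res <- s$atoms[1, c("chain", "resno")]
    expect_equal(min_interchain_distance(s, c(res$chain, res$resno)),
                 oracle_min_interchain(s, c(res$chain, res$resno)),
                 tolerance = 1e-9)
  }
})

test_that("detector outputs are invariant under rigid transforms", {
  s <- random_geometry_fixture(n_res = 30, seed = 6)
  R <- random_rotation(77)
  s2 <- transform_structure(s, R, c(11.3, -7.2, 4.4))
  hb1 <- find_hbonds(s); hb2 <- find_hbonds(s2)
  expect_equal(hb2$distance, hb1$distance, tolerance = 1e-6)
  expect_equal(record_keys(hb2), record_keys(hb1))
  sb1 <- find_salt_bridges(s); sb2 <- find_salt_bridges(s2)
  expect_equal(sb2$distance, sb1$distance, tolerance = 1e-6)
  cp1 <- find_cation_pi(s); cp2 <- find_cation_pi(s2)
  expect_equal(cp2$distance, cp1$distance, tolerance = 1e-6)
  expect_equal(cp2$angle, cp1$angle, tolerance = 1e-4)
  res <- s$atoms[5, c("chain", "resno")]
  expect_equal(min_interchain_distance(s2, c(res$chain, res$resno)),
               min_interchain_distance(s, c(res$chain, res$resno)),
               tolerance = 1e-6)
})

test_that("inter-chain distance needs two chains and an existing residue", {
  h <- gen_structure("ideal_helix", list(length = 5))
  expect_error(min_interchain_distance(h, c("A", 1)),
               class = "vuscope_not_applicable_error")
  d <- gen_structure("toy_dimer", list(separation = 12, length = 8))
  expect_error(min_interchain_distance(d, c("A", 99)),
               class = "vuscope_input_error")
  # the interface residue of the planted dimer sits exactly at separation
  at <- d$atoms
  xyz <- coords(d)
  dm <- cross_dist(xyz[at$chain == "A", ], xyz[at$chain == "B", ])
  nearest <- at$resno[at$chain == "A"][which(dm == min(dm),
                                             arr.ind = TRUE)[1, 1]]
  expect_equal(min_interchain_distance(d, c("A", nearest)), 12,
               tolerance = 1e-6)
})

test_that("solvent exposure is 1 when isolated, 0 when caged, and additive", {
  lone <- chk_structure(data.frame(
    chain = "A", resno = 1, resid = "SER",
    elety = c("N", "CA", "C", "O", "CB", "OG"),
    elem = c("N", "C", "C", "O", "C", "O"), het = FALSE,
    x = c(-1.4, 0, 1.2, 1.4, -0.2, 0.5),
    y = c(0.9, 1.4, 0.7, -0.5, -1.0, -2.2),
    z = c(0, 0.2, -0.2, -0.3, 0.5, 0.3)))
  expect_equal(relative_exposure(lone, c("A", 1))$ratio, 1,
               tolerance = 1e-9)
  caged <- gen_structure("planted_interactions", list(cage = list()))
  expect_lt(relative_exposure(caged, c("A", 40))$ratio, 0.02)
  expect_equal(relative_exposure(caged, c("A", 40))$class, "buried")
  # total SASA equals the sum of per-atom SASA by construction; check the
  # per-atom areas respond monotonically to added occluders
  s <- gen_structure("ideal_helix", list(length = 6))
  hv <- which(s$atoms$elem != "H")
  a <- sasa_atoms(coords(s)[hv, ], s$atoms$elem[hv])
  expect_true(all(a >= 0))
  expect_equal(sum(a), sum(a[1:10]) + sum(a[-(1:10)]), tolerance = 1e-9)
  # occlusion: adding a second copy nearby cannot increase any atom's area
  shifted <- coords(s)[hv, ]; shifted[, 1] <- shifted[, 1] + 4
  a2 <- sasa_atoms(rbind(coords(s)[hv, ], shifted),
                   rep(s$atoms$elem[hv], 2))[seq_along(hv)]
  expect_true(all(a2 <= a + 1e-9))
})

test_that("substitution screening flags growth into crowded sites only", {
  caged <- gen_structure("planted_interactions", list(cage = list()))
  his_tyr <- substitution_clash_screen(caged, c("A", 40), "TYR")
  expect_gt(his_tyr$delta_volume, 0)
  expect_true(his_tyr$potential_clash)
  # the same substitution at an exposed site is not flagged
  open_site <- gen_structure("planted_interactions")
  sc <- substitution_clash_screen(open_site, c("A", 20), "TRP")
  expect_gt(sc$delta_volume, 0)
  expect_false(sc$potential_clash)
  # shrinking substitutions are never flagged, however crowded
  ala_gly <- substitution_clash_screen(caged, c("A", 40), "GLY")
  expect_lt(ala_gly$delta_volume, 0)
  expect_false(ala_gly$potential_clash)
  expect_error(substitution_clash_screen(caged, c("A", 40), "XXX"),
               class = "vuscope_typing_error")
})
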