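helix_ref <- function(n = 30) gen_structure("ideal_helix", list(length = n))

test_that("superposition recovers rigid transforms exactly and is optimal", {
  ref <- coords(helix_ref(12))
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(5)
  moved <- sweep(ref %*% R, 2, c(8, -4, 13), "+")
  expect_lt(superpose(moved, ref)$rmsd, 1e-10)
  # optimality: no sampled rotation does better than the Kabsch fit
  noisy <- ref + withr::with_seed(2, matrix(rnorm(length(ref), sd = 1),
                                            ncol = 3))
  best <- superpose(noisy, ref)$rmsd
  for (k in 1:200) {
    Rk <- random_rotation(k)
    cand <- sweep(noisy %*% Rk, 2, colMeans(noisy %*% Rk) - colMeans(ref))
    expect_gte(sqrt(mean(rowSums((cand - ref)^2))) / 10, best - 1e-12)
  }
  expect_error(superpose(ref[1:2, ], ref[1:2, ]),
               class = "vuscope_degenerate_selection_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line),
               class = "vuscope_degenerate_selection_error")
})

test_that("superposition matches an established reference implementation", {
  ref <- coords(helix_ref(15))
  noisy <- ref + withr::with_seed(8, matrix(rnorm(length(ref), sd = 0.8),
                                            ncol = 3))
  ours <- superpose(noisy, ref)$rmsd * 10
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(noisy)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("zero-noise trajectories give identity global metrics", {
  tr <- gen_trajectory(helix_ref(20), "stable", 4, noise_sigma = 0,
                       seed = 1)
  gs <- global_series(tr, compute_sasa = FALSE, compute_ss = TRUE)
  expect_true(all(gs$rmsd < 1e-12))
  expect_true(all(gs$native_contact_fraction == 1))
  expect_true(all(abs(gs$tm_score - 1) < 1e-12))
  expect_true(all(gs$ss_alpha >= 0.9))
  expect_true(attr(gs, "global_stable"))
})

test_that("a moderate-noise stable trajectory stays under the 1-nm global flag", {
  tr <- gen_trajectory(helix_ref(20), "stable", 10, noise_sigma = 0.5,
                       seed = 4)
  gs <- global_series(tr, compute_sasa = FALSE, compute_ss = FALSE)
  expect_true(attr(gs, "global_stable"))
  expect_true(all(gs$rmsd < 0.1))
})

test_that("dissociation grows the radius of gyration after onset", {
  dm <- gen_structure("toy_dimer", list(separation = 2.5, length = 10))
  tr <- gen_trajectory(dm, "dissociation", 20, noise_sigma = 0,
                       params = list(chain = "B", t0 = 10, velocity = 1),
                       seed = 1)
  gs <- global_series(tr, compute_sasa = FALSE, compute_ss = FALSE)
  rg <- gs$radius_of_gyration
  expect_true(all(diff(rg[10:20]) > 0))
  expect_equal(rg[1], rg[9], tolerance = 1e-12)
})

test_that("TM-score needs more than 15 residues", {
  tr <- gen_trajectory(helix_ref(10), "stable", 3, noise_sigma = 0,
                       seed = 1)
  expect_error(global_series(tr), class = "vuscope_undefined_error")
})

test_that("native contact fraction decreases as planted displacement grows", {
  ref <- helix_ref(30)
  qs <- vapply(c(0, 2, 4, 8), function(d) {
    tr <- gen_trajectory(ref, "local_departure", 4, noise_sigma = 0,
                         params = list(site = c("A", 15), t0 = 2,
                                       displacement = d), seed = 1)
    gs <- global_series(tr, compute_sasa = FALSE, compute_ss = FALSE)
    gs$native_contact_fraction[4]
  }, numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_lt(qs[4], qs[1])
})

test_that("RMSF is zero without noise, localizes the planted site, and scales", {
  ref <- helix_ref(30)
  still <- gen_trajectory(ref, "stable", 5, noise_sigma = 0, seed = 1)
  expect_true(all(rmsf(still)$rmsf < 1e-12))
  dep <- gen_trajectory(ref, "local_departure", 40, noise_sigma = 0.3,
                        params = list(site = c("A", 15), t0 = 20,
                                      displacement = 5, radius = 6),
                        seed = 3)
  r <- rmsf(dep)
  top <- r$resno[which.max(r$rmsf)]
  site_ctr <- colMeans(coords(ref)[ref$atoms$resno == 15, ])
  d_top <- min(cross_dist(coords(ref)[ref$atoms$resno == top, , drop = FALSE],
                          matrix(site_ctr, 1)))
  expect_lte(d_top, 6)
  lo <- rmsf(gen_trajectory(ref, "stable", 60, noise_sigma = 0.5, seed = 9))
  hi <- rmsf(gen_trajectory(ref, "stable", 60, noise_sigma = 1.0, seed = 9))
  expect_equal(median(hi$rmsf) / median(lo$rmsf), 2, tolerance = 0.1)
  # two frames are the minimum for a defined RMSF
  two <- chk_trajectory(ref, list(coords(ref), coords(ref)))
  expect_true(all(rmsf(two)$rmsf == 0))
})

test_that("local selection obeys its radius and matches a brute-force scan", {
  ref <- helix_ref(20)
  at <- ref$atoms
  only_site <- local_selection(ref, c("A", 10), radius = 0)
  expect_equal(nrow(only_site), 1)
  expect_equal(only_site$resno, 10)
  everything <- local_selection(ref, c("A", 10), radius = 100)
  expect_equal(nrow(everything), 20)
  sel <- local_selection(ref, c("A", 10), radius = 0.8)
  xyz <- coords(ref)
  site_atoms <- which(at$resno == 10)
  manual <- sort(unique(at$resno[vapply(seq_len(nrow(at)), function(i)
    min(cross_dist(xyz[i, , drop = FALSE],
                   xyz[site_atoms, , drop = FALSE])) <= 8, logical(1))]))
  expect_equal(sort(sel$resno), manual)
  expect_error(local_selection(ref, c("B", 1)),
               class = "vuscope_input_error")
})

test_that("pairwise RMSD matrices are symmetric, zero-diagonal and see planted blocks", {
  ref <- helix_ref(20)
  still <- gen_trajectory(ref, "stable", 12, noise_sigma = 0, seed = 1)
  m0 <- rmsd_matrix(still, stride = 1)
  expect_true(all(m0 == 0))
  noisy <- gen_trajectory(ref, "stable", 12, noise_sigma = 0.6, seed = 2)
  m <- rmsd_matrix(noisy, stride = 1)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
  dep <- gen_trajectory(ref, "local_departure", 40, noise_sigma = 0.3,
                        params = list(site = c("A", 10), t0 = 21,
                                      displacement = 6), seed = 3)
  sel <- local_selection(ref, c("A", 10), radius = 1.0)
  md <- rmsd_matrix(dep, sel, stride = 1)
  pre <- 1:20; post <- 21:40
  within <- mean(c(md[pre, pre][upper.tri(md[pre, pre])],
                   md[post, post][upper.tri(md[post, post])]))
  across <- mean(md[pre, post])
  expect_gt(across, within)
  expect_error(rmsd_matrix(noisy, data.frame(chain = character(0),
                                             resno = integer(0))),
               class = "vuscope_input_error")
})

test_that("neighbour-count clustering satisfies its own postconditions", {
  ref <- helix_ref(20)
  still <- gen_trajectory(ref, "stable", 10, noise_sigma = 0, seed = 1)
  m <- rmsd_matrix(still, stride = 1)
  cl <- cluster_frames(m)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(cl$basal_cluster, 1)
  dep <- gen_trajectory(ref, "local_departure", 30, noise_sigma = 0.2,
                        params = list(site = c("A", 10), t0 = 16,
                                      displacement = 6), seed = 5)
  sel <- local_selection(ref, c("A", 10), radius = 1.0)
  md <- rmsd_matrix(dep, sel, stride = 1)
  cld <- cluster_frames(md)
  expect_equal(length(unique(cld$cluster)), 2)
  expect_equal(unique(cld$cluster[1:15]), cld$basal_cluster)
  expect_equal(length(unique(cld$cluster[16:30])), 1)
  # every frame lies within the cutoff of its cluster medoid
  for (k in unique(cld$cluster)) {
    members <- which(cld$cluster == k)
    expect_true(all(md[cld$medoids[k], members] <= cld$cutoff))
  }
  # determinism
  expect_identical(cluster_frames(md), cluster_frames(md))
})

test_that("point excursions stay stable; sustained terminal departures do not", {
  mk_assign <- function(cluster) {
    structure(list(cluster = cluster, frames = seq_along(cluster),
                   medoids = seq_along(unique(cluster)),
                   basal_cluster = cluster[1], cutoff = 0.15),
              class = "cluster_assignment")
  }
  # mid-trajectory excursion that returns immediately
  exc <- mk_assign(c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1))
  v <- stability_verdict(exc)
  expect_equal(v$verdict, "stable")
  expect_true(is.na(v$departure_frame))
  expect_equal(v$final_outside_fraction, 0)
  # sustained terminal departure
  dep <- mk_assign(c(rep(1, 6), rep(2, 6)))
  vd <- stability_verdict(dep)
  expect_equal(vd$verdict, "unstable")
  expect_equal(vd$departure_frame, 7)
  expect_equal(vd$final_outside_fraction, 1)
  expect_error(stability_verdict(mk_assign(c(1, 1, 1))),
               class = "vuscope_input_error")
})

test_that("planted departure frames are recovered within tolerance", {
  ref <- helix_ref(30)
  sel <- local_selection(ref, c("A", 15), radius = 1.0)
  tr <- gen_trajectory(ref, "local_departure", 500, noise_sigma = 0.5,
                       params = list(site = c("A", 15), t0 = 250,
                                     displacement = 6), seed = 21)
  v <- stability_verdict(cluster_frames(rmsd_matrix(tr, sel)))
  expect_equal(v$verdict, "unstable")
  expect_lt(abs(v$departure_frame - 250), 0.05 * 500)
})

test_that("dimer state tracks the planted interface over the final window", {
  dm <- gen_structure("toy_dimer", list(separation = 2.5, length = 20))
  bound <- gen_trajectory(dm, "stable", 40, noise_sigma = 0.3, seed = 1)
  expect_equal(dimer_state(bound), "bound")
  apart <- gen_trajectory(dm, "dissociation", 40, noise_sigma = 0.3,
                          params = list(chain = "B", t0 = 15,
                                        velocity = 0.5), seed = 1)
  expect_equal(dimer_state(apart), "unbound")
  # drift so slow the final window is still in contact
  slow <- gen_trajectory(dm, "dissociation", 40, noise_sigma = 0.1,
                         params = list(chain = "B", t0 = 39,
                                       velocity = 0.05), seed = 1)
  expect_equal(dimer_state(slow), "bound")
  mono <- gen_trajectory(helix_ref(10), "stable", 4, noise_sigma = 0,
                         seed = 1)
  expect_error(dimer_state(mono), class = "vuscope_not_applicable_error")
})

test_that("replica summaries format fractions and aggregate chains worst-case", {
  mk <- function(id, verdict, chain = "all")
    structure(list(replica_id = id, chain = chain, verdict = verdict,
                   departure_frame = NA, final_outside_fraction = 0),
              class = "stability_verdict")
  s <- replica_summary(list(mk("r1", "stable"), mk("r2", "stable"),
                            mk("r3", "unstable")))
  expect_equal(s$fraction_text, "2/3 (67%)")
  expect_equal(replica_summary(list(mk("r1", "stable"), mk("r2", "stable"),
                                    mk("r3", "stable")))$fraction_text,
               "3/3 (100%)")
  expect_equal(replica_summary(list(mk("r1", "unstable"),
                                    mk("r2", "unstable"),
                                    mk("r3", "unstable")))$fraction_text,
               "0/3 (0%)")
  # one unstable chain makes the whole replica unstable
  mixed <- replica_summary(list(mk("r1", "stable", "A"),
                                mk("r1", "unstable", "B"),
                                mk("r2", "stable", "A"),
                                mk("r2", "stable", "B")))
  expect_equal(mixed$fraction_text, "1/2 (50%)")
})

test_that("trajectories round-trip through multi-model PDB with frame order kept", {
  ref <- helix_ref(10)
  tr <- gen_trajectory(ref, "local_departure", 6, noise_sigma = 0.1,
                       params = list(site = c("A", 5), t0 = 4,
                                     displacement = 4), seed = 6)
  fp <- withr::local_tempfile(fileext = ".pdb")
  rp <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, fp); write_pdb(ref, rp)
  back <- load_trajectory(fp, rp)
  expect_length(back$frames, 6)
  # frame order: displacement appears exactly from the planted frame on
  moved <- vapply(back$frames, function(f)
    max(abs(f - coords(ref))), numeric(1))
  expect_true(all(moved[4:6] > 2))
  expect_true(all(moved[1:3] < 1))
  bad_ref <- helix_ref(9)
  rp2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(bad_ref, rp2)
  expect_error(load_trajectory(fp, rp2), class = "vuscope_input_error")
})

test_that("global metrics are invariant under a rigid transform of all frames", {
  ref <- helix_ref(20)
  tr <- gen_trajectory(ref, "stable", 5, noise_sigma = 0.5, seed = 11)
  R <- random_rotation(13)
  tr2 <- tr
  tr2$frames <- lapply(tr$frames, function(f)
    sweep(f %*% R, 2, c(-20, 4, 9), "-"))
  g1 <- global_series(tr, compute_sasa = FALSE, compute_ss = FALSE)
  g2 <- global_series(tr2, compute_sasa = FALSE, compute_ss = FALSE)
  expect_equal(g2$rmsd, g1$rmsd, tolerance = 1e-9)
  expect_equal(g2$radius_of_gyration, g1$radius_of_gyration,
               tolerance = 1e-9)
  expect_equal(g2$native_contact_fraction, g1$native_contact_fraction)
  expect_equal(g2$tm_score, g1$tm_score, tolerance = 1e-9)
  m1 <- rmsd_matrix(tr, stride = 1)
  m2 <- rmsd_matrix(tr2, stride = 1)
  expect_equal(m1, m2, tolerance = 1e-9)
})
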