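# Seeded generators for every input the pipeline consumes: predictor
# verdict tables, alignments with planted per-column conservation, toy
# structures with planted interactions, and trajectories that are stable,
# locally departing, or dimer-dissociating by construction. The planted
# parameters are the oracles for the analysis stages' recovery tests. All
# randomness flows from the explicit `seed` argument; no generator touches
# the global RNG state. These are statistical stand-ins, not physical
# simulations.

#' Generate a synthetic predictor verdict table
#'
#' Each variant receives 15 i.i.d. verdicts drawn as benign with
#' probability `benign_prob`, missing with probability `na_prob`, and
#' pathogenic otherwise. Scores are uniform on `[0,1]` metadata.
#'
#' @param n_variants number of variants.
#' @param benign_prob,na_prob per-predictor probabilities;
#'   `benign_prob + na_prob <= 1`.
#' @param seed integer seed (required).
#' @return List of [variant_score_set()] objects.
#' @export
gen_predictor_table <- function(n_variants, benign_prob, na_prob, seed) {
  check_prob(benign_prob, "benign_prob")
  check_prob(na_prob, "na_prob")
  if (benign_prob + na_prob > 1)
    stop_vuscope("benign_prob + na_prob must be <= 1",
                 class = "vuscope_parameter_error")
  withr::with_seed(seed, {
    lapply(seq_len(n_variants), function(i) {
      v <- sample(c("B", "NA", "P"), length(predictor_panel()),
                  replace = TRUE,
                  prob = c(benign_prob, na_prob,
                           1 - benign_prob - na_prob))
      if (all(v == "NA")) v[1] <- "P"   # keep the rate defined
      variant_score_set(sprintf("V%03d", i), v,
                        scores = stats::runif(length(predictor_panel())),
                        cdna = sprintf("c.%dA>G", i))
    })
  })
}

#' Write a predictor table (list of variant score sets) as TSV
#'
#' @param table list of [variant_score_set()] objects.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(table, path) {
  panel <- predictor_panel()
  rows <- lapply(table, function(s) {
    d <- c(list(variant_id = s$variant_id, cdna = s$cdna),
           stats::setNames(as.list(s$entries$verdict),
                           paste0(panel, "_verdict")),
           stats::setNames(as.list(ifelse(is.na(s$entries$score), "NA",
                                          format(s$entries$score))),
                           paste0(panel, "_score")))
    as.data.frame(d, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate an alignment with planted per-column conservation
#'
#' Row 1 is the consensus itself (the reference/target sequence); each
#' further sequence carries `consensus[j]` at column `j` with probability
#' `conservation[j]` and otherwise a residue uniform over the other 19.
#' Optional i.i.d. gaps at rate `gap_prob`.
#'
#' @param n_seqs total number of rows (including the target row).
#' @param length alignment width.
#' @param conservation per-column probability vector (recycled if scalar).
#' @param consensus residue string of length `length`.
#' @param seed integer seed.
#' @param gap_prob per-cell gap probability for non-target rows.
#' @return An [msa_alignment()] with `target_index = 1`.
#' @export
gen_msa <- function(n_seqs, length, conservation, consensus, seed,
                    gap_prob = 0) {
  if (base::length(conservation) == 1)
    conservation <- rep(conservation, length)
  check_prob(conservation, "conservation")
  check_prob(gap_prob, "gap_prob")
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (base::length(cons) != length ||
      base::length(conservation) != length)
    stop_vuscope("consensus/conservation length must equal alignment width",
                 class = "vuscope_parameter_error")
  if (!all(cons %in% AA20))
    stop_vuscope("consensus must use the 20 canonical residues",
                 class = "vuscope_parameter_error")
  withr::with_seed(seed, {
    m <- matrix("", nrow = n_seqs, ncol = length)
    m[1, ] <- cons
    for (j in seq_len(length)) {
      hit <- stats::runif(n_seqs - 1) < conservation[j]
      alt <- sample(setdiff(AA20, cons[j]), n_seqs - 1, replace = TRUE)
      m[-1, j] <- ifelse(hit, cons[j], alt)
    }
    if (gap_prob > 0) {
      g <- matrix(stats::runif((n_seqs - 1) * length) < gap_prob,
                  nrow = n_seqs - 1)
      m[-1, ][g] <- "-"
    }
    msa_alignment(apply(m, 1, paste, collapse = ""),
                  ids = c("target", sprintf("hom%03d", seq_len(n_seqs - 1) + 1)),
                  target_index = 1)
  })
}

# --- peptide geometry ------------------------------------------------------

# NeRF atom placement: position d given bonded chain a-b-c, bond length
# |cd|, bond angle b-c-d and torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, tors) {
  angle <- angle * pi / 180; tors <- -tors * pi / 180
  bc <- unit(c - b)
  n <- unit(c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
              (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
              (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d_local <- bond * c(-cos(angle), sin(angle) * cos(tors),
                      sin(angle) * sin(tors))
  c + d_local[1] * bc + d_local[2] * m2 + d_local[3] * n
}

# Build an all-backbone (+CB, +O) peptide with per-residue phi/psi.
build_peptide <- function(phi, psi, resid = "ALA", chain = "A",
                          resno_start = 1, with_cb = TRUE) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  resid <- rep_len(resid, n_res)
  rows <- list()
  add <- function(rn, rid, ety, elem, p)
    rows[[length(rows) + 1]] <<- data.frame(chain = chain, resno = rn,
                                            resid = rid, elety = ety,
                                            elem = elem, het = FALSE,
                                            x = p[1], y = p[2], z = p[3])
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C <- CA + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    rid <- resid[i]
    add(i + resno_start - 1, rid, "N", "N", N)
    add(i + resno_start - 1, rid, "CA", "C", CA)
    add(i + resno_start - 1, rid, "C", "C", C)
    add(i + resno_start - 1, rid, "O", "O",
        place_atom(N, CA, C, 1.231, 120.8, psi[i] + 180))
    if (with_cb && rid != "GLY")
      add(i + resno_start - 1, rid, "CB", "C",
          place_atom(C, N, CA, 1.53, 110.4, 122.5))
    if (i < n_res) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2, psi[i])
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7, 180)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.2, phi[i + 1])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  do.call(rbind, rows)
}

atom_row <- function(chain, resno, resid, elety, elem, p)
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elem = elem, het = FALSE, x = p[1], y = p[2], z = p[3])

hexagon <- function(center, radius = 1.39) {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

#' Generate a toy structure
#'
#' Topologies:
#' * `ideal_helix` — poly-Ala with backbone dihedrals phi = -57, psi = -47
#'   (`params$length`, default 20).
#' * `beta_hairpin` — two extended strands (phi = -135, psi = 135) joined
#'   by a two-residue turn (`params$strand_length`, default 6 per strand).
#' * `planted_interactions` — spatially separated probe groups
#'   (`params$probes`, any subset of `c("hbond", "salt_bridge",
#'   "cation_pi")`, default all) at exactly
#'   specified geometry: a Ser OG donor / backbone O acceptor pair at
#'   `params$hbond_distance` (default 2.7), an Arg/Glu nitrogen-oxygen
#'   pair across chains A/B at `params$salt_distance` (default 3.5), a Lys
#'   NZ cation at `params$catpi_distance` (default 4.0) and elevation
#'   angle `params$catpi_angle` degrees from the ring normal (default 0)
#'   over a Tyr ring; optionally a His residue enclosed in a spherical
#'   carbon cage (`params$cage = list(radius =, n_atoms =)`).
#' * `toy_dimer` — helix chain A plus a rigid copy as chain B translated
#'   so the minimum inter-chain heavy-atom distance equals
#'   `params$separation` (default 12) to within 1e-6.
#'
#' @param topology one of the four names above.
#' @param params topology-specific parameter list.
#' @return A [chk_structure()].
#' @export
gen_structure <- function(topology, params = list()) {
  if (topology == "ideal_helix") {
    n <- params$length %||% 20
    at <- build_peptide(rep(-57, n), rep(-47, n))
    return(chk_structure(at))
  }
  if (topology == "beta_hairpin") {
    n <- params$strand_length %||% 6
    phi <- c(rep(-135, n), -60, 80, rep(-135, n))
    psi <- c(rep(135, n), -30, 0, rep(135, n))
    return(chk_structure(build_peptide(phi, psi)))
  }
  if (topology == "planted_interactions") {
    d_hb <- params$hbond_distance %||% 2.7
    d_sb <- params$salt_distance %||% 3.5
    d_cp <- params$catpi_distance %||% 4.0
    a_cp <- params$catpi_angle %||% 0
    probes <- params$probes %||% c("hbond", "salt_bridge", "cation_pi")
    rows <- list(
      # region 1: H-bond probe (Ser OG donor at origin, Gly O at +x)
      atom_row("A", 1, "SER", "N", "N", c(-1.4, 0.9, 0)),
      atom_row("A", 1, "SER", "CA", "C", c(-1.0, 2.2, 0)),
      atom_row("A", 1, "SER", "C", "C", c(-2.0, 3.3, 0)),
      atom_row("A", 1, "SER", "CB", "C", c(-0.8, -1.0, 0)),
      atom_row("A", 1, "SER", "OG", "O", c(0, 0, 0)),
      atom_row("A", 3, "GLY", "N", "N", c(d_hb + 2.4, 1.0, 0)),
      atom_row("A", 3, "GLY", "CA", "C", c(d_hb + 2.0, 2.2, 0.4)),
      atom_row("A", 3, "GLY", "C", "C", c(d_hb + 1.2, 0.6, 0.8)),
      atom_row("A", 3, "GLY", "O", "O", c(d_hb, 0, 0)),
      # region 2: salt bridge probe across chains (Arg NH1 / Glu OE1)
      atom_row("A", 10, "ARG", "CZ", "C", c(50 - 1.0, 0.6, 0)),
      atom_row("A", 10, "ARG", "NE", "N", c(50 - 1.6, 1.7, 0)),
      atom_row("A", 10, "ARG", "NH1", "N", c(50, 0, 0)),
      atom_row("A", 10, "ARG", "NH2", "N", c(50 - 1.6, -0.4, 0.9)),
      atom_row("B", 10, "GLU", "CD", "C", c(50 + d_sb + 0.7, 0.9, 0)),
      atom_row("B", 10, "GLU", "OE1", "O", c(50 + d_sb, 0, 0)),
      atom_row("B", 10, "GLU", "OE2", "O", c(50 + d_sb + 1.9, 0.6, 0.6)),
      # region 3: cation-pi probe (Tyr six-ring in the xy-plane, Lys NZ
      # at elevation angle a_cp from the ring normal)
      atom_row("A", 30, "LYS", "NZ", "N",
               c(100 + d_cp * sin(a_cp * pi / 180), 0,
                 d_cp * cos(a_cp * pi / 180)))
    )
    keep_probe <- c(rep("hbond", 9), rep("salt_bridge", 7), "cation_pi")
    rows <- rows[keep_probe %in% probes]
    if ("cation_pi" %in% probes) {
      ring <- hexagon(c(100, 0, 0))
      ringnm <- RING_ATOMS$TYR
      for (k in seq_len(6))
        rows[[length(rows) + 1]] <- atom_row("A", 20, "TYR", ringnm[k],
                                             substr(ringnm[k], 1, 1), ring[k, ])
    }
    if (!is.null(params$cage)) {
      cg <- params$cage
      ctr <- c(150, 0, 0)
      rows[[length(rows) + 1]] <- atom_row("A", 40, "HIS", "N", "N",
                                           ctr + c(-1.4, 0.9, 0))
      rows[[length(rows) + 1]] <- atom_row("A", 40, "HIS", "CA", "C",
                                           ctr + c(-1.0, 2.2, 0))
      rows[[length(rows) + 1]] <- atom_row("A", 40, "HIS", "C", "C",
                                           ctr + c(-2.2, 3.0, 0))
      rows[[length(rows) + 1]] <- atom_row("A", 40, "HIS", "CB", "C",
                                           ctr + c(-0.4, -0.9, 0.8))
      his_ring <- hexagon(ctr, 1.17)[1:5, ]
      hr <- RING_ATOMS$HIS
      for (k in 1:5)
        rows[[length(rows) + 1]] <- atom_row("A", 40, "HIS", hr[k],
                                             substr(hr[k], 1, 1),
                                             his_ring[k, ])
      np <- cg$n_atoms %||% 200
      rad <- cg$radius %||% 4.5
      pts <- sweep(sphere_points(np) * rad, 2, ctr, "+")
      for (k in seq_len(np))
        rows[[length(rows) + 1]] <- atom_row("A", 1000 + k, "GLY", "CA",
                                             "C", pts[k, ])
    }
    return(chk_structure(do.call(rbind, rows)))
  }
  if (topology == "toy_dimer") {
    sep <- params$separation %||% 12
    n <- params$length %||% 10
    a <- build_peptide(rep(-57, n), rep(-47, n), chain = "A")
    b <- build_peptide(rep(-57, n), rep(-47, n), chain = "B")
    # side-by-side: translate the copy perpendicular to the helix axis so
    # small separations plant a contact-rich interface along the length
    t <- sep + max(a$y) - min(b$y)   # generous initial guess
    for (iter in 1:60) {
      d <- min(cross_dist(as.matrix(a[, c("x", "y", "z")]),
                          sweep(as.matrix(b[, c("x", "y", "z")]), 2,
                                c(0, t, 0), "+")))
      if (abs(d - sep) < 1e-9) break
      t <- t + (sep - d)
    }
    b$y <- b$y + t
    return(chk_structure(rbind(a, b)))
  }
  stop_vuscope("unknown topology: %s", topology,
               class = "vuscope_parameter_error")
}

#' Generate a synthetic trajectory with planted dynamics
#'
#' Modes:
#' * `stable` — every frame is the reference plus i.i.d. isotropic
#'   Gaussian noise; `noise_sigma` is the RMS displacement per atom in
#'   Angstrom (per-coordinate s.d. `noise_sigma / sqrt(3)`).
#' * `local_departure` — stable before frame `params$t0`; from `t0` on,
#'   all residues with a heavy atom within `params$radius` (default 10 A)
#'   of residue `params$site = c(chain, resno)` are rigidly displaced by
#'   `params$displacement` Angstrom away from the structure centroid, plus
#'   noise.
#' * `dissociation` — chain `params$chain` translates away from the rest
#'   at `params$velocity` Angstrom/frame starting at `params$t0`.
#'
#' @param reference a [chk_structure()].
#' @param mode one of `"stable"`, `"local_departure"`, `"dissociation"`.
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-atom RMS displacement of the noise, Angstrom.
#' @param params mode-specific parameters (see above).
#' @param seed integer seed.
#' @param replica_id label carried into verdicts.
#' @return An object of class `chk_trajectory`.
#' @export
gen_trajectory <- function(reference, mode, n_frames, noise_sigma = 0.5,
                           params = list(), seed = 1, replica_id = "r1") {
  stopifnot(inherits(reference, "chk_structure"))
  if (n_frames < 2)
    stop_vuscope("need at least 2 frames", class = "vuscope_parameter_error")
  ref <- coords(reference)
  at <- reference$atoms
  n_at <- nrow(ref)
  shift <- matrix(0, n_at, 3)
  t0 <- Inf
  per_frame <- NULL
  if (mode == "local_departure") {
    site <- params$site
    if (is.null(site) || !any(at$chain == site[[1]] &
                              at$resno == as.integer(site[[2]])))
      stop_vuscope("local_departure: site absent from reference",
                   class = "vuscope_input_error")
    t0 <- params$t0
    radius <- params$radius %||% 10
    site_idx <- which(at$chain == site[[1]] & at$resno == as.integer(site[[2]]))
    # displaced set: residues with an atom within `radius` of the site
    # centroid (a point); the analyzer's window reaches from all site
    # atoms, so it strictly contains unmoved anchor residues and the
    # rigid local displacement stays visible after superposition
    site_ctr <- colMeans(ref[site_idx, , drop = FALSE])
    d_to_site <- cross_dist(ref, matrix(site_ctr, 1))[, 1]
    moved_res <- unique(paste(at$chain, at$resno)[d_to_site <= radius])
    idx <- which(paste(at$chain, at$resno) %in% moved_res)
    dir <- colMeans(ref[site_idx, , drop = FALSE]) - colMeans(ref)
    dir <- if (vnorm(dir) > 1e-6) unit(dir) else c(0, 0, 1)
    shift[idx, ] <- matrix(rep(dir * params$displacement, each = length(idx)),
                           ncol = 3)
  } else if (mode == "dissociation") {
    ch <- params$chain
    if (is.null(ch) || !any(at$chain == ch))
      stop_vuscope("dissociation: chain absent from reference",
                   class = "vuscope_input_error")
    t0 <- params$t0 %||% 1
    idx <- which(at$chain == ch)
    dir <- unit(colMeans(ref[idx, , drop = FALSE]) -
                  colMeans(ref[-idx, , drop = FALSE]))
    per_frame <- function(i) {
      sh <- matrix(0, n_at, 3)
      if (i >= t0)
        sh[idx, ] <- matrix(rep(dir * params$velocity * (i - t0 + 1),
                                each = length(idx)), ncol = 3)
      sh
    }
  } else if (mode != "stable") {
    stop_vuscope("unknown trajectory mode: %s", mode,
                 class = "vuscope_parameter_error")
  }
  frames <- withr::with_seed(seed, {
    sd_coord <- noise_sigma / sqrt(3)   # noise_sigma = per-atom RMS displacement
    lapply(seq_len(n_frames), function(i) {
      noise <- if (noise_sigma > 0)
        matrix(stats::rnorm(n_at * 3, sd = sd_coord), n_at, 3)
      else matrix(0, n_at, 3)
      sh <- if (!is.null(per_frame)) per_frame(i)
            else if (i >= t0) shift else matrix(0, n_at, 3)
      ref + sh + noise
    })
  })
  structure(list(reference = reference, frames = frames,
                 replica_id = replica_id,
                 temperature_label = params$temperature_label %||% NA,
                 chain_ids = unique(at$chain)),
            class = "chk_trajectory")
}

#' Generate a pedigree and cohort records from an explicit specification
#'
#' The output is deterministic and internally consistent: every non-founder
#' must list two resolvable parents and parentage must be acyclic. Carrier
#' status comes only from the listed genotypes; transmission is not
#' simulated.
#'
#' @param spec list with `pedigree = list(proband =, individuals = list of
#'   lists with id, sex, father, mother, affected, cancer_type, age_dx,
#'   tested, carrier)` and optionally `cohort = list of record lists`.
#' @param seed integer seed (reserved; current generators are
#'   deterministic).
#' @return List with elements `pedigree` (a [pedigree()]) and `cohort`
#'   (data.frame, possibly empty).
#' @export
gen_pedigree_and_cohort <- function(spec, seed = 1) {
  ped <- pedigree(spec$pedigree$individuals, proband = spec$pedigree$proband)
  cohort <- if (!is.null(spec$cohort))
    do.call(rbind, lapply(spec$cohort, function(r)
      as.data.frame(r, check.names = FALSE)))
  else data.frame()
  list(pedigree = ped, cohort = cohort)
}
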