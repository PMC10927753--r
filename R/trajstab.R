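# Trajectory stability assessment: global per-frame metrics, selection of
# the 1-nm neighbourhood around a mutation site, pairwise-RMSD (2D-RMSD)
# clustering of frames, basal-cluster stability verdicts, dimer
# association state, and replica aggregation. Coordinates are Angstrom
# internally; reported RMSD/Rg/SASA use nm (and nm^2), the convention of
# the MD literature this mirrors.

#' Construct a trajectory object
#'
#' @param reference a [chk_structure()] congruent with every frame.
#' @param frames list of n_atoms x 3 coordinate matrices, Angstrom.
#' @param replica_id replica label.
#' @param temperature_label optional metadata (e.g. `"398K"`).
#' @return An object of class `chk_trajectory`.
#' @export
chk_trajectory <- function(reference, frames, replica_id = "r1",
                           temperature_label = NA) {
  stopifnot(inherits(reference, "chk_structure"))
  if (length(frames) < 2)
    stop_vuscope("a trajectory needs at least 2 frames",
                 class = "vuscope_input_error")
  n_at <- nrow(reference$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_at &&
                 ncol(f) == 3, logical(1))
  if (!all(ok))
    stop_vuscope("frame %d does not match the reference atom set",
                 which(!ok)[1], class = "vuscope_input_error")
  structure(list(reference = reference, frames = frames,
                 replica_id = replica_id,
                 temperature_label = temperature_label,
                 chain_ids = unique(reference$atoms$chain)),
            class = "chk_trajectory")
}

#' @export
print.chk_trajectory <- function(x, ...) {
  cat(sprintf("<chk_trajectory> %s: %d frames x %d atoms, chains %s\n",
              x$replica_id, length(x$frames), nrow(x$reference$atoms),
              paste(x$chain_ids, collapse = ",")))
  invisible(x)
}

#' Load a multi-model PDB trajectory against a reference topology
#'
#' @param path multi-model PDB of frames.
#' @param reference_path PDB of the reference structure (model 1 used).
#' @param replica_id replica label.
#' @return A [chk_trajectory()].
#' @export
load_trajectory <- function(path, reference_path, replica_id = "r1") {
  ref <- parse_pdb(reference_path)
  trj <- parse_pdb(path)
  if (nrow(trj$atoms) != nrow(ref$atoms))
    stop_vuscope("atom count mismatch: trajectory %d vs reference %d",
                 nrow(trj$atoms), nrow(ref$atoms),
                 class = "vuscope_input_error")
  chk_trajectory(ref, trj$models, replica_id = replica_id)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [chk_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$reference
  s$models <- traj$frames
  write_pdb(s, path)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over
#' `selection` (row indices; default all), applying the fitted transform
#' to all rows of `mobile`. The returned RMSD (over the selection) is the
#' minimum over all rigid transforms.
#'
#' @param mobile,reference n x 3 coordinate matrices, Angstrom.
#' @param selection integer row indices to fit on.
#' @return List with `coords` (transformed mobile, Angstrom) and `rmsd`
#'   (nm).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop_vuscope("need at least 3 atoms to superpose",
                 class = "vuscope_degenerate_selection_error")
  X <- mobile[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  if (qr(sweep(X, 2, colMeans(X)))$rank < 2)
    stop_vuscope("collinear selection: superposition degenerate",
                 class = "vuscope_degenerate_selection_error")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sv <- svd(crossprod(Xc, Yc))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  out <- sweep(sweep(mobile, 2, mx) %*% R, 2, -my)
  rmsd <- sqrt(mean(rowSums((out[selection, , drop = FALSE] - Y)^2))) / 10
  list(coords = out, rmsd = rmsd)
}

# Minimal Kabsch RMSD (Angstrom in, Angstrom out) on pre-centered blocks.
kabsch_rmsd <- function(Xc, Yc) {
  sv <- svd(crossprod(Xc, Yc))
  d <- sv$d
  if (det(sv$u) * det(sv$v) < 0) d[3] <- -d[3]
  sqrt(max(0, (sum(Xc^2) + sum(Yc^2) - 2 * sum(d)) / nrow(Xc)))
}

native_contact_pairs <- function(s, cutoff = 4.5, min_sep = 4) {
  at <- s$atoms
  hv <- which(at$elem != "H" & !at$het)
  xyz <- coords(s)[hv, , drop = FALSE]
  dm <- cross_dist(xyz, xyz)
  hit <- which(dm <= cutoff & upper.tri(dm), arr.ind = TRUE)
  i <- hv[hit[, 1]]; j <- hv[hit[, 2]]
  same_chain <- at$chain[i] == at$chain[j]
  sep_ok <- !same_chain | abs(at$resno[i] - at$resno[j]) >= min_sep
  keep <- sep_ok & !(same_chain & at$resno[i] == at$resno[j])
  data.frame(i = i[keep], j = j[keep], ref_dist = dm[hit][keep])
}

hbond_count <- function(xyz, flags, at, d_max = 3.5, partner = c("intra", "water")) {
  partner <- match.arg(partner)
  di <- flags$donor; ai <- flags$acceptor
  if (partner == "intra") {
    di <- di[!at$het[di]]; ai <- ai[!at$het[ai]]
  } else {
    w <- at$resid %in% c("HOH", "WAT")
    if (!any(w)) return(0L)
    # protein donor -> water acceptor, plus water donor -> protein acceptor
    n1 <- hbond_count_pairs(xyz, di[!w[di]], ai[w[ai]], at, d_max)
    n2 <- hbond_count_pairs(xyz, di[w[di]], ai[!w[ai] & !at$het[ai]], at, d_max)
    return(n1 + n2)
  }
  hbond_count_pairs(xyz, di, ai, at, d_max)
}

hbond_count_pairs <- function(xyz, di, ai, at, d_max) {
  if (!length(di) || !length(ai)) return(0L)
  dm <- cross_dist(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
  hit <- which(dm <= d_max, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  i <- di[hit[, 1]]; j <- ai[hit[, 2]]
  same_res <- at$chain[i] == at$chain[j] & at$resno[i] == at$resno[j]
  adj_bb <- at$chain[i] == at$chain[j] & abs(at$resno[i] - at$resno[j]) == 1 &
    at$elety[i] %in% BACKBONE_ATOMS & at$elety[j] %in% BACKBONE_ATOMS
  sum(!same_res & !adj_bb)
}

#' Per-frame global metrics
#'
#' For every frame: heavy-atom RMSD to the reference after Kabsch
#' superposition (nm), radius of gyration (nm), solvent-accessible surface
#' area (nm^2), fraction of native contacts, intra-protein and
#' protein-water hydrogen-bond counts, TM-score, and secondary-structure
#' fractions from backbone-dihedral bins. Native contacts are defined on
#' the reference: heavy-atom pairs under `contact_cutoff` between residues
#' at sequence separation of at least 4 (or on different chains); a
#' contact is retained in a frame while its distance stays within
#' `retention_factor` times the reference distance. The TM-score is
#' computed on the Kabsch superposition of the C-alpha trace with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` Angstrom, so the self-score is 1; it
#' requires more than 15 residues.
#'
#' @param traj a [chk_trajectory()].
#' @param contact_cutoff native-contact definition cutoff, Angstrom.
#' @param retention_factor per-frame contact retention multiplier.
#' @param compute_sasa,compute_ss toggles for the costlier columns.
#' @param sasa_points sphere points per atom for SASA.
#' @return data.frame with one row per frame.
#' @export
global_series <- function(traj, contact_cutoff = 4.5, retention_factor = 1.2,
                          compute_sasa = TRUE, compute_ss = TRUE,
                          sasa_points = 192) {
  s <- traj$reference
  at <- s$atoms
  hv <- which(at$elem != "H" & !at$het)
  ref <- coords(s)
  ca <- which(at$elety == "CA" & !at$het)
  L <- length(ca)
  if (L <= 15)
    stop_vuscope("TM-score undefined for %d residues (need > 15)", L,
                 class = "vuscope_undefined_error")
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  pairs <- native_contact_pairs(s, cutoff = contact_cutoff)
  flags <- atom_flags(s)
  rows <- lapply(seq_along(traj$frames), function(fi) {
    f <- traj$frames[[fi]]
    fit <- superpose(f, ref, selection = hv)
    xyz <- fit$coords
    ctr <- colMeans(xyz[hv, , drop = FALSE])
    rg <- sqrt(mean(rowSums(sweep(xyz[hv, , drop = FALSE], 2, ctr)^2))) / 10
    qf <- if (nrow(pairs) > 0) {
      d <- sqrt(rowSums((f[pairs$i, , drop = FALSE] -
                           f[pairs$j, , drop = FALSE])^2))
      mean(d <= retention_factor * pairs$ref_dist)
    } else NA_real_
    cafit <- superpose(f, ref, selection = ca)
    dca <- sqrt(rowSums((cafit$coords[ca, , drop = FALSE] -
                           ref[ca, , drop = FALSE])^2))
    tm <- mean(1 / (1 + (dca / d0)^2))
    sasa <- if (compute_sasa)
      sum(sasa_atoms(f[hv, , drop = FALSE], at$elem[hv],
                     n_points = sasa_points)) / 100
    else NA_real_
    ssf <- if (compute_ss) {
      stmp <- s; stmp$models <- list(f)
      tab <- table(factor(ss_assign(stmp), levels = c("alpha", "beta", "coil")))
      as.numeric(tab) / sum(tab)
    } else rep(NA_real_, 3)
    data.frame(frame = fi, rmsd = fit$rmsd, radius_of_gyration = rg,
               sasa = sasa, native_contact_fraction = qf,
               intra_hbonds = hbond_count(f, flags, at, partner = "intra"),
               protein_water_hbonds = hbond_count(f, flags, at,
                                                  partner = "water"),
               tm_score = tm, ss_alpha = ssf[1], ss_beta = ssf[2],
               ss_coil = ssf[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "global_stable") <- all(out$rmsd < 1.0)
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed on the reference C-alpha set; the RMSF of each
#' C-alpha about its mean position over frames is reported in nm.
#'
#' @param traj a [chk_trajectory()].
#' @return data.frame with `chain`, `resno`, `rmsf` (nm).
#' @export
rmsf <- function(traj) {
  if (length(traj$frames) < 2)
    stop_vuscope("RMSF undefined for a single frame",
                 class = "vuscope_undefined_error")
  at <- traj$reference$atoms
  ca <- which(at$elety == "CA" & !at$het)
  ref <- coords(traj$reference)
  fitted <- lapply(traj$frames, function(f)
    superpose(f, ref, selection = ca)$coords[ca, , drop = FALSE])
  arr <- simplify2array(fitted)           # n_ca x 3 x n_frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sapply(seq_len(dim(arr)[3]), function(k)
    rowSums((arr[, , k] - mean_pos)^2))
  data.frame(chain = at$chain[ca], resno = at$resno[ca],
             rmsf = sqrt(rowMeans(dev2)) / 10)
}

#' Residues within a radius of a site
#'
#' All residues with any heavy atom within `radius` (nm) of any heavy atom
#' of the site residue, in the reference frame; the site itself is always
#' included.
#'
#' @param reference a [chk_structure()].
#' @param site `c(chain, resno)`.
#' @param radius nm (default 1.0, i.e. 10 Angstrom).
#' @return data.frame with `chain` and `resno` of the selected residues.
#' @export
local_selection <- function(reference, site, radius = 1.0) {
  at <- reference$atoms
  ch <- as.character(site[[1]]); rn <- as.integer(site[[2]])
  si <- which(at$chain == ch & at$resno == rn & at$elem != "H")
  if (!length(si))
    stop_vuscope("site %s:%d absent from reference", ch, rn,
                 class = "vuscope_input_error")
  hv <- which(at$elem != "H" & !at$het)
  dm <- cross_dist(coords(reference)[hv, , drop = FALSE],
                   coords(reference)[si, , drop = FALSE])
  near <- hv[apply(dm <= radius * 10, 1, any)]
  keys <- unique(data.frame(chain = at$chain[near], resno = at$resno[near]))
  keys <- rbind(keys, data.frame(chain = ch, resno = rn))
  unique(keys[order(keys$chain, keys$resno), ])
}

#' Pairwise (2D) RMSD matrix over a local selection
#'
#' RMSD between every pair of (strided) frames on the selection's heavy
#' atoms, each pair superposed independently on that selection. The matrix
#' is symmetric with a zero diagonal; the original frame index of each row
#' is carried in the `"frames"` attribute.
#'
#' @param traj a [chk_trajectory()].
#' @param selection data.frame of `chain`/`resno` (from
#'   [local_selection()]); NULL means all residues.
#' @param stride frame stride; `NULL` picks the smallest stride keeping at
#'   most `max_frames` frames.
#' @param max_frames cap on strided frame count for the automatic stride.
#' @return Symmetric matrix of RMSD in nm, attribute `frames` = original
#'   1-based frame indices.
#' @export
rmsd_matrix <- function(traj, selection = NULL, stride = NULL,
                        max_frames = 150) {
  at <- traj$reference$atoms
  if (is.null(selection))
    selection <- unique(at[!at$het, c("chain", "resno")])
  if (nrow(selection) == 0)
    stop_vuscope("empty selection", class = "vuscope_input_error")
  idx <- which(paste(at$chain, at$resno) %in%
                 paste(selection$chain, selection$resno) & at$elem != "H")
  if (length(idx) < 3)
    stop_vuscope("selection has fewer than 3 heavy atoms",
                 class = "vuscope_input_error")
  n <- length(traj$frames)
  if (is.null(stride)) stride <- max(1L, ceiling(n / max_frames))
  fidx <- seq(1L, n, by = stride)
  centered <- lapply(fidx, function(i) {
    X <- traj$frames[[i]][idx, , drop = FALSE]
    sweep(X, 2, colMeans(X))
  })
  m <- length(fidx)
  out <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    out[i, j] <- out[j, i] <- kabsch_rmsd(centered[[i]], centered[[j]]) / 10
  }
  attr(out, "frames") <- fidx
  out
}

#' Cluster frames by neighbour counting (GROMOS style)
#'
#' Iteratively selects the frame with the most neighbours within `cutoff`
#' as a cluster medoid (ties broken by the lowest frame index), assigns
#' its whole neighbourhood to that cluster, removes it, and repeats.
#' Cluster ids are assigned in order of extraction. The basal cluster is
#' the one containing the first frame, even when it is not the most
#' populated: stability is anchored to the starting (crystal-like)
#' conformation.
#'
#' @param matrix pairwise RMSD matrix from [rmsd_matrix()] (nm).
#' @param cutoff neighbour cutoff, nm.
#' @return Object of class `cluster_assignment`: `cluster` (id per strided
#'   frame), `frames` (original frame indices), `medoids` (strided
#'   positions), `basal_cluster`, `cutoff`.
#' @export
cluster_frames <- function(matrix, cutoff = 0.15) {
  m <- nrow(matrix)
  fidx <- attr(matrix, "frames") %||% seq_len(m)
  assign <- rep(NA_integer_, m)
  medoids <- integer(0)
  remaining <- rep(TRUE, m)
  k <- 0L
  while (any(remaining)) {
    nb_count <- vapply(seq_len(m), function(i) {
      if (!remaining[i]) return(-1L)
      sum(matrix[i, ] <= cutoff & remaining)
    }, integer(1))
    k <- k + 1L
    med <- which.max(nb_count)          # first index on ties
    members <- which(remaining & matrix[med, ] <= cutoff)
    assign[members] <- k
    medoids[k] <- med
    remaining[members] <- FALSE
  }
  structure(list(cluster = assign, frames = fidx, medoids = medoids,
                 basal_cluster = assign[1], cutoff = cutoff),
            class = "cluster_assignment")
}

#' Stability verdict from a cluster timeline
#'
#' The trajectory is called unstable when the fraction of frames in the
#' final window (`window_fraction` of the frames) lying outside the basal
#' cluster reaches `outside_threshold`: point departures that return
#' immediately to the basal cluster stay stable; a sustained terminal
#' departure does not. The departure frame is the first frame of the
#' terminal run outside the basal cluster (NA when the trajectory ends in
#' the basal cluster).
#'
#' @param assignment a [cluster_frames()] result.
#' @param window_fraction final-window width as a fraction of frames.
#' @param outside_threshold outside-fraction at/above which the verdict is
#'   unstable.
#' @param replica_id,chain labels carried into the verdict.
#' @return Object of class `stability_verdict`: `replica_id`, `chain`,
#'   `verdict`, `departure_frame` (original frame index or NA),
#'   `final_outside_fraction`.
#' @export
stability_verdict <- function(assignment, window_fraction = 0.25,
                              outside_threshold = 0.5, replica_id = "r1",
                              chain = "all") {
  cl <- assignment$cluster
  n <- length(cl)
  if (n < 4)
    stop_vuscope("need at least 4 frames for a stability verdict",
                 class = "vuscope_input_error")
  w <- max(1L, ceiling(window_fraction * n))
  win <- cl[(n - w + 1):n]
  outside <- mean(win != assignment$basal_cluster)
  verdict <- if (outside >= outside_threshold) "unstable" else "stable"
  departure <- NA_integer_
  if (cl[n] != assignment$basal_cluster) {
    run_start <- n
    while (run_start > 1 && cl[run_start - 1] != assignment$basal_cluster)
      run_start <- run_start - 1
    departure <- assignment$frames[run_start]
  }
  structure(list(replica_id = replica_id, chain = chain, verdict = verdict,
                 departure_frame = departure,
                 final_outside_fraction = outside),
            class = "stability_verdict")
}

#' Dimer association state over the final window
#'
#' Counts inter-chain heavy-atom contact pairs (distance under
#' `contact_cutoff`) in each frame of the final window; the dimer is
#' unbound when the mean count falls below `min_contacts`. The state
#' depends only on the final window.
#'
#' @param traj a [chk_trajectory()] with at least two chains.
#' @param contact_cutoff contact distance, Angstrom.
#' @param min_contacts minimum mean contact count to stay bound.
#' @param window_fraction final-window width as a fraction of frames.
#' @return `"bound"` or `"unbound"`.
#' @export
dimer_state <- function(traj, contact_cutoff = 4.5, min_contacts = 10,
                        window_fraction = 0.25) {
  at <- traj$reference$atoms
  chains <- unique(at$chain[!at$het])
  if (length(chains) < 2)
    stop_vuscope("single chain: dimer state not applicable",
                 class = "vuscope_not_applicable_error")
  g1 <- which(at$chain == chains[1] & at$elem != "H" & !at$het)
  g2 <- which(at$chain != chains[1] & at$elem != "H" & !at$het)
  n <- length(traj$frames)
  w <- max(1L, ceiling(window_fraction * n))
  counts <- vapply((n - w + 1):n, function(i) {
    f <- traj$frames[[i]]
    sum(cross_dist(f[g1, , drop = FALSE], f[g2, , drop = FALSE]) <
          contact_cutoff)
  }, numeric(1))
  if (mean(counts) < min_contacts) "unbound" else "bound"
}

#' Aggregate per-replica stability verdicts
#'
#' Per-chain verdicts of one replica aggregate by worst case: a replica
#' counts unstable when any of its chains is unstable. The textual
#' fraction is formatted `"k/n (p%)"` with the percentage rounded half-up.
#'
#' @param verdicts list of [stability_verdict()] objects.
#' @param dimer_states optional named (by replica) or unnamed vector of
#'   `"bound"`/`"unbound"` states.
#' @return Object of class `replica_summary`: `n_stable`, `n_total`,
#'   `fraction_text`, `per_replica`, `dimer_states`.
#' @export
replica_summary <- function(verdicts, dimer_states = NULL) {
  if (!length(verdicts))
    stop_vuscope("no verdicts to summarize", class = "vuscope_input_error")
  reps <- vapply(verdicts, `[[`, character(1), "replica_id")
  per <- vapply(split(verdicts, reps), function(v)
    ifelse(any(vapply(v, `[[`, character(1), "verdict") == "unstable"),
           "unstable", "stable"), character(1))
  per <- per[unique(reps)]   # preserve first-appearance order
  k <- sum(per == "stable"); n <- length(per)
  structure(list(n_stable = k, n_total = n,
                 fraction_text = sprintf("%d/%d (%d%%)", k, n,
                                         as.integer(round_half_up(100 * k / n))),
                 per_replica = per, dimer_states = dimer_states),
            class = "replica_summary")
}

#' @export
print.replica_summary <- function(x, ...) {
  cat(sprintf("<replica_summary> stable in %s", x$fraction_text))
  if (!is.null(x$dimer_states))
    cat(sprintf("; dimer bound in %d/%d", sum(x$dimer_states == "bound"),
                length(x$dimer_states)))
  cat("\n")
  invisible(x)
}
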