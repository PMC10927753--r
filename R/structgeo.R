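# Static interaction geometry: hydrogen bonds, salt bridges, cation-pi
# interactions, inter-chain proximity, solvent exposure and substitution
# clash screening. Distance cutoffs follow common structural-biology
# practice and are exposed as arguments. Crystal structures usually lack
# hydrogens, so the default H-bond test is distance-only; the donor-H-
# acceptor angle test activates only when hydrogens are present.

# Heavy-atom donor/acceptor typing. Backbone N donates (except proline),
# backbone O accepts; hydroxyls donate and accept; water does both.
DONOR_SIDE <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"), ASN = "ND2", GLN = "NE2",
                   TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH",
                   HOH = "O", WAT = "O")
ACCEPTOR_SIDE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                      ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                      TYR = "OH", HIS = c("ND1", "NE2"),
                      HOH = "O", WAT = "O")
CATION_GROUPS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
ANION_GROUPS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
RING_ATOMS <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                   HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# Mean amino acid residue volumes (A^3), Zamyatnin-style tabulation, used
# as a side-chain bulk proxy for substitution screening.
RESIDUE_VOLUME <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1,
                    CYS = 108.5, GLN = 143.8, GLU = 138.4, GLY = 60.1,
                    HIS = 153.2, ILE = 166.7, LEU = 166.7, LYS = 168.6,
                    MET = 162.9, PHE = 189.9, PRO = 112.7, SER = 89.0,
                    THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

atom_flags <- function(s) {
  at <- s$atoms
  is_donor <- (at$elety == "N" & at$resid != "PRO" & !at$het)
  is_acceptor <- (at$elety %in% c("O", "OXT") & !at$het)
  for (r in names(DONOR_SIDE))
    is_donor <- is_donor | (at$resid == r & at$elety %in% DONOR_SIDE[[r]])
  for (r in names(ACCEPTOR_SIDE))
    is_acceptor <- is_acceptor | (at$resid == r & at$elety %in% ACCEPTOR_SIDE[[r]])
  list(donor = which(is_donor), acceptor = which(is_acceptor))
}

interaction_record <- function(kind, at, i, j, distance, angle = NA_real_) {
  data.frame(kind = rep(kind, length(i)),
             chain_a = at$chain[i], resno_a = at$resno[i],
             resid_a = at$resid[i], atom_a = at$elety[i],
             chain_b = at$chain[j], resno_b = at$resno[j],
             resid_b = at$resid[j], atom_b = at$elety[j],
             distance = distance, angle = rep(angle, length.out = length(i)),
             interchain = at$chain[i] != at$chain[j])
}

#' Detect hydrogen bonds
#'
#' Reports every donor/acceptor heavy-atom pair (N/O typing table) from
#' distinct residues within `d_max`. Pairs of backbone atoms from
#' sequence-adjacent residues of the same chain are excluded (covalent
#' geometry, not H-bonds). When the structure contains hydrogens and
#' `require_h` is TRUE, a donor-H...acceptor angle of at least `angle_min`
#' (for some H within 1.2 A of the donor) is additionally required, and
#' the realized angle is reported.
#'
#' @param s a [chk_structure()].
#' @param d_max donor-acceptor distance cutoff, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees.
#' @param require_h enforce the angle criterion when hydrogens exist?
#' @return data.frame of interaction records sorted by distance.
#' @export
find_hbonds <- function(s, d_max = 3.5, angle_min = 120, require_h = FALSE) {
  at <- s$atoms
  xyz <- coords(s)
  fl <- atom_flags(s)
  empty <- interaction_record("hbond", at, integer(0), integer(0), numeric(0))
  if (!length(fl$donor) || !length(fl$acceptor)) return(empty)
  dm <- cross_dist(xyz[fl$donor, , drop = FALSE],
                   xyz[fl$acceptor, , drop = FALSE])
  hit <- which(dm <= d_max, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- fl$donor[hit[, 1]]; ai <- fl$acceptor[hit[, 2]]
  same_res <- at$chain[di] == at$chain[ai] & at$resno[di] == at$resno[ai]
  adj_bb <- at$chain[di] == at$chain[ai] &
    abs(at$resno[di] - at$resno[ai]) == 1 &
    at$elety[di] %in% BACKBONE_ATOMS & at$elety[ai] %in% BACKBONE_ATOMS
  keep <- !same_res & !adj_bb
  di <- di[keep]; ai <- ai[keep]
  ang <- rep(NA_real_, length(di))
  hydrogens <- which(at$elem == "H")
  if (require_h && length(hydrogens)) {
    ok <- logical(length(di))
    for (k in seq_along(di)) {
      hd <- cross_dist(xyz[hydrogens, , drop = FALSE],
                       xyz[di[k], , drop = FALSE])
      hs <- hydrogens[hd[, 1] <= 1.2]
      if (!length(hs)) next
      angs <- vapply(hs, function(h) {
        v1 <- xyz[di[k], ] - xyz[h, ]; v2 <- xyz[ai[k], ] - xyz[h, ]
        acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
      }, numeric(1))
      if (max(angs) >= angle_min) { ok[k] <- TRUE; ang[k] <- max(angs) }
    }
    di <- di[ok]; ai <- ai[ok]; ang <- ang[ok]
  }
  if (!length(di)) return(empty)
  d <- sqrt(rowSums((xyz[di, , drop = FALSE] - xyz[ai, , drop = FALSE])^2))
  rec <- interaction_record("hbond", at, di, ai, d, ang)
  rec[order(rec$distance), ]
}

#' Detect salt bridges
#'
#' A salt bridge is recorded when the minimum nitrogen-oxygen distance
#' between a cationic side-chain group (Arg NE/NH1/NH2, Lys NZ, His
#' ND1/NE2) and an anionic one (Asp OD1/OD2, Glu OE1/OE2) is at most
#' `d_max`. One record per residue pair, at the minimal N-O distance;
#' `interchain` marks cross-chain bridges.
#'
#' @param s a [chk_structure()].
#' @param d_max N-O distance cutoff, Angstrom.
#' @return data.frame of interaction records.
#' @export
find_salt_bridges <- function(s, d_max = 4.0) {
  at <- s$atoms
  xyz <- coords(s)
  cat_i <- which(!at$het &
    mapply(function(r, a) r %in% names(CATION_GROUPS) &&
             a %in% CATION_GROUPS[[r]], at$resid, at$elety))
  an_i <- which(!at$het &
    mapply(function(r, a) r %in% names(ANION_GROUPS) &&
             a %in% ANION_GROUPS[[r]], at$resid, at$elety))
  empty <- interaction_record("salt_bridge", at, integer(0), integer(0),
                              numeric(0))
  if (!length(cat_i) || !length(an_i)) return(empty)
  dm <- cross_dist(xyz[cat_i, , drop = FALSE], xyz[an_i, , drop = FALSE])
  hit <- which(dm <= d_max, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  recs <- interaction_record("salt_bridge", at, cat_i[hit[, 1]],
                             an_i[hit[, 2]], dm[hit])
  pair <- paste(recs$chain_a, recs$resno_a, recs$chain_b, recs$resno_b)
  recs <- recs[order(pair, recs$distance), ]
  recs <- recs[!duplicated(paste(recs$chain_a, recs$resno_a,
                                 recs$chain_b, recs$resno_b)), ]
  recs[order(recs$distance), ]
}

ring_geometry <- function(at, xyz, i_set) {
  ctr <- colMeans(xyz[i_set, , drop = FALSE])
  sv <- svd(sweep(xyz[i_set, , drop = FALSE], 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

#' Detect cation-pi interactions
#'
#' A cation-pi interaction is recorded when a cationic group (Arg
#' guanidinium centroid, Lys NZ, optionally the His ring centroid treated
#' as a cation) sits within `d_max` of an aromatic ring centroid
#' (Phe/Tyr/Trp/His) with the angle between the ring normal and the
#' centroid-to-cation vector at most `angle_max` (i.e. above the ring
#' face, not in its plane).
#'
#' @param s a [chk_structure()].
#' @param d_max cation-to-ring-centroid cutoff, Angstrom.
#' @param angle_max maximal normal/vector angle, degrees.
#' @param his_as_cation treat His as a potential cation?
#' @return data.frame of interaction records (atom fields name the group's
#'   representative atom/residue).
#' @export
find_cation_pi <- function(s, d_max = 6.0, angle_max = 60,
                           his_as_cation = TRUE) {
  at <- s$atoms
  xyz <- coords(s)
  res <- unique(at[!at$het, c("chain", "resno", "resid")])
  cations <- list(); rings <- list()
  for (k in seq_len(nrow(res))) {
    sel <- which(at$chain == res$chain[k] & at$resno == res$resno[k])
    r <- res$resid[k]
    if (r == "ARG") {
      g <- sel[at$elety[sel] %in% c("CZ", "NE", "NH1", "NH2")]
      if (length(g) >= 3)
        cations[[length(cations) + 1]] <-
          list(row = k, pos = colMeans(xyz[g, , drop = FALSE]), atom = "CZ")
    } else if (r == "LYS") {
      g <- sel[at$elety[sel] == "NZ"]
      if (length(g) == 1)
        cations[[length(cations) + 1]] <- list(row = k, pos = xyz[g, ],
                                               atom = "NZ")
    }
    if (r %in% names(RING_ATOMS)) {
      g <- sel[at$elety[sel] %in% RING_ATOMS[[r]]]
      if (length(g) == length(RING_ATOMS[[r]])) {
        geom <- ring_geometry(at, xyz, g)
        rings[[length(rings) + 1]] <- list(row = k, geom = geom)
        if (r == "HIS" && his_as_cation)
          cations[[length(cations) + 1]] <-
            list(row = k, pos = geom$center, atom = "ring")
      }
    }
  }
  out <- list()
  for (ca in cations) for (ri in rings) {
    if (ca$row == ri$row) next
    v <- ca$pos - ri$geom$center
    d <- vnorm(v)
    if (d > d_max) next
    ang <- acos(max(-1, min(1, abs(sum(unit(v) * ri$geom$normal))))) * 180 / pi
    if (ang > angle_max) next
    a <- res[ca$row, ]; b <- res[ri$row, ]
    out[[length(out) + 1]] <- data.frame(kind = "cation_pi",
      chain_a = a$chain, resno_a = a$resno, resid_a = a$resid, atom_a = ca$atom,
      chain_b = b$chain, resno_b = b$resno, resid_b = b$resid, atom_b = "ring",
      distance = d, angle = ang, interchain = a$chain != b$chain)
  }
  if (!length(out))
    return(data.frame(kind = character(0), chain_a = character(0),
                      resno_a = integer(0), resid_a = character(0),
                      atom_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      atom_b = character(0), distance = numeric(0),
                      angle = numeric(0), interchain = logical(0)))
  recs <- do.call(rbind, out)
  recs[order(recs$distance), ]
}

#' Minimum heavy-atom distance from a residue to any other chain
#'
#' @param s a [chk_structure()] with at least two chains.
#' @param residue `c(chain, resno)` pair.
#' @return Minimum distance in Angstrom.
#' @export
min_interchain_distance <- function(s, residue) {
  at <- s$atoms
  if (length(unique(at$chain[!at$het])) < 2)
    stop_vuscope("single-chain structure: inter-chain distance not applicable",
                 class = "vuscope_not_applicable_error")
  ch <- as.character(residue[[1]]); rn <- as.integer(residue[[2]])
  sel <- which(at$chain == ch & at$resno == rn & at$elem != "H")
  if (!length(sel))
    stop_vuscope("residue %s:%d not found", ch, rn,
                 class = "vuscope_input_error")
  other <- which(at$chain != ch & at$elem != "H" & !at$het)
  min(cross_dist(coords(s)[sel, , drop = FALSE],
                 coords(s)[other, , drop = FALSE]))
}

# Deterministic quasi-uniform sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by counting sphere points on each atom's solvent-expanded
#' surface not buried inside any neighbouring atom's expanded sphere.
#'
#' @param xyz n x 3 heavy-atom coordinate matrix, Angstrom.
#' @param elements element symbols per atom (C/N/O/S/P).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere points per atom (at least 192).
#' @return Numeric vector of per-atom areas, Angstrom^2.
#' @export
sasa_atoms <- function(xyz, elements, probe = 1.4, n_points = 960) {
  stopifnot(n_points >= 192)
  n <- nrow(xyz)
  radii <- VDW_RADIUS[elements]
  radii[is.na(radii)] <- 1.70
  radii <- radii + probe
  pts <- sphere_points(n_points)
  dm <- cross_dist(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < radii[i] + radii & seq_len(n) != i)
    sp <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      d2 <- cross_dist(sp, xyz[nb, , drop = FALSE])
      buried <- rowSums(d2 < rep(radii[nb], each = nrow(d2))) > 0
      frac <- mean(!buried)
    } else frac <- 1
    out[i] <- 4 * pi * radii[i]^2 * frac
  }
  out
}

sidechain_sel <- function(at, ch, rn) {
  sel <- which(at$chain == ch & at$resno == rn & at$elem != "H")
  sc <- sel[!at$elety[sel] %in% BACKBONE_ATOMS]
  if (!length(sc)) sc <- sel[at$elety[sel] == "CA"]   # glycine: CA proxy
  list(residue = sel, sidechain = sc)
}

#' Relative solvent exposure of a residue side chain
#'
#' Side-chain SASA in the full structure divided by the side-chain SASA of
#' the same residue isolated (own atoms only, same probe and sphere
#' discretization), so a fully isolated residue scores 1 by construction
#' and a fully occluded one 0. Classified exposed at or above
#' `exposed_min`, buried below `buried_max`, intermediate otherwise.
#'
#' @param s a [chk_structure()].
#' @param residue `c(chain, resno)`.
#' @param probe probe radius, Angstrom.
#' @param n_points sphere points per atom.
#' @param exposed_min,buried_max classification cutoffs on the ratio.
#' @return List with `ratio`, `sasa`, `sasa_max`, `class`.
#' @export
relative_exposure <- function(s, residue, probe = 1.4, n_points = 960,
                              exposed_min = 0.25, buried_max = 0.10) {
  at <- s$atoms
  ch <- as.character(residue[[1]]); rn <- as.integer(residue[[2]])
  sel <- sidechain_sel(at, ch, rn)
  if (!length(sel$residue))
    stop_vuscope("residue %s:%d not found", ch, rn,
                 class = "vuscope_input_error")
  if (!all(at$resid[sel$residue][1] %in% names(RESIDUE_VOLUME)))
    stop_vuscope("unknown residue type %s", at$resid[sel$residue][1],
                 class = "vuscope_typing_error")
  hv <- which(at$elem != "H")
  a_all <- sasa_atoms(coords(s)[hv, , drop = FALSE], at$elem[hv],
                      probe = probe, n_points = n_points)
  sasa <- sum(a_all[match(sel$sidechain, hv)])
  iso <- sasa_atoms(coords(s)[sel$residue, , drop = FALSE],
                    at$elem[sel$residue], probe = probe, n_points = n_points)
  sasa_max <- sum(iso[match(sel$sidechain, sel$residue)])
  ratio <- if (sasa_max > 0) sasa / sasa_max else 0
  cls <- if (ratio >= exposed_min) "exposed"
         else if (ratio < buried_max) "buried" else "intermediate"
  list(ratio = ratio, sasa = sasa, sasa_max = sasa_max, class = cls)
}

#' Screen an amino acid substitution for potential steric clash
#'
#' Volume-and-density proxy: the change in tabulated mean residue volume
#' (`delta_volume`, new minus old) together with the heavy-atom crowding
#' around the current side-chain centroid (`neighbor_count` within
#' `radius`, excluding the residue's own atoms). A substitution is flagged
#' `potential_clash` when it grows (`delta_volume > 0`) into a dense
#' environment (`neighbor_count >= density_threshold`). The report carries
#' the raw numbers; it is not a pathogenicity verdict.
#'
#' @param s a [chk_structure()].
#' @param residue `c(chain, resno)`.
#' @param new_residue_name three-letter code of the replacement.
#' @param radius neighbourhood radius, Angstrom.
#' @param density_threshold neighbour count at/above which a growing
#'   substitution is flagged.
#' @return List with `old_residue`, `new_residue`, `delta_volume`,
#'   `neighbor_count`, `potential_clash`.
#' @export
substitution_clash_screen <- function(s, residue, new_residue_name,
                                      radius = 5, density_threshold = 30) {
  at <- s$atoms
  ch <- as.character(residue[[1]]); rn <- as.integer(residue[[2]])
  new_residue_name <- toupper(new_residue_name)
  if (!new_residue_name %in% names(RESIDUE_VOLUME))
    stop_vuscope("unknown residue name %s", new_residue_name,
                 class = "vuscope_typing_error")
  sel <- sidechain_sel(at, ch, rn)
  if (!length(sel$residue))
    stop_vuscope("residue %s:%d not found", ch, rn,
                 class = "vuscope_input_error")
  old <- at$resid[sel$residue][1]
  ctr <- colMeans(coords(s)[sel$sidechain, , drop = FALSE])
  others <- setdiff(which(at$elem != "H"), sel$residue)
  nb <- sum(cross_dist(matrix(ctr, 1), coords(s)[others, , drop = FALSE])
            <= radius)
  dv <- RESIDUE_VOLUME[[new_residue_name]] - RESIDUE_VOLUME[[old]]
  list(old_residue = old, new_residue = new_residue_name,
       delta_volume = dv, neighbor_count = nb,
       potential_clash = dv > 0 && nb >= density_threshold)
}
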