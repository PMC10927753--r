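# Atomic structure container and PDB I/O (bio3d-backed), plus backbone
# dihedral and coarse secondary-structure utilities shared by the static
# geometry and trajectory modules. Coordinates are Angstrom throughout.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure object
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elem` (element), `het` (logical), `x`, `y`, `z`.
#' @param models optional list of additional coordinate matrices
#'   (n_atoms x 3); model 1 is always the `x/y/z` in `atoms`.
#' @return Object of class `chk_structure`.
#' @export
chk_structure <- function(atoms, models = NULL) {
  req <- c("chain", "resno", "resid", "elety", "elem", "het", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_vuscope("non-finite coordinates", class = "vuscope_format_error")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop_vuscope("duplicate (chain, residue, atom) records",
                 class = "vuscope_format_error")
  if (is.null(models))
    models <- list(as.matrix(atoms[, c("x", "y", "z")]))
  structure(list(atoms = atoms, models = models), class = "chk_structure")
}

#' @export
print.chk_structure <- function(x, ...) {
  cat(sprintf("<chk_structure> %d atoms, %d residue(s), chains: %s, %d model(s)\n",
              nrow(x$atoms), nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ","),
              length(x$models)))
  invisible(x)
}

#' Coordinates of one model
#'
#' @param s a [chk_structure()].
#' @param model model index (default 1).
#' @return n_atoms x 3 matrix, Angstrom.
#' @export
coords <- function(s, model = 1) {
  m <- s$models[[model]]
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

infer_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  first <- substr(e, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

#' Read a PDB file
#'
#' Reads ATOM and HETATM records through [bio3d::read.pdb()]. Alternate
#' locations are resolved to the highest-occupancy conformer (ties: first
#' in file). Waters and other heteroatoms are retained and tagged via the
#' `het` column. Multi-model files become additional coordinate models.
#'
#' @param path PDB file.
#' @return A [chk_structure()].
#' @export
parse_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0)
    stop_vuscope("no ATOM/HETATM records in %s", path,
                 class = "vuscope_format_error")
  keep <- rep(TRUE, nrow(at))
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    grp <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      best <- idx[which.max(occ[idx])]   # which.max: first on ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cidx <- rep(which(keep), each = 3) * 3 - c(2, 1, 0)
  xyz <- xyz[, as.vector(matrix(cidx, nrow = 3)), drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(chain = chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, elem = elem,
                      het = at$type == "HETATM",
                      x = xyz[1, seq(1, ncol(xyz), 3)],
                      y = xyz[1, seq(2, ncol(xyz), 3)],
                      z = xyz[1, seq(3, ncol(xyz), 3)])
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  chk_structure(atoms, models)
}

#' Write a structure (or trajectory frames) as PDB
#'
#' Delegates to [bio3d::write.pdb()]; multiple models produce a multi-model
#' PDB with MODEL/ENDMDL blocks.
#'
#' @param s a [chk_structure()].
#' @param path output file.
#' @param models which models to write (default all).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, models = seq_along(s$models)) {
  xyz <- do.call(rbind, lapply(s$models[models], function(m) as.vector(t(m))))
  at <- s$atoms
  bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)), elesy = at$elem)
  invisible(path)
}

#' Apply a rigid transform to every model
#'
#' @param s a [chk_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, Angstrom.
#' @return Transformed [chk_structure()].
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  s$models <- lapply(s$models, function(m)
    sweep(m %*% t(rotation), 2, -translation))
  s$atoms[, c("x", "y", "z")] <- s$models[[1]]
  s
}

heavy_idx <- function(s) which(s$atoms$elem != "H")

residue_keys <- function(s) paste(s$atoms$chain, s$atoms$resno)

# Torsion angle (degrees) for points p1-p2-p3-p4.
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedral angles
#'
#' @param s a [chk_structure()].
#' @param model model index.
#' @return data.frame with `chain`, `resno`, `phi`, `psi` (degrees; NA at
#'   chain termini).
#' @export
backbone_dihedrals <- function(s, model = 1) {
  at <- s$atoms[!s$atoms$het, ]
  xyz <- coords(s, model)[!s$atoms$het, , drop = FALSE]
  out <- list()
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    resnos <- sort(unique(at$resno[sel]))
    get <- function(rn, name) {
      i <- which(sel & at$resno == rn & at$elety == name)
      if (length(i) != 1) return(NULL)
      xyz[i, ]
    }
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
      phi <- psi <- NA_real_
      if (!is.null(N) && !is.null(CA) && !is.null(C)) {
        if (k > 1) {
          Cprev <- get(resnos[k - 1], "C")
          if (!is.null(Cprev)) phi <- torsion(Cprev, N, CA, C)
        }
        if (k < length(resnos)) {
          Nnext <- get(resnos[k + 1], "N")
          if (!is.null(Nnext)) psi <- torsion(N, CA, C, Nnext)
        }
      }
      out[[length(out) + 1]] <- data.frame(chain = ch, resno = rn,
                                           phi = phi, psi = psi)
    }
  }
  do.call(rbind, out)
}

#' Coarse secondary structure from dihedral bins
#'
#' Alpha: phi in `[-100,-30]` and psi in `[-80,-5]`. Beta: phi in
#' `[-180,-40]` and psi in `[60,180]`. Everything else (including termini
#' with undefined dihedrals) is coil.
#'
#' @param s a [chk_structure()].
#' @param model model index.
#' @return Character vector (`"alpha"`, `"beta"`, `"coil"`) per residue.
#' @export
ss_assign <- function(s, model = 1) {
  d <- backbone_dihedrals(s, model)
  ifelse(!is.na(d$phi) & !is.na(d$psi) &
           d$phi >= -100 & d$phi <= -30 & d$psi >= -80 & d$psi <= -5, "alpha",
  ifelse(!is.na(d$phi) & !is.na(d$psi) &
           d$phi >= -180 & d$phi <= -40 & d$psi >= 60 & d$psi <= 180, "beta",
         "coil"))
}
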