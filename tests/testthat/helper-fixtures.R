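# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive double loops with their own typing tables so they do
# not share code paths with the package's vectorized detectors.

table2_path <- function() system.file("extdata", "table2.tsv",
                                      package = "vuscope")
table1_path <- function() system.file("extdata", "table1.tsv",
                                      package = "vuscope")

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

# Random multi-residue fixture with typed side-chain atoms spread in a box.
# Residues are internally compact clusters so the typed groups are intact.
random_geometry_fixture <- function(n_res = 50, seed = 1, n_chains = 2,
                                    box = 35) {
  side <- list(
    ARG = list(c("CZ", "C"), c("NE", "N"), c("NH1", "N"), c("NH2", "N")),
    LYS = list(c("NZ", "N")),
    ASP = list(c("OD1", "O"), c("OD2", "O")),
    GLU = list(c("OE1", "O"), c("OE2", "O")),
    SER = list(c("OG", "O")),
    THR = list(c("OG1", "O")),
    TYR = list(c("CG", "C"), c("CD1", "C"), c("CD2", "C"), c("CE1", "C"),
               c("CE2", "C"), c("CZ", "C"), c("OH", "O")),
    PHE = list(c("CG", "C"), c("CD1", "C"), c("CD2", "C"), c("CE1", "C"),
               c("CE2", "C"), c("CZ", "C")),
    HIS = list(c("CG", "C"), c("ND1", "N"), c("CD2", "C"), c("CE1", "C"),
               c("NE2", "N")),
    ALA = list(c("CB", "C")))
  ring_res <- c("TYR", "PHE", "HIS")
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_res)) {
      rid <- sample(names(side), 1)
      ctr <- runif(3, 0, box)
      ch <- LETTERS[sample.int(n_chains, 1)]
      add <- function(ety, el, p)
        rows[[length(rows) + 1]] <<- data.frame(chain = ch, resno = i,
                                                resid = rid, elety = ety,
                                                elem = el, het = FALSE,
                                                x = p[1], y = p[2], z = p[3])
      add("N", "N", ctr + c(-1.2, 0.8, 0))
      add("CA", "C", ctr + c(0, 1.4, 0.2))
      add("C", "C", ctr + c(1.2, 0.7, -0.2))
      add("O", "O", ctr + c(1.4, -0.5, -0.3))
      if (rid %in% ring_res) {
        # keep the ring planar so ring geometry is well defined
        th <- seq(0, 2 * pi, length.out = 7)[-7]
        ring <- cbind(1.3 * cos(th), 1.3 * sin(th), 0)
        R <- random_rotation(seed * 1000 + i)
        ring <- sweep(ring %*% R, 2, ctr + c(-0.5, -1.2, 0.6), "+")
        nm <- side[[rid]]
        for (k in seq_len(min(length(nm), 6)))
          add(nm[[k]][1], nm[[k]][2], ring[k, ])
        if (rid == "TYR") add("OH", "O", ctr + c(-0.5, -3.2, 0.9))
      } else {
        for (k in seq_along(side[[rid]]))
          add(side[[rid]][[k]][1], side[[rid]][[k]][2],
              ctr + c(-0.8, -1.0, 0) + 0.9 * k * c(-0.4, -0.5, 0.3))
      }
    }
    chk_structure(do.call(rbind, rows))
  })
}

dist3 <- function(p, q) sqrt(sum((p - q)^2))

# O(n^2) H-bond oracle: every donor/acceptor heavy-atom pair from distinct
# residues within d_max, skipping adjacent-residue backbone pairs.
oracle_hbonds <- function(s, d_max = 3.5) {
  at <- s$atoms
  xyz <- coords(s)
  donors <- c("N", "NE", "NH1", "NH2", "NZ", "ND1", "NE2", "ND2", "NE1",
              "OG", "OG1", "OH")
  donor_ok <- function(k) {
    if (at$elety[k] == "N") return(at$resid[k] != "PRO" && !at$het[k])
    if (at$resid[k] %in% c("HOH", "WAT")) return(at$elety[k] == "O")
    paste(at$resid[k], at$elety[k]) %in%
      c("ARG NE", "ARG NH1", "ARG NH2", "LYS NZ", "HIS ND1", "HIS NE2",
        "ASN ND2", "GLN NE2", "TRP NE1", "SER OG", "THR OG1", "TYR OH")
  }
  acceptor_ok <- function(k) {
    if (at$elety[k] %in% c("O", "OXT")) return(TRUE)
    paste(at$resid[k], at$elety[k]) %in%
      c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2", "ASN OD1", "GLN OE1",
        "SER OG", "THR OG1", "TYR OH", "HIS ND1", "HIS NE2")
  }
  bb <- c("N", "CA", "C", "O", "OXT")
  out <- 0L
  pairs <- character(0)
  for (i in seq_len(nrow(at))) for (j in seq_len(nrow(at))) {
    if (!donor_ok(i) || !acceptor_ok(j)) next
    if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
    if (at$chain[i] == at$chain[j] && abs(at$resno[i] - at$resno[j]) == 1 &&
        at$elety[i] %in% bb && at$elety[j] %in% bb) next
    if (dist3(xyz[i, ], xyz[j, ]) <= d_max) {
      out <- out + 1L
      pairs <- c(pairs, paste(at$chain[i], at$resno[i], at$elety[i], "->",
                              at$chain[j], at$resno[j], at$elety[j]))
    }
  }
  sort(pairs)
}

oracle_salt_bridges <- function(s, d_max = 4.0) {
  at <- s$atoms
  xyz <- coords(s)
  cat_tab <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"))
  an_tab <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  res <- unique(at[, c("chain", "resno", "resid")])
  pairs <- character(0)
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    ri <- res$resid[i]; rj <- res$resid[j]
    if (!ri %in% names(cat_tab) || !rj %in% names(an_tab)) next
    ai <- which(at$chain == res$chain[i] & at$resno == res$resno[i] &
                  at$elety %in% cat_tab[[ri]])
    aj <- which(at$chain == res$chain[j] & at$resno == res$resno[j] &
                  at$elety %in% an_tab[[rj]])
    if (!length(ai) || !length(aj)) next
    dmin <- min(apply(expand.grid(ai, aj), 1, function(p)
      dist3(xyz[p[1], ], xyz[p[2], ])))
    if (dmin <= d_max)
      pairs <- c(pairs, paste(res$chain[i], res$resno[i], "->",
                              res$chain[j], res$resno[j]))
  }
  sort(pairs)
}

oracle_cation_pi <- function(s, d_max = 6.0, angle_max = 60) {
  at <- s$atoms
  xyz <- coords(s)
  rings <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  res <- unique(at[, c("chain", "resno", "resid")])
  get_ring <- function(k) {
    r <- res$resid[k]
    if (!r %in% names(rings)) return(NULL)
    idx <- which(at$chain == res$chain[k] & at$resno == res$resno[k] &
                   at$elety %in% rings[[r]])
    if (length(idx) != length(rings[[r]])) return(NULL)
    pts <- xyz[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    list(center = ctr, normal = sv$v[, 3])
  }
  get_cation <- function(k) {
    r <- res$resid[k]
    idx <- which(at$chain == res$chain[k] & at$resno == res$resno[k])
    if (r == "ARG") {
      g <- idx[at$elety[idx] %in% c("CZ", "NE", "NH1", "NH2")]
      if (length(g) >= 3) return(colMeans(xyz[g, , drop = FALSE]))
    }
    if (r == "LYS") {
      g <- idx[at$elety[idx] == "NZ"]
      if (length(g) == 1) return(xyz[g, ])
    }
    if (r == "HIS") {
      ring <- get_ring(k)
      if (!is.null(ring)) return(ring$center)
    }
    NULL
  }
  pairs <- character(0)
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    if (i == j) next
    cp <- get_cation(i); rg <- get_ring(j)
    if (is.null(cp) || is.null(rg)) next
    v <- cp - rg$center
    d <- sqrt(sum(v^2))
    if (d > d_max) next
    cosang <- abs(sum(v / d * rg$normal))
    if (acos(min(1, cosang)) * 180 / pi > angle_max) next
    pairs <- c(pairs, paste(res$chain[i], res$resno[i], "->",
                            res$chain[j], res$resno[j]))
  }
  sort(pairs)
}

oracle_min_interchain <- function(s, residue) {
  at <- s$atoms
  xyz <- coords(s)
  sel <- which(at$chain == residue[1] & at$resno == as.integer(residue[2]) &
                 at$elem != "H")
  other <- which(at$chain != residue[1] & at$elem != "H" & !at$het)
  best <- Inf
  for (i in sel) for (j in other)
    best <- min(best, dist3(xyz[i, ], xyz[j, ]))
  best
}

record_keys <- function(rec) {
  if (nrow(rec) == 0) return(character(0))
  sort(paste(rec$chain_a, rec$resno_a, "->", rec$chain_b, rec$resno_b))
}
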