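# Synthetic-data generator: a toy component dictionary built from ideal
# geometry (tetrahedral 109.47 deg, trigonal 120 deg, canonical bond
# lengths) and synthetic structure entries assembled from perturbable
# copies of those definitions. Everything is deterministic given the seed.

.TET <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# canonical fixture bond lengths (Angstrom)
.L <- list(CC = 1.53, CC_AR = 1.38, CN = 1.46, CN_AMIDE = 1.45,
           CO = 1.43, CO_ACID = 1.40, CO_DBL = 1.23, CS = 1.80,
           SO = 1.66, SO_DBL = 1.44,
           # pyranose ring/anomeric bonds are built slightly long so that
           # sp2-flattening of the anomeric carbon (which shortens its
           # bonds geometrically) cannot push any of them across an
           # order-classification midpoint
           CC_RING = 1.55, CO_ANOMER = 1.46)

# -- tiny molecule-builder DSL ----------------------------------------------

mol_new <- function() {
  list(pos = list(),
       atoms = data.frame(atom_id = character(), element = character(),
                          charge = integer(), aromatic = logical(),
                          stereo = character(), leaving = logical(),
                          stringsAsFactors = FALSE),
       bonds = data.frame(atom_1 = character(), atom_2 = character(),
                          order = character(), aromatic = logical(),
                          stringsAsFactors = FALSE))
}

mol_atom <- function(m, id, element, pos, stereo = "N", aromatic = FALSE,
                     leaving = FALSE, charge = 0L) {
  m$pos[[id]] <- as.numeric(pos)
  m$atoms <- rbind(m$atoms, data.frame(
    atom_id = id, element = element, charge = as.integer(charge),
    aromatic = aromatic, stereo = stereo, leaving = leaving,
    stringsAsFactors = FALSE))
  m
}

mol_bond <- function(m, a1, a2, order = "single", aromatic = FALSE) {
  m$bonds <- rbind(m$bonds, data.frame(atom_1 = a1, atom_2 = a2,
                                       order = order, aromatic = aromatic,
                                       stringsAsFactors = FALSE))
  m
}

mol_def <- function(comp_id, name, m) {
  a <- m$atoms
  p <- do.call(rbind, m$pos[a$atom_id])
  a$x <- p[, 1]; a$y <- p[, 2]; a$z <- p[, 3]
  component_definition(comp_id, name, a, m$bonds)
}

mp <- function(m, id) m$pos[[id]]

# -- amino-acid and small-molecule templates --------------------------------

build_gly <- function() {
  m <- mol_new()
  ca <- c(0, 0, 0)
  nn <- ca + .L$CN * .TET[1, ]
  cc <- ca + .L$CC * .TET[2, ]
  dd <- trig_dirs1(unitv(ca - cc), ref = unitv(nn - ca))
  m <- mol_atom(m, "N", "N", nn)
  m <- mol_atom(m, "CA", "C", ca)
  m <- mol_atom(m, "C", "C", cc)
  m <- mol_atom(m, "O", "O", cc + .L$CO_DBL * dd[[1]])
  m <- mol_atom(m, "OXT", "O", cc + .L$CO_ACID * dd[[2]], leaving = TRUE)
  m <- mol_bond(m, "N", "CA")
  m <- mol_bond(m, "CA", "C")
  m <- mol_bond(m, "C", "O", "double")
  m <- mol_bond(m, "C", "OXT")
  m
}

build_ala <- function() {
  m <- build_gly()
  m <- mol_atom(m, "CB", "C", mp(m, "CA") + .L$CC * .TET[3, ])
  m <- mol_bond(m, "CA", "CB")
  m$atoms$stereo[m$atoms$atom_id == "CA"] <- "S"
  m
}

build_asn <- function() {
  m <- build_gly()
  cb <- mp(m, "CA") + .L$CC * .TET[3, ]
  cg <- nerf_place(mp(m, "N"), mp(m, "CA"), cb, 1.50)
  dd <- trig_dirs1(unitv(cb - cg), ref = unitv(mp(m, "CA") - cb))
  m <- mol_atom(m, "CB", "C", cb)
  m <- mol_atom(m, "CG", "C", cg)
  m <- mol_atom(m, "OD1", "O", cg + .L$CO_DBL * dd[[1]])
  m <- mol_atom(m, "ND2", "N", cg + .L$CN_AMIDE * dd[[2]])
  m <- mol_bond(m, "CA", "CB")
  m <- mol_bond(m, "CB", "CG")
  m <- mol_bond(m, "CG", "OD1", "double")
  m <- mol_bond(m, "CG", "ND2")
  m$atoms$stereo[m$atoms$atom_id == "CA"] <- "S"
  m
}

build_lys <- function() {
  m <- build_ala()
  cg <- nerf_place(mp(m, "N"), mp(m, "CA"), mp(m, "CB"), .L$CC)
  cd <- nerf_place(mp(m, "CA"), mp(m, "CB"), cg, .L$CC)
  ce <- nerf_place(mp(m, "CB"), cg, cd, .L$CC)
  nz <- nerf_place(cg, cd, ce, .L$CN)
  m <- mol_atom(m, "CG", "C", cg); m <- mol_bond(m, "CB", "CG")
  m <- mol_atom(m, "CD", "C", cd); m <- mol_bond(m, "CG", "CD")
  m <- mol_atom(m, "CE", "C", ce); m <- mol_bond(m, "CD", "CE")
  m <- mol_atom(m, "NZ", "N", nz); m <- mol_bond(m, "CE", "NZ")
  m
}

build_pro <- function() {
  ring <- ring_flat(5, 1.52)
  nm <- c("N", "CA", "CB", "CG", "CD")
  el <- c("N", "C", "C", "C", "C")
  m <- mol_new()
  for (k in 1:5) m <- mol_atom(m, nm[k], el[k], ring[k, ])
  for (k in 1:5) m <- mol_bond(m, nm[k], nm[if (k == 5) 1 else k + 1])
  dd <- tet_dirs2(unitv(mp(m, "N") - mp(m, "CA")),
                  unitv(mp(m, "CB") - mp(m, "CA")))
  up <- if (dd[[1]][3] > 0) dd[[1]] else dd[[2]]
  cc <- mp(m, "CA") + .L$CC * up
  d2 <- trig_dirs1(unitv(mp(m, "CA") - cc), ref = unitv(mp(m, "N") -
                                                          mp(m, "CA")))
  m <- mol_atom(m, "C", "C", cc)
  m <- mol_atom(m, "O", "O", cc + .L$CO_DBL * d2[[1]])
  m <- mol_atom(m, "OXT", "O", cc + .L$CO_ACID * d2[[2]], leaving = TRUE)
  m <- mol_bond(m, "CA", "C")
  m <- mol_bond(m, "C", "O", "double")
  m <- mol_bond(m, "C", "OXT")
  m$atoms$stereo[m$atoms$atom_id == "CA"] <- "S"
  m
}

# chair substituent directions at ring position idx (1-based into the 6
# positions): list(axial, equatorial)
chair_subst <- function(ring, idx) {
  prv <- if (idx == 1) 6 else idx - 1
  nxt <- if (idx == 6) 1 else idx + 1
  dd <- tet_dirs2(unitv(ring[prv, ] - ring[idx, ]),
                  unitv(ring[nxt, ] - ring[idx, ]))
  if (abs(dd[[1]][3]) >= abs(dd[[2]][3])) list(ax = dd[[1]], eq = dd[[2]])
  else list(ax = dd[[2]], eq = dd[[1]])
}

# Pyranose sugar on an ideal chair: ring O5,C1..C5; anomeric O1 on C1
# axial or equatorial; either a 2-hydroxyl (mannose-like, axial) or an
# N-acetyl at C2. Five stereocenters C1..C5; O1 is the leaving hydroxyl.
build_pyranose <- function(anomeric = c("equatorial", "axial"),
                           nacetyl = FALSE) {
  anomeric <- match.arg(anomeric)
  ring <- ring_chair(.L$CC_RING)
  nm <- c("O5", "C1", "C2", "C3", "C4", "C5")
  el <- c("O", "C", "C", "C", "C", "C")
  m <- mol_new()
  for (k in 1:6) m <- mol_atom(m, nm[k], el[k], ring[k, ])
  for (k in 1:6) m <- mol_bond(m, nm[k], nm[if (k == 6) 1 else k + 1])
  s1 <- chair_subst(ring, 2)               # C1
  o1dir <- if (anomeric == "equatorial") s1$eq else s1$ax
  m <- mol_atom(m, "O1", "O", ring[2, ] + .L$CO_ANOMER * o1dir,
                leaving = TRUE)
  m <- mol_bond(m, "C1", "O1")
  s2 <- chair_subst(ring, 3)               # C2
  if (nacetyl) {
    n2 <- ring[3, ] + .L$CN * s2$eq
    c7 <- nerf_place(ring[2, ], ring[3, ], n2, .L$CN_AMIDE, 120, 180)
    d7 <- trig_dirs1(unitv(n2 - c7), ref = unitv(ring[3, ] - n2))
    m <- mol_atom(m, "N2", "N", n2)
    m <- mol_atom(m, "C7", "C", c7)
    m <- mol_atom(m, "O7", "O", c7 + .L$CO_DBL * d7[[1]])
    m <- mol_atom(m, "C8", "C", c7 + 1.50 * d7[[2]])
    m <- mol_bond(m, "C2", "N2")
    m <- mol_bond(m, "N2", "C7")
    m <- mol_bond(m, "C7", "O7", "double")
    m <- mol_bond(m, "C7", "C8")
  } else {
    m <- mol_atom(m, "O2", "O", ring[3, ] + .L$CO * s2$ax)
    m <- mol_bond(m, "C2", "O2")
  }
  s3 <- chair_subst(ring, 4)
  m <- mol_atom(m, "O3", "O", ring[4, ] + .L$CO * s3$eq)
  m <- mol_bond(m, "C3", "O3")
  s4 <- chair_subst(ring, 5)
  m <- mol_atom(m, "O4", "O", ring[5, ] + .L$CO * s4$eq)
  m <- mol_bond(m, "C4", "O4")
  s5 <- chair_subst(ring, 6)
  c6 <- ring[6, ] + .L$CC * s5$eq
  o6 <- nerf_place(ring[5, ], ring[6, ], c6, .L$CO)
  m <- mol_atom(m, "C6", "C", c6); m <- mol_bond(m, "C5", "C6")
  m <- mol_atom(m, "O6", "O", o6); m <- mol_bond(m, "C6", "O6")
  st <- c(C1 = if (anomeric == "equatorial") "R" else "S",
          C2 = "S", C3 = "S", C4 = "S", C5 = "R")
  for (a in names(st)) m$atoms$stereo[m$atoms$atom_id == a] <- st[[a]]
  m
}

# Morpholine-ethanesulfonic acid analog: chair ring O1,C2,C3,N4,C5,C6 with
# an N-ethylsulfonate arm (neutral sulfonic acid form).
build_mes <- function() {
  ring <- ring_chair(1.53)
  nm <- c("O1", "C2", "C3", "N4", "C5", "C6")
  el <- c("O", "C", "C", "N", "C", "C")
  m <- mol_new()
  for (k in 1:6) m <- mol_atom(m, nm[k], el[k], ring[k, ])
  for (k in 1:6) m <- mol_bond(m, nm[k], nm[if (k == 6) 1 else k + 1])
  s4 <- chair_subst(ring, 4)
  c7 <- ring[4, ] + .L$CN * s4$eq
  c8 <- nerf_place(ring[3, ], ring[4, ], c7, .L$CC)
  ss <- nerf_place(ring[4, ], c7, c8, .L$CS)
  m <- mol_atom(m, "C7", "C", c7); m <- mol_bond(m, "N4", "C7")
  m <- mol_atom(m, "C8", "C", c8); m <- mol_bond(m, "C7", "C8")
  m <- mol_atom(m, "S", "S", ss); m <- mol_bond(m, "C8", "S")
  d3 <- tet_dirs1(unitv(c8 - ss))
  m <- mol_atom(m, "O1S", "O", ss + .L$SO_DBL * d3[[1]])
  m <- mol_atom(m, "O2S", "O", ss + .L$SO_DBL * d3[[2]])
  m <- mol_atom(m, "O3S", "O", ss + .L$SO * d3[[3]])
  m <- mol_bond(m, "S", "O1S", "double")
  m <- mol_bond(m, "S", "O2S", "double")
  m <- mol_bond(m, "S", "O3S")
  m
}

build_benzene <- function() {
  ring <- ring_flat(6, .L$CC_AR)
  m <- mol_new()
  for (k in 1:6) m <- mol_atom(m, paste0("C", k), "C", ring[k, ],
                               aromatic = TRUE)
  for (k in 1:6) {
    m <- mol_bond(m, paste0("C", k), paste0("C", if (k == 6) 1 else k + 1),
                  order = if (k %% 2 == 1) "double" else "single",
                  aromatic = TRUE)
  }
  m
}

build_pyridine <- function() {
  r_c <- .L$CC_AR
  # pull the nitrogen vertex inward so both C-N bonds are 1.30 A
  rho <- (r_c + sqrt(4 * 1.30^2 - 3 * r_c^2)) / 2
  m <- mol_new()
  pos <- lapply(0:5, function(k) {
    th <- 2 * pi * k / 6
    r <- if (k == 0) rho else r_c
    c(r * cos(th), r * sin(th), 0)
  })
  nm <- c("N1", "C2", "C3", "C4", "C5", "C6")
  el <- c("N", rep("C", 5))
  for (k in 1:6) m <- mol_atom(m, nm[k], el[k], pos[[k]], aromatic = TRUE)
  kek <- c("double", "single", "double", "single", "double", "single")
  for (k in 1:6) m <- mol_bond(m, nm[k], nm[if (k == 6) 1 else k + 1],
                               order = kek[k], aromatic = TRUE)
  m
}

build_cyclohexane <- function() {
  ring <- ring_chair(.L$CC)
  m <- mol_new()
  for (k in 1:6) m <- mol_atom(m, paste0("C", k), "C", ring[k, ])
  for (k in 1:6) m <- mol_bond(m, paste0("C", k),
                               paste0("C", if (k == 6) 1 else k + 1))
  m
}

build_zn <- function() {
  mol_atom(mol_new(), "ZN", "ZN", c(0, 0, 0), charge = 2L)
}

build_hoh <- function() mol_atom(mol_new(), "O", "O", c(0, 0, 0))

# 2-hydroxy-4-phenylbutanoic acid analog: the free, neutral, capped form of
# the carboxyphenylbutyl fragment produced by chopping the lisinopril-like
# parent. O3 (the 2-hydroxyl) is the leaving/capping site.
build_clt <- function() {
  m <- mol_new()
  c2 <- c(0, 0, 0)
  c1 <- c2 + .L$CC * .TET[1, ]
  c3 <- c2 + .L$CC * .TET[2, ]
  o3 <- c2 + .L$CO * .TET[3, ]
  dd <- trig_dirs1(unitv(c2 - c1), ref = unitv(c3 - c2))
  c4 <- nerf_place(c1, c2, c3, .L$CC)
  c5 <- nerf_place(c2, c3, c4, 1.51)
  m <- mol_atom(m, "C1", "C", c1)
  m <- mol_atom(m, "C2", "C", c2, stereo = "S")
  m <- mol_atom(m, "C3", "C", c3)
  m <- mol_atom(m, "C4", "C", c4)
  m <- mol_atom(m, "O1", "O", c1 + .L$CO_DBL * dd[[1]])
  m <- mol_atom(m, "O2", "O", c1 + .L$CO_ACID * dd[[2]])
  m <- mol_atom(m, "O3", "O", o3, leaving = TRUE)
  m <- mol_bond(m, "C1", "C2")
  m <- mol_bond(m, "C2", "C3")
  m <- mol_bond(m, "C2", "O3")
  m <- mol_bond(m, "C3", "C4")
  m <- mol_bond(m, "C1", "O1", "double")
  m <- mol_bond(m, "C1", "O2")
  # phenyl ring: C5 is the attachment vertex; para axis along C4->C5
  d <- unitv(c5 - c4)
  nref <- unitv(c3 - c4)
  n <- unitv(vcross(d, nref))
  e1 <- -d; e2 <- vcross(n, e1)
  ctr <- c5 + .L$CC_AR * d
  ringnm <- paste0("C", 5:10)
  for (k in 0:5) {
    th <- 2 * pi * k / 6
    p <- ctr + .L$CC_AR * (cos(th) * e1 + sin(th) * e2)
    m <- mol_atom(m, ringnm[k + 1], "C", p, aromatic = TRUE)
  }
  m <- mol_bond(m, "C4", "C5")
  kek <- c("double", "single", "double", "single", "double", "single")
  for (k in 1:6) m <- mol_bond(m, ringnm[k],
                               ringnm[if (k == 6) 1 else k + 1],
                               order = kek[k], aromatic = TRUE)
  m
}

# rigid-transform helper: R applied about pivot, then translate to target
mol_transform <- function(m, rot, pivot, target) {
  m$pos <- lapply(m$pos, function(p) as.vector(rot %*% (p - pivot)) + target)
  m
}

mol_rename <- function(m, map) {
  old <- names(m$pos)
  nn <- ifelse(old %in% names(map), unname(map[old]), old)
  names(m$pos) <- nn
  m$atoms$atom_id <- ifelse(m$atoms$atom_id %in% names(map),
                            unname(map[m$atoms$atom_id]), m$atoms$atom_id)
  m$bonds$atom_1 <- ifelse(m$bonds$atom_1 %in% names(map),
                           unname(map[m$bonds$atom_1]), m$bonds$atom_1)
  m$bonds$atom_2 <- ifelse(m$bonds$atom_2 %in% names(map),
                           unname(map[m$bonds$atom_2]), m$bonds$atom_2)
  m
}

mol_drop_atom <- function(m, id) {
  m$pos[[id]] <- NULL
  m$atoms <- m$atoms[m$atoms$atom_id != id, , drop = FALSE]
  m$bonds <- m$bonds[m$bonds$atom_1 != id & m$bonds$atom_2 != id, ,
                     drop = FALSE]
  m
}

mol_merge <- function(m1, m2) {
  stopifnot(!any(names(m2$pos) %in% names(m1$pos)))
  m1$pos <- c(m1$pos, m2$pos)
  m1$atoms <- rbind(m1$atoms, m2$atoms)
  m1$bonds <- rbind(m1$bonds, m2$bonds)
  m1
}

# Lisinopril-like parent: carboxyphenylbutyl fragment N-alkylating a lysine
# whose carboxyl forms an amide to a proline. Assembled by rigidly attaching
# the free-residue templates, so every stereocenter's parity equals its
# template's. Spin angles orient the attached residues to avoid clashes.
build_lpr <- function(spin_lys = 0, spin_pro = 90) {
  clt <- build_clt()
  n1 <- mp(clt, "C2") + .L$CN * unitv(mp(clt, "O3") - mp(clt, "C2"))
  m <- mol_drop_atom(clt, "O3")
  m$atoms$leaving <- FALSE
  m$atoms$stereo[m$atoms$atom_id == "C2"] <- "S"
  m <- mol_atom(m, "N1", "N", n1)
  m <- mol_bond(m, "C2", "N1")

  lys <- build_lys()
  tau <- tet_dirs1(unitv(mp(m, "C2") - n1))[[1]]
  rot <- rot_axis(tau, spin_lys) %*%
    rot_align(unitv(mp(lys, "CA") - mp(lys, "N")), tau)
  lys <- mol_transform(lys, rot, mp(lys, "N"), n1)
  lys <- mol_drop_atom(lys, "OXT")
  lys <- mol_drop_atom(lys, "N")            # merged into N1
  lys <- mol_rename(lys, c(O = "O3"))
  lys$atoms$leaving <- FALSE
  m <- mol_merge(m, lys)
  m <- mol_bond(m, "N1", "CA")

  # amide C->proline N along the carbonyl carbon's third trigonal direction
  cpos <- mp(m, "C"); n2 <- cpos + .L$CN_AMIDE *
    trig_dir2(unitv(mp(m, "CA") - cpos), unitv(mp(m, "O3") - cpos))
  pro <- build_pro()
  # amide nitrogens are planar: the acyl bond takes the in-plane trigonal
  # direction so N2 is perceived sp2 (and hence not a stereocenter)
  fd <- trig_dir2(unitv(mp(pro, "CA") - mp(pro, "N")),
                  unitv(mp(pro, "CD") - mp(pro, "N")))
  axis <- unitv(cpos - n2)
  rot <- rot_axis(axis, spin_pro) %*% rot_align(fd, axis)
  pro <- mol_transform(pro, rot, mp(pro, "N"), n2)
  pro <- mol_rename(pro, c(N = "N2", CA = "CA2", CB = "CB2", CG = "CG2",
                           CD = "CD2", C = "C15", O = "O4", OXT = "O5"))
  pro$atoms$leaving <- FALSE
  m <- mol_merge(m, pro)
  m <- mol_bond(m, "C", "N2")
  m
}

# Triglycine parent assembled by forming two peptide bonds between glycine
# templates; residue i atoms are N<i>, CA<i>, C<i>, O<i>, plus terminal OXT.
build_ggg <- function(spins = c(150, 210)) {
  res <- build_gly()
  res <- mol_rename(res, c(N = "N1", CA = "CA1", C = "C1", O = "O1"))
  res$atoms$leaving <- FALSE
  for (i in 2:3) {
    cpos <- mp(res, paste0("C", i - 1))
    oxt <- mp(res, "OXT")
    nn <- cpos + .L$CN_AMIDE * unitv(oxt - cpos)
    res <- mol_drop_atom(res, "OXT")
    nxt <- build_gly()
    tau <- tet_dirs1(unitv(cpos - nn))[[1]]
    rot <- rot_axis(tau, spins[i - 1]) %*%
      rot_align(unitv(mp(nxt, "CA") - mp(nxt, "N")), tau)
    nxt <- mol_transform(nxt, rot, mp(nxt, "N"), nn)
    nxt <- mol_drop_atom(nxt, "N")
    nxt <- mol_rename(nxt, stats::setNames(
      c(paste0("CA", i), paste0("C", i), paste0("O", i)),
      c("CA", "C", "O")))
    if (i < 3) nxt$atoms$leaving <- FALSE
    res <- mol_atom(res, paste0("N", i), "N", nn)
    res <- mol_merge(res, nxt)
    res <- mol_bond(res, paste0("C", i - 1), paste0("N", i))
    res <- mol_bond(res, paste0("N", i), paste0("CA", i))
  }
  res
}

# -- the toy dictionary -----------------------------------------------------

#' Build the deterministic toy component dictionary
#'
#' Seventeen hand-built definitions with idealized coordinates from ideal
#' bond geometry: glycine/alanine/proline/lysine/asparagine-like amino
#' acids, a five-stereocenter pyranose in mannose-like and N-acetyl
#' (glucosamine-like) variants plus the C1 anomer of the latter, a
#' morpholine-ethanesulfonate, benzene, pyridine, cyclohexane, a zinc ion,
#' water, a carboxyphenylbutyl fragment, a lisinopril-like parent and a
#' triglycine parent. Two calls produce identical dictionaries.
#'
#' @return A \code{chem_comp_dict}.
#' @export
make_toy_dictionary <- function() {
  defs <- list(
    mol_def("GLY", "glycine analog", build_gly()),
    mol_def("ALA", "alanine analog", build_ala()),
    mol_def("PRO", "proline analog", build_pro()),
    mol_def("LYS", "lysine analog", build_lys()),
    mol_def("ASN", "asparagine analog", build_asn()),
    mol_def("MAN", "alpha-mannopyranose analog",
            build_pyranose("axial", nacetyl = FALSE)),
    mol_def("NAG", "N-acetyl-beta-glucosamine analog",
            build_pyranose("equatorial", nacetyl = TRUE)),
    mol_def("NDG", "N-acetyl-alpha-glucosamine analog (C1 anomer)",
            build_pyranose("axial", nacetyl = TRUE)),
    mol_def("MES", "morpholine-ethanesulfonic acid analog", build_mes()),
    mol_def("BNZ", "benzene", build_benzene()),
    mol_def("PYR", "pyridine", build_pyridine()),
    mol_def("CHX", "cyclohexane", build_cyclohexane()),
    mol_def("ZN", "zinc ion", build_zn()),
    mol_def("HOH", "water", build_hoh()),
    mol_def("CLT", "2-hydroxy-4-phenylbutanoic acid analog", build_clt()),
    mol_def("LPR", "lisinopril analog", build_lpr()),
    mol_def("GGG", "triglycine parent", build_ggg())
  )
  dictionary(defs)
}

# comp_ids treated as standard polymer components when residues are
# polymer-flagged (they are skipped by instance extraction)
.STANDARD_POLYMER <- c("GLY", "ALA", "PRO", "LYS", "ASN")
.WATER_IDS <- c("HOH", "DOD", "WAT")

# -- synthetic entries ------------------------------------------------------

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rot_axis(unitv(ax), stats::runif(1, 0, 360))
}

# move `atom` toward the plane of its three bonded heavy neighbors until the
# bond-angle sum reaches `target` degrees (sp2 flattening)
flatten_atom <- function(df, atom, target = 358) {
  g <- perceive_bonds(df[, c("atom_id", "element", "x", "y", "z")] |>
                        stats::setNames(c("name", "element", "x", "y", "z")))
  i <- match(atom, g$atoms$name)
  if (is.na(i)) stop("unknown atom ", atom)
  adj <- adjacency_list(g)
  nb <- adj[[i]]
  if (length(nb) != 3) stop("flatten_chiral needs exactly 3 bonded heavy ",
                            "neighbors at ", atom)
  p <- atom_xyz(g, i)
  q <- lapply(nb, function(k) atom_xyz(g, k))
  nrm <- plane_normal(q[[1]], q[[2]], q[[3]])
  foot <- plane_project(p, q[[1]], nrm)
  angsum <- function(t) {
    x <- p + t * (foot - p)
    angle_deg(q[[1]], x, q[[2]]) + angle_deg(q[[1]], x, q[[3]]) +
      angle_deg(q[[2]], x, q[[3]])
  }
  t0 <- if (angsum(1) <= target) 1 else
    stats::uniroot(function(t) angsum(t) - target, c(0, 1))$root
  newp <- p + t0 * (foot - p)
  ridx <- match(atom, df$atom_id)
  df[ridx, c("x", "y", "z")] <- as.list(newp)
  df
}

# Invert the handedness at `atom` by reflecting one of its terminal
# (degree-1) substituents through the plane spanned by the center and two
# of its other neighbors: the center's geometry, all bond lengths and every
# other stereocenter are untouched (epimerization, e.g. axial <->
# equatorial at a sugar carbon).
invert_atom <- function(df, atom) {
  g <- perceive_bonds(df[, c("atom_id", "element", "x", "y", "z")] |>
                        stats::setNames(c("name", "element", "x", "y", "z")))
  i <- match(atom, g$atoms$name)
  if (is.na(i)) stop("unknown atom ", atom)
  adj <- adjacency_list(g)
  nb <- adj[[i]]
  if (length(nb) < 3) stop("invert_parity needs 3 bonded heavy neighbors")
  term <- nb[lengths(adj[nb]) == 1]
  if (!length(term)) {
    stop("invert_parity needs a terminal substituent at ", atom)
  }
  t <- term[1]
  others <- setdiff(nb, t)[1:2]
  p <- atom_xyz(g, i)
  nrm <- plane_normal(p, atom_xyz(g, others[1]), atom_xyz(g, others[2]))
  tp <- atom_xyz(g, t)
  newp <- tp - 2 * sum((tp - p) * nrm) * nrm
  ridx <- match(g$atoms$name[t], df$atom_id)
  df[ridx, c("x", "y", "z")] <- as.list(newp)
  df
}

# stretch or shrink bond a1-a2 (moving the less-connected end) so that its
# length re-classifies to the other order
retype_bond <- function(df, a1, a2) {
  g <- perceive_bonds(df[, c("atom_id", "element", "x", "y", "z")] |>
                        stats::setNames(c("name", "element", "x", "y", "z")))
  i <- match(a1, g$atoms$name); j <- match(a2, g$atoms$name)
  if (is.na(i) || is.na(j)) stop("unknown atom in change_bond_order")
  adj <- adjacency_list(g)
  if (!j %in% adj[[i]]) stop("atoms ", a1, " and ", a2, " are not bonded")
  mover <- if (length(adj[[j]]) <= length(adj[[i]])) j else i
  fixed <- if (mover == j) i else j
  e1 <- g$atoms$element[fixed]; e2 <- g$atoms$element[mover]
  d <- vnorm(atom_xyz(g, mover) - atom_xyz(g, fixed))
  cur <- classify_order(e1, e2, d)
  newlen <- if (cur == "single") .RD[toupper(e1)] + .RD[toupper(e2)]
            else .RS[toupper(e1)] + .RS[toupper(e2)]
  if (is.na(newlen)) stop("no multiple-bond radii for ", e1, "-", e2)
  newp <- atom_xyz(g, fixed) +
    newlen * unitv(atom_xyz(g, mover) - atom_xyz(g, fixed))
  ridx <- match(g$atoms$name[mover], df$atom_id)
  df[ridx, c("x", "y", "z")] <- as.list(newp)
  df
}

apply_perturbation <- function(df, perturb, dict) {
  if (is.null(perturb)) return(list(atoms = df, extra = NULL))
  extra <- NULL
  switch(perturb$type,
    none = {},
    flatten_chiral = { df <- flatten_atom(df, perturb$atom) },
    invert_parity = { df <- invert_atom(df, perturb$atom) },
    change_bond_order = { df <- retype_bond(df, perturb$a1, perturb$a2) },
    rename_atoms = { df$atom_id <- sprintf("X%d", seq_len(nrow(df))) },
    relabel_id = { df$comp_id <- toupper(perturb$new) },
    delete_atom = {
      k <- match(perturb$atom, df$atom_id)
      if (is.na(k)) stop("unknown atom ", perturb$atom)
      df <- df[-k, , drop = FALSE]
    },
    link_to_polymer = {
      res <- link_to_polymer(df, perturb$atom, dict)
      df <- res$atoms; extra <- res$extra
    },
    stop("unknown perturbation type: ", perturb$type)
  )
  list(atoms = df, extra = extra)
}

# Replace the terminal O bonded to `atom` by the amide nitrogen of an
# asparagine-like polymer residue (glycosylation-style covalent link).
link_to_polymer <- function(df, atom, dict) {
  g <- perceive_bonds(df[, c("atom_id", "element", "x", "y", "z")] |>
                        stats::setNames(c("name", "element", "x", "y", "z")))
  i <- match(atom, g$atoms$name)
  if (is.na(i)) stop("unknown atom ", atom)
  adj <- adjacency_list(g)
  os <- adj[[i]][g$atoms$element[adj[[i]]] == "O" &
                   lengths(adj[adj[[i]]]) == 1]
  if (!length(os)) stop("no terminal O bonded to ", atom, " to replace")
  oname <- g$atoms$name[os[1]]
  apos <- atom_xyz(g, i); opos <- atom_xyz(g, os[1])
  ndir <- unitv(opos - apos)
  npos <- apos + 1.45 * ndir
  df <- df[df$atom_id != oname, , drop = FALSE]
  asn <- build_asn()
  rot <- rot_align(unitv(mp(asn, "CG") - mp(asn, "ND2")), ndir)
  asn <- mol_transform(asn, rot, mp(asn, "ND2"), npos)
  p <- do.call(rbind, asn$pos[asn$atoms$atom_id])
  extra <- data.frame(chain = "A", resno = 219L, ins = "",
                      comp_id = "ASN", atom_id = asn$atoms$atom_id,
                      element = asn$atoms$element,
                      x = p[, 1], y = p[, 2], z = p[, 3],
                      occ = 1, altloc = "", hetero = FALSE,
                      stringsAsFactors = FALSE)
  list(atoms = df, extra = extra)
}

#' Assemble a synthetic structure entry from dictionary components
#'
#' Places the requested number of copies of each component at non-clashing
#' offsets with a seeded random rigid rotation and a small coordinate
#' jitter, then applies the requested perturbation to coordinates/labels
#' only (never to the dictionary).
#'
#' @param spec List of \code{list(comp_id=, count=, perturb=)} elements.
#'   \code{perturb} is \code{NULL} or a list with a \code{type} of
#'   \code{"flatten_chiral"} (\code{atom}), \code{"invert_parity"}
#'   (\code{atom}), \code{"change_bond_order"} (\code{a1}, \code{a2}),
#'   \code{"rename_atoms"}, \code{"relabel_id"} (\code{new}),
#'   \code{"delete_atom"} (\code{atom}) or \code{"link_to_polymer"}
#'   (\code{atom}); it applies to the first copy of that component.
#' @param seed Integer seed; identical spec + seed give identical entries.
#' @param dict Dictionary the comp_ids refer to (default: the toy
#'   dictionary).
#' @param jitter Half-width (Angstrom) of the uniform coordinate jitter
#'   (kept well below perception classification margins).
#' @return A \code{structure_entry} whose hetero residues sit on chain "C"
#'   numbered from 1001 (polymer residues added by \code{link_to_polymer}
#'   go to chain "A").
#' @export
make_entry <- function(spec, seed = 1L, dict = make_toy_dictionary(),
                       jitter = 0.005) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  rows <- list(); extras <- list()
  resno <- 1000L
  inst <- 0L
  for (item in spec) {
    if (!dict_has(dict, item$comp_id)) {
      stop("unknown comp_id in entry spec: ", item$comp_id)
    }
    def <- dict_get(dict, item$comp_id)
    for (c in seq_len(item$count)) {
      inst <- inst + 1L; resno <- resno + 1L
      rot <- random_rotation()
      shift <- c(25 * ((inst - 1) %% 5), 25 * ((inst - 1) %/% 5), 0)
      xyz <- t(apply(as.matrix(def$atoms[, c("x", "y", "z")]), 1,
                     function(p) as.vector(rot %*% p) + shift))
      if (jitter > 0) {
        xyz <- xyz + matrix(stats::runif(length(xyz), -jitter, jitter),
                            nrow = nrow(xyz))
      }
      df <- data.frame(chain = "C", resno = resno, ins = "",
                       comp_id = def$comp_id, atom_id = def$atoms$atom_id,
                       element = def$atoms$element,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       occ = 1, altloc = "", hetero = TRUE,
                       stringsAsFactors = FALSE)
      if (c == 1 && !is.null(item$perturb)) {
        pr <- apply_perturbation(df, item$perturb, dict)
        df <- pr$atoms
        # the polymer partner is placed relative to the already-rotated,
        # already-shifted ligand coordinates, so it needs no further shift
        if (!is.null(pr$extra)) extras[[length(extras) + 1]] <- pr$extra
      }
      rows[[length(rows) + 1]] <- df
    }
  }
  atoms <- do.call(rbind, c(rows, extras))
  structure_entry(sprintf("SYN%04d", seed %% 10000), atoms)
}
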