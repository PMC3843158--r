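# Perception from 3D coordinates: bonds, orders, hybridization, chirality
# parity, aromaticity, and their invariances.

tet_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                  c(-1, -1, 1)) / sqrt(3)

test_that("covalent bonds follow the radius-plus-tolerance rule", {
  g <- perceive_bonds(data.frame(element = c("C", "C"),
                                 x = c(0, 1.54), y = 0, z = 0))
  expect_equal(nrow(g$bonds), 1)
  expect_equal(g$bonds$order, "single")
  g <- perceive_bonds(data.frame(element = c("C", "C"),
                                 x = c(0, 3.0), y = 0, z = 0))
  expect_equal(nrow(g$bonds), 0)
  expect_error(perceive_bonds(data.frame(element = c("C", "XX"),
                                         x = c(0, 1), y = 0, z = 0)),
               "covalent radius")
})

test_that("metal contacts are coordination, never covalent edges", {
  g <- perceive_bonds(data.frame(element = c("ZN", "O"),
                                 x = c(0, 2.1), y = 0, z = 0))
  expect_equal(nrow(g$bonds), 0)
  expect_equal(nrow(g$contacts), 1)
  expect_equal(g$contacts$dist, 2.1)
  # beyond the 3.0 A cutoff: nothing at all
  g <- perceive_bonds(data.frame(element = c("ZN", "O"),
                                 x = c(0, 3.2), y = 0, z = 0))
  expect_equal(nrow(g$contacts), 0)
})

test_that("hybridization comes from bond-angle sums", {
  center_with <- function(dirs, flat = FALSE) {
    pos <- rbind(c(0, 0, 0), 1.53 * dirs)
    if (flat) pos[, 3] <- 0
    df <- data.frame(element = c("C", "C", "C", "C"),
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
    perceive_hybridization(perceive_bonds(df))
  }
  g <- center_with(tet_dirs[1:3, ])                  # angle sum ~328.5
  expect_equal(g$atoms$hybrid[1], "sp3")
  flat_dirs <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                     c(-0.5, -sqrt(3) / 2, 0))       # angle sum 360
  g <- center_with(flat_dirs)
  expect_equal(g$atoms$hybrid[1], "sp2")
  lin <- data.frame(element = "C", x = c(-1.2, 0, 1.2), y = 0, z = 0)
  g <- perceive_hybridization(perceive_bonds(lin))
  expect_equal(g$atoms$hybrid[2], "sp")
})

test_that("handedness parity flips under reflection and only then", {
  def <- dict_get(toy, "NAG")
  gi <- def_as_instance(def)
  mirror <- def$atoms
  mirror$z <- -mirror$z
  gm <- perceive(data.frame(name = mirror$atom_id, element = mirror$element,
                            x = mirror$x, y = mirror$y, z = mirror$z))
  expect_equal(gm$atoms$chiral, gi$atoms$chiral)
  expect_equal(gm$atoms$parity, -gi$atoms$parity)
  expect_equal(gm$atoms$aromatic, gi$atoms$aromatic)
  expect_equal(gm$atoms$hybrid, gi$atoms$hybrid)
})

test_that("sp2 and rank-degenerate centers get handedness none", {
  # flattened anomeric carbon: not chiral despite 3 distinct neighbors
  e <- make_entry(list(list(comp_id = "NAG", count = 1,
                            perturb = list(type = "flatten_chiral",
                                           atom = "C1"))),
                  seed = 2, dict = toy)
  g <- extract_instances(e, toy)[[1]]$graph
  k <- match("C1", g$atoms$name)
  expect_equal(g$atoms$hybrid[k], "sp2")
  expect_false(g$atoms$chiral[k])
  expect_equal(g$atoms$parity[k], 0L)
  # pro-chiral center: two neighbors with equal canonical ranks
  pos <- rbind(c(0, 0, 0), 1.43 * tet_dirs[1, ], 1.43 * tet_dirs[2, ],
               1.53 * tet_dirs[3, ])
  g2 <- perceive(data.frame(element = c("C", "O", "O", "C"),
                            x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  expect_false(g2$atoms$chiral[1])
})

test_that("aromaticity: benzene and pyridine rings pass, saturated fail", {
  counts <- vapply(c("BNZ", "PYR", "CHX", "MES"), function(id) {
    sum(def_as_instance(dict_get(toy, id))$atoms$aromatic)
  }, 0)
  expect_equal(unname(counts), c(6, 6, 0, 0))
  # aromatic ring bonds carry their own order on both sides
  gb <- def_as_instance(dict_get(toy, "BNZ"))
  expect_true(all(gb$bonds$order == "aromatic"))
  gd <- graph_from_definition(dict_get(toy, "BNZ"))
  expect_true(all(gd$bonds$order == "aromatic"))
})

test_that("definition graphs agree with perception on idealized coords", {
  for (id in names(toy$defs)) {
    def <- dict_get(toy, id)
    gd <- graph_from_definition(def)
    gi <- def_as_instance(def)
    key <- function(g) sort(paste(pmin(g$atoms$name[g$bonds$i],
                                       g$atoms$name[g$bonds$j]),
                                  pmax(g$atoms$name[g$bonds$i],
                                       g$atoms$name[g$bonds$j]),
                                  g$bonds$order))
    expect_equal(key(gi), key(gd), info = id)
    expect_equal(sort(gi$atoms$name[gi$atoms$chiral]),
                 sort(gd$atoms$name[gd$atoms$chiral]), info = id)
    ord <- match(gd$atoms$name, gi$atoms$name)
    expect_equal(gi$atoms$parity[ord], gd$atoms$parity, info = id)
    expect_equal(gi$atoms$aromatic[ord], gd$atoms$aromatic, info = id)
    # stereo-flag count equals perceived chiral-center count
    expect_equal(sum(def$atoms$stereo %in% c("R", "S")),
                 sum(gi$atoms$chiral), info = id)
  }
})

test_that("derived attributes are invariant under atom relabeling", {
  def <- dict_get(toy, "NAG")
  base <- def_as_instance(def)
  set.seed(99)
  for (rep in 1:5) {
    prm <- sample(nrow(def$atoms))
    at <- def$atoms[prm, ]
    g <- perceive(data.frame(name = at$atom_id, element = at$element,
                             x = at$x, y = at$y, z = at$z))
    ord <- match(base$atoms$name, g$atoms$name)
    expect_equal(g$atoms$chiral[ord], base$atoms$chiral)
    expect_equal(g$atoms$parity[ord], base$atoms$parity)
    expect_equal(g$atoms$hybrid[ord], base$atoms$hybrid)
    expect_equal(sort(g$atoms$rank), sort(base$atoms$rank))
  }
})

test_that("graph_from_definition rejects ineligible stereo flags", {
  expect_error(
    component_definition("BAD", "x",
                         data.frame(atom_id = c("C1", "O1"),
                                    element = c("C", "O"),
                                    stereo = c("R", "N")),
                         data.frame(atom_1 = "C1", atom_2 = "O1",
                                    order = "single")),
    "stereo flag")
  # single-atom metal: 1 node, 0 edges
  g <- graph_from_definition(dict_get(toy, "ZN"))
  expect_equal(nrow(g$atoms), 1)
  expect_equal(nrow(g$bonds), 0)
})
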