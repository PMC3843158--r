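# Candidate search, composite scoring, ranking, status, nomenclature,
# ID assignment and redundancy checking.

test_that("candidate search finds both anomers for a sugar instance", {
  gi <- def_as_instance(dict_get(toy, "NAG"))
  ids <- vapply(find_candidates(gi, toy), function(cd) cd$comp_id, "")
  expect_setequal(ids, c("NAG", "NDG"))
  # flattened C1 excludes neither anomer (stereo ignored at this stage)
  e <- make_entry(list(list(comp_id = "NAG", count = 1,
                            perturb = list(type = "flatten_chiral",
                                           atom = "C1"))),
                  seed = 5, dict = toy)
  i <- extract_instances(e, toy)[[1]]
  ids <- vapply(find_candidates(i, toy), function(cd) cd$comp_id, "")
  expect_setequal(ids, c("NAG", "NDG"))
})

test_that("single-atom and unmatchable instances behave", {
  gz <- def_as_instance(dict_get(toy, "ZN"))
  ids <- vapply(find_candidates(gz, toy), function(cd) cd$comp_id, "")
  expect_equal(ids, "ZN")
  # an element foreign to the dictionary matches nothing
  gs <- perceive(data.frame(element = "BR", x = 0, y = 0, z = 0))
  expect_length(find_candidates(gs, toy), 0)
  res <- match_instance(gs, toy, deposited_id = "BR")
  expect_equal(res$status, "no match")
  expect_true(is.na(res$top_hit))
})

test_that("composite score reproduces the worked sugar comparisons", {
  # flattened anomeric carbon: 4 of 5 chiral centers remain -> 80%
  e <- make_entry(list(list(comp_id = "NAG", count = 1,
                            perturb = list(type = "flatten_chiral",
                                           atom = "C1"))),
                  seed = 13, dict = toy)
  res <- match_instance(extract_instances(e, toy)[[1]], toy)
  sc <- unclass(score_of(res, "NAG"))
  expect_equal(sc[["chiral_count"]], 80)
  expect_equal(sc[["heavy_atoms"]], 100)
  expect_equal(sc[["handedness"]], 100)   # the 4 surviving parities agree
  expect_equal(res$status, "close match")
  # inverted C1 parity, sp3 kept: count 100, handedness 4/5 = 80
  e2 <- make_entry(list(list(comp_id = "NAG", count = 1,
                             perturb = list(type = "invert_parity",
                                            atom = "C1"))),
                   seed = 13, dict = toy)
  res2 <- match_instance(extract_instances(e2, toy)[[1]], toy)
  sc2 <- unclass(score_of(res2, "NAG"))
  expect_equal(sc2[["chiral_count"]], 100)
  expect_equal(sc2[["handedness"]], 80)
  # ... and the other anomer now matches perfectly (top hit NDG)
  expect_equal(res2$top_hit, "NDG")
  expect_all_perfect(score_of(res2, "NDG"))
})

test_that("every definition self-matches at 100 in all defined categories", {
  for (id in names(toy$defs)) {
    res <- match_instance(def_as_instance(dict_get(toy, id)), toy,
                          deposited_id = id)
    expect_equal(res$top_hit, id, info = id)
    expect_equal(res$status, "passed", info = id)
    expect_all_perfect(res$candidates[[1]]$score)
  }
})

test_that("status depends on both chemistry and the deposited code", {
  gi <- def_as_instance(dict_get(toy, "MAN"))
  res <- match_instance(gi, toy, deposited_id = "MAN")
  expect_equal(res$status, "passed")
  res2 <- match_instance(gi, toy, deposited_id = "GLA")
  expect_equal(res2$status, "close match")
  expect_equal(res2$top_hit, "MAN")
  expect_all_perfect(res2$candidates[[1]]$score)
})

test_that("candidate ranking is deterministic with documented tie-breaks", {
  s100 <- structure(c(heavy_atoms = 100, chiral_count = 100,
                      handedness = 100, aromatic = NA, bond_order = 100),
                    class = "composite_score")
  s90 <- structure(c(heavy_atoms = 100, chiral_count = 80,
                     handedness = 80, aromatic = NA, bond_order = 100),
                   class = "composite_score")
  a <- list(comp_id = "BBB", score = s100)
  b <- list(comp_id = "AAA", score = s100)
  c3 <- list(comp_id = "CCC", score = s90)
  # equal keys (1)-(3): lexicographically smaller comp_id first
  r <- rank_candidates(list(a, b), deposited_id = "ZZZ")
  expect_equal(vapply(r, function(x) x$comp_id, ""), c("AAA", "BBB"))
  # deposited-id key only wins with exact chemistry
  r <- rank_candidates(list(c3, b), deposited_id = "CCC")
  expect_equal(r[[1]]$comp_id, "AAA")
  r <- rank_candidates(list(a, b), deposited_id = "BBB")
  expect_equal(r[[1]]$comp_id, "BBB")
  # single candidate unchanged
  expect_equal(rank_candidates(list(a), "X")[[1]]$comp_id, "BBB")
})

test_that("scores are stable under instance atom relabeling", {
  def <- dict_get(toy, "MES")
  base <- unclass(match_instance(def_as_instance(def), toy,
                                 deposited_id = "MES")$candidates[[1]]$score)
  set.seed(4)
  for (rep in 1:4) {
    at <- def$atoms[sample(nrow(def$atoms)), ]
    at$atom_id <- sprintf("Q%d", seq_len(nrow(at)))
    g <- perceive(data.frame(name = at$atom_id, element = at$element,
                             x = at$x, y = at$y, z = at$z))
    sc <- unclass(match_instance(g, toy,
                                 deposited_id = "MES")$candidates[[1]]$score)
    expect_equal(sc, base)
  }
})

test_that("flattening additional centers never raises the chiral score", {
  def <- dict_get(toy, "MAN")
  at <- data.frame(atom_id = def$atoms$atom_id, element = def$atoms$element,
                   x = def$atoms$x, y = def$atoms$y, z = def$atoms$z,
                   comp_id = "MAN", stringsAsFactors = FALSE)
  flatten <- ccannotate:::flatten_atom
  prev <- 100
  df <- at
  for (atom in c("C2", "C3", "C4")) {
    df <- flatten(df, atom)
    g <- perceive(data.frame(name = df$atom_id, element = df$element,
                             x = df$x, y = df$y, z = df$z))
    sc <- unclass(match_instance(g, toy,
                                 deposited_id = "MAN")$candidates[[1]]$score)
    expect_lte(sc[["chiral_count"]], prev)
    prev <- sc[["chiral_count"]]
  }
  expect_equal(prev, 100 * 2 / 5)
})

test_that("missing-atom instances fall back to subgraph matching", {
  e <- make_entry(list(list(comp_id = "NAG", count = 1,
                            perturb = list(type = "delete_atom",
                                           atom = "O6"))),
                  seed = 21, dict = toy)
  res <- match_instance(extract_instances(e, toy)[[1]], toy)
  expect_equal(res$status, "close match")
  expect_equal(res$top_hit, "NAG")
  sc <- unclass(res$candidates[[1]]$score)
  expect_equal(sc[["heavy_atoms"]], 100 * 14 / 15)
})

test_that("nomenclature standardization renames through the mapping", {
  e <- make_entry(list(list(comp_id = "MES", count = 1,
                            perturb = list(type = "rename_atoms"))),
                  seed = 31, dict = toy)
  expect_true(all(grepl("^X\\d+$",
                        e$atoms$atom_id[e$atoms$comp_id == "MES"])))
  res <- match_entry(e, toy)
  std <- standardize_nomenclature(e, res)
  mes_atoms <- std$entry$atoms$atom_id[std$entry$atoms$comp_id == "MES"]
  expect_setequal(mes_atoms, dict_get(toy, "MES")$atoms$atom_id)
  expect_gt(nrow(std$log), 0)
  # idempotence: a standard entry is returned unchanged with an empty log
  res2 <- match_entry(std$entry, toy)
  std2 <- standardize_nomenclature(std$entry, res2)
  expect_identical(std2$entry$atoms, std$entry$atoms)
  expect_equal(nrow(std2$log), 0)
  # unresolved instances block standardization
  gs <- structure_entry("X", data.frame(
    chain = "C", resno = 1L, ins = "", comp_id = "UNK", atom_id = "BR1",
    element = "BR", x = 0, y = 0, z = 0, occ = 1, altloc = "",
    hetero = TRUE))
  res3 <- match_entry(gs, toy)
  expect_error(standardize_nomenclature(gs, res3), "no match|unresolved")
})

test_that("new component codes enumerate the 0-9A-Z space", {
  mk <- function(id) component_definition(id, id, data.frame(
    atom_id = "O", element = "O"))
  d0 <- dictionary(list(mk("000")))
  expect_equal(assign_new_id(d0), "001")
  expect_equal(assign_new_id(d0, "R12"), "R12")
  expect_error(assign_new_id(d0, "000"), "already")
  d1 <- dictionary(list())
  expect_equal(assign_new_id(d1), "000")
})

test_that("redundancy check sees through atom renaming but not chemistry", {
  bnz <- dict_get(toy, "BNZ")
  ren <- bnz
  ren$comp_id <- "NEW"
  ren$atoms$atom_id <- sprintf("Q%d", seq_len(nrow(ren$atoms)))
  ren$bonds$atom_1 <- sprintf("Q%d", match(bnz$bonds$atom_1,
                                           bnz$atoms$atom_id))
  ren$bonds$atom_2 <- sprintf("Q%d", match(bnz$bonds$atom_2,
                                           bnz$atoms$atom_id))
  expect_equal(redundancy_check(ren, toy), "BNZ")
  # same skeleton, different bond orders: not redundant
  chx <- dict_get(toy, "CHX")
  mod <- chx
  mod$comp_id <- "NEW"
  mod$bonds$order[1] <- "double"
  expect_length(redundancy_check(mod, toy), 0)
  novel <- component_definition("NEW", "bromide", data.frame(
    atom_id = "BR", element = "BR"))
  expect_length(redundancy_check(novel, toy), 0)
})

test_that("VF2 route agrees with the brute-force oracle on small pairs", {
  small <- Filter(function(d) sum(d$atoms$element != "H") <= 12, toy$defs)
  graphs <- lapply(small, graph_from_definition)
  iso_mappings <- ccannotate:::iso_mappings
  for (id1 in names(graphs)) {
    for (id2 in names(graphs)) {
      got <- iso_mappings(graphs[[id1]], graphs[[id2]])
      want <- oracle_isomorphisms(graphs[[id1]], graphs[[id2]])
      expect_equal(length(got), length(want),
                   info = paste(id1, "vs", id2))
      if (length(want)) {
        keyfun <- function(m) paste(m, collapse = ",")
        expect_setequal(vapply(got, keyfun, ""), vapply(want, keyfun, ""))
      }
    }
  }
})

test_that("the chosen mapping maximizes the score over all isomorphisms", {
  iso_mappings <- ccannotate:::iso_mappings
  score_graphs <- ccannotate:::score_graphs
  for (id in c("BNZ", "PYR", "MES", "MAN", "NAG")) {
    def <- dict_get(toy, id)
    gi <- def_as_instance(def)
    gd <- graph_from_definition(def)
    res <- match_instance(gi, toy, deposited_id = id)
    chosen <- unclass(score_of(res, id))
    best <- -Inf
    for (m in oracle_isomorphisms(gi, gd)) {
      v <- unclass(score_graphs(gi, gd, m))
      best <- max(best, mean(v, na.rm = TRUE))
    }
    expect_equal(mean(chosen, na.rm = TRUE), best, info = id)
  }
})
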