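# Peptide-like decomposition: cleavage-bond selection, capping, fragment
# matching, ordering, and application to the entry.

test_that("cleavage-bond selection follows the amide/pseudo-peptide rule", {
  counts <- vapply(c("GGG", "LPR", "GLY", "PRO", "LYS"), function(id) {
    length(select_cleavage_bonds(graph_from_definition(dict_get(toy, id))))
  }, 0L)
  expect_equal(unname(counts), c(2L, 2L, 0L, 0L, 0L))
  # lisinopril-like: the amine bond to the lysine nitrogen and the amide
  # bond to the (ring) proline nitrogen, and nothing else
  bs <- select_cleavage_bonds(graph_from_definition(dict_get(toy, "LPR")))
  expect_setequal(vapply(bs, paste, "", collapse = "-"),
                  c("C2-N1", "C-N2"))
})

test_that("triglycine chops into three free neutral glycines", {
  e <- make_entry(list(list(comp_id = "GGG", count = 1)), seed = 3,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, d = toy)
  expect_length(dec$fragments, 3)
  for (f in dec$fragments) {
    expect_equal(f$match$top_hit, "GLY")
    expect_all_perfect(f$match$candidates[[1]]$score)
  }
  # fragment 1 holds the free amine (no carbonyl cut on its N side)
  expect_true("N1" %in% dec$fragments[[1]]$members)
})

test_that("the lisinopril-like parent chops into CLT, LYS, PRO in order", {
  e <- make_entry(list(list(comp_id = "LPR", count = 1)), seed = 4,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, d = toy)
  hits <- vapply(dec$fragments, function(f) f$match$top_hit, "")
  expect_equal(hits, c("CLT", "LYS", "PRO"))
  for (f in dec$fragments) {
    expect_all_perfect(f$match$candidates[[1]]$score)
  }
})

test_that("heavy atoms are conserved up to one O per hydroxyl cap", {
  for (id in c("GGG", "LPR")) {
    e <- make_entry(list(list(comp_id = id, count = 1)), seed = 8,
                    dict = toy)
    i <- extract_instances(e, toy)[[1]]
    dec <- chop(i, d = toy)
    n_oh <- sum(vapply(dec$fragments, function(f) {
      sum(!grepl("^H@", f$caps))
    }, 0L))
    total <- sum(vapply(dec$fragments, function(f) nrow(f$graph$atoms), 0L))
    expect_equal(total, nrow(i$graph$atoms) + n_oh, info = id)
    # member lists partition the parent's heavy atoms
    members <- unlist(lapply(dec$fragments, function(f) f$members))
    expect_setequal(members, i$graph$atoms$name)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("an empty cut list returns the parent as one fragment", {
  e <- make_entry(list(list(comp_id = "MAN", count = 1)), seed = 6,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, bonds = list(), d = toy)
  expect_length(dec$fragments, 1)
  expect_equal(dec$fragments[[1]]$match$top_hit, "MAN")
})

test_that("ordering modes permute the fragments as documented", {
  e <- make_entry(list(list(comp_id = "LPR", count = 1)), seed = 4,
                  dict = toy)
  dec <- chop(extract_instances(e, toy)[[1]], d = toy)
  hits <- function(d) vapply(d$fragments, function(f) f$match$top_hit, "")
  expect_equal(hits(order_sequence(dec, "reverse")),
               c("PRO", "LYS", "CLT"))
  # reversing twice is the identity
  expect_equal(hits(order_sequence(order_sequence(dec, "reverse"),
                                   "reverse")), hits(dec))
  expect_equal(hits(order_sequence(dec, "rotate:2")),
               c("LYS", "PRO", "CLT"))
})

test_that("invalid cuts are rejected", {
  # a ring bond whose removal does not separate its ends
  gp <- graph_from_definition(dict_get(toy, "PYR"))
  expect_error(chop(gp, bonds = list(c("C2", "N1")), d = toy),
               "does not open")
  # a non-C-N bond has no capping rule
  gb <- graph_from_definition(dict_get(toy, "BNZ"))
  expect_error(chop(gb, bonds = list(c("C1", "C2"))), "C-N")
  # branched topology requires manual ordering
  e <- make_entry(list(list(comp_id = "LPR", count = 1)), seed = 4,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  expect_error(chop(i, bonds = list(c("C2", "N1"), c("C", "N2"),
                                    c("CE", "NZ")), d = toy),
               "branched")
})

test_that("polymer-mode application yields matchable sequential residues", {
  e <- make_entry(list(list(comp_id = "GGG", count = 1)), seed = 3,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, d = toy)
  e2 <- apply_chop_to_entry(e, dec, "polymer")
  rs <- entry_residues(e2)
  expect_equal(nrow(rs), 3)
  expect_equal(rs$comp_id, rep("GLY", 3))
  expect_equal(rs$resno, c(1001L, 1002L, 1003L))
  expect_false(any(rs$hetero))
  # re-extraction matches each residue at 100 against the fragment hits
  for (ri in extract_instances(e2, toy, standard_ids = character())) {
    res <- match_instance(ri, toy)
    expect_equal(res$top_hit, "GLY")
    expect_equal(res$status, "passed")
    expect_all_perfect(res$candidates[[1]]$score)
  }
})

test_that("subcomponent mode records the ordered code list", {
  e <- make_entry(list(list(comp_id = "LPR", count = 1)), seed = 4,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, d = toy)
  e2 <- apply_chop_to_entry(e, dec, "subcomponent")
  expect_equal(entry_residues(e2)$comp_id, "LPR")   # parent kept
  expect_equal(e2$subcomponents[[paste("C", 1001, "", sep = "_")]],
               c("CLT", "LYS", "PRO"))
})

test_that("unmatched fragments block application", {
  e <- make_entry(list(list(comp_id = "GGG", count = 1)), seed = 3,
                  dict = toy)
  i <- extract_instances(e, toy)[[1]]
  dec <- chop(i, d = NULL)    # no dictionary: fragments unmatched
  expect_error(apply_chop_to_entry(e, dec, "polymer"), "without a")
})
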