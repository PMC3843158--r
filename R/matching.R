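# Candidate search, composite scoring, ranking, match status, nomenclature
# standardization, new-ID assignment and redundancy checking.
#
# Candidate generation requires full heavy-atom element-labeled graph
# isomorphism (prescreened by element-count vector); instances with missing
# atoms fall back to an induced subgraph-isomorphism pass. Isomorphism
# enumeration is igraph's VF2.

.SCORE_CATS <- c("heavy_atoms", "chiral_count", "handedness", "aromatic",
                 "bond_order")

to_igraph <- function(g, colors) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds)) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j))
  }
  ig
}

element_colors <- function(g1, g2) {
  els <- sort(unique(c(g1$atoms$element, g2$atoms$element)))
  list(c1 = match(g1$atoms$element, els), c2 = match(g2$atoms$element, els))
}

# all element-preserving isomorphisms g1 -> g2, as integer vectors
iso_mappings <- function(g1, g2) {
  if (nrow(g1$atoms) != nrow(g2$atoms)) return(list())
  if (element_count_key(g1$atoms$element) !=
      element_count_key(g2$atoms$element)) return(list())
  cl <- element_colors(g1, g2)
  maps <- igraph::graph.get.isomorphisms.vf2(
    to_igraph(g1), to_igraph(g2),
    vertex.color1 = cl$c1, vertex.color2 = cl$c2)
  # igraph returns vectors indexed by g2's vertices (the g2 -> g1
  # correspondence); invert to get g1 -> g2
  lapply(maps, function(r) {
    r <- as.integer(r)
    m <- integer(length(r))
    m[r] <- seq_along(r)
    m
  })
}

# induced element-preserving subgraph isomorphisms small -> big
subiso_mappings <- function(small, big) {
  if (nrow(small$atoms) >= nrow(big$atoms)) return(list())
  cl <- element_colors(big, small)
  maps <- igraph::graph.get.subisomorphisms.vf2(
    to_igraph(big), to_igraph(small),
    vertex.color1 = cl$c1, vertex.color2 = cl$c2)
  maps <- lapply(maps, as.integer)
  # keep only induced embeddings: every big-graph edge between image atoms
  # must correspond to a small-graph edge
  nb <- nrow(small$bonds)
  Filter(function(m) {
    img <- m
    cnt <- sum(big$bonds$i %in% img & big$bonds$j %in% img)
    cnt == nb
  }, maps)
}

order_multiset <- function(g, i) {
  k <- which(g$bonds$i == i | g$bonds$j == i)
  paste(sort(g$bonds$order[k]), collapse = ",")
}

# core scorer: mapping m is instance-index -> definition-index (NA allowed)
score_graphs <- function(gi, gd, m) {
  nd <- nrow(gd$atoms)
  inv <- rep(NA_integer_, nd)
  mapped <- which(!is.na(m))
  inv[m[mapped]] <- mapped
  pct <- function(matched, elig) if (elig == 0) NA_real_ else
    100 * matched / elig
  # heavy atoms
  h_elig <- nd
  h_match <- sum(vapply(seq_len(nd), function(j) {
    !is.na(inv[j]) && gi$atoms$element[inv[j]] == gd$atoms$element[j]
  }, TRUE))
  # chiral-center count (independent of handedness)
  dchir <- which(gd$atoms$chiral)
  c_match <- sum(vapply(dchir, function(j) {
    !is.na(inv[j]) && gi$atoms$chiral[inv[j]]
  }, TRUE))
  # handedness among centers chiral on both sides
  both <- dchir[vapply(dchir, function(j) {
    !is.na(inv[j]) && gi$atoms$chiral[inv[j]]
  }, TRUE)]
  p_match <- sum(vapply(both, function(j) {
    gd$atoms$parity[j] != 0L && gi$atoms$parity[inv[j]] == gd$atoms$parity[j]
  }, TRUE))
  # aromatic atoms
  darom <- which(gd$atoms$aromatic)
  a_match <- sum(vapply(darom, function(j) {
    !is.na(inv[j]) && gi$atoms$aromatic[inv[j]]
  }, TRUE))
  # per-atom incident bond-order multisets
  b_match <- sum(vapply(seq_len(nd), function(j) {
    !is.na(inv[j]) && order_multiset(gd, j) == order_multiset(gi, inv[j])
  }, TRUE))
  structure(c(heavy_atoms = pct(h_match, h_elig),
              chiral_count = pct(c_match, length(dchir)),
              handedness = pct(p_match, length(both)),
              aromatic = pct(a_match, length(darom)),
              bond_order = pct(b_match, nd)),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  v <- ifelse(is.na(unclass(x)), "-", sprintf("%g", unclass(x)))
  cat(paste(.SCORE_CATS, v, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Among all isomorphisms, prefer the mapping maximizing handedness matches,
# then bond-order matches; remaining ties broken by the lexicographically
# smallest definition-index sequence (deterministic).
best_mapping <- function(gi, gd, maps) {
  if (length(maps) == 1) return(maps[[1]])
  keyed <- lapply(maps, function(m) {
    s <- unclass(score_graphs(gi, gd, m))
    c(h = ifelse(is.na(s["handedness"]), 0, s["handedness"]),
      b = ifelse(is.na(s["bond_order"]), 0, s["bond_order"]))
  })
  hvec <- vapply(keyed, function(k) k[1], 0)
  bvec <- vapply(keyed, function(k) k[2], 0)
  best <- which(hvec == max(hvec))
  best <- best[bvec[best] == max(bvec[best])]
  if (length(best) > 1) {
    seqs <- vapply(maps[best], function(m) {
      paste(sprintf("%04d", m), collapse = ",")
    }, "")
    best <- best[order(seqs)][1]
  } else best <- best[1]
  maps[[best]]
}

instance_graph <- function(i) {
  if (inherits(i, "component_instance")) i$graph
  else if (inherits(i, "molgraph")) i
  else stop("expected a component_instance or molgraph")
}

definition_graph <- function(def, form = "full") {
  if (inherits(def, "molgraph")) return(def)
  graph_from_definition(def, drop_leaving = identical(form, "linked"))
}

#' Find dictionary candidates for an instance
#'
#' Candidates are definitions whose heavy-atom element-labeled graph is
#' isomorphic to the instance's graph (bond order, aromaticity and stereo
#' are ignored at this stage), prescreened by element-count vector equality.
#' Both the full definition and, where leaving-flag atoms exist, its
#' linked/polymer form are tried. If the strict pass returns nothing, a
#' fallback induced subgraph-isomorphism pass (instance contained in
#' definition) handles instances with missing (unobserved) atoms. The
#' mapping returned for each candidate is the score-maximizing isomorphism.
#'
#' @param i A \code{component_instance} or \code{molgraph}.
#' @param d A \code{chem_comp_dict}.
#' @param k Maximum number of candidates returned.
#' @return List of candidates: \code{list(comp_id, form, mapping)} with
#'   \code{mapping} a named character vector (instance atom -> definition
#'   atom).
#' @export
find_candidates <- function(i, d, k = 10L) {
  gi <- instance_graph(i)
  out <- list()
  key <- element_count_key(gi$atoms$element)
  hits <- d$index[[key]]
  if (!is.null(hits)) {
    for (r in seq_len(nrow(hits))) {
      def <- dict_get(d, hits$comp_id[r])
      gd <- definition_graph(def, hits$form[r])
      maps <- iso_mappings(gi, gd)
      if (!length(maps)) next
      m <- best_mapping(gi, gd, maps)
      out[[length(out) + 1]] <- list(
        comp_id = def$comp_id, form = hits$form[r],
        mapping = stats::setNames(gd$atoms$name[m], gi$atoms$name),
        .gi = gi, .gd = gd, .m = m)
    }
  }
  if (!length(out)) {
    # missing-atom fallback: instance must embed as an induced subgraph
    ni <- table(gi$atoms$element)
    for (id in sort(names(d$defs))) {
      def <- d$defs[[id]]
      gd <- definition_graph(def, "full")
      ndf <- table(gd$atoms$element)
      if (nrow(gd$atoms) <= nrow(gi$atoms)) next
      if (!all(names(ni) %in% names(ndf)) ||
          !all(ni <= ndf[names(ni)])) next
      maps <- subiso_mappings(gi, gd)
      if (!length(maps)) next
      m <- best_mapping(gi, gd, maps)
      out[[length(out) + 1]] <- list(
        comp_id = def$comp_id, form = "partial",
        mapping = stats::setNames(gd$atoms$name[m], gi$atoms$name),
        .gi = gi, .gd = gd, .m = m)
    }
  }
  if (length(out) > k) out <- out[seq_len(k)]
  out
}

#' Composite score of an instance against a definition
#'
#' Five categories, each 100 x matched / eligible with the eligible set
#' taken from the definition side: heavy atoms (same element under the
#' mapping), chiral-center count (independent of handedness), handedness
#' (among centers chiral on both sides, equal parity), aromatic atoms, and
#' bond order (per-atom incident heavy-bond order multisets, aromatic bonds
#' comparing as their own order). An empty eligible set gives NA ("n/a").
#'
#' @param i A \code{component_instance} or perceived \code{molgraph}.
#' @param def A \code{chem_comp} definition or its \code{molgraph}.
#' @param mapping Named character vector: instance atom -> definition atom.
#' @param form \code{"full"} or \code{"linked"} (leaving atoms removed)
#'   when \code{def} is a definition.
#' @return A \code{composite_score}: named numeric of five percentages
#'   (NA = category not applicable).
#' @export
composite_score <- function(i, def, mapping, form = "full") {
  gi <- instance_graph(i)
  gd <- definition_graph(def, form)
  if (!all(names(mapping) %in% gi$atoms$name)) {
    stop("mapping references unknown instance atom(s): ",
         paste(setdiff(names(mapping), gi$atoms$name), collapse = ", "))
  }
  if (!all(mapping %in% gd$atoms$name)) {
    stop("mapping references unknown definition atom(s): ",
         paste(setdiff(mapping, gd$atoms$name), collapse = ", "))
  }
  m <- rep(NA_integer_, nrow(gi$atoms))
  m[match(names(mapping), gi$atoms$name)] <- match(mapping, gd$atoms$name)
  score_graphs(gi, gd, m)
}

score_means <- function(s) {
  v <- unclass(s)
  if (all(is.na(v))) 100 else mean(v, na.rm = TRUE)
}

all_perfect <- function(s) {
  v <- unclass(s)
  all(is.na(v) | v == 100)
}

#' Rank scored candidates
#'
#' Descending sort key: (1) deposited-id equality with exact chemistry
#' (all defined categories 100), (2) mean of the defined category
#' percentages, (3) handedness percentage (n/a sorts last), (4) ascending
#' component code. Deterministic.
#'
#' @param candidates List of candidates, each carrying \code{comp_id} and
#'   \code{score} (a \code{composite_score}).
#' @param deposited_id The instance's deposited component code.
#' @return The reordered candidate list.
#' @export
rank_candidates <- function(candidates, deposited_id = NA_character_) {
  if (length(candidates) <= 1) return(candidates)
  key1 <- vapply(candidates, function(cd) {
    as.numeric(!is.na(deposited_id) && cd$comp_id == deposited_id &&
                 all_perfect(cd$score))
  }, 0)
  key2 <- vapply(candidates, function(cd) score_means(cd$score), 0)
  key3 <- vapply(candidates, function(cd) {
    h <- unclass(cd$score)["handedness"]
    if (is.na(h)) -1 else h
  }, 0)
  key4 <- vapply(candidates, function(cd) cd$comp_id, "")
  candidates[order(-key1, -key2, -key3, key4)]
}

#' Assign the match status of a ranked result
#'
#' \code{passed} iff the top hit scores 100 (or n/a) in every category and
#' its code equals the deposited code; \code{close match} iff candidates
#' exist but a category falls short or the codes differ; \code{no match}
#' iff there are no candidates.
#'
#' @param result A \code{match_result} with ranked candidates.
#' @param deposited_id Deposited component code (defaults to the result's).
#' @return The result with \code{status} (and \code{top_hit}) set.
#' @export
assign_status <- function(result, deposited_id = result$deposited_id) {
  if (!length(result$candidates)) {
    result$top_hit <- NA_character_
    result$status <- "no match"
    return(result)
  }
  top <- result$candidates[[1]]
  result$top_hit <- top$comp_id
  result$status <- if (all_perfect(top$score) &&
                       !is.na(deposited_id) &&
                       top$comp_id == deposited_id) "passed"
                   else "close match"
  result
}

#' Match one instance against the dictionary
#'
#' Runs candidate search, composite scoring, ranking and status
#' assignment.
#'
#' @param i A \code{component_instance} (or perceived \code{molgraph}).
#' @param d A \code{chem_comp_dict}.
#' @param deposited_id Deposited code (defaults to the instance's).
#' @param k Maximum candidates kept.
#' @return A \code{match_result}: instance key, deposited id, ranked
#'   candidates (comp_id, score, mapping), top hit and status.
#' @export
match_instance <- function(i, d, deposited_id = NULL, k = 10L) {
  gi <- instance_graph(i)
  if (is.null(deposited_id)) {
    deposited_id <- if (inherits(i, "component_instance")) i$comp_id
                    else NA_character_
  }
  raw <- find_candidates(i, d, k = max(k, length(d$defs)))
  cands <- lapply(raw, function(cd) {
    m <- rep(NA_integer_, nrow(gi$atoms))
    m[match(names(cd$mapping), gi$atoms$name)] <-
      match(cd$mapping, cd$.gd$atoms$name)
    list(comp_id = cd$comp_id, form = cd$form,
         score = score_graphs(gi, cd$.gd, m), mapping = cd$mapping)
  })
  cands <- rank_candidates(cands, deposited_id)
  if (length(cands) > k) cands <- cands[seq_len(k)]
  res <- structure(list(
    key = if (inherits(i, "component_instance")) i$key else NA_character_,
    chain = if (inherits(i, "component_instance")) i$chain else NA,
    resno = if (inherits(i, "component_instance")) i$resno else NA,
    ins = if (inherits(i, "component_instance")) i$ins else "",
    deposited_id = deposited_id,
    candidates = cands, top_hit = NA_character_, status = NA_character_),
    class = "match_result")
  assign_status(res)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$key %||% "?", " deposited=", x$deposited_id,
      " top_hit=", x$top_hit %||% "-", " status=", x$status, "\n", sep = "")
  if (length(x$candidates)) {
    for (cd in x$candidates) {
      cat("  ", cd$comp_id, ": ", sep = "")
      print(cd$score)
    }
  }
  invisible(x)
}

#' Extract component instances from an entry
#'
#' One instance per hetero residue plus every non-standard polymer residue;
#' waters are skipped by default. Inter-residue covalent contacts are
#' recorded as linkage records on each instance (instances are never fused
#' across residues; the linkage records carry the connectivity).
#'
#' @param e A \code{structure_entry}.
#' @param d A \code{chem_comp_dict} (consulted only for water codes here;
#'   matching happens separately).
#' @param include_waters Keep water residues as instances.
#' @param standard_ids Component codes treated as standard polymer residues
#'   (skipped when the residue is polymer-flagged).
#' @param link Record inter-residue covalent/coordination linkages.
#' @return List of \code{component_instance} objects in (chain, residue)
#'   order, each with a perceived graph.
#' @export
extract_instances <- function(e, d = NULL, include_waters = FALSE,
                              standard_ids = .STANDARD_POLYMER,
                              link = TRUE) {
  rs <- entry_residues(e)
  sel <- rs$hetero | !(rs$comp_id %in% standard_ids)
  if (!include_waters) sel <- sel & !(rs$comp_id %in% .WATER_IDS)
  rs <- rs[sel, , drop = FALSE]
  out <- list()
  idx <- 0L
  for (r in seq_len(nrow(rs))) {
    a <- residue_atoms(e, rs$chain[r], rs$resno[r], rs$ins[r])
    a <- a[a$element != "H", , drop = FALSE]
    if (!nrow(a)) next
    idx <- idx + 1L
    g <- perceive(data.frame(name = a$atom_id, element = a$element,
                             x = a$x, y = a$y, z = a$z,
                             stringsAsFactors = FALSE))
    inst <- structure(list(
      key = paste(idx, rs$chain[r], rs$comp_id[r], rs$resno[r], sep = "_"),
      index = idx, chain = rs$chain[r], resno = rs$resno[r],
      ins = rs$ins[r], comp_id = rs$comp_id[r],
      graph = g, linkages = NULL, caps = character()),
      class = "component_instance")
    if (link) inst$linkages <- detect_linkages(inst, e)
    out[[idx]] <- inst
  }
  out
}

#' @export
print.component_instance <- function(x, ...) {
  cat("<component_instance> ", x$key, ": ", nrow(x$graph$atoms),
      " heavy atoms", sep = "")
  if (!is.null(x$linkages) && nrow(x$linkages)) {
    cat(", ", nrow(x$linkages), " linkage(s)", sep = "")
  }
  if (length(x$caps)) cat(", caps:", paste(x$caps, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Match every instance of an entry
#'
#' @inheritParams extract_instances
#' @return List of \code{match_result} objects, one per instance.
#' @export
match_entry <- function(e, d, include_waters = FALSE) {
  lapply(extract_instances(e, d, include_waters = include_waters),
         function(i) match_instance(i, d))
}

#' Standardize nomenclature of an entry
#'
#' Rewrites instance atom names and residue component codes through each
#' instance's top-hit mapping; coordinates are unchanged and a rename log
#' is returned. An unresolved ("no match") instance is an error: a new
#' definition must be created first.
#'
#' @param e A \code{structure_entry}.
#' @param results List of \code{match_result} (from [match_entry()]).
#' @return \code{list(entry = <updated entry>, log = <data.frame>)}.
#' @export
standardize_nomenclature <- function(e, results) {
  unresolved <- Filter(function(r) r$status == "no match", results)
  if (length(unresolved)) {
    stop("unresolved instance(s) with no dictionary match: ",
         paste(vapply(unresolved, function(r) r$key, ""), collapse = ", "),
         "; create a new definition first")
  }
  log <- data.frame(chain = character(), resno = integer(),
                    old_comp = character(), new_comp = character(),
                    old_atom = character(), new_atom = character(),
                    stringsAsFactors = FALSE)
  for (r in results) {
    top <- r$candidates[[1]]
    rows <- which(e$atoms$chain == r$chain & e$atoms$resno == r$resno &
                    e$atoms$ins == r$ins)
    for (ri in rows) {
      old_a <- e$atoms$atom_id[ri]
      new_a <- if (old_a %in% names(top$mapping))
        unname(top$mapping[old_a]) else old_a
      old_c <- e$atoms$comp_id[ri]
      if (!identical(old_a, new_a) || !identical(old_c, top$comp_id)) {
        log <- rbind(log, data.frame(
          chain = r$chain, resno = r$resno, old_comp = old_c,
          new_comp = top$comp_id, old_atom = old_a, new_atom = new_a,
          stringsAsFactors = FALSE))
      }
      e$atoms$atom_id[ri] <- new_a
      e$atoms$comp_id[ri] <- top$comp_id
    }
  }
  list(entry = e, log = log)
}

.ID_ALPHABET <- c(0:9, LETTERS)

#' Assign a new component code
#'
#' Returns the requested code when free, otherwise the lexicographically
#' first unused 3-character code over 0-9A-Z.
#'
#' @param d A \code{chem_comp_dict}.
#' @param requested Optional requested code.
#' @return A free component code.
#' @export
assign_new_id <- function(d, requested = NULL) {
  if (!is.null(requested)) {
    requested <- toupper(requested)
    if (dict_has(d, requested)) {
      stop("requested comp_id already in dictionary: ", requested)
    }
    return(requested)
  }
  n <- length(.ID_ALPHABET)
  for (code in seq_len(n^3) - 1L) {
    id <- paste0(.ID_ALPHABET[code %/% n^2 + 1],
                 .ID_ALPHABET[(code %/% n) %% n + 1],
                 .ID_ALPHABET[code %% n + 1])
    if (!dict_has(d, id)) return(id)
  }
  stop("component code space exhausted")
}

#' Redundancy check of a new definition against the dictionary
#'
#' Reports component codes of existing definitions whose graphs are
#' isomorphic to the new definition with every defined composite-score
#' category at 100. An empty result means the definition is safe to commit.
#'
#' @param new_def A \code{chem_comp} definition.
#' @param d A \code{chem_comp_dict}.
#' @return Character vector of duplicate component codes (possibly empty).
#' @export
redundancy_check <- function(new_def, d) {
  gi <- graph_from_definition(new_def)
  dup <- character()
  key <- element_count_key(gi$atoms$element)
  hits <- d$index[[key]]
  if (is.null(hits)) return(dup)
  for (r in which(hits$form == "full")) {
    id <- hits$comp_id[r]
    if (identical(id, new_def$comp_id)) next
    gd <- definition_graph(dict_get(d, id), "full")
    maps <- iso_mappings(gi, gd)
    if (!length(maps)) next
    m <- best_mapping(gi, gd, maps)
    if (all_perfect(score_graphs(gi, gd, m))) dup <- c(dup, id)
  }
  dup
}
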