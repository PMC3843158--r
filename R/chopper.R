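# Decomposition ("chopping") of peptide-like ligands into capped,
# free-neutral subcomponents that are matched against the dictionary and
# ordered N-terminus to C-terminus.

#' Select cleavage bonds of a peptide-like molecule
#'
#' Returns every acyclic C-N bond where either (a) the carbon bears a
#' double-bonded oxygen (a true amide), or (b) the carbon is attached to a
#' free-carboxyl carbon and the nitrogen is a secondary amine that is not
#' an amide nitrogen (the N-alkyl pseudo-peptide bond of lisinopril-type
#' backbones). The selection is a default: callers may add or remove bonds
#' before chopping.
#'
#' @param g A perceived \code{molgraph}.
#' @return List of length-2 character vectors \code{c(carbon, nitrogen)}.
#' @export
select_cleavage_bonds <- function(g) {
  adj <- adjacency_list(g)
  rings <- smallest_rings(g, max_size = 12)
  in_ring <- function(i, j) {
    for (rg in rings) {
      pi <- match(i, rg); pj <- match(j, rg)
      if (!is.na(pi) && !is.na(pj) &&
          (abs(pi - pj) == 1 || abs(pi - pj) == length(rg) - 1)) return(TRUE)
    }
    FALSE
  }
  has_double_o <- function(i) {
    k <- which((g$bonds$i == i | g$bonds$j == i) & g$bonds$order == "double")
    other <- ifelse(g$bonds$i[k] == i, g$bonds$j[k], g$bonds$i[k])
    any(g$atoms$element[other] == "O")
  }
  has_single_o <- function(i) {
    k <- which((g$bonds$i == i | g$bonds$j == i) & g$bonds$order == "single")
    other <- ifelse(g$bonds$i[k] == i, g$bonds$j[k], g$bonds$i[k])
    any(g$atoms$element[other] == "O")
  }
  is_carboxyl <- function(i) {
    g$atoms$element[i] == "C" && has_double_o(i) && has_single_o(i)
  }
  is_amide_n <- function(i) {
    any(vapply(adj[[i]], function(k) {
      g$atoms$element[k] == "C" && has_double_o(k)
    }, TRUE))
  }
  out <- list()
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    els <- g$atoms$element[c(i, j)]
    if (!setequal(els, c("C", "N"))) next
    ci <- if (els[1] == "C") i else j
    ni <- if (els[1] == "C") j else i
    if (in_ring(ci, ni)) next
    rule_a <- has_double_o(ci)
    rule_b <- !rule_a &&
      any(vapply(setdiff(adj[[ci]], ni), is_carboxyl, TRUE)) &&
      length(adj[[ni]]) >= 2 && !is_amide_n(ni)
    if (rule_a || rule_b) {
      out[[length(out) + 1]] <- c(g$atoms$name[ci], g$atoms$name[ni])
    }
  }
  out
}

unique_cap_name <- function(existing, base = "OXC") {
  if (!base %in% existing) return(base)
  k <- 1
  repeat {
    nm <- paste0(base, k)
    if (!nm %in% existing) return(nm)
    k <- k + 1
  }
}

#' Chop a molecule along cleavage bonds
#'
#' Removes the given bonds; the carbonyl/carbon side of each cut is capped
#' with a hydroxyl oxygen (-OH) and the nitrogen side with an implicit
#' hydrogen (-H), restoring each fragment to its free, neutral state. Each
#' capped fragment is matched against the dictionary and the fragments are
#' ordered N-terminus to C-terminus by default.
#'
#' @param g A perceived \code{molgraph} or \code{component_instance}.
#' @param bonds List of length-2 character vectors (carbon atom, nitrogen
#'   atom); defaults to [select_cleavage_bonds()].
#' @param d A \code{chem_comp_dict} for fragment matching.
#' @param deposited_id Parent component code carried into fragment match
#'   results.
#' @return A \code{decomposition}: parent, cleaved-bond table, and ordered
#'   fragments each holding the capped graph, member-atom list, cap-atom
#'   list and \code{match_result}.
#' @export
chop <- function(g, bonds = NULL, d = NULL, deposited_id = NULL) {
  inst <- if (inherits(g, "component_instance")) g else NULL
  if (!is.null(inst)) {
    if (is.null(deposited_id)) deposited_id <- inst$comp_id
    g <- inst$graph
  }
  if (is.null(bonds)) bonds <- select_cleavage_bonds(g)
  nms <- g$atoms$name
  cut <- data.frame(atom_c = character(), atom_n = character(),
                    i = integer(), j = integer(), stringsAsFactors = FALSE)
  for (b in bonds) {
    i <- match(b[1], nms); j <- match(b[2], nms)
    if (is.na(i) || is.na(j)) {
      stop("cleavage bond names unknown atom: ", paste(b, collapse = "-"))
    }
    hit <- which((g$bonds$i == i & g$bonds$j == j) |
                   (g$bonds$i == j & g$bonds$j == i))
    if (!length(hit)) {
      stop("cleavage bond ", b[1], "-", b[2], " is not an edge")
    }
    els <- g$atoms$element[c(i, j)]
    if (!setequal(els, c("C", "N"))) {
      stop("capping rules require a C-N cleavage bond, got ",
           paste(els, collapse = "-"))
    }
    if (els[1] != "C") { tmp <- i; i <- j; j <- tmp; b <- rev(b) }
    cut <- rbind(cut, data.frame(atom_c = b[1], atom_n = b[2],
                                 i = i, j = j, stringsAsFactors = FALSE))
  }
  # component labels after removing the cut bonds
  keep <- rep(TRUE, nrow(g$bonds))
  for (r in seq_len(nrow(cut))) {
    keep[(g$bonds$i == cut$i[r] & g$bonds$j == cut$j[r]) |
           (g$bonds$i == cut$j[r] & g$bonds$j == cut$i[r])] <- FALSE
  }
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (k in which(keep)) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n); ncomp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    ncomp <- ncomp + 1L
    q <- s; comp[s] <- ncomp
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- ncomp; q <- c(q, w) }
    }
  }
  same <- which(comp[cut$i] == comp[cut$j])
  if (length(same)) {
    stop("cleaving bond ", cut$atom_c[same[1]], "-", cut$atom_n[same[1]],
         " does not open the macrocycle backbone (its ends remain ",
         "connected)")
  }
  fragments <- list()
  for (f in seq_len(ncomp)) {
    members <- nms[comp == f]
    at <- g$atoms[comp == f, c("name", "element", "x", "y", "z"),
                  drop = FALSE]
    caps <- character()
    for (r in seq_len(nrow(cut))) {
      if (comp[cut$i[r]] == f) {                      # carbon side: -OH cap
        cpos <- atom_xyz(g, cut$i[r]); npos <- atom_xyz(g, cut$j[r])
        dir <- unitv(npos - cpos)
        nm <- unique_cap_name(at$name)
        at <- rbind(at, data.frame(name = nm, element = "O",
                                   x = cpos[1] + 1.40 * dir[1],
                                   y = cpos[2] + 1.40 * dir[2],
                                   z = cpos[3] + 1.40 * dir[3],
                                   stringsAsFactors = FALSE))
        caps <- c(caps, nm)
      } else if (comp[cut$j[r]] == f) {               # nitrogen side: -H cap
        caps <- c(caps, paste0("H@", cut$atom_n[r]))
      }
    }
    gf <- perceive(at)
    mres <- if (!is.null(d)) match_instance(gf, d, deposited_id =
                                              deposited_id) else NULL
    fragments[[f]] <- list(graph = gf, members = members, caps = caps,
                           match = mres)
  }
  dec <- structure(list(parent = inst %||% g, parent_id = deposited_id,
                        cleaved = cut, fragments = fragments,
                        mode = "unordered"),
                   class = "decomposition")
  if (nrow(cut)) dec <- order_sequence(dec, "auto") else dec$mode <- "auto"
  dec
}

#' @export
print.decomposition <- function(x, ...) {
  hits <- vapply(x$fragments, function(f) {
    if (is.null(f$match) || is.na(f$match$top_hit)) "-" else f$match$top_hit
  }, "")
  cat("<decomposition> ", length(x$fragments), " fragment(s), ",
      nrow(x$cleaved), " cleaved bond(s), order mode ", x$mode, "\n",
      "  sequence: ", paste(hits, collapse = " - "), "\n", sep = "")
  invisible(x)
}

fragment_of <- function(dec, atom) {
  for (f in seq_along(dec$fragments)) {
    if (atom %in% dec$fragments[[f]]$members) return(f)
  }
  NA_integer_
}

#' Order the fragments of a decomposition
#'
#' Linear backbones are ordered by following the cleaved C->N bonds from
#' the unique fragment with a free (capped) N-terminus; cyclic backbones
#' start at the fragment with the lexicographically smallest top-hit code.
#' Modes: \code{"auto"} (N to C), \code{"reverse"}, or \code{"rotate:k"}
#' (cyclic rotation starting at position k of the auto order).
#'
#' @param dec A \code{decomposition}.
#' @param mode Ordering mode.
#' @return The decomposition with fragments permuted.
#' @export
order_sequence <- function(dec, mode = "auto") {
  nf <- length(dec$fragments)
  if (!nrow(dec$cleaved) || nf == 1) { dec$mode <- mode; return(dec) }
  # non-auto modes permute the current order, so reversing twice is the
  # identity and rotations compose
  if (identical(mode, "reverse")) {
    dec$fragments <- rev(dec$fragments)
    dec$mode <- mode
    return(dec)
  }
  if (grepl("^rotate:", mode)) {
    k <- as.integer(sub("^rotate:", "", mode))
    if (is.na(k) || k < 1 || k > nf) stop("rotate index out of range")
    ord <- c(k:nf, seq_len(k - 1))
    dec$fragments <- dec$fragments[ord]
    dec$mode <- mode
    return(dec)
  }
  if (!identical(mode, "auto")) stop("unknown ordering mode: ", mode)
  from <- vapply(dec$cleaved$atom_c, function(a) fragment_of(dec, a), 0L)
  to <- vapply(dec$cleaved$atom_n, function(a) fragment_of(dec, a), 0L)
  degree <- table(factor(c(from, to), levels = seq_len(nf)))
  if (any(degree >= 3)) {
    stop("branched topology: fragment ", names(which(degree >= 3))[1],
         " takes part in 3+ cleaved bonds; order manually")
  }
  outmap <- rep(NA_integer_, nf); inn <- rep(NA_integer_, nf)
  for (k in seq_along(from)) { outmap[from[k]] <- to[k]; inn[to[k]] <- from[k] }
  starts <- which(is.na(inn))
  if (length(starts) == 1) {
    ord <- starts
    while (!is.na(outmap[ord[length(ord)]])) {
      ord <- c(ord, outmap[ord[length(ord)]])
    }
    cyclic <- FALSE
  } else if (length(starts) == 0) {
    cyclic <- TRUE
    hits <- vapply(dec$fragments, function(f) {
      if (is.null(f$match) || is.na(f$match$top_hit)) "ZZZ"
      else f$match$top_hit
    }, "")
    s <- order(hits)[1]
    ord <- s
    while (length(ord) < nf) ord <- c(ord, outmap[ord[length(ord)]])
  } else {
    stop("cleaved bonds do not form a single path or cycle")
  }
  if (length(ord) != nf) {
    stop("cleaved bonds do not form a single path or cycle")
  }
  dec$fragments <- dec$fragments[ord]
  dec$mode <- mode
  dec
}

#' Apply a decomposition to the structure entry
#'
#' Polymer mode replaces the parent residue by sequential residues carrying
#' the fragments' top-hit codes and standardized atom names (cap atoms are
#' excluded from the entry); subcomponent mode keeps the parent as one
#' residue and records the ordered subcomponent code list.
#'
#' @param e A \code{structure_entry}.
#' @param dec A \code{decomposition} whose parent is a
#'   \code{component_instance} of \code{e} and whose fragments all matched.
#' @param representation \code{"polymer"} or \code{"subcomponent"}.
#' @return The updated \code{structure_entry}.
#' @export
apply_chop_to_entry <- function(e, dec,
                                representation = c("polymer",
                                                   "subcomponent")) {
  representation <- match.arg(representation)
  inst <- dec$parent
  if (!inherits(inst, "component_instance")) {
    stop("decomposition parent is not an entry instance")
  }
  bad <- Filter(function(f) is.null(f$match) ||
                  f$match$status == "no match", dec$fragments)
  if (length(bad)) {
    stop("fragment(s) without a dictionary match; create definitions ",
         "before applying the decomposition")
  }
  hits <- vapply(dec$fragments, function(f) f$match$top_hit, "")
  key <- paste(inst$chain, inst$resno, inst$ins, sep = "_")
  if (representation == "subcomponent") {
    e$subcomponents[[key]] <- hits
    return(e)
  }
  sel <- e$atoms$chain == inst$chain & e$atoms$resno == inst$resno &
    e$atoms$ins == inst$ins
  parent_rows <- e$atoms[sel, , drop = FALSE]
  rest <- e$atoms[!sel, , drop = FALSE]
  new_rows <- list()
  for (f in seq_along(dec$fragments)) {
    fr <- dec$fragments[[f]]
    resno <- inst$resno + f - 1L
    clash <- rest$chain == inst$chain & rest$resno == resno
    if (any(clash)) {
      stop("cannot renumber fragments: residue ", inst$chain, "/", resno,
           " already exists")
    }
    top <- fr$match$candidates[[1]]
    rows <- parent_rows[parent_rows$atom_id %in% fr$members, , drop = FALSE]
    rows$atom_id <- ifelse(rows$atom_id %in% names(top$mapping),
                           unname(top$mapping[rows$atom_id]), rows$atom_id)
    rows$comp_id <- top$comp_id
    rows$resno <- resno
    rows$hetero <- FALSE
    new_rows[[f]] <- rows
  }
  e$atoms <- rbind(rest, do.call(rbind, new_rows))
  e$atoms <- e$atoms[order(e$atoms$chain, e$atoms$resno, e$atoms$ins), ,
                     drop = FALSE]
  rownames(e$atoms) <- NULL
  e
}
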