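# Perception of the chemical graph from 3D coordinates: bonds and bond
# orders (covalent-radius rules), hybridization (bond-angle sums), canonical
# atom ranks (Morgan-style refinement), chirality handedness (signed volume),
# and aromaticity (smallest rings + Hueckel electron count).

PLANARITY_THRESHOLD <- 355   # deg; 3-neighbor centers at/above are sp2
METAL_CONTACT_MAX <- 3.0     # A; metal to N/O/S coordination cutoff
BOND_TOLERANCE <- 0.40       # A; added to the sum of covalent radii

new_molgraph <- function(atoms, bonds, contacts = NULL) {
  if (is.null(contacts)) {
    contacts <- data.frame(i = integer(), j = integer(), dist = numeric())
  }
  structure(list(atoms = atoms, bonds = bonds, contacts = contacts),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds", sep = "")
  if (!is.null(x$atoms$chiral)) {
    cat(", ", sum(x$atoms$chiral), " chiral centers, ",
        sum(x$atoms$aromatic), " aromatic atoms", sep = "")
  }
  cat("\n")
  invisible(x)
}

adjacency_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

atom_xyz <- function(g, i) as.numeric(g$atoms[i, c("x", "y", "z")])

#' Perceive covalent bonds from 3D coordinates
#'
#' Two non-metal atoms are bonded iff their distance is at most the sum of
#' their single-bond covalent radii plus a tolerance (0.40 Angstrom). The
#' bond's order is classified from its length against double/triple-bond
#' radii sums. Contacts from a metal to N, O or S within 3.0 Angstrom are
#' recorded as coordination contacts, never as covalent edges, so metal
#' sites do not merge ligands. Hydrogens are excluded from the graph.
#'
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} and optionally \code{name}.
#' @param tol Distance tolerance in Angstrom.
#' @return A \code{molgraph} (bonds only; run the other perception passes or
#'   [perceive()] for derived attributes).
#' @export
perceive_bonds <- function(atoms, tol = BOND_TOLERANCE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1) stop("need at least one atom")
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element,
                                                seq_len(nrow(atoms)))
  atoms$element <- toupper(atoms$element)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0) stop("need at least one heavy atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  bad <- !known_element(atoms$element)
  if (any(bad)) {
    stop("no covalent radius entry for element(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  }
  n <- nrow(atoms)
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      aromatic = logical(), stringsAsFactors = FALSE)
  contacts <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n > 1) {
    dm <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
    metal <- is_metal(atoms$element)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- dm[i, j]
        if (metal[i] || metal[j]) {
          m <- if (metal[i]) i else j
          o <- if (metal[i]) j else i
          if (!metal[o] && atoms$element[o] %in% c("N", "O", "S") &&
              d <= METAL_CONTACT_MAX) {
            contacts <- rbind(contacts, data.frame(i = m, j = o, dist = d))
          }
          next
        }
        if (d <= covalent_threshold(atoms$element[i], atoms$element[j],
                                    tol)) {
          bonds <- rbind(bonds, data.frame(
            i = i, j = j,
            order = classify_order(atoms$element[i], atoms$element[j], d),
            aromatic = FALSE, stringsAsFactors = FALSE))
        }
      }
    }
  }
  new_molgraph(atoms, bonds, contacts)
}

#' Perceive hybridization from bond angles
#'
#' A center with three neighbors is sp2 iff the sum of its three bond angles
#' reaches the planarity threshold (355 degrees), else sp3; four or more
#' neighbors give sp3; two neighbors give sp near 180 degrees, sp2 for wide
#' (aromatic-like, >= 115 degrees) angles and sp3 otherwise; fewer than two
#' neighbors give "other".
#'
#' @param g A \code{molgraph} with coordinates and perceived bonds.
#' @return The graph with an atom column \code{hybrid}.
#' @export
perceive_hybridization <- function(g) {
  adj <- adjacency_list(g)
  n <- nrow(g$atoms)
  hyb <- character(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k >= 4) { hyb[i] <- "sp3"; next }
    if (k == 3) {
      p <- atom_xyz(g, i)
      s <- angle_deg(atom_xyz(g, nb[1]), p, atom_xyz(g, nb[2])) +
           angle_deg(atom_xyz(g, nb[1]), p, atom_xyz(g, nb[3])) +
           angle_deg(atom_xyz(g, nb[2]), p, atom_xyz(g, nb[3]))
      hyb[i] <- if (s >= PLANARITY_THRESHOLD) "sp2" else "sp3"
      next
    }
    if (k == 2) {
      a <- angle_deg(atom_xyz(g, nb[1]), atom_xyz(g, i), atom_xyz(g, nb[2]))
      hyb[i] <- if (a >= 160) "sp" else if (a >= 115) "sp2" else "sp3"
      next
    }
    hyb[i] <- "other"
  }
  g$atoms$hybrid <- hyb
  g
}

# Morgan-style canonical ranks: seeded by (element, heavy degree), refined
# by sorted neighbor-rank multisets to a fixed point. Equal inputs under
# atom relabeling yield equal rank multisets.
canonical_ranks <- function(g) {
  n <- nrow(g$atoms)
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  key <- paste(g$atoms$element, sprintf("%03d", deg))
  rank <- match(key, sort(unique(key)))
  repeat {
    key <- vapply(seq_len(n), function(i) {
      paste(sprintf("%04d", rank[i]),
            paste(sprintf("%04d", sort(rank[adj[[i]]])), collapse = ","))
    }, "")
    new_rank <- match(key, sort(unique(key)))
    if (length(unique(new_rank)) == length(unique(rank))) {
      rank <- new_rank
      break
    }
    rank <- new_rank
  }
  rank
}

#' Assign chirality handedness parity
#'
#' For each sp3 atom with at least three heavy neighbors whose canonical
#' ranks are pairwise distinct, the parity is the sign of the determinant of
#' the vectors to the three highest-ranked neighbors taken in rank order.
#' Parity is a convention-independent binary handedness: it is compared
#' between an instance and a definition computed identically on both sides.
#' All other atoms get handedness "none" (parity 0).
#'
#' @param g A \code{molgraph} with hybridization assigned.
#' @return The graph with atom columns \code{rank}, \code{chiral},
#'   \code{parity}.
#' @export
assign_handedness <- function(g) {
  n <- nrow(g$atoms)
  g$atoms$rank <- canonical_ranks(g)
  adj <- adjacency_list(g)
  chiral <- logical(n); parity <- integer(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) < 3 || g$atoms$hybrid[i] != "sp3") next
    r <- g$atoms$rank[nb]
    if (anyDuplicated(r)) next
    top <- nb[order(-r)][1:3]
    p <- atom_xyz(g, i)
    m <- cbind(atom_xyz(g, top[1]) - p,
               atom_xyz(g, top[2]) - p,
               atom_xyz(g, top[3]) - p)
    dt <- det(m)
    if (abs(dt) < 1e-6) next                 # degenerate (planar) geometry
    chiral[i] <- TRUE
    parity[i] <- if (dt > 0) 1L else -1L
  }
  g$atoms$chiral <- chiral
  g$atoms$parity <- parity
  g
}

# Smallest rings: for each bond, the shortest cycle through it (BFS in the
# graph with that bond removed); unique rings up to atom-set identity.
smallest_rings <- function(g, max_size = 8) {
  adj <- adjacency_list(g)
  rings <- list(); seen <- character()
  if (!nrow(g$bonds)) return(rings)
  for (k in seq_len(nrow(g$bonds))) {
    s <- g$bonds$i[k]; t <- g$bonds$j[k]
    # BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, nrow(g$atoms))
    prev[s] <- 0L
    q <- s
    found <- FALSE
    while (length(q) && !found) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (v == s && w == t) next
        if (is.na(prev[w])) {
          prev[w] <- v
          if (w == t) { found <- TRUE; break }
          q <- c(q, w)
        }
      }
    }
    if (!found) next
    path <- t
    v <- t
    while (prev[v] != 0L) { v <- prev[v]; path <- c(path, v) }
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

# pi-electron contribution of ring atom i within ring (vector of indices);
# NA means the ring cannot be aromatic.
pi_contribution <- function(g, i, ring, adj) {
  in_ring <- function(a, b) {
    k <- which((g$bonds$i == a & g$bonds$j == b) |
                 (g$bonds$i == b & g$bonds$j == a))
    length(k) > 0 && a %in% ring && b %in% ring
  }
  bnd <- g$bonds
  mine <- which(bnd$i == i | bnd$j == i)
  other <- ifelse(bnd$i[mine] == i, bnd$j[mine], bnd$i[mine])
  ord <- bnd$order[mine]
  ring_dbl <- any(ord %in% c("double", "aromatic") & other %in% ring)
  if (ring_dbl) return(1)
  el <- g$atoms$element[i]
  if (!is.null(g$atoms$hybrid) && g$atoms$hybrid[i] == "sp3") return(NA)
  if (el %in% c("N", "O", "S")) return(2)
  if (el == "C" && any(ord == "double" & !(other %in% ring))) return(0)
  NA
}

#' Perceive aromaticity
#'
#' Smallest-ring perception followed by a per-ring Hueckel test. Ring-atom
#' pi contributions: an atom in a ring double bond contributes 1; ring
#' N/O/S with no ring double bond contribute the lone pair (2); ring carbon
#' with an exocyclic double bond contributes 0; a ring sp3 atom (or any
#' other unhandled pattern) fails the ring. A ring with 4n+2 pi electrons is
#' aromatic: its atoms are flagged and its ring bonds reclassified to order
#' "aromatic".
#'
#' @param g A \code{molgraph} (for instances, with hybridization assigned).
#' @return The graph with atom column \code{aromatic} updated and aromatic
#'   ring bonds set to order \code{"aromatic"}.
#' @export
perceive_aromaticity <- function(g) {
  n <- nrow(g$atoms)
  if (is.null(g$atoms$aromatic)) g$atoms$aromatic <- logical(n)
  adj <- adjacency_list(g)
  for (ring in smallest_rings(g)) {
    if (length(ring) < 5) next
    contrib <- vapply(ring, function(i) {
      v <- pi_contribution(g, i, ring, adj)
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, 0)
    if (anyNA(contrib)) next
    total <- sum(contrib)
    if (total >= 2 && (total - 2) %% 4 == 0) {
      g$atoms$aromatic[ring] <- TRUE
      sel <- (g$bonds$i %in% ring) & (g$bonds$j %in% ring)
      # only the ring's own bonds, not cross-ring chords
      for (k in which(sel)) {
        a <- g$bonds$i[k]; b <- g$bonds$j[k]
        pa <- match(a, ring); pb <- match(b, ring)
        if (abs(pa - pb) == 1 || abs(pa - pb) == length(ring) - 1) {
          g$bonds$order[k] <- "aromatic"
          g$bonds$aromatic[k] <- TRUE
        }
      }
    }
  }
  g
}

#' Full perception pipeline for an instance
#'
#' Bonds, bond orders, hybridization, canonical ranks, handedness and
#' aromaticity, in that order.
#'
#' @inheritParams perceive_bonds
#' @return A fully annotated \code{molgraph}.
#' @export
perceive <- function(atoms, tol = BOND_TOLERANCE) {
  g <- perceive_bonds(atoms, tol = tol)
  g <- perceive_hybridization(g)
  g <- assign_handedness(g)
  perceive_aromaticity(g)
}

#' Build the molecular graph of a definition
#'
#' Uses the definition's stored bonds and orders; chirality comes from the
#' stereo flags (parity is computed from the idealized coordinates with the
#' same signed-volume rule used for instances); aromaticity comes from the
#' stored flags when present, otherwise it is perceived from the stored
#' orders.
#'
#' @param d A \code{chem_comp} definition.
#' @param drop_leaving Drop leaving-flag atoms first (the linked/polymer
#'   form); stereo flags that lose eligibility are dropped with them.
#' @return A \code{molgraph}.
#' @export
graph_from_definition <- function(d, drop_leaving = FALSE) {
  stopifnot(inherits(d, "chem_comp"))
  at <- d$atoms[d$atoms$element != "H", , drop = FALSE]
  if (drop_leaving) at <- at[!at$leaving, , drop = FALSE]
  keep <- at$atom_id
  bd <- d$bonds[d$bonds$atom_1 %in% keep & d$bonds$atom_2 %in% keep, ,
                drop = FALSE]
  atoms <- data.frame(name = at$atom_id, element = at$element,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = match(bd$atom_1, keep), j = match(bd$atom_2, keep),
                      order = bd$order, aromatic = bd$aromatic,
                      stringsAsFactors = FALSE)
  g <- new_molgraph(atoms, bonds)
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  # stereo flag on an under-coordinated atom is invalid on the full form;
  # in the linked form such flags are silently dropped (the center is no
  # longer determinable without its leaving substituent)
  flagged <- at$stereo %in% c("R", "S")
  if (any(flagged & deg < 3)) {
    if (!drop_leaving) {
      stop("stereo flag on atom ", at$atom_id[flagged & deg < 3][1], " of ",
           d$comp_id, " with fewer than 3 heavy neighbors")
    }
    flagged <- flagged & deg >= 3
  }
  # hybridization from stored orders
  ordsum <- vapply(seq_len(nrow(atoms)), function(i) {
    k <- which(g$bonds$i == i | g$bonds$j == i)
    if (!length(k)) return("other")
    o <- g$bonds$order[k]
    if (any(o == "triple")) "sp"
    else if (any(o == "double") || any(g$bonds$aromatic[k])) "sp2"
    else "sp3"
  }, "")
  g$atoms$hybrid <- ordsum
  g$atoms$rank <- canonical_ranks(g)
  # aromaticity: stored flags win; otherwise perceive from stored orders
  if (any(at$aromatic) || any(bd$aromatic)) {
    g$atoms$aromatic <- at$aromatic
    g$bonds$order[g$bonds$aromatic] <- "aromatic"
  } else {
    g$atoms$aromatic <- logical(nrow(atoms))
    g <- perceive_aromaticity(g)
  }
  # chirality: flagged centers; parity from idealized coordinates
  chiral <- flagged
  parity <- integer(nrow(atoms))
  for (i in which(chiral)) {
    nb <- adj[[i]]
    r <- g$atoms$rank[nb]
    if (anyDuplicated(r)) { chiral[i] <- FALSE; next }
    top <- nb[order(-r)][1:3]
    p <- atom_xyz(g, i)
    m <- cbind(atom_xyz(g, top[1]) - p, atom_xyz(g, top[2]) - p,
               atom_xyz(g, top[3]) - p)
    dt <- det(m)
    parity[i] <- if (dt > 0) 1L else if (dt < 0) -1L else 0L
  }
  g$atoms$chiral <- chiral
  g$atoms$parity <- parity
  g
}
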