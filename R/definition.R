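# Component definitions (dictionary records) and the indexed dictionary.

#' Construct a chemical component definition
#'
#' A definition is the dictionary record for one chemical component: named
#' atoms with elements, formal charges, aromatic/stereo/leaving flags and
#' idealized coordinates, plus bonds with orders and aromatic flags. The
#' molecular formula (implicit hydrogens included) is recomputed on
#' construction.
#'
#' @param comp_id Component code, 1-3 alphanumeric characters (upper-cased).
#' @param name Free-text chemical name.
#' @param atoms data.frame with columns \code{atom_id}, \code{element},
#'   and optionally \code{charge} (integer, default 0), \code{aromatic}
#'   (logical), \code{stereo} (\code{"R"}, \code{"S"} or \code{"N"}),
#'   \code{x}, \code{y}, \code{z} (idealized coordinates, Angstrom) and
#'   \code{leaving} (logical leaving-atom flag).
#' @param bonds data.frame with columns \code{atom_1}, \code{atom_2},
#'   \code{order} (\code{"single"}, \code{"double"}, \code{"triple"}) and
#'   optionally \code{aromatic} (logical). May have zero rows.
#' @param ideal_approximate Flag marking idealized coordinates that were
#'   produced by local templates after editing rather than full embedding.
#' @return An object of class \code{chem_comp}.
#' @export
component_definition <- function(comp_id, name, atoms, bonds = NULL,
                                 ideal_approximate = FALSE) {
  comp_id <- toupper(as.character(comp_id))
  if (!grepl("^[0-9A-Z]{1,3}$", comp_id)) {
    stop("comp_id must be 1-3 alphanumeric characters, got: ", comp_id)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$stereo)) atoms$stereo <- "N"
  if (is.null(atoms$leaving)) atoms$leaving <- FALSE
  if (is.null(atoms$x)) { atoms$x <- 0; atoms$y <- 0; atoms$z <- 0 }
  atoms$element <- toupper(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  if (anyDuplicated(atoms$atom_id)) {
    stop("duplicate atom names in ", comp_id, ": ",
         paste(atoms$atom_id[duplicated(atoms$atom_id)], collapse = ", "))
  }
  bad <- !known_element(atoms$element)
  if (any(bad)) {
    stop("unknown element symbol(s) in ", comp_id, ": ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  }
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(atom_1 = character(), atom_2 = character(),
                        order = character(), aromatic = logical(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    for (col in c("atom_1", "atom_2")) {
      miss <- !(bonds[[col]] %in% atoms$atom_id)
      if (any(miss)) {
        i <- which(miss)[1]
        stop("bond ", bonds$atom_1[i], "-", bonds$atom_2[i], " in ", comp_id,
             " names a missing atom: ", bonds[[col]][i])
      }
    }
    if (any(bonds$atom_1 == bonds$atom_2)) stop("self-bond in ", comp_id)
    if (!all(bonds$order %in% c("single", "double", "triple"))) {
      stop("bond order must be single/double/triple in ", comp_id)
    }
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  d <- structure(list(comp_id = comp_id, name = name,
                      formula = NA_character_, atoms = atoms, bonds = bonds,
                      ideal_approximate = isTRUE(ideal_approximate)),
                 class = "chem_comp")
  d$formula <- definition_formula(d)
  validate_definition(d)
  d
}

# Bond-order sum per atom (explicit graph, aromatic flag irrelevant: stored
# orders are kekulized).
bond_order_sums <- function(d) {
  w <- c(single = 1, double = 2, triple = 3)
  s <- stats::setNames(numeric(nrow(d$atoms)), d$atoms$atom_id)
  if (nrow(d$bonds)) {
    for (k in seq_len(nrow(d$bonds))) {
      o <- w[[d$bonds$order[k]]]
      s[d$bonds$atom_1[k]] <- s[d$bonds$atom_1[k]] + o
      s[d$bonds$atom_2[k]] <- s[d$bonds$atom_2[k]] + o
    }
  }
  s
}

#' Implicit hydrogen counts of a definition
#'
#' For every atom, the implicit hydrogen count is the smallest allowed
#' valence state (after formal-charge adjustment) minus the explicit
#' bond-order sum; explicit hydrogens in the atom table reduce the count at
#' their bonding partner. An edit that would exceed every allowed valence is
#' an error.
#'
#' @param d A \code{chem_comp} definition.
#' @return Named integer vector (heavy atoms only).
#' @export
implicit_hydrogens <- function(d) {
  sums <- bond_order_sums(d)
  heavy <- d$atoms$element != "H"
  out <- stats::setNames(integer(sum(heavy)), d$atoms$atom_id[heavy])
  for (a in names(out)) {
    i <- match(a, d$atoms$atom_id)
    vals <- effective_valences(d$atoms$element[i], d$atoms$charge[i])
    if (is.null(vals)) { out[a] <- 0L; next }          # no valence model
    if (length(vals) == 1 && vals == 0) { out[a] <- 0L; next }
    ok <- vals[vals >= sums[a]]
    if (!length(ok)) {
      stop("valence overflow at atom ", a, " of ", d$comp_id,
           ": bond-order sum ", sums[a], " exceeds allowed valence ",
           max(vals))
    }
    out[a] <- as.integer(round(min(ok) - sums[a]))
  }
  out
}

definition_formula <- function(d) {
  hill_formula(d$atoms$element, n_implicit_h = sum(implicit_hydrogens(d)))
}

validate_definition <- function(d) {
  stopifnot(inherits(d, "chem_comp"))
  # stereo flags require at least three heavy neighbors
  if (nrow(d$atoms)) {
    adj <- lapply(d$atoms$atom_id, function(a) {
      nb <- c(d$bonds$atom_2[d$bonds$atom_1 == a],
              d$bonds$atom_1[d$bonds$atom_2 == a])
      nb[d$atoms$element[match(nb, d$atoms$atom_id)] != "H"]
    })
    flagged <- d$atoms$stereo %in% c("R", "S")
    deg <- lengths(adj)
    if (any(flagged & deg < 3)) {
      bad <- d$atoms$atom_id[flagged & deg < 3][1]
      stop("stereo flag on atom ", bad, " of ", d$comp_id,
           " with fewer than 3 heavy neighbors")
    }
  }
  implicit_hydrogens(d)   # errors on valence overflow
  invisible(d)
}

n_heavy_atoms <- function(d) sum(d$atoms$element != "H")

#' @export
print.chem_comp <- function(x, ...) {
  cat("<chem_comp> ", x$comp_id, " - ", x$name, "\n",
      "  formula: ", x$formula,
      " | ", n_heavy_atoms(x), " heavy atoms, ",
      nrow(x$bonds), " bonds, ",
      sum(x$atoms$stereo %in% c("R", "S")), " stereocenters\n", sep = "")
  invisible(x)
}

## ---- dictionary -----------------------------------------------------------

#' Build a component dictionary from definitions
#'
#' The dictionary maps component codes to definitions and maintains a
#' prescreen index keyed by the heavy-atom element-count vector of each
#' definition (and, where different, of its linked/polymer form with
#' leaving-flag atoms removed).
#'
#' @param defs List of \code{chem_comp} objects.
#' @return An object of class \code{chem_comp_dict}.
#' @export
dictionary <- function(defs = list()) {
  ids <- vapply(defs, function(d) d$comp_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate comp_id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  }
  names(defs) <- ids
  d <- structure(list(defs = defs, index = NULL), class = "chem_comp_dict")
  rebuild_index(d)
}

rebuild_index <- function(dict) {
  idx <- list()
  for (d in dict$defs) {
    key_full <- element_count_key(d$atoms$element)
    idx[[key_full]] <- rbind(idx[[key_full]],
                             data.frame(comp_id = d$comp_id, form = "full"))
    if (any(d$atoms$leaving & d$atoms$element != "H")) {
      key_red <- element_count_key(d$atoms$element[!d$atoms$leaving])
      idx[[key_red]] <- rbind(idx[[key_red]],
                              data.frame(comp_id = d$comp_id,
                                         form = "linked"))
    }
  }
  dict$index <- idx
  dict
}

#' @export
print.chem_comp_dict <- function(x, ...) {
  cat("<chem_comp_dict> with", length(x$defs), "definitions:",
      paste(sort(names(x$defs)), collapse = " "), "\n")
  invisible(x)
}

#' Dictionary accessors
#'
#' @param dict A \code{chem_comp_dict}.
#' @param comp_id Component code.
#' @param def A \code{chem_comp} definition.
#' @return \code{dict_size}: number of definitions; \code{dict_get}: the
#'   definition; \code{dict_has}: logical; \code{dict_add} /
#'   \code{dict_remove}: the updated dictionary (the prescreen index is
#'   rebuilt).
#' @name dictionary-accessors
NULL

#' @rdname dictionary-accessors
#' @export
dict_size <- function(dict) length(dict$defs)

#' @rdname dictionary-accessors
#' @export
dict_get <- function(dict, comp_id) {
  d <- dict$defs[[toupper(comp_id)]]
  if (is.null(d)) stop("no definition for comp_id ", comp_id)
  d
}

#' @rdname dictionary-accessors
#' @export
dict_has <- function(dict, comp_id) toupper(comp_id) %in% names(dict$defs)

#' @rdname dictionary-accessors
#' @export
dict_add <- function(dict, def) {
  if (dict_has(dict, def$comp_id)) {
    stop("comp_id already in dictionary: ", def$comp_id)
  }
  dict$defs[[def$comp_id]] <- def
  rebuild_index(dict)
}

#' @rdname dictionary-accessors
#' @export
dict_remove <- function(dict, comp_id) {
  comp_id <- toupper(comp_id)
  if (!dict_has(dict, comp_id)) stop("no definition for comp_id ", comp_id)
  dict$defs[[comp_id]] <- NULL
  rebuild_index(dict)
}
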