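# Programmatic definition editing: add atoms, change bond orders, keep
# implicit hydrogens and descriptors (formula, aromatic flags, stereo
# eligibility) consistent, and commit new definitions to the dictionary.

# placeholder idealized position for a new atom bonded to `anchor`: local
# tetrahedral/trigonal template completion around the anchor
placeholder_position <- function(d, anchor, element) {
  g <- graph_from_definition(d)
  k <- match(anchor, g$atoms$name)
  p <- atom_xyz(g, k)
  adj <- adjacency_list(g)
  dirs <- lapply(adj[[k]], function(j) unitv(atom_xyz(g, j) - p))
  len <- single_radius(g$atoms$element[k]) + single_radius(element)
  dir <- switch(as.character(length(dirs)),
                "0" = c(1, 0, 0),
                "1" = tet_dirs1(dirs[[1]])[[1]],
                "2" = tet_dirs2(dirs[[1]], dirs[[2]])[[1]],
                tet_dir3(dirs[[1]], dirs[[2]], dirs[[3]]))
  p + len * dir
}

#' Add an atom to a definition
#'
#' The atom is appended with a placeholder idealized position from a local
#' geometry template around its anchor (the definition is flagged as having
#' approximate idealized coordinates); implicit hydrogens and the formula
#' are recomputed. Adding an explicit hydrogen decrements the implicit
#' count at its partner.
#'
#' @param d A \code{chem_comp}.
#' @param name New atom name (must be unused).
#' @param element Element symbol.
#' @param bonded_to Existing atom to bond to.
#' @param order Bond order of the new bond.
#' @return The updated definition.
#' @export
add_atom <- function(d, name, element, bonded_to, order = "single") {
  stopifnot(inherits(d, "chem_comp"))
  element <- toupper(element)
  if (name %in% d$atoms$atom_id) stop("atom name already used: ", name)
  if (!bonded_to %in% d$atoms$atom_id) {
    stop("anchor atom not in definition: ", bonded_to)
  }
  pos <- if (element == "H") {
    k <- match(bonded_to, d$atoms$atom_id)
    as.numeric(d$atoms[k, c("x", "y", "z")]) + c(1, 0, 0)
  } else placeholder_position(d, bonded_to, element)
  d$atoms <- rbind(d$atoms, data.frame(
    atom_id = name, element = element, charge = 0L, aromatic = FALSE,
    stereo = "N", leaving = FALSE, x = pos[1], y = pos[2], z = pos[3],
    stringsAsFactors = FALSE))
  d$bonds <- rbind(d$bonds, data.frame(
    atom_1 = bonded_to, atom_2 = name, order = order, aromatic = FALSE,
    stringsAsFactors = FALSE))
  d$ideal_approximate <- TRUE
  implicit_hydrogens(d)       # errors on valence overflow
  recompute_descriptors(d)
}

find_bond <- function(d, a1, a2) {
  which((d$bonds$atom_1 == a1 & d$bonds$atom_2 == a2) |
          (d$bonds$atom_1 == a2 & d$bonds$atom_2 == a1))
}

#' Change the order of an existing bond
#'
#' Implicit hydrogens at both ends are recomputed through the valence
#' model; an order that would exceed an allowed valence state is rejected.
#'
#' @param d A \code{chem_comp}.
#' @param a1,a2 Bond endpoints.
#' @param new_order \code{"single"}, \code{"double"} or \code{"triple"}.
#' @return The updated definition.
#' @export
set_bond_order <- function(d, a1, a2, new_order) {
  stopifnot(inherits(d, "chem_comp"))
  if (!new_order %in% c("single", "double", "triple")) {
    stop("invalid bond order: ", new_order)
  }
  k <- find_bond(d, a1, a2)
  if (!length(k)) stop("no bond between ", a1, " and ", a2)
  d$bonds$order[k] <- new_order
  implicit_hydrogens(d)       # errors on valence overflow
  recompute_descriptors(d)
}

#' Recompute derived descriptors of a definition
#'
#' Refreshes the Hill formula (implicit hydrogens included), aromatic flags
#' (perceived from the stored bond orders via ring + Hueckel analysis) and
#' the stereo-flag eligibility (flags on atoms that no longer have three
#' heavy neighbors are dropped). Idempotent and invariant under atom
#' reordering. Formal charges are taken as stated, never perceived.
#'
#' @param d A \code{chem_comp}.
#' @return The updated definition.
#' @export
recompute_descriptors <- function(d) {
  stopifnot(inherits(d, "chem_comp"))
  # aromatic perception from stored orders (ignore previous flags)
  tmp <- d
  tmp$atoms$aromatic <- FALSE
  tmp$bonds$aromatic <- FALSE
  g <- graph_from_definition(tmp)
  heavy_ids <- g$atoms$name
  arom_atoms <- g$atoms$name[g$atoms$aromatic]
  d$atoms$aromatic <- d$atoms$atom_id %in% arom_atoms
  d$bonds$aromatic <- d$bonds$atom_1 %in% arom_atoms &
    d$bonds$atom_2 %in% arom_atoms &
    mapply(function(x1, x2) {
      k1 <- match(x1, heavy_ids); k2 <- match(x2, heavy_ids)
      any((g$bonds$i == k1 & g$bonds$j == k2 |
             g$bonds$i == k2 & g$bonds$j == k1) &
            g$bonds$order == "aromatic")
    }, d$bonds$atom_1, d$bonds$atom_2)
  if (!nrow(d$bonds)) d$bonds$aromatic <- logical(0)
  # stereo flags only on atoms with >= 3 heavy neighbors
  adj <- adjacency_list(g)
  deg <- stats::setNames(lengths(adj), heavy_ids)
  drop <- d$atoms$stereo %in% c("R", "S") &
    (is.na(deg[d$atoms$atom_id]) | deg[d$atoms$atom_id] < 3)
  d$atoms$stereo[drop] <- "N"
  d$formula <- definition_formula(d)
  d
}

#' Commit a new definition to the dictionary
#'
#' Runs the redundancy check first; a definition whose chemistry duplicates
#' an existing component (all categories 100 under isomorphism) or whose
#' code is taken is rejected.
#'
#' @param d A \code{chem_comp_dict}.
#' @param new_def A validated \code{chem_comp} with an assigned code.
#' @return The updated dictionary.
#' @export
commit_definition <- function(d, new_def) {
  stopifnot(inherits(d, "chem_comp_dict"), inherits(new_def, "chem_comp"))
  validate_definition(new_def)
  if (dict_has(d, new_def$comp_id)) {
    stop("comp_id already in dictionary: ", new_def$comp_id)
  }
  dup <- redundancy_check(new_def, d)
  if (length(dup)) {
    stop("definition duplicates existing component(s): ",
         paste(dup, collapse = ", "))
  }
  dict_add(d, new_def)
}

#' Run a line-oriented edit script against a definition
#'
#' Commands (one per line, whitespace-separated; \code{#} comments):
#' \describe{
#'   \item{\code{addatom NAME ELEMENT ANCHOR [ORDER]}}{add an atom}
#'   \item{\code{bond A1 A2 [ORDER]}}{add a bond between existing atoms}
#'   \item{\code{order A1 A2 ORDER}}{change a bond order}
#'   \item{\code{commit}}{redundancy-check and commit to the dictionary}
#' }
#'
#' @param dict A \code{chem_comp_dict}.
#' @param def The \code{chem_comp} being edited.
#' @param lines Character vector of commands.
#' @return \code{list(dict = , def = , committed = logical)}.
#' @export
run_edit_script <- function(dict, def, lines) {
  committed <- FALSE
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    tk <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (!length(tk) || tk[1] == "") next
    switch(tk[1],
      addatom = {
        def <- add_atom(def, tk[2], tk[3], tk[4],
                        if (length(tk) >= 5) tk[5] else "single")
      },
      bond = {
        if (length(find_bond(def, tk[2], tk[3]))) {
          stop("bond already exists: ", tk[2], "-", tk[3])
        }
        def$bonds <- rbind(def$bonds, data.frame(
          atom_1 = tk[2], atom_2 = tk[3],
          order = if (length(tk) >= 4) tk[4] else "single",
          aromatic = FALSE, stringsAsFactors = FALSE))
        validate_definition(def)
        def <- recompute_descriptors(def)
      },
      order = { def <- set_bond_order(def, tk[2], tk[3], tk[4]) },
      commit = { dict <- commit_definition(dict, def); committed <- TRUE },
      stop("unknown edit command: ", tk[1])
    )
  }
  list(dict = dict, def = def, committed = committed)
}
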