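# Covalent/coordination linkage detection between an instance and its
# surroundings, and leaving-group augmentation so that the absolute
# stereochemistry of covalent attachment points becomes determinable.

CAP_CO_LENGTH <- 1.43   # A, carbon attachment -> hydroxyl-oxygen cap
CAP_NH_LENGTH <- 1.01   # A, nitrogen/oxygen attachment -> implicit H cap

#' Detect linkages between an instance and the rest of the entry
#'
#' Every inter-residue contact satisfying the covalent-distance rule is
#' reported as covalent; metal contacts to N/O/S within the coordination
#' cutoff are reported as coordination.
#'
#' @param i A \code{component_instance}.
#' @param e The \code{structure_entry} it came from.
#' @return data.frame with columns \code{atom}, \code{partner_chain},
#'   \code{partner_resno}, \code{partner_ins}, \code{partner_comp},
#'   \code{partner_atom}, \code{dist}, \code{class} and partner coordinates
#'   \code{px}, \code{py}, \code{pz}.
#' @export
detect_linkages <- function(i, e) {
  out <- data.frame(atom = character(), partner_chain = character(),
                    partner_resno = integer(), partner_ins = character(),
                    partner_comp = character(), partner_atom = character(),
                    dist = numeric(), class = character(),
                    px = numeric(), py = numeric(), pz = numeric(),
                    stringsAsFactors = FALSE)
  a <- e$atoms
  ext <- a[!(a$chain == i$chain & a$resno == i$resno & a$ins == i$ins) &
             a$element != "H", , drop = FALSE]
  if (!nrow(ext)) return(out)
  gi <- i$graph
  for (k in seq_len(nrow(gi$atoms))) {
    el1 <- gi$atoms$element[k]
    p1 <- atom_xyz(gi, k)
    dx <- ext$x - p1[1]; dy <- ext$y - p1[2]; dz <- ext$z - p1[3]
    dd <- sqrt(dx * dx + dy * dy + dz * dz)
    # covalent rule (non-metal pairs)
    for (j in which(dd <= 3.5)) {
      el2 <- ext$element[j]
      cls <- NA_character_
      if (is_metal(el1) || is_metal(el2)) {
        other <- if (is_metal(el1)) el2 else el1
        if (!is_metal(other) && other %in% c("N", "O", "S") &&
            dd[j] <= METAL_CONTACT_MAX) {
          cls <- "coordination"
        }
      } else if (dd[j] <= covalent_threshold(el1, el2)) {
        cls <- "covalent"
      }
      if (!is.na(cls)) {
        out <- rbind(out, data.frame(
          atom = gi$atoms$name[k], partner_chain = ext$chain[j],
          partner_resno = ext$resno[j], partner_ins = ext$ins[j],
          partner_comp = ext$comp_id[j], partner_atom = ext$atom_id[j],
          dist = dd[j], class = cls,
          px = ext$x[j], py = ext$y[j], pz = ext$z[j],
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Augment an instance with leaving-group cap atoms
#'
#' For each covalent linkage, a cap is appended along the direction from
#' the attachment atom to the former partner at a standard bond length: a
#' hydroxyl oxygen (implicit H) when the attachment atom is carbon, an
#' implicit hydrogen when it is nitrogen or oxygen. Coordinates of existing
#' atoms never change; the capped instance is re-perceived so the
#' attachment center's handedness becomes defined (unless the center is
#' geometrically sp2, which takes precedence).
#'
#' @param i A \code{component_instance}.
#' @param links Linkage table from [detect_linkages()] (defaults to the
#'   instance's own records); only covalent rows are used.
#' @return The capped \code{component_instance} (unchanged if there are no
#'   covalent linkages).
#' @export
add_leaving_group <- function(i, links = i$linkages) {
  if (is.null(links) || !nrow(links)) return(i)
  links <- links[links$class == "covalent", , drop = FALSE]
  if (!nrow(links)) return(i)
  g <- i$graph
  atoms <- data.frame(name = g$atoms$name, element = g$atoms$element,
                      x = g$atoms$x, y = g$atoms$y, z = g$atoms$z,
                      stringsAsFactors = FALSE)
  adj <- adjacency_list(g)
  caps <- character()
  capn <- 0L
  for (r in seq_len(nrow(links))) {
    at <- links$atom[r]
    k <- match(at, g$atoms$name)
    if (is.na(k)) stop("linkage attachment atom not in instance: ", at)
    el <- g$atoms$element[k]
    p <- atom_xyz(g, k)
    dir <- unitv(c(links$px[r], links$py[r], links$pz[r]) - p)
    if (el == "C") {
      if (length(adj[[k]]) >= 4) {
        stop("attachment atom ", at, " already at full valence")
      }
      repeat {
        capn <- capn + 1L
        nm <- paste0("OL", capn)
        if (!nm %in% atoms$name) break
      }
      atoms <- rbind(atoms, data.frame(
        name = nm, element = "O",
        x = p[1] + CAP_CO_LENGTH * dir[1],
        y = p[2] + CAP_CO_LENGTH * dir[2],
        z = p[3] + CAP_CO_LENGTH * dir[3], stringsAsFactors = FALSE))
      caps <- c(caps, nm)
    } else if (el %in% c("N", "O")) {
      # hydrogen cap: hydrogens are implicit, no heavy atom is added
      caps <- c(caps, paste0("H@", at))
    } else {
      stop("no capping rule for attachment element ", el)
    }
  }
  i$graph <- perceive(atoms)
  i$caps <- c(i$caps, caps)
  i
}
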