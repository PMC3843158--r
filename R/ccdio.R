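# Reading and writing component dictionaries (PDBx/mmCIF chem_comp dialect)
# and structure entries (PDB or mmCIF coordinates).
#
# Only the chem_comp, chem_comp_atom and chem_comp_bond categories (with the
# field names used by the public component dictionary) are interpreted;
# unrecognized categories are ignored so real dictionary files stay readable.

.ORDER_TO_CIF <- c(single = "SING", double = "DOUB", triple = "TRIP")
.CIF_TO_ORDER <- c(SING = "single", DOUB = "double", TRIP = "triple",
                   AROM = "single")

# -- low-level mmCIF tokenizer ----------------------------------------------

cif_tokens <- function(line) {
  out <- character(); i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      out <- c(out, substr(line, i, j - 1))
      i <- j
    }
  }
  out
}

cif_quote <- function(x) {
  needs <- grepl("[ '\"]", x) | x == "" | grepl("^[_#$\\[\\]]", x)
  ifelse(needs, paste0('"', x, '"'), x)
}

# Parse one mmCIF file into a list of blocks; each block is a list of
# categories; each category a data.frame of character columns.
parse_cif_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list(); cur <- NULL; cur_name <- NULL
  i <- 1; n <- length(lines)
  flush <- function() {
    if (!is.null(cur_name)) blocks[[length(blocks) + 1]] <<-
        list(name = cur_name, cats = cur)
  }
  cur <- list()
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1; next }
    if (startsWith(ln, "data_")) {
      flush()
      cur_name <- sub("^data_", "", ln); cur <- list()
      i <- i + 1; next
    }
    if (startsWith(ln, "loop_")) {
      i <- i + 1
      fields <- character()
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        fields <- c(fields, trimws(lines[i])); i <- i + 1
      }
      if (!length(fields)) stop("malformed loop_ at line ", i, " of ", path)
      cat_name <- sub("\\..*$", "", sub("^_", "", fields[1]))
      cols <- sub("^[^.]*\\.", "", sub("^_", "", fields))
      vals <- character()
      while (i <= n) {
        lt <- trimws(lines[i])
        if (lt == "" || startsWith(lt, "_") || startsWith(lt, "loop_") ||
            startsWith(lt, "data_") || startsWith(lt, "#")) break
        vals <- c(vals, cif_tokens(lines[i])); i <- i + 1
      }
      if (length(vals) %% length(fields) != 0) {
        stop("ragged loop for category ", cat_name, " in block ",
             cur_name %||% "?", " of ", path, " (near line ", i, ")")
      }
      m <- matrix(vals, ncol = length(fields), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- cols
      cur[[cat_name]] <- df
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      key <- toks[1]
      val <- if (length(toks) >= 2) toks[2] else {
        i <- i + 1
        trimws(lines[i])
      }
      cat_name <- sub("\\..*$", "", sub("^_", "", key))
      col <- sub("^[^.]*\\.", "", sub("^_", "", key))
      if (is.null(cur[[cat_name]])) {
        cur[[cat_name]] <- data.frame(row.names = 1)
      }
      cur[[cat_name]][[col]] <- val
      i <- i + 1; next
    }
    stop("cannot parse line ", i, " of ", path, ": ", ln)
  }
  flush()
  blocks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

yn <- function(x) toupper(x) %in% c("Y", "YES", "TRUE")

# -- dictionary I/O ---------------------------------------------------------

#' Read a component dictionary from mmCIF
#'
#' Parses a file (or every \code{*.cif} file in a directory) of chem_comp
#' definition blocks and builds an indexed dictionary. Each \code{data_}
#' block yields one definition. Parse failures report the block and
#' approximate line; a bond naming a missing atom or a duplicated component
#' code is an error.
#'
#' @param path Path to an mmCIF file, or a directory of \code{.cif} files.
#' @return A \code{chem_comp_dict}.
#' @seealso [write_dictionary()]
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such path: ", path)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.cif$", full.names = TRUE)
  } else path
  defs <- list()
  for (f in files) {
    for (b in parse_cif_blocks(f)) {
      cc <- b$cats$chem_comp
      at <- b$cats$chem_comp_atom
      bd <- b$cats$chem_comp_bond
      if (is.null(at)) next                  # not a component block
      comp_id <- toupper(cc$id %||% b$name)
      atoms <- data.frame(
        atom_id = at$atom_id,
        element = toupper(at$type_symbol),
        charge = as.integer(ifelse((at$charge %||% "0") %in% c("?", "."),
                                   "0", at$charge %||% "0")),
        aromatic = yn(at$pdbx_aromatic_flag %||% "N"),
        stereo = toupper(at$pdbx_stereo_config %||% "N"),
        x = as.numeric(at$pdbx_model_Cartn_x_ideal %||% at$model_Cartn_x),
        y = as.numeric(at$pdbx_model_Cartn_y_ideal %||% at$model_Cartn_y),
        z = as.numeric(at$pdbx_model_Cartn_z_ideal %||% at$model_Cartn_z),
        leaving = yn(at$pdbx_leaving_atom_flag %||% "N"),
        stringsAsFactors = FALSE)
      atoms$stereo[!atoms$stereo %in% c("R", "S")] <- "N"
      bonds <- if (is.null(bd)) NULL else data.frame(
        atom_1 = bd$atom_id_1,
        atom_2 = bd$atom_id_2,
        order = unname(.CIF_TO_ORDER[toupper(bd$value_order)]),
        aromatic = yn(bd$pdbx_aromatic_flag %||% "N"),
        stringsAsFactors = FALSE)
      if (!is.null(bonds) && anyNA(bonds$order)) {
        stop("unknown bond order in block ", b$name, " of ", f)
      }
      def <- component_definition(
        comp_id = comp_id,
        name = cc$name %||% comp_id,
        atoms = atoms, bonds = bonds,
        ideal_approximate = yn(cc$ccannotate_ideal_approximate %||% "N"))
      if (comp_id %in% names(defs)) {
        stop("duplicate comp_id across blocks: ", comp_id, " (", f, ")")
      }
      defs[[comp_id]] <- def
    }
  }
  dictionary(defs)
}

#' Write a component dictionary to mmCIF
#'
#' Serialization is deterministic: components are sorted by code, atoms and
#' bonds keep their stored order, and numeric fields use fixed formatting,
#' so equal dictionaries produce byte-identical files.
#'
#' @param d A \code{chem_comp_dict}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_dictionary <- function(d, path) {
  stopifnot(inherits(d, "chem_comp_dict"))
  out <- character()
  for (id in sort(names(d$defs))) {
    def <- d$defs[[id]]
    out <- c(out,
      paste0("data_", id),
      "#",
      paste("_chem_comp.id", id),
      paste("_chem_comp.name", cif_quote(def$name)),
      paste("_chem_comp.formula", cif_quote(def$formula)),
      paste("_chem_comp.ccannotate_ideal_approximate",
            if (def$ideal_approximate) "Y" else "N"),
      "#")
    if (nrow(def$atoms)) {
      out <- c(out, "loop_",
        paste0("_chem_comp_atom.",
               c("comp_id", "atom_id", "type_symbol", "charge",
                 "pdbx_aromatic_flag", "pdbx_stereo_config",
                 "pdbx_leaving_atom_flag", "pdbx_model_Cartn_x_ideal",
                 "pdbx_model_Cartn_y_ideal", "pdbx_model_Cartn_z_ideal")))
      a <- def$atoms
      out <- c(out, sprintf("%s %s %s %d %s %s %s %.4f %.4f %.4f",
                            id, cif_quote(a$atom_id), a$element, a$charge,
                            ifelse(a$aromatic, "Y", "N"), a$stereo,
                            ifelse(a$leaving, "Y", "N"), a$x, a$y, a$z))
      out <- c(out, "#")
    }
    if (nrow(def$bonds)) {
      out <- c(out, "loop_",
        paste0("_chem_comp_bond.",
               c("comp_id", "atom_id_1", "atom_id_2", "value_order",
                 "pdbx_aromatic_flag")))
      b <- def$bonds
      out <- c(out, sprintf("%s %s %s %s %s", id,
                            cif_quote(b$atom_1), cif_quote(b$atom_2),
                            unname(.ORDER_TO_CIF[b$order]),
                            ifelse(b$aromatic, "Y", "N")))
      out <- c(out, "#")
    }
  }
  writeLines(out, path)
  invisible(path)
}

# -- structure entries ------------------------------------------------------

#' Construct a structure entry
#'
#' @param entry_id Entry identifier.
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{ins}, \code{comp_id}, \code{atom_id}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ}, \code{altloc}, \code{hetero}.
#' @return An object of class \code{structure_entry}.
#' @export
structure_entry <- function(entry_id, atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0) stop("no atoms")
  need <- c("chain", "resno", "ins", "comp_id", "atom_id", "element",
            "x", "y", "z", "occ", "altloc", "hetero")
  for (col in setdiff(need, names(atoms))) {
    atoms[[col]] <- switch(col, ins = "", altloc = "", occ = 1,
                           hetero = TRUE, stop("missing column ", col))
  }
  atoms <- atoms[, need]
  rownames(atoms) <- NULL
  atoms$element <- toupper(atoms$element)
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in entry ", entry_id)
  }
  bad <- !known_element(atoms$element)
  if (any(bad)) {
    stop("unknown element symbol(s) in entry: ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$altloc,
               atoms$atom_id)
  if (anyDuplicated(key)) {
    stop("duplicate atom within residue: ", key[duplicated(key)][1])
  }
  structure(list(entry_id = entry_id, atoms = atoms,
                 subcomponents = list()),
            class = "structure_entry")
}

#' @export
print.structure_entry <- function(x, ...) {
  rs <- entry_residues(x)
  cat("<structure_entry> ", x$entry_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(rs), " residues (", sum(rs$hetero), " hetero)\n", sep = "")
  invisible(x)
}

#' Residue table of an entry
#'
#' @param e A \code{structure_entry}.
#' @return data.frame with one row per residue (chain, resno, ins, comp_id,
#'   hetero), ordered by chain then residue number.
#' @export
entry_residues <- function(e) {
  a <- e$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  first <- !duplicated(key)
  rs <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   ins = a$ins[first], comp_id = a$comp_id[first],
                   hetero = a$hetero[first], stringsAsFactors = FALSE)
  rs[order(rs$chain, rs$resno, rs$ins), , drop = FALSE]
}

# Atoms of one residue with the single-conformer rule applied: for each atom
# name keep the alt-loc with highest occupancy (ties: alphabetically first).
residue_atoms <- function(e, chain, resno, ins = "") {
  a <- e$atoms[e$atoms$chain == chain & e$atoms$resno == resno &
                 e$atoms$ins == ins, , drop = FALSE]
  if (nrow(a) <= 1) return(a)
  a <- a[order(a$atom_id, -a$occ, a$altloc), , drop = FALSE]
  a[!duplicated(a$atom_id), , drop = FALSE]
}

#' Read a structure entry
#'
#' @param path Coordinate file.
#' @param format \code{"mmcif"} or \code{"pdb"}. Hetero vs polymer flags come
#'   from the file's records (HETATM/ATOM or atom_site.group_PDB).
#' @return A \code{structure_entry}.
#' @export
read_entry <- function(path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    if (is.null(a) || nrow(a) == 0) stop("no atoms in ", path)
    atoms <- data.frame(
      chain = ifelse(is.na(a$chain), "", a$chain),
      resno = a$resno,
      ins = ifelse(is.na(a$insert), "", a$insert),
      comp_id = a$resid,
      atom_id = a$elety,
      element = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                               substr(trimws(a$elety), 1, 1), a$elesy)),
      x = a$x, y = a$y, z = a$z,
      occ = ifelse(is.na(a$o), 1, a$o),
      altloc = ifelse(is.na(a$alt), "", a$alt),
      hetero = a$type == "HETATM",
      stringsAsFactors = FALSE)
    return(structure_entry(sub("\\.pdb$", "", basename(path)), atoms))
  }
  blocks <- parse_cif_blocks(path)
  if (!length(blocks)) stop("no atoms in ", path)
  b <- blocks[[1]]
  s <- b$cats$atom_site
  if (is.null(s) || nrow(s) == 0) stop("no atoms in ", path)
  dot <- function(x, d = "") {
    if (is.null(x)) return(d)
    ifelse(x %in% c(".", "?"), d, x)
  }
  atoms <- data.frame(
    chain = dot(s$auth_asym_id %||% s$label_asym_id),
    resno = as.integer(s$auth_seq_id %||% s$label_seq_id),
    ins = dot(s$pdbx_PDB_ins_code %||% ""),
    comp_id = s$label_comp_id,
    atom_id = s$label_atom_id,
    element = toupper(s$type_symbol),
    x = as.numeric(s$Cartn_x), y = as.numeric(s$Cartn_y),
    z = as.numeric(s$Cartn_z),
    occ = as.numeric(dot(s$occupancy %||% "1", "1")),
    altloc = dot(s$label_alt_id %||% ""),
    hetero = (s$group_PDB %||% "HETATM") == "HETATM",
    stringsAsFactors = FALSE)
  structure_entry(b$name, atoms)
}

#' Write a structure entry
#'
#' @param e A \code{structure_entry}.
#' @param path Output path.
#' @param format \code{"mmcif"} or \code{"pdb"}.
#' @return Invisibly, \code{path}.
#' @export
write_entry <- function(e, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  a <- e$atoms
  a <- a[order(a$chain, a$resno, a$ins), , drop = FALSE]
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$hetero, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$comp_id,
                     eleno = seq_len(nrow(a)), elety = a$atom_id,
                     chain = a$chain,
                     insert = ifelse(a$ins == "", NA, a$ins),
                     alt = ifelse(a$altloc == "", NA, a$altloc),
                     o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
    return(invisible(path))
  }
  hdr <- c(paste0("data_", e$entry_id), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "auth_asym_id",
                    "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                    "Cartn_y", "Cartn_z", "occupancy")))
  rows <- sprintf("%s %d %s %s %s %s %s %d %s %.4f %.4f %.4f %.3f",
                  ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
                  a$element, cif_quote(a$atom_id),
                  ifelse(a$altloc == "", ".", a$altloc),
                  a$comp_id, ifelse(a$chain == "", ".", a$chain),
                  a$resno, ifelse(a$ins == "", ".", a$ins),
                  a$x, a$y, a$z, a$occ)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
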