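# Element data used throughout perception and editing.
#
# Single-bond covalent radii follow Cordero et al. (2008); double- and
# triple-bond radii follow Pyykko & Atsumi (2009). Values in Angstrom.

.RS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, SE = 1.20, BR = 1.20, I = 1.39,
  LI = 1.28, "NA" = 1.66, MG = 1.41, AL = 1.21, K = 2.03, CA = 1.76,
  V = 1.53, CR = 1.39, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24,
  CU = 1.32, ZN = 1.22, MO = 1.54, W = 1.62, CD = 1.44, HG = 1.32,
  PT = 1.36, PD = 1.39, AG = 1.45, AU = 1.36
)

.RD <- c(C = 0.67, N = 0.60, O = 0.57, S = 0.94, P = 1.02, SE = 1.07,
         B = 0.78, SI = 1.07)

# triple bonds are only classified for C/N/O pairs; S/P triples are not
# chemically meaningful here and their radii sit too close to the doubles
.RT <- c(C = 0.60, N = 0.54, O = 0.53)

.METALS <- c("LI", "NA", "MG", "AL", "K", "CA", "V", "CR", "MN", "FE",
             "CO", "NI", "CU", "ZN", "MO", "W", "CD", "HG", "PT", "PD",
             "AG", "AU")

# Allowed valence states per element (smallest state >= bond-order sum is
# used when computing implicit hydrogens). Metals carry valence 0: they never
# receive implicit hydrogens.
.VALENCES <- list(
  H = 1, C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
  F = 1, CL = 1, BR = 1, I = 1, B = 3, SE = c(2, 4, 6), SI = 4
)

#' Covalent-bond distance threshold for an element pair
#'
#' Sum of single-bond covalent radii plus the perception tolerance
#' (0.40 Angstrom by default). Unknown elements raise an error.
#'
#' @param e1,e2 Element symbols (case-insensitive).
#' @param tol Distance tolerance in Angstrom.
#' @return Numeric threshold in Angstrom.
#' @keywords internal
covalent_threshold <- function(e1, e2, tol = 0.40) {
  single_radius(e1) + single_radius(e2) + tol
}

single_radius <- function(el) {
  el <- toupper(el)
  r <- .RS[el]
  if (any(is.na(r))) {
    stop("no covalent radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}

is_metal <- function(el) toupper(el) %in% .METALS

known_element <- function(el) toupper(el) %in% names(.RS)

# Classify a covalent bond's order from its length: thresholds are midpoints
# between the sums of single/double (and double/triple) bond radii. Pairs
# without tabulated multiple-bond radii are always single.
classify_order <- function(e1, e2, d) {
  e1 <- toupper(e1); e2 <- toupper(e2)
  rs <- .RS[e1] + .RS[e2]
  if (e1 %in% names(.RD) && e2 %in% names(.RD)) {
    rd <- .RD[e1] + .RD[e2]
    if (e1 %in% names(.RT) && e2 %in% names(.RT)) {
      rt <- .RT[e1] + .RT[e2]
      if (d <= (rd + rt) / 2) return("triple")
    }
    if (d <= (rs + rd) / 2) return("double")
  }
  "single"
}

# Effective valence after formal-charge adjustment; NULL if element unknown.
effective_valences <- function(element, charge = 0L) {
  el <- toupper(element)
  if (is_metal(el)) return(0)
  v <- .VALENCES[[el]]
  if (is.null(v)) return(NULL)
  if (el %in% c("N", "P", "O")) v <- v + charge     # N+ 4, O- 1, ...
  else if (el == "C") v <- v - abs(charge)
  else if (el %in% c("S", "SE")) v <- v + charge
  v[v >= 0]
}

#' Hill-order molecular formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; when no
#' carbon is present all elements (including H) are alphabetical. Counts of
#' one are omitted, elements separated by spaces (the convention used by
#' component dictionaries).
#'
#' @param elements Character vector of heavy-atom element symbols
#'   (one entry per atom; may include explicit "H").
#' @param n_implicit_h Number of implicit hydrogens to add to the H count.
#' @return A single string, e.g. \code{"C2 H5 N O2"}.
#' @export
#' @examples
#' hill_formula(c("C", "C", "N", "O", "O"), n_implicit_h = 5)
hill_formula <- function(elements, n_implicit_h = 0L) {
  el <- toupper(elements)
  cnt <- table(el)
  nh <- n_implicit_h + if ("H" %in% names(cnt)) cnt[["H"]] else 0L
  cnt <- cnt[setdiff(names(cnt), "H")]
  nms <- names(cnt)
  if ("C" %in% nms) {
    rest <- sort(setdiff(nms, "C"))
    ord <- c("C", if (nh > 0) "H", rest)
    counts <- c(cnt[["C"]], if (nh > 0) nh, cnt[rest])
  } else {
    nmall <- nms
    counts <- as.integer(cnt)
    if (nh > 0) { nmall <- c(nmall, "H"); counts <- c(counts, nh) }
    ord <- order(nmall)
    counts <- counts[ord]
    ord <- nmall[ord]
  }
  # element symbols in formulas use standard capitalization (Cl, Zn, ...)
  pretty <- function(e) paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
  paste(ifelse(counts == 1L, pretty(ord), paste0(pretty(ord), counts)),
        collapse = " ")
}

# Element-count key ("C6 N1 O6") used by the dictionary prescreen index.
element_count_key <- function(elements) {
  el <- toupper(elements)
  el <- el[el != "H"]
  cnt <- table(el)
  paste(paste0(names(cnt), as.integer(cnt)), collapse = " ")
}
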