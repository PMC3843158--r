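# Shared fixtures: the toy dictionary is deterministic, so it is built once
# per test file.
toy <- make_toy_dictionary()

def_as_instance <- function(def) {
  perceive(data.frame(name = def$atoms$atom_id, element = def$atoms$element,
                      x = def$atoms$x, y = def$atoms$y, z = def$atoms$z,
                      stringsAsFactors = FALSE))
}

adjacency_matrix <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    A[g$bonds$i[k], g$bonds$j[k]] <- TRUE
    A[g$bonds$j[k], g$bonds$i[k]] <- TRUE
  }
  A
}

# Brute-force reference matcher: enumerates every element-consistent atom
# assignment exhaustively, abandoning a partial assignment only once it
# already violates adjacency. Independent of the package's VF2 route.
oracle_isomorphisms <- function(g1, g2) {
  n <- nrow(g1$atoms)
  if (n != nrow(g2$atoms)) return(list())
  A1 <- adjacency_matrix(g1)
  A2 <- adjacency_matrix(g2)
  out <- list()
  m <- integer(n)
  used <- logical(n)
  recurse <- function(i) {
    if (i > n) {
      out[[length(out) + 1]] <<- m
      return(invisible(NULL))
    }
    for (j in which(!used & g2$atoms$element == g1$atoms$element[i])) {
      ok <- TRUE
      for (p in seq_len(i - 1)) {
        if (A1[i, p] != A2[j, m[p]]) { ok <- FALSE; break }
      }
      if (ok) {
        m[i] <<- j; used[j] <<- TRUE
        recurse(i + 1)
        used[j] <<- FALSE
      }
    }
  }
  recurse(1L)
  out
}

score_of <- function(res, comp_id) {
  for (cd in res$candidates) if (cd$comp_id == comp_id) return(cd$score)
  NULL
}

expect_all_perfect <- function(score) {
  v <- unclass(score)
  expect_true(all(is.na(v) | v == 100))
}
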