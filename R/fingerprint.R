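## Linear path-fragment fingerprints and Tanimoto similarity.

BOND_MARK <- c("-", "=", "#")  # order 1-3; aromatic bonds use ":"

#' Linear path-fragment fingerprint
#'
#' Enumerates all simple paths of 2 to `max_len` heavy atoms (hydrogens
#' excluded) by depth-first search and renders each as alternating element
#' symbols and bond-order marks (`-`, `=`, `#`, `:` for aromatic).  Each
#' fragment is direction-canonical — the lexicographic minimum of the
#' forward and reversed rendering — and duplicates collapse into a set.
#'
#' @param mol a [molecule()].
#' @param max_len maximum path length in atoms (default 7, the classic
#'   linear-fragment fingerprint length).
#' @return Object of class `"fingerprint"`: list with `fragments`, a
#'   sorted character vector (set) of canonical path strings.
#' @export
path_fragments <- function(mol, max_len = 7L) {
  stopifnot(inherits(mol, "molecule"), max_len >= 2)
  heavy <- which(mol$atoms$element != "H")
  frag_env <- new.env(parent = emptyenv())
  if (length(heavy) >= 2) {
    ## heavy-atom subgraph
    idx <- match(seq_len(n_atoms(mol)), heavy)   # NA for hydrogens
    b <- mol$bonds
    keep <- !is.na(idx[b$i]) & !is.na(idx[b$j])
    bi <- idx[b$i[keep]]; bj <- idx[b$j[keep]]
    mark <- ifelse(b$aromatic[keep], ":", BOND_MARK[b$order[keep]])
    m <- length(heavy)
    adj <- vector("list", m)
    bnd <- vector("list", m)
    for (k in seq_along(bi)) {
      adj[[bi[k]]] <- c(adj[[bi[k]]], bj[k])
      bnd[[bi[k]]] <- c(bnd[[bi[k]]], mark[k])
      adj[[bj[k]]] <- c(adj[[bj[k]]], bi[k])
      bnd[[bj[k]]] <- c(bnd[[bj[k]]], mark[k])
    }
    el <- mol$atoms$element[heavy]

    emit <- function(atoms_seq, marks_seq) {
      fwd <- paste(c(rbind(el[atoms_seq],
                           c(marks_seq, "")))[seq_len(2 * length(atoms_seq) - 1)],
                   collapse = "")
      rev_atoms <- rev(atoms_seq); rev_marks <- rev(marks_seq)
      bwd <- paste(c(rbind(el[rev_atoms],
                           c(rev_marks, "")))[seq_len(2 * length(atoms_seq) - 1)],
                   collapse = "")
      key <- if (fwd <= bwd) fwd else bwd
      assign(key, TRUE, envir = frag_env)
    }

    walk <- function(path, marks, on_path) {
      tip <- path[length(path)]
      for (t in seq_along(adj[[tip]])) {
        w <- adj[[tip]][t]
        if (on_path[w]) next
        new_path <- c(path, w)
        new_marks <- c(marks, bnd[[tip]][t])
        emit(new_path, new_marks)
        if (length(new_path) < max_len) {
          on_path[w] <- TRUE
          walk(new_path, new_marks, on_path)
          on_path[w] <- FALSE
        }
      }
    }
    on_path <- logical(m)
    for (s in seq_len(m)) {
      on_path[s] <- TRUE
      walk(s, character(0), on_path)
      on_path[s] <- FALSE
    }
  }
  structure(list(fragments = sort(ls(frag_env))), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d linear fragment(s)>\n", length(x$fragments)))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the exact fragment sets (no
#' hashing, hence no collisions).  Undefined when both sets are empty.
#'
#' @param a,b [path_fragments()] outputs.
#' @return Coefficient in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  fa <- a$fragments; fb <- b$fragments
  if (length(fa) == 0 && length(fb) == 0) {
    stop("Tanimoto undefined: both fragment sets empty", call. = FALSE)
  }
  length(intersect(fa, fb)) / length(union(fa, fb))
}

#' Pairwise Tanimoto matrix and diversity summary
#'
#' Compares every molecule to each other; the summary (median and
#' quartiles) is taken over the strict upper triangle.
#'
#' @param mols list of at least two [molecule()] objects.
#' @param max_len fragment length cap in atoms.
#' @return List with `matrix` (symmetric, unit diagonal) and `summary`
#'   (`median`, `q1`, `q3`, `n_pairs`).
#' @export
pairwise_tanimoto <- function(mols, max_len = 7L) {
  if (length(mols) < 2) stop("need at least 2 molecules", call. = FALSE)
  fps <- lapply(mols, path_fragments, max_len = max_len)
  n <- length(fps)
  M <- diag(1, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      v <- tanimoto(fps[[a]], fps[[b]])
      M[a, b] <- v; M[b, a] <- v
    }
  }
  upper <- M[upper.tri(M)]
  q <- stats::quantile(upper, c(0.25, 0.5, 0.75), names = FALSE)
  list(matrix = M,
       summary = list(median = q[2], q1 = q[1], q3 = q[3],
                      n_pairs = length(upper)))
}
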