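#' Construct a molecule object
#'
#' A molecule is a cyclic undirected graph: atoms are vertices, bonds are
#' edges.  Atoms carry element symbols, optional 3D coordinates (Angstrom)
#' and integer formal charges; bonds carry an integer order (1-3) and an
#' aromatic flag.  Validation enforces the supported element set, index
#' sanity, absence of self-loops and duplicate edges, and per-element
#' valence caps (C 4, H 1, N 4, O 2, P 5, S 6, halogens 1, counting bond
#' orders).
#'
#' @param atoms data.frame with columns `element`, `name`, `x`, `y`, `z`,
#'   `formal_charge`.  Coordinates may be `NA` (e.g. SMILES input before
#'   embedding).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices,
#'   `i < j`), `order` (integer 1-3) and `aromatic` (logical).
#' @param id character molecule identifier.
#' @param source_format one of `"pdb"`, `"sdf"`, `"smiles"`, `"synthetic"`.
#' @param orders_known logical; `FALSE` when bonds were perceived from
#'   geometry so orders are nominal (affects hybridization rules).
#' @return An object of class `"molecule"`.
#' @export
molecule <- function(atoms, bonds, id = "MOL", source_format = "synthetic",
                     orders_known = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("element", "name", "x", "y", "z", "formal_charge")
  for (col in setdiff(need, names(atoms))) {
    atoms[[col]] <- switch(col,
      name = atoms$element, formal_charge = 0L,
      x = NA_real_, y = NA_real_, z = NA_real_)
  }
  atoms <- atoms[, need]
  atoms$element <- as.character(atoms$element)
  atoms$formal_charge <- as.integer(atoms$formal_charge)
  check_elements(atoms$element, "molecule")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.na(coords) & !is.finite(coords))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = integer(0), aromatic = logical(0))
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (!"order" %in% names(bonds)) bonds$order <- 1L
  if (!"aromatic" %in% names(bonds)) bonds$aromatic <- FALSE
  bonds <- bonds[, c("i", "j", "order", "aromatic")]
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  bonds$aromatic <- as.logical(bonds$aromatic)

  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    ## canonicalize i < j
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (any(bonds$i < 1L | bonds$j > n)) {
      stop("bond endpoint outside atom range", call. = FALSE)
    }
    if (anyDuplicated(bonds[, c("i", "j")])) {
      stop("duplicate bond", call. = FALSE)
    }
    if (any(bonds$order < 1L | bonds$order > 3L)) {
      stop("bond order must be 1-3", call. = FALSE)
    }
    ## valence caps, counting bond orders
    val <- numeric(n)
    ords <- as.numeric(bonds$order)
    for (k in seq_len(nrow(bonds))) {
      val[bonds$i[k]] <- val[bonds$i[k]] + ords[k]
      val[bonds$j[k]] <- val[bonds$j[k]] + ords[k]
    }
    caps <- MAX_VALENCE[atoms$element]
    over <- which(val > caps)
    if (length(over) > 0) {
      stop(sprintf("valence cap exceeded for atom %d (%s: %g > %g)",
                   over[1], atoms$element[over[1]], val[over[1]],
                   caps[over[1]]), call. = FALSE)
    }
  }
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         source_format = match.arg(source_format,
                                   c("pdb", "sdf", "smiles", "synthetic")),
         orders_known = isTRUE(orders_known)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds, source=%s>\n",
              x$id, n_atoms(x), sum(x$atoms$element != "H"),
              nrow(x$bonds), x$source_format))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

## Coordinate matrix (n x 3); NA rows where coordinates are absent.
coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

has_coords <- function(mol) {
  n_atoms(mol) > 0 && !anyNA(coords_matrix(mol))
}

## Adjacency list (list of integer vectors, sorted) for graph traversals.
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  lapply(adj, sort)
}

## Dense logical adjacency matrix.
adjacency_matrix <- function(mol) {
  n <- n_atoms(mol)
  A <- matrix(FALSE, n, n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    A[cbind(b$i, b$j)] <- TRUE
    A[cbind(b$j, b$i)] <- TRUE
  }
  A
}

#' Perceive bonds from interatomic distances
#'
#' Places a single bond between atoms `i`, `j` whenever
#' `0.4 <= d(i,j) <= r_cov(i) + r_cov(j) + 0.45` Angstrom, using standard
#' single-bond covalent radii.  The 0.4 A floor rejects clashing duplicate
#' positions.  Valence caps are enforced by dropping the longest offending
#' bonds first, so the result is always a legal molecule graph.
#'
#' @param atoms data.frame of atoms with `element`, `x`, `y`, `z` columns
#'   (all coordinates present and finite).
#' @return data.frame of bonds (`i`, `j`, `order` = 1, `aromatic` = FALSE).
#' @export
perceive_bonds <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  check_elements(atoms$element, "perceive_bonds")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyNA(xyz) || any(!is.finite(xyz))) {
    stop("perceive_bonds requires finite coordinates for every atom",
         call. = FALSE)
  }
  n <- nrow(atoms)
  if (n < 2) {
    return(data.frame(i = integer(0), j = integer(0),
                      order = integer(0), aromatic = logical(0)))
  }
  d <- as.matrix(stats::dist(xyz))
  rc <- COVALENT_RADIUS[atoms$element]
  cutoff <- outer(rc, rc, `+`) + 0.45
  hit <- which(upper.tri(d) & d >= 0.4 & d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      order = integer(0), aromatic = logical(0)))
  }
  cand <- data.frame(i = hit[, 1], j = hit[, 2], len = d[hit])
  ## enforce valence caps: accept shortest bonds first
  cand <- cand[order(cand$len, cand$i, cand$j), ]
  caps <- MAX_VALENCE[atoms$element]
  used <- numeric(n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used[i] + 1 <= caps[i] && used[j] + 1 <= caps[j]) {
      keep[k] <- TRUE
      used[i] <- used[i] + 1
      used[j] <- used[j] + 1
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(i = as.integer(cand$i), j = as.integer(cand$j),
                    order = 1L, aromatic = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}
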