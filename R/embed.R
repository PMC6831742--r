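#' Synthesize approximate 3D coordinates for a molecule
#'
#' Deterministic greedy embedding for inputs without coordinates (SMILES,
#' generated molecules): atoms are placed in breadth-first order from atom
#' 1, each at 1.5 Angstrom from its parent along whichever of a fixed set
#' of 26 lattice directions maximizes the minimum distance to all
#' previously placed atoms (first direction wins ties).  The geometry is
#' approximate — bond lengths are uniform and angles come from the lattice,
#' not from element-specific templates — but it is deterministic, keeps
#' bonded atoms close and non-bonded atoms spread out, so radial features
#' remain computable.  Molecules embedded this way carry
#' `coords_approx = TRUE`.
#'
#' @param mol a [molecule()]; existing coordinates are kept unless
#'   `force = TRUE`.
#' @param bond_length placement distance in Angstrom (default 1.5).
#' @param force re-embed even when coordinates are present.
#' @return The molecule with filled `x`, `y`, `z`.
#' @export
embed_coordinates <- function(mol, bond_length = 1.5, force = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (has_coords(mol) && !force) return(mol)
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)

  ## fixed direction set: the 26 non-zero lattice vectors, normalized,
  ## ordered deterministically
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  dirs <- g / sqrt(rowSums(g^2))

  pos <- matrix(NA_real_, n, 3)
  placed <- logical(n)
  ## BFS over components; roots at lowest unplaced index
  for (root in seq_len(n)) {
    if (placed[root]) next
    if (!any(placed)) {
      pos[root, ] <- c(0, 0, 0)
    } else {
      ## offset later components away from everything placed so far
      pos[root, ] <- c(max(pos[placed, 1]) + 10, 0, 0)
    }
    placed[root] <- TRUE
    queue <- root
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (placed[w]) next
        cand <- sweep(dirs * bond_length, 2, pos[v, ], `+`)
        ref <- pos[placed, , drop = FALSE]
        ## min distance from each candidate to every placed atom
        d2 <- outer(rowSums(cand^2), rowSums(ref^2), `+`) -
          2 * cand %*% t(ref)
        score <- d2[, 1]
        for (j in seq_len(ncol(d2))[-1]) score <- pmin(score, d2[, j])
        pick <- which.max(score)
        pos[w, ] <- cand[pick, ]
        placed[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  mol$atoms$x <- pos[, 1]; mol$atoms$y <- pos[, 2]; mol$atoms$z <- pos[, 3]
  mol$coords_approx <- TRUE
  mol
}
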