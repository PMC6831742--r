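#' Ring perception by depth-first search
#'
#' Computes a fundamental cycle basis from a DFS spanning forest: the tree
#' is rooted at the lowest-index atom of each connected component with
#' children visited in index order, and every non-tree edge contributes the
#' unique cycle it closes through the tree.  The basis size therefore
#' equals `|E| - |V| + #components` exactly.  Per-atom ring statistics and
#' fused ring systems (rings sharing at least one atom, merged
#' transitively) are derived from the basis.  Deterministic for a fixed
#' atom ordering.  This is a cycle *basis*, not the
#' smallest-set-of-smallest-rings.
#'
#' @param mol a [molecule()].
#' @return An object of class `"ring_info"`: a list with
#'   \describe{
#'     \item{rings}{list of integer vectors, each an ordered simple cycle
#'       (vertex sequence, no repeated vertex).}
#'     \item{atom_ring_count}{integer per atom: number of basis rings it
#'       belongs to.}
#'     \item{atom_min_ring_size, atom_max_ring_size}{integer per atom, 0
#'       when the atom is in no ring.}
#'     \item{ring_systems}{list of fused components, each with
#'       `ring_indices`, `n_rings`, `atoms`, `n_atoms`.}
#'   }
#' @export
find_rings <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  depth <- rep(0L, n)
  back_edges <- list()

  for (root in seq_len(n)) {
    if (visited[root]) next
    ## iterative DFS, children in increasing index order
    stack <- list(list(v = root, nbrs = adj[[root]], ptr = 1L))
    visited[root] <- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      if (top$ptr > length(top$nbrs)) {
        stack[[length(stack)]] <- NULL
        next
      }
      w <- top$nbrs[top$ptr]
      stack[[length(stack)]]$ptr <- top$ptr + 1L
      v <- top$v
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        depth[w] <- depth[v] + 1L
        stack[[length(stack) + 1]] <- list(v = w, nbrs = adj[[w]], ptr = 1L)
      } else if (is.na(parent[v]) || w != parent[v]) {
        ## non-tree (back) edge; record once, from the deeper endpoint
        if (depth[w] < depth[v]) {
          back_edges[[length(back_edges) + 1]] <- c(v, w)
        }
      }
    }
  }
  ## deduplicate (each back edge is seen from both endpoints in general)
  if (length(back_edges) > 0) {
    key <- vapply(back_edges, function(e) paste(sort(e), collapse = "-"), "")
    back_edges <- back_edges[!duplicated(key)]
  }

  rings <- lapply(back_edges, function(e) {
    ## fundamental cycle: tree paths from both endpoints to their LCA
    a <- e[1]; b <- e[2]
    pa <- a; pb <- b
    path_a <- a; path_b <- b
    while (depth[pa] > depth[pb]) { pa <- parent[pa]; path_a <- c(path_a, pa) }
    while (depth[pb] > depth[pa]) { pb <- parent[pb]; path_b <- c(path_b, pb) }
    while (pa != pb) {
      pa <- parent[pa]; path_a <- c(path_a, pa)
      pb <- parent[pb]; path_b <- c(path_b, pb)
    }
    ## path_a ends at LCA, path_b too; concatenate as an ordered cycle
    as.integer(c(path_a, rev(path_b[-length(path_b)])))
  })

  atom_ring_count <- integer(n)
  atom_min <- integer(n)
  atom_max <- integer(n)
  for (r in rings) {
    sz <- length(r)
    atom_ring_count[r] <- atom_ring_count[r] + 1L
    upd_min <- atom_min[r] == 0L | atom_min[r] > sz
    atom_min[r][upd_min] <- sz
    atom_max[r] <- pmax(atom_max[r], sz)
  }

  ## fused ring systems: union-find over rings sharing >= 1 atom
  nr <- length(rings)
  comp <- seq_len(nr)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (nr > 1) {
    for (a in seq_len(nr - 1)) {
      for (b in (a + 1):nr) {
        if (length(intersect(rings[[a]], rings[[b]])) > 0) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  roots <- if (nr > 0) vapply(seq_len(nr), find, 1L) else integer(0)
  ring_systems <- lapply(unique(roots), function(rt) {
    members <- which(roots == rt)
    atoms <- sort(unique(unlist(rings[members])))
    list(ring_indices = members, n_rings = length(members),
         atoms = atoms, n_atoms = length(atoms))
  })

  structure(list(rings = rings,
                 atom_ring_count = atom_ring_count,
                 atom_min_ring_size = atom_min,
                 atom_max_ring_size = atom_max,
                 ring_systems = ring_systems),
            class = "ring_info")
}

#' @export
print.ring_info <- function(x, ...) {
  cat(sprintf("<ring_info: %d basis ring(s), %d ring system(s)>\n",
              length(x$rings), length(x$ring_systems)))
  invisible(x)
}
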