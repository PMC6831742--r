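## Independent oracles and small builders used across the test files.

## Build a molecule straight from an edge list over heavy atoms (all C by
## default).  With validate = FALSE the molecule object is assembled
## directly so abstract test graphs may exceed chemical valence caps
## (ring perception only reads the edge list).
graph_molecule <- function(n, edges, elements = rep("C", n),
                           validate = TRUE) {
  bonds <- if (length(edges) > 0) {
    data.frame(i = vapply(edges, function(e) as.integer(min(e[1], e[2])), 1L),
               j = vapply(edges, function(e) as.integer(max(e[1], e[2])), 1L),
               order = 1L, aromatic = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0))
  }
  atoms <- data.frame(element = elements, name = elements,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      formal_charge = 0L, stringsAsFactors = FALSE)
  if (validate) {
    molecule(atoms, bonds, id = "G", source_format = "synthetic")
  } else {
    structure(list(id = "G", atoms = atoms,
                   bonds = bonds[order(bonds$i, bonds$j), , drop = FALSE],
                   source_format = "synthetic", orders_known = TRUE),
              class = "molecule")
  }
}

## Random connected graph: random spanning tree + extra random edges.
## Elements are all carbon with inflated valence irrelevant: we bypass the
## molecule valence cap by using sulfur (cap 6) where degree demands it.
random_connected_graph <- function(n, extra_edges) {
  edges <- list()
  for (v in 2:n) {
    edges[[length(edges) + 1]] <- c(sample.int(v - 1, 1), v)
  }
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  have <- vapply(edges, function(e) paste(sort(e), collapse = "-"), "")
  pool <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2], sep = "-") %in% have, ,
                    drop = FALSE]
  if (extra_edges > 0 && nrow(pool) > 0) {
    pick <- pool[sample.int(nrow(pool), min(extra_edges, nrow(pool))), ,
                 drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      edges[[length(edges) + 1]] <- c(pick[r, 1], pick[r, 2])
    }
  }
  edges
}

## Adjacency list from an edge list.
edges_to_adj <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  lapply(adj, sort)
}

## Brute-force enumeration of every simple cycle of an undirected graph,
## as canonical vertex sets.  Each cycle is found from its lowest vertex.
all_simple_cycles <- function(n, edges) {
  adj <- edges_to_adj(n, edges)
  found <- new.env(parent = emptyenv())
  extend <- function(path, on_path) {
    tip <- path[length(path)]
    for (w in adj[[tip]]) {
      if (w == path[1] && length(path) >= 3) {
        assign(paste(sort(path), collapse = "-"), path, envir = found)
      } else if (!on_path[w] && w > path[1]) {
        on_path[w] <- TRUE
        extend(c(path, w), on_path)
        on_path[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    on_path <- logical(n)
    on_path[s] <- TRUE
    extend(s, on_path)
  }
  ls(found)
}

## Verify a returned ring is an actual simple cycle of its molecule.
is_simple_cycle <- function(mol, ring) {
  if (length(ring) < 3 || anyDuplicated(ring)) return(FALSE)
  A <- matrix(FALSE, n_atoms(mol), n_atoms(mol))
  A[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
  A[cbind(mol$bonds$j, mol$bonds$i)] <- TRUE
  closed <- c(ring, ring[1])
  all(A[cbind(closed[-length(closed)], closed[-1])])
}

## Direct-summation metric implementations, kept deliberately naive and
## separate from the package's versions.
rmse_direct <- function(y, yh) {
  s <- 0
  for (t in seq_along(y)) s <- s + (yh[t] - y[t])^2
  sqrt(s / length(y))
}
nrmse_direct <- function(y, yh) {
  rmse_direct(y, yh) / (max(y) - min(y)) * 100
}
pearson2_direct <- function(y, yh) {
  my <- sum(y) / length(y); mh <- sum(yh) / length(yh)
  num <- sum((y - my) * (yh - mh))
  (num / sqrt(sum((y - my)^2) * sum((yh - mh)^2)))^2
}

## A methane molecule with ideal tetrahedral geometry (C-H 1.09 A).
methane <- function() {
  d <- 1.09 / sqrt(3)
  molecule(data.frame(
    element = c("C", "H", "H", "H", "H"),
    name = c("C1", "H1", "H2", "H3", "H4"),
    x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d),
    z = c(0, d, -d, -d, d), formal_charge = 0L),
    data.frame(i = 1L, j = 2:5, order = 1L, aromatic = FALSE),
    id = "methane", source_format = "synthetic")
}
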