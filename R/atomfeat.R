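## Per-atom feature encoding: a fixed 61-slot numeric schema.

DEFAULT_RADII <- c(2.0, 4.0, 6.0)
RADIAL_BINS <- c("C", "N", "O", "heavy", "H")

#' The fixed 61-name feature schema
#'
#' Slot layout (61 = 10 + 3 + 6 + 10 + 1 + 10 + 15 + 3 + 1 + 1 + 1):
#' element one-hot over the ten supported elements; carbon hybridization
#' one-hot (sp/sp2/sp3); ring block (in-ring flag, ring count, min/max ring
#' size, fused-system ring count and atom count); level-1 neighbor element
#' counts; heavy+H degree; level-2 neighbor element counts; radial
#' neighbor counts for three radii binned by C/N/O/other-heavy/H; counts
#' of single/double/triple bonds at the atom; aromatic-bond flag; formal
#' charge; molecule heavy-atom count.
#'
#' @return Character vector of the 61 feature names, fixed order.
#' @export
feature_schema <- function() {
  c(paste0("elem_", supported_elements()),
    c("hyb_sp", "hyb_sp2", "hyb_sp3"),
    c("in_ring", "ring_count", "min_ring_size", "max_ring_size",
      "ringsys_n_rings", "ringsys_n_atoms"),
    paste0("n1_", supported_elements()),
    "degree",
    paste0("n2_", supported_elements()),
    paste0("rad", rep(1:3, each = 5), "_", rep(RADIAL_BINS, 3)),
    c("n_single", "n_double", "n_triple"),
    "has_aromatic",
    "formal_charge",
    "n_heavy_mol")
}

## digest of the schema; recorded in trained models and checked at predict
schema_hash <- function(schema = feature_schema()) fnv1a32(schema)

#' Carbon hybridization state
#'
#' Non-carbon atoms return `"n/a"`.  For carbon: a triple bond (or, when
#' bond orders were perceived rather than read, a heavy+H degree of at most
#' 2 with a mean bond angle of at least 155 degrees) gives `"sp"`; a
#' double or aromatic bond (or perceived orders with degree 3) gives
#' `"sp2"`; otherwise `"sp3"`.
#'
#' @param mol a [molecule()].
#' @param atom 1-based atom index.
#' @return One of `"sp"`, `"sp2"`, `"sp3"`, `"n/a"`.
#' @export
hybridization <- function(mol, atom) {
  stopifnot(inherits(mol, "molecule"), atom >= 1, atom <= n_atoms(mol))
  if (mol$atoms$element[atom] != "C") return("n/a")
  b <- mol$bonds
  mine <- b[b$i == atom | b$j == atom, , drop = FALSE]
  degree <- nrow(mine)
  if (mol$orders_known) {
    if (any(mine$order == 3L)) return("sp")
    if (any(mine$order == 2L) || any(mine$aromatic)) return("sp2")
    return("sp3")
  }
  ## orders unknown (perceived bonds): fall back to geometry/degree
  if (degree <= 2 && degree == 2 && has_coords(mol)) {
    nbrs <- ifelse(mine$i == atom, mine$j, mine$i)
    xyz <- coords_matrix(mol)
    v1 <- xyz[nbrs[1], ] - xyz[atom, ]
    v2 <- xyz[nbrs[2], ] - xyz[atom, ]
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    if (ang >= 155) return("sp")
  }
  if (degree == 3) return("sp2")
  "sp3"
}

#' Radial neighbor counts
#'
#' For each of three radii, counts atoms (excluding the query atom) within
#' Euclidean distance `r`, binned by element class C / N / O / other-heavy
#' / H.  Counts are cumulative in the radius, hence monotone non-decreasing
#' across the triple.  The distance comparison uses a 1e-9 Angstrom
#' tolerance so rigid-body transforms cannot flip counts away from bin
#' boundaries.
#'
#' @param mol a [molecule()] with coordinates (embed first if absent).
#' @param atom 1-based atom index.
#' @param radii increasing triple of distances in Angstrom.
#' @return Named numeric vector of 15 counts (3 radii x 5 bins).
#' @export
radial_counts <- function(mol, atom, radii = DEFAULT_RADII) {
  stopifnot(length(radii) == 3)
  if (!has_coords(mol)) {
    stop("radial_counts requires coordinates; call embed_coordinates() first",
         call. = FALSE)
  }
  xyz <- coords_matrix(mol)
  d <- sqrt(colSums((t(xyz) - xyz[atom, ])^2))
  d <- d[-atom]
  el <- mol$atoms$element[-atom]
  bin <- ifelse(el == "C", "C",
         ifelse(el == "N", "N",
         ifelse(el == "O", "O",
         ifelse(el == "H", "H", "heavy"))))
  out <- numeric(15)
  names(out) <- paste0("rad", rep(1:3, each = 5), "_", rep(RADIAL_BINS, 3))
  for (ri in 1:3) {
    inside <- d <= radii[ri] + 1e-9
    tab <- table(factor(bin[inside], levels = RADIAL_BINS))
    out[(ri - 1) * 5 + 1:5] <- as.numeric(tab)
  }
  out
}

#' First- and second-level neighbor element counts
#'
#' Counts each of the ten supported elements among atoms at graph distance
#' exactly 1 and exactly 2 from the query atom.  An atom reachable at both
#' distances counts only at distance 1 (shortest-path semantics).
#'
#' @param mol a [molecule()].
#' @param atom 1-based atom index.
#' @return Named numeric vector of 20 counts (`n1_*` then `n2_*`).
#' @export
neighbor_trace <- function(mol, atom) {
  stopifnot(atom >= 1, atom <= n_atoms(mol))
  adj <- adjacency_list(mol)
  lev1 <- adj[[atom]]
  lev2 <- setdiff(unique(unlist(adj[lev1])), c(atom, lev1))
  els <- supported_elements()
  c1 <- table(factor(mol$atoms$element[lev1], levels = els))
  c2 <- table(factor(mol$atoms$element[lev2], levels = els))
  out <- c(as.numeric(c1), as.numeric(c2))
  names(out) <- c(paste0("n1_", els), paste0("n2_", els))
  out
}

## Core: full feature matrix for a molecule (rows = atoms, cols = schema).
## Shared by encode_atom / encode_molecule so the two can never diverge.
encode_core <- function(mol, rings, radii = DEFAULT_RADII) {
  n <- n_atoms(mol)
  if (n == 0) stop("cannot encode an empty molecule", call. = FALSE)
  mol <- embed_coordinates(mol)
  els <- supported_elements()
  schema <- feature_schema()
  M <- matrix(0, n, length(schema), dimnames = list(NULL, schema))
  elem <- mol$atoms$element

  ## element one-hot
  M[cbind(seq_len(n), match(elem, els))] <- 1

  ## bond-order counts and aromatic flag (also feed hybridization below)
  b <- mol$bonds
  ends <- c(b$i, b$j)
  ord2 <- c(b$order, b$order)
  arom2 <- c(b$aromatic, b$aromatic)
  M[, "n_single"] <- tabulate(ends[ord2 == 1L], n)
  M[, "n_double"] <- tabulate(ends[ord2 == 2L], n)
  M[, "n_triple"] <- tabulate(ends[ord2 == 3L], n)
  M[, "has_aromatic"] <- as.numeric(tabulate(ends[arom2], n) > 0)

  ## hybridization one-hot (carbon only)
  is_c <- elem == "C"
  if (mol$orders_known) {
    hyb <- ifelse(M[, "n_triple"] > 0, "sp",
           ifelse(M[, "n_double"] > 0 | M[, "has_aromatic"] > 0, "sp2", "sp3"))
    for (h in c("sp", "sp2", "sp3")) {
      M[is_c & hyb == h, paste0("hyb_", h)] <- 1
    }
  } else {
    for (a in which(is_c)) {
      M[a, paste0("hyb_", hybridization(mol, a))] <- 1
    }
  }

  ## ring block
  M[, "in_ring"] <- as.numeric(rings$atom_ring_count >= 1L)
  M[, "ring_count"] <- rings$atom_ring_count
  M[, "min_ring_size"] <- rings$atom_min_ring_size
  M[, "max_ring_size"] <- rings$atom_max_ring_size
  for (rs in rings$ring_systems) {
    M[rs$atoms, "ringsys_n_rings"] <- rs$n_rings
    M[rs$atoms, "ringsys_n_atoms"] <- rs$n_atoms
  }

  ## neighbor traces via adjacency algebra
  A <- adjacency_matrix(mol)
  storage.mode(A) <- "numeric"
  elem_ind <- outer(elem, els, `==`) * 1          # n x 10 indicator
  lev1 <- A %*% elem_ind                           # counts at distance 1
  A2 <- (A %*% A > 0) * 1
  diag(A2) <- 0
  A2[A > 0] <- 0                                   # exactly distance 2
  lev2 <- A2 %*% elem_ind
  M[, paste0("n1_", els)] <- lev1
  M[, "degree"] <- rowSums(A)
  M[, paste0("n2_", els)] <- lev2

  ## radial counts
  xyz <- coords_matrix(mol)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  bin_ind <- cbind(C = elem == "C", N = elem == "N", O = elem == "O",
                   heavy = !elem %in% c("C", "N", "O", "H"), H = elem == "H") * 1
  for (ri in 1:3) {
    inside <- (d <= radii[ri] + 1e-9) * 1
    diag(inside) <- 0
    M[, paste0("rad", ri, "_", RADIAL_BINS)] <- inside %*% bin_ind
  }

  M[, "formal_charge"] <- mol$atoms$formal_charge
  M[, "n_heavy_mol"] <- sum(elem != "H")
  if (any(!is.finite(M))) stop("non-finite feature value", call. = FALSE)
  M
}

#' Encode a single atom as a 61-slot feature vector
#'
#' @param mol a [molecule()].
#' @param rings output of [find_rings()] for `mol`.
#' @param atom 1-based atom index.
#' @param radii radial-search radii in Angstrom.
#' @return Named numeric vector of length 61 following [feature_schema()].
#' @export
encode_atom <- function(mol, rings, atom, radii = DEFAULT_RADII) {
  stopifnot(atom >= 1, atom <= n_atoms(mol))
  encode_core(mol, rings, radii)[atom, ]
}

#' Encode every atom of a molecule as a feature table
#'
#' Rings are perceived once and shared across atoms.  Rows follow atom
#' order.
#'
#' @param mol a [molecule()].
#' @param radii radial-search radii in Angstrom.
#' @return data.frame with the 61 schema columns plus `element`.
#' @export
encode_molecule <- function(mol, radii = DEFAULT_RADII) {
  stopifnot(inherits(mol, "molecule"))
  rings <- find_rings(mol)
  M <- encode_core(mol, rings, radii)
  out <- as.data.frame(M)
  out$element <- mol$atoms$element
  out
}

#' Write / read a feature table as CSV
#'
#' Deterministic column order: the 61 schema names, then `element`, then
#' `label` when present.
#'
#' @param table feature table data.frame.
#' @param path file path.
#' @return `read_feature_table` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c(feature_schema(), "element",
            if ("label" %in% names(table)) "label")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(feature_schema(), "element"), names(out))
  if (length(missing) > 0) {
    stop(sprintf("feature table misses column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out
}
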