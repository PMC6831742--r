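## Charge post-processing: united-atom merging, excess redistribution, PQR.

#' Construct a charge assignment
#'
#' Per-atom partial charges (units of e) aligned to a molecule's atom
#' order, together with the intended integer net charge.
#'
#' @param charges numeric vector, one value per atom.
#' @param target_net intended total charge (defaults to 0; for parsed
#'   molecules use the sum of formal charges).
#' @return Object of class `"charge_assignment"` with fields `charges`,
#'   `net` (= `sum(charges)`), `target_net`.
#' @export
charge_assignment <- function(charges, target_net = 0) {
  charges <- as.numeric(charges)
  if (length(charges) == 0) stop("empty charge assignment", call. = FALSE)
  if (any(!is.finite(charges))) stop("non-finite charge", call. = FALSE)
  structure(list(charges = charges, net = sum(charges),
                 target_net = target_net),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat(sprintf("<charge_assignment: %d atoms, net %+.4f e (target %+g)>\n",
              length(x$charges), x$net, x$target_net))
  invisible(x)
}

#' Merge nonpolar hydrogens into their parent carbons
#'
#' United-atom remapping in the GROMOS convention: every hydrogen bonded
#' to a carbon is removed and its charge added to that carbon; hydrogens
#' on N, O or S (polar) are retained.  Total charge is conserved exactly.
#'
#' @param mol a [molecule()].
#' @param ca a [charge_assignment()] aligned to `mol`.
#' @return List with the reduced `molecule` and the remapped
#'   `charge_assignment`.
#' @export
merge_nonpolar_hydrogens <- function(mol, ca) {
  stopifnot(inherits(mol, "molecule"), inherits(ca, "charge_assignment"))
  n <- n_atoms(mol)
  if (length(ca$charges) != n) {
    stop("charge assignment not aligned to molecule", call. = FALSE)
  }
  b <- mol$bonds
  elem <- mol$atoms$element
  h_idx <- which(elem == "H")
  drop <- logical(n)
  charges <- ca$charges
  for (h in h_idx) {
    partners <- c(b$j[b$i == h], b$i[b$j == h])
    if (length(partners) != 1) {
      stop(sprintf("hydrogen atom %d has %d bonds (expected exactly 1)",
                   h, length(partners)), call. = FALSE)
    }
    if (elem[partners] == "C") {
      charges[partners] <- charges[partners] + charges[h]
      drop[h] <- TRUE
    }
  }
  if (!any(drop)) {
    return(list(molecule = mol, charges = charge_assignment(charges,
                                                            ca$target_net)))
  }
  keep <- which(!drop)
  remap <- match(seq_len(n), keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  bonds <- b[!(drop[b$i] | drop[b$j]), , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  out_mol <- molecule(atoms, bonds, id = mol$id,
                      source_format = mol$source_format,
                      orders_known = mol$orders_known)
  list(molecule = out_mol,
       charges = charge_assignment(charges[keep], ca$target_net))
}

#' Redistribute excess net charge equally over all atoms
#'
#' Prediction can leave a molecule with a fractional net charge; the
#' excess `net - target_net` is removed by subtracting an equal share from
#' every atom.  Idempotent, and preserves all pairwise charge differences.
#'
#' @param ca a [charge_assignment()].
#' @return Corrected `charge_assignment` whose net equals `target_net` (to
#'   1e-9).
#' @export
redistribute_excess <- function(ca) {
  stopifnot(inherits(ca, "charge_assignment"))
  n <- length(ca$charges)
  shift <- (sum(ca$charges) - ca$target_net) / n
  charge_assignment(ca$charges - shift, ca$target_net)
}

#' Write a charge-annotated PQR file
#'
#' Whitespace-dialect PQR: `ATOM` records with serial, atom name, residue,
#' coordinates, then charge (4 decimals) and radius from the covalent
#' radius table.  `parse_pqr()` recovers the charges to 1e-4.
#'
#' @param mol a [molecule()] with coordinates.
#' @param ca a [charge_assignment()] aligned to `mol`.
#' @param radius_table named radii (Angstrom) per element; defaults to the
#'   covalent radii.
#' @return A single PQR string.
#' @export
write_pqr <- function(mol, ca, radius_table = COVALENT_RADIUS) {
  stopifnot(inherits(mol, "molecule"), inherits(ca, "charge_assignment"))
  if (length(ca$charges) != n_atoms(mol)) {
    stop("charge assignment not aligned to molecule", call. = FALSE)
  }
  mol <- embed_coordinates(mol)
  xyz <- coords_matrix(mol)
  lines <- sprintf("ATOM  %5d %-4s %-4s %5d %11.4f %8.4f %8.4f %8.4f %7.4f",
                   seq_len(n_atoms(mol)), mol$atoms$name, "MOL", 1L,
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   ca$charges, radius_table[mol$atoms$element])
  paste(c(lines, "END"), collapse = "\n")
}

#' @rdname write_pqr
#' @param text PQR content (string or lines).
#' @return `parse_pqr` returns a data.frame with `name`, `x`, `y`, `z`,
#'   `charge`, `radius`.
#' @export
parse_pqr <- function(text) {
  lines <- split_lines(text)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0) stop("no ATOM records in PQR", call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(name = p[3],
               x = as.numeric(p[6]), y = as.numeric(p[7]),
               z = as.numeric(p[8]),
               charge = as.numeric(p[9]), radius = as.numeric(p[10]),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Write per-atom charges as CSV
#'
#' Columns: atom index, name, element, charge (units of e).
#'
#' @param mol a [molecule()].
#' @param ca aligned [charge_assignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charge_csv <- function(mol, ca, path) {
  stopifnot(length(ca$charges) == n_atoms(mol))
  utils::write.csv(data.frame(index = seq_len(n_atoms(mol)),
                              name = mol$atoms$name,
                              element = mol$atoms$element,
                              charge = ca$charges),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
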