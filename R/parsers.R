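## Native readers/writers for PDB, SDF V2000 and a SMILES subset.

split_lines <- function(text) {
  if (length(text) == 1) text <- strsplit(text, "\r?\n")[[1]]
  text
}

#' Parse a PDB file into a molecule
#'
#' Reads ATOM/HETATM records in file order.  The element symbol is taken
#' from columns 77-78, falling back to the atom-name field (columns 13-16)
#' when absent.  Bonds come from CONECT records when any are present;
#' otherwise they are perceived from interatomic distances with
#' [perceive_bonds()].
#'
#' @param text PDB file content: a single string or a character vector of
#'   lines.
#' @return A [molecule()] with `source_format = "pdb"`.
#' @export
parse_pdb <- function(text) {
  lines <- split_lines(text)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(atom_lines) == 0) {
    stop("no ATOM/HETATM records found", call. = FALSE)
  }
  serials <- integer(length(atom_lines))
  atoms <- data.frame(element = character(length(atom_lines)),
                      name = character(length(atom_lines)),
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      formal_charge = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(atom_lines)) {
    ln <- lines[atom_lines[k]]
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    name <- trimws(substr(ln, 13, 16))
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    if (is.na(serial) || is.na(x) || is.na(y) || is.na(z)) {
      stop(sprintf("malformed ATOM/HETATM record at line %d", atom_lines[k]),
           call. = FALSE)
    }
    el <- normalize_element(substr(ln, 77, 78))
    if (el == "") {
      ## fall back to the atom-name field: leading element symbol
      el <- sub("[^A-Za-z].*$", "", name)
      el <- normalize_element(el)
      if (!el %in% supported_elements() && nchar(el) > 1) {
        el <- normalize_element(substr(el, 1, 1))
      }
    }
    check_elements(el, sprintf("PDB line %d", atom_lines[k]))
    serials[k] <- serial
    atoms$element[k] <- el
    atoms$name[k] <- if (nzchar(name)) name else el
    atoms$x[k] <- x; atoms$y[k] <- y; atoms$z[k] <- z
  }
  idx_of <- stats::setNames(seq_along(serials), serials)

  conect <- which(trimws(rec) == "CONECT")
  orders_known <- TRUE
  if (length(conect) > 0) {
    pairs <- list()
    for (ln in lines[conect]) {
      ids <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                  "\\s+")[[1]]))
      ids <- ids[!is.na(ids)]
      if (length(ids) < 2) next
      a <- idx_of[as.character(ids[1])]
      for (b0 in ids[-1]) {
        b <- idx_of[as.character(b0)]
        if (is.na(a) || is.na(b) || a == b) next
        pairs[[length(pairs) + 1]] <- c(min(a, b), max(a, b))
      }
    }
    bm <- unique(do.call(rbind, pairs))
    bonds <- data.frame(i = bm[, 1], j = bm[, 2], order = 1L, aromatic = FALSE)
    orders_known <- FALSE  # CONECT carries connectivity only, not orders
  } else {
    bonds <- perceive_bonds(atoms)
    orders_known <- FALSE
  }
  molecule(atoms, bonds, id = "PDB", source_format = "pdb",
           orders_known = orders_known)
}

#' Parse an SDF/MOL V2000 block into a molecule
#'
#' Atoms and bonds are transcribed exactly as listed.  Bond order 4 (the
#' V2000 aromatic convention) maps to `order = 1` with `aromatic = TRUE`.
#'
#' @param text SDF V2000 content (single string or lines); only the first
#'   molecule block is read.
#' @return A [molecule()] with `source_format = "sdf"`.
#' @export
parse_sdf <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 4) stop("truncated SDF block", call. = FALSE)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed V2000 counts line", call. = FALSE)
  if (na < 1) stop("SDF molecule has no atoms", call. = FALSE)
  if (length(lines) < 4 + na + nb) {
    stop("SDF counts line does not match block length", call. = FALSE)
  }
  atom_block <- lines[4 + seq_len(na)]
  x <- suppressWarnings(as.numeric(substr(atom_block, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_block, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_block, 21, 30)))
  el <- normalize_element(substr(atom_block, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed SDF atom block", call. = FALSE)
  }
  check_elements(el, "SDF atom block")
  atoms <- data.frame(element = el, name = el, x = x, y = y, z = z,
                      formal_charge = 0L, stringsAsFactors = FALSE)
  if (nb > 0) {
    bond_block <- lines[4 + na + seq_len(nb)]
    bi <- suppressWarnings(as.integer(substr(bond_block, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bond_block, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(bond_block, 7, 9)))
    if (anyNA(bi) || anyNA(bj) || anyNA(bo)) {
      stop("malformed SDF bond block", call. = FALSE)
    }
    aromatic <- bo == 4L
    bo[aromatic] <- 1L
    bonds <- data.frame(i = bi, j = bj, order = bo, aromatic = aromatic)
  } else {
    bonds <- NULL
  }
  id <- trimws(lines[1])
  molecule(atoms, bonds, id = if (nzchar(id)) id else "SDF",
           source_format = "sdf", orders_known = TRUE)
}

#' Write a molecule as an SDF V2000 block
#'
#' Output is bit-stable for a fixed molecule; aromatic bonds are emitted as
#' V2000 order 4.  `parse_sdf(write_sdf(mol))` reproduces atoms, bonds and
#' orders exactly.
#'
#' @param mol a [molecule()] with coordinates.
#' @return A single string holding the SDF block (terminated by `$$$$`).
#' @export
write_sdf <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  xyz <- coords_matrix(mol)
  if (anyNA(xyz)) stop("write_sdf requires coordinates", call. = FALSE)
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  header <- c(mol$id, "  molcharge", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element)
  b <- mol$bonds
  ord <- ifelse(b$aromatic, 4L, b$order)
  bonds <- if (nb > 0) sprintf("%3d%3d%3d  0", b$i, b$j, ord) else character(0)
  paste(c(header, counts, atoms, bonds, "M  END", "$$$$"), collapse = "\n")
}

## ---- SMILES subset ---------------------------------------------------------

SMILES_BOND_ORDER <- c("-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L)

#' Parse a SMILES string (connectivity subset)
#'
#' Supports the organic-subset atoms of the ten supported elements
#' (aromatic lowercase `c n o s` included), bracket atoms with explicit H
#' count and formal charge, bond symbols `- = # :`, branches and ring
#' closures (digits and `%nn`).  Stereochemistry marks (`/ \ @`) are
#' rejected as unsupported.  Implicit hydrogens are added to fill standard
#' valences (aromatic bonds counting 1.5); coordinates are left absent and
#' can be synthesized with [embed_coordinates()].
#'
#' @param text a SMILES string.
#' @return A [molecule()] with `source_format = "smiles"` and `NA`
#'   coordinates.
#' @export
parse_smiles <- function(text) {
  s <- trimws(text[1])
  if (!nzchar(s)) stop("empty SMILES", call. = FALSE)
  if (grepl("[/\\\\@]", s)) {
    stop("stereochemistry symbols are not supported", call. = FALSE)
  }
  chars <- strsplit(s, "")[[1]]
  n_el <- character(0); n_arom <- logical(0)
  n_hexp <- integer(0)   # explicit bracket H count (NA = implicit fill)
  n_chg <- integer(0)
  bonds <- list()
  stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list()    # closure label -> list(atom, bond)

  add_atom <- function(el, arom, hexp, chg) {
    n_el[length(n_el) + 1] <<- el
    n_arom[length(n_arom) + 1] <<- arom
    n_hexp[length(n_hexp) + 1] <<- hexp
    n_chg[length(n_chg) + 1] <<- chg
    idx <- length(n_el)
    if (prev > 0L) {
      arom_bond <- if (!is.na(pending_bond)) pending_bond == ":" else
        (arom && n_arom[prev])
      ord <- if (!is.na(pending_bond)) SMILES_BOND_ORDER[[pending_bond]] else 1L
      bonds[[length(bonds) + 1]] <<- list(i = prev, j = idx, order = ord,
                                          aromatic = arom_bond)
    }
    prev <<- idx
    pending_bond <<- NA_character_
  }
  close_ring <- function(label) {
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      ring_open[[label]] <<- NULL
      bsym <- if (!is.na(pending_bond)) pending_bond else op$bond
      arom_bond <- if (!is.na(bsym)) bsym == ":" else
        (n_arom[prev] && n_arom[op$atom])
      ord <- if (!is.na(bsym)) SMILES_BOND_ORDER[[bsym]] else 1L
      if (op$atom == prev) stop("ring closure to self", call. = FALSE)
      bonds[[length(bonds) + 1]] <<- list(i = op$atom, j = prev, order = ord,
                                          aromatic = arom_bond)
    } else {
      ring_open[[label]] <<- list(atom = prev, bond = pending_bond)
    }
    pending_bond <<- NA_character_
  }

  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    nxt <- if (i < length(chars)) chars[i + 1] else ""
    if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch before any atom", call. = FALSE)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unmatched closing parenthesis", call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) stop("ring closure before any atom", call. = FALSE)
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2 > length(chars) || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2]))) {
        stop("malformed %nn ring closure", call. = FALSE)
      }
      close_ring(paste0(chars[i + 1], chars[i + 2])); i <- i + 3L
    } else if (ch == "[") {
      close_idx <- i + match("]", chars[(i + 1):length(chars)])
      if (is.na(close_idx)) stop("unmatched bracket", call. = FALSE)
      inner <- paste(chars[(i + 1):(close_idx - 1)], collapse = "")
      m <- regmatches(inner, regexec(
        "^([A-IK-PR-Za-ik-pr-z][a-z]?)(H([0-9]*))?(([+-])([0-9]*)|([+]+)|(-+))?$",
        inner))[[1]]
      if (length(m) == 0) stop(sprintf("unsupported bracket atom [%s]", inner),
                               call. = FALSE)
      raw_el <- m[2]
      arom <- raw_el %in% c("c", "n", "o", "s", "p")
      el <- normalize_element(raw_el)
      check_elements(el, "SMILES")
      hexp <- if (nzchar(m[3])) {
        if (nzchar(m[4])) as.integer(m[4]) else 1L
      } else 0L
      chg <- 0L
      if (nzchar(m[5] %||% "")) {
        if (nzchar(m[6])) {
          mag <- if (nzchar(m[7])) as.integer(m[7]) else 1L
          chg <- if (m[6] == "+") mag else -mag
        } else if (nzchar(m[8])) {
          chg <- nchar(m[8])
        } else if (nzchar(m[9])) {
          chg <- -nchar(m[9])
        }
      }
      add_atom(el, arom, hexp, chg)
      i <- close_idx + 1L
    } else {
      ## organic-subset atom, two-letter symbols first
      two <- paste0(ch, nxt)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, NA_integer_, 0L); i <- i + 2L
      } else if (ch %in% c("C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, NA_integer_, 0L); i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s")) {
        add_atom(toupper(ch), TRUE, NA_integer_, 0L); i <- i + 1L
      } else {
        stop(sprintf("unsupported SMILES character '%s'", ch), call. = FALSE)
      }
    }
  }
  if (length(stack) > 0) stop("unmatched opening parenthesis", call. = FALSE)
  if (length(ring_open) > 0) {
    stop(sprintf("unmatched ring closure digit(s): %s",
                 paste(names(ring_open), collapse = ", ")), call. = FALSE)
  }
  if (length(n_el) == 0) stop("no atoms in SMILES", call. = FALSE)

  ## implicit hydrogen fill: valence minus bond-order sum (aromatic = 1.5)
  nheavy <- length(n_el)
  bsum <- numeric(nheavy)
  for (b in bonds) {
    w <- if (b$aromatic) 1.5 else as.numeric(b$order)
    bsum[b$i] <- bsum[b$i] + w
    bsum[b$j] <- bsum[b$j] + w
  }
  n_h <- integer(nheavy)
  for (k in seq_len(nheavy)) {
    if (is.na(n_hexp[k])) {
      want <- FILL_VALENCE[[n_el[k]]] + abs(n_chg[k]) * 0  # charge not valence-adjusted
      n_h[k] <- max(0L, as.integer(floor(want - bsum[k])))
    } else {
      n_h[k] <- n_hexp[k]
    }
  }
  el_all <- c(n_el, rep("H", sum(n_h)))
  chg_all <- c(n_chg, rep(0L, sum(n_h)))
  h_idx <- nheavy
  for (k in seq_len(nheavy)) {
    for (u in seq_len(n_h[k])) {
      h_idx <- h_idx + 1L
      bonds[[length(bonds) + 1]] <- list(i = k, j = h_idx, order = 1L,
                                         aromatic = FALSE)
    }
  }
  atoms <- data.frame(element = el_all, name = el_all,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      formal_charge = chg_all, stringsAsFactors = FALSE)
  bdf <- do.call(rbind, lapply(bonds, as.data.frame))
  molecule(atoms, bdf, id = s, source_format = "smiles", orders_known = TRUE)
}
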