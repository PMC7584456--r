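# Structure data model and PDB/mmCIF input/output.
#
# A `Structure` keeps the atom table (identity only) separate from the
# coordinates, which live in `models`: a list of n_atoms x 3 matrices,
# one per MODEL in the source file. Author residue numbering is
# preserved exactly; no renumbering happens anywhere in the package.

new_structure <- function(atom, models, metadata = list()) {
  stopifnot(is.data.frame(atom), is.list(models), length(models) >= 1)
  for (m in models) {
    stopifnot(is.matrix(m), nrow(m) == nrow(atom), ncol(m) == 3)
  }
  rownames(atom) <- NULL
  structure(
    list(atom = atom, models = models, metadata = metadata),
    class = "Structure"
  )
}

#' Number of atoms / models in a Structure
#' @param s a `Structure`.
#' @return integer count.
#' @export
n_atoms <- function(s) nrow(s$atom)

#' @rdname n_atoms
#' @export
n_models <- function(s) length(s$models)

#' Coordinates of one model
#' @param s a `Structure`.
#' @param model model index (1-based).
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
coords <- function(s, model = 1) s$models[[model]]

#' Replace coordinates of one model
#' @param s a `Structure`.
#' @param xyz n_atoms x 3 matrix.
#' @param model model index.
#' @return the modified `Structure`.
#' @export
set_coords <- function(s, xyz, model = 1) {
  stopifnot(nrow(xyz) == n_atoms(s), ncol(xyz) == 3)
  s$models[[model]] <- xyz
  s
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf(
    "Structure: %d atoms, %d chain(s) [%s], %d model(s)\n",
    n_atoms(x), length(unique(x$atom$chain)),
    paste(sort(unique(x$atom$chain)), collapse = ","), n_models(x)
  ))
  invisible(x)
}

infer_element <- function(name) {
  # First alphabetic character of the stripped atom name; two-letter
  # elements in protein context are rare and handled by the vdW fallback.
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name)))
  toupper(substr(nm, 1, 1))
}

# Resolve alternate locations: keep the highest-occupancy conformer,
# ties broken in favour of altloc 'A' (then alphabetical).
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(rep(TRUE, nrow(atom)))
  key <- paste(atom$chain, atom$resno, atom$elety, sep = "|")
  occ <- atom$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) <= 1) next
    ord <- order(-occ[idx], alt[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  keep
}

#' Read a structure from PDB or mmCIF
#'
#' Parses fixed-column PDB (including multi-MODEL NMR-style ensembles)
#' or mmCIF files into a [Structure]. Atom order follows the file,
#' author residue numbers are kept exactly, hydrogens are flagged, and
#' alternate locations are reduced to the highest-occupancy conformer
#' (ties resolved toward altloc 'A').
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`. mmCIF is
#'   read-only; [write_structure()] emits PDB.
#' @return a `Structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)

  elem <- trimws(atom$elesy %||% rep("", nrow(atom)))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    warning(sum(bad), " atom(s) without element symbol; inferred from atom name")
    elem[bad] <- infer_element(atom$elety[bad])
  }
  keep <- resolve_altloc(atom)

  models <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    colnames(m) <- c("x", "y", "z")
    m[keep, , drop = FALSE]
  })
  atom <- atom[keep, , drop = FALSE]
  elem <- toupper(elem[keep])
  tab <- data.frame(
    serial = atom$eleno,
    name = trimws(atom$elety),
    element = elem,
    resname = trimws(atom$resid),
    chain = ifelse(is.na(atom$chain), " ", atom$chain),
    resid = atom$resno,
    is_hydrogen = elem %in% c("H", "D"),
    stringsAsFactors = FALSE
  )
  new_structure(tab, models, metadata = list(source = path, format = format))
}

#' Write a structure as fixed-column PDB
#'
#' Emits a standard PDB file re-readable by [read_structure()];
#' multi-model structures are written with MODEL/ENDMDL records.
#'
#' @param s a `Structure` (must contain at least one atom).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  if (n_atoms(s) == 0) stop("cannot write an empty Structure")
  xyz_all <- do.call(rbind, s$models)
  if (any(abs(xyz_all) > 9999.999)) {
    stop("coordinate overflow: PDB fixed columns hold at most 9999.999 A")
  }
  xyz <- do.call(rbind, lapply(s$models, function(m) as.vector(t(m))))
  bio3d::write.pdb(
    file = path,
    xyz = if (nrow(xyz) == 1) xyz[1, ] else xyz,
    resno = s$atom$resid,
    resid = s$atom$resname,
    eleno = s$atom$serial,
    elety = s$atom$name,
    chain = s$atom$chain,
    elesy = s$atom$element
  )
  invisible(path)
}

#' Select atoms with a minimal chain:resid:atom grammar
#'
#' Selection strings have the form `"chain:resid_range:atom_names"`,
#' e.g. `"A:100-200:CA"`. Each of the three fields may be `*` (any);
#' chains and atom names accept `+`-separated alternatives, residue
#' ranges accept `lo-hi` or `+`-separated single values. Several
#' selections may be joined with `;` (union). `hydrogens = FALSE`
#' restricts to heavy atoms.
#'
#' @param s a `Structure`.
#' @param selection selection string (default `"*:*:*"`).
#' @param hydrogens keep hydrogen/deuterium atoms?
#' @return logical vector over atoms.
#' @export
select_atoms <- function(s, selection = "*:*:*", hydrogens = TRUE) {
  hit <- rep(FALSE, n_atoms(s))
  for (term in strsplit(selection, ";", fixed = TRUE)[[1]]) {
    parts <- strsplit(trimws(term), ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop("bad selection term '", term, "'; expected chain:resid:atoms")
    }
    ok <- rep(TRUE, n_atoms(s))
    if (parts[1] != "*") {
      ok <- ok & s$atom$chain %in% strsplit(parts[1], "+", fixed = TRUE)[[1]]
    }
    if (parts[2] != "*") {
      resids <- integer(0)
      for (piece in strsplit(parts[2], "+", fixed = TRUE)[[1]]) {
        if (grepl("-", piece) && !grepl("^-", piece)) {
          lim <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
          resids <- c(resids, seq(lim[1], lim[2]))
        } else {
          resids <- c(resids, as.integer(piece))
        }
      }
      ok <- ok & s$atom$resid %in% resids
    }
    if (parts[3] != "*") {
      ok <- ok & s$atom$name %in% strsplit(parts[3], "+", fixed = TRUE)[[1]]
    }
    hit <- hit | ok
  }
  if (!hydrogens) hit <- hit & !s$atom$is_hydrogen
  hit
}

#' Extract chains into a new Structure
#' @param s a `Structure`.
#' @param chains character vector of chain identifiers.
#' @return a `Structure` restricted to those chains.
#' @export
extract_chains <- function(s, chains) {
  idx <- s$atom$chain %in% chains
  if (!any(idx)) stop("no atoms in chain(s) ", paste(chains, collapse = ","))
  new_structure(
    s$atom[idx, , drop = FALSE],
    lapply(s$models, function(m) m[idx, , drop = FALSE]),
    s$metadata
  )
}

#' Merge two structures (atom tables concatenated, model 1 only)
#' @param a,b `Structure` objects with disjoint chain identifiers.
#' @return combined `Structure` (single model).
#' @export
merge_structures <- function(a, b) {
  if (length(intersect(unique(a$atom$chain), unique(b$atom$chain)))) {
    stop("chain identifiers overlap; rename before merging")
  }
  atom <- rbind(a$atom, b$atom)
  atom$serial <- seq_len(nrow(atom))
  new_structure(atom, list(rbind(coords(a), coords(b))), a$metadata)
}

# Atom identity key used for pairing atoms across structures.
atom_key <- function(atom) paste(atom$chain, atom$resid, atom$name, sep = "|")

# Residue-level key.
res_key <- function(atom) paste(atom$chain, atom$resid, sep = "|")
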