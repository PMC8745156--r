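# Structure container and PDB/mmCIF reading (via bio3d).

water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a protein structure from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' generators. Coordinates must be finite, every element must have a
#' radius, and (chain, residue number, atom name) must be unique.
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer),
#'   `resname` (three-letter code), `atomname`, `element`, `x`, `y`, `z`
#'   (Angstrom) and `het` (logical heteroatom flag).
#' @param radii Named numeric vector of van der Waals radii per element.
#' @return A `protein_structure` object.
#' @export
protein_structure <- function(atoms, radii = default_vdw_radii) {
  need <- c("chain", "resno", "resname", "atomname", "element",
            "x", "y", "z", "het")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  if (nrow(atoms) == 0) stop("empty atom selection")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  if (any(radii[unique(atoms$element)] <= 0)) stop("radii must be > 0")
  key <- paste(atoms$chain, atoms$resno, atoms$atomname)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 radii = radii[sort(unique(atoms$element))]),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d atoms, %d residue(s), chain(s) %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resno")])),
              paste(sort(unique(x$atoms$chain)), collapse = ",")))
  invisible(x)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d (`read.pdb` / `read.cif`); the result is
#' reduced to the heavy-atom protein content the surface-area layer needs.
#' Waters and hydrogens are always dropped; other heteroatoms (e.g. bound
#' FAD and SAH cofactors) are dropped unless `keep_hetero = TRUE` —
#' the packaged relative-accessibility values are protein-only surfaces.
#' Alternate locations are resolved to the highest occupancy, ties to the
#' lowest altloc identifier.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chains Optional character vector; keep only these chains.
#' @param keep_hetero Keep non-water heteroatom residues (default FALSE).
#' @param radii Van der Waals radii table, see [default_vdw_radii].
#' @return A `protein_structure`.
#' @export
read_structure <- function(path, chains = NULL, keep_hetero = FALSE,
                           radii = default_vdw_radii) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot read structure '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at$element <- toupper(trimws(at$elesy))
  no_elem <- is.na(at$element) | at$element == ""
  at$element[no_elem] <- guess_element(at$elety[no_elem])
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  at <- at[!at$resid %in% water_resnames, , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("empty selection (no protein atoms",
                          if (!is.null(chains))
                            paste0(" in chain(s) ",
                                   paste(chains, collapse = ",")),
                          ")")
  at <- resolve_altloc(at)
  protein_structure(data.frame(
    chain = at$chain, resno = as.integer(at$resno), resname = at$resid,
    atomname = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z, het = at$type != "ATOM",
    stringsAsFactors = FALSE), radii = radii)
}

# element from an atom name: strip digits/primes, take leading letters;
# two-letter elements only when they match a known radius key
guess_element <- function(atomname) {
  vapply(atomname, function(a) {
    a <- gsub("[0-9'\"]", "", trimws(a))
    if (nchar(a) == 0) return(NA_character_)
    two <- toupper(substr(a, 1, 2))
    if (two %in% c("SE")) two else toupper(substr(a, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  at$..row <- seq_len(nrow(at))
  # best occupancy first, ties to the lowest altloc letter; keep first per key
  ord <- order(paste(at$chain, at$resno, at$elety), -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$..row), , drop = FALSE]
  at$..row <- NULL
  at
}

#' Atom coordinates as a matrix
#' @param struct A `protein_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
structure_xyz <- function(struct) {
  as.matrix(struct$atoms[c("x", "y", "z")])
}

# per-atom van der Waals radii
structure_radii <- function(struct) {
  unname(struct$radii[struct$atoms$element])
}

#' Subset a structure by chain
#' @param struct A `protein_structure`.
#' @param chains Chains to keep.
#' @return A `protein_structure`.
#' @export
subset_chains <- function(struct, chains) {
  keep <- struct$atoms$chain %in% chains
  if (!any(keep)) stop("empty selection (no atoms in chain(s) ",
                       paste(chains, collapse = ","), ")")
  protein_structure(struct$atoms[keep, , drop = FALSE], radii = struct$radii)
}

#' Write a structure as minimal PDB text
#'
#' Emits plain `ATOM`/`HETATM` records (the dialect [read_structure()]
#' consumes); used by the synthetic generators to exercise file I/O.
#'
#' @param struct A `protein_structure`.
#' @param path Output path ending in `.pdb`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  a <- struct$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  lines <- sprintf(
    "%s%5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), substr(a$atomname, 1, 4),
    substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resno,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
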