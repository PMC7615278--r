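#' Atom tibbles
#'
#' Structures are represented as one tibble row per atom with columns:
#' `serial`, `chain`, `res_seq` (author numbering), `ins` (insertion code,
#' "" if none), `res_name` (3-letter), `atom_name`, `alt_loc`, `element`,
#' `x`, `y`, `z` (Angstrom), `occupancy`, `b_factor`, `is_heavy`
#' (element is not H/D), `is_het` (HETATM record, includes waters).
#' The tibble carries attributes `id` and `source_format` and class
#' `fl_structure` so that methods can dispatch, but every verb that works on
#' a tibble works on it unchanged.
#'
#' @param atoms a data frame with at least `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`. Missing bookkeeping columns are
#'   filled with defaults.
#' @param id structure identifier string.
#' @param source_format `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @return An atom tibble of class `fl_structure`.
#' @export
as_structure <- function(atoms, id = "model", source_format = "synthetic") {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n)
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"alt_loc" %in% names(atoms)) atoms$alt_loc <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  if (!"is_het" %in% names(atoms)) atoms$is_het <- FALSE
  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  if (!all(is.finite(coords(atoms))))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]", call. = FALSE)
  cols <- c("serial", "chain", "res_seq", "ins", "res_name", "atom_name",
            "alt_loc", "element", "x", "y", "z", "occupancy", "b_factor",
            "is_heavy", "is_het")
  atoms <- atoms[, c(cols, setdiff(names(atoms), cols))]
  attr(atoms, "id") <- id
  attr(atoms, "source_format") <- source_format
  class(atoms) <- c("fl_structure", class(tibble::tibble()))
  atoms
}

#' Element inferred from a PDB atom name (fallback when the element column
#' is absent or blank): first alphabetic character, with the conventional
#' exception that names starting with a digit (e.g. "1HB") are hydrogens.
#' @noRd
infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z0-9]", "", atom_name)
  first <- substr(nm, 1, 1)
  el <- ifelse(grepl("^[0-9]", nm), "H", toupper(first))
  el
}

#' Read a structure file
#'
#' Reads PDB or mmCIF into an atom tibble. All ATOM and HETATM records are
#' kept; waters and other het groups are flagged via `is_het` rather than
#' dropped. Alternate locations are reduced to a single conformer per atom:
#' the highest occupancy wins, ties go to the alphabetically first alt-loc
#' id, because every downstream geometric operation assumes one position per
#' atom. Unknown or blank elements are inferred from the atom name with a
#' warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An atom tibble (class `fl_structure`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  element <- a$elesy
  bad <- is.na(element) | element == "" | !grepl("^[A-Za-z]", element)
  if (any(bad)) {
    warning(sum(bad), " atom(s) without a usable element symbol; inferred from atom names")
    element[bad] <- infer_element(a$elety[bad])
  }
  atoms <- tibble::tibble(
    serial = a$eleno,
    chain = as.character(a$chain),
    res_seq = as.integer(a$resno),
    ins = ifelse(is.na(a$insert) | a$insert == " ", "", as.character(a$insert)),
    res_name = as.character(a$resid),
    atom_name = as.character(a$elety),
    alt_loc = ifelse(is.na(a$alt) | a$alt == " ", "", as.character(a$alt)),
    element = toupper(element),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, pmin(pmax(a$o, 0), 1)),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    is_het = a$type == "HETATM"
  )
  atoms <- collapse_altlocs(atoms)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$res_seq, atoms$ins), ]
  as_structure(atoms, id = tools::file_path_sans_ext(basename(path)),
               source_format = format)
}

# Keep one conformer per (chain, res, atom name): highest occupancy, ties to
# the first alt-loc id alphabetically.
collapse_altlocs <- function(atoms) {
  if (!any(atoms$alt_loc != "")) return(atoms)
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$atom_name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$alt_loc)
  keep <- !duplicated(key[ord])
  idx <- sort(ord[keep])
  atoms[idx, ]
}

#' Select atoms
#'
#' Filters an atom tibble by chain, residue range, atom names and heavy/het
#' status. Never reorders atoms and is idempotent; selecting a chain that is
#' absent returns an empty tibble, not an error.
#'
#' @param atoms atom tibble.
#' @param chain character vector of chain ids, or `NULL` for all.
#' @param res_range `c(lo, hi)` inclusive author-numbering range, or `NULL`.
#' @param atom_names character vector (e.g. `"CA"`), or `NULL`.
#' @param heavy_only drop hydrogens/deuteriums (default `FALSE`).
#' @param drop_het drop HETATM records including waters (default `FALSE`).
#' @return The filtered atom tibble.
#' @export
select_atoms <- function(atoms, chain = NULL, res_range = NULL,
                         atom_names = NULL, heavy_only = FALSE,
                         drop_het = FALSE) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(res_range))
    keep <- keep & atoms$res_seq >= res_range[1] & atoms$res_seq <= res_range[2]
  if (!is.null(atom_names)) keep <- keep & atoms$atom_name %in% atom_names
  if (heavy_only) keep <- keep & atoms$is_heavy
  if (drop_het) keep <- keep & !atoms$is_het
  atoms[keep, ]
}

#' Write a structure as PDB
#'
#' Coordinates are written at PDB precision (3 decimals). The PDB dialect
#' carries at most 62 single-character chain ids ([A-Za-z0-9]); larger
#' models (e.g. big lattice patches) are rejected with advice to split.
#'
#' @param atoms atom tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  xyz <- coords(atoms)
  if (!all(is.finite(xyz))) stop("refusing to write non-finite coordinates",
                                 call. = FALSE)
  chains <- unique(atoms$chain)
  if (length(chains) > 62)
    stop("PDB format supports at most 62 chain ids (", length(chains),
         " present); split the model or use mmCIF-style segments", call. = FALSE)
  if (any(nchar(chains) != 1)) {
    map <- stats::setNames(chain_id_pool(length(chains)), chains)
    atoms$chain <- unname(map[atoms$chain])
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = ifelse(atoms$is_het, "HETATM", "ATOM"),
    resno = atoms$res_seq,
    resid = atoms$res_name,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain,
    insert = ifelse(atoms$ins == "", NA, atoms$ins),
    o = atoms$occupancy,
    b = atoms$b_factor,
    elesy = atoms$element
  )
  invisible(path)
}

# Sequential chain id pool A..Z, a..z, 0..9 for emitted multi-copy models.
chain_id_pool <- function(n) {
  pool <- c(LETTERS, letters, 0:9)
  if (n > length(pool)) stop("chain id pool exhausted (> 62 chains)", call. = FALSE)
  pool[seq_len(n)]
}

#' Per-chain residue table
#'
#' One row per residue in chain order: chain, res_seq, ins, res_name, and
#' the one-letter code (`X` for non-standard residues).
#' @param atoms atom tibble.
#' @return A tibble with one row per residue.
#' @export
residue_table <- function(atoms) {
  key <- !duplicated(paste(atoms$chain, atoms$res_seq, atoms$ins, sep = "\r"))
  res <- atoms[key, c("chain", "res_seq", "ins", "res_name")]
  res$aa1 <- aa_three_to_one(res$res_name)
  tibble::as_tibble(res)
}

aa_three_to_one <- function(res_name) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", MSE = "M", MLY = "K", KCX = "K")
  out <- unname(tab[toupper(res_name)])
  out[is.na(out)] <- "X"
  out
}

#' One-letter sequence of a chain (Cα-bearing residues only)
#' @param atoms atom tibble.
#' @param chain chain id.
#' @return A single string.
#' @export
chain_sequence <- function(atoms, chain) {
  ca <- select_atoms(atoms, chain = chain, atom_names = "CA", drop_het = TRUE)
  if (nrow(ca) == 0) stop("chain '", chain, "' has no CA atoms", call. = FALSE)
  paste(aa_three_to_one(ca$res_name), collapse = "")
}
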