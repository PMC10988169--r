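# Structure ingestion: PDB and mmCIF atom records as a tidy atom table.
# Parsing is delegated to bio3d; this layer applies the selection rules
# (polymer ATOM records only, first model, one conformer per altloc group)
# and normalises the result into a tibble.

STRUCTURE_COLS <- c(
  "chain", "res_seq", "icode", "res_name", "atom_name",
  "element", "x", "y", "z", "occupancy", "altloc", "b"
)

#' Read a macromolecular structure into an atom tibble
#'
#' Reads PDB (fixed-column v3.3) or mmCIF coordinates and returns a tibble
#' of polymer atoms. Defaults follow the usual comparison conventions:
#' HETATM records (ligands, waters) are excluded, only the first model of a
#' multi-model file is kept, and when a position has several alternate
#' conformers only the highest-occupancy one is retained (ties broken by
#' alphabetically first altloc id). For mmCIF, author (`auth_`) chain and
#' residue numbering is used, matching PDB-format numbering and
#' UniProt-aligned annotations.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"mmcif"`; `"auto"` picks by file extension
#'   (`.cif`/`.mmcif` vs anything else).
#' @param keep_hetatm If `TRUE`, HETATM records other than water are kept.
#' @return A tibble with columns `chain`, `res_seq`, `icode`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z` (Angstrom), `occupancy`,
#'   `altloc`, `b`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetatm = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  atoms <- as_tibble(parsed$atom)
  atoms <- structure_from_bio3d(atoms, keep_hetatm = keep_hetatm)
  if (nrow(atoms) == 0L) {
    abort(paste0("no polymer atoms in ", path,
                 " (HETATM-only files are rejected under default settings)"))
  }
  atoms
}

# Normalise a bio3d atom data frame into the package's atom tibble.
structure_from_bio3d <- function(atoms, keep_hetatm = FALSE) {
  blank_to <- function(x, fill) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- fill
    x
  }
  atoms <- mutate(atoms,
    type = as.character(.data$type),
    resid = as.character(.data$resid)
  )
  keep <- atoms$type == "ATOM"
  if (keep_hetatm) keep <- keep | (atoms$type == "HETATM" & atoms$resid != "HOH")
  atoms <- atoms[keep, , drop = FALSE]
  out <- tibble(
    chain = blank_to(atoms$chain, " "),
    res_seq = as.integer(atoms$resno),
    icode = blank_to(atoms$insert, ""),
    res_name = atoms$resid,
    atom_name = as.character(atoms$elety),
    element = blank_to(atoms$elesy, ""),
    x = as.numeric(atoms$x),
    y = as.numeric(atoms$y),
    z = as.numeric(atoms$z),
    occupancy = ifelse(is.na(atoms$o), 1, as.numeric(atoms$o)),
    altloc = blank_to(atoms$alt, ""),
    b = ifelse(is.na(atoms$b), 0, as.numeric(atoms$b))
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("malformed coordinate fields (non-finite x/y/z)")
  }
  if (is.na(out$element[1]) || any(out$element == "")) {
    out$element <- ifelse(out$element == "",
      toupper(substr(gsub("[0-9]", "", out$atom_name), 1L, 1L)),
      out$element
    )
  }
  resolve_altloc(out)
}

# Keep one conformer per (chain, res_seq, icode, atom_name): the highest
# occupancy, ties broken by alphabetically first altloc.
resolve_altloc <- function(atoms) {
  atoms |>
    group_by(.data$chain, .data$res_seq, .data$icode, .data$atom_name) |>
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$chain, .data$res_seq, .data$icode, .data$atom_name)
}

#' Write an atom tibble as a PDB file
#'
#' @param model An atom tibble (see [read_structure()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    resno = model$res_seq,
    resid = model$res_name,
    eleno = seq_len(nrow(model)),
    elety = model$atom_name,
    chain = ifelse(model$chain == "", " ", model$chain),
    insert = ifelse(model$icode == "", "", model$icode),
    alt = ifelse(model$altloc == "", "", model$altloc),
    o = model$occupancy,
    b = model$b,
    elesy = model$element
  )
  invisible(path)
}

# Internal: C-alpha records of one chain, ordered by residue number then
# insertion code. `chain = NULL` means the first chain in file order.
ca_table <- function(model, chain = NULL) {
  if (is.null(chain)) chain <- model$chain[[1L]]
  if (!chain %in% model$chain) {
    abort(paste0("chain '", chain, "' not present in model"))
  }
  model |>
    filter(.data$chain == !!chain, .data$atom_name == "CA") |>
    arrange(.data$res_seq, .data$icode)
}
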