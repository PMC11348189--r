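#' Coordinate-model container
#'
#' A `cap_structure` holds one coordinate model as a flat atom table, the
#' representation used throughout the package. Columns: `chain`, `resno`
#' (author residue number), `insert` (insertion code, `""` if none), `resid`
#' (3-letter residue code), `aa` (1-letter code, `"X"` for het groups),
#' `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z` (angstrom),
#' `o` (occupancy), `b` (B-factor or pLDDT), `het` (logical, HETATM).
#'
#' @param atoms data.frame with the columns listed above.
#' @param id text label for the model.
#' @param source_format `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @return An object of class `cap_structure`.
#' @export
cap_structure <- function(atoms, id = "structure", source_format = "synthetic") {
  needed <- c("chain", "resno", "insert", "resid", "aa", "elety", "elesy",
              "x", "y", "z", "o", "b", "het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    cap_stop("capscan_argument_error", "atom table lacks columns: %s",
             paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L)
    cap_stop("capscan_argument_error", "structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    cap_stop("capscan_validation_error", "non-finite coordinates in atom table")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    cap_stop("capscan_validation_error", "occupancies must lie in [0, 1]")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "cap_structure")
}

#' @export
print.cap_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<cap_structure> %s [%s]: %d atoms, %d chain(s): %s\n",
              x$id, x$source_format, nrow(x$atoms), length(ch),
              paste(ch, collapse = ", ")))
  invisible(x)
}

# 3-letter codes treated as polymer amino acids even when flagged HETATM
MODIFIED_AA <- c(MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S",
                 TPO = "T", PTR = "Y", CSO = "C", MLY = "K", M3L = "K")

aa_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  mod <- resid %in% names(MODIFIED_AA)
  out[mod] <- MODIFIED_AA[resid[mod]]
  out
}

#' Read a coordinate model from PDB or mmCIF
#'
#' Alternate locations are resolved to the highest-occupancy conformer (ties
#' broken by altloc letter order). Waters, ions and other het groups are
#' retained as het residues. Common modified residues (e.g. MSE) are mapped
#' to their parent amino acid.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, default).
#' @param id label for the model; defaults to the file name.
#' @return A [cap_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    cap_stop("capscan_io_error", "file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
                     cap_stop("capscan_format_error",
                              "cannot infer format from extension '.%s'", ext))
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) cap_stop("capscan_parse_error",
                                 "failed to parse %s as %s: %s",
                                 path, format, conditionMessage(e)))
  a <- parsed$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a$chain[is.na(a$chain)] <- "A"
  if (is.null(a$elesy) || all(is.na(a$elesy)))
    a$elesy <- toupper(substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1))

  # altloc policy: highest occupancy wins, ties by altloc letter order
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")), ,
           drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }

  aa <- aa_one(a$resid)
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    aa = aa, elety = a$elety, elesy = toupper(a$elesy),
    x = a$x, y = a$y, z = a$z, o = a$o, b = a$b,
    het = a$type == "HETATM" & !(a$resid %in% names(MODIFIED_AA)),
    stringsAsFactors = FALSE)
  atoms$aa[atoms$het] <- "X"
  cap_structure(atoms, id = id %||% basename(path), source_format = format)
}

#' Write a structure to a PDB file
#'
#' @param structure a [cap_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  ok <- tryCatch({
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, insert = a$insert,
                     chain = a$chain, elety = a$elety, elesy = a$elesy,
                     o = a$o, b = a$b)
    TRUE
  }, error = function(e) cap_stop("capscan_io_error",
                                  "cannot write %s: %s", path,
                                  conditionMessage(e)))
  invisible(path)
}

#' Residue-level view of one chain
#'
#' @param structure a [cap_structure].
#' @param chain_id chain identifier.
#' @param polymer_only drop het residues (waters, ions, ligands)?
#' @return data.frame with one row per residue: `resno`, `insert`, `resid`,
#'   `aa`, `het`, `has_ca`.
#' @export
residue_table <- function(structure, chain_id, polymer_only = FALSE) {
  a <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0L)
    cap_stop("capscan_lookup_error", "chain '%s' not present in %s",
             chain_id, structure$id)
  key <- paste(a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  res <- a[first, c("resno", "insert", "resid", "aa", "het")]
  res$has_ca <- vapply(split(a$elety == "CA", factor(key, levels = key[first])),
                       any, logical(1))
  if (polymer_only) res <- res[!res$het & res$aa != "X", , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' One-letter sequence of the modeled polymer residues of a chain
#' @inheritParams residue_table
#' @return character scalar.
#' @export
chain_sequence <- function(structure, chain_id) {
  res <- residue_table(structure, chain_id, polymer_only = TRUE)
  paste(res$aa, collapse = "")
}

# C-alpha coordinates for one chain as an n x 3 matrix keyed "resno|insert"
ca_xyz <- function(structure, chain_id) {
  a <- structure$atoms
  if (!chain_id %in% a$chain)
    cap_stop("capscan_lookup_error", "chain '%s' not present in %s",
             chain_id, structure$id)
  a <- a[a$chain == chain_id & a$elety == "CA" & !a$het, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$resno, a$insert, sep = "|")
  m
}

# resolve an atom selector list(chain=, resno=, elety=, insert="") to one row
resolve_selector <- function(structure, sel, what = "atom") {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain == sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno == sel$resno
  if (!is.null(sel$insert)) keep <- keep & a$insert == sel$insert
  if (!is.null(sel$resid)) keep <- keep & a$resid == sel$resid
  if (!is.null(sel$elety)) keep <- keep & a$elety == sel$elety
  idx <- which(keep)
  if (length(idx) == 0L)
    cap_stop("capscan_selection_error", "%s selector matches no atom", what)
  if (length(idx) > 1L)
    cap_stop("capscan_selection_error",
             "%s selector is ambiguous (%d matches); add chain/resno/elety",
             what, length(idx))
  idx
}
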