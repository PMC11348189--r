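#' Per-residue pLDDT confidence profile
#'
#' @param values numeric vector of pLDDT values (0-100) indexed by reference
#'   position; `NA` where the source has no value.
#' @param source short text describing where the profile came from.
#' @return A `cap_plddt` object (numeric vector with attributes).
#' @export
cap_plddt <- function(values, source = "unknown") {
  v <- as.numeric(values)
  bad <- which(!is.na(v) & (v < 0 | v > 100))
  if (length(bad))
    cap_stop("capscan_validation_error",
             "pLDDT values outside [0, 100] at positions: %s",
             paste(head(bad, 5), collapse = ", "))
  structure(v, source = source, class = "cap_plddt")
}

#' @export
print.cap_plddt <- function(x, ...) {
  cat(sprintf("<cap_plddt> %d positions (%d with values), source: %s\n",
              length(x), sum(!is.na(x)), attr(x, "source")))
  invisible(x)
}

#' Read a pLDDT profile
#'
#' Accepts either a plain two-column table (residue number, pLDDT; whitespace
#' or tab separated, `#` comments allowed) or an AlphaFold-style coordinate
#' file that stores pLDDT in the B-factor column (the per-residue value is
#' taken from the CA atom).
#'
#' @param path file path.
#' @param length_out total profile length; defaults to the largest residue
#'   number present.
#' @param chain_id chain to read when `path` is a coordinate file.
#' @return A [cap_plddt] profile.
#' @export
read_plddt <- function(path, length_out = NULL, chain_id = NULL) {
  if (!file.exists(path))
    cap_stop("capscan_io_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent", "cif", "mmcif")) {
    s <- read_structure(path)
    chain_id <- chain_id %||% s$atoms$chain[1]
    a <- s$atoms[s$atoms$chain == chain_id & s$atoms$elety == "CA" & !s$atoms$het, ]
    pos <- a$resno; val <- a$b
    src <- sprintf("B-factor column of %s", basename(path))
  } else {
    tab <- read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("pos", "plddt"))
    pos <- as.integer(tab$pos); val <- as.numeric(tab$plddt)
    src <- sprintf("table %s", basename(path))
  }
  L <- length_out %||% max(pos)
  v <- rep(NA_real_, L)
  v[pos] <- val
  cap_plddt(v, source = src)
}
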