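#' Map a chain onto a reference sequence
#'
#' Aligns the modeled polymer sequence of one chain globally
#' (Needleman-Wunsch, identity scoring with affine gaps: match +1,
#' mismatch 0, gap open 5, gap extend 0.5) against a reference amino-acid
#' sequence, so that ensemble members with different author numbering or
#' missing regions become comparable position by position.
#'
#' @param structure a [cap_structure].
#' @param chain_id chain identifier.
#' @param reference reference amino-acid sequence (character scalar).
#' @param min_identity mapping fails below this alignment identity
#'   (fraction of modeled residues identical to their mapped reference
#'   position; guards against mapping the wrong protein). Default 0.3.
#' @return A `cap_residue_map`: list with `chain_id`, `reference_length`,
#'   `resno` and `insert` vectors of length `reference_length` (`NA` where a
#'   reference position has no modeled residue), and `identity`.
#' @export
map_to_reference <- function(structure, chain_id, reference, min_identity = 0.3) {
  if (!nzchar(reference))
    cap_stop("capscan_argument_error", "reference sequence is empty")
  res <- residue_table(structure, chain_id, polymer_only = TRUE)
  if (nrow(res) == 0L)
    cap_stop("capscan_lookup_error", "chain '%s' has no polymer residues", chain_id)
  chain_seq <- paste(res$aa, collapse = "")

  alph <- unique(c(strsplit(chain_seq, "")[[1]], strsplit(reference, "")[[1]]))
  submat <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = chain_seq, subject = reference, type = "global",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 0.5)

  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  L <- nchar(reference)
  resno <- rep(NA_integer_, L)
  insert <- rep(NA_character_, L)
  i <- 0L; j <- 0L; matches <- 0L
  for (k in seq_along(pat)) {
    pi <- pat[k] != "-"; sj <- sub[k] != "-"
    if (pi) i <- i + 1L
    if (sj) j <- j + 1L
    if (pi && sj) {
      resno[j] <- res$resno[i]
      insert[j] <- res$insert[i]
      if (pat[k] == sub[k]) matches <- matches + 1L
    }
  }
  identity <- matches / nrow(res)
  if (identity < min_identity)
    cap_stop("capscan_mapping_error",
             "chain '%s' aligns to the reference with identity %.2f < %.2f; wrong protein?",
             chain_id, identity, min_identity)
  structure(list(chain_id = chain_id, reference_length = L,
                 resno = resno, insert = insert, identity = identity),
            class = "cap_residue_map")
}

#' @export
print.cap_residue_map <- function(x, ...) {
  cat(sprintf("<cap_residue_map> chain %s: %d/%d reference positions mapped, identity %.3f\n",
              x$chain_id, sum(!is.na(x$resno)), x$reference_length, x$identity))
  invisible(x)
}

#' Mapped reference positions of a residue map
#' @param map a `cap_residue_map`.
#' @return integer vector of reference positions with a modeled residue.
#' @export
mapped_positions <- function(map) which(!is.na(map$resno))

# C-alpha coordinates on the reference frame: L x 3 matrix, NA rows unmapped
reference_ca <- function(structure, chain_id, map) {
  m <- ca_xyz(structure, chain_id)
  out <- matrix(NA_real_, map$reference_length, 3)
  pos <- mapped_positions(map)
  key <- paste(map$resno[pos], ifelse(map$insert[pos] == "" | is.na(map$insert[pos]),
                                      "", map$insert[pos]), sep = "|")
  hit <- match(key, rownames(m))
  ok <- !is.na(hit)
  out[pos[ok], ] <- m[hit[ok], , drop = FALSE]
  out
}
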