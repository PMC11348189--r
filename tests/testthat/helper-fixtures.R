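# shared fixture builders (everything generated in code; no binary data)

# CA-only structure from a coordinate matrix, author numbering 1..n
ca_struct <- function(xyz, aa = NULL, id = "fixture", resno = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  aa <- aa %||% rep("A", n)
  capscan:::ca_chain_structure(xyz, resno = resno, aa = aa, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

identity_map <- function(structure, chain_id = "A") {
  map_to_reference(structure, chain_id, chain_sequence(structure, chain_id))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(structure, R, t) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(R), 2, t, "+")
  s <- structure
  s$atoms$x <- moved[, 1]; s$atoms$y <- moved[, 2]; s$atoms$z <- moved[, 3]
  s
}

# minimal hand-written PDB text fixture (3 residues + one altloc pair + water)
write_mini_pdb <- function(path) {
  lines <- c(
    "HEADER    TEST FIXTURE",
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1L, " N  ", " ", "ALA", "A", 40L, " ", 0.0, 0.0, 0.0, 1.00, 10.0, "N"),
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            2L, " CA ", " ", "ALA", "A", 40L, " ", 1.5, 0.0, 0.0, 1.00, 11.0, "C"),
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            3L, " CA ", "A", "GLY", "A", 41L, " ", 4.2, 1.1, 0.0, 0.60, 12.0, "C"),
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            4L, " CA ", "B", "GLY", "A", 41L, " ", 4.9, 1.4, 0.0, 0.40, 12.5, "C"),
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            5L, " CA ", " ", "SER", "A", 42L, " ", 7.8, 2.2, 0.1, 1.00, 13.0, "C"),
    sprintf("HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            6L, " O  ", " ", "HOH", "A", 201L, " ", 9.0, 9.0, 9.0, 1.00, 20.0, "O"),
    "END")
  writeLines(lines, path)
  path
}

# small planted ensemble for fast screen tests
small_ensemble <- function(n_members = 20L, chain_length = 120L,
                           event_segment = c(40L, 55L),
                           state_fractions = c(0.25, 0.65, 0.10),
                           displacement = 8, missing_prefix = 0L,
                           noise_sigma = 0, seed = 7L) {
  make_ensemble(ensemble_spec(
    n_members = n_members, chain_length = chain_length,
    event_segment = event_segment, state_fractions = state_fractions,
    displacement = displacement, missing_prefix = missing_prefix,
    noise_sigma = noise_sigma, seed = seed))
}

ensemble_maps <- function(ens, chain_id = "A") {
  lapply(ens$members, map_to_reference, chain_id = chain_id,
         reference = ens$reference)
}
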