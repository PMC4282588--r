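# Test helpers: independent oracles and structure builders.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Full 20-letter frequency vector from a few named probabilities.
freqs <- function(...) {
  p <- c(...)
  out <- setNames(rep(0, 20), AA20)
  out[names(p)] <- p
  out
}

# Independent entropy oracle: Shannon entropy in nats divided by ln 20,
# computed with a different code path than cleavage_entropy().
shannon_over_ln20 <- function(p) {
  p <- p[p > 0]
  sum(vapply(p, function(pi) -pi * log(pi), numeric(1))) / log(20)
}

# Brute-force window oracle: slice the P4..P4' residues out of a
# sequence string by direct indexing.
slice_window <- function(sequence, p1) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- p1 + c(-3, -2, -1, 0, 1, 2, 3, 4)
  out <- vapply(idx, function(j) {
    if (j >= 1 && j <= length(chars)) chars[j] else NA_character_
  }, character(1))
  out[!is.na(out) & out == "-"] <- NA
  setNames(out, c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'"))
}

# Brute-force per-position entropy of a substrate set: count canonical
# letters by hand and apply the normalized-entropy formula.
brute_profile <- function(set) {
  wins <- t(sapply(seq_len(nrow(set)),
                   function(i) slice_window(set$sequence[i], set$p1_pos[i])))
  sapply(colnames(wins), function(pos) {
    col <- wins[, pos]
    col <- col[!is.na(col) & col %in% AA20]
    if (length(col) == 0) return(NA_real_)
    shannon_over_ln20(table(col) / length(col))
  })
}

# Spearman oracle via the classic d^2 formula (valid without ties).
spearman_d2 <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# A rotation matrix about the z axis.
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

# Build a toy protein structure (CA-only) with the given one-letter
# sequence per chain; coordinates are a seeded random walk so the
# geometry is never degenerate. Returns list(topology, trajectory).
make_ca_structure <- function(seqs, seed = 1) {
  aa3 <- setNames(c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                    "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                    "THR", "VAL", "TRP", "TYR"), AA20)
  atoms <- do.call(rbind, lapply(names(seqs), function(ch) {
    letters1 <- strsplit(seqs[[ch]], "")[[1]]
    data.frame(elety = "CA", resid = aa3[letters1], chain = ch,
               resno = seq_along(letters1), stringsAsFactors = FALSE)
  }))
  top <- specflex::topology(atoms)
  set.seed(seed)
  steps <- matrix(rnorm(3 * nrow(top), sd = 2), ncol = 3)
  coords <- apply(steps, 2, cumsum)
  coords[, 2] <- coords[, 2] + 30 * (match(top$chain, names(seqs)) - 1)
  list(topology = top,
       trajectory = specflex::trajectory(matrix(as.numeric(t(coords)),
                                                nrow = 1)))
}

# Write a multi-model PDB by hand (text fixture built in code).
write_multimodel_pdb <- function(path, frames_atoms) {
  # frames_atoms: list of data.frames with elety, resid, chain, resno, x, y, z
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames_atoms)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    a <- frames_atoms[[m]]
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, a$elety[i], a$resid[i], a$chain[i], a$resno[i],
        a$x[i], a$y[i], a$z[i], 1.0, 0.0,
        substr(a$elety[i], 1, 1)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
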