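# Shared constants and small helpers.

# Canonical amino-acid one-letter codes, alphabetical.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Standard residue names treated as protein when classifying topologies.
AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
         "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
         "TRP", "TYR",
         # common protonation-state variants
         "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN")

# Schechter-Berger window positions, N- to C-terminal.
SB_POSITIONS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

#' Run code with a fixed RNG seed, restoring global RNG state afterwards
#'
#' All generators in the package take explicit seeds; none touches the
#' global random state of the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Coerce a coordinate argument (flat xyz vector of length 3N or an N x 3
# matrix) to an N x 3 matrix.
as_coord_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) {
    return(unname(x))
  }
  x <- as.numeric(x)
  if (length(x) %% 3L != 0L) {
    stop("coordinates must be an N x 3 matrix or a length-3N vector",
         call. = FALSE)
  }
  matrix(x, ncol = 3L, byrow = TRUE)
}

# Flatten an N x 3 coordinate matrix back to bio3d-style xyz vector.
as_xyz_vector <- function(m) {
  as.numeric(t(m))
}

# Residue key used throughout: chain + residue number (+ insertion code).
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(chain, ":", resno, insert)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
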