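# Substrate tables, scissile-bond alignment and cleavage entropy.
#
# Cleavage entropy is the normalized Shannon entropy of the amino-acid
# frequencies observed at one substrate position across all known
# cleavage events of a protease:
#
#   S_i = -sum_a p_a(i) * log20( p_a(i) ),   0*log(0) := 0
#
# The base-20 logarithm makes S_i exactly 0 for a fully specific
# position (point mass) and exactly 1 for a fully promiscuous one
# (uniform over the 20 canonical residues).

#' Construct a substrate set
#'
#' @param records data.frame with columns `id`, `sequence` (one-letter
#'   codes; `-` marks an explicit gap in pre-aligned windows) and
#'   `p1_pos` (1-based index of the P1 residue, i.e. the residue
#'   N-terminal of the scissile bond).
#' @return object of class `substrate_set`. A logical column `flagged`
#'   marks records whose window contains non-canonical residue codes.
#' @export
substrate_set <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "sequence", "p1_pos")
  if (!all(need %in% names(records))) {
    stop("substrate records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$id <- as.character(records$id)
  records$sequence <- toupper(as.character(records$sequence))
  records$p1_pos <- as.integer(records$p1_pos)
  bad_len <- !nzchar(records$sequence)
  if (any(bad_len)) stop("empty substrate sequence", call. = FALSE)
  bad_idx <- records$p1_pos < 1L |
    records$p1_pos >= nchar(records$sequence)
  if (any(bad_idx)) {
    stop("scissile index out of range for record(s): ",
         paste(records$id[bad_idx], collapse = ", "), call. = FALSE)
  }
  records$flagged <- vapply(seq_len(nrow(records)), function(i) {
    win <- window_residues(records$sequence[i], records$p1_pos[i])
    any(!is.na(win) & !(win %in% AA1))
  }, logical(1))
  class(records) <- c("substrate_set", "data.frame")
  records
}

# Residues of the P4...P4' window for one record; NA for positions
# outside the sequence or explicit "-" gaps.
window_residues <- function(sequence, p1_pos,
                            window = SB_POSITIONS) {
  chars <- strsplit(sequence, "")[[1]]
  offsets <- position_offsets(window)
  idx <- p1_pos + offsets
  out <- rep(NA_character_, length(window))
  ok <- idx >= 1L & idx <= length(chars)
  out[ok] <- chars[idx[ok]]
  out[!is.na(out) & out == "-"] <- NA_character_
  setNames(out, window)
}

# Offset of each window position relative to P1 (P1 -> 0, P4 -> -3,
# P1' -> +1, ...).
position_offsets <- function(positions) {
  vapply(positions, function(p) {
    i <- match(p, SB_POSITIONS)
    if (is.na(i)) stop("unknown window position: ", p, call. = FALSE)
    if (i <= 4L) i - 4L else i - 4L
  }, numeric(1))
}

#' Parse a substrate cleavage-site table
#'
#' Two dialects are supported. The long dialect (MEROPS-style export)
#' has columns `id`, `sequence` and `p1_position` (1-based index of the
#' P1 residue); the window dialect has eight single-residue columns
#' `P4, P3, P2, P1, P1p, P2p, P3p, P4p` (prime positions spelled with a
#' trailing `p`) and an optional `id`, with `-` or an empty cell
#' marking a gap. Rows whose scissile index is out of range are skipped
#' and collected into the `skipped` attribute; rows containing
#' non-canonical residue codes in the window are retained but flagged.
#'
#' @param path TSV/CSV file path.
#' @param dialect `"auto"` (default), `"long"` or `"window"`.
#' @param sep field separator; default tab.
#' @return a `substrate_set`; attribute `skipped` is a data.frame of
#'   rejected rows and reasons.
#' @export
parse_substrate_table <- function(path, dialect = c("auto", "long", "window"),
                                  sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty substrate table: ", path, call. = FALSE)
    out <- substrate_set(data.frame(id = "x", sequence = "AD", p1_pos = 1L))
    out <- out[0L, , drop = FALSE]
    class(out) <- c("substrate_set", "data.frame")
    attr(out, "skipped") <- data.frame(id = character(0), reason = character(0))
    return(out)
  }
  raw <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("empty substrate table: ", path, call. = FALSE)
    out <- substrate_set(data.frame(id = "x", sequence = "AD", p1_pos = 1L))
    out <- out[0L, , drop = FALSE]
    class(out) <- c("substrate_set", "data.frame")
    attr(out, "skipped") <- data.frame(id = character(0), reason = character(0))
    return(out)
  }
  wincols <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
  has_long <- all(c("sequence", "p1_position") %in% names(raw))
  has_win <- all(wincols %in% names(raw))
  if (dialect == "auto") {
    dialect <- if (has_long) "long" else if (has_win) "window" else
      stop("unrecognised substrate table format; found columns: ",
           paste(names(raw), collapse = ", "), call. = FALSE)
  }
  if (dialect == "long" && !has_long) {
    stop("long dialect requires columns id, sequence, p1_position; found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  if (dialect == "window" && !has_win) {
    stop("window dialect requires columns ",
         paste(wincols, collapse = ", "), "; found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }

  if (dialect == "long") {
    id <- if ("id" %in% names(raw)) raw$id else sprintf("row%d", seq_len(nrow(raw)))
    seqs <- toupper(raw$sequence)
    p1 <- suppressWarnings(as.integer(raw$p1_position))
    ok <- !is.na(p1) & p1 >= 1L & nzchar(seqs) & p1 < nchar(seqs)
    skipped <- data.frame(id = id[!ok],
                          reason = rep("scissile index out of range",
                                       sum(!ok)),
                          stringsAsFactors = FALSE)
    records <- data.frame(id = id[ok], sequence = seqs[ok], p1_pos = p1[ok],
                          stringsAsFactors = FALSE)
  } else {
    id <- if ("id" %in% names(raw)) raw$id else sprintf("row%d", seq_len(nrow(raw)))
    win <- as.matrix(raw[, wincols])
    win[win == "" | is.na(win)] <- "-"
    win <- toupper(win)
    seqs <- apply(win, 1L, paste, collapse = "")
    ok <- win[, "P1"] != "-"   # a window without a P1 residue has no cut
    skipped <- data.frame(id = id[!ok],
                          reason = rep("no P1 residue in window", sum(!ok)),
                          stringsAsFactors = FALSE)
    records <- data.frame(id = id[ok], sequence = seqs[ok], p1_pos = 4L,
                          stringsAsFactors = FALSE)
  }
  if (nrow(skipped) > 0L) {
    warning(nrow(skipped), " row(s) skipped (", skipped$reason[1L], ")",
            call. = FALSE)
  }
  if (nrow(records) == 0L) {
    warning("no valid substrate records in ", path, call. = FALSE)
    out <- substrate_set(data.frame(id = "x", sequence = "AD", p1_pos = 1L))
    out <- out[0L, , drop = FALSE]
    class(out) <- c("substrate_set", "data.frame")
  } else {
    out <- substrate_set(records)
    if (any(out$flagged)) {
      warning(sum(out$flagged),
              " record(s) contain non-canonical residues in the window",
              call. = FALSE)
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Align substrates at the scissile bond into a positional matrix
#'
#' Column P1 holds the residue immediately N-terminal of the cut, P1'
#' the residue immediately C-terminal; positions falling outside a
#' substrate's sequence become gaps (NA).
#'
#' @param set a `substrate_set`.
#' @param window contiguous range of positions within P4...P4'
#'   (character vector in N-to-C order; default the full window).
#' @return object of class `positional_matrix`: list with `positions`,
#'   `residues` (records x positions character matrix, NA = gap) and
#'   `n_records`.
#' @export
align_at_scissile <- function(set, window = SB_POSITIONS) {
  stopifnot(inherits(set, "substrate_set"))
  idx <- match(window, SB_POSITIONS)
  if (anyNA(idx)) {
    stop("unknown window position(s): ",
         paste(window[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    stop("window must be a contiguous range within P4...P4'", call. = FALSE)
  }
  if (nrow(set) == 0L) {
    m <- matrix(NA_character_, nrow = 0L, ncol = length(window),
                dimnames = list(NULL, window))
  } else {
    m <- t(vapply(seq_len(nrow(set)), function(i) {
      window_residues(set$sequence[i], set$p1_pos[i], window)
    }, character(length(window))))
    colnames(m) <- window
  }
  structure(list(positions = window, residues = m, n_records = nrow(set)),
            class = "positional_matrix")
}

#' Amino-acid frequencies at one window position
#'
#' Gaps and non-canonical codes are excluded from the denominator, so
#' frequencies sum to 1 over the observed canonical residues. A
#' position with zero canonical observations yields an all-NA vector
#' (an undefined-frequency signal, distinct from a zero vector) with a
#' warning.
#'
#' @param matrix a `positional_matrix`.
#' @param position position label present in the matrix.
#' @return named numeric vector over the 20 canonical residues, with
#'   attribute `n` = number of observations counted.
#' @export
positional_frequencies <- function(matrix, position) {
  stopifnot(inherits(matrix, "positional_matrix"))
  if (!position %in% matrix$positions) {
    stop("position ", position, " not in matrix window", call. = FALSE)
  }
  col <- matrix$residues[, position]
  obs <- col[!is.na(col) & col %in% AA1]
  out <- setNames(rep(0, 20L), AA1)
  if (length(obs) == 0L) {
    warning("no canonical observations at position ", position,
            "; frequencies undefined", call. = FALSE)
    out[] <- NA_real_
  } else {
    tab <- table(factor(obs, levels = AA1))
    out[] <- as.numeric(tab) / length(obs)
  }
  attr(out, "n") <- length(obs)
  out
}

#' Cleavage entropy of an amino-acid frequency vector
#'
#' Normalized Shannon entropy with base-20 logarithm:
#' `-sum(p * log(p)) / log(20)`, with the `0 * log(0) := 0` convention.
#' Ranges from 0 (fully specific, point mass) to 1 (fully promiscuous,
#' uniform over the 20 canonical residues). Undefined (all-NA)
#' frequency vectors propagate to `NA`.
#'
#' @param freqs numeric probability vector (sums to 1 within 1e-6).
#' @return entropy on `[0, 1]`, or `NA` for undefined input.
#' @export
cleavage_entropy <- function(freqs) {
  p <- as.numeric(freqs)
  if (all(is.na(p))) return(NA_real_)
  if (anyNA(p)) stop("frequency vector mixes NA and numbers", call. = FALSE)
  if (any(p < 0)) stop("negative frequency", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop(sprintf("frequencies sum to %.8f, not 1", sum(p)), call. = FALSE)
  }
  p <- p[p > 0]
  s <- -sum(p * log(p)) / log(20)
  # clip tiny negative rounding on point masses
  min(max(s, 0), 1)
}

#' Per-subpocket specificity profile of a substrate set
#'
#' Aligns the set at the scissile bond and computes cleavage entropy
#' and observation count for every window position. Following common
#' practice for substrate databases, sets with 50 or fewer records
#' trigger an inclusion warning (small sets give noisy entropies) but
#' are still profiled; no small-sample correction is applied and the
#' counts `n` are reported so users can judge.
#'
#' @param set a `substrate_set`.
#' @param window positions to profile (default P4...P4').
#' @param label protease label stored with the profile.
#' @param min_records inclusion threshold for the warning (default 50).
#' @return object of class `specificity_profile`: data.frame with
#'   columns `position`, `entropy`, `n`.
#' @export
specificity_profile <- function(set, window = SB_POSITIONS,
                                label = "protease", min_records = 50L) {
  stopifnot(inherits(set, "substrate_set"))
  if (nrow(set) < 1L) stop("substrate set is empty", call. = FALSE)
  if (nrow(set) <= min_records) {
    warning("only ", nrow(set), " substrate records (inclusion threshold ",
            min_records, "); entropies may be noisy", call. = FALSE)
  }
  mat <- align_at_scissile(set, window)
  rows <- lapply(window, function(p) {
    f <- suppressWarnings(positional_frequencies(mat, p))
    data.frame(position = p,
               entropy = suppressWarnings(cleavage_entropy(f)),
               n = attr(f, "n"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, label = label,
            class = c("specificity_profile", "data.frame"))
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("Cleavage-entropy profile:", attr(x, "label"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a specificity profile as TSV
#'
#' @param profile a `specificity_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
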