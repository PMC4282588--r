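#' Construct an atom topology
#'
#' An ordered atom table in PDB convention: atom name, element, residue
#' name, 1-based residue number, chain identifier, insertion code and
#' record type. Atom order defines the coordinate layout of every
#' [trajectory()] frame.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno`; optional `insert`, `elem`,
#'   `type` (`"ATOM"`/`"HETATM"`), `o` (occupancy).
#' @return object of class `topology`: the atom data.frame with derived
#'   columns `elem`, `type`, `insert`, `o`, `is_protein` and `eleno`.
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$elety <- as.character(atoms$elety)
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$type)) {
    atoms$type <- ifelse(atoms$resid %in% AA3, "ATOM", "HETATM")
  }
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$elem) || anyNA(atoms$elem) || any(atoms$elem == "")) {
    guessed <- infer_elements(atoms$elety)
    if (is.null(atoms$elem)) {
      atoms$elem <- guessed
    } else {
      idx <- is.na(atoms$elem) | atoms$elem == ""
      atoms$elem[idx] <- guessed[idx]
    }
  }
  atoms$elem <- toupper(atoms$elem)
  atoms$is_protein <- atoms$resid %in% AA3 & atoms$type == "ATOM"
  atoms$eleno <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate atom identity in topology: ", dup, call. = FALSE)
  }
  class(atoms) <- c("topology", "data.frame")
  atoms
}

# Infer element symbols from PDB atom names (first alphabetic character
# after stripping digits; two-letter elements only for obvious cases).
infer_elements <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  elem <- substr(nm, 1L, 1L)
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CA2", "SE")
  elem[nm %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE")] <-
    nm[nm %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE")]
  # hydrogens named like 1HB / HB2 etc.
  elem[grepl("^[0-9]*H", toupper(elety))] <- "H"
  elem
}

#' Construct a trajectory
#'
#' Per-frame Cartesian coordinates (Angstrom) aligned with a topology's
#' atom order, stored bio3d-style: one row per frame, columns
#' `x1,y1,z1,x2,...`.
#'
#' @param xyz numeric matrix, frames x 3*natoms.
#' @param time_step_ps optional frame spacing metadata (picoseconds).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(xyz, time_step_ps = NA_real_) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) {
    stop("trajectory must have 3*natoms columns", call. = FALSE)
  }
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame", call. = FALSE)
  if (!all(is.finite(xyz))) {
    stop("trajectory coordinates must be finite", call. = FALSE)
  }
  structure(xyz,
            time_step_ps = time_step_ps,
            class = c("trajectory", class(matrix())))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms\n", nrow(x), ncol(x) / 3L))
  invisible(x)
}

n_frames <- function(traj) nrow(traj)
n_atoms <- function(traj) ncol(traj) / 3L

# Coordinates of frame f as an N x 3 matrix.
frame_coords <- function(traj, f) {
  as_coord_matrix(traj[f, ])
}

#' Read a (multi-model) PDB structure into topology + trajectory
#'
#' MODEL/ENDMDL blocks become frames; a single-model file yields a
#' one-frame trajectory. Alternate locations are resolved to the highest
#' occupancy (ties broken toward altloc "A") with a warning; insertion
#' codes are preserved in the residue key. Atom counts must agree across
#' models.
#'
#' @param path PDB file.
#' @return list with elements `topology` and `trajectory`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  check_model_consistency(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)

  # resolve altlocs: keep highest occupancy, then altloc "A"
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(atom))
  if (any(alt != "")) {
    ins <- atom$insert
    ins[is.na(ins)] <- ""
    key <- paste(atom$chain, atom$resno, ins, atom$elety)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      occ <- atom$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[order(-occ, alt[idx] != "A")][1L]
      keep[setdiff(idx, best)] <- FALSE
    }
    if (!all(keep)) {
      warning(sum(!keep), " alternate-location atom(s) dropped ",
              "(kept highest occupancy, then altloc 'A')", call. = FALSE)
    }
  }
  atom <- atom[keep, , drop = FALSE]
  xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]

  elem <- atom$elesy
  if (is.null(elem)) elem <- NA_character_
  if (anyNA(elem) || any(elem == "")) {
    warning("element missing for some atoms; inferred from atom names",
            call. = FALSE)
  }
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  top <- topology(data.frame(
    elety = atom$elety, resid = atom$resid, chain = chain,
    resno = atom$resno, insert = atom$insert, elem = elem,
    type = atom$type, o = ifelse(is.na(atom$o), 1, atom$o),
    stringsAsFactors = FALSE
  ))
  list(topology = top, trajectory = trajectory(xyz))
}

# Verify all MODEL blocks carry the same number of coordinate records;
# error names the first offending model.
check_model_consistency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) <= 1L) return(invisible(TRUE))
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
  }
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop(sprintf(
      "inconsistent atom counts across models in %s: model %d has %d atoms, expected %d",
      path, bad, counts[bad], counts[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Kabsch least-squares superposition with optional outlier rejection
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` over matched atom pairs (SVD solution with
#' determinant correction, so reflections are never returned). With
#' `refine = TRUE`, pairs deviating by more than `cutoff` Angstrom under
#' the current fit are dropped and the fit repeated, up to `cycles`
#' times; both the all-pair and the refined RMSD are reported.
#'
#' @param mobile,reference coordinates: N x 3 matrices or length-3N
#'   vectors.
#' @param pairs optional 2-column integer matrix (mobile index,
#'   reference index); default pairs atoms 1:1 (requires equal counts).
#' @param refine logical, run outlier-rejection cycles.
#' @param cycles maximum refinement cycles (default 5).
#' @param cutoff per-pair deviation cutoff in Angstrom (default 2.0).
#' @return object of class `superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (applied as `x %*% rotation +
#'   translation`), `rmsd` (refined pair set), `rmsd_all` (all pairs
#'   under the final transform), `n_pairs`, `n_pairs_refined`, `cycles`
#'   (per-cycle log), and `fitted` (all mobile coordinates transformed).
#' @export
kabsch_superpose <- function(mobile, reference, pairs = NULL,
                             refine = TRUE, cycles = 5L, cutoff = 2.0) {
  mob <- as_coord_matrix(mobile)
  ref <- as_coord_matrix(reference)
  if (is.null(pairs)) {
    if (nrow(mob) != nrow(ref)) {
      stop("mobile and reference have different atom counts; supply `pairs`",
           call. = FALSE)
    }
    pairs <- cbind(seq_len(nrow(mob)), seq_len(nrow(ref)))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
  if (nrow(pairs) < 3L) {
    stop("superposition needs at least 3 matched pairs", call. = FALSE)
  }

  fit_subset <- function(idx) {
    P <- mob[pairs[idx, 1L], , drop = FALSE]
    Q <- ref[pairs[idx, 2L], , drop = FALSE]
    pc <- colMeans(P)
    qc <- colMeans(Q)
    P0 <- sweep(P, 2L, pc)
    Q0 <- sweep(Q, 2L, qc)
    H <- crossprod(P0, Q0)            # 3x3
    s <- svd(H)
    if (s$d[2L] < 1e-10) {
      stop("degenerate (collinear) geometry: superposition unsolvable",
           call. = FALSE)
    }
    d <- sign(det(s$v %*% t(s$u)))
    D <- diag(c(1, 1, d))
    R <- s$u %*% D %*% t(s$v)         # row-vector convention: x %*% R
    t <- qc - pc %*% R
    list(R = R, t = as.numeric(t))
  }

  pair_dev <- function(fit) {
    moved <- sweep(mob[pairs[, 1L], , drop = FALSE] %*% fit$R, 2L, fit$t, "+")
    sqrt(rowSums((moved - ref[pairs[, 2L], , drop = FALSE])^2))
  }

  active <- seq_len(nrow(pairs))
  fit <- fit_subset(active)
  log <- list(list(cycle = 0L, n_pairs = length(active),
                   rmsd = sqrt(mean(pair_dev(fit)[active]^2))))
  if (isTRUE(refine)) {
    for (cyc in seq_len(cycles)) {
      dev <- pair_dev(fit)
      new_active <- which(dev <= cutoff)
      if (length(new_active) < 3L || identical(new_active, active)) break
      active <- new_active
      fit <- fit_subset(active)
      log[[length(log) + 1L]] <- list(
        cycle = cyc, n_pairs = length(active),
        rmsd = sqrt(mean(pair_dev(fit)[active]^2)))
    }
  }
  dev <- pair_dev(fit)
  structure(list(
    rotation = fit$R,
    translation = fit$t,
    rmsd = sqrt(mean(dev[active]^2)),
    rmsd_all = sqrt(mean(dev^2)),
    n_pairs = nrow(pairs),
    n_pairs_refined = length(active),
    refined_pairs = active,
    cycles = log,
    fitted = sweep(mob %*% fit$R, 2L, fit$t, "+")
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: RMSD %.3f A over %d/%d pairs (all-pair %.3f A)\n",
              x$rmsd, x$n_pairs_refined, x$n_pairs, x$rmsd_all))
  invisible(x)
}

#' Least-squares fit all trajectory frames onto their average structure
#'
#' Removes rigid-body motion before fluctuation analysis. Each frame is
#' superposed (no outlier rejection) on the time-average coordinates of
#' the selection; the average is then recomputed from the fitted frames
#' and the frames re-fitted, iterating until the fit is self-consistent
#' (maximum coordinate change below `tol`). The procedure is
#' deterministic and idempotent: applying it to an already-fitted
#' trajectory changes nothing beyond `tol`.
#'
#' @param traj trajectory (>= 2 frames).
#' @param selection integer atom indices used for fitting (e.g. all
#'   C-alpha atoms); the transform is applied to every atom.
#' @param tol convergence tolerance in Angstrom (default 1e-10).
#' @param max_passes iteration cap (default 50).
#' @return fitted trajectory.
#' @export
fit_trajectory <- function(traj, selection, tol = 1e-10, max_passes = 50L) {
  if (n_frames(traj) < 2L) {
    stop("fit_trajectory needs at least 2 frames", call. = FALSE)
  }
  selection <- as.integer(selection)
  if (length(selection) == 0L) {
    stop("fit selection is empty", call. = FALSE)
  }
  if (length(selection) < 3L) {
    stop("fit selection needs at least 3 atoms", call. = FALSE)
  }
  sel_cols <- bio3d::atom2xyz(selection)

  one_pass <- function(xyz, ref_sel) {
    out <- xyz
    for (f in seq_len(nrow(xyz))) {
      sup <- kabsch_superpose(frame_coords(xyz, f)[selection, , drop = FALSE],
                              ref_sel, refine = FALSE)
      moved <- sweep(frame_coords(xyz, f) %*% sup$rotation, 2L,
                     sup$translation, "+")
      out[f, ] <- as_xyz_vector(moved)
    }
    out
  }

  cur <- unclass(traj)
  for (pass in seq_len(max_passes)) {
    ref <- as_coord_matrix(colMeans(cur[, sel_cols, drop = FALSE]))
    nxt <- one_pass(cur, ref)
    delta <- max(abs(nxt - cur))
    cur <- nxt
    if (delta < tol) break
  }
  trajectory(cur, time_step_ps = attr(traj, "time_step_ps"))
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Writes a standard PDB in which every atom of a residue carries that
#' residue's value in the B-factor field (columns 61-66, fixed point,
#' two decimals) -- the format used for mapping specificity or
#' flexibility landscapes onto a binding site. Residues without a value
#' get 0.00; values outside the representable range are clamped with a
#' warning.
#'
#' @param topology a [topology()].
#' @param frame coordinates for one frame (N x 3 matrix or 3N vector).
#' @param values data.frame with columns `chain`, `resno`, `value`.
#' @param path output PDB path.
#' @return invisibly, the per-atom B-factor vector written.
#' @export
write_bfactor_pdb <- function(topology, frame, values, path) {
  stopifnot(inherits(topology, "topology"))
  coords <- as_coord_matrix(frame)
  if (nrow(coords) != nrow(topology)) {
    stop("frame does not match topology atom count", call. = FALSE)
  }
  b <- rep(0, nrow(topology))
  if (!is.null(values) && nrow(values) > 0L) {
    stopifnot(all(c("chain", "resno", "value") %in% names(values)))
    vkey <- residue_key(values$chain, values$resno)
    akey <- residue_key(topology$chain, topology$resno, topology$insert)
    m <- match(akey, vkey)
    b[!is.na(m)] <- values$value[m[!is.na(m)]]
  }
  if (any(b >= 10000 | b < -999.99)) {
    warning("B-factor values outside %6.2f range clamped", call. = FALSE)
    b <- pmin(pmax(b, -999.99), 9999.99)
  }
  bio3d::write.pdb(file = path,
                   xyz = as_xyz_vector(coords),
                   type = topology$type,
                   resno = topology$resno,
                   resid = topology$resid,
                   chain = ifelse(topology$chain == " ", "", topology$chain),
                   insert = ifelse(topology$insert == "", NA, topology$insert),
                   elety = topology$elety,
                   o = topology$o,
                   b = round(b, 2),
                   elesy = topology$elem)
  invisible(b)
}

#' Superpose two protein structures on sequence-aligned C-alpha atoms
#'
#' Cross-protein comparison (e.g. two caspase isoforms): chains are
#' matched in order, chain sequences are globally aligned
#' (Biostrings, BLOSUM62), aligned residue pairs contribute their
#' C-alpha atoms, and [kabsch_superpose()] is run with iterative outlier
#' rejection (default 5 cycles at 2.0 Angstrom).
#'
#' @param mobile,reference results of [read_structure()] (lists with
#'   `topology` and `trajectory`; frame 1 is used).
#' @param chains_mobile,chains_reference chain identifiers to use, in
#'   matching order; default all protein chains in order of appearance.
#' @param cycles,cutoff refinement parameters passed on.
#' @return a `superposition` object (see [kabsch_superpose()]).
#' @export
superpose_structures <- function(mobile, reference,
                                 chains_mobile = NULL, chains_reference = NULL,
                                 cycles = 5L, cutoff = 2.0) {
  ca_table <- function(s, chains) {
    top <- s$topology
    ca <- top[top$is_protein & top$elety == "CA", , drop = FALSE]
    if (is.null(chains)) chains <- unique(ca$chain)
    list(ca = ca, chains = chains,
         coords = frame_coords(s$trajectory, 1L))
  }
  m <- ca_table(mobile, chains_mobile)
  r <- ca_table(reference, chains_reference)
  if (length(m$chains) != length(r$chains)) {
    stop("chain lists must have equal length for pairing", call. = FALSE)
  }
  pair_m <- integer(0)
  pair_r <- integer(0)
  for (i in seq_along(m$chains)) {
    cm <- m$ca[m$ca$chain == m$chains[i], , drop = FALSE]
    cr <- r$ca[r$ca$chain == r$chains[i], , drop = FALSE]
    if (nrow(cm) == 0L || nrow(cr) == 0L) {
      stop("no C-alpha atoms for chain pair ", m$chains[i], "/", r$chains[i],
           call. = FALSE)
    }
    sm <- paste(bio3d::aa321(cm$resid), collapse = "")
    sr <- paste(bio3d::aa321(cr$resid), collapse = "")
    aln <- Biostrings::pairwiseAlignment(sm, sr, type = "global",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 0.5)
    pm <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pr <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    im <- 0L; ir <- 0L
    for (k in seq_along(pm)) {
      if (pm[k] != "-") im <- im + 1L
      if (pr[k] != "-") ir <- ir + 1L
      if (pm[k] != "-" && pr[k] != "-") {
        pair_m <- c(pair_m, cm$eleno[im])
        pair_r <- c(pair_r, cr$eleno[ir])
      }
    }
  }
  kabsch_superpose(m$coords, r$coords,
                   pairs = cbind(pair_m, pair_r),
                   refine = TRUE, cycles = cycles, cutoff = cutoff)
}
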