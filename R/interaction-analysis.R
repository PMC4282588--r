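# Protein-ligand hydrogen-bond detection under geometric criteria,
# per-subpocket occupancy bookkeeping and distance statistics.

#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair is bonded in a frame iff the donor-acceptor
#' heavy-atom distance is at most `max_distance` AND the
#' donor-hydrogen-acceptor angle is at least `min_angle` (i.e. at most
#' 45 degrees from linearity at the defaults). Both boundaries are
#' inclusive, so counts are bit-reproducible at the cutoffs.
#'
#' @param max_distance maximum donor-acceptor heavy-atom distance in
#'   Angstrom (default 3.0).
#' @param min_angle minimum D-H-A angle in degrees (default 135).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.0, min_angle = 135) {
  if (max_distance <= 0) stop("max_distance must be > 0", call. = FALSE)
  if (min_angle <= 0 || min_angle > 180) {
    stop("min_angle must be in (0, 180]", call. = FALSE)
  }
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Assign hydrogen-bond donors and acceptors from a topology
#'
#' Default chemistry: every N or O with at least one bonded hydrogen is
#' a donor (one donor entry per hydrogen, so e.g. a lysine NZ with
#' three hydrogens contributes three entries); every N or O is an
#' acceptor. Bonds are inferred geometrically: a hydrogen belongs to
#' the nearest heavy atom within 1.2 Angstrom in the reference frame.
#' Candidate pairs within the same residue are excluded downstream.
#'
#' @param topology a [topology()].
#' @param ref_coords reference coordinates (N x 3 or 3N vector) used
#'   for bond inference, typically frame 1.
#' @return object of class `donor_acceptor_sets`: list with `donors`
#'   (data.frame: `d_idx`, `h_idx`, `chain`, `resno`, `is_protein`) and
#'   `acceptors` (data.frame: `a_idx`, `chain`, `resno`, `is_protein`).
#' @export
assign_donors_acceptors <- function(topology, ref_coords) {
  stopifnot(inherits(topology, "topology"))
  coords <- as_coord_matrix(ref_coords)
  if (nrow(coords) != nrow(topology)) {
    stop("reference coordinates do not match topology", call. = FALSE)
  }
  h_idx <- which(topology$elem == "H")
  if (length(h_idx) == 0L) {
    stop("topology contains no hydrogens; the geometric hydrogen-bond ",
         "criteria require explicit hydrogens (protonate the structure ",
         "before analysis)", call. = FALSE)
  }
  heavy_no <- which(topology$elem %in% c("N", "O"))
  heavy_any <- which(topology$elem != "H")

  donors <- do.call(rbind, lapply(h_idx, function(h) {
    d2 <- rowSums(sweep(coords[heavy_any, , drop = FALSE], 2L,
                        coords[h, ], "-")^2)
    j <- heavy_any[which.min(d2)]
    if (sqrt(min(d2)) > 1.2) return(NULL)        # unbound hydrogen
    if (!j %in% heavy_no) return(NULL)           # C-H etc.: not a donor
    data.frame(d_idx = j, h_idx = h,
               chain = topology$chain[j], resno = topology$resno[j],
               is_protein = topology$is_protein[j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(donors)) {
    donors <- data.frame(d_idx = integer(0), h_idx = integer(0),
                         chain = character(0), resno = integer(0),
                         is_protein = logical(0))
  }
  acceptors <- data.frame(a_idx = heavy_no,
                          chain = topology$chain[heavy_no],
                          resno = topology$resno[heavy_no],
                          is_protein = topology$is_protein[heavy_no],
                          stringsAsFactors = FALSE)
  structure(list(donors = donors, acceptors = acceptors),
            class = "donor_acceptor_sets")
}

# All candidate donor-acceptor combinations, self-residue pairs
# excluded. Returns a data.frame of indices.
candidate_pairs <- function(sets) {
  d <- sets$donors
  a <- sets$acceptors
  if (nrow(d) == 0L || nrow(a) == 0L) {
    return(data.frame(d_idx = integer(0), h_idx = integer(0),
                      a_idx = integer(0)))
  }
  g <- expand.grid(di = seq_len(nrow(d)), ai = seq_len(nrow(a)))
  same_res <- d$chain[g$di] == a$chain[g$ai] & d$resno[g$di] == a$resno[g$ai]
  same_atom <- d$d_idx[g$di] == a$a_idx[g$ai]
  g <- g[!(same_res | same_atom), , drop = FALSE]
  data.frame(d_idx = d$d_idx[g$di], h_idx = d$h_idx[g$di],
             a_idx = a$a_idx[g$ai],
             d_chain = d$chain[g$di], d_resno = d$resno[g$di],
             d_is_protein = d$is_protein[g$di],
             a_chain = a$chain[g$ai], a_resno = a$resno[g$ai],
             a_is_protein = a$is_protein[g$ai],
             stringsAsFactors = FALSE)
}

#' Hydrogen bonds realized in a single frame
#'
#' @param coords frame coordinates (N x 3 or 3N vector).
#' @param sets a [assign_donors_acceptors()] result.
#' @param criteria a [hbond_criteria()].
#' @return data.frame of realized bonds with donor/hydrogen/acceptor
#'   atom indices, distance (Angstrom) and D-H-A angle (degrees).
#' @export
hbonds_in_frame <- function(coords, sets, criteria = hbond_criteria()) {
  coords <- as_coord_matrix(coords)
  cand <- candidate_pairs(sets)
  if (nrow(cand) == 0L) return(cbind(cand, dist = numeric(0), angle = numeric(0)))
  D <- coords[cand$d_idx, , drop = FALSE]
  H <- coords[cand$h_idx, , drop = FALSE]
  A <- coords[cand$a_idx, , drop = FALSE]
  dist <- sqrt(rowSums((D - A)^2))
  v1 <- D - H
  v2 <- A - H
  cosang <- rowSums(v1 * v2) /
    sqrt(rowSums(v1^2) * rowSums(v2^2))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- dist <= criteria$max_distance & angle >= criteria$min_angle
  out <- cand[ok, , drop = FALSE]
  out$dist <- dist[ok]
  out$angle <- angle[ok]
  rownames(out) <- NULL
  out
}

#' Per-subpocket hydrogen-bond occupancies over a trajectory
#'
#' For every protein-ligand donor-acceptor pair the occupancy is the
#' fraction of frames in which the pair satisfies the criteria. Pairs
#' are grouped by (subpocket of the protein residue, position of the
#' ligand residue); the group value is the SUM of its pair occupancies
#' (so it may exceed 1), per-protomer group values are averaged over
#' protomers, and the total is the sum of the reported group values.
#'
#' @param traj a [trajectory()].
#' @param sets a [assign_donors_acceptors()] result for the matching
#'   topology.
#' @param criteria a [hbond_criteria()].
#' @param grouping list with `protein` (data.frame `chain`, `resno`,
#'   `subpocket`), `ligand` (data.frame `chain`, `resno`, `position`)
#'   and optional `protomers` (named list protomer -> protein chain
#'   id(s); default: one protomer holding all protein chains).
#' @return a `hbond_report` (see [hbond_report()]); attribute `pairs`
#'   carries the per-pair occupancies.
#' @export
hbond_occupancy <- function(traj, sets, criteria = hbond_criteria(),
                            grouping) {
  stopifnot(is.list(grouping),
            all(c("protein", "ligand") %in% names(grouping)))
  cand <- candidate_pairs(sets)
  # protein-side donor or acceptor paired with a ligand-side partner
  cross <- (cand$d_is_protein & !cand$a_is_protein) |
    (!cand$d_is_protein & cand$a_is_protein)
  cand <- cand[cross, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no protein-ligand donor-acceptor pairs found", call. = FALSE)
  }
  prot_key <- residue_key(grouping$protein$chain, grouping$protein$resno)
  lig_key <- residue_key(grouping$ligand$chain, grouping$ligand$resno)

  pkey <- ifelse(cand$d_is_protein,
                 residue_key(cand$d_chain, cand$d_resno),
                 residue_key(cand$a_chain, cand$a_resno))
  lkey <- ifelse(cand$d_is_protein,
                 residue_key(cand$a_chain, cand$a_resno),
                 residue_key(cand$d_chain, cand$d_resno))
  sp <- grouping$protein$subpocket[match(pkey, prot_key)]
  pos <- grouping$ligand$position[match(lkey, lig_key)]
  keep <- !is.na(sp) & !is.na(pos)
  cand <- cand[keep, , drop = FALSE]
  sp <- sp[keep]
  pos <- pos[keep]
  if (nrow(cand) == 0L) {
    stop("grouping matches no protein-ligand pair; check chain/residue ",
         "identifiers", call. = FALSE)
  }

  nf <- n_frames(traj)
  hits <- numeric(nrow(cand))
  for (f in seq_len(nf)) {
    coords <- frame_coords(traj, f)
    D <- coords[cand$d_idx, , drop = FALSE]
    H <- coords[cand$h_idx, , drop = FALSE]
    A <- coords[cand$a_idx, , drop = FALSE]
    dist <- sqrt(rowSums((D - A)^2))
    v1 <- D - H
    v2 <- A - H
    cosang <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
    angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    hits <- hits + (dist <= criteria$max_distance &
                      angle >= criteria$min_angle)
  }
  occ <- hits / nf

  protomers <- grouping$protomers %||%
    list(all = unique(grouping$protein$chain))
  pchain <- ifelse(cand$d_is_protein, cand$d_chain, cand$a_chain)
  protomer_of <- rep(NA_character_, nrow(cand))
  for (pn in names(protomers)) {
    protomer_of[pchain %in% protomers[[pn]]] <- pn
  }
  if (anyNA(protomer_of)) {
    stop("protein chain(s) not covered by the protomer layout: ",
         paste(unique(pchain[is.na(protomer_of)]), collapse = ", "),
         call. = FALSE)
  }
  all_groups <- unique(data.frame(subpocket = sp, position = pos,
                                  stringsAsFactors = FALSE))
  all_groups <- all_groups[order(all_groups$subpocket, all_groups$position), ]
  per <- matrix(0, nrow = nrow(all_groups), ncol = length(protomers),
                dimnames = list(paste(all_groups$subpocket,
                                      all_groups$position, sep = "-"),
                                names(protomers)))
  for (i in seq_along(occ)) {
    per[paste(sp[i], pos[i], sep = "-"), protomer_of[i]] <-
      per[paste(sp[i], pos[i], sep = "-"), protomer_of[i]] + occ[i]
  }
  values <- data.frame(subpocket = all_groups$subpocket,
                       position = all_groups$position,
                       value = rowMeans(per),
                       stringsAsFactors = FALSE)
  rep <- hbond_report(values, per_protomer = per)
  attr(rep, "pairs") <- data.frame(cand[c("d_idx", "h_idx", "a_idx")],
                                   subpocket = sp, position = pos,
                                   protomer = protomer_of,
                                   occupancy = occ)
  attr(rep, "n_frames") <- nf
  rep
}

#' Assemble a hydrogen-bond occupancy report
#'
#' The total is always recomputed as the sum of the group values
#' (conservation: group values are sums of pair occupancies, the total
#' is the sum over groups). Useful both as the return type of
#' [hbond_occupancy()] and for ingesting published per-subpocket
#' occupancies to check their totals.
#'
#' @param values data.frame with columns `subpocket`, `position`,
#'   `value` (average bond count, may exceed 1).
#' @param per_protomer optional matrix of per-protomer group values.
#' @return object of class `hbond_report` with attribute `total`.
#' @export
hbond_report <- function(values, per_protomer = NULL) {
  stopifnot(is.data.frame(values),
            all(c("subpocket", "position", "value") %in% names(values)))
  if (any(values$value < 0)) stop("negative occupancy", call. = FALSE)
  structure(values,
            per_protomer = per_protomer,
            total = sum(values$value),
            class = c("hbond_report", "data.frame"))
}

#' @export
print.hbond_report <- function(x, ...) {
  cat("Hydrogen-bond occupancies (average bonds per frame)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Total %.2f\n", attr(x, "total")))
  invisible(x)
}

#' Distance statistics (mean and SD as percent of mean)
#'
#' Generic: works on a raw numeric series (e.g. from
#' [gen_distance_series()]) or on a trajectory plus atom-pair
#' specifications, in which case the equivalent pair of each protomer
#' is pooled over all frames before computing the statistics, matching
#' how dimer simulations are reported. The SD is the population
#' standard deviation, reported as a coefficient of variation
#' `100 * sd / mean`.
#'
#' @param x numeric series or [trajectory()].
#' @param ... passed to methods.
#' @return object of class `distance_stats`: list with `mean`, `sd`,
#'   `sd_percent`, `n`.
#' @export
distance_stats <- function(x, ...) UseMethod("distance_stats")

new_distance_stats <- function(values, label = NULL) {
  n <- length(values)
  if (n < 1L) stop("no distance observations", call. = FALSE)
  m <- mean(values)
  if (n == 1L) {
    warning("single observation: SD reported as 0%", call. = FALSE)
    s <- 0
  } else {
    s <- sqrt(mean((values - m)^2))   # population sigma
  }
  structure(list(mean = m, sd = s,
                 sd_percent = if (m > 0) 100 * s / m else NA_real_,
                 n = n, label = label),
            class = "distance_stats")
}

#' @rdname distance_stats
#' @export
distance_stats.numeric <- function(x, label = NULL, ...) {
  new_distance_stats(x, label)
}

#' @rdname distance_stats
#' @param topology matching [topology()].
#' @param pairs list of atom pairs, one per protomer; each pair is a
#'   list of two atom specs `list(chain =, resno =, elety =)`.
#' @param label optional label stored with the result.
#' @export
distance_stats.trajectory <- function(x, topology, pairs, label = NULL, ...) {
  stopifnot(inherits(topology, "topology"))
  if (!is.null(pairs[[1]]$chain)) pairs <- list(pairs)  # single bare pair
  find_atom <- function(spec) {
    i <- which(topology$chain == spec$chain &
                 topology$resno == spec$resno &
                 topology$elety == spec$elety)
    if (length(i) != 1L) {
      stop(sprintf("atom %s:%s:%s %s in topology", spec$chain, spec$resno,
                   spec$elety,
                   if (length(i) == 0L) "not found" else "ambiguous"),
           call. = FALSE)
    }
    i
  }
  values <- unlist(lapply(pairs, function(pr) {
    i <- find_atom(pr[[1]])
    j <- find_atom(pr[[2]])
    ci <- 3L * (i - 1L) + 1:3
    cj <- 3L * (j - 1L) + 1:3
    sqrt(rowSums((x[, ci, drop = FALSE] - x[, cj, drop = FALSE])^2))
  }))
  new_distance_stats(values, label)
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("distance%s: mean %.2f A, SD %.2f%% (n = %d)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$mean, x$sd_percent, x$n))
  invisible(x)
}
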