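# Synthetic-data generators: substrate sets, toy dimeric trajectories,
# hydrogen-bond series and distance series with analytic ground truth.
# These emulate the study conditions (substrate-database extraction and
# 50-ns production trajectories) at desk scale; no force field, solvent
# or bonded dynamics is modelled -- each residue fluctuates as a rigid
# unit with isotropic Gaussian noise, which makes the C-alpha B-factor
# analytic (B = 8*pi^2*sigma^2).

#' Per-position amino-acid distribution for substrate generation
#'
#' @param position one of `"P4","P3","P2","P1","P1'","P2'","P3'","P4'"`.
#' @param probs named numeric vector of probabilities over one-letter
#'   amino-acid codes; unspecified residues get probability 0. `NULL`
#'   means uniform over the 20 canonical residues. Must sum to 1 within
#'   1e-9.
#' @return object of class `position_dist_spec`.
#' @export
position_dist_spec <- function(position, probs = NULL) {
  if (!position %in% SB_POSITIONS) {
    stop("unknown position label: ", position, call. = FALSE)
  }
  full <- setNames(rep(0, 20L), AA1)
  if (is.null(probs)) {
    full[] <- 1 / 20
  } else {
    if (is.null(names(probs)) || any(names(probs) == "")) {
      stop("probabilities for position ", position,
           " must be named by one-letter amino-acid codes", call. = FALSE)
    }
    bad <- setdiff(names(probs), AA1)
    if (length(bad) > 0L) {
      stop("non-canonical amino-acid code(s) at position ", position, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(probs < 0)) {
      stop("negative probability at position ", position, call. = FALSE)
    }
    if (abs(sum(probs) - 1) > 1e-9) {
      stop(sprintf("probabilities at position %s sum to %.12f, not 1",
                   position, sum(probs)), call. = FALSE)
    }
    full[names(probs)] <- probs
  }
  structure(list(position = position, probs = full),
            class = "position_dist_spec")
}

#' Generate a synthetic substrate set with prescribed positional
#' distributions
#'
#' Draws `n` cleavage windows (P4...P4') whose residues at each position
#' are independent draws from the given distributions; positions
#' without a spec are uniform over the 20 canonical residues. Records
#' carry the full 8-residue window as their sequence with the scissile
#' bond after position 4, so they exercise the same alignment path as
#' parsed database tables.
#'
#' @param specs list of [position_dist_spec()]; each position at most
#'   once.
#' @param n number of substrate records (>= 1).
#' @param seed integer seed (required; generation is deterministic).
#' @return a `substrate_set` (see [substrate_set()]).
#' @export
gen_substrates <- function(specs = list(), n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!all(vapply(specs, inherits, logical(1), "position_dist_spec"))) {
    stop("`specs` must be a list of position_dist_spec objects", call. = FALSE)
  }
  pos <- vapply(specs, function(s) s$position, character(1))
  if (anyDuplicated(pos)) {
    stop("position specified more than once: ", pos[duplicated(pos)][1L],
         call. = FALSE)
  }
  prob_table <- lapply(setNames(SB_POSITIONS, SB_POSITIONS), function(p) {
    i <- match(p, pos)
    if (is.na(i)) setNames(rep(1 / 20, 20L), AA1) else specs[[i]]$probs
  })
  windows <- with_seed(seed, {
    cols <- lapply(SB_POSITIONS, function(p) {
      sample(AA1, n, replace = TRUE, prob = prob_table[[p]])
    })
    do.call(cbind, cols)
  })
  substrate_set(data.frame(
    id = sprintf("syn%04d", seq_len(n)),
    sequence = apply(windows, 1L, paste, collapse = ""),
    p1_pos = 4L,
    stringsAsFactors = FALSE
  ))
}

#' Per-residue fluctuation specification for toy trajectories
#'
#' @param sigma numeric vector of per-residue isotropic standard
#'   deviations (Angstrom) of Gaussian positional noise, one per residue
#'   of a single protomer (applied to both chains of a dimer).
#' @param frames number of frames (>= 1).
#' @param seed integer seed.
#' @return object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(sigma, frames, seed) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (frames < 1) stop("frames must be >= 1", call. = FALSE)
  structure(list(sigma = as.numeric(sigma), frames = as.integer(frames),
                 seed = seed),
            class = "fluctuation_spec")
}

# Idealised backbone template for one residue (Angstrom offsets from
# the residue origin); alanine-like naming so PDB writers accept it.
.residue_template <- function() {
  data.frame(
    elety = c("N", "CA", "C", "O", "CB"),
    dx = c(-1.20, 0.00, 1.30, 1.55, -0.50),
    dy = c(0.80, 0.00, 0.60, 1.80, -1.40),
    dz = c(0.00, 0.00, 0.00, 0.00, -0.70),
    stringsAsFactors = FALSE
  )
}

#' Generate a toy dimeric trajectory with prescribed per-residue
#' fluctuations
#'
#' Builds an extended poly-alanine reference for each chain (residues
#' 3.8 Angstrom apart, chains offset in y) and adds, per frame and per
#' residue, one isotropic Gaussian displacement with that residue's
#' sigma applied rigidly to all of the residue's atoms. No net
#' rigid-body drift is added. The same sigma vector is used for every
#' chain, so a two-chain layout is a statistically symmetric dimer.
#'
#' @param spec a [fluctuation_spec()].
#' @param chains character vector of chain identifiers (default
#'   `c("A","B")`, the dimer layout).
#' @return list with `topology` and `trajectory`.
#' @export
gen_trajectory <- function(spec, chains = c("A", "B")) {
  stopifnot(inherits(spec, "fluctuation_spec"))
  n_res <- length(spec$sigma)
  if (n_res < 1L) stop("layout needs at least one residue per chain",
                       call. = FALSE)
  tmpl <- .residue_template()
  atoms <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    do.call(rbind, lapply(seq_len(n_res), function(ri) {
      data.frame(elety = tmpl$elety, resid = "ALA", chain = chains[ci],
                 resno = ri, stringsAsFactors = FALSE)
    }))
  }))
  top <- topology(atoms)

  n_at_res <- nrow(tmpl)
  ref <- matrix(0, nrow = nrow(top), ncol = 3L)
  for (ci in seq_along(chains)) {
    for (ri in seq_len(n_res)) {
      rows <- (ci - 1L) * n_res * n_at_res + (ri - 1L) * n_at_res +
        seq_len(n_at_res)
      # zigzag keeps the C-alpha trace non-collinear (Kabsch fitting
      # needs at least planar geometry)
      origin <- c(3.8 * ri, 20 * (ci - 1L) + 1.9 * (ri %% 2L), 0)
      ref[rows, ] <- cbind(tmpl$dx + origin[1L],
                           tmpl$dy + origin[2L],
                           tmpl$dz + origin[3L])
    }
  }

  nf <- spec$frames
  # one 3-vector of noise per (frame, chain, residue), applied rigidly
  # to all atoms of the residue; vectorized over frames
  n_ch <- length(chains)
  noise <- with_seed(spec$seed, {
    array(rnorm(nf * n_ch * n_res * 3L), dim = c(nf, n_ch, n_res, 3L))
  })
  noise_flat <- matrix(noise, nrow = nf)  # columns indexed (ci, ri, k)
  atom_ci <- rep(seq_len(n_ch), each = n_res * n_at_res)
  atom_ri <- rep(rep(seq_len(n_res), each = n_at_res), times = n_ch)
  # coordinate column c (x,y,z interleaved) -> noise_flat column
  coord_k <- rep(1:3, times = nrow(top))
  coord_ci <- rep(atom_ci, each = 3L)
  coord_ri <- rep(atom_ri, each = 3L)
  nmap <- coord_ci + (coord_ri - 1L) * n_ch + (coord_k - 1L) * n_ch * n_res
  xyz <- matrix(rep(as_xyz_vector(ref), each = nf), nrow = nf) +
    noise_flat[, nmap, drop = FALSE] *
    rep(spec$sigma[coord_ri], each = nf)
  list(topology = top, trajectory = trajectory(xyz, time_step_ps = 1))
}

#' Hydrogen-bond series specification
#'
#' Defines a two-state geometry series: a "bonded" donor-acceptor
#' geometry that satisfies the detection criteria and a "broken" one
#' that violates them, plus the exact fraction of frames to spend
#' bonded.
#'
#' @param occupancy target occupancy fraction in `[0, 1]`.
#' @param frames number of frames.
#' @param seed integer seed (controls which frames are bonded).
#' @param bonded,broken numeric `c(dist =, angle =)`: donor-acceptor
#'   heavy-atom distance (Angstrom) and donor-hydrogen-acceptor angle
#'   (degrees).
#' @return object of class `hbond_series_spec`.
#' @export
hbond_series_spec <- function(occupancy, frames, seed,
                              bonded = c(dist = 2.9, angle = 180),
                              broken = c(dist = 4.5, angle = 180)) {
  if (occupancy < 0 || occupancy > 1) {
    stop("occupancy must be in [0, 1]", call. = FALSE)
  }
  if (frames < 1) stop("frames must be >= 1", call. = FALSE)
  structure(list(occupancy = occupancy, frames = as.integer(frames),
                 seed = seed, bonded = bonded, broken = broken),
            class = "hbond_series_spec")
}

# Place donor N, hydrogen H (1.0 A bond) and acceptor O so that the
# N...O distance and the N-H-O angle match the requested geometry.
# Acceptor at origin, donor on the +x axis.
.hbond_geometry <- function(dist, angle_deg) {
  A <- c(0, 0, 0)
  N <- c(dist, 0, 0)
  place_h <- function(phi) N + c(-cos(phi), sin(phi), 0)
  angle_at_h <- function(phi) {
    H <- place_h(phi)
    v1 <- N - H
    v2 <- A - H
    acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
      180 / pi
  }
  if (angle_deg >= 180 - 1e-9) {
    H <- place_h(0)
  } else {
    phi <- uniroot(function(p) angle_at_h(p) - angle_deg,
                   lower = 1e-8, upper = pi / 2 - 1e-8, tol = 1e-12)$root
    H <- place_h(phi)
  }
  rbind(N = N, H = H, A = A)
}

#' Generate a hydrogen-bond geometry series with exact occupancy
#'
#' Builds a minimal donor residue (glycine backbone with an amide
#' hydrogen) and a ligand acceptor (acetate-like oxygen) whose relative
#' geometry toggles between the spec's "bonded" and "broken" states.
#' Exactly `round(occupancy * frames)` frames are bonded; which frames
#' is decided deterministically from the seed. The bonded geometry must
#' satisfy, and the broken geometry violate, the supplied criteria --
#' otherwise generation fails.
#'
#' @param spec a [hbond_series_spec()].
#' @param criteria a [hbond_criteria()] used to validate the two
#'   geometries (default: the standard 3.0 Angstrom / 135 degree
#'   criteria).
#' @return list with `topology`, `trajectory`, and `bonded_frames`
#'   (logical ground truth per frame).
#' @export
gen_hbond_series <- function(spec, criteria = hbond_criteria()) {
  stopifnot(inherits(spec, "hbond_series_spec"))
  geom_b <- .hbond_geometry(spec$bonded[["dist"]], spec$bonded[["angle"]])
  geom_x <- .hbond_geometry(spec$broken[["dist"]], spec$broken[["angle"]])

  passes <- function(g) {
    d <- sqrt(sum((g["N", ] - g["A", ])^2))
    v1 <- g["N", ] - g["H", ]
    v2 <- g["A", ] - g["H", ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    d <= criteria$max_distance && ang >= criteria$min_angle
  }
  if (!passes(geom_b)) {
    stop("'bonded' geometry does not satisfy the hydrogen-bond criteria",
         call. = FALSE)
  }
  if (passes(geom_x)) {
    stop("'broken' geometry satisfies the hydrogen-bond criteria",
         call. = FALSE)
  }

  top <- topology(data.frame(
    elety = c("N", "H", "CA", "C", "O", "OXT"),
    resid = c(rep("GLY", 5L), "ACT"),
    chain = c(rep("A", 5L), "L"),
    resno = c(rep(1L, 5L), 1L),
    elem = c("N", "H", "C", "C", "O", "O"),
    type = c(rep("ATOM", 5L), "HETATM"),
    stringsAsFactors = FALSE
  ))

  # static filler atoms far from the donor-acceptor axis
  filler <- rbind(CA = c(0, 8, 0), C = c(1.4, 8.6, 0), O = c(2.2, 9.5, 0))
  frame_xyz <- function(g) {
    as_xyz_vector(rbind(g["N", , drop = FALSE],
                        g["H", , drop = FALSE],
                        filler,
                        g["A", , drop = FALSE]))
  }
  n_bond <- round(spec$occupancy * spec$frames)
  bonded_frames <- with_seed(spec$seed, {
    idx <- sample.int(spec$frames, n_bond)
    seq_len(spec$frames) %in% idx
  })
  xyz <- matrix(0, nrow = spec$frames, ncol = 3L * nrow(top))
  row_b <- frame_xyz(geom_b)
  row_x <- frame_xyz(geom_x)
  for (f in seq_len(spec$frames)) {
    xyz[f, ] <- if (bonded_frames[f]) row_b else row_x
  }
  list(topology = top, trajectory = trajectory(xyz, time_step_ps = 1),
       bonded_frames = bonded_frames)
}

#' Generate a Gaussian distance series with prescribed mean and CV
#'
#' @param mean mean distance (Angstrom, > 0).
#' @param cv_percent coefficient of variation as percent of the mean
#'   (>= 0).
#' @param n series length.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
gen_distance_series <- function(mean, cv_percent, n, seed) {
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (cv_percent < 0) stop("`cv_percent` must be >= 0", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  with_seed(seed, rnorm(as.integer(n), mean = mean,
                        sd = mean * cv_percent / 100))
}
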