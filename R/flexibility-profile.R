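# Per-residue B-factors from fitted trajectories and subpocket-wise
# normalized flexibilities with dimer averaging.
#
# B-factors follow the crystallographic convention
#   B = (8*pi^2 / 3) * MSF,   MSF = <|r - <r>|^2>
# computed on C-alpha atoms; for the isotropic Gaussian toy model with
# per-component standard deviation sigma, MSF = 3*sigma^2 and hence
# B = 8*pi^2*sigma^2 analytically.

#' Per-residue C-alpha B-factors of a fitted trajectory
#'
#' The mean-square fluctuation of each protein residue's C-alpha about
#' its time-mean position is converted to a B-factor. The protein-wide
#' average is taken over all C-alpha atoms of all protein chains
#' (ligands, ions and caps are excluded); protein residues lacking a
#' C-alpha are excluded and reported in the `excluded` attribute.
#'
#' @param traj a fitted [trajectory()] with >= 2 frames (see
#'   [fit_trajectory()]; fitting removes rigid-body motion that would
#'   otherwise dominate the fluctuations).
#' @param topology matching [topology()].
#' @return object of class `flexibility_profile`: data.frame with
#'   columns `chain`, `resno`, `resid`, `msf` (A^2) and `bfactor`
#'   (A^2); attribute `protein_avg_b` holds the normalization constant.
#' @export
residue_bfactors <- function(traj, topology) {
  stopifnot(inherits(topology, "topology"))
  if (n_frames(traj) < 2L) {
    stop("B-factors need at least 2 frames", call. = FALSE)
  }
  if (n_atoms(traj) != nrow(topology)) {
    stop("trajectory does not match topology atom count", call. = FALSE)
  }
  prot <- topology[topology$is_protein, , drop = FALSE]
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  pres_key <- unique(residue_key(prot$chain, prot$resno, prot$insert))
  ca_key <- residue_key(ca$chain, ca$resno, ca$insert)
  excluded <- setdiff(pres_key, ca_key)
  if (length(excluded) > 0L) {
    message(length(excluded), " protein residue(s) without C-alpha excluded")
  }
  cols_x <- 3L * (ca$eleno - 1L) + 1L
  msf <- vapply(seq_len(nrow(ca)), function(i) {
    cx <- traj[, cols_x[i]]
    cy <- traj[, cols_x[i] + 1L]
    cz <- traj[, cols_x[i] + 2L]
    mean((cx - mean(cx))^2 + (cy - mean(cy))^2 + (cz - mean(cz))^2)
  }, numeric(1))
  b <- (8 * pi^2 / 3) * msf
  out <- data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
                    msf = msf, bfactor = b, stringsAsFactors = FALSE)
  structure(out,
            protein_avg_b = mean(b),
            excluded = excluded,
            n_frames = n_frames(traj),
            class = c("flexibility_profile", "data.frame"))
}

#' Define subpockets over a dimeric binding site
#'
#' Groups binding-site residues into named subpockets (S1...S4 in
#' Schechter-Berger nomenclature) per protomer, with a chain layout
#' mapping each protomer of the dimer to its chain(s) and an optional
#' residue-number offset realising the equivalence between protomers.
#'
#' @param subpockets named list; each element a data.frame with columns
#'   `resno` and optionally `resid` (numbering of the first protomer).
#' @param protomers named list mapping protomer name to its chain
#'   identifier(s), e.g. `list(A = "A", B = "B")`.
#' @param offsets named numeric vector of residue-number offsets per
#'   protomer (default 0: protomers share numbering).
#' @return object of class `subpocket_definition`.
#' @export
subpocket_definition <- function(subpockets,
                                 protomers = list(A = "A", B = "B"),
                                 offsets = NULL) {
  stopifnot(is.list(subpockets), !is.null(names(subpockets)))
  subpockets <- lapply(subpockets, function(d) {
    d <- as.data.frame(d)
    stopifnot("resno" %in% names(d))
    d$resno <- as.integer(d$resno)
    if (is.null(d$resid)) d$resid <- NA_character_
    d
  })
  all_res <- unlist(lapply(subpockets, function(d) d$resno))
  if (anyDuplicated(all_res)) {
    stop("residue ", all_res[duplicated(all_res)][1L],
         " assigned to more than one subpocket", call. = FALSE)
  }
  if (is.null(offsets)) {
    offsets <- setNames(rep(0L, length(protomers)), names(protomers))
  }
  structure(list(subpockets = subpockets, protomers = protomers,
                 offsets = offsets),
            class = "subpocket_definition")
}

#' Read a subpocket definition from a YAML config
#'
#' Expected layout: a `subpockets` map (name -> list of residue
#' numbers, or of `{resno, resid}` maps), a `protomers` map (protomer
#' -> chain id(s)) and an optional `offsets` map.
#'
#' @param path YAML file.
#' @return a [subpocket_definition()].
#' @export
read_subpocket_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$subpockets)) {
    stop("config has no `subpockets` section", call. = FALSE)
  }
  sp <- lapply(cfg$subpockets, function(x) {
    if (is.list(x) && !is.null(x[[1]]$resno)) {
      data.frame(resno = vapply(x, function(e) as.integer(e$resno), integer(1)),
                 resid = vapply(x, function(e) as.character(e$resid %||% NA),
                                character(1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(resno = as.integer(unlist(x)), stringsAsFactors = FALSE)
    }
  })
  protomers <- cfg$protomers %||% list(A = "A", B = "B")
  offsets <- if (is.null(cfg$offsets)) NULL else unlist(cfg$offsets)
  subpocket_definition(sp, protomers = protomers, offsets = offsets)
}

#' Subpocket-wise normalized flexibility with dimer averaging
#'
#' For each protomer, the subpocket value is the mean C-alpha B-factor
#' over the subpocket's residues divided by the protein-wide average
#' C-alpha B-factor (one pooled constant per system, so protomer values
#' are directly comparable); the reported value is the mean over the
#' protomers. A value of 1 means average flexibility; a subpocket whose
#' residues all fluctuate like the protein average scores exactly 1.
#'
#' @param profile a [residue_bfactors()] result.
#' @param definition a [subpocket_definition()].
#' @return object of class `subpocket_flexibility`: data.frame with
#'   columns `subpocket` and `value`; attributes `per_protomer` (matrix
#'   subpockets x protomers) and `normalization` (the pooled average).
#' @export
subpocket_flexibility <- function(profile, definition) {
  stopifnot(inherits(profile, "flexibility_profile"),
            inherits(definition, "subpocket_definition"))
  navg <- attr(profile, "protein_avg_b")
  if (!is.finite(navg) || navg <= 0) {
    stop("protein-average B-factor is zero; normalized values undefined",
         call. = FALSE)
  }
  key <- residue_key(profile$chain, profile$resno)
  pnames <- names(definition$protomers)
  spnames <- names(definition$subpockets)
  per <- matrix(NA_real_, nrow = length(spnames), ncol = length(pnames),
                dimnames = list(spnames, pnames))
  for (pn in pnames) {
    chains <- definition$protomers[[pn]]
    off <- definition$offsets[[pn]] %||% 0L
    for (sn in spnames) {
      resnos <- definition$subpockets[[sn]]$resno + off
      want <- as.vector(outer(chains, resnos, residue_key))
      hit <- match(want, key)
      if (anyNA(hit)) {
        # a residue may live on either chain of a multi-chain protomer;
        # require each resno found on exactly one of the chains
        found <- !is.na(hit)
        per_res <- matrix(found, nrow = length(chains))
        ok <- colSums(per_res) >= 1L
        if (!all(ok)) {
          miss <- resnos[!ok][1L]
          stop(sprintf("subpocket %s: residue %d not found on chain(s) %s",
                       sn, miss, paste(chains, collapse = ",")),
               call. = FALSE)
        }
        hit <- hit[found]
      }
      per[sn, pn] <- mean(profile$bfactor[hit]) / navg
    }
  }
  out <- data.frame(subpocket = spnames, value = rowMeans(per),
                    stringsAsFactors = FALSE)
  structure(out, per_protomer = per, normalization = navg,
            n_frames = attr(profile, "n_frames"),
            class = c("subpocket_flexibility", "data.frame"))
}

#' @export
print.subpocket_flexibility <- function(x, ...) {
  cat("Normalized subpocket B-factors (1 = average flexibility)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Signed percent change of subpocket flexibility (mutant vs native)
#'
#' `100 * (mutant - native) / native` per subpocket, rounded to the
#' nearest integer percent for reporting; the unrounded value is
#' retained. Subpockets with a zero native value yield `NA` with a
#' warning.
#'
#' @param native,mutant `subpocket_flexibility` objects (or data.frames
#'   with `subpocket` and `value`) sharing subpocket names.
#' @return data.frame with columns `subpocket`, `native`, `mutant`,
#'   `percent` (unrounded) and `percent_rounded`.
#' @export
percent_change <- function(native, mutant) {
  nd <- as.data.frame(native)
  md <- as.data.frame(mutant)
  stopifnot(all(c("subpocket", "value") %in% names(nd)),
            all(c("subpocket", "value") %in% names(md)))
  if (!setequal(nd$subpocket, md$subpocket)) {
    stop("native and mutant profiles have different subpocket names",
         call. = FALSE)
  }
  md <- md[match(nd$subpocket, md$subpocket), ]
  pct <- 100 * (md$value - nd$value) / nd$value
  zero <- nd$value == 0
  if (any(zero)) {
    warning("native value 0 for subpocket(s) ",
            paste(nd$subpocket[zero], collapse = ", "),
            "; percent change undefined", call. = FALSE)
    pct[zero] <- NA_real_
  }
  data.frame(subpocket = nd$subpocket,
             native = nd$value, mutant = md$value,
             percent = pct,
             percent_rounded = round(pct),
             stringsAsFactors = FALSE)
}
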