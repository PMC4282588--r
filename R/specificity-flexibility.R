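# The headline analysis: rank correlation between per-subpocket
# cleavage entropy (specificity) and normalized flexibility, with an
# optional S2-exclusion variant, plus report assembly.

#' Spearman rank correlation
#'
#' Pearson correlation of (average-tie) ranks, delegated to
#' [stats::cor()]. Zero rank variance in either vector makes the
#' coefficient undefined: `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2, finite.
#' @return rho in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    warning("zero rank variance: Spearman rho undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Correlate a specificity profile with a subpocket flexibility profile
#'
#' Pairs cleavage entropies with normalized subpocket B-factors by the
#' Schechter-Berger index correspondence (subpocket S_i binds substrate
#' position P_i) and computes the Spearman rank correlation. When
#' `exclude` is given, the excluded-variant coefficient is computed as
#' well (the classic use: dropping the hydrophobic S2 pocket, whose
#' substrate readout is not mediated by hydrogen bonds). With fewer
#' than `min_pairs` shared subpockets the result is flagged; four-pocket
#' coefficients are always flagged descriptive-only (no p-value is
#' attached at such n).
#'
#' @param spec a [specificity_profile()].
#' @param flex a [subpocket_flexibility()].
#' @param exclude character vector of subpocket names to drop in the
#'   variant (e.g. `"S2"`), or `NULL`.
#' @param min_pairs minimum shared subpockets before flagging
#'   (default 3).
#' @return object of class `correlation_result`: list with `rho`, `n`,
#'   `subpockets`, `pairs` (data.frame of matched values),
#'   `descriptive_only`, `flagged`, and -- when `exclude` is used --
#'   `excluded` (the variant as another `correlation_result`).
#' @export
correlate_profiles <- function(spec, flex, exclude = NULL, min_pairs = 3L) {
  stopifnot(inherits(spec, "specificity_profile") ||
              all(c("position", "entropy") %in% names(spec)),
            inherits(flex, "subpocket_flexibility") ||
              all(c("subpocket", "value") %in% names(flex)))
  sp_idx <- as.integer(sub("^S", "", flex$subpocket))
  want_pos <- paste0("P", sp_idx)
  m <- match(want_pos, spec$position)
  ok <- !is.na(m) & !is.na(spec$entropy[m]) & !is.na(flex$value)
  if (!any(ok)) stop("no shared subpockets between profiles", call. = FALSE)
  pairs <- data.frame(subpocket = flex$subpocket[ok],
                      position = want_pos[ok],
                      entropy = spec$entropy[m[ok]],
                      flexibility = flex$value[ok],
                      stringsAsFactors = FALSE)
  if (!is.null(exclude)) {
    keep <- !(pairs$subpocket %in% exclude)
  } else {
    keep <- rep(TRUE, nrow(pairs))
  }

  one_result <- function(p) {
    flagged <- nrow(p) < min_pairs
    if (flagged) {
      warning("only ", nrow(p), " shared subpocket(s); correlation ",
              "weakly informative", call. = FALSE)
    }
    rho <- if (nrow(p) >= 2L) spearman(p$entropy, p$flexibility) else NA_real_
    structure(list(rho = rho, n = nrow(p), subpockets = p$subpocket,
                   pairs = p, descriptive_only = nrow(p) <= 4L,
                   flagged = flagged || is.na(rho)),
              class = "correlation_result")
  }
  out <- one_result(pairs)
  if (!is.null(exclude)) out$excluded <- one_result(pairs[keep, , drop = FALSE])
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f over %d subpockets (%s)%s\n",
              x$rho, x$n, paste(x$subpockets, collapse = ", "),
              if (x$descriptive_only) " [descriptive only]" else ""))
  if (!is.null(x$excluded)) {
    cat(sprintf("  excluding %s: rho = %.3f over %d subpockets\n",
                paste(setdiff(x$subpockets, x$excluded$subpockets),
                      collapse = ","),
                x$excluded$rho, x$excluded$n))
  }
  invisible(x)
}

#' Assemble a machine-readable specificity-flexibility report
#'
#' Collects whatever stages were run -- specificity profiles,
#' subpocket flexibilities, hydrogen-bond reports, distance statistics,
#' correlations -- into one versioned structure that serialises to JSON
#' and to per-table TSV. Every numeric section carries the record or
#' frame counts it was computed from. Sections for stages not run are
#' simply absent.
#'
#' @param specificity named list of [specificity_profile()] objects
#'   (names are system labels), or `NULL`.
#' @param flexibility named list of [subpocket_flexibility()] objects.
#' @param hbonds named list of `hbond_report` objects.
#' @param distances named list of `distance_stats` objects.
#' @param correlations named list of `correlation_result` objects.
#' @return object of class `specflex_report` (a nested list).
#' @export
build_report <- function(specificity = NULL, flexibility = NULL,
                         hbonds = NULL, distances = NULL,
                         correlations = NULL) {
  sections <- list(specificity = specificity, flexibility = flexibility,
                   hbonds = hbonds, distances = distances,
                   correlations = correlations)
  if (all(vapply(sections, is.null, logical(1)))) {
    stop("at least one profile or report must be supplied", call. = FALSE)
  }
  for (nm in names(sections)) {
    s <- sections[[nm]]
    if (!is.null(s) && (!is.list(s) || is.null(names(s)) ||
                        any(names(s) == ""))) {
      stop("section `", nm, "` must be a named list (system labels)",
           call. = FALSE)
    }
  }

  rpt <- list(schema_version = "1.0", sections = list())
  if (!is.null(specificity)) {
    rpt$sections$specificity <- lapply(specificity, function(p) {
      list(label = attr(p, "label"),
           positions = as.data.frame(p))
    })
  }
  if (!is.null(flexibility)) {
    rpt$sections$flexibility <- lapply(flexibility, function(f) {
      list(values = as.data.frame(f),
           normalization = attr(f, "normalization"),
           n_frames = attr(f, "n_frames"))
    })
  }
  if (!is.null(hbonds)) {
    rpt$sections$hbonds <- lapply(hbonds, function(h) {
      list(groups = as.data.frame(h),
           total = attr(h, "total"),
           n_frames = attr(h, "n_frames"))
    })
  }
  if (!is.null(distances)) {
    rpt$sections$distances <- lapply(distances, function(d) {
      d[c("mean", "sd", "sd_percent", "n")]
    })
  }
  if (!is.null(correlations)) {
    rpt$sections$correlations <- lapply(correlations, function(cr) {
      out <- cr[c("rho", "n", "subpockets", "descriptive_only", "flagged")]
      if (!is.null(cr$excluded)) {
        out$excluded <- cr$excluded[c("rho", "n", "subpockets")]
      }
      out
    })
  }
  class(rpt) <- "specflex_report"
  rpt
}

#' Write a report to disk (JSON plus TSV tables)
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "specflex_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths <- c(paths, json_path)
  flat_tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  sec <- report$sections
  if (!is.null(sec$specificity)) {
    df <- do.call(rbind, lapply(names(sec$specificity), function(l) {
      cbind(system = l, sec$specificity[[l]]$positions)
    }))
    paths <- c(paths, flat_tsv(df, "specificity.tsv"))
  }
  if (!is.null(sec$flexibility)) {
    df <- do.call(rbind, lapply(names(sec$flexibility), function(l) {
      cbind(system = l, sec$flexibility[[l]]$values)
    }))
    paths <- c(paths, flat_tsv(df, "flexibility.tsv"))
  }
  if (!is.null(sec$hbonds)) {
    df <- do.call(rbind, lapply(names(sec$hbonds), function(l) {
      g <- sec$hbonds[[l]]$groups
      rbind(cbind(system = l, g),
            data.frame(system = l, subpocket = "Total", position = "",
                       value = sec$hbonds[[l]]$total))
    }))
    paths <- c(paths, flat_tsv(df, "hbonds.tsv"))
  }
  if (!is.null(sec$distances)) {
    df <- do.call(rbind, lapply(names(sec$distances), function(l) {
      data.frame(system = l, mean = sec$distances[[l]]$mean,
                 sd_percent = sec$distances[[l]]$sd_percent,
                 n = sec$distances[[l]]$n)
    }))
    paths <- c(paths, flat_tsv(df, "distances.tsv"))
  }
  invisible(paths)
}
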