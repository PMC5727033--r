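#' @title Ambiguous distance restraint generation
#' @description Shift-matching of amide-amide and carbon-carbon peak lists,
#'   redundancy-based pruning of assignment options, intensity-based
#'   distance classes, hydrogen-bond restraint emission and torsion
#'   restraint emission.
#' @name restraints
NULL

#' Ambiguous distance restraint (ADR)
#'
#' @param options data.frame of assignment options with columns
#'   \code{res_a}, \code{atom_a}, \code{res_b}, \code{atom_b},
#'   \code{product} (labeling product; NA for 1H restraints),
#'   \code{support} (peak support count; NA until counted).
#' @param lower,upper distance bounds in Angstrom.
#' @param peak_id source peak id(s).
#' @param spectrum source spectrum name.
#' @param intensity source peak intensity.
#' @param active logical; rejected restraints are deactivated, never deleted.
#' @param source restraint family, \code{"h"} or \code{"c"}.
#' @return object of class \code{adr}.
#' @export
adr <- function(options, lower, upper, peak_id = integer(0), spectrum = NULL,
                intensity = NA_real_, active = TRUE, source = "h") {
  stopifnot(is.data.frame(options), lower < upper)
  if (!"product" %in% names(options)) options$product <- NA_real_
  if (!"support" %in% names(options)) options$support <- NA_integer_
  if (nrow(options) > 0) {
    same <- options$res_a == options$res_b & options$atom_a == options$atom_b
    if (any(same)) stop("assignment option connects an atom to itself")
    if (any(options$res_a == options$res_b)) {
      stop("intra-residue assignment option not allowed")
    }
  }
  rownames(options) <- NULL
  structure(list(options = options, lower = lower, upper = upper,
                 peak_id = peak_id, spectrum = spectrum, intensity = intensity,
                 active = active, source = source),
            class = "adr")
}

#' @export
print.adr <- function(x, ...) {
  cat(sprintf("ADR [%.1f, %.1f] A, %d option(s)%s\n", x$lower, x$upper,
              nrow(x$options), if (x$active) "" else " (inactive)"))
  for (k in seq_len(nrow(x$options))) {
    o <- x$options[k, ]
    cat(sprintf("  %d.%s <-> %d.%s", o$res_a, o$atom_a, o$res_b, o$atom_b))
    if (!is.na(o$support)) cat(sprintf("  support=%d", o$support))
    if (!is.na(o$product)) cat(sprintf("  labeling=%.2f", o$product))
    cat("\n")
  }
  invisible(x)
}

n_options <- function(a) nrow(a$options)

#' Summary counts over a list of ADRs
#' @param adrs list of \code{adr} objects.
#' @return list with total, active, unambiguous counts and mean ambiguity
#'   (options per active restraint).
#' @export
adr_stats <- function(adrs) {
  act <- vapply(adrs, function(a) isTRUE(a$active), logical(1))
  nopt <- vapply(adrs, n_options, integer(1))
  list(total = length(adrs), active = sum(act),
       unambiguous = sum(act & nopt == 1),
       mean_ambiguity = if (any(act)) mean(nopt[act]) else NA_real_)
}

# residues with both N and H shifts (the amide-visible set)
amide_table <- function(shifts) {
  hs <- shifts[shifts$atom == "H", c("residue", "shift")]
  ns <- shifts[shifts$atom == "N", c("residue", "shift")]
  m <- merge(hs, ns, by = "residue", suffixes = c("_H", "_N"))
  m[order(m$residue), ]
}

#' Match amide-amide peaks against a shift list
#'
#' For each 3D peak, every residue pair (i, j) whose amide 15N/1H shifts
#' fall within the per-dimension tolerances of the peak position (boundary
#' inclusive), with the roles of the spectrum's dimensions deciding which
#' residue each dimension reports, becomes an assignment option.
#' Peaks on the 1H-1H diagonal (within \code{diagonal_mask} ppm) are
#' excluded as auto-correlation peaks, and auto-correlation matches
#' (i == j) of off-diagonal peaks are discarded; peaks that match nothing
#' yield no restraint and are reported via the \code{unassigned} attribute
#' (with a warning).  Bounds are set to the wide 1H class (1.0, 5.5) and
#' are refined later by \code{\link{classify_h_bounds}}.
#'
#' @param peaks a \code{peak_list} from one of the paired 3D amide spectra.
#' @param shifts a \code{shift_list} (the dedicated deuterated-sample list).
#' @param diagonal_mask half-width in ppm of the excluded diagonal ridge.
#' @return list of \code{adr} objects (attributes \code{unassigned} and
#'   \code{autocorrelation}: peak ids).
#' @export
match_peaks_h <- function(peaks, shifts, diagonal_mask = 0.05) {
  stopifnot(inherits(peaks, "peak_list"), inherits(shifts, "shift_list"))
  def <- peaks$spectrum
  if (!def$type %in% c("hnhh", "hnhhnh")) {
    stop("spectrum '", def$name, "' is not a 3D amide-amide experiment")
  }
  if (nrow(shifts) == 0) stop("empty shift list")
  am <- amide_table(shifts)
  if (nrow(am) == 0) stop("shift list contains no amide N/H entries")
  tol <- def$tolerances
  origin_dims <- which(def$roles == "origin")
  dest_dims <- which(def$roles == "destination")
  hdims <- which(def$nuclei == "H")
  out <- list(); unassigned <- integer(0); autocorr <- integer(0)
  for (k in seq_len(nrow(peaks$peaks))) {
    w <- as.numeric(peaks$peaks[k, seq_along(def$nuclei)])
    if (abs(w[hdims[1]] - w[hdims[2]]) <= diagonal_mask) {
      # on the 1H-1H diagonal: auto-correlation ridge, excluded
      autocorr <- c(autocorr, peaks$peaks$id[k]); next
    }
    match_res <- function(dims) {
      ok <- rep(TRUE, nrow(am))
      for (d in dims) {
        val <- if (def$nuclei[d] == "N") am$shift_N else am$shift_H
        ok <- ok & abs(val - w[d]) <= tol[d]
      }
      am$residue[ok]
    }
    ri <- match_res(origin_dims)
    rj <- match_res(dest_dims)
    if (length(ri) == 0 || length(rj) == 0) {
      unassigned <- c(unassigned, peaks$peaks$id[k]); next
    }
    opt <- expand.grid(res_a = ri, res_b = rj, KEEP.OUT.ATTRS = FALSE)
    opt <- opt[opt$res_a != opt$res_b, , drop = FALSE]   # i == j discarded
    if (nrow(opt) == 0) { unassigned <- c(unassigned, peaks$peaks$id[k]); next }
    opt$atom_a <- "H"; opt$atom_b <- "H"
    out[[length(out) + 1]] <- adr(
      options = opt[, c("res_a", "atom_a", "res_b", "atom_b")],
      lower = 1.0, upper = 5.5,
      peak_id = peaks$peaks$id[k], spectrum = def$name,
      intensity = peaks$peaks$intensity[k], source = "h")
  }
  if (length(unassigned) > 0) {
    warning(length(unassigned), " peak(s) in '", def$name,
            "' matched no inter-residue amide pair and were excluded")
  }
  attr(out, "unassigned") <- unassigned
  attr(out, "autocorrelation") <- autocorr
  out
}

# does any peak of `pl` support transfer origin ri -> destination rj?
peaks_supporting <- function(pl, shifts, ri, rj) {
  def <- pl$spectrum
  tol <- def$tolerances
  pos <- peak_position_h(def, shifts, ri, rj)
  if (any(is.na(pos))) return(integer(0))
  ok <- rep(TRUE, nrow(pl$peaks))
  for (d in seq_along(pos)) {
    ok <- ok & abs(pl$peaks[[paste0("w", d)]] - pos[d]) <= tol[d]
  }
  pl$peaks$id[ok]
}

#' Count peak support for every assignment option
#'
#' An amide pair close in space shows up to four cross peaks: two transfer
#' directions in each of the two paired 3D spectra.  The support of an
#' option (i, j) is the number of these four (spectrum, direction) slots in
#' which at least one observed peak is consistent, in every dimension and
#' under the spectrum's dimension roles and matching tolerances, with the
#' amide shifts of i and j; the maximum support is therefore four.
#'
#' @param adrs list of \code{adr} objects.
#' @param peak_lists list of the paired \code{peak_list}s.
#' @param shifts the \code{shift_list} used for matching.
#' @return the ADRs with \code{options$support} filled in.
#' @export
count_support <- function(adrs, peak_lists, shifts) {
  lapply(adrs, function(a) {
    sup <- integer(nrow(a$options))
    for (k in seq_len(nrow(a$options))) {
      i <- a$options$res_a[k]; j <- a$options$res_b[k]
      slots <- 0L
      for (pl in peak_lists) {
        if (length(peaks_supporting(pl, shifts, i, j)) > 0) slots <- slots + 1L
        if (length(peaks_supporting(pl, shifts, j, i)) > 0) slots <- slots + 1L
      }
      sup[k] <- slots
    }
    a$options$support <- sup
    a
  })
}

#' Redundancy-based pruning of assignment options
#'
#' Applies the four-fold-redundancy rule of the paired 3D amide spectra:
#' when an ADR has an option supported by four peaks, options supported by
#' only one or two peaks are removed; when the best option present is
#' supported by three peaks, options supported by a single peak are
#' removed.  Restraints whose option list empties are deactivated (cannot
#' occur under the rule itself, which always keeps the best option).
#'
#' @param adrs list of \code{adr}s with support counts
#'   (see \code{\link{count_support}}).
#' @return pruned list of \code{adr}s.
#' @export
redundancy_filter <- function(adrs) {
  lapply(adrs, function(a) {
    if (nrow(a$options) == 0) { a$active <- FALSE; return(a) }
    sup <- a$options$support
    if (any(is.na(sup))) stop("support counts missing; run count_support first")
    best <- max(sup)
    keep <- if (best >= 4) sup >= 3 else if (best == 3) sup >= 2 else rep(TRUE, length(sup))
    a$options <- a$options[keep, , drop = FALSE]
    rownames(a$options) <- NULL
    if (nrow(a$options) == 0) a$active <- FALSE
    a
  })
}

#' Intensity-based distance classes for amide-amide restraints
#'
#' The peak list of one spectrum is sorted by intensity; the threshold is
#' the most intense peak carrying a sequential assignment option
#' (|i - j| = 1, the longer ~4.3 A distance in a beta sheet).  Peaks
#' strictly stronger than the threshold are classified (1.0, 3.5) A; all
#' peaks less or equally intense get (1.0, 5.5) A.  Without any sequential
#' peak every restraint conservatively gets the wide class, with a warning.
#'
#' @param adrs list of \code{adr}s from one spectrum, carrying intensities.
#' @return the ADRs with bounds set.
#' @export
classify_h_bounds <- function(adrs) {
  if (length(adrs) == 0) return(adrs)
  seq_opt <- vapply(adrs, function(a)
    any(abs(a$options$res_a - a$options$res_b) == 1), logical(1))
  if (!any(seq_opt)) {
    warning("no sequential assignment found; all restraints set to (1.0, 5.5) A")
    return(lapply(adrs, function(a) { a$lower <- 1.0; a$upper <- 5.5; a }))
  }
  threshold <- max(vapply(adrs[seq_opt], function(a) a$intensity, numeric(1)))
  lapply(adrs, function(a) {
    a$lower <- 1.0
    a$upper <- if (!is.na(a$intensity) && a$intensity > threshold) 3.5 else 5.5
    a
  })
}

#' Remove intra-residue-dominated and off-region carbon peaks
#'
#' Long-mixing peaks that coincide (within tolerance) with a peak of the
#' short-mixing spectrum are removed as intra-residue correlations; peaks
#' outside the given spectral region are removed as well.
#'
#' @param long_mix,short_mix \code{peak_list}s sharing the 2D carbon
#'   geometry.
#' @param region list of ppm windows per dimension, default the aliphatic
#'   window 5-75 ppm in both dimensions.
#' @param tol matching tolerance per dimension (defaults to the long-mix
#'   spectrum's tolerances).
#' @return filtered \code{peak_list}.
#' @export
exclude_intra_and_region <- function(long_mix, short_mix = NULL,
                                     region = list(c(5, 75), c(5, 75)),
                                     tol = NULL) {
  stopifnot(inherits(long_mix, "peak_list"))
  if (is.null(tol)) tol <- long_mix$spectrum$tolerances
  pk <- long_mix$peaks
  keep <- pk$w1 >= region[[1]][1] & pk$w1 <= region[[1]][2] &
    pk$w2 >= region[[2]][1] & pk$w2 <= region[[2]][2]
  if (!is.null(short_mix) && nrow(short_mix$peaks) > 0) {
    sp <- short_mix$peaks
    near_short <- vapply(seq_len(nrow(pk)), function(k) {
      any(abs(sp$w1 - pk$w1[k]) <= tol[1] & abs(sp$w2 - pk$w2[k]) <= tol[2])
    }, logical(1))
    keep <- keep & !near_short
  }
  peak_list(long_mix$spectrum, pk[keep, , drop = FALSE])
}

#' Match carbon-carbon peaks against a shift list under a labeling scheme
#'
#' Every carbon shift within tolerance of each dimension yields candidate
#' atoms; inter-residue candidate pairs whose joint labeling product
#' exceeds \code{min_product} (strictly) become assignment options.  Each
#' peak with surviving options yields one ADR in the configured distance
#' class; peaks without surviving options are reported via the
#' \code{unassigned} attribute.
#'
#' @param peaks 2D carbon \code{peak_list} (after
#'   \code{\link{exclude_intra_and_region}}).
#' @param shifts a \code{shift_list}.
#' @param scheme the sample's \code{labeling_scheme}.
#' @param min_product labeling-product threshold (default 0.10).
#' @param bounds distance class; \code{NULL} selects by mode:
#'   \code{single_class} gives (1.5, 8.0) for every carbon restraint,
#'   \code{by_mixing} gives (1.5, 5.5) for medium and (1.5, 7.0) for long
#'   mixing.
#' @param class_mode \code{"single_class"} (default) or \code{"by_mixing"}.
#' @return list of \code{adr} objects.
#' @export
match_peaks_c <- function(peaks, shifts, scheme, min_product = 0.10,
                          bounds = NULL, class_mode = c("single_class", "by_mixing")) {
  stopifnot(inherits(peaks, "peak_list"), inherits(shifts, "shift_list"))
  if (missing(scheme) || is.null(scheme)) stop("a labeling scheme is required")
  stopifnot(inherits(scheme, "labeling_scheme"))
  class_mode <- match.arg(class_mode)
  def <- peaks$spectrum
  if (def$type != "cc") stop("spectrum '", def$name, "' is not a 2D 13C-13C experiment")
  if (is.null(bounds)) {
    bounds <- if (class_mode == "single_class") c(1.5, 8.0)
    else if (def$mixing_class == "darr_long") c(1.5, 7.0) else c(1.5, 5.5)
  }
  tol <- def$tolerances
  cs <- shifts[grepl("^C", shifts$atom), , drop = FALSE]
  out <- list(); unassigned <- integer(0)
  for (k in seq_len(nrow(peaks$peaks))) {
    w1 <- peaks$peaks$w1[k]; w2 <- peaks$peaks$w2[k]
    c1 <- cs[abs(cs$shift - w1) <= tol[1], , drop = FALSE]
    c2 <- cs[abs(cs$shift - w2) <= tol[2], , drop = FALSE]
    opts <- NULL
    if (nrow(c1) > 0 && nrow(c2) > 0) {
      for (a in seq_len(nrow(c1))) for (b in seq_len(nrow(c2))) {
        if (c1$residue[a] == c2$residue[b]) next   # intra-residue excluded
        p <- pair_observability(scheme, c1$type[a], c1$atom[a],
                                c2$type[b], c2$atom[b])
        if (p > min_product) {
          opts <- rbind(opts, data.frame(
            res_a = c1$residue[a], atom_a = c1$atom[a],
            res_b = c2$residue[b], atom_b = c2$atom[b],
            product = p, support = NA_integer_, stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(opts)) { unassigned <- c(unassigned, peaks$peaks$id[k]); next }
    out[[length(out) + 1]] <- adr(options = opts, lower = bounds[1],
                                  upper = bounds[2],
                                  peak_id = peaks$peaks$id[k],
                                  spectrum = def$name,
                                  intensity = peaks$peaks$intensity[k],
                                  source = "c")
  }
  attr(out, "unassigned") <- unassigned
  out
}

#' Emit co-linear hydrogen-bond restraints
#'
#' For every residue couple passing both gates (beta-sheet torsion
#' classification for both residues, and the complete four-peak amide
#' cross-peak pattern, i.e. support count 4), two restraints are emitted:
#' H-O with bounds (1.73, 2.70) A and N-O with bounds (2.52, 3.93) A.
#' Couples failing a gate are reported in the \code{rejected} attribute
#' with a reason, not emitted.
#'
#' @param couples data.frame with columns \code{res_i}, \code{res_j}.
#' @param beta_residues residue numbers classified beta-sheet (e.g. from a
#'   TALOS table: reliable rows with phi/psi in the beta region).
#' @param support named integer: amide cross-peak support per couple, named
#'   \code{"i-j"}; alternatively a data.frame res_i, res_j, support.
#' @return data.frame of restraints (columns donor, acceptor, kind, lower,
#'   upper), two rows per accepted couple, with attribute \code{rejected}.
#' @export
emit_hbond_restraints <- function(couples, beta_residues, support) {
  stopifnot(is.data.frame(couples), all(c("res_i", "res_j") %in% names(couples)))
  key <- paste(pmin(couples$res_i, couples$res_j),
               pmax(couples$res_i, couples$res_j), sep = "-")
  if (anyDuplicated(key)) {
    stop("duplicate residue couple(s): ", paste(unique(key[duplicated(key)]),
                                                collapse = ", "))
  }
  if (is.data.frame(support)) {
    support <- stats::setNames(support$support,
                               paste(pmin(support$res_i, support$res_j),
                                     pmax(support$res_i, support$res_j), sep = "-"))
  }
  out <- NULL; rejected <- NULL
  for (k in seq_len(nrow(couples))) {
    i <- couples$res_i[k]; j <- couples$res_j[k]
    kk <- paste(min(i, j), max(i, j), sep = "-")
    if (!(i %in% beta_residues) || !(j %in% beta_residues)) {
      rejected <- rbind(rejected, data.frame(res_i = i, res_j = j,
                                             reason = "not beta-sheet by torsion prediction"))
      next
    }
    sup <- if (kk %in% names(support)) support[[kk]] else 0L
    if (sup < 4) {
      rejected <- rbind(rejected, data.frame(res_i = i, res_j = j,
                                             reason = "incomplete cross-peak pattern"))
      next
    }
    out <- rbind(out,
                 data.frame(donor = i, acceptor = j, kind = "H_O",
                            lower = 1.73, upper = 2.70),
                 data.frame(donor = i, acceptor = j, kind = "N_O",
                            lower = 2.52, upper = 3.93))
  }
  if (is.null(out)) {
    out <- data.frame(donor = integer(0), acceptor = integer(0),
                      kind = character(0), lower = numeric(0), upper = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# beta-sheet region of the Ramachandran map, used to gate H-bond couples
is_beta_torsion <- function(phi, psi) {
  phi >= -180 & phi <= -90 & psi >= 90 & psi <= 180
}

#' Residues classified beta-sheet by a TALOS-style table
#' @param talos data.frame from \code{\link{read_talos}}.
#' @return residue numbers with reliable beta-region predictions.
#' @export
beta_residues_from_talos <- function(talos) {
  ok <- talos$class == "Good" & is_beta_torsion(talos$phi, talos$psi)
  talos$residue[ok]
}

#' Emit torsion restraints from a TALOS-style prediction table
#'
#' Two restraints (phi and psi) per reliable row (class \code{Good});
#' centers and half-widths copied from the table.
#'
#' @param talos data.frame from \code{\link{read_talos}}.
#' @param min_half_width floor on the half-width in degrees (predictions
#'   with tiny reported uncertainty still get a usable band).
#' @return data.frame residue, angle, center, half_width.
#' @export
emit_torsion_restraints <- function(talos, min_half_width = 10) {
  out <- NULL
  for (k in seq_len(nrow(talos))) {
    if (talos$class[k] != "Good") next
    if (!is.finite(talos$phi[k]) || !is.finite(talos$psi[k])) {
      stop("malformed TALOS row ", k, ": non-finite angle")
    }
    out <- rbind(out,
                 data.frame(residue = talos$residue[k], angle = "phi",
                            center = talos$phi[k],
                            half_width = max(min_half_width, talos$dphi[k])),
                 data.frame(residue = talos$residue[k], angle = "psi",
                            center = talos$psi[k],
                            half_width = max(min_half_width, talos$dpsi[k])))
  }
  if (is.null(out)) {
    out <- data.frame(residue = integer(0), angle = character(0),
                      center = numeric(0), half_width = numeric(0))
  }
  rownames(out) <- NULL
  out
}
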