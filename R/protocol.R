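#' @title Iterative assignment protocol
#' @description The iterative loop: staged introduction of restraint
#'   families, ensemble refinement, violation analysis against the
#'   lowest-energy structures, ambiguity pruning, 4-to-4 combination and
#'   merging of equivalent restraints.
#' @name protocol
NULL

#' Protocol configuration
#'
#' Defaults follow the full-scale protocol: 9 iterations numbered 0-8,
#' ensembles of 200 structures of which the 15 lowest-energy are selected,
#' amide-proton restraints and torsions from iteration 0, carbon-carbon
#' restraints from iteration 4, 4-to-4 combination of the carbon restraints
#' in iterations 4-6, and rejection of restraints not satisfied in at
#' least half of the selected structures.  The violation-tolerance
#' schedule (not printed at full scale) defaults to 1000, 5, 3, 1, 1, 1,
#' 0.1, 0.1, 0.1 Angstrom so the first iteration is effectively
#' unfiltered; the ambiguity cutoff decreases linearly from 1.0 to 0.8.
#' "At least half" is implemented as
#' \code{satisfied >= ceiling(satisfied_fraction * n_select)} (15 is odd).
#'
#' @param n_iterations number of iterations.
#' @param n_structures models per iteration.
#' @param n_select models selected for analysis.
#' @param h_from_iteration,c_from_iteration first iteration (0-based) in
#'   which each restraint family is used.
#' @param combine_iterations 0-based iterations with restraint combination.
#' @param combine_arity combination group size.
#' @param violation_tolerance Angstrom per iteration (recycled if short).
#' @param satisfied_fraction minimum fraction of selected models.
#' @param ambiguity_cutoff cumulative-weight cutoff per iteration.
#' @param seed integer seed for the stochastic steps.
#' @export
protocol_config <- function(n_iterations = 9, n_structures = 200, n_select = 15,
                            h_from_iteration = 0, c_from_iteration = 4,
                            combine_iterations = 4:6, combine_arity = 4,
                            violation_tolerance = c(1000, 5, 3, 1, 1, 1, 0.1, 0.1, 0.1),
                            satisfied_fraction = 0.5,
                            ambiguity_cutoff = seq(1.0, 0.8, length.out = 9),
                            seed = 1) {
  stopifnot(n_select <= n_structures, n_iterations >= 1,
            all(combine_iterations >= 0), all(combine_iterations < n_iterations),
            satisfied_fraction > 0, satisfied_fraction <= 1)
  vt <- rep_len(violation_tolerance, n_iterations)
  ac <- rep_len(ambiguity_cutoff, n_iterations)
  structure(list(n_iterations = n_iterations, n_structures = n_structures,
                 n_select = n_select, h_from_iteration = h_from_iteration,
                 c_from_iteration = c_from_iteration,
                 combine_iterations = combine_iterations,
                 combine_arity = combine_arity, violation_tolerance = vt,
                 satisfied_fraction = satisfied_fraction,
                 ambiguity_cutoff = ac, seed = seed),
            class = "protocol_config")
}

#' Effective distance of an ambiguous restraint in one model
#'
#' The r^-6-pooled effective distance
#' \eqn{(\sum_o d_o^{-6})^{-1/6}} over the restraint's assignment
#' options; equal to the plain distance for a single option, and never
#' larger than the shortest option distance.
#'
#' @param ensemble a \code{\link{structure_ensemble}}.
#' @param restraint an \code{\link{adr}}.
#' @param model model index.
#' @return distance in Angstrom.
#' @export
effective_distance <- function(ensemble, restraint, model = 1) {
  op <- restraint$options
  if (nrow(op) == 0) stop("restraint has no assignment options")
  m <- ensemble$models[[model]]
  d <- vapply(seq_len(nrow(op)), function(k) {
    ia <- proxy_atom_row(ensemble$atoms, op$res_a[k], op$atom_a[k])
    ib <- proxy_atom_row(ensemble$atoms, op$res_b[k], op$atom_b[k])
    corr <- proxy_correction(op$atom_a[k]) + proxy_correction(op$atom_b[k])
    d1 <- sqrt(sum((m[ia, ] - m[ib, ])^2))
    if (corr > 0) d1 <- max(d1 - corr, max(0.5, restraint$lower)) else d1
  }, numeric(1))
  sum(d^-6)^(-1 / 6)
}

#' Violation analysis against the selected ensemble
#'
#' A restraint is satisfied in a model when its effective distance lies in
#' \code{[lower - tol, upper + tol]}.  Restraints satisfied in fewer than
#' \code{ceiling(satisfied_fraction * n_select)} of the selected models are
#' rejected: set inactive for the next iteration, never deleted.  Every
#' restraint (including previously rejected ones) is re-evaluated, so a
#' restraint rejected against an early ensemble is recovered as soon as
#' the ensembles satisfy it again.
#'
#' @param adrs list of \code{\link{adr}}s.
#' @param ensemble refined ensemble, sorted by pseudo-energy.
#' @param config a \code{\link{protocol_config}}.
#' @param tol violation tolerance in Angstrom.
#' @return list with \code{adrs} (updated activity flags) and
#'   \code{report}: data.frame restraint, satisfied, n_models, decision.
#' @export
violation_analysis <- function(adrs, ensemble, config, tol) {
  if (length(ensemble$models) == 0) stop("empty ensemble")
  sel <- sort_by_energy(ensemble, config$n_select)
  nsel <- length(sel$models)
  need <- ceiling(config$satisfied_fraction * nsel)
  report <- NULL
  for (k in seq_along(adrs)) {
    a <- adrs[[k]]
    if (nrow(a$options) == 0) {
      report <- rbind(report, data.frame(restraint = k, satisfied = NA_integer_,
                                         n_models = nsel, decision = "inactive"))
      next
    }
    sat <- 0L
    for (m in seq_len(nsel)) {
      d <- effective_distance(sel, a, m)
      if (d >= a$lower - tol && d <= a$upper + tol) sat <- sat + 1L
    }
    keep <- sat >= need
    adrs[[k]]$active <- keep
    report <- rbind(report, data.frame(restraint = k, satisfied = sat,
                                       n_models = nsel,
                                       decision = if (keep) "kept" else "rejected"))
  }
  list(adrs = adrs, report = report)
}

#' Ambiguity pruning of one restraint
#'
#' Options are weighted proportionally to their mean r^-6 contribution over
#' the selected models, sorted by weight, and the smallest prefix whose
#' cumulative weight reaches the cutoff is retained.
#'
#' @param restraint an \code{\link{adr}}.
#' @param ensemble selected ensemble.
#' @param cutoff cumulative weight cutoff in (0, 1]; 1 keeps everything.
#' @param n_select number of models used.
#' @return the pruned \code{adr}.
#' @export
prune_options <- function(restraint, ensemble, cutoff, n_select = length(ensemble$models)) {
  op <- restraint$options
  if (nrow(op) <= 1 || cutoff >= 1) return(restraint)
  sel <- sort_by_energy(ensemble, n_select)
  w <- numeric(nrow(op))
  for (k in seq_len(nrow(op))) {
    ia <- proxy_atom_row(sel$atoms, op$res_a[k], op$atom_a[k])
    ib <- proxy_atom_row(sel$atoms, op$res_b[k], op$atom_b[k])
    corr <- proxy_correction(op$atom_a[k]) + proxy_correction(op$atom_b[k])
    d <- vapply(seq_along(sel$models), function(m) {
      d1 <- sqrt(sum((sel$models[[m]][ia, ] - sel$models[[m]][ib, ])^2))
      if (corr > 0) max(d1 - corr, max(0.5, restraint$lower)) else d1
    }, numeric(1))
    w[k] <- mean(d^-6)
  }
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  keep_n <- which(cum >= cutoff - 1e-12)[1]
  keep <- sort(ord[seq_len(keep_n)])
  restraint$options <- op[keep, , drop = FALSE]
  rownames(restraint$options) <- NULL
  restraint
}

#' 4-to-4 combination of restraints
#'
#' Random groups of \code{arity} restraints are merged into one restraint
#' whose option set is the union of the group's options and whose bounds
#' are the widest in the group; fewer than \code{arity} leftovers pass
#' through unchanged.  Grouping is seed-reproducible.
#'
#' @param adrs list of \code{\link{adr}}s (the carbon-carbon family).
#' @param arity group size (>= 2).
#' @param seed integer seed.
#' @return list of combined \code{adr}s.
#' @export
combine_restraints <- function(adrs, arity = 4, seed = 1) {
  if (arity < 2) stop("combination arity must be at least 2")
  n <- length(adrs)
  if (n == 0) return(adrs)
  perm <- withr_seed(seed, sample.int(n))
  ngroup <- floor(n / arity)
  out <- list()
  for (g in seq_len(ngroup)) {
    members <- adrs[perm[((g - 1) * arity + 1):(g * arity)]]
    op <- unique(do.call(rbind, lapply(members, function(a) a$options)))
    rownames(op) <- NULL
    out[[length(out) + 1]] <- adr(
      options = op,
      lower = min(vapply(members, function(a) a$lower, numeric(1))),
      upper = max(vapply(members, function(a) a$upper, numeric(1))),
      peak_id = unlist(lapply(members, function(a) a$peak_id)),
      spectrum = members[[1]]$spectrum,
      source = members[[1]]$source)
  }
  if (ngroup * arity < n) {
    out <- c(out, adrs[perm[(ngroup * arity + 1):n]])
  }
  out
}

#' Merge restraints with identical option sets
#'
#' Restraints whose option sets are equal (ignoring order) are merged into
#' one, keeping the tighter bounds and the union of source peaks.
#'
#' @param adrs list of \code{\link{adr}}s.
#' @return merged list.
#' @export
merge_equivalent <- function(adrs) {
  if (length(adrs) <= 1) return(adrs)
  keyof <- function(a) {
    op <- a$options
    parts <- vapply(seq_len(nrow(op)), function(k) {
      a1 <- paste0(op$res_a[k], ".", op$atom_a[k])
      b1 <- paste0(op$res_b[k], ".", op$atom_b[k])
      paste(sort(c(a1, b1)), collapse = "~")
    }, character(1))
    paste(sort(parts), collapse = "|")
  }
  keys <- vapply(adrs, keyof, character(1))
  out <- list()
  for (key in unique(keys)) {
    grp <- adrs[keys == key]
    a <- grp[[1]]
    a$lower <- max(vapply(grp, function(x) x$lower, numeric(1)))
    a$upper <- min(vapply(grp, function(x) x$upper, numeric(1)))
    a$peak_id <- unlist(lapply(grp, function(x) x$peak_id))
    a$active <- any(vapply(grp, function(x) isTRUE(x$active), logical(1)))
    out[[length(out) + 1]] <- a
  }
  out
}

#' Run the iterative assignment protocol
#'
#' The central fitting loop.  Iterations 0-3 refine against amide-proton
#' restraints and torsions only; carbon-carbon restraints join at
#' iteration 4 (4-to-4 combined and merged in iterations 4-6); after each
#' iteration the lowest-energy structures drive violation analysis
#' (restraints failing the at-least-half rule are deactivated, recoverably)
#' and ambiguity pruning.  When hydrogen-bond restraints are supplied, a
#' final run adds them to the full restraint set.
#'
#' @param atoms atom table (or \code{structure_ensemble}) defining the chain.
#' @param h_adrs amide-proton \code{\link{adr}}s.
#' @param c_adrs carbon-carbon \code{\link{adr}}s.
#' @param torsions torsion restraints data.frame.
#' @param hbonds optional hydrogen-bond restraints
#'   (\code{\link{emit_hbond_restraints}}).
#' @param config a \code{\link{protocol_config}}.
#' @param anneal_cfg an \code{\link{anneal_config}} template; its seed and
#'   model count are overridden per iteration from \code{config}.
#' @return object of class \code{adr_protocol}: per-iteration history
#'   (restraint counts, ambiguity, violation reports), final restraint
#'   states and the final ensemble.
#' @export
run_protocol <- function(atoms, h_adrs, c_adrs = list(), torsions = NULL,
                         hbonds = NULL, config = protocol_config(),
                         anneal_cfg = anneal_config()) {
  if (inherits(atoms, "structure_ensemble")) atoms <- atoms$atoms
  history <- list()
  ens <- NULL
  for (it in seq_len(config$n_iterations) - 1L) {
    pool_h <- if (it >= config$h_from_iteration) Filter(function(a) a$active, h_adrs) else list()
    pool_c <- if (it >= config$c_from_iteration) Filter(function(a) a$active, c_adrs) else list()
    c_used <- pool_c
    if (length(pool_c) > 0 && it %in% config$combine_iterations) {
      c_used <- merge_equivalent(
        combine_restraints(pool_c, config$combine_arity,
                           seed = config$seed + 31L * it))
    }
    used <- c(pool_h, c_used)
    acfg <- anneal_cfg
    acfg$n_models <- config$n_structures
    acfg$seed <- config$seed + 1000L * it
    ens <- anneal(atoms, used, torsions, acfg)
    sel <- sort_by_energy(ens, config$n_select)

    # violation analysis + pruning on the master pools (families in use)
    tol <- config$violation_tolerance[it + 1L]
    va_h <- violation_analysis(h_adrs, sel, config, tol)
    h_adrs <- va_h$adrs
    va_c <- NULL
    if (it >= config$c_from_iteration) {
      va_c <- violation_analysis(c_adrs, sel, config, tol)
      c_adrs <- va_c$adrs
    }
    cut <- config$ambiguity_cutoff[it + 1L]
    h_adrs <- lapply(h_adrs, function(a)
      if (a$active) prune_options(a, sel, cut, config$n_select) else a)
    if (it >= config$c_from_iteration) {
      c_adrs <- lapply(c_adrs, function(a)
        if (a$active) prune_options(a, sel, cut, config$n_select) else a)
    }
    history[[it + 1L]] <- list(
      iteration = it,
      n_restraints_used = length(used),
      n_h_active = sum(vapply(h_adrs, function(a) a$active, logical(1))),
      n_c_active = sum(vapply(c_adrs, function(a) a$active, logical(1))),
      n_c_in_pool = length(pool_c),
      combined = length(pool_c) > 0 && it %in% config$combine_iterations,
      mean_ambiguity = adr_stats(c(h_adrs, c_adrs))$mean_ambiguity,
      violation_tolerance = tol,
      report_h = va_h$report,
      report_c = if (!is.null(va_c)) va_c$report else NULL,
      energies = ens$energies)
  }
  final <- ens
  if (!is.null(hbonds) && nrow(hbonds) > 0) {
    used <- c(Filter(function(a) a$active, h_adrs),
              Filter(function(a) a$active, c_adrs),
              hbonds_as_restraints(hbonds))
    acfg <- anneal_cfg
    acfg$n_models <- config$n_structures
    acfg$seed <- config$seed + 999983L
    final <- anneal(atoms, used, torsions, acfg)
  }
  structure(list(config = config, history = history, h_adrs = h_adrs,
                 c_adrs = c_adrs, torsions = torsions, hbonds = hbonds,
                 final = final, atoms = atoms),
            class = "adr_protocol")
}

#' @export
print.adr_protocol <- function(x, ...) {
  cat(sprintf("Iterative assignment protocol: %d iteration(s)\n",
              length(x$history)))
  for (h in x$history) {
    cat(sprintf("  it %d: used %d restraints (H active %d, C active %d%s), mean ambiguity %.2f\n",
                h$iteration, h$n_restraints_used, h$n_h_active, h$n_c_active,
                if (h$combined) ", combined" else "", h$mean_ambiguity))
  }
  cat(sprintf("Final ensemble: %d models, best energy %.2f\n",
              length(x$final$models), min(x$final$energies)))
  invisible(x)
}

#' @export
summary.adr_protocol <- function(object, ...) {
  hs <- object$history
  df <- data.frame(
    iteration = vapply(hs, function(h) h$iteration, numeric(1)),
    restraints_used = vapply(hs, function(h) h$n_restraints_used, numeric(1)),
    h_active = vapply(hs, function(h) h$n_h_active, numeric(1)),
    c_active = vapply(hs, function(h) h$n_c_active, numeric(1)),
    mean_ambiguity = vapply(hs, function(h) h$mean_ambiguity, numeric(1)),
    tolerance = vapply(hs, function(h) h$violation_tolerance, numeric(1)),
    best_energy = vapply(hs, function(h) min(h$energies), numeric(1)))
  class(df) <- c("summary.adr_protocol", "data.frame")
  df
}

#' @export
plot.adr_protocol <- function(x, ...) {
  s <- summary(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(s$iteration, s$mean_ambiguity, type = "b", pch = 19,
                 xlab = "iteration", ylab = "mean options per restraint",
                 main = "Disambiguation")
  graphics::plot(s$iteration, s$h_active + s$c_active, type = "b", pch = 19,
                 xlab = "iteration", ylab = "active restraints",
                 main = "Violation analysis")
  invisible(x)
}

#' Hydrogen-bond couple candidates from a refined ensemble
#'
#' Reads the hydrogen-bonding pattern off a converged ensemble the way the
#' final calculation stage expects it: for every amide-carrying residue,
#' its mutual nearest cross-strand amide partner (sequence separation > 2)
#' within \code{max_distance} is a candidate couple; couples are kept when
#' the pattern recurs in at least \code{min_fraction} of the selected
#' models.  The returned couples are usually passed through the torsion
#' and cross-peak gates of \code{\link{emit_hbond_restraints}}.
#'
#' @param ensemble refined \code{\link{structure_ensemble}}.
#' @param residues residues with observable amides (e.g. those carrying
#'   amide shifts); defaults to every residue with an H atom.
#' @param n_select number of lowest-energy models read.
#' @param max_distance maximal HN-HN distance of a facing pair, Angstrom.
#' @param min_fraction minimal fraction of models showing the pair.
#' @return data.frame res_i, res_j (res_i < res_j).
#' @export
derive_hbond_couples <- function(ensemble, residues = NULL, n_select = 5,
                                 max_distance = 5.0, min_fraction = 0.5) {
  sel <- sort_by_energy(ensemble, n_select)
  at <- sel$atoms
  if (is.null(residues)) residues <- sort(unique(at$residue[at$atom == "H"]))
  rows <- match(paste(residues, "H"), paste(at$residue, at$atom))
  ok <- !is.na(rows)
  residues <- residues[ok]; rows <- rows[ok]
  votes <- new.env(parent = emptyenv())
  seqmask <- abs(outer(residues, residues, "-")) <= 2
  for (m in seq_along(sel$models)) {
    D <- as.matrix(stats::dist(sel$models[[m]][rows, , drop = FALSE]))
    D[seqmask] <- Inf
    diag(D) <- Inf
    for (a in seq_along(residues)) {
      b <- which.min(D[a, ])
      if (is.finite(D[a, b]) && D[a, b] <= max_distance &&
          which.min(D[b, ]) == a) {
        key <- paste(min(residues[a], residues[b]),
                     max(residues[a], residues[b]))
        votes[[key]] <- (if (is.null(votes[[key]])) 0L else votes[[key]]) + 1L
      }
    }
  }
  need <- ceiling(min_fraction * length(sel$models))
  keys <- ls(votes)
  counts <- vapply(keys, function(k) votes[[k]], integer(1)) / 2L
  keep <- keys[counts >= need]
  if (length(keep) == 0) {
    return(data.frame(res_i = integer(0), res_j = integer(0)))
  }
  out <- do.call(rbind, lapply(keep, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    data.frame(res_i = v[1], res_j = v[2])
  }))
  out[order(out$res_i, out$res_j), , drop = FALSE]
}
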