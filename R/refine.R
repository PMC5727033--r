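#' @title Desk-scale restraint-satisfaction engine
#' @description A simplified Cartesian simulated-annealing refiner standing
#'   in for a full structure-calculation engine: overdamped Langevin
#'   dynamics with a linear cooling schedule and a FIRE quench on a
#'   pseudo-energy of covalent-geometry terms, flat-bottom ambiguous
#'   distance restraints (r^-6 pooled), flat-bottom torsion restraints and
#'   a soft CA-CA repulsion.  It is not a CNS reimplementation: no
#'   torsion-angle dynamics, no Ramachandran potential, no solvent
#'   refinement.
#' @name toy_refine
NULL

#' Reference simulated-annealing parameters
#'
#' The full-scale refinement schedule (TAD high temperature 20000 K, 9.0
#' time-step factor, Cartesian high temperature 3000 K, two 100000-step
#' cooling stages to 1000 K and 50 K, 20000 high-temperature steps, 8000
#' refine steps) kept as provenance; \code{\link{anneal_config}} derives
#' its desk-scale defaults from it (temperatures / 10, steps / 100).
#' @export
table2_reference <- function() {
  list(tad_high_temperature_K = 20000, tad_time_step_factor = 9.0,
       cartesian_high_temperature_K = 3000, time_step = 0.003,
       cool1_final_K = 1000, cool1_steps = 100000,
       cool2_final_K = 50, cool2_steps = 100000,
       high_temperature_steps = 20000, refine_steps = 8000)
}

#' Annealing configuration
#'
#' Desk-scale schedule derived from the reference parameters
#' (\code{\link{table2_reference}}): step counts divided by 100,
#' temperatures divided by 10 and mapped onto the engine's reduced units
#' by a fixed calibration factor.
#'
#' @param n_models models per ensemble.
#' @param seed base integer seed; model m uses \code{seed + 7919 * m}.
#' @param n_high hot-phase Langevin steps.
#' @param n_cool cooling-phase steps.
#' @param n_quench FIRE quench iterations.
#' @param temp_high hot-phase temperature in reduced units.
#' @param dt Langevin step size.
#' @param force_cap per-atom force cap (stability).
#' @param bond_k,angle_k,improper_k,torsion_k,restraint_k,nb_k force
#'   constants (reduced units; angles/torsions per rad^2).
#' @param nb_rmin CA-CA soft-repulsion onset distance, Angstrom.
#' @export
anneal_config <- function(n_models = 20, seed = 1,
                          n_high = 2000, n_cool = 10000, n_quench = 8000,
                          temp_high = 0.5, dt = 0.0015, dt_hot = 0.002,
                          force_cap = 40, geom_soft = 0.1,
                          bond_k = 100, angle_k = 30, improper_k = 20,
                          torsion_k = 10, restraint_k = 20,
                          nb_k = 5, nb_rmin = 4.0) {
  stopifnot(n_models >= 1, n_high > 0, n_cool > 0, n_quench > 0,
            temp_high > 0, dt > 0, dt_hot > 0,
            geom_soft > 0, geom_soft <= 1)
  structure(list(n_models = n_models, seed = seed, n_high = n_high,
                 n_cool = n_cool, n_quench = n_quench, temp_high = temp_high,
                 dt = dt, dt_hot = dt_hot, force_cap = force_cap,
                 geom_soft = geom_soft, bond_k = bond_k,
                 angle_k = angle_k, improper_k = improper_k,
                 torsion_k = torsion_k, restraint_k = restraint_k,
                 nb_k = nb_k, nb_rmin = nb_rmin,
                 reference = table2_reference()),
            class = "anneal_config")
}

# planarity improper center: CA, N(next), C, O around the carbonyl carbon
IMPROPER_CO_CENTER <- 180

# Build the C++ system description (0-based indices) for an atom table.
build_system_list <- function(atoms, restraints, torsions, cfg) {
  g <- SHEET_GEOM
  idx <- function(res, at) {
    i <- which(atoms$residue == res & atoms$atom == at)
    if (length(i) != 1) NA_integer_ else i
  }
  resn <- sort(unique(atoms$residue))
  bonds <- NULL; br0 <- NULL
  angles <- NULL; at0 <- NULL
  dihs <- NULL; dc <- NULL; dw <- NULL; dk <- NULL
  addb <- function(i, j, r0) {
    if (!is.na(i) && !is.na(j)) { bonds <<- rbind(bonds, c(i, j)); br0 <<- c(br0, r0) }
  }
  adda <- function(i, j, k, t0) {
    if (!is.na(i) && !is.na(j) && !is.na(k)) {
      angles <<- rbind(angles, c(i, j, k)); at0 <<- c(at0, t0 * pi / 180)
    }
  }
  addd <- function(i, j, k, l, center, hw, kk) {
    if (!any(is.na(c(i, j, k, l)))) {
      dihs <<- rbind(dihs, c(i, j, k, l))
      dc <<- c(dc, center * pi / 180); dw <<- c(dw, hw * pi / 180); dk <<- c(dk, kk)
    }
  }
  for (r in resn) {
    iN <- idx(r, "N"); iH <- idx(r, "H"); iCA <- idx(r, "CA")
    iCB <- idx(r, "CB"); iC <- idx(r, "C"); iO <- idx(r, "O")
    addb(iN, iCA, g$b_NCA); addb(iCA, iC, g$b_CAC); addb(iC, iO, g$b_CO)
    addb(iN, iH, g$b_NH); addb(iCA, iCB, g$b_CACB)
    adda(iN, iCA, iC, g$tau); adda(iCA, iC, iO, g$a_CACO)
    adda(iH, iN, iCA, 119.3)
    adda(iN, iCA, iCB, g$a_NCACB); adda(iC, iCA, iCB, 110.1)
    if (!is.na(iCB)) addd(iC, iN, iCA, iCB, g$chi_CB, 0, cfg$improper_k)
    if ((r + 1) %in% resn) {
      jN <- idx(r + 1, "N"); jCA <- idx(r + 1, "CA"); jH <- idx(r + 1, "H")
      addb(iC, jN, g$b_CN)
      adda(iCA, iC, jN, g$a_CACN); adda(iC, jN, jCA, g$a_CNCA)
      adda(iO, iC, jN, 123.0); adda(iC, jN, jH, g$a_HNC)
      addd(iCA, iC, jN, jCA, 180, 0, cfg$improper_k)       # omega
      addd(iO, iC, jN, jH, 180, 0, cfg$improper_k)          # amide H planarity
      addd(iCA, jN, iC, iO, IMPROPER_CO_CENTER, 0, cfg$improper_k)  # carbonyl planarity
    }
  }
  # torsion restraints (flat-bottom)
  if (!is.null(torsions) && nrow(torsions) > 0) {
    for (k in seq_len(nrow(torsions))) {
      r <- torsions$residue[k]
      if (torsions$angle[k] == "phi") {
        addd(idx(r - 1, "C"), idx(r, "N"), idx(r, "CA"), idx(r, "C"),
             torsions$center[k], torsions$half_width[k], cfg$torsion_k)
      } else {
        addd(idx(r, "N"), idx(r, "CA"), idx(r, "C"), idx(r + 1, "N"),
             torsions$center[k], torsions$half_width[k], cfg$torsion_k)
      }
    }
  }
  # distance restraints: active ADRs; side-chain carbons map to their CB
  # proxy with a pseudo-atom correction subtracted from the distance
  rstart <- 0L; oi <- integer(0); oj <- integer(0); ocorr <- numeric(0)
  rlo <- numeric(0); rup <- numeric(0)
  for (a in restraints) {
    if (!isTRUE(a$active) || nrow(a$options) == 0) next
    ii <- jj <- integer(0); cc <- numeric(0)
    for (t in seq_len(nrow(a$options))) {
      i1 <- proxy_atom_row(atoms, a$options$res_a[t], a$options$atom_a[t])
      j1 <- proxy_atom_row(atoms, a$options$res_b[t], a$options$atom_b[t])
      ii <- c(ii, i1); jj <- c(jj, j1)
      cc <- c(cc, proxy_correction(a$options$atom_a[t]) +
                proxy_correction(a$options$atom_b[t]))
    }
    oi <- c(oi, ii); oj <- c(oj, jj); ocorr <- c(ocorr, cc)
    rstart <- c(rstart, length(oi))
    rlo <- c(rlo, a$lower); rup <- c(rup, a$upper)
  }
  ca <- which(atoms$atom == "CA")
  list(n_atoms = nrow(atoms),
       bonds = if (is.null(bonds)) matrix(0L, 0, 2) else bonds - 1L,
       bond_r0 = if (is.null(br0)) numeric(0) else br0, bond_k = cfg$bond_k,
       angles = if (is.null(angles)) matrix(0L, 0, 3) else angles - 1L,
       angle_t0 = if (is.null(at0)) numeric(0) else at0, angle_k = cfg$angle_k,
       dihedrals = if (is.null(dihs)) matrix(0L, 0, 4) else dihs - 1L,
       dih_center = if (is.null(dc)) numeric(0) else dc,
       dih_halfwidth = if (is.null(dw)) numeric(0) else dw,
       dih_k = if (is.null(dk)) numeric(0) else dk,
       rest_start = as.integer(rstart), opt_i = as.integer(oi - 1L),
       opt_j = as.integer(oj - 1L), opt_corr = ocorr,
       rest_lower = rlo, rest_upper = rup,
       rest_k = cfg$restraint_k,
       ca_idx = as.integer(ca - 1L), ca_res = as.integer(atoms$residue[ca]),
       nb_rmin = cfg$nb_rmin, nb_k = cfg$nb_k)
}

# Distance-geometry initial coordinates: a sparse graph of known distances
# (covalent bonds, 1-3 distances from the ideal angles, unambiguous active
# distance restraints at their bound midpoints) is completed by
# shortest-path bound smoothing and embedded with classical MDS.  The
# embedding is defined up to reflection; alternate models start from the
# mirrored embedding and the annealer's pseudo-energy decides which
# handedness survives selection.
dg_initial_coords <- function(atoms, sys) {
  n <- nrow(atoms)
  B <- sys$bonds + 1L
  edges <- cbind(B[, 1], B[, 2]); w <- sys$bond_r0
  A <- sys$angles + 1L
  if (nrow(A) > 0) {
    # 1-3 distance via the law of cosines using the bonded r0 values
    r0_of <- function(i, j) {
      hit <- which((B[, 1] == i & B[, 2] == j) | (B[, 1] == j & B[, 2] == i))
      if (length(hit) > 0) sys$bond_r0[hit[1]] else 1.5
    }
    for (k in seq_len(nrow(A))) {
      r12 <- r0_of(A[k, 1], A[k, 2]); r23 <- r0_of(A[k, 2], A[k, 3])
      d13 <- sqrt(r12^2 + r23^2 - 2 * r12 * r23 * cos(sys$angle_t0[k]))
      edges <- rbind(edges, c(A[k, 1], A[k, 3])); w <- c(w, d13)
    }
  }
  n_base <- nrow(edges)
  nopt <- diff(sys$rest_start)
  for (r in seq_along(nopt)) {
    if (nopt[r] != 1) next
    t <- sys$rest_start[r] + 1L
    edges <- rbind(edges, c(sys$opt_i[t] + 1L, sys$opt_j[t] + 1L))
    w <- c(w, (sys$rest_lower[r] + min(sys$rest_upper[r], 6.5)) / 2 +
            sys$opt_corr[t] / 2)
  }
  embed1 <- function(edges, w) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- w
    GD <- igraph::distances(g)
    if (any(!is.finite(GD))) GD[!is.finite(GD)] <- max(GD[is.finite(GD)])
    unname(stats::cmdscale(GD, k = 3))
  }
  fit <- embed1(edges, w)
  # trimmed second pass: restraint edges grossly inconsistent with the
  # first embedding (wrongly assigned restraints act as shortcuts that
  # warp the shortest-path metric) are dropped before re-embedding
  if (nrow(edges) > n_base) {
    ridx <- (n_base + 1):nrow(edges)
    derr <- vapply(ridx, function(k)
      sqrt(sum((fit[edges[k, 1], ] - fit[edges[k, 2], ])^2)) - w[k], numeric(1))
    bad <- ridx[derr > 4]
    if (length(bad) > 0 && length(bad) < length(ridx)) {
      fit <- embed1(edges[-bad, , drop = FALSE], w[-bad])
    }
  }
  fit
}

# Extended starting conformation over the atom table's residues.
extended_chain <- function(atoms) {
  resn <- sort(unique(atoms$residue))
  types <- vapply(resn, function(r) atoms$type[atoms$residue == r][1], character(1))
  strand <- build_ideal_strand(length(resn))
  xyz <- matrix(NA_real_, nrow(atoms), 3)
  for (k in seq_along(resn)) {
    at <- strand[[k]]
    for (a in c("N", "H", "CA", "CB", "C", "O")) {
      i <- which(atoms$residue == resn[k] & atoms$atom == a)
      if (length(i) == 1) xyz[i, ] <- at[[a]]
    }
  }
  xyz
}

#' Simulated-annealing refinement against a restraint set
#'
#' Computes \code{n_models} models from independent seeds by Langevin
#' annealing followed by a FIRE quench of the pseudo-energy.  Models start
#' from a distance-geometry embedding of the unambiguous restraint network
#' (shortest-path bound smoothing + classical MDS; alternate models use
#' the mirrored embedding so both handednesses compete on energy), each
#' perturbed with seeded noise.  With zero distance restraints models
#' start from, and stay at, an extended geometry-regularized chain.
#'
#' @param atoms atom table (data.frame residue/type/atom) defining the
#'   chain, e.g. from a \code{\link{structure_ensemble}}.
#' @param restraints list of \code{\link{adr}} objects (plus optional
#'   hydrogen-bond restraints converted via
#'   \code{\link{hbonds_as_restraints}}).
#' @param torsions torsion restraint data.frame
#'   (\code{\link{emit_torsion_restraints}}).
#' @param config an \code{\link{anneal_config}}.
#' @return a \code{\link{structure_ensemble}} sorted by pseudo-energy.
#' @export
anneal <- function(atoms, restraints, torsions = NULL, config = anneal_config()) {
  if (inherits(atoms, "structure_ensemble")) atoms <- atoms$atoms
  sys <- build_system_list(atoms, restraints, torsions, config)
  have_restraints <- length(sys$rest_lower) > 0
  x_dg <- if (have_restraints) dg_initial_coords(atoms, sys) else NULL
  x_ext <- extended_chain(atoms)
  sched <- list(n_high = config$n_high, n_cool = config$n_cool,
                n_quench = config$n_quench, temp_high = config$temp_high,
                dt = config$dt, dt_hot = config$dt_hot,
                force_cap = config$force_cap, geom_soft = config$geom_soft)
  models <- vector("list", config$n_models)
  energies <- numeric(config$n_models)
  for (m in seq_len(config$n_models)) {
    seed_m <- (config$seed + 7919L * m) %% .Machine$integer.max
    if (have_restraints) {
      x0 <- withr_seed(seed_m, x_dg + matrix(stats::rnorm(3 * nrow(x_dg), 0, 0.5),
                                             ncol = 3))
      if (m %% 2 == 0) x0[, 1] <- -x0[, 1]   # mirrored embedding
    } else {
      x0 <- x_ext
    }
    res <- .cpp_anneal(x0, sys, sched, as.integer(seed_m))
    models[[m]] <- res$coords
    energies[m] <- res$energy
  }
  ens <- structure_ensemble(atoms, models, energies,
                            provenance = list(seed = config$seed,
                                              n_models = config$n_models))
  sort_by_energy(ens)
}

#' Pseudo-energy of one model
#'
#' Total pseudo-energy and its decomposition; the restraint term is zero
#' exactly when every distance restraint is satisfied.
#'
#' @param ensemble a \code{\link{structure_ensemble}}.
#' @param restraints list of \code{\link{adr}}s.
#' @param torsions torsion restraint data.frame or NULL.
#' @param model model index.
#' @param config force-constant configuration.
#' @return list with \code{total}, \code{restraint}, \code{geometry}.
#' @export
pseudo_energy <- function(ensemble, restraints, torsions = NULL, model = 1,
                          config = anneal_config()) {
  sys <- build_system_list(ensemble$atoms, restraints, torsions, config)
  .cpp_energy(ensemble$models[[model]], sys)
}

#' Convert hydrogen-bond restraints into distance restraints
#'
#' Each H-O / N-O record becomes an unambiguous \code{\link{adr}} between
#' the donor's amide H (or N) and the acceptor's carbonyl O.
#'
#' @param hbonds data.frame from \code{\link{emit_hbond_restraints}}.
#' @return list of \code{adr}s.
#' @export
hbonds_as_restraints <- function(hbonds) {
  out <- list()
  for (k in seq_len(nrow(hbonds))) {
    atom_a <- if (hbonds$kind[k] == "H_O") "H" else "N"
    out[[length(out) + 1]] <- adr(
      options = data.frame(res_a = hbonds$donor[k], atom_a = atom_a,
                           res_b = hbonds$acceptor[k], atom_b = "O",
                           product = NA_real_, support = NA_integer_,
                           stringsAsFactors = FALSE),
      lower = hbonds$lower[k], upper = hbonds$upper[k], source = "hbond")
  }
  out
}

#' Backbone RMSD of an ensemble
#'
#' Mean and standard deviation of the pairwise backbone (N, CA, C, O)
#' RMSD after optimal superposition over a residue subset; or, when a
#' single-model \code{reference} is given, statistics of each model's RMSD
#' to that reference.
#'
#' @param ensemble a \code{\link{structure_ensemble}} with >= 2 models (or
#'   >= 1 when \code{reference} is used).
#' @param residues residue subset (default: all shared residues).
#' @param reference optional single-model \code{structure_ensemble}.
#' @return list with \code{mean}, \code{sd} and the individual
#'   \code{values}, in Angstrom.
#' @export
backbone_rmsd <- function(ensemble, residues = NULL, reference = NULL) {
  at <- ensemble$atoms
  if (is.null(residues)) residues <- unique(at$residue)
  if (length(residues) == 0) stop("empty residue subset")
  sel <- which(at$residue %in% residues & at$atom %in% c("N", "CA", "C", "O"))
  if (length(sel) == 0) stop("no backbone atoms in the residue subset")
  if (!is.null(reference)) {
    rat <- reference$atoms
    key <- paste(at$residue[sel], at$atom[sel])
    rsel <- match(key, paste(rat$residue, rat$atom))
    if (any(is.na(rsel))) stop("reference lacks atoms of the residue subset")
    ref <- reference$models[[1]][rsel, , drop = FALSE]
    vals <- vapply(ensemble$models, function(m)
      superposed_rmsd(m[sel, , drop = FALSE], ref), numeric(1))
  } else {
    nm <- length(ensemble$models)
    if (nm < 2) stop("pairwise RMSD needs at least two models")
    vals <- numeric(0)
    for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
      vals <- c(vals, superposed_rmsd(ensemble$models[[a]][sel, , drop = FALSE],
                                      ensemble$models[[b]][sel, , drop = FALSE]))
    }
  }
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
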