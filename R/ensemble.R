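#' Structure ensembles
#'
#' A \code{structure_ensemble} holds one or more backbone models over a
#' fixed atom table (residue number, residue type, atom name), together
#' with per-model pseudo-energies and provenance.  The synthetic generator
#' returns a single-model ensemble (the ground truth); the refinement
#' engine returns multi-model ensembles.
#'
#' @param atoms data.frame with columns \code{residue}, \code{type}
#'   (one-letter code), \code{atom} (N, H, CA, CB, C, O).
#' @param models list of numeric matrices (n_atoms x 3), coordinates in
#'   Angstrom.
#' @param energies numeric vector of per-model pseudo-energies (NA when not
#'   refined).
#' @param provenance free-form list (seed, iteration, generator settings).
#' @return object of class \code{structure_ensemble}.
#' @export
structure_ensemble <- function(atoms, models, energies = rep(NA_real_, length(models)),
                               provenance = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("residue", "type", "atom") %in% names(atoms)),
            length(models) >= 1,
            all(vapply(models, function(m) nrow(m) == nrow(atoms), logical(1))),
            length(energies) == length(models))
  structure(list(atoms = atoms, models = models, energies = energies,
                 provenance = provenance),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d model(s), %d residues (%d atoms)\n",
              length(x$models), length(unique(x$atoms$residue)), nrow(x$atoms)))
  if (!all(is.na(x$energies))) {
    cat(sprintf("  pseudo-energy range: %.2f .. %.2f\n",
                min(x$energies, na.rm = TRUE), max(x$energies, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble a \code{structure_ensemble}.
#' @export
n_models <- function(ensemble) length(ensemble$models)

# Row index of one atom; error (with the atom named) when unresolvable.
atom_row <- function(ensemble, residue, atom) {
  i <- which(ensemble$atoms$residue == residue & ensemble$atoms$atom == atom)
  if (length(i) != 1) {
    stop(sprintf("cannot resolve atom %s of residue %d in ensemble", atom, residue))
  }
  i
}

# Backbone-level proxy: side-chain carbons beyond CB are represented by the
# residue's CB (CA for glycine) in the desk-scale engine.  Distances to a
# proxied atom carry a pseudo-atom bound correction equal to the maximal
# extension of the true atom from its proxy (cf. NMR pseudo-atom
# corrections for unresolved protons).
proxy_correction <- function(atom) {
  if (atom %in% c("N", "H", "CA", "CB", "C", "O")) return(0)
  if (grepl("^CG", atom)) return(1.6)
  if (grepl("^CD", atom)) return(2.8)
  if (grepl("^CE", atom)) return(3.9)
  if (grepl("^CZ", atom)) return(4.4)
  if (grepl("^CH", atom)) return(4.9)
  2.5
}
proxy_atom_row <- function(atoms, residue, atom) {
  i <- which(atoms$residue == residue & atoms$atom == atom)
  if (length(i) == 1) return(i)
  if (grepl("^C", atom)) {
    i <- which(atoms$residue == residue & atoms$atom == "CB")
    if (length(i) == 1) return(i)
    i <- which(atoms$residue == residue & atoms$atom == "CA")
    if (length(i) == 1) return(i)
  }
  stop(sprintf("cannot resolve atom %s of residue %d in ensemble", atom, residue))
}

#' Sort models by pseudo-energy
#'
#' Stable, deterministic ordering: ties keep the original model order.
#'
#' @param ensemble a \code{structure_ensemble}.
#' @param n keep only the first \code{n} models after sorting (optional).
#' @export
sort_by_energy <- function(ensemble, n = NULL) {
  ord <- order(ensemble$energies)   # order() is stable
  if (!is.null(n)) ord <- ord[seq_len(min(n, length(ord)))]
  structure_ensemble(ensemble$atoms, ensemble$models[ord],
                     ensemble$energies[ord], ensemble$provenance)
}

#' Distance between two atoms in one model
#' @param ensemble a \code{structure_ensemble}.
#' @param model model index.
#' @param res_a,atom_a,res_b,atom_b atom addresses.
#' @export
atom_distance <- function(ensemble, model, res_a, atom_a, res_b, atom_b) {
  m <- ensemble$models[[model]]
  ia <- atom_row(ensemble, res_a, atom_a)
  ib <- atom_row(ensemble, res_b, atom_b)
  sqrt(sum((m[ia, ] - m[ib, ])^2))
}
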