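#' @title Readers and writers for the NMR pipeline formats
#' @description Tabular / NMR-STAR-subset shift lists, Sparky-style peak
#'   lists, TALOS-style torsion prediction tables, CNS-style .tbl restraint
#'   files and (multi-model) PDB coordinates.  All readers round-trip with
#'   the corresponding writers and never mutate their inputs.
#' @name io_nmr
NULL

AA_123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")
AA_321 <- stats::setNames(names(AA_123), AA_123)

normalize_atom <- function(atom) {
  a <- toupper(atom)
  a[a == "CO"] <- "C"
  a[a == "HN"] <- "H"
  a
}

#' Assigned chemical shift list
#'
#' @param entries data.frame with columns \code{residue} (integer),
#'   \code{type} (one-letter code), \code{atom}, \code{shift} (ppm).
#' @param deuterated flag marking the dedicated shift list of a
#'   perdeuterated, amide-back-exchanged sample.
#' @return object of class \code{shift_list} (a data.frame).
#' @export
shift_list <- function(entries, deuterated = FALSE) {
  stopifnot(is.data.frame(entries),
            all(c("residue", "type", "atom", "shift") %in% names(entries)))
  entries$atom <- normalize_atom(entries$atom)
  key <- paste(entries$residue, entries$atom)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, atom) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(!is.finite(entries$shift))) stop("non-finite chemical shift(s)")
  nbad <- entries$atom == "N" & (entries$shift < 90 | entries$shift > 140)
  hbad <- entries$atom == "H" & (entries$shift < 5 | entries$shift > 12)
  if (any(nbad)) warning(sum(nbad), " 15N shift(s) outside 90-140 ppm")
  if (any(hbad)) warning(sum(hbad), " amide 1H shift(s) outside 5-12 ppm")
  rownames(entries) <- NULL
  structure(entries, class = c("shift_list", "data.frame"),
            deuterated = deuterated)
}

#' Read a shift list
#'
#' @param path input file.
#' @param dialect \code{"tabular"} (whitespace columns residue type atom
#'   shift, \code{#} comments) or \code{"nmrstar"} (minimal subset: an
#'   \code{_Atom_chem_shift} loop).
#' @param deuterated passed through to \code{\link{shift_list}}.
#' @return a \code{shift_list}.
#' @export
load_shift_list <- function(path, dialect = c("tabular", "nmrstar"),
                            deuterated = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "tabular") {
    body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
    if (length(body) > 0 && grepl("residue", body[1], ignore.case = TRUE)) {
      body <- body[-1]
    }
    entries <- NULL
    for (k in seq_along(body)) {
      f <- strsplit(trimws(body[k]), "\\s+")[[1]]
      if (length(f) < 4) stop("malformed shift-list line ", k, ": ", body[k])
      shift <- suppressWarnings(as.numeric(f[4]))
      if (is.na(shift)) stop("malformed shift on line ", k, ": ", body[k])
      entries <- rbind(entries, data.frame(
        residue = as.integer(f[1]), type = toupper(f[2]), atom = f[3],
        shift = shift, stringsAsFactors = FALSE))
    }
    if (is.null(entries)) {
      entries <- data.frame(residue = integer(0), type = character(0),
                            atom = character(0), shift = numeric(0))
    }
    return(shift_list(entries, deuterated = deuterated))
  }
  # nmrstar subset: locate the _Atom_chem_shift loop
  tagpat <- "^\\s*_Atom_chem_shift\\."
  tagidx <- grep(tagpat, lines)
  if (length(tagidx) == 0) stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("\\s*$", "", sub(tagpat, "", lines[tagidx]))
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  pos <- match(need, tags)
  if (any(is.na(pos))) {
    stop("NMR-STAR loop lacks tag(s): ", paste(need[is.na(pos)], collapse = ", "))
  }
  body <- lines[(max(tagidx) + 1):length(lines)]
  entries <- NULL
  for (k in seq_along(body)) {
    ln <- trimws(body[k])
    if (ln == "" || startsWith(ln, "#")) next
    if (ln %in% c("stop_", "save_")) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < max(pos)) stop("malformed NMR-STAR row ", k, ": ", ln)
    comp <- toupper(f[pos[2]])
    ty <- if (comp %in% names(AA_321)) AA_321[[comp]] else comp
    shift <- suppressWarnings(as.numeric(f[pos[4]]))
    if (is.na(shift)) stop("malformed shift in NMR-STAR row ", k, ": ", ln)
    entries <- rbind(entries, data.frame(
      residue = as.integer(f[pos[1]]), type = ty, atom = f[pos[3]],
      shift = shift, stringsAsFactors = FALSE))
  }
  shift_list(entries, deuterated = deuterated)
}

#' Write a shift list (tabular dialect)
#' @param x a \code{shift_list}.
#' @param path output file.
#' @export
write_shift_list <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# residue type atom shift", con)
  for (k in seq_len(nrow(x))) {
    writeLines(sprintf("%d %s %s %.4f",
                       x$residue[k], x$type[k], x$atom[k], x$shift[k]), con)
  }
  invisible(path)
}

#' Spectrum definition
#'
#' Describes one experiment: dimension nuclei and roles (which residue of a
#' through-space transfer each dimension reports), matching tolerances, the
#' mixing class that sets distance-class defaults, and the sample.
#'
#' Supported types: \code{hnhh} (3D, dims N / H-indirect / H-direct with
#' roles origin / destination / origin), \code{hnhhnh} (the paired 3D, roles
#' destination / origin / destination) and \code{cc} (2D carbon-carbon).
#'
#' @param name spectrum label.
#' @param type \code{"hnhh"}, \code{"hnhhnh"} or \code{"cc"}.
#' @param tolerances ppm per dimension; defaults: 0.4 (15N), 0.1 (indirect
#'   1H), 0.7 (direct 1H) for the amide spectra; 0.4/0.4 for carbon.
#' @param mixing_class \code{rfdr_2ms}, \code{darr_short}, \code{darr_medium}
#'   or \code{darr_long}.
#' @param sample labeling scheme name or object associated with the sample.
#' @return object of class \code{spectrum_def}.
#' @export
spectrum_def <- function(name, type = c("hnhh", "hnhhnh", "cc"),
                         tolerances = NULL, mixing_class = NULL, sample = NULL) {
  type <- match.arg(type)
  if (type == "hnhh") {
    nuclei <- c("N", "H", "H"); roles <- c("origin", "destination", "origin")
    if (is.null(tolerances)) tolerances <- c(0.4, 0.1, 0.7)
    if (is.null(mixing_class)) mixing_class <- "rfdr_2ms"
  } else if (type == "hnhhnh") {
    nuclei <- c("N", "H", "H"); roles <- c("destination", "origin", "destination")
    if (is.null(tolerances)) tolerances <- c(0.4, 0.1, 0.7)
    if (is.null(mixing_class)) mixing_class <- "rfdr_2ms"
  } else {
    nuclei <- c("C", "C"); roles <- c("origin", "destination")
    if (is.null(tolerances)) tolerances <- c(0.4, 0.4)
    if (is.null(mixing_class)) mixing_class <- "darr_medium"
  }
  stopifnot(length(tolerances) == length(nuclei), all(tolerances > 0))
  mixing_class <- match.arg(mixing_class,
                            c("rfdr_2ms", "darr_short", "darr_medium", "darr_long"))
  structure(list(name = name, type = type, nuclei = nuclei, roles = roles,
                 tolerances = tolerances, mixing_class = mixing_class,
                 sample = sample),
            class = "spectrum_def")
}

#' Peak list bound to a spectrum definition
#'
#' @param spectrum a \code{\link{spectrum_def}}.
#' @param peaks data.frame with one position column per dimension
#'   (\code{w1}, \code{w2}, ...) plus \code{intensity}; an \code{id} column
#'   is added when absent.
#' @return object of class \code{peak_list}.
#' @export
peak_list <- function(spectrum, peaks) {
  stopifnot(inherits(spectrum, "spectrum_def"), is.data.frame(peaks))
  ndim <- length(spectrum$nuclei)
  wcols <- paste0("w", seq_len(ndim))
  if (!all(wcols %in% names(peaks))) {
    stop(sprintf("peak table needs %d position column(s) (%s) for spectrum '%s'",
                 ndim, paste(wcols, collapse = ", "), spectrum$name))
  }
  if (!"intensity" %in% names(peaks)) stop("peak table lacks an intensity column")
  if (nrow(peaks) > 0 && any(!is.finite(as.matrix(peaks[, c(wcols, "intensity")])))) {
    stop("non-finite peak position or intensity")
  }
  if (!"id" %in% names(peaks)) {
    peaks$id <- if (nrow(peaks) > 0) seq_len(nrow(peaks)) else integer(0)
  }
  rownames(peaks) <- NULL
  structure(list(spectrum = spectrum, peaks = peaks[, c(wcols, "intensity", "id")]),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s' (%s): %d peaks, %dD\n", x$spectrum$name,
              x$spectrum$type, nrow(x$peaks), length(x$spectrum$nuclei)))
  invisible(x)
}

#' Read a Sparky-style peak list
#'
#' Whitespace table with one position column per dimension plus an
#' intensity column; a leading non-numeric assignment column and a Sparky
#' header line are tolerated.
#'
#' @param path input file.
#' @param spectrum a \code{\link{spectrum_def}}; the file's column count
#'   must match its dimensionality.
#' @return a \code{peak_list}.
#' @export
load_peak_list <- function(path, spectrum) {
  stopifnot(inherits(spectrum, "spectrum_def"))
  ndim <- length(spectrum$nuclei)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  if (length(lines) > 0 && grepl("w1|Assignment|Height", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), ndim + 1), c(paste0("w", seq_len(ndim)), "intensity")))
    return(peak_list(spectrum, empty))
  }
  rows <- NULL
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (suppressWarnings(is.na(as.numeric(f[1])))) f <- f[-1]  # assignment label
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != ndim + 1 || any(is.na(v))) {
      stop(sprintf("peak line %d has %d numeric column(s); spectrum '%s' needs %d positions + intensity",
                   k, sum(!is.na(v)), spectrum$name, ndim))
    }
    rows <- rbind(rows, v)
  }
  pk <- as.data.frame(rows)
  names(pk) <- c(paste0("w", seq_len(ndim)), "intensity")
  rownames(pk) <- NULL
  peak_list(spectrum, pk)
}

#' Write a peak list (Sparky-style)
#' @param x a \code{peak_list}.
#' @param path output file.
#' @export
write_peak_list <- function(x, path) {
  ndim <- length(x$spectrum$nuclei)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c(paste0("w", seq_len(ndim)), "intensity"), collapse = " "), con)
  for (k in seq_len(nrow(x$peaks))) {
    writeLines(paste(c(sprintf("%.4f", as.numeric(x$peaks[k, seq_len(ndim)])),
                       sprintf("%.6g", x$peaks$intensity[k])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a TALOS-style torsion prediction table
#'
#' Accepts the VARS/FORMAT header convention or a plain whitespace table
#' with columns RESID RESNAME PHI PSI DPHI DPSI and CLASS (extra columns
#' ignored).
#'
#' @param path input file.
#' @return data.frame residue, type, phi, psi, dphi, dpsi, class.
#' @export
read_talos <- function(path) {
  lines <- readLines(path)
  vars <- grep("^\\s*VARS\\b", lines, value = TRUE)
  cols <- c("RESID", "RESNAME", "PHI", "PSI", "DPHI", "DPSI", "CLASS")
  if (length(vars) > 0) {
    cols_all <- strsplit(trimws(sub("^\\s*VARS\\s+", "", vars[1])), "\\s+")[[1]]
  } else {
    header <- grep("RESID", lines, value = TRUE)
    cols_all <- if (length(header) > 0)
      strsplit(trimws(header[1]), "\\s+")[[1]] else cols
  }
  pos <- match(cols, toupper(cols_all))
  if (any(is.na(pos))) {
    stop("TALOS table lacks column(s): ", paste(cols[is.na(pos)], collapse = ", "))
  }
  body <- grep("^\\s*(VARS|FORMAT|DATA|REMARK|#|$)|RESID", lines, invert = TRUE,
               value = TRUE)
  out <- NULL
  for (k in seq_along(body)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(f) < max(pos, na.rm = TRUE)) {
      stop("malformed TALOS row ", k, ": ", body[k])
    }
    num <- suppressWarnings(as.numeric(f[pos[3:6]]))
    if (any(is.na(num))) stop("malformed TALOS row ", k, ": ", body[k])
    ty <- toupper(f[pos[2]])
    if (ty %in% names(AA_321)) ty <- AA_321[[ty]]
    out <- rbind(out, data.frame(residue = as.integer(f[pos[1]]), type = ty,
                                 phi = num[1], psi = num[2], dphi = num[3],
                                 dpsi = num[4], class = f[pos[7]],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(residue = integer(0), type = character(0), phi = numeric(0),
                      psi = numeric(0), dphi = numeric(0), dpsi = numeric(0),
                      class = character(0))
  }
  out
}

#' Write a TALOS-style table (fixture helper)
#' @param tab data.frame as returned by \code{\link{read_talos}}.
#' @param path output file.
#' @export
write_talos <- function(tab, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("VARS RESID RESNAME PHI PSI DPHI DPSI CLASS", con)
  writeLines("FORMAT %4d %s %8.3f %8.3f %8.3f %8.3f %s", con)
  for (k in seq_len(nrow(tab))) {
    writeLines(sprintf("%4d %s %8.3f %8.3f %8.3f %8.3f %s",
                       tab$residue[k], tab$type[k], tab$phi[k], tab$psi[k],
                       tab$dphi[k], tab$dpsi[k], tab$class[k]), con)
  }
  invisible(path)
}

#' Write ambiguous distance restraints
#'
#' \code{cns_tbl} emits one \code{assign} statement per restraint with
#' OR-continuation records for additional assignment options; the bounds
#' are encoded as \code{d dminus dplus} with \code{d = upper},
#' \code{dminus = upper - lower}, \code{dplus = 0}, which preserves
#' asymmetric distance classes exactly.  \code{tabular} emits one row per
#' option.
#'
#' @param adrs list of \code{adr} objects.
#' @param path output file.
#' @param dialect \code{"cns_tbl"} or \code{"tabular"}.
#' @export
write_restraints <- function(adrs, path, dialect = c("cns_tbl", "tabular")) {
  dialect <- match.arg(dialect)
  for (k in seq_along(adrs)) {
    if (nrow(adrs[[k]]$options) == 0) {
      stop("restraint ", k, " has an empty assignment option set")
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "cns_tbl") {
    for (k in seq_along(adrs)) {
      a <- adrs[[k]]
      op <- a$options
      writeLines(sprintf(
        "assign (resid %d and name %s) (resid %d and name %s) %.2f %.2f %.2f ! id %d peak %s spectrum %s%s",
        op$res_a[1], op$atom_a[1], op$res_b[1], op$atom_b[1],
        a$upper, a$upper - a$lower, 0,
        k, paste(a$peak_id, collapse = ","),
        if (is.null(a$spectrum)) "-" else a$spectrum,
        if (isTRUE(a$active)) "" else " inactive"), con)
      if (nrow(op) > 1) {
        for (j in 2:nrow(op)) {
          writeLines(sprintf("  or (resid %d and name %s) (resid %d and name %s)",
                             op$res_a[j], op$atom_a[j], op$res_b[j], op$atom_b[j]),
                     con)
        }
      }
    }
  } else {
    writeLines("# restraint lower upper res_a atom_a res_b atom_b product support peak spectrum active", con)
    for (k in seq_along(adrs)) {
      a <- adrs[[k]]
      for (j in seq_len(nrow(a$options))) {
        op <- a$options[j, ]
        writeLines(sprintf("%d %.2f %.2f %d %s %d %s %.4f %d %s %s %d",
                           k, a$lower, a$upper, op$res_a, op$atom_a, op$res_b,
                           op$atom_b, op$product, op$support,
                           paste(a$peak_id, collapse = ","),
                           if (is.null(a$spectrum)) "-" else a$spectrum,
                           as.integer(isTRUE(a$active))), con)
      }
    }
  }
  invisible(path)
}

#' Read restraints written by \code{\link{write_restraints}}
#' @param path input file.
#' @param dialect \code{"cns_tbl"} or \code{"tabular"}.
#' @return list of \code{adr} objects.
#' @export
read_restraints <- function(path, dialect = c("cns_tbl", "tabular")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  out <- list()
  if (dialect == "cns_tbl") {
    sel <- "\\(resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+)\\s*\\)"
    cur <- NULL
    flush <- function() if (!is.null(cur)) out[[length(out) + 1]] <<- do.call(adr, cur)
    for (ln in lines) {
      ln2 <- trimws(ln)
      if (startsWith(ln2, "assign")) {
        flush()
        m <- regmatches(ln2, gregexpr(sel, ln2))[[1]]
        if (length(m) != 2) stop("cannot parse assign statement: ", ln2)
        p <- function(s) {
          g <- regmatches(s, regexec(sel, s))[[1]]
          list(res = as.integer(g[2]), atom = g[3])
        }
        a1 <- p(m[1]); a2 <- p(m[2])
        nums <- regmatches(ln2, regexec(
          "\\)\\s+([0-9.]+)\\s+([0-9.]+)\\s+([0-9.]+)\\s*(!.*)?$", ln2))[[1]]
        d <- as.numeric(nums[2]); dminus <- as.numeric(nums[3])
        pk <- regmatches(ln2, regexec("peak\\s+(\\S+)", ln2))[[1]]
        sp <- regmatches(ln2, regexec("spectrum\\s+(\\S+)", ln2))[[1]]
        cur <- list(options = data.frame(res_a = a1$res, atom_a = a1$atom,
                                         res_b = a2$res, atom_b = a2$atom,
                                         product = NA_real_, support = NA_integer_,
                                         stringsAsFactors = FALSE),
                    lower = d - dminus, upper = d,
                    peak_id = if (length(pk) > 1 && pk[2] != "-")
                      as.integer(strsplit(pk[2], ",")[[1]]) else integer(0),
                    spectrum = if (length(sp) > 1 && sp[2] != "-") sp[2] else NULL,
                    active = !grepl("inactive", ln2))
      } else if (startsWith(ln2, "or")) {
        m <- regmatches(ln2, gregexpr(sel, ln2))[[1]]
        if (length(m) != 2) stop("cannot parse OR record: ", ln2)
        p <- function(s) {
          g <- regmatches(s, regexec(sel, s))[[1]]
          list(res = as.integer(g[2]), atom = g[3])
        }
        a1 <- p(m[1]); a2 <- p(m[2])
        cur$options <- rbind(cur$options, data.frame(
          res_a = a1$res, atom_a = a1$atom, res_b = a2$res, atom_b = a2$atom,
          product = NA_real_, support = NA_integer_, stringsAsFactors = FALSE))
      }
    }
    flush()
  } else {
    body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
    rows <- lapply(body, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
    ids <- vapply(rows, function(f) as.integer(f[1]), integer(1))
    for (id in unique(ids)) {
      rr <- rows[ids == id]
      f1 <- rr[[1]]
      op <- do.call(rbind, lapply(rr, function(f) data.frame(
        res_a = as.integer(f[4]), atom_a = f[5], res_b = as.integer(f[6]),
        atom_b = f[7], product = as.numeric(f[8]),
        support = suppressWarnings(as.integer(f[9])), stringsAsFactors = FALSE)))
      out[[length(out) + 1]] <- adr(
        options = op, lower = as.numeric(f1[2]), upper = as.numeric(f1[3]),
        peak_id = if (f1[10] != "-") as.integer(strsplit(f1[10], ",")[[1]]) else integer(0),
        spectrum = if (f1[11] != "-") f1[11] else NULL,
        active = f1[12] == "1")
    }
  }
  out
}

#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Backbone atoms N, H, CA, CB, C, O are kept, indexed by residue.  When a
#' model lacks amide protons they are reconstructed from N, CA and the
#' preceding carbonyl (N-H 1.02 A, opposed to the C/CA bisector) and the
#' ensemble is flagged via attribute \code{h_reconstructed}.
#'
#' @param path PDB file.
#' @param chain restrict to one chain id (default: first chain present).
#' @return a \code{\link{structure_ensemble}}.
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop("chain ", chain, " not present in ", path)
    sel <- at$chain == chain
  } else {
    sel <- at$chain == at$chain[1]
  }
  keep <- sel & at$elety %in% c("N", "H", "HN", "CA", "CB", "C", "O")
  if (!any(keep)) stop("no backbone atoms found in ", path)
  nmodels <- nrow(pdb$xyz)
  if (is.null(nmodels) || nmodels == 0) stop("no models in ", path)
  idx <- which(keep)
  atoms <- data.frame(residue = at$resno[idx],
                      type = unname(AA_321[at$resid[idx]]),
                      atom = normalize_atom(at$elety[idx]),
                      stringsAsFactors = FALSE)
  atoms$type[is.na(atoms$type)] <- "X"
  models <- lapply(seq_len(nmodels), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    xyz[idx, , drop = FALSE]
  })
  h_flag <- FALSE
  if (!any(atoms$atom == "H")) {
    rebuilt <- reconstruct_amide_h(atoms, models)
    atoms <- rebuilt$atoms; models <- rebuilt$models; h_flag <- TRUE
  }
  ens <- structure_ensemble(atoms, models,
                            provenance = list(source = path))
  attr(ens, "h_reconstructed") <- h_flag
  ens
}

reconstruct_amide_h <- function(atoms, models) {
  resn <- sort(unique(atoms$residue))
  new_atoms <- atoms
  add <- NULL
  for (r in resn[-1]) {
    if (!any(atoms$residue == r & atoms$atom == "N")) next
    prev <- r - 1
    if (!any(atoms$residue == prev & atoms$atom == "C")) next
    ty <- atoms$type[atoms$residue == r][1]
    if (ty == "P") next
    add <- rbind(add, data.frame(residue = r, type = ty, atom = "H",
                                 stringsAsFactors = FALSE))
  }
  if (is.null(add)) return(list(atoms = atoms, models = models))
  new_atoms <- rbind(atoms, add)
  ord <- order(new_atoms$residue,
               match(new_atoms$atom, c("N", "H", "CA", "CB", "C", "O")))
  new_models <- lapply(models, function(m) {
    hpos <- matrix(NA_real_, nrow(add), 3)
    for (k in seq_len(nrow(add))) {
      r <- add$residue[k]
      iN <- which(atoms$residue == r & atoms$atom == "N")[1]
      iCA <- which(atoms$residue == r & atoms$atom == "CA")[1]
      iC <- which(atoms$residue == r - 1 & atoms$atom == "C")[1]
      dirH <- -unitv(unitv(m[iCA, ] - m[iN, ]) + unitv(m[iC, ] - m[iN, ]))
      hpos[k, ] <- m[iN, ] + 1.02 * dirH
    }
    rbind(m, hpos)[ord, , drop = FALSE]
  })
  list(atoms = new_atoms[ord, ], models = new_models)
}

#' Write a structure ensemble as a (multi-model) PDB file
#' @param ensemble a \code{\link{structure_ensemble}}.
#' @param path output file.
#' @export
write_structure <- function(ensemble, path) {
  at <- ensemble$atoms
  xyz <- do.call(rbind, lapply(ensemble$models, function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residue,
                   resid = unname(AA_123[at$type]),
                   elety = at$atom,
                   chain = rep("A", nrow(at)))
  invisible(path)
}
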