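# Shared fixtures, built in code at test time.

# a small assigned shift list: three residues with full amide + carbon sets
small_shifts <- function() {
  shift_list(data.frame(
    residue = c(75, 75, 75, 75, 87, 87, 87, 87, 88, 88, 88, 88),
    type    = c("Y", "Y", "Y", "Y", "L", "L", "L", "L", "A", "A", "A", "A"),
    atom    = c("N", "H", "CA", "CB", "N", "H", "CA", "CB", "N", "H", "CA", "CB"),
    shift   = c(115.4, 8.25, 57.9, 38.8, 121.3, 9.20, 55.1, 42.3, 123.9, 8.61, 52.5, 19.1),
    stringsAsFactors = FALSE), deuterated = TRUE)
}

# one 3D peak at given positions bound to a spectrum definition
one_peak <- function(def, w, intensity = 100) {
  peak_list(def, as.data.frame(as.list(stats::setNames(
    c(w, intensity), c(paste0("w", seq_along(w)), "intensity")))))
}

adr1 <- function(res_a, res_b, lower = 1, upper = 5.5, atom = "H",
                 support = NA_integer_, intensity = NA_real_, source = "h") {
  adr(options = data.frame(res_a = res_a, atom_a = atom, res_b = res_b,
                           atom_b = atom, product = NA_real_,
                           support = support, stringsAsFactors = FALSE),
      lower = lower, upper = upper, intensity = intensity, source = source)
}

# two-residue atom table for refiner toys
toy_atoms <- function(n = 2) {
  data.frame(residue = rep(seq_len(n), each = 6), type = "A",
             atom = rep(c("N", "H", "CA", "CB", "C", "O"), n),
             stringsAsFactors = FALSE)
}
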