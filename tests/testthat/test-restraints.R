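test_that("amide matching applies per-dimension tolerances inclusively and drops autocorrelation", {
  sl <- small_shifts()
  def <- spectrum_def("hnhh", "hnhh")   # roles: N origin, H_ind destination, H_dir origin
  # peak consistent with origin 75, destination 87:
  # dN = 0.2 <= 0.4, dH_ind = |9.20-9.26| = 0.06 <= 0.1, dH_dir = |8.25-8.43| <= 0.7
  pk <- one_peak(def, c(115.6, 9.26, 8.43))
  adrs <- match_peaks_h(pk, sl)
  expect_length(adrs, 1)
  expect_equal(adrs[[1]]$options$res_a, 75)
  expect_equal(adrs[[1]]$options$res_b, 87)
  # boundary inclusive: dN exactly 0.4
  pk2 <- one_peak(def, c(115.8, 9.20, 8.25))
  expect_equal(match_peaks_h(pk2, sl)[[1]]$options$res_a, 75)
  # peak matching only residue 75 in both H dimensions: on the diagonal -> excluded
  pk3 <- one_peak(def, c(115.4, 8.25, 8.25))
  res3 <- match_peaks_h(pk3, sl)
  expect_length(res3, 0)
  expect_equal(attr(res3, "autocorrelation"), 1L)
  # peak matching nothing -> warning, no restraint
  pk4 <- one_peak(def, c(100.0, 6.0, 7.5))
  expect_warning(res4 <- match_peaks_h(pk4, sl), "excluded")
  expect_length(res4, 0)
  expect_equal(attr(res4, "unassigned"), 1L)
  # empty shift list errors
  empty <- shift_list(data.frame(residue = integer(0), type = character(0),
                                 atom = character(0), shift = numeric(0)))
  expect_error(match_peaks_h(pk, empty), "empty shift list")
})

test_that("support counting finds up to four (spectrum x direction) slots", {
  sl <- small_shifts()
  d1 <- spectrum_def("hnhh", "hnhh")
  d2 <- spectrum_def("hnhhnh", "hnhhnh")
  # all four peaks of the 75-87 pair at exact positions
  pos <- function(def, i, j) adriter:::peak_position_h(def, sl, i, j)
  p1 <- peak_list(d1, data.frame(rbind(c(pos(d1, 75, 87), 10), c(pos(d1, 87, 75), 9)),
                                 row.names = NULL) |> stats::setNames(c("w1", "w2", "w3", "intensity")))
  p2 <- peak_list(d2, data.frame(rbind(c(pos(d2, 75, 87), 8), c(pos(d2, 87, 75), 7)),
                                 row.names = NULL) |> stats::setNames(c("w1", "w2", "w3", "intensity")))
  a <- match_peaks_h(p1, sl)
  a <- count_support(a, list(p1, p2), sl)
  sup <- a[[1]]$options$support[a[[1]]$options$res_a == 75 |
                                  a[[1]]$options$res_b == 75]
  expect_equal(max(sup), 4)
  # with only one spectrum available the same option supports at most 2
  a2 <- count_support(match_peaks_h(p1, sl), list(p1), sl)
  expect_lte(max(a2[[1]]$options$support), 2)
})

test_that("the redundancy rule keeps and drops exactly per the 4- and 3-support cases", {
  mk <- function(supports) {
    a <- adr(options = data.frame(res_a = seq_along(supports), atom_a = "H",
                                  res_b = 100 + seq_along(supports), atom_b = "H",
                                  product = NA, support = supports),
             lower = 1, upper = 5.5)
    redundancy_filter(list(a))[[1]]$options$support
  }
  expect_equal(mk(c(4, 2, 1)), 4)          # 4-rule removes 1s and 2s
  expect_equal(mk(c(3, 1, 2)), c(3, 2))    # 3-rule removes only 1s
  expect_equal(mk(c(2, 2)), c(2, 2))       # no rule fires
  expect_equal(mk(c(4, 3, 2, 1)), c(4, 3))
  expect_error(redundancy_filter(list(adr1(1, 2))), "support counts missing")
})

test_that("redundancy filtering never removes the best-supported option (all patterns up to 4 options)", {
  grids <- list()
  for (n in 1:4) grids <- c(grids, asplit(as.matrix(
    expand.grid(rep(list(1:4), n))), 1))
  for (sup in grids) {
    a <- adr(options = data.frame(res_a = seq_along(sup), atom_a = "H",
                                  res_b = 100 + seq_along(sup), atom_b = "H",
                                  product = NA, support = as.integer(sup)),
             lower = 1, upper = 5.5)
    out <- redundancy_filter(list(a))[[1]]
    expect_true(max(sup) %in% out$options$support)
    expect_true(out$active)
  }
})

test_that("intensity classification splits at the strongest sequentially-assignable peak", {
  # threshold peak: intensity 5.0 with a sequential option (87-88)
  mk <- function(int, res_b) {
    adr(options = data.frame(res_a = 87, atom_a = "H", res_b = res_b,
                             atom_b = "H", product = NA, support = NA),
        lower = 1, upper = 5.5, intensity = int)
  }
  adrs <- list(mk(9.0, 75), mk(5.0, 88), mk(4.0, 75), mk(5.0, 75))
  out <- classify_h_bounds(adrs)
  expect_equal(vapply(out, function(a) a$upper, numeric(1)),
               c(3.5, 5.5, 5.5, 5.5))   # strictly stronger -> narrow class
  expect_true(all(vapply(out, function(a) a$lower, numeric(1)) == 1.0))
  # bounds never leave the two classes
  expect_true(all(vapply(out, function(a) a$upper, numeric(1)) %in% c(3.5, 5.5)))
  # no sequential peak at all -> conservative wide class with warning
  expect_warning(out2 <- classify_h_bounds(list(mk(9, 75), mk(2, 75))),
                 "no sequential")
  expect_true(all(vapply(out2, function(a) a$upper, numeric(1)) == 5.5))
  expect_equal(classify_h_bounds(list()), list())
})

test_that("carbon matching excludes intra-residue options and applies the labeling filter", {
  sl <- small_shifts()
  scheme <- build_labeling_scheme("uniform")
  def <- spectrum_def("darr", "cc")
  # peak at (CA 55.1 [L87], CB 42.3 [L87]) + (CA 55.1 close to nothing else):
  # the only candidate pair is intra-residue -> no ADR
  pk <- one_peak(def, c(55.1, 42.3))
  res <- match_peaks_c(pk, sl, scheme)
  expect_length(res, 0)
  expect_equal(attr(res, "unassigned"), 1L)
  # inter-residue candidates survive
  pk2 <- one_peak(def, c(55.1, 19.1))    # L87 CA x A88 CB
  res2 <- match_peaks_c(pk2, sl, scheme)
  expect_length(res2, 1)
  expect_equal(res2[[1]]$lower, 1.5)
  expect_equal(res2[[1]]$upper, 8.0)
  # labeling filter: scheme labeling only L -> the A88 option is dropped
  schL <- build_labeling_scheme("forward", residues = "L")
  res3 <- match_peaks_c(pk2, sl, schL)
  expect_length(res3, 0)
  # two-class mode by mixing time
  defl <- spectrum_def("darr400", "cc", mixing_class = "darr_long")
  res4 <- match_peaks_c(one_peak(defl, c(55.1, 19.1)), sl, scheme,
                        class_mode = "by_mixing")
  expect_equal(res4[[1]]$upper, 7.0)
  res5 <- match_peaks_c(pk2, sl, scheme, class_mode = "by_mixing")
  expect_equal(res5[[1]]$upper, 5.5)
  expect_error(match_peaks_c(pk2, sl, NULL), "labeling scheme")
})

test_that("short-mixing comparison and the aliphatic region filter peaks", {
  def <- spectrum_def("darr", "cc")
  long <- peak_list(def, data.frame(w1 = c(55.2, 30.0, 175.1),
                                    w2 = c(24.8, 40.0, 55.0),
                                    intensity = c(5, 4, 9)))
  short <- one_peak(def, c(55.0, 24.9))
  out <- exclude_intra_and_region(long, short)
  # peak 1 removed (short-mix counterpart within 0.4/0.4), peak 3 outside region
  expect_equal(nrow(out$peaks), 1)
  expect_equal(out$peaks$w1, 30.0)
  # without a short-mix list only the region filter applies
  out2 <- exclude_intra_and_region(long)
  expect_equal(nrow(out2$peaks), 2)
})

test_that("hydrogen-bond emission gates couples and emits fixed-bound pairs", {
  couples <- data.frame(res_i = c(75, 75, 10), res_j = c(87, 88, 20))
  support <- data.frame(res_i = c(75, 75, 10), res_j = c(87, 88, 20),
                        support = c(4, 3, 4))
  beta <- c(75, 87, 88, 20)   # residue 10 not beta
  hb <- emit_hbond_restraints(couples, beta, support)
  # only (75, 87) passes both gates -> exactly two records
  expect_equal(nrow(hb), 2)
  expect_equal(hb$kind, c("H_O", "N_O"))
  expect_equal(hb$lower, c(1.73, 2.52))
  expect_equal(hb$upper, c(2.70, 3.93))
  rej <- attr(hb, "rejected")
  expect_equal(nrow(rej), 2)
  expect_true("incomplete cross-peak pattern" %in% rej$reason)
  expect_error(emit_hbond_restraints(rbind(couples, couples[1, ]), beta, support),
               "duplicate")
})

test_that("92 qualifying couples yield 184 hydrogen-bond restraints", {
  couples <- data.frame(res_i = 1:92, res_j = 101:192)
  support <- data.frame(res_i = 1:92, res_j = 101:192, support = 4L)
  hb <- emit_hbond_restraints(couples, beta_residues = c(1:92, 101:192), support)
  expect_equal(nrow(hb), 184)
})

test_that("torsion emission uses only reliable rows, two restraints each", {
  tab <- data.frame(residue = 1:5, type = "VAL",
                    phi = -139, psi = 135, dphi = 12, dpsi = 14,
                    class = c("Good", "Good", "Ambig", "Dyn", "Good"))
  tors <- emit_torsion_restraints(tab)
  expect_equal(nrow(tors), 6)
  expect_setequal(unique(tors$angle), c("phi", "psi"))
  expect_equal(tors$center[tors$angle == "phi"], rep(-139, 3))
  expect_equal(nrow(emit_torsion_restraints(tab[0, ])), 0)
})

test_that("every pipeline ADR is inter-residue and labeling-consistent", {
  spec <- sheet_spec(4, 6, barrel = FALSE, seed = 2)
  study <- synthetic_study(spec, seed = 2,
                           schemes = c("gavls_w", "glycerol_2"))
  for (a in c(study$h_adrs, study$c_adrs)) {
    expect_true(all(a$options$res_a != a$options$res_b))
    cidx <- grepl("^C", a$options$atom_a)
    if (any(cidx)) expect_true(all(a$options$product[cidx] > 0.10))
  }
})
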