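test_that("the ideal antiparallel sheet reproduces the canonical HN-HN geometry", {
  spec <- sheet_spec(2, 6, seed = 1)
  tr <- build_ideal_sheet(spec)
  reg <- attr(tr, "registry")
  nar <- reg[reg$narrow, ]
  expect_gt(nrow(nar), 0)
  facing <- mapply(function(i, j) atom_distance(tr, 1, i, "H", j, "H"),
                   nar$res_i, nar$res_j)
  # hydrogen-bonded facing amide protons at ~3.3 A (+-0.2)
  expect_true(all(abs(facing - 3.3) < 0.2))
  # sequential amide protons at ~4.3 A within a strand
  seqd <- sapply(2:5, function(i) atom_distance(tr, 1, i, "H", i + 1, "H"))
  expect_true(all(abs(seqd - 4.3) < 0.2))
  # hydrogen-bond geometry of the registry is canonical
  hb <- mapply(function(i, j) atom_distance(tr, 1, i, "H", j, "O"),
               nar$res_i, nar$res_j)
  expect_true(all(hb > 1.7 & hb < 2.2))
})

test_that("a single strand has sequential but no cross-strand contacts", {
  tr <- build_ideal_sheet(sheet_spec(1, 8, seed = 1))
  tc <- true_hn_contacts(tr, 4.6)
  expect_true(all(abs(tc$res_i - tc$res_j) == 1))
})

test_that("barrel mode closes strand n against strand 1 with sound geometry", {
  spec <- sheet_spec(8, 8, barrel = TRUE, seed = 7)
  tr <- build_ideal_sheet(spec)
  reg <- attr(tr, "registry")
  # registry includes the seam (strands 8 and 1)
  s8 <- spec$strands[[8]]; s1 <- spec$strands[[1]]
  seam <- reg[reg$res_i %in% s8 & reg$res_j %in% s1, ]
  expect_gt(nrow(seam), 0)
  nar <- seam[seam$narrow, ]
  d <- mapply(function(i, j) atom_distance(tr, 1, i, "H", j, "H"),
              nar$res_i, nar$res_j)
  expect_true(all(d < 4.5))
  # regularized barrel keeps near-ideal covalent geometry
  at <- tr$atoms; m <- tr$models[[1]]
  bl <- sapply(unlist(spec$strands), function(r) {
    sqrt(sum((m[which(at$residue == r & at$atom == "N"), ] -
                m[which(at$residue == r & at$atom == "CA"), ])^2))
  })
  expect_true(all(abs(bl - 1.458) < 0.05))
  # infeasible radius errors
  expect_error(build_ideal_sheet(sheet_spec(8, 8, barrel = TRUE, radius = 3,
                                            seed = 7)),
               "infeasible")
})

test_that("simulated shifts are deterministic, omit disordered residues, and look like amide shifts", {
  spec <- sheet_spec(3, 6, seed = 4)
  tr <- build_ideal_sheet(spec)
  s1 <- simulate_shifts(tr, seed = 11)
  s2 <- simulate_shifts(tr, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_shifts(tr, seed = 12)
  expect_false(identical(s1$shift, s3$shift))
  # loop (disorder) residues carry no shifts
  loopres <- unlist(lapply(spec$loops, function(r) r[1]:r[2]))
  expect_false(any(s1$residue %in% loopres))
  # amide 1H in the 5-12 ppm window
  h <- s1$shift[s1$atom == "H"]
  expect_true(all(h > 5 & h < 12))
})

test_that("disorder ranges remove exactly the requested residues", {
  spec <- sheet_spec(2, 8, disorder = list(c(3, 7)), seed = 4)
  tr <- build_ideal_sheet(spec)
  sl <- simulate_shifts(tr, seed = 1)
  expect_false(any(sl$residue %in% 3:7))
  expect_true(all(c(1, 2, 8) %in% sl$residue))
})

test_that("a visible amide pair yields four cross peaks across the paired spectra", {
  spec <- sheet_spec(2, 6, loop_length = 0, seed = 2)
  tr <- build_ideal_sheet(spec)
  sh <- simulate_shifts(tr, seed = 2)
  cfg <- peak_sim_config(noise_sd = 0, seed = 2)
  d1 <- spectrum_def("hnhh", "hnhh")
  d2 <- spectrum_def("hnhhnh", "hnhhnh")
  p1 <- simulate_peaks(tr, sh, d1, cfg)
  p2 <- simulate_peaks(tr, sh, d2, cfg)
  reg <- attr(tr, "registry"); nar <- reg[reg$narrow, ][1, ]
  hits <- 0
  for (pl in list(p1, p2)) for (dir in 1:2) {
    i <- if (dir == 1) nar$res_i else nar$res_j
    j <- if (dir == 1) nar$res_j else nar$res_i
    pos <- adriter:::peak_position_h(pl$spectrum, sh, i, j)
    hit <- any(abs(pl$peaks$w1 - pos[1]) < 1e-6 &
                 abs(pl$peaks$w2 - pos[2]) < 1e-6 &
                 abs(pl$peaks$w3 - pos[3]) < 1e-6)
    hits <- hits + hit
  }
  expect_equal(hits, 4)
  # intensity follows r^-6: the ~3.3 A facing peak beats the ~4.3 A sequential peak
  pos_face <- adriter:::peak_position_h(d1, sh, nar$res_i, nar$res_j)
  i_face <- p1$peaks$intensity[abs(p1$peaks$w1 - pos_face[1]) < 1e-6 &
                                 abs(p1$peaks$w2 - pos_face[2]) < 1e-6][1]
  r <- nar$res_i
  pos_seq <- adriter:::peak_position_h(d1, sh, r, r + 1)
  i_seq <- p1$peaks$intensity[abs(p1$peaks$w1 - pos_seq[1]) < 1e-6 &
                                abs(p1$peaks$w2 - pos_seq[2]) < 1e-6][1]
  expect_gt(i_face, i_seq)
  # pair beyond the cutoff produces no peak
  far <- c(spec$strands[[1]][1], spec$strands[[2]][1])
  dfar <- atom_distance(tr, 1, far[1], "H", far[2], "H")
  if (dfar > 4.6) {
    pos_far <- adriter:::peak_position_h(d1, sh, far[1], far[2])
    expect_false(any(abs(p1$peaks$w1 - pos_far[1]) < 1e-6 &
                       abs(p1$peaks$w2 - pos_far[2]) < 1e-6 &
                       abs(p1$peaks$w3 - pos_far[3]) < 1e-6))
  }
  # generator outputs are bit-reproducible per seed
  expect_identical(simulate_peaks(tr, sh, d1, cfg), p1)
})

test_that("noise-free matching recovers the true pair for >= 95% of emitted contacts", {
  spec <- sheet_spec(8, 8, barrel = TRUE, seed = 5)
  study <- synthetic_study(spec, seed = 5, schemes = character(0))
  tc <- true_hn_contacts(study$truth, 4.6, study$shifts)
  key <- paste(tc$res_i, tc$res_j)
  allopts <- unique(do.call(rbind, lapply(study$h_adrs, function(a)
    data.frame(i = pmin(a$options$res_a, a$options$res_b),
               j = pmax(a$options$res_a, a$options$res_b)))))
  expect_gte(mean(key %in% paste(allopts$i, allopts$j)), 0.95)
  # and every ADR contains a true contact among its options
  rec <- vapply(study$h_adrs, function(a)
    any(paste(pmin(a$options$res_a, a$options$res_b),
              pmax(a$options$res_a, a$options$res_b)) %in% key), logical(1))
  expect_gte(mean(rec), 0.95)
})

test_that("injected shift overlap strictly increases mean ambiguity", {
  spec <- sheet_spec(6, 8, barrel = TRUE, seed = 9)
  tr <- build_ideal_sheet(spec)
  cfg <- peak_sim_config(seed = 9)
  amb <- sapply(c(0, 6), function(ov) {
    sh <- simulate_shifts(tr, seed = 9, overlap_injection = ov)
    p1 <- simulate_peaks(tr, sh, spectrum_def("hnhh", "hnhh"), cfg)
    a <- suppressWarnings(match_peaks_h(p1, sh))
    mean(vapply(a, function(z) nrow(z$options), numeric(1)))
  })
  expect_gt(amb[2], amb[1])
})
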