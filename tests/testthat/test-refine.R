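test_that("analytic gradients match numerical differentiation", {
  atoms <- toy_atoms(2)
  r <- adr1(1, 2, lower = 3.0, upper = 3.5)
  tors <- data.frame(residue = 1, angle = "psi", center = 135, half_width = 5)
  sys <- adriter:::build_system_list(atoms, list(r), tors, anneal_config())
  set.seed(1)
  x <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
  g <- adriter:::.cpp_gradient(x, sys)
  num <- matrix(0, nrow(x), 3); h <- 1e-6
  for (i in seq_len(nrow(x))) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num[i, d] <- (adriter:::.cpp_energy(xp, sys)$total -
                    adriter:::.cpp_energy(xm, sys)$total) / (2 * h)
  }
  expect_lt(max(abs(g - num)), 1e-4)
})

test_that("a single amide-amide restraint is satisfied by the annealed toy", {
  atoms <- toy_atoms(2)
  r <- adr1(1, 2, lower = 3.0, upper = 3.5)
  cfg <- anneal_config(n_models = 3, seed = 42, n_high = 100, n_cool = 500,
                       n_quench = 600)
  ens <- anneal(atoms, list(r), NULL, cfg)
  for (m in 1:3) {
    d <- atom_distance(ens, m, 1, "H", 2, "H")
    expect_gt(d, 3.0 - 0.2)
    expect_lt(d, 3.5 + 0.2)
  }
  # same seed, identical ensemble
  ens2 <- anneal(atoms, list(r), NULL, cfg)
  expect_identical(ens$models, ens2$models)
  expect_identical(ens$energies, ens2$energies)
})

test_that("zero restraints return geometry-regularized extended chains", {
  atoms <- toy_atoms(4)
  cfg <- anneal_config(n_models = 2, seed = 3, n_high = 50, n_cool = 300,
                       n_quench = 500)
  ens <- anneal(atoms, list(), NULL, cfg)
  # still extended: CA(1)-CA(4) close to 3 * 3.45 (strand-like rise)
  d14 <- atom_distance(ens, 1, 1, "CA", 4, "CA")
  expect_gt(d14, 9)
  # geometry near ideal
  expect_equal(atom_distance(ens, 1, 2, "N", 2, "CA"), 1.458, tolerance = 0.02)
})

test_that("pseudo-energy decomposes and the restraint term is zero iff satisfied", {
  atoms <- toy_atoms(2)
  sat <- adr1(1, 2, lower = 1.0, upper = 20)
  cfg <- anneal_config(n_models = 1, seed = 1, n_high = 50, n_cool = 400,
                       n_quench = 500)
  ens <- anneal(atoms, list(sat), NULL, cfg)
  pe <- pseudo_energy(ens, list(sat), NULL, 1, cfg)
  expect_equal(pe$restraint, 0)
  # violation by delta with force constant k adds k * delta^2
  d <- atom_distance(ens, 1, 1, "H", 2, "H")
  viol <- adr1(1, 2, lower = 0.5, upper = d - 1.0)
  pe2 <- pseudo_energy(ens, list(viol), NULL, 1, cfg)
  expect_equal(pe2$restraint, cfg$restraint_k * 1.0^2, tolerance = 1e-6)
})

test_that("quench monotonically decreases energy on a fixed seed", {
  atoms <- toy_atoms(3)
  r <- adr1(1, 3, lower = 4, upper = 6)
  cfg <- anneal_config()
  sys <- adriter:::build_system_list(atoms, list(r), NULL, cfg)
  set.seed(7)
  x <- adriter:::extended_chain(atoms) + matrix(rnorm(18 * 3, 0, 0.4), ncol = 3)
  sched <- function(nq) list(n_high = 1, n_cool = 1, n_quench = nq,
                             temp_high = 1e-9, dt = cfg$dt, dt_hot = cfg$dt,
                             geom_soft = 1, force_cap = cfg$force_cap)
  e <- vapply(c(10, 100, 1000), function(nq)
    adriter:::.cpp_anneal(x, sys, sched(nq), 1L)$energy, numeric(1))
  expect_true(all(diff(e) <= 1e-9))
})

test_that("backbone RMSD is zero for duplicates and translations, exact on a hand-built pair", {
  spec <- sheet_spec(2, 5, seed = 6)
  tr <- build_ideal_sheet(spec)
  dup <- structure_ensemble(tr$atoms, list(tr$models[[1]], tr$models[[1]]),
                            c(1, 2))
  expect_equal(backbone_rmsd(dup)$mean, 0, tolerance = 1e-9)
  shifted <- structure_ensemble(tr$atoms,
                                list(tr$models[[1]], tr$models[[1]] + 5), c(1, 2))
  expect_equal(backbone_rmsd(shifted)$mean, 0, tolerance = 1e-9)
  expect_error(backbone_rmsd(dup, residues = integer(0)), "empty")
  # brute-force Kabsch oracle on a 3-atom toy
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  B <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2.5, 0))
  # optimal superposition computed independently: centroids + 2D rotation by
  # angle minimizing sum |R a - b|^2 (closed form via cross/dot sums)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  num <- sum(A0[, 1] * B0[, 2] - A0[, 2] * B0[, 1])
  den <- sum(A0[, 1] * B0[, 1] + A0[, 2] * B0[, 2])
  th <- atan2(num, den)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A2 <- A0; A2[, 1:2] <- A0[, 1:2] %*% t(R)
  oracle <- sqrt(mean(rowSums((A2 - B0)^2)))
  expect_equal(adriter:::superposed_rmsd(A, B), oracle, tolerance = 1e-9)
})

test_that("annealing against noise-free barrel restraints recovers the fold", {
  spec <- sheet_spec(6, 8, barrel = TRUE, seed = 13)
  tr <- build_ideal_sheet(spec)
  tc <- true_hn_contacts(tr, 4.6)
  h <- lapply(seq_len(nrow(tc)), function(k) adr1(
    tc$res_i[k], tc$res_j[k], lower = 1.0,
    upper = if (tc$distance[k] < 3.5) 3.5 else 5.5))
  at <- tr$atoms; m <- tr$models[[1]]
  idx <- which(at$atom %in% c("CA", "CB"))
  D <- as.matrix(dist(m[idx, ]))
  cadr <- list()
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a >= b || at$residue[idx[a]] >= at$residue[idx[b]] || D[a, b] > 5.5) next
    cadr[[length(cadr) + 1]] <- adr(options = data.frame(
      res_a = at$residue[idx[a]], atom_a = at$atom[idx[a]],
      res_b = at$residue[idx[b]], atom_b = at$atom[idx[b]],
      product = 1, support = NA_integer_), lower = 1.5, upper = 8.0,
      source = "c")
  }
  tors <- ideal_sheet_torsions(spec)
  ens <- anneal(tr$atoms, c(h, cadr), tors, anneal_config(n_models = 4, seed = 2))
  sel <- sort_by_energy(ens, 2)
  r <- backbone_rmsd(sel, unlist(spec$strands), reference = tr)
  expect_lt(min(r$values), 2.0)
})
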