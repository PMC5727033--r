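# effective-distance oracle: direct closed-form evaluation
eff_ref <- function(d) sum(d^-6)^(-1 / 6)

test_that("effective distance matches the closed form", {
  atoms <- data.frame(residue = 1:5, type = "A", atom = "H")
  m <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 6, 0), c(4, 0, 0), c(0, 0, 4))
  ens <- structure_ensemble(atoms, list(m))
  one <- adr(options = data.frame(res_a = 1, atom_a = "H", res_b = 2, atom_b = "H",
                                  product = NA, support = NA), lower = 1, upper = 5)
  expect_equal(effective_distance(ens, one), 3.0)
  two <- adr(options = data.frame(res_a = c(1, 1), atom_a = "H",
                                  res_b = c(2, 3), atom_b = "H",
                                  product = NA, support = NA), lower = 1, upper = 5)
  expect_equal(effective_distance(ens, two), eff_ref(c(3, 6)), tolerance = 1e-12)
  expect_equal(eff_ref(c(3, 6)), 2.992, tolerance = 1e-3)
  sym <- adr(options = data.frame(res_a = c(1, 1), atom_a = "H",
                                  res_b = c(4, 5), atom_b = "H",
                                  product = NA, support = NA), lower = 1, upper = 5)
  expect_equal(effective_distance(ens, sym), 4 * 2^(-1 / 6), tolerance = 1e-12)
  # pooling never exceeds the shortest option distance; equality iff single option
  expect_lt(effective_distance(ens, two), 3.0)
  expect_error(effective_distance(ens, adr1(1, 2)[c()]), class = "error")
})

test_that("the at-least-half violation rule follows the ceiling convention", {
  # 15 models: need ceil(7.5) = 8
  atoms <- data.frame(residue = 1:2, type = "A", atom = "H")
  mk_ens <- function(n_sat, n = 15) {
    models <- lapply(seq_len(n), function(m) {
      d <- if (m <= n_sat) 3.0 else 9.0
      rbind(c(0, 0, 0), c(d, 0, 0))
    })
    structure_ensemble(atoms, models, energies = seq_len(n))
  }
  cfg <- protocol_config(n_structures = 15, n_select = 15)
  a <- list(adr1(1, 2, lower = 1, upper = 5.5))
  for (sat in 0:15) {
    va <- violation_analysis(a, mk_ens(sat), cfg, tol = 0.1)
    expect_equal(va$report$decision,
                 if (sat >= 8) "kept" else "rejected",
                 info = paste("satisfied =", sat))
    expect_equal(va$report$satisfied, sat)
  }
  expect_error(violation_analysis(a, structure_ensemble(atoms, list())),
               class = "error")
})

test_that("rejected restraints are recoverable, never deleted", {
  atoms <- data.frame(residue = 1:2, type = "A", atom = "H")
  bad <- structure_ensemble(atoms, list(rbind(c(0, 0, 0), c(20, 0, 0))), 1)
  good <- structure_ensemble(atoms, list(rbind(c(0, 0, 0), c(3, 0, 0))), 1)
  cfg <- protocol_config(n_structures = 1, n_select = 1)
  a <- list(adr1(1, 2, lower = 1, upper = 5.5))
  va1 <- violation_analysis(a, bad, cfg, tol = 0.1)
  expect_false(va1$adrs[[1]]$active)
  expect_equal(nrow(va1$adrs[[1]]$options), 1)    # soft delete
  va2 <- violation_analysis(va1$adrs, good, cfg, tol = 0.1)
  expect_true(va2$adrs[[1]]$active)               # recovered
})

test_that("option pruning keeps the smallest prefix reaching the cutoff", {
  atoms <- data.frame(residue = 1:4, type = "A", atom = "H")
  # distances 2, 4, 6 -> r^-6 weights ~ {0.9859, 0.0154, 0.00086} normalized
  m <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0), c(0, 0, 6))
  ens <- structure_ensemble(atoms, list(m), 1)
  a <- adr(options = data.frame(res_a = 1, atom_a = "H", res_b = 2:4, atom_b = "H",
                                product = NA, support = NA), lower = 1, upper = 8)
  p1 <- prune_options(a, ens, cutoff = 0.8)
  expect_equal(nrow(p1$options), 1)
  expect_equal(p1$options$res_b, 2)
  expect_equal(nrow(prune_options(a, ens, cutoff = 1.0)$options), 3)
  expect_equal(nrow(prune_options(adr1(1, 2), ens, cutoff = 0.5)$options), 1)
})

test_that("restraint combination builds seed-reproducible groups with widest bounds", {
  adrs <- lapply(1:8, function(k) adr1(k, 100 + k, lower = 1.5,
                                       upper = c(5.5, 8)[k %% 2 + 1], source = "c"))
  out <- combine_restraints(adrs, arity = 4, seed = 5)
  expect_length(out, 2)
  expect_true(all(vapply(out, function(a) nrow(a$options), numeric(1)) == 4))
  expect_true(all(vapply(out, function(a) a$upper, numeric(1)) == 8))
  out2 <- combine_restraints(adrs, arity = 4, seed = 5)
  expect_identical(out, out2)
  # leftover rule: 5 restraints -> 1 combined + 1 passthrough
  out3 <- combine_restraints(adrs[1:5], arity = 4, seed = 5)
  expect_length(out3, 2)
  expect_setequal(vapply(out3, function(a) nrow(a$options), numeric(1)), c(4, 1))
  expect_error(combine_restraints(adrs, arity = 1), "arity")
  expect_length(combine_restraints(list(), 4, 1), 0)
})

test_that("merging collapses identical option sets keeping tighter bounds and all peaks", {
  a1 <- adr(options = data.frame(res_a = 75, atom_a = "H", res_b = 87,
                                 atom_b = "H", product = NA, support = NA),
            lower = 1, upper = 3.5, peak_id = 1L)
  a2 <- adr(options = data.frame(res_a = 87, atom_a = "H", res_b = 75,
                                 atom_b = "H", product = NA, support = NA),
            lower = 1, upper = 5.5, peak_id = 2L)
  b <- adr1(10, 20)
  out <- merge_equivalent(list(a1, a2, b))
  expect_length(out, 2)
  merged <- out[[which(vapply(out, function(a) 75 %in% a$options$res_a ||
                                75 %in% a$options$res_b, logical(1)))]]
  expect_equal(merged$upper, 3.5)
  expect_setequal(merged$peak_id, c(1L, 2L))
  expect_length(merge_equivalent(list()), 0)
  expect_identical(merge_equivalent(list(b))[[1]]$options, b$options)
})

test_that("the protocol stages restraint families and logs every iteration", {
  spec <- sheet_spec(3, 6, seed = 21)
  study <- synthetic_study(spec, seed = 21, schemes = c("glycerol_2"))
  cfg <- protocol_config(n_iterations = 3, n_structures = 4, n_select = 2,
                         c_from_iteration = 1, combine_iterations = 1,
                         violation_tolerance = c(1000, 3, 1),
                         ambiguity_cutoff = c(1, 1, 0.95), seed = 3)
  acfg <- anneal_config(n_high = 300, n_cool = 1500, n_quench = 1000, seed = 3)
  fit <- run_protocol(study$truth$atoms, study$h_adrs, study$c_adrs,
                      study$torsions, config = cfg, anneal_cfg = acfg)
  expect_s3_class(fit, "adr_protocol")
  expect_length(fit$history, 3)
  # iteration 0 uses only the amide family
  expect_equal(fit$history[[1]]$n_restraints_used, length(study$h_adrs))
  # carbon restraints join at iteration 1 (with combination active there)
  expect_gt(fit$history[[2]]$n_restraints_used, length(study$h_adrs))
  expect_true(fit$history[[2]]$combined)
  s <- summary(fit)
  expect_equal(nrow(s), 3)
  expect_true(all(c("iteration", "mean_ambiguity", "best_energy") %in% names(s)))
  # audit: violation reports reconstruct every decision
  expect_true(all(fit$history[[2]]$report_h$decision %in%
                    c("kept", "rejected", "inactive")))
})
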