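test_that("forward scheme labels its amino-acid set at nominal and leaves others at zero", {
  sch <- build_labeling_scheme("forward", residues = c("G", "A", "V", "L", "S"),
                               accidental = "W")
  expect_equal(enrichment(sch, "L", "CA"), 1.0)
  expect_equal(enrichment(sch, "F", "CA"), 0.0)
  expect_equal(enrichment(sch, "W", "CA"), 0.3)   # accidental default
  # every fraction in [0, 1]
  fr <- unlist(sch$enrichment)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("uniform scheme puts every carbon at the nominal enrichment", {
  sch <- build_labeling_scheme("uniform", nominal = 1.0)
  fr <- unlist(sch$enrichment)
  expect_true(all(fr == 1.0))
  # and every pair is observable at enrichment 1
  expect_true(pair_observable(sch, "A", "CA", "L", "CD1"))
})

test_that("glycerol schemes read the encoded pattern table", {
  sch2 <- build_labeling_scheme("glycerol_2")
  tab <- utils::read.csv(system.file("extdata", "glycerol_patterns.csv",
                                     package = "adriter"), comment.char = "#")
  expected <- tab$fraction[tab$scheme == "glycerol_2" & tab$res == "A" &
                             tab$atom == "CA"]
  expect_equal(enrichment(sch2, "A", "CA"), expected)
  # [2-13C]: Ala CA labeled, CB not; [1,3-13C]: the reverse
  sch13 <- build_labeling_scheme("glycerol_1_3")
  expect_gt(enrichment(sch2, "A", "CA"), 0.5)
  expect_lt(enrichment(sch2, "A", "CB"), 0.1)
  expect_lt(enrichment(sch13, "A", "CA"), 0.1)
  expect_gt(enrichment(sch13, "A", "CB"), 0.5)
})

test_that("pair observability is the product of enrichments, symmetric, filtered at 10%", {
  sch <- build_labeling_scheme("forward", residues = c("A", "L"),
                               accidental = "V", accidental_fraction = 0.15,
                               enrichment_overrides = data.frame(
                                 res = "L", atom = "CA", fraction = 0.5))
  expect_equal(pair_observability(sch, "L", "CA", "V", "CA"), 0.5 * 0.15)
  expect_equal(pair_observability(sch, "L", "CA", "V", "CA"),
               pair_observability(sch, "V", "CA", "L", "CA"))
  # 0.5 * 0.15 = 0.075 -> discarded (strictly > 0.10 required)
  expect_false(pair_observable(sch, "L", "CA", "V", "CA"))
  # 0.4 * 0.3 = 0.12 -> kept
  sch2 <- build_labeling_scheme("forward", residues = character(),
                                enrichment_overrides = data.frame(
                                  res = c("A", "L"), atom = c("CA", "CA"),
                                  fraction = c(0.4, 0.3)))
  expect_true(pair_observable(sch2, "A", "CA", "L", "CA"))
  # boundary: exactly 0.10 is discarded
  sch3 <- build_labeling_scheme("forward", residues = character(),
                                enrichment_overrides = data.frame(
                                  res = c("A", "L"), atom = c("CA", "CA"),
                                  fraction = c(0.5, 0.2)))
  expect_false(pair_observable(sch3, "A", "CA", "L", "CA"))
})

test_that("errors: unknown residue, non-carbon atom, missing pattern cell", {
  expect_error(build_labeling_scheme("forward", residues = "Z"), "unknown residue")
  sch <- build_labeling_scheme("uniform")
  expect_error(enrichment(sch, "A", "N"), "not a carbon")
  expect_error(enrichment(sch, "A", "CQ9"), "no carbon named")
})

test_that("forward-scheme pairs involving unlabeled, non-accidental types are filtered", {
  sch <- builtin_scheme("gavls_w")
  for (other in c("F", "E", "K")) {
    expect_false(pair_observable(sch, "A", "CA", other, "CA"))
  }
  expect_true(pair_observable(sch, "A", "CA", "L", "CA"))
})

test_that("labeling config round-trips through YAML", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("kind: forward",
               "residues: GAVLS",
               "accidental: W",
               "accidental_fraction: 0.25"), tf)
  sch <- read_labeling_config(tf)
  expect_s3_class(sch, "labeling_scheme")
  expect_equal(enrichment(sch, "W", "CA"), 0.25)
  expect_equal(enrichment(sch, "V", "CB"), 1.0)
})
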