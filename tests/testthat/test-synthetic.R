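test_that("all generators are bit-reproducible given (spec, seed)", {
  spec <- phenotype_preset("cortex")
  m1 <- generate_cross_section(spec, seed = 12)
  m2 <- generate_cross_section(spec, seed = 12)
  expect_identical(m1$capillaries, m2$capillaries)
  expect_identical(m1$fibres, m2$fibres)
  m3 <- generate_cross_section(spec, seed = 13)
  expect_false(identical(m1$capillaries, m3$capillaries))

  t1 <- generate_tension_trace(seed = 4, duration = 10)
  t2 <- generate_tension_trace(seed = 4, duration = 10)
  expect_identical(t1$tension, t2$tension)

  f1 <- generate_flow_trace(seed = 4)
  f2 <- generate_flow_trace(seed = 4)
  expect_identical(f1$flow, f2$flow)

  mm1 <- generate_metabolome(seed = 4, compounds = 10)
  mm2 <- generate_metabolome(seed = 4, compounds = 10)
  expect_identical(mm1$intensities, mm2$intensities)
})

test_that("thinning hits the expected capillary count on average", {
  # core preset: expected count = 984 * 0.145 = 142.68 per frame
  spec <- phenotype_preset("core")
  counts <- vapply(1:60, function(s) {
    n_capillaries(generate_cross_section(spec, seed = 2000 + s))
  }, numeric(1))
  target <- 984 * 0.145
  # mean count within a 99% band around the thinning expectation
  expect_lt(abs(mean(counts) - target), 2.6 * sd(counts) / sqrt(60))
  expect_equal(mean(counts), target, tolerance = 0.05)
})

test_that("measured capillary density recovers the target within 5%", {
  for (preset in c("core", "cortex")) {
    spec <- phenotype_preset(preset)
    cds <- vapply(1:25, function(s) {
      compute_global_indices(
        generate_cross_section(spec, seed = 3000 + s))$CD_per_mm2
    }, numeric(1))
    expect_equal(mean(cds), spec$target_CD, tolerance = 0.05)
  }
})

test_that("angiogenic targets beyond the triple-point supply use edge sites", {
  spec <- phenotype_spec(target_CD = 1360, fibre_CSA_mean = 1870)
  m <- generate_cross_section(spec, seed = 8)
  expect_equal(n_capillaries(m) / frame_area(m, "mm2"), 1360,
               tolerance = 0.15)
  # far beyond any candidate supply: hard error
  spec_hi <- phenotype_spec(target_CD = 20000, fibre_CSA_mean = 2800)
  expect_error(generate_cross_section(spec_hi, seed = 1), "candidate sites")
})

test_that("tension generator plants a recoverable fatigue index", {
  tr1 <- generate_tension_trace(FI_target = 1, noise_sd = 0, seed = 3,
                                duration = 60)
  expect_equal(fatigue_index(tr1)$FI, 1, tolerance = 1e-3)
  tr2 <- generate_tension_trace(FI_target = 0.5, noise_sd = 0, seed = 3)
  expect_equal(fatigue_index(tr2)$FI, 0.5, tolerance = 0.005)
  for (fi in c(0.47, 0.82)) {
    tr <- generate_tension_trace(FI_target = fi, noise_sd = 0.02, seed = 101)
    expect_equal(fatigue_index(tr)$FI, fi, tolerance = 0.02)
  }
})

test_that("metabolome generator plants arithmetic-mean fold changes", {
  ratios <- vapply(1:40, function(s) {
    mat <- generate_metabolome(n_per_group = 5, compounds = 5, seed = s)
    v <- volcano_table(mat, "CT", "10Hz")
    2^v$log2_fold_change[v$compound_id == "kynurenic_acid"]
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("a strong planted effect ranks first by p-value in most seeds", {
  firsts <- vapply(1:50, function(s) {
    folds <- data.frame(compound = "hit", group = "ES", fold = 2)
    mat <- generate_metabolome(n_per_group = 5, compounds = 30,
                               effects = folds, sigma_log = 0.1,
                               seed = 600 + s, groups = c("CT", "ES"))
    v <- volcano_table(mat, "CT", "ES")
    v$compound_id[which.min(v$raw_p)] == "hit"
  }, logical(1))
  expect_gte(mean(firsts), 0.95)
})

test_that("null metabolomes produce near-nominal false-positive counts", {
  hits <- vapply(1:10, function(s) {
    mat <- generate_metabolome(n_per_group = 5, compounds = 200,
                               effects = NULL, seed = 800 + s,
                               groups = c("CT", "ES"))
    v <- volcano_table(mat, "CT", "ES")
    mean(v$raw_p < 0.05)
  }, numeric(1))
  # 2000 independent null tests: 3-sigma Monte-Carlo band ~ 0.015
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("capillary density monotonically drives modelled oxygenation", {
  p <- oxygen_params("exercise")
  po2 <- vapply(c(400, 800, 1600), function(cd) {
    spec <- phenotype_spec(target_CD = cd, fibre_CSA_mean = 1200,
                           frame_area_mm2 = 0.01)
    m <- generate_cross_section(spec, seed = 55)
    solve_frame(tessellate(m), m, p, h = 2)$mean_PO2
  }, numeric(1))
  expect_true(all(diff(po2) > 0))
})
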