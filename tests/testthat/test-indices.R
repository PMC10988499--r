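test_that("capillary density is count over frame area", {
  m <- capillary_map(tibble::tibble(x_um = 50, y_um = 50), 100, 100)
  expect_equal(compute_global_indices(m)$CD_per_mm2, 100)  # 1 / 0.01 mm^2
  # brute-force recount on a random frame
  m2 <- random_map(37, w = 250, h = 180, seed = 2)
  expect_equal(compute_global_indices(m2)$CD_per_mm2,
               37 / (250 * 180 / 1e6))
})

test_that("C:F uses the forbidden-line counting rule", {
  fibres <- list(
    square_fibre(50, 50, 20),    # interior: counted
    square_fibre(0, 50, 20),     # crosses left (forbidden) edge: excluded
    square_fibre(100, 50, 20),   # crosses right edge: counted
    square_fibre(50, -2, 20)     # crosses bottom (forbidden) edge: excluded
  )
  m <- capillary_map(
    tibble::tibble(x_um = c(10, 20, 30, 40), y_um = c(80, 80, 80, 80)),
    100, 100, fibres = fibres)
  gi <- compute_global_indices(m)
  expect_equal(gi$n_fibres_counted, 2L)
  expect_equal(gi$CF, 2.0)       # 4 capillaries / 2 counted fibres
  expect_equal(gi$CSA_um2, 400)  # whole-polygon area of counted fibres
  gi_all <- compute_global_indices(m, counting_rule = "all")
  expect_equal(gi_all$n_fibres_counted, 4L)
  # no fibres: CF/CSA absent, CD still returned
  m_no <- capillary_map(tibble::tibble(x_um = 10, y_um = 10), 100, 100)
  gi_no <- compute_global_indices(m_no)
  expect_true(is.na(gi_no$CF) && is.na(gi_no$CSA_um2))
  expect_equal(gi_no$CD_per_mm2, 100)
})

test_that("equal domains give logSD 0 and CDA_mean = 1/CD exactly", {
  m <- capillary_map(tibble::tibble(x_um = c(25, 75), y_um = c(50, 50)),
                     100, 100)
  tess <- tessellate(m)
  li <- compute_local_indices(tess)
  expect_equal(li$summary$logSD, 0)
  expect_equal(li$summary$CDA_mean_um2, 5000)
  # identity over a random frame: CDA_mean (um^2) = 1e6 / CD (mm^-2)
  m2 <- random_map(60, w = 300, h = 300, seed = 8)
  cda <- compute_local_indices(tessellate(m2))$summary$CDA_mean_um2
  cd <- compute_global_indices(m2)$CD_per_mm2
  expect_equal(cda, 1e6 / cd)
})

test_that("spatial scaling multiplies CDA by k^2 and leaves logSD unchanged", {
  m <- random_map(40, w = 200, h = 200, seed = 11)
  k <- 3.7
  ms <- capillary_map(
    tibble::tibble(x_um = m$capillaries$x_um * k, y_um = m$capillaries$y_um * k),
    frame_width = 200 * k, frame_height = 200 * k)
  li <- compute_local_indices(tessellate(m))$summary
  lis <- compute_local_indices(tessellate(ms))$summary
  expect_equal(lis$CDA_mean_um2, li$CDA_mean_um2 * k^2, tolerance = 1e-10)
  expect_equal(lis$logSD, li$logSD, tolerance = 1e-10)
})

test_that("a perfect capillary lattice has (interior) logSD below 1e-6", {
  spec <- phenotype_spec(target_CD = 984, fibre_CSA_mean = 1870, jitter = 0)
  m <- generate_cross_section(spec, seed = 1, thinning = FALSE)
  tess <- tessellate(m)
  interior <- log(domain_areas(tess)[!tess$boundary_flags])
  expect_lt(sd(interior), 1e-6)
})

test_that("lattice jitter monotonically inflates logSD", {
  jitters <- c(0.02, 0.1, 0.25)
  mean_logsd <- vapply(jitters, function(j) {
    vals <- vapply(1:15, function(s) {
      spec <- phenotype_spec(target_CD = 600, fibre_CSA_mean = 2500,
                             jitter = j, frame_area_mm2 = 0.04)
      tess <- tessellate(generate_cross_section(spec, seed = 700 + s,
                                                thinning = FALSE))
      compute_local_indices(tess)$summary$logSD
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_logsd) > 0))
})

test_that("core:cortex ratios behave proportionally", {
  core <- tibble::tibble(CF = 1.84, CD_per_mm2 = 984, CSA_um2 = 1870)
  cortex <- tibble::tibble(CF = 1.84, CD_per_mm2 = 984, CSA_um2 = 1870)
  expect_true(all(core_cortex_ratio(core, cortex) == 1))
  cortex2 <- dplyr::mutate(cortex, CD_per_mm2 = CD_per_mm2 * 2)
  r <- core_cortex_ratio(core, cortex2)
  expect_equal(r$CD_per_mm2, 0.5)
  expect_error(core_cortex_ratio(core, dplyr::mutate(cortex, CD_per_mm2 = 0)),
               "zero cortex")
})

test_that("planted core:cortex CD ratio is recovered from synthetic frames", {
  cds <- function(preset, seeds) {
    mean(vapply(seeds, function(s) {
      compute_global_indices(
        generate_cross_section(phenotype_preset(preset), seed = s))$CD_per_mm2
    }, numeric(1)))
  }
  ratio <- cds("core", 1:12) / cds("cortex", 101:112)
  expect_equal(ratio, 984 / 533, tolerance = 0.05)
})

test_that("percent change reproduces the printed worked examples", {
  expect_equal(percent_change(533, 921)$percent_change, 72.7955, tolerance = 1e-4)
  expect_equal(percent_change(533, 921)$percent_change_rounded, 73)
  expect_equal(percent_change(533, 1120)$percent_change_rounded, 110)
  expect_equal(percent_change(5, 5)$percent_change, 0)
  expect_error(percent_change(0, 10), "positive")
  expect_error(percent_change(-2, 10), "positive")
})
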