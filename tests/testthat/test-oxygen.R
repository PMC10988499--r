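test_that("Krogh-Erlang reference satisfies its boundary conditions", {
  p <- oxygen_params("exercise")
  R <- 17.6
  expect_equal(krogh_erlang_reference(p$r_cap, R, p), p$P_cap)
  # no-flux at R: central difference of the profile vanishes
  eps <- 1e-6
  dPdr <- (krogh_erlang_reference(R, R, p) -
             krogh_erlang_reference(R - eps, R, p)) / eps
  expect_lt(abs(dPdr), 1e-6)
})

test_that("Krogh-Erlang profile matches an independent ODE quadrature", {
  # solve (1/r) d/dr (r dP/dr) = M0 / (D alpha), P(r_cap) = P_cap,
  # P'(R) = 0, via the flux integral: r P'(r) = (M0/(2 D alpha)) (r^2 - R^2)
  p <- oxygen_params("exercise", D = 2400, alpha = 3.89e-5, M0 = 1.5e-3,
                     r_cap = 2.5, P_cap = 40)
  R <- 17.6
  rs <- seq(p$r_cap, R, length.out = 4000)
  k <- p$M0 / (p$D * p$alpha)
  dP <- function(r) k / 2 * (r^2 - R^2) / r
  # trapezoid quadrature of dP from r_cap
  P_num <- p$P_cap + c(0, cumsum((dP(rs[-1]) + dP(rs[-length(rs)])) / 2 *
                                   diff(rs)))
  P_ref <- krogh_erlang_reference(rs, R, p)
  expect_equal(P_num, P_ref, tolerance = 1e-6)
  # anoxic-core parameterisation is flagged
  p_hot <- oxygen_params("exercise", M0 = 2e-2)
  expect_warning(krogh_erlang_reference(10, 25, p_hot), "anoxic")
})

test_that("zero consumption gives a uniform field at capillary PO2", {
  m <- random_map(8, w = 80, h = 80, seed = 21)
  tess <- tessellate(m)
  f <- solve_frame(tess, m, oxygen_params("rest", M0 = 0), h = 2)
  expect_true(all(f$grid[!is.na(f$grid)] == 40))
  expect_equal(hypoxic_fraction(f), 0)
  expect_equal(f$mean_PO2, 40)
})

test_that("disc solve matches the closed form in the zero-order limit", {
  p <- oxygen_params("exercise", P50 = 1e-6)
  R <- 12
  disk <- capdomain:::circle_polygon(0, 0, R, n = 360)
  f <- solve_domain(disk, c(0, 0), p, h = 0.5)
  expect_lt(krogh_profile_error(f, R, p), 2)
})

test_that("the solution respects the maximum principle and monotonicity in M0", {
  m <- random_map(10, w = 100, h = 100, seed = 31)
  tess <- tessellate(m)
  p1 <- oxygen_params("exercise")
  f1 <- solve_frame(tess, m, p1, h = 2)
  vals <- f1$grid[!is.na(f1$grid)]
  expect_true(all(vals <= p1$P_cap + 1e-9))
  expect_true(all(vals >= 0))
  expect_equal(f1$n_clamped, 0L)
  f2 <- solve_frame(tess, m, oxygen_params("exercise", M0 = 2 * p1$M0), h = 2)
  expect_lt(f2$mean_PO2, f1$mean_PO2)
  # increasing capillary PO2 raises the field
  f3 <- solve_frame(tess, m, oxygen_params("exercise", P_cap = 60), h = 2)
  expect_gt(f3$mean_PO2, f1$mean_PO2)
})

test_that("congruent domains produce identical subfields after assembly", {
  # two translate-congruent domains: identical cell enumeration, so the
  # assembled subfields must agree bitwise
  m <- capillary_map(tibble::tibble(x_um = c(50, 50), y_um = c(50, 150)),
                     100, 200)
  tess <- tessellate(m)
  f <- solve_frame(tess, m, oxygen_params("exercise"), h = 1)
  expect_identical(f$grid[, 1:100], f$grid[, 101:200])
  # mirror-congruent domains agree to numerical round-off
  mm <- capillary_map(tibble::tibble(x_um = c(25, 75), y_um = c(50, 50)),
                      100, 100)
  fm <- solve_frame(tessellate(mm), mm, oxygen_params("exercise"), h = 1)
  expect_equal(fm$grid[1:50, ], fm$grid[100:51, ], tolerance = 1e-10)
})

test_that("hypoxic fraction counts tissue cells below threshold", {
  m <- random_map(6, w = 60, h = 60, seed = 41)
  tess <- tessellate(m)
  f <- solve_frame(tess, m, oxygen_params("exercise"), h = 2)
  expect_equal(hypoxic_fraction(f, threshold = 0), 0)
  expect_equal(hypoxic_fraction(f, threshold = 100), 100)
  tissue_vals <- f$grid[!is.na(f$grid) & !f$lumen]
  med <- stats::median(tissue_vals)
  expect_equal(hypoxic_fraction(f, threshold = med),
               100 * mean(tissue_vals < med))
})

test_that("grid refinement changes mean PO2 by less than 1%", {
  spec <- phenotype_spec(target_CD = 900, fibre_CSA_mean = 1400,
                         frame_area_mm2 = 0.0225)
  m <- generate_cross_section(spec, seed = 5)
  tess <- tessellate(m)
  p <- oxygen_params("exercise")
  f1 <- solve_frame(tess, m, p, h = 1)
  f2 <- solve_frame(tess, m, p, h = 0.5)
  expect_lt(abs(f2$mean_PO2 - f1$mean_PO2) / f1$mean_PO2, 0.01)
})

test_that("denser capillary networks are better oxygenated", {
  set.seed(77)
  wins <- vapply(1:20, function(k) {
    dense <- random_map(14, w = 100, h = 100, seed = 900 + k)
    sparse_pts <- dense$capillaries[1:7, ]
    sparse <- capillary_map(sparse_pts, 100, 100)
    p <- oxygen_params("exercise")
    fd <- solve_frame(tessellate(dense), dense, p, h = 2)
    fs <- solve_frame(tessellate(sparse), sparse, p, h = 2)
    fd$mean_PO2 > fs$mean_PO2
  }, logical(1))
  # one-sided sign test at p < 0.01
  expect_lt(stats::binom.test(sum(wins), length(wins),
                              alternative = "greater")$p.value, 0.01)
})

test_that("solver guards its preconditions", {
  m <- capillary_map(tibble::tibble(x_um = 50, y_um = 50), 100, 100)
  tess <- tessellate(m)
  expect_error(solve_frame(tess, m, oxygen_params("rest"), h = 5),
               "must not exceed")
  sq <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  expect_error(solve_domain(sq, c(20, 20), oxygen_params("rest"), h = 1),
               "inside the domain")
  expect_error(oxygen_params("rest", M0 = -1))
})
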