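#' Oxygen transport model parameters
#'
#' Parameters of the steady-state diffusion-consumption model
#' `D * alpha * laplacian(P) = M0 * P / (P50 + P)` solved on each capillary
#' domain (trapping region): Fickian diffusion with Michaelis-Menten tissue
#' consumption, a fixed capillary-surface PO2 Dirichlet condition on the
#' capillary lumen, and no-flux (reflective) conditions on the domain
#' boundary — each capillary supplies only its own domain.
#'
#' Defaults are literature-magnitude values for mammalian skeletal muscle,
#' all exposed here because measured values vary across preparations:
#' `D` = 2400 um^2/s (tissue O2 diffusivity), `alpha` = 3.89e-5 mL O2 /
#' (mL tissue mmHg) (solubility), `P50` = 0.5 mmHg (Michaelis constant),
#' `r_cap` = 2.5 um (capillary radius), `P_cap` = 40 mmHg (capillary-surface
#' PO2). Maximal consumption `M0` defaults to 1e-4 mL O2/(mL s) at rest and
#' 1.5e-3 in the simulated intense-exercise mode. Tissue below
#' `hypoxia_threshold` (default 1 mmHg) counts as hypoxic.
#'
#' @param mode `"rest"` or `"exercise"`; selects the default `M0`.
#' @param D O2 diffusivity, um^2/s.
#' @param alpha O2 solubility, mL O2 / (mL tissue mmHg).
#' @param M0 Maximal consumption rate, mL O2 / (mL tissue s). Default set by
#'   `mode`. `M0 = 0` (no consumption) is allowed and gives `P == P_cap`.
#' @param P50 PO2 at half-maximal consumption, mmHg.
#' @param P_cap Capillary-surface PO2, mmHg; must exceed the hypoxia
#'   threshold.
#' @param r_cap Capillary radius, um.
#' @param hypoxia_threshold Hypoxia cutoff, mmHg (>= 0).
#' @return An `oxygen_params` list.
#' @export
oxygen_params <- function(mode = c("rest", "exercise"),
                          D = 2400, alpha = 3.89e-5, M0 = NULL,
                          P50 = 0.5, P_cap = 40, r_cap = 2.5,
                          hypoxia_threshold = 1) {
  mode <- match.arg(mode)
  if (is.null(M0)) M0 <- if (mode == "rest") 1e-4 else 1.5e-3
  stopifnot(D > 0, alpha > 0, M0 >= 0, P50 > 0, P_cap > 0, r_cap > 0,
            hypoxia_threshold >= 0, P_cap > hypoxia_threshold)
  structure(list(mode = mode, D = D, alpha = alpha, M0 = M0, P50 = P50,
                 P_cap = P_cap, r_cap = r_cap,
                 hypoxia_threshold = hypoxia_threshold),
            class = "oxygen_params")
}

#' Krogh-Erlang radial PO2 profile (zero-order consumption)
#'
#' Closed-form PO2 at radius `r` for a single capillary of radius `r_cap`
#' supplying a disc of radius `R` with uniform (zero-order) consumption
#' `M0`, capillary-surface PO2 `P_cap` and no flux at `R`:
#' `P(r) = P_cap + (M0 / (2 D alpha)) * ((r^2 - r_cap^2)/2 - R^2 * log(r / r_cap))`.
#' This is the `P50 -> 0` radially symmetric limit of the trapping-region
#' model and serves as its analytical validation oracle.
#'
#' @param r Radii at which to evaluate (um), `r_cap <= r <= R`.
#' @param R Disc (domain) radius, um.
#' @param params An [oxygen_params()].
#' @return Numeric PO2 (mmHg) at each `r`. If the zero-order form predicts
#'   `P(R) < 0` the profile is invalid (anoxic core) and a warning is
#'   raised.
#' @export
krogh_erlang_reference <- function(r, R, params) {
  stopifnot(inherits(params, "oxygen_params"), R > params$r_cap)
  if (any(r < params$r_cap - 1e-12) || any(r > R + 1e-12)) {
    abort("`r` must satisfy r_cap <= r <= R")
  }
  k <- params$M0 / (2 * params$D * params$alpha)
  p_of <- function(rr) {
    params$P_cap + k * ((rr^2 - params$r_cap^2) / 2 -
                          R^2 * log(rr / params$r_cap))
  }
  if (p_of(R) < 0) {
    warn("zero-order Krogh-Erlang form invalid: P(R) < 0 (anoxic core)")
  }
  p_of(r)
}

# Core finite-difference solve on a set of grid cells.
#
# cells: integer matrix (m x 2) of (ix, iy) grid indices; grid spacing hx, hy
# (cell centres at (ix - 0.5) * hx + x0, similarly y). site: (x, y) of the
# capillary in the same coordinates. Returns list(P, lumen, clamped, iters).
#
# Discretisation: 5-point Laplacian with reflective (no-flux) ghost cells on
# the domain boundary, and a Shortley-Weller embedded-boundary stencil at
# the capillary surface -- links crossing the lumen circle apply the
# Dirichlet value at the exact circle intersection (distance theta * h,
# theta in (0, 1]) with coefficients 2 / (hW (hW + hE)) etc., keeping the
# boundary position error at O(h^2) instead of the O(h) of a binary
# lumen-cell treatment.
solve_cells <- function(cells, site, params, hx, hy, x0 = 0, y0 = 0,
                        max_iter = 500L, tol = 1e-6) {
  m <- nrow(cells)
  cx <- x0 + (cells[, 1L] - 0.5) * hx
  cy <- y0 + (cells[, 2L] - 0.5) * hy
  r2 <- (cx - site[1L])^2 + (cy - site[2L])^2
  lumen <- r2 <= params$r_cap^2
  if (!any(lumen)) {
    abort("no lumen cell: grid step must not exceed r_cap (capillary missed)")
  }
  if (all(lumen) || params$M0 == 0) {
    return(list(P = rep(params$P_cap, m), lumen = lumen, clamped = 0L,
                iters = 0L))
  }

  # index map over the bounding box for neighbour lookup
  ix <- cells[, 1L] - min(cells[, 1L]) + 1L
  iy <- cells[, 2L] - min(cells[, 2L]) + 1L
  nix <- max(ix); niy <- max(iy)
  idx <- matrix(0L, nix, niy)
  idx[cbind(ix, iy)] <- seq_len(m)

  unknown <- which(!lumen)
  uid <- integer(m)             # cell -> unknown rank (0 if Dirichlet)
  uid[unknown] <- seq_along(unknown)
  nu <- length(unknown)
  uix <- ix[unknown]; uiy <- iy[unknown]
  ucx <- cx[unknown]; ucy <- cy[unknown]

  # fraction of the link at which it crosses the lumen circle, for an
  # unknown cell at (px, py) stepping (dx, dy) * h towards a lumen cell
  theta_cross <- function(px, py, dx, dy, h) {
    if (dx != 0) {
      disc <- sqrt(pmax(0, params$r_cap^2 - (py - site[2L])^2))
      roots <- cbind(dx * (site[1L] - px) - disc, dx * (site[1L] - px) + disc)
    } else {
      disc <- sqrt(pmax(0, params$r_cap^2 - (px - site[1L])^2))
      roots <- cbind(dy * (site[2L] - py) - disc, dy * (site[2L] - py) + disc)
    }
    roots[roots <= 0] <- Inf
    t <- pmin(roots[, 1L], roots[, 2L]) / h
    pmax(pmin(t, 1), 1e-6)
  }

  # per-side neighbour classification: distance (in units of the step) and
  # kind (0 reflect/no-flux, 1 unknown, 2 Dirichlet at the circle)
  sides <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  dist <- matrix(1, nu, 4L)
  kind <- matrix(0L, nu, 4L)
  nbid <- matrix(0L, nu, 4L)
  for (s in seq_along(sides)) {
    dx <- sides[[s]][1L]; dy <- sides[[s]][2L]
    h <- if (dx != 0) hx else hy
    nx2 <- uix + dx; ny2 <- uiy + dy
    ok <- nx2 >= 1L & nx2 <= nix & ny2 >= 1L & ny2 <= niy
    nb <- integer(nu)
    nb[ok] <- idx[cbind(nx2[ok], ny2[ok])]
    present <- nb > 0L
    is_unknown <- present & uid[pmax(nb, 1L)] > 0L
    is_dir <- present & !is_unknown
    kind[is_unknown, s] <- 1L
    nbid[is_unknown, s] <- uid[nb[is_unknown]]
    kind[is_dir, s] <- 2L
    if (any(is_dir)) {
      dist[is_dir, s] <- theta_cross(ucx[is_dir], ucy[is_dir], dx, dy, h)
    }
  }

  Dalpha <- params$D * params$alpha
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_lap <- numeric(nu)       # negated Laplacian diagonal (positive)
  b0 <- numeric(nu)             # Dirichlet contribution to RHS
  for (axis in 1:2) {
    sW <- 2L * axis - 1L; sE <- 2L * axis
    h <- if (axis == 1L) hx else hy
    hW <- dist[, sW] * h; hE <- dist[, sE] * h
    for (s in c(sW, sE)) {
      hS <- if (s == sW) hW else hE
      a <- Dalpha * 2 / (hS * (hW + hE))
      active <- kind[, s] != 0L
      diag_lap[active] <- diag_lap[active] + a[active]
      un <- kind[, s] == 1L
      if (any(un)) {
        ii <- c(ii, which(un)); jj <- c(jj, nbid[un, s]); vv <- c(vv, -a[un])
      }
      dir <- kind[, s] == 2L
      if (any(dir)) b0[dir] <- b0[dir] + a[dir] * params$P_cap
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(ii, seq_len(nu)), j = c(jj, seq_len(nu)),
    x = c(vv, diag_lap), dims = c(nu, nu)
  )

  P <- rep(params$P_cap, nu)
  clamped <- 0L
  iters <- 0L
  repeat {
    iters <- iters + 1L
    q <- params$M0 / (params$P50 + P)
    M <- A + Matrix::Diagonal(nu, q)
    Pn <- as.numeric(Matrix::solve(M, b0))
    neg <- Pn < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg)
      Pn[neg] <- 0
    }
    dP <- max(abs(Pn - P))
    P <- Pn
    if (dP < tol) break
    if (iters >= max_iter) {
      abort(sprintf(
        "oxygen solver did not converge in %d Picard iterations (last max |dP| = %.3g mmHg)",
        max_iter, dP))
    }
  }
  if (clamped > 0L) {
    warn(sprintf("clamped %d negative intermediate PO2 values to 0", clamped))
  }
  out <- rep(params$P_cap, m)
  out[unknown] <- P
  list(P = out, lumen = lumen, clamped = clamped, iters = iters)
}

#' Solve the oxygen model on a single capillary domain
#'
#' Rasterises the domain polygon at grid step `h` and solves the
#' diffusion-consumption equation with the capillary as a Dirichlet disc
#' (cells with centre within `r_cap` of the capillary held at `P_cap`) and
#' no-flux conditions on the rasterised domain boundary. The Michaelis-
#' Menten term is handled by Picard iteration with a lagged denominator;
#' each linear step is solved by a sparse direct factorisation. Iteration
#' stops when `max |dP| < 1e-6` mmHg (at most 500 iterations).
#'
#' @param domain Polygon (data frame with `x`, `y`, micrometres).
#' @param capillary Length-2 numeric: capillary position, inside the domain.
#' @param params An [oxygen_params()].
#' @param h Grid step in micrometres; must not exceed `r_cap`.
#' @return An `oxygen_field` restricted to this domain.
#' @export
solve_domain <- function(domain, capillary, params, h = 1) {
  stopifnot(inherits(params, "oxygen_params"), h > 0)
  if (h > params$r_cap) abort("grid step `h` must not exceed the capillary radius")
  if (!points_in_polygon(capillary[1L], capillary[2L], domain$x, domain$y)) {
    abort("capillary point must lie inside the domain polygon")
  }
  x0 <- floor(min(domain$x) / h) * h
  y0 <- floor(min(domain$y) / h) * h
  nx <- ceiling((max(domain$x) - x0) / h)
  ny <- ceiling((max(domain$y) - y0) / h)
  gx <- x0 + (seq_len(nx) - 0.5) * h
  gy <- y0 + (seq_len(ny) - 0.5) * h
  cand <- cbind(rep(seq_len(nx), times = ny), rep(seq_len(ny), each = nx))
  inside <- points_in_polygon(x0 + (cand[, 1L] - 0.5) * h,
                              y0 + (cand[, 2L] - 0.5) * h,
                              domain$x, domain$y)
  cells <- cand[inside, , drop = FALSE]
  if (nrow(cells) == 0) abort("domain polygon rasterised to zero cells")
  sol <- solve_cells(cells, capillary, params, h, h, x0, y0)

  grid <- matrix(NA_real_, nx, ny)
  grid[cells] <- sol$P
  lumen <- matrix(FALSE, nx, ny)
  lumen[cells] <- sol$lumen
  new_oxygen_field(grid, lumen, labels = NULL, h, h, x0, y0, params,
                   n_clamped = sol$clamped)
}

new_oxygen_field <- function(grid, lumen, labels, hx, hy, x0, y0, params,
                             n_clamped = 0L) {
  tissue <- !is.na(grid) & !lumen
  vals <- grid[tissue]
  structure(
    list(grid = grid, lumen = lumen, labels = labels,
         hx = hx, hy = hy, x0 = x0, y0 = y0, params = params,
         mean_PO2 = mean(vals), min_PO2 = min(vals),
         hypoxic_fraction = 100 * mean(vals < params$hypoxia_threshold),
         n_clamped = n_clamped),
    class = "oxygen_field"
  )
}

#' Solve the oxygen model over a whole sampling frame
#'
#' Partitions the frame grid into trapping regions by nearest-capillary
#' assignment (the raster counterpart of the Voronoi tessellation, so that
#' the per-domain grids tile the frame exactly), solves each domain
#' independently, and assembles the full-frame PO2 field with its
#' summaries: area-weighted mean tissue PO2, minimum PO2 and hypoxic
#' fraction, all over tissue cells (capillary-lumen cells excluded).
#'
#' @param tess The [tessellate()] result for `map` (consistency checked).
#' @param map The [capillary_map()].
#' @param params An [oxygen_params()].
#' @param h Grid step, micrometres (`h <= r_cap`).
#' @return An `oxygen_field` covering the frame, with `labels` giving each
#'   cell's domain (capillary) index.
#' @export
solve_frame <- function(tess, map, params, h = 1) {
  stopifnot(inherits(tess, "domain_tessellation"),
            inherits(map, "capillary_map"),
            inherits(params, "oxygen_params"))
  if (length(tess$domains) != n_capillaries(map)) {
    abort("tessellation does not match the map (domain/capillary counts differ)")
  }
  if (h > params$r_cap) abort("grid step `h` must not exceed the capillary radius")
  px <- assign_pixels_bruteforce(map, h)
  labels <- px$labels
  nx <- px$nx; ny <- px$ny
  grid <- matrix(NA_real_, nx, ny)
  lumen <- matrix(FALSE, nx, ny)
  n_clamped <- 0L
  cell_idx <- cbind(rep(seq_len(nx), times = ny), rep(seq_len(ny), each = nx))
  lab_vec <- as.integer(labels)
  for (i in seq_len(n_capillaries(map))) {
    cells <- cell_idx[lab_vec == i, , drop = FALSE]
    site <- c(map$capillaries$x_um[i], map$capillaries$y_um[i])
    sol <- tryCatch(
      solve_cells(cells, site, params, px$cell_width, px$cell_height),
      error = function(e) {
        abort(sprintf("oxygen solve failed on domain %d: %s", i,
                      conditionMessage(e)))
      }
    )
    grid[cells] <- sol$P
    lumen[cells] <- sol$lumen
    n_clamped <- n_clamped + sol$clamped
  }
  new_oxygen_field(grid, lumen, labels, px$cell_width, px$cell_height,
                   0, 0, params, n_clamped = n_clamped)
}

#' Hypoxic tissue fraction of a solved field
#'
#' Percentage of tissue cells (lumen excluded) with PO2 below `threshold`.
#'
#' @param field An `oxygen_field`.
#' @param threshold Cutoff in mmHg; defaults to the field's configured
#'   hypoxia threshold.
#' @return Percentage in `[0, 100]`.
#' @export
hypoxic_fraction <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "oxygen_field"))
  threshold <- threshold %||% field$params$hypoxia_threshold
  tissue <- !is.na(field$grid) & !field$lumen
  100 * mean(field$grid[tissue] < threshold)
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf(
    "<oxygen_field> %d x %d cells (h = %.3g um): mean PO2 %.2f mmHg, min %.2f, hypoxic %.3g%%\n",
    nrow(x$grid), ncol(x$grid), x$hx, x$mean_PO2, x$min_PO2,
    x$hypoxic_fraction))
  invisible(x)
}

#' @describeIn solve_frame Tidy cell-level table: one row per in-domain grid
#'   cell with centre coordinates, PO2, lumen flag and domain label.
#' @param x An `oxygen_field`.
#' @param ... Unused.
#' @export
tidy.oxygen_field <- function(x, ...) {
  nx <- nrow(x$grid); ny <- ncol(x$grid)
  keep <- !is.na(x$grid)
  idx <- which(keep, arr.ind = TRUE)
  tibble(
    x_um = x$x0 + (idx[, 1L] - 0.5) * x$hx,
    y_um = x$y0 + (idx[, 2L] - 0.5) * x$hy,
    po2_mmHg = x$grid[keep],
    lumen = x$lumen[keep],
    domain = if (is.null(x$labels)) NA_integer_ else as.integer(x$labels[keep])
  )
}

#' @describeIn solve_frame One-row field summary: mean/min PO2, hypoxic
#'   fraction, cell counts and clamp count.
#' @export
glance.oxygen_field <- function(x, ...) {
  tissue <- !is.na(x$grid) & !x$lumen
  tibble(
    mean_PO2_mmHg = x$mean_PO2,
    min_PO2_mmHg = x$min_PO2,
    hypoxic_fraction_pct = x$hypoxic_fraction,
    hypoxia_threshold_mmHg = x$params$hypoxia_threshold,
    n_tissue_cells = sum(tissue),
    n_lumen_cells = sum(x$lumen, na.rm = TRUE),
    n_clamped = x$n_clamped
  )
}

#' Write an oxygen-field summary to JSON
#'
#' @param field An `oxygen_field`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_oxygen_summary <- function(field, path) {
  jsonlite::write_json(as.list(glance(field)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
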