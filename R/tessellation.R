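#' Capillary-domain (trapping-region) tessellation
#'
#' Partitions the sampling frame into capillary domains: the Voronoi cell of
#' each capillary clipped to the frame rectangle. Each domain is the region
#' of tissue closer to its capillary than to any other — the "trapping
#' region" used both for local supply statistics (capillary domain area,
#' logSD heterogeneity) and as the closed geometric unit of the oxygen
#' transport model.
#'
#' Cells are computed by intersecting the frame rectangle with the
#' perpendicular-bisector half-planes against every other site, which is
#' exact for these convex cells and clips to the frame by construction
#' (unbounded cells of collinear or hull sites are handled the same way).
#'
#' @param map A [capillary_map()] with at least one capillary.
#' @return A `domain_tessellation`: one simple convex polygon per capillary
#'   (order matches the capillary table), exact shoelace areas (um^2), a
#'   boundary flag marking domains that touch the frame edge, and the frame
#'   dimensions.
#' @examples
#' m <- capillary_map(tibble::tibble(x_um = c(50, 50), y_um = c(50, 150)),
#'                    frame_width = 100, frame_height = 200)
#' tess <- tessellate(m)
#' domain_areas(tess)  # two 100 x 100 domains
#' @export
tessellate <- function(map) {
  stopifnot(inherits(map, "capillary_map"))
  n <- n_capillaries(map)
  if (n == 0) abort("cannot tessellate a map with zero capillaries")
  w <- map$frame_width
  h <- map$frame_height
  sx <- map$capillaries$x_um
  sy <- map$capillaries$y_um
  rect_x <- c(0, w, w, 0)
  rect_y <- c(0, 0, h, h)
  eps <- 1e-9 * max(w, h)

  domains <- vector("list", n)
  areas <- numeric(n)
  boundary <- logical(n)

  for (i in seq_len(n)) {
    px <- rect_x
    py <- rect_y
    if (n > 1) {
      d2 <- (sx - sx[i])^2 + (sy - sy[i])^2
      ord <- order(d2)
      ord <- ord[ord != i]
      # prune: a site farther than twice the current max vertex distance
      # cannot cut the cell
      r2max <- max((px - sx[i])^2 + (py - sy[i])^2)
      for (j in ord) {
        if (d2[j] > 4 * r2max) break
        mx <- (sx[i] + sx[j]) / 2
        my <- (sy[i] + sy[j]) / 2
        clipped <- clip_halfplane(px, py, mx, my, sx[j] - sx[i], sy[j] - sy[i])
        px <- clipped$x
        py <- clipped$y
        if (length(px) < 3) {
          abort(sprintf("degenerate (empty) domain for capillary %d", i))
        }
        r2max <- max((px - sx[i])^2 + (py - sy[i])^2)
      }
    }
    domains[[i]] <- tibble(x = px, y = py)
    areas[i] <- polygon_area(px, py)
    boundary[i] <- any(px < eps | px > w - eps | py < eps | py > h - eps)
  }

  structure(
    list(domains = domains, areas = areas, boundary_flags = boundary,
         source_index = seq_len(n), frame_width = w, frame_height = h,
         sites = tibble(x_um = sx, y_um = sy)),
    class = "domain_tessellation"
  )
}

#' @export
print.domain_tessellation <- function(x, ...) {
  cat(sprintf(
    "<domain_tessellation> %d domains, frame %.1f x %.1f um, total area %.6g um^2\n",
    length(x$domains), x$frame_width, x$frame_height, sum(x$areas)))
  invisible(x)
}

#' Domain areas of a tessellation
#' @param tess A `domain_tessellation`.
#' @return Numeric vector of areas (um^2), one per capillary.
#' @export
domain_areas <- function(tess) tess$areas

#' @describeIn tessellate Tidy per-domain summary: one row per domain with
#'   its source capillary index, area, vertex count and boundary flag.
#' @param x A `domain_tessellation`.
#' @param ... Unused.
#' @export
tidy.domain_tessellation <- function(x, ...) {
  tibble(
    source_index = x$source_index,
    area_um2 = x$areas,
    n_vertices = purrr::map_int(x$domains, nrow),
    boundary = x$boundary_flags
  )
}

#' @describeIn tessellate One-row summary: domain count, total area,
#'   relative area-conservation error against the frame.
#' @export
glance.domain_tessellation <- function(x, ...) {
  fa <- x$frame_width * x$frame_height
  tibble(
    n_domains = length(x$domains),
    total_area_um2 = sum(x$areas),
    frame_area_um2 = fa,
    area_conservation_rel_err = abs(sum(x$areas) - fa) / fa,
    n_boundary = sum(x$boundary_flags)
  )
}

#' Export a tessellation as GeoJSON
#'
#' One Polygon feature per domain with properties `area_um2`,
#' `boundary_flag` and `source_index`.
#'
#' @param tess A `domain_tessellation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tessellation_geojson <- function(tess, path) {
  feats <- purrr::imap(tess$domains, function(p, i) {
    ring <- purrr::map2(c(p$x, p$x[1L]), c(p$y, p$y[1L]), ~ c(.x, .y))
    list(
      type = "Feature",
      properties = list(area_um2 = tess$areas[i],
                        boundary_flag = tess$boundary_flags[i],
                        source_index = tess$source_index[i]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Brute-force nearest-capillary pixel assignment
#'
#' Independent raster oracle for the polygon tessellation: lays a uniform
#' grid over the frame and labels every cell centre with the index of its
#' nearest capillary (Euclidean distance, ties broken in favour of the
#' lowest capillary index). Cell size is adjusted marginally from
#' `resolution` so that the grid tiles the frame exactly.
#'
#' @param map A [capillary_map()].
#' @param resolution Nominal cell size in micrometres (> 0).
#' @return A `pixel_assignment`: integer label matrix (`nx` by `ny`, x
#'   index first) plus cell dimensions.
#' @export
assign_pixels_bruteforce <- function(map, resolution) {
  stopifnot(inherits(map, "capillary_map"), resolution > 0)
  n <- n_capillaries(map)
  if (n == 0) abort("map has no capillaries")
  w <- map$frame_width
  h <- map$frame_height
  nx <- max(1L, as.integer(round(w / resolution)))
  ny <- max(1L, as.integer(round(h / resolution)))
  cw <- w / nx
  ch <- h / ny
  gx <- (seq_len(nx) - 0.5) * cw
  gy <- (seq_len(ny) - 0.5) * ch
  sx <- map$capillaries$x_um
  sy <- map$capillaries$y_um

  labels <- matrix(1L, nx, ny)
  best <- outer((gx - sx[1L])^2, (gy - sy[1L])^2, `+`)
  if (n > 1) {
    for (i in 2:n) {
      d2 <- outer((gx - sx[i])^2, (gy - sy[i])^2, `+`)
      closer <- d2 < best   # strict: ties keep the lower index
      labels[closer] <- i
      best[closer] <- d2[closer]
    }
  }
  structure(
    list(labels = labels, cell_width = cw, cell_height = ch,
         nx = nx, ny = ny, n_sites = n),
    class = "pixel_assignment"
  )
}

#' Per-site areas from a pixel assignment
#'
#' @param px A `pixel_assignment`.
#' @return Numeric vector: label counts times cell area (um^2), one per site.
#' @export
pixel_areas <- function(px) {
  tabulate(px$labels, nbins = px$n_sites) * px$cell_width * px$cell_height
}
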