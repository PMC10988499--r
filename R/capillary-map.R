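#' Construct a capillary map
#'
#' A capillary map records the capillary transverse-section positions observed
#' in one rectangular histological sampling frame, optionally together with
#' the muscle-fibre outline polygons, for one region of a muscle (e.g. the
#' oxidative core or glycolytic cortex of the rat tibialis anterior).
#' Coordinates are continuous micrometres in a frame-local system with the
#' origin at the bottom-left corner.
#'
#' @param capillaries A data frame with numeric columns `x_um`, `y_um`; one
#'   row per capillary. All points must lie within the frame and be pairwise
#'   distinct (Voronoi tessellation requires distinct sites).
#' @param frame_width,frame_height Frame dimensions in micrometres. Defaults
#'   give a square frame of area 0.145 mm^2, the standard sampling-frame size
#'   for muscle capillary counting.
#' @param fibres Optional list of fibre outline polygons, each a data frame
#'   with columns `x`, `y` (micrometres) and optionally an attribute-like
#'   column is ignored; polygons must be simple with positive area. May also
#'   carry a `fiber_type` attribute per polygon.
#' @param region_label One of `"core"`, `"cortex"`, `"whole"`.
#' @param animal_id,group_label Free-text identifiers carried through to
#'   results tables.
#' @return An object of class `capillary_map`.
#' @examples
#' pts <- tibble::tibble(x_um = c(50, 150), y_um = c(100, 250))
#' m <- capillary_map(pts, frame_width = 300, frame_height = 300)
#' n_capillaries(m)
#' @export
capillary_map <- function(capillaries,
                          frame_width = default_frame_side(),
                          frame_height = default_frame_side(),
                          fibres = NULL,
                          region_label = c("whole", "core", "cortex"),
                          animal_id = NA_character_,
                          group_label = NA_character_) {
  region_label <- match.arg(region_label)
  stopifnot(is.numeric(frame_width), frame_width > 0,
            is.numeric(frame_height), frame_height > 0)
  capillaries <- as_tibble(capillaries)
  if (!all(c("x_um", "y_um") %in% names(capillaries))) {
    abort("`capillaries` must have columns `x_um` and `y_um`.")
  }
  capillaries <- capillaries[c("x_um", "y_um")]
  validate_points(capillaries, frame_width, frame_height)
  if (!is.null(fibres)) validate_fibres(fibres)
  structure(
    list(
      frame_width = as.numeric(frame_width),
      frame_height = as.numeric(frame_height),
      capillaries = capillaries,
      fibres = fibres,
      region_label = region_label,
      animal_id = animal_id,
      group_label = group_label
    ),
    class = "capillary_map"
  )
}

#' Side length (micrometres) of the default square sampling frame
#'
#' The default frame has area 0.145 mm^2, so the side is
#' `sqrt(0.145) * 1000` = 380.789 um.
#' @return Length-one numeric, micrometres.
#' @export
default_frame_side <- function() sqrt(0.145) * 1000

#' @export
print.capillary_map <- function(x, ...) {
  cat(sprintf(
    "<capillary_map> %d capillaries, %s fibres, frame %.1f x %.1f um (%s)\n",
    nrow(x$capillaries),
    if (is.null(x$fibres)) "no" else length(x$fibres),
    x$frame_width, x$frame_height, x$region_label
  ))
  invisible(x)
}

#' Number of capillaries in a map
#' @param map A `capillary_map`.
#' @return Integer count.
#' @export
n_capillaries <- function(map) nrow(map$capillaries)

#' Frame area of a capillary map
#' @param map A `capillary_map`.
#' @param unit `"um2"` or `"mm2"`.
#' @return Numeric area.
#' @export
frame_area <- function(map, unit = c("um2", "mm2")) {
  unit <- match.arg(unit)
  a <- map$frame_width * map$frame_height
  if (unit == "mm2") a / 1e6 else a
}

validate_points <- function(pts, w, h) {
  if (nrow(pts) == 0) return(invisible(pts))
  if (anyNA(pts$x_um) || anyNA(pts$y_um)) {
    abort("capillary coordinates contain missing values")
  }
  out <- which(pts$x_um < 0 | pts$x_um > w | pts$y_um < 0 | pts$y_um > h)
  if (length(out)) {
    abort(sprintf(
      "capillary point outside frame at row %d: (%.6g, %.6g), frame %g x %g um",
      out[1L], pts$x_um[out[1L]], pts$y_um[out[1L]], w, h
    ))
  }
  dup <- which(duplicated(pts[c("x_um", "y_um")]))
  if (length(dup)) {
    abort(sprintf(
      "duplicate capillary point at row %d: (%.6g, %.6g); sites must be distinct",
      dup[1L], pts$x_um[dup[1L]], pts$y_um[dup[1L]]
    ))
  }
  invisible(pts)
}

validate_fibres <- function(fibres) {
  if (!is.list(fibres)) abort("`fibres` must be a list of polygons")
  for (i in seq_along(fibres)) {
    p <- fibres[[i]]
    if (!all(c("x", "y") %in% names(p))) {
      abort(sprintf("fibre polygon %d lacks `x`/`y` columns", i))
    }
    if (nrow(as.data.frame(p)) < 3 || polygon_area(p$x, p$y) <= 0) {
      abort(sprintf("fibre polygon %d is degenerate (area <= 0)", i))
    }
    if (polygon_self_intersects(p$x, p$y)) {
      abort(sprintf("fibre polygon %d is self-intersecting", i))
    }
  }
  invisible(fibres)
}

# Brute-force simple-polygon check: no two non-adjacent edges intersect.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  x2 <- c(x, x[1L]); y2 <- c(y, y[1L])
  seg_int <- function(a, b) {
    p1 <- c(x2[a], y2[a]); p2 <- c(x2[a + 1L], y2[a + 1L])
    p3 <- c(x2[b], y2[b]); p4 <- c(x2[b + 1L], y2[b + 1L])
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (a in seq_len(n - 2L)) {
    for (b in seq.int(a + 2L, n)) {
      if (a == 1L && b == n) next  # adjacent through closure
      if (seg_int(a, b)) return(TRUE)
    }
  }
  FALSE
}

#' Read a capillary map from CSV (optionally with a fibre GeoJSON sidecar)
#'
#' The CSV must have header columns `x_um,y_um`. Coordinates are used as-is
#' (no rescaling). Validation errors name the offending row.
#'
#' @param path Path to the capillary CSV.
#' @param frame_width,frame_height Frame dimensions in micrometres.
#' @param fibres_path Optional path to a GeoJSON FeatureCollection of fibre
#'   outline Polygons (property `fiber_type` retained when present).
#' @inheritParams capillary_map
#' @return A validated [capillary_map()].
#' @export
read_capillary_map <- function(path,
                               frame_width = default_frame_side(),
                               frame_height = default_frame_side(),
                               fibres_path = NULL,
                               region_label = "whole",
                               animal_id = NA_character_,
                               group_label = NA_character_) {
  # parse via strtod (correctly rounded) so write/read round trips are
  # bit-exact
  pts <- readr::read_csv(path, col_types = readr::cols(
    x_um = readr::col_character(), y_um = readr::col_character()
  ), progress = FALSE)
  pts$x_um <- as.numeric(pts$x_um)
  pts$y_um <- as.numeric(pts$y_um)
  fibres <- if (!is.null(fibres_path)) read_fibres_geojson(fibres_path)
  capillary_map(pts, frame_width, frame_height, fibres = fibres,
                region_label = region_label, animal_id = animal_id,
                group_label = group_label)
}

#' Write a capillary map's point table to CSV
#'
#' Writes the `x_um,y_um` table at full precision so that a write/read round
#' trip is lossless.
#'
#' @param map A `capillary_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_capillary_map <- function(map, path) {
  write_csv_full(map$capillaries, path)
  invisible(path)
}

# CSV writer with doubles rendered at 17 significant digits, the shortest
# representation guaranteed to round-trip bit-exactly
write_csv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' Read fibre outlines from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file of Polygon features; optional property
#'   `fiber_type` is attached to each polygon as an attribute.
#' @return List of polygons (tibbles with `x`, `y` in micrometres).
#' @export
read_fibres_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("fibre GeoJSON must be a FeatureCollection")
  }
  purrr::map(gj$features, function(f) {
    if (f$geometry$type != "Polygon") abort("fibre features must be Polygons")
    ring <- f$geometry$coordinates[[1L]]
    xy <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))))
    # drop closing vertex if repeated
    n <- nrow(xy)
    if (n > 1 && all(xy[1L, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
    p <- tibble(x = xy[, 1L], y = xy[, 2L])
    ft <- f$properties$fiber_type
    if (!is.null(ft)) attr(p, "fiber_type") <- ft
    p
  })
}

#' Write fibre outlines to GeoJSON
#'
#' @param fibres List of polygons (`x`, `y` columns), as stored in a
#'   `capillary_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fibres_geojson <- function(fibres, path) {
  feats <- purrr::map(fibres, function(p) {
    ring <- purrr::map2(c(p$x, p$x[1L]), c(p$y, p$y[1L]), ~ c(.x, .y))
    props <- if (!is.null(attr(p, "fiber_type"))) {
      list(fiber_type = attr(p, "fiber_type"))
    } else {
      stats::setNames(list(), character(0))
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Generic results writer used by every stage: stable column order, full
#' float precision, and a hard error (rather than an empty file) on an empty
#' record set.
#'
#' @param records A non-empty data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) abort("refusing to write an empty results table")
  write_csv_full(records, path)
  invisible(path)
}
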