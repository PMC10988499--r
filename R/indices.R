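#' Global capillary supply indices
#'
#' Computes the classical global indices from a capillary map: capillary
#' density (CD, capillaries per mm^2 of frame), capillary-to-fibre ratio
#' (C:F) and mean fibre cross-sectional area (CSA, um^2). Fibres are counted
#' with an unbiased (Gundersen forbidden-line) counting frame: fibres whose
#' outline intersects the left or bottom frame edge are excluded, those
#' touching only the right or top edge are included; CSA averages the whole
#' polygon area of counted fibres.
#'
#' @param map A [capillary_map()]. C:F and CSA require fibre outlines; when
#'   absent they are reported as `NA` and only CD is computed.
#' @param counting_rule `"forbidden_line"` (default, unbiased) or `"all"`
#'   (count every fibre whose polygon intersects the frame).
#' @return One-row tibble: `region`, `n_capillaries`, `n_fibres_counted`,
#'   `CF`, `CD_per_mm2`, `CSA_um2`.
#' @examples
#' m <- capillary_map(tibble::tibble(x_um = 50, y_um = 50),
#'                    frame_width = 100, frame_height = 100)
#' compute_global_indices(m)$CD_per_mm2  # 1 capillary / 0.01 mm^2 = 100
#' @export
compute_global_indices <- function(map, counting_rule = c("forbidden_line", "all")) {
  stopifnot(inherits(map, "capillary_map"))
  counting_rule <- match.arg(counting_rule)
  ncap <- n_capillaries(map)
  if (ncap == 0) abort("map has no capillaries")
  cd <- ncap / frame_area(map, "mm2")
  if (is.null(map$fibres) || length(map$fibres) == 0) {
    return(tibble(region = map$region_label, n_capillaries = ncap,
                  n_fibres_counted = NA_integer_, CF = NA_real_,
                  CD_per_mm2 = cd, CSA_um2 = NA_real_))
  }
  counted <- purrr::map_lgl(map$fibres, function(p) {
    count_fibre(p, map$frame_width, map$frame_height, counting_rule)
  })
  nf <- sum(counted)
  csa <- if (nf > 0) {
    mean(purrr::map_dbl(map$fibres[counted], ~ polygon_area(.x$x, .x$y)))
  } else {
    NA_real_
  }
  tibble(region = map$region_label, n_capillaries = ncap,
         n_fibres_counted = as.integer(nf),
         CF = if (nf > 0) ncap / nf else NA_real_,
         CD_per_mm2 = cd, CSA_um2 = csa)
}

# Forbidden-line rule: exclude fibres crossing the left (x = 0) or bottom
# (y = 0) frame edges; include those inside or crossing only right/top.
count_fibre <- function(p, w, h, rule) {
  inside_any <- any(p$x > 0 & p$x < w & p$y > 0 & p$y < h)
  if (!inside_any) return(FALSE)
  if (rule == "all") return(TRUE)
  !(any(p$x < 0) || any(p$y < 0))
}

#' Local capillary supply indices
#'
#' Capillary domain area (CDA) statistics from a trapping-region
#' tessellation: arithmetic mean CDA, the logSD heterogeneity index (sample
#' standard deviation, n - 1 denominator, of natural-log-transformed domain
#' areas) and a binned CDA frequency distribution. logSD is dimensionless
#' and invariant to spatial rescaling and to the area unit; switching log
#' base would only rescale it by a constant.
#'
#' @param tess A [tessellate()] result.
#' @param bins CDA histogram bin edges in um^2 (default 100 um^2 bins from 0
#'   to 3000, with a final open bin for larger domains).
#' @param exclude_boundary_domains If `TRUE`, domains touching the frame
#'   edge are dropped from all statistics (reduces edge bias at the cost of
#'   exact area conservation). Default `FALSE`.
#' @return A list with `summary` (one-row tibble: `n_domains`, `CDA_mean_um2`,
#'   `logSD`) and `domain_hist` (tibble of bin edges and counts). With a
#'   single included domain logSD is reported `NA`.
#' @export
compute_local_indices <- function(tess, bins = seq(0, 3000, by = 100),
                                  exclude_boundary_domains = FALSE) {
  stopifnot(inherits(tess, "domain_tessellation"))
  areas <- tess$areas
  if (exclude_boundary_domains) areas <- areas[!tess$boundary_flags]
  if (length(areas) == 0) abort("no domains left after boundary exclusion")
  cda_mean <- mean(areas)
  logsd <- if (length(areas) >= 2) sd(log(areas)) else NA_real_
  edges <- sort(unique(c(bins, Inf)))
  counts <- as.integer(table(cut(areas, breaks = edges, right = FALSE,
                                 include.lowest = TRUE)))
  list(
    summary = tibble(n_domains = length(areas), CDA_mean_um2 = cda_mean,
                     logSD = logsd),
    domain_hist = tibble(bin_lower_um2 = head(edges, -1L),
                         bin_upper_um2 = tail(edges, -1L),
                         count = counts)
  )
}

#' Core:cortex ratio of supply indices
#'
#' Element-wise core/cortex ratios used to express whole-muscle phenotype
#' shifts: a ratio of 1 means the two compartments match for that index.
#'
#' @param core,cortex One-row data frames of indices (any shared numeric
#'   columns, e.g. `CF`, `CD_per_mm2`, `CSA_um2`, `CDA_mean_um2`, `logSD`,
#'   `mean_PO2_mmHg`).
#' @return One-row tibble of core/cortex ratios for every shared numeric
#'   column.
#' @export
core_cortex_ratio <- function(core, cortex) {
  core <- as_tibble(core)
  cortex <- as_tibble(cortex)
  if (nrow(core) != 1 || nrow(cortex) != 1) {
    abort("`core` and `cortex` must be one-row index tables")
  }
  shared <- intersect(names(core), names(cortex))
  shared <- shared[purrr::map_lgl(shared, function(nm) {
    is.numeric(core[[nm]]) && is.numeric(cortex[[nm]])
  })]
  if (length(shared) == 0) abort("no shared numeric index columns")
  vals <- purrr::map_dbl(shared, function(nm) {
    den <- cortex[[nm]]
    if (is.na(den) || is.na(core[[nm]])) return(NA_real_)
    if (den == 0) abort(sprintf("zero cortex value for index `%s`", nm))
    core[[nm]] / den
  })
  as_tibble(as.list(setNames(vals, shared)))
}

#' Percent change between a control and a treated value
#'
#' `100 * (treated - control) / control`, reported at full precision and
#' rounded to the nearest integer (the form usually printed for group-mean
#' contrasts, e.g. capillary-density increases after stimulation).
#'
#' @param control Control value (> 0).
#' @param treated Treated value.
#' @return One-row tibble: `control`, `treated`, `percent_change`,
#'   `percent_change_rounded`.
#' @examples
#' percent_change(533, 921)$percent_change_rounded   # 73
#' percent_change(533, 1120)$percent_change_rounded  # 110
#' @export
percent_change <- function(control, treated) {
  if (!is.numeric(control) || any(control <= 0)) {
    abort("`control` must be strictly positive")
  }
  pc <- 100 * (treated - control) / control
  tibble(control = control, treated = treated,
         percent_change = pc,
         percent_change_rounded = round(pc))
}
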