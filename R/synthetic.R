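#' Phenotype specification for synthetic muscle cross-sections
#'
#' Parameter bundle for the cross-section generator: target capillary
#' density, mean fibre size, fibre-size variability and spatial jitter.
#' Two presets encode the control phenotypes of the two compartments of the
#' rat tibialis anterior: the oxidative core (high capillary density, small
#' fibres; CD 984 mm^-2) and the glycolytic cortex (low capillary density,
#' large fibres; CD 533 mm^-2). Preset mean fibre areas are chosen for
#' internal consistency with the printed capillary-to-fibre ratios via
#' CSA ~ C:F / CD (core ~1870 um^2, cortex ~2758 um^2).
#'
#' @param target_CD Target capillary density, capillaries per mm^2 (> 0).
#' @param fibre_CSA_mean Mean fibre cross-sectional area, um^2.
#' @param fibre_CSA_cv Nominal coefficient of variation of fibre size; the
#'   realised variability emerges from `jitter`.
#' @param jitter Lattice perturbation as a fraction of the fibre lattice
#'   spacing, in `[0, 1]`; the spatial-heterogeneity control (0 gives a
#'   perfect honeycomb with logSD ~ 0).
#' @param frame_area_mm2 Sampling-frame area (square frame), mm^2.
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(target_CD, fibre_CSA_mean, fibre_CSA_cv = 0.2,
                           jitter = 0.15, frame_area_mm2 = 0.145) {
  stopifnot(target_CD > 0, fibre_CSA_mean > 0, jitter >= 0, jitter <= 1,
            frame_area_mm2 > 0)
  structure(list(target_CD = target_CD, fibre_CSA_mean = fibre_CSA_mean,
                 fibre_CSA_cv = fibre_CSA_cv, jitter = jitter,
                 frame_area_mm2 = frame_area_mm2),
            class = "phenotype_spec")
}

#' @rdname phenotype_spec
#' @param preset `"core"` or `"cortex"`.
#' @param ... Overrides passed to [phenotype_spec()].
#' @export
phenotype_preset <- function(preset = c("core", "cortex"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    core = list(target_CD = 984, fibre_CSA_mean = 1870),
    cortex = list(target_CD = 533, fibre_CSA_mean = 2758)
  )
  do.call(phenotype_spec, utils::modifyList(defaults, list(...)))
}

#' Per-group effect specification
#'
#' Planted ground-truth effects for the synthetic study: per-group
#' multipliers for capillary density and fibre size in each compartment,
#' fatigue-index targets, hyperaemia targets and metabolite fold changes.
#' The default preset encodes the headline stimulated-group effects of a
#' 7-day pacing study: cortex CD multiplied by 1.728 / 2.101 / 1.556 at
#' 4 / 10 / 40 Hz (533 -> 921 / 1120 / 829 mm^-2), core CD 1.382 at 10 Hz
#' (984 -> 1360), FI 0.47 (control) rising to 0.58 / 0.75 / 0.82, doubling
#' of kynurenic acid and a 50% glutamate rise at 10 Hz, among others.
#'
#' @param cd_multiplier Tibble `group, core, cortex` of CD multipliers.
#' @param csa_multiplier Tibble `group, core, cortex` of fibre-CSA
#'   multipliers.
#' @param fi_target Named numeric: target fatigue index (ratio) per group.
#' @param hyperaemia_target Named numeric: target peak/resting flow ratio
#'   per group.
#' @param metabolite_folds Tibble `compound, group, fold` of planted
#'   arithmetic-mean fold changes (unlisted pairs default to fold 1).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(cd_multiplier = NULL, csa_multiplier = NULL,
                        fi_target = NULL, hyperaemia_target = NULL,
                        metabolite_folds = NULL) {
  groups <- c("CT", "4Hz", "10Hz3", "10Hz", "40Hz")
  if (is.null(cd_multiplier)) {
    cd_multiplier <- tibble(
      group = c("CT", "4Hz", "10Hz", "40Hz"),
      core = c(1, 1, 1360 / 984, 1),
      cortex = c(1, 921 / 533, 1120 / 533, 829 / 533)
    )
  }
  if (is.null(csa_multiplier)) {
    csa_multiplier <- tibble(
      group = c("CT", "4Hz", "10Hz", "40Hz"),
      core = c(1, 1, 1, 1),
      cortex = c(1, 1, 0.81, 0.91)
    )
  }
  if (is.null(fi_target)) {
    fi_target <- c(CT = 0.47, `4Hz` = 0.58, `10Hz` = 0.75, `40Hz` = 0.82)
  }
  if (is.null(hyperaemia_target)) {
    hyperaemia_target <- c(CT = 3, `4Hz` = 3, `10Hz` = 3, `40Hz` = 3)
  }
  if (is.null(metabolite_folds)) {
    metabolite_folds <- dplyr::tribble(
      ~compound,            ~group,   ~fold,
      "kynurenic_acid",     "10Hz3",  1.5,
      "kynurenic_acid",     "10Hz",   2.0,
      "glutamate",          "10Hz",   1.5,
      "carnitine",          "4Hz",    1.5,
      "beta_alanine",       "4Hz",    1.25,
      "beta_alanine",       "40Hz",   1.25,
      "anserine",           "4Hz",    2.0,
      "anserine",           "10Hz3",  1.6,
      "anserine",           "10Hz",   1.6,
      "anserine",           "40Hz",   2.0,
      "methylhistidine_1",  "4Hz",    2.0,
      "methylhistidine_1",  "10Hz3",  2.0,
      "methylhistidine_1",  "10Hz",   2.0,
      "methylhistidine_1",  "40Hz",   2.0,
      "lysine",             "10Hz3",  0.5,
      "malate",             "10Hz3",  1.2,
      "oxaloacetate",       "4Hz",    0.8,
      "oxaloacetate",       "10Hz",   0.8,
      "oxaloacetate",       "40Hz",   0.75,
      "tmaba",              "4Hz",    1.2
    )
  }
  stopifnot(all(cd_multiplier$core > 0), all(cd_multiplier$cortex > 0),
            all(csa_multiplier$core > 0), all(csa_multiplier$cortex > 0),
            all(fi_target > 0), all(fi_target <= 1),
            all(hyperaemia_target > 0), all(metabolite_folds$fold > 0))
  structure(list(groups = groups, cd_multiplier = cd_multiplier,
                 csa_multiplier = csa_multiplier, fi_target = fi_target,
                 hyperaemia_target = hyperaemia_target,
                 metabolite_folds = metabolite_folds),
            class = "effect_spec")
}

#' Generate a synthetic muscle cross-section
#'
#' Emulates a histological sampling frame: fibre centres sit on a hexagonal
#' lattice scaled so each Voronoi cell has the target mean fibre area,
#' perturbed by Gaussian jitter (SD = `jitter` x lattice spacing); fibre
#' outlines are the Voronoi cells of the perturbed centres; capillaries are
#' placed at fibre-boundary triple points (the anatomical position of
#' capillaries in the interstitium between fibres) and thinned by Bernoulli
#' sampling so the expected capillary count equals
#' `target_CD * frame_area`. Strongly angiogenic phenotypes (more than two
#' capillaries per fibre) exceed the triple-point supply; the generator then
#' keeps every triple point and recruits fibre-edge midpoints as secondary
#' interstitial sites, preserving the expected count. Deterministic given
#' `(spec, seed)`.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed fixing all randomness.
#' @param region_label,animal_id,group_label Metadata for the returned map.
#' @param thinning If `FALSE`, keep a capillary at every triple point
#'   (ignoring `target_CD`); with `jitter = 0` this yields the perfect
#'   honeycomb capillary lattice (interior-domain logSD ~ 0).
#' @return A [capillary_map()] with fibre outlines attached.
#' @export
generate_cross_section <- function(spec, seed = 1L, region_label = "whole",
                                   animal_id = NA_character_,
                                   group_label = NA_character_,
                                   thinning = TRUE) {
  stopifnot(inherits(spec, "phenotype_spec"))
  set.seed(seed)
  side <- sqrt(spec$frame_area_mm2) * 1000
  # hexagonal lattice: Voronoi cell area = sqrt(3)/2 * a^2 for spacing a
  a <- sqrt(2 * spec$fibre_CSA_mean / sqrt(3))
  margin <- 2.5 * a
  dy <- a * sqrt(3) / 2
  ys <- seq(-margin, side + margin, by = dy)
  centres <- purrr::imap_dfr(ys, function(y, irow) {
    off <- if (irow %% 2L == 0L) a / 2 else 0
    xs <- seq(-margin + off, side + margin, by = a)
    tibble(x = xs, y = y)
  })
  centres$x <- centres$x + rnorm(nrow(centres), sd = spec$jitter * a)
  centres$y <- centres$y + rnorm(nrow(centres), sd = spec$jitter * a)
  # jitter can push outermost centres off the extended frame; drop them
  ok <- centres$x > -margin & centres$x < side + margin &
    centres$y > -margin & centres$y < side + margin
  centres <- centres[ok, ]

  # fibre outlines = Voronoi cells of the centres on the extended frame
  ext <- side + 2 * margin
  ext_map <- capillary_map(
    tibble(x_um = centres$x + margin, y_um = centres$y + margin),
    frame_width = ext, frame_height = ext
  )
  ext_tess <- tessellate(ext_map)
  fibres <- purrr::map(ext_tess$domains,
                       ~ tibble(x = .x$x - margin, y = .x$y - margin))
  # keep fibres overlapping the frame; drop cells clipped by the extended
  # boundary (edge artefacts of the enlarged tessellation)
  keep <- purrr::map_lgl(seq_along(fibres), function(i) {
    p <- fibres[[i]]
    !ext_tess$boundary_flags[i] &&
      any(p$x > 0 & p$x < side & p$y > 0 & p$y < side)
  })
  fibres <- fibres[keep]

  # capillary candidates: fibre-boundary triple points inside the frame
  vx <- unlist(purrr::map(fibres, "x"))
  vy <- unlist(purrr::map(fibres, "y"))
  key <- paste(round(vx, 6), round(vy, 6))
  first <- !duplicated(key)
  vx <- vx[first]; vy <- vy[first]
  inside <- vx > 0 & vx < side & vy > 0 & vy < side
  vx <- vx[inside]; vy <- vy[inside]
  n_vert <- length(vx)

  if (thinning) {
    target_n <- spec$target_CD * spec$frame_area_mm2
    if (target_n <= n_vert) {
      take <- as.logical(rbinom(n_vert, 1L, target_n / n_vert))
      if (sum(take) == 0) take[sample.int(n_vert, 1L)] <- TRUE
      vx <- vx[take]; vy <- vy[take]
    } else {
      # angiogenic phenotypes can exceed one capillary per triple point
      # (capillary-to-fibre ratio > 2): recruit fibre-edge midpoints as
      # secondary interstitial sites
      mx <- unlist(purrr::map(fibres, ~ (.x$x + c(.x$x[-1L], .x$x[1L])) / 2))
      my <- unlist(purrr::map(fibres, ~ (.x$y + c(.x$y[-1L], .x$y[1L])) / 2))
      mkey <- paste(round(mx, 6), round(my, 6))
      mfirst <- !duplicated(mkey)
      mx <- mx[mfirst]; my <- my[mfirst]
      min_frame <- mx > 0 & mx < side & my > 0 & my < side
      mx <- mx[min_frame]; my <- my[min_frame]
      if (target_n > n_vert + length(mx)) {
        abort(sprintf(
          "target CD %.0f mm^-2 needs %.1f capillaries but only %d candidate sites are available; use smaller fibres",
          spec$target_CD, target_n, n_vert + length(mx)))
      }
      p2 <- (target_n - n_vert) / length(mx)
      take2 <- as.logical(rbinom(length(mx), 1L, p2))
      vx <- c(vx, mx[take2]); vy <- c(vy, my[take2])
    }
  }
  capillary_map(tibble(x_um = vx, y_um = vy),
                frame_width = side, frame_height = side,
                fibres = fibres, region_label = region_label,
                animal_id = animal_id, group_label = group_label)
}

#' Generate a synthetic twitch-train tension trace
#'
#' Raised-cosine twitches at the stimulation frequency for the duration of
#' the protocol, with peak amplitude decaying exponentially from 1.0 at the
#' first twitch to `FI_target` at the last, multiplicative Gaussian noise
#' on each twitch amplitude, and quiet pre/post baseline segments.
#'
#' @param freq Stimulation frequency, Hz.
#' @param duration Stimulation duration, seconds (default 180 s = 3 min).
#' @param FI_target Planted fatigue index (final/peak tension), in `(0, 1]`.
#' @param noise_sd Multiplicative amplitude noise SD (fraction).
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz.
#' @param pre_s,post_s Baseline durations before/after stimulation.
#' @return A [tension_trace()].
#' @export
generate_tension_trace <- function(freq = 10, duration = 180, FI_target = 0.75,
                                   noise_sd = 0.02, seed = 1L, fs = 500,
                                   pre_s = 5, post_s = 5) {
  stopifnot(FI_target > 0, FI_target <= 1, freq > 0, duration > 0)
  set.seed(seed)
  total <- pre_s + duration + post_s
  time <- seq(0, total, by = 1 / fs)
  y <- numeric(length(time))
  n_tw <- floor(duration * freq)
  tw_width <- min(0.08, 0.9 / freq)
  decay <- if (n_tw > 1) FI_target^(1 / (n_tw - 1)) else 1
  amp <- decay^(seq_len(n_tw) - 1L)
  amp <- amp * (1 + rnorm(n_tw, sd = noise_sd))
  half <- as.integer(round(tw_width * fs / 2))
  prof <- 0.5 * (1 - cos(2 * pi * seq(0, 2 * half) / (2 * half)))
  for (k in seq_len(n_tw)) {
    i0 <- as.integer(round((pre_s + (k - 1) / freq) * fs)) + 1L
    idx <- i0:(i0 + 2L * half)
    idx <- idx[idx <= length(y)]
    y[idx] <- pmax(y[idx], amp[k] * prof[seq_along(idx)])
  }
  y[y < 0] <- 0
  tension_trace(time, y, stimulation_window = c(pre_s, pre_s + duration))
}

#' Generate a synthetic hyperaemia flow trace
#'
#' Blood flow rising logistically from baseline towards
#' `baseline * peak_ratio`, with the time-to-peak set by the stimulation
#' mode — at the end of the 3-min window for 4 Hz, mid-window for 10 Hz,
#' and after the window ends for 40 Hz (fatigue-attenuated stenosis) — then
#' returning exponentially to baseline. Constant arterial pressure is
#' attached so conductance equals flow up to a scale factor.
#'
#' @param baseline Resting flow, ml/min (> 0).
#' @param peak_ratio Planted peak/resting flow ratio (>= 1).
#' @param kinetics `"4Hz"`, `"10Hz"` or `"40Hz"`.
#' @param noise_sd Multiplicative flow noise SD (fraction).
#' @param seed Integer seed.
#' @param stim_duration Stimulation duration, seconds.
#' @param pre_s,post_s Baseline/recovery durations, seconds.
#' @param fs Sampling rate, Hz.
#' @param pressure_mmHg Constant arterial pressure attached to the trace.
#' @return A [flow_trace()].
#' @export
generate_flow_trace <- function(baseline = 1, peak_ratio = 3,
                                kinetics = c("4Hz", "10Hz", "40Hz"),
                                noise_sd = 0.05, seed = 1L,
                                stim_duration = 180, pre_s = 60, post_s = 120,
                                fs = 10, pressure_mmHg = 100) {
  kinetics <- match.arg(kinetics)
  stopifnot(baseline > 0, peak_ratio >= 1)
  set.seed(seed)
  total <- pre_s + stim_duration + post_s
  time <- seq(0, total, by = 1 / fs)
  w0 <- pre_s
  w1 <- pre_s + stim_duration
  t_peak <- switch(kinetics,
    "4Hz" = w1,
    "10Hz" = (w0 + w1) / 2,
    "40Hz" = w1 + 30
  )
  scale <- (t_peak - w0) / 8
  rise <- 1 / (1 + exp(-(time - (w0 + t_peak) / 2) / scale))
  rise <- rise / (1 / (1 + exp(-(t_peak - (w0 + t_peak) / 2) / scale)))
  shape <- ifelse(time <= t_peak, rise, exp(-(time - t_peak) / 30))
  shape[time < w0] <- 0
  flow <- baseline * (1 + (peak_ratio - 1) * shape)
  flow <- pmax(0, flow * (1 + rnorm(length(flow), sd = noise_sd)))
  flow_trace(time, flow, pressure = rep(pressure_mmHg, length(time)),
             stimulation_window = c(w0, w1))
}

#' Generate a synthetic metabolite matrix with planted fold changes
#'
#' Log-normal intensities per compound and sample:
#' `ln(intensity) ~ Normal(ln(base * fold) - sigma_log^2 / 2, sigma_log)`,
#' so that the arithmetic group mean equals `base * fold` in expectation
#' (the log-normal mean correction). Per-compound base intensities are
#' drawn once (log-normal around 1e6) from the same seed; fold defaults to
#' 1 for any compound/group pair not listed in `effects`.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param compounds Character vector of compound ids, or a count (ids
#'   `compound_1..n`). Compounds named in `effects` are appended if absent.
#' @param effects An [effect_spec()] (its `metabolite_folds` table is used)
#'   or a `compound, group, fold` data frame; `NULL` for no effects.
#' @param sigma_log Log-scale noise SD.
#' @param seed Integer seed.
#' @param groups Group labels to generate.
#' @return A [metabolite_matrix()].
#' @export
generate_metabolome <- function(n_per_group = 5, compounds = 240,
                                effects = effect_spec(), sigma_log = 0.2,
                                seed = 1L,
                                groups = c("CT", "4Hz", "10Hz3", "10Hz", "40Hz")) {
  stopifnot(n_per_group >= 2)
  set.seed(seed)
  folds <- if (is.null(effects)) {
    tibble(compound = character(), group = character(), fold = numeric())
  } else if (inherits(effects, "effect_spec")) {
    effects$metabolite_folds
  } else {
    as_tibble(effects)
  }
  if (is.numeric(compounds)) compounds <- paste0("compound_", seq_len(compounds))
  compounds <- union(compounds, folds$compound)
  m <- length(compounds)
  base <- exp(rnorm(m, mean = log(1e6), sd = 1))
  names(base) <- compounds

  rows <- list()
  glabels <- character(0)
  for (g in groups) {
    fold <- setNames(rep(1, m), compounds)
    fg <- folds[folds$group == g & folds$compound %in% compounds, ]
    if (nrow(fg)) fold[fg$compound] <- fg$fold
    mu <- log(base * fold) - sigma_log^2 / 2
    block <- matrix(
      exp(rnorm(n_per_group * m, mean = rep(mu, each = n_per_group),
                sd = sigma_log)),
      nrow = n_per_group, ncol = m
    )
    rows[[g]] <- block
    glabels <- c(glabels, rep(g, n_per_group))
  }
  intens <- do.call(rbind, rows)
  colnames(intens) <- compounds
  metabolite_matrix(intens, glabels)
}
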