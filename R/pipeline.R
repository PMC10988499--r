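#' Pipeline configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Unknown keys are
#' rejected; the effective configuration is echoed into the run manifest.
#'
#' @param seed Root integer seed; every stage derives its randomness from
#'   it.
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite`).
#' @param groups Stimulation groups to simulate (subset of the effect-spec
#'   groups; first is treated as control).
#' @param n_animals Animals per group.
#' @param mode Oxygen consumption mode, `"rest"` or `"exercise"`.
#' @param h Oxygen-model grid step, um.
#' @param oxygen Named list of [oxygen_params()] overrides (e.g.
#'   `list(M0 = 2e-4)`).
#' @param n_compounds Compounds in the synthetic metabolome.
#' @param n_per_group Metabolome samples per group.
#' @param sigma_log Metabolome log-scale noise SD.
#' @param exclude_boundary_domains Drop frame-edge domains from CDA/logSD
#'   statistics.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("capdomain_run_"),
                            groups = c("CT", "10Hz"),
                            n_animals = 2L,
                            mode = "exercise",
                            h = 1.5,
                            oxygen = list(),
                            n_compounds = 60L,
                            n_per_group = 5L,
                            sigma_log = 0.2,
                            exclude_boundary_domains = FALSE,
                            overwrite = FALSE) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, groups = groups,
              n_animals = as.integer(n_animals), mode = mode, h = h,
              oxygen = oxygen, n_compounds = as.integer(n_compounds),
              n_per_group = as.integer(n_per_group), sigma_log = sigma_log,
              exclude_boundary_domains = exclude_boundary_domains,
              overwrite = overwrite)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) abort(paste("unknown config keys:", paste(extra, collapse = ", ")))
  if (!is.list(cfg$oxygen)) abort("`oxygen` must be a named list of overrides")
  ox_known <- setdiff(names(formals(oxygen_params)), "mode")
  ox_extra <- setdiff(names(cfg$oxygen), ox_known)
  if (length(ox_extra)) {
    abort(paste("unknown oxygen parameter overrides:",
                paste(ox_extra, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full demonstration pipeline
#'
#' End-to-end analysis on synthetic data: generates core and cortex
#' cross-sections per animal and group (with the preset planted effects),
#' tessellates them, computes global and local supply indices, solves the
#' oxygen model per frame, forms per-animal core:cortex ratios, analyses
#' group differences (ANOVA + Tukey on cortex capillary density), computes
#' fatigue indices and hyperaemia ratios from synthetic traces, and builds
#' a control-vs-treated metabolomics volcano table. All numeric outputs are
#' written to `config$out_dir` as CSV/JSON/GeoJSON together with a run
#' manifest (seed, configuration, package version), and the same tables are
#' returned invisibly as a list. Parameters are validated before any
#' computation; a stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a named list of result tibbles:
#'   `indices`, `ratios`, `anova_cd_cortex`, `fatigue`, `hyperaemia`,
#'   `volcano`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- do.call(oxygen_params, c(list(mode = config$mode), config$oxygen))
  eff <- effect_spec()
  bad <- setdiff(config$groups, eff$groups)
  if (length(bad)) abort(paste("unknown groups:", paste(bad, collapse = ", ")))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(dir(config$out_dir)) && !config$overwrite) {
    abort(sprintf("output directory %s is not empty (set overwrite = TRUE)",
                  config$out_dir))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  seed0 <- config$seed
  indices <- list()
  first_tess <- NULL
  first_field <- NULL
  k <- 0L
  for (g in config$groups) {
    for (animal in seq_len(config$n_animals)) {
      for (region in c("core", "cortex")) {
        k <- k + 1L
        cdm <- eff$cd_multiplier
        csm <- eff$csa_multiplier
        cd_mult <- if (g %in% cdm$group) cdm[[region]][cdm$group == g] else 1
        csa_mult <- if (g %in% csm$group) csm[[region]][csm$group == g] else 1
        spec <- phenotype_preset(region,
                                 target_CD = phenotype_preset(region)$target_CD * cd_mult,
                                 fibre_CSA_mean = phenotype_preset(region)$fibre_CSA_mean * csa_mult)
        map <- stage("synth", generate_cross_section(
          spec, seed = seed0 + 1000L * k, region_label = region,
          animal_id = sprintf("%s_a%d", g, animal), group_label = g))
        tess <- stage("tessellate", tessellate(map))
        gi <- stage("indices", compute_global_indices(map))
        li <- stage("indices", compute_local_indices(
          tess, exclude_boundary_domains = config$exclude_boundary_domains))
        field <- stage("oxygen", solve_frame(tess, map, params, h = config$h))
        indices[[k]] <- dplyr::bind_cols(
          tibble(group = g, animal = animal),
          gi, li$summary[c("CDA_mean_um2", "logSD")],
          tibble(mean_PO2_mmHg = field$mean_PO2,
                 hypoxic_fraction_pct = field$hypoxic_fraction)
        )
        if (is.null(first_tess)) {
          first_tess <- tess
          first_field <- field
        }
      }
    }
  }
  indices <- dplyr::bind_rows(indices)

  ratios <- stage("ratios", {
    indices %>%
      dplyr::group_by(.data$group, .data$animal) %>%
      dplyr::group_modify(function(d, key) {
        core_cortex_ratio(
          d[d$region == "core",
            c("CF", "CD_per_mm2", "CSA_um2", "CDA_mean_um2", "logSD",
              "mean_PO2_mmHg")],
          d[d$region == "cortex",
            c("CF", "CD_per_mm2", "CSA_um2", "CDA_mean_um2", "logSD",
              "mean_PO2_mmHg")]
        )
      }) %>%
      dplyr::ungroup()
  })

  anova_cd <- stage("group_stats", {
    cort <- indices[indices$region == "cortex", ]
    if (length(unique(cort$group)) >= 2 && all(table(cort$group) >= 2)) {
      fit <- one_way_anova(cort, "CD_per_mm2", "group")
      dplyr::bind_cols(glance(fit))
    } else {
      tibble(F = NA_real_, df_between = NA_integer_,
             df_within = NA_integer_, p = NA_real_)
    }
  })

  fatigue <- stage("fatigue", {
    purrr::imap_dfr(eff$fi_target[intersect(config$groups, names(eff$fi_target))],
                    function(fi, g) {
      purrr::map_dfr(seq_len(config$n_animals), function(animal) {
        tr <- generate_tension_trace(
          FI_target = fi, seed = seed0 + 77L * animal + match(g, eff$groups))
        dplyr::bind_cols(tibble(group = g, animal = animal, FI_target = fi),
                         fatigue_index(tr)[c("FI", "FI_pct", "peak_tension",
                                             "final_tension")])
      })
    })
  })

  hyperaemia <- stage("hyperaemia", {
    purrr::imap_dfr(
      eff$hyperaemia_target[intersect(config$groups, names(eff$hyperaemia_target))],
      function(pr, g) {
        kin <- if (g %in% c("4Hz", "10Hz", "40Hz")) g else "10Hz"
        fl <- generate_flow_trace(peak_ratio = pr, kinetics = kin,
                                  seed = seed0 + 31L * match(g, eff$groups))
        dplyr::bind_cols(tibble(group = g, peak_ratio_target = pr),
                         relative_conductance(fl)$summary)
      })
  })

  volcano <- stage("volcano", {
    mg <- intersect(config$groups, eff$groups)
    treated <- setdiff(mg, "CT")
    if (length(treated) == 0 || !("CT" %in% mg)) {
      tibble()
    } else {
      mat <- generate_metabolome(
        n_per_group = config$n_per_group, compounds = config$n_compounds,
        effects = eff, sigma_log = config$sigma_log, seed = seed0 + 5L,
        groups = mg)
      volcano_table(mat, "CT", treated[1L])
    }
  })

  manifest <- tibble(
    package = "capdomain",
    version = as.character(utils::packageVersion("capdomain")),
    seed = seed0,
    groups = paste(config$groups, collapse = ","),
    n_animals = config$n_animals,
    mode = config$mode,
    h = config$h,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  stage("write", {
    write_results_table(indices, file.path(config$out_dir, "indices.csv"))
    write_results_table(ratios, file.path(config$out_dir, "core_cortex_ratios.csv"))
    write_results_table(anova_cd, file.path(config$out_dir, "anova_cd_cortex.csv"))
    write_results_table(fatigue, file.path(config$out_dir, "fatigue.csv"))
    write_results_table(hyperaemia, file.path(config$out_dir, "hyperaemia.csv"))
    if (nrow(volcano)) {
      write_results_table(volcano, file.path(config$out_dir, "volcano.csv"))
    }
    write_tessellation_geojson(first_tess,
                               file.path(config$out_dir, "tessellation_example.geojson"))
    write_oxygen_summary(first_field,
                         file.path(config$out_dir, "oxygen_summary_example.json"))
    jsonlite::write_json(as.list(manifest), file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(indices = indices, ratios = ratios,
                 anova_cd_cortex = anova_cd, fatigue = fatigue,
                 hyperaemia = hyperaemia, volcano = volcano,
                 manifest = manifest))
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
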