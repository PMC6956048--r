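#' Load the shipped five-group study presets
#'
#' Reads the bundled YAML describing the five experimental groups (untreated
#' control; the enzyme-weakened ectatic model KC; and KC treated with
#' tissue-derived particles from cornea, cartilage, or lymph node: COR,
#' CART, LN). Each group carries fibril-field, tensile, DSC and qPCR
#' generator settings whose ordering encodes the study's qualitative
#' findings; absolute values are plausible but arbitrary.
#'
#' @param path Optional path to an alternative preset YAML.
#' @return Named list of group presets.
#' @export
group_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets", "default_groups.yaml",
                        package = "stromaquant", mustWork = TRUE)
  yaml::read_yaml(path)
}

pipeline_defaults <- function(seed = 1L) {
  list(
    seed = seed,
    stages = c("tem", "tensile", "dsc", "qpcr"),
    groups = group_presets(),
    tem = list(field_width_px = 2048L, field_height_px = 2048L,
               pixel_size_nm = 2, min_gap_nm = 6, noise_sd = 0.05,
               blur_sigma_px = 0.8, n_images = 3L,
               window_px = 300L, n_windows = 200L, min_images = 3L,
               local_window_px = 51L, offset = 0.2, min_area_px = 20,
               max_area_px = 1e4, min_circularity = 0.6, connectivity = 8L,
               bin_width_nm = 2),
    tensile = list(n_replicates = 6L, fit_lo_frac = 0.7, fit_hi_frac = 0.9,
                   strip_width_mm = 5, thickness_mm = 0.4,
                   gauge_length_mm = 8, displacement_rate_mm_s = 0.1,
                   max_strain = 0.3, n_points = 500L, noise_sd_N = 0.005),
    dsc = list(n_replicates = 3L, peak_width_C = 2.5, peak_depth_mW = 2,
               baseline_intercept_mW = 5, baseline_slope_mW_per_C = 0.02,
               t_start_C = 10, t_end_C = 95, sampling_interval_C = 0.1,
               noise_sd_mW = 0.05, smooth_sigma_C = 1,
               replicate_td_sd_C = 0.3),
    qpcr = list(housekeeping = "Gapdh", control_group = "control",
                replicates_per_group = 6L, ct_noise_sd = 0.3))
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])) && k != "groups")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

collect_unknown_keys <- function(user, template, prefix) {
  bad <- character(0)
  for (k in names(user)) {
    if (!k %in% names(template)) {
      bad <- c(bad, sprintf("unknown key `%s%s`", prefix, k))
    } else if (is.list(user[[k]]) && is.list(template[[k]]) &&
               !is.null(names(template[[k]])) && k != "groups") {
      bad <- c(bad, collect_unknown_keys(user[[k]], template[[k]],
                                         paste0(prefix, k, ".")))
    }
  }
  bad
}

group_template <- list(fibril = list(target_density = 0,
                                     diameter_mean_nm = 0,
                                     diameter_sd_nm = 0,
                                     diameter_law = "", min_gap_nm = 0),
                       tensile = list(model = "", E_linear = 0,
                                      toe_amplitude = 0, toe_rate = 0),
                       dsc = list(td_C = 0),
                       qpcr = list(Tnfa = 0, Aldh = 0, Kera = 0, Bgn = 0))

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (an empty or missing file yields the full
#' default configuration), merges it over the defaults, and checks every
#' sub-configuration invariant plus unknown keys. All violations are
#' collected, not just the first.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param seed Seed used when the file does not set one.
#' @return A `pipeline_config` list when valid; otherwise an object of
#'   class `config_violations` whose `violations` element lists every
#'   problem found.
#' @export
validate_config <- function(path = NULL, seed = 1L) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config parse failure in `", path, "`: ", conditionMessage(e),
           call. = FALSE))
    if (is.null(user)) user <- list()   # empty file
  }
  defaults <- pipeline_defaults(seed)
  violations <- collect_unknown_keys(user, defaults, "")
  for (g in names(user$groups))
    violations <- c(violations,
                    collect_unknown_keys(user$groups[[g]], group_template,
                                         paste0("groups.", g, ".")))
  cfg <- merge_config(defaults, user)

  chk <- function(ok, msg) if (!ok) violations <<- c(violations, msg)
  tem <- cfg$tem
  chk(tem$window_px >= 1,
      "DensityConfig invariant violated: tem.window_px must be >= 1")
  chk(tem$window_px <= min(tem$field_width_px, tem$field_height_px),
      "DensityConfig invariant violated: tem.window_px must fit inside the image")
  chk(tem$n_windows >= 1, "tem.n_windows must be >= 1")
  chk(tem$min_images >= 1, "tem.min_images must be >= 1")
  chk(tem$local_window_px >= 3 && tem$local_window_px %% 2 == 1,
      "tem.local_window_px must be an odd integer >= 3")
  chk(tem$min_circularity >= 0 && tem$min_circularity <= 1,
      "tem.min_circularity must be in [0, 1]")
  chk(tem$min_area_px < tem$max_area_px,
      "tem.min_area_px must be below tem.max_area_px")
  chk(tem$connectivity %in% c(4, 8), "tem.connectivity must be 4 or 8")
  chk(cfg$tensile$fit_lo_frac >= 0 && cfg$tensile$fit_hi_frac <= 1 &&
        cfg$tensile$fit_lo_frac < cfg$tensile$fit_hi_frac,
      "tensile fit window must satisfy 0 <= lo < hi <= 1")
  chk(cfg$tensile$max_strain > 0 && cfg$tensile$max_strain <= 1,
      "tensile.max_strain must be in (0, 1]")
  chk(cfg$qpcr$replicates_per_group >= 2,
      "qpcr.replicates_per_group must be >= 2")
  chk(cfg$dsc$sampling_interval_C > 0, "dsc.sampling_interval_C must be > 0")
  chk(cfg$dsc$t_start_C < cfg$dsc$t_end_C,
      "dsc.t_start_C must be below dsc.t_end_C")
  chk(all(cfg$stages %in% c("tem", "tensile", "dsc", "qpcr")),
      "stages must be a subset of tem, tensile, dsc, qpcr")
  for (g in names(cfg$groups)) {
    td <- cfg$groups[[g]]$dsc$td_C
    if (!is.null(td))
      chk(td > cfg$dsc$t_start_C && td < cfg$dsc$t_end_C,
          sprintf("groups.%s.dsc.td_C lies outside the DSC scan range", g))
  }
  if (length(violations))
    return(structure(list(violations = violations),
                     class = "config_violations"))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.config_violations <- function(x, ...) {
  cat("invalid pipeline configuration:\n")
  for (v in x$violations) cat("  -", v, "\n")
  invisible(x)
}

group_field_params <- function(cfg, g, seed) {
  fp <- cfg$groups[[g]]$fibril
  fibril_field_params(
    target_density = fp$target_density,
    diameter_mean_nm = fp$diameter_mean_nm,
    diameter_sd_nm = fp$diameter_sd_nm,
    diameter_law = if (is.null(fp$diameter_law)) "lognormal"
                   else fp$diameter_law,
    min_gap_nm = if (is.null(fp$min_gap_nm)) cfg$tem$min_gap_nm
                 else fp$min_gap_nm,
    field_width_px = cfg$tem$field_width_px,
    field_height_px = cfg$tem$field_height_px,
    pixel_size_nm = cfg$tem$pixel_size_nm,
    noise_sd = cfg$tem$noise_sd, blur_sigma_px = cfg$tem$blur_sigma_px,
    seed = seed)
}

seg_config_of <- function(cfg) {
  segmentation_config(local_window_px = cfg$tem$local_window_px,
                      offset = cfg$tem$offset,
                      min_area_px = cfg$tem$min_area_px,
                      max_area_px = cfg$tem$max_area_px,
                      min_circularity = cfg$tem$min_circularity,
                      connectivity = cfg$tem$connectivity)
}

run_tem_stage <- function(cfg) {
  seg <- seg_config_of(cfg)
  density <- list(); diameters <- list(); per_image_density <- list()
  for (g in names(cfg$groups)) {
    ests <- list(); dets_all <- list(); realized <- numeric(0)
    for (i in seq_len(cfg$tem$n_images)) {
      fld <- generate_fibril_field(
        group_field_params(cfg, g, derive_seed(cfg$seed,
                                               paste0("tem:", g, ":", i))))
      det <- segment_fibrils(fld$image, cfg$tem$pixel_size_nm, seg)
      dcfg <- density_config(cfg$tem$window_px, cfg$tem$n_windows,
                             cfg$tem$min_images,
                             seed = derive_seed(cfg$seed,
                                                paste0("win:", g, ":", i)))
      ests[[i]] <- estimate_density(det, config = dcfg)
      dets_all[[i]] <- det
      realized[i] <- fld$realized_density
    }
    agg <- aggregate_density(ests, cfg$tem$min_images)
    dd <- diameter_distribution(
      unlist(lapply(dets_all, `[[`, "equivalent_diameter_nm")),
      cfg$tem$bin_width_nm)
    density[[g]] <- list(
      density_per_um2 = agg$density_per_um2,
      median_count = agg$median_count,
      n_images = agg$n_images,
      per_image_density = vapply(ests, `[[`, 0, "density_per_um2"),
      realized_density_mean = mean(realized))
    diameters[[g]] <- list(n = dd$n, median_nm = dd$median_nm,
                           iqr_nm = dd$iqr_nm, mean_nm = dd$mean_nm,
                           sd_nm = dd$sd_nm)
    per_image_density[[g]] <- list(
      values = vapply(ests, `[[`, 0, "density_per_um2"),
      diameters_nm = unlist(lapply(dets_all, `[[`,
                                   "equivalent_diameter_nm")))
  }
  list(density = density, diameters = diameters,
       samples = per_image_density)
}

run_tensile_stage <- function(cfg) {
  out <- list(); values <- list()
  for (g in names(cfg$groups)) {
    tp <- cfg$groups[[g]]$tensile
    E <- vapply(seq_len(cfg$tensile$n_replicates), function(r) {
      params <- tensile_params(
        model = if (is.null(tp$model)) "toe-exponential" else tp$model,
        E_linear = if (is.null(tp$E_linear)) 5 else tp$E_linear,
        toe_amplitude = tp$toe_amplitude, toe_rate = tp$toe_rate,
        strip_width_mm = cfg$tensile$strip_width_mm,
        thickness_mm = cfg$tensile$thickness_mm,
        gauge_length_mm = cfg$tensile$gauge_length_mm,
        displacement_rate_mm_s = cfg$tensile$displacement_rate_mm_s,
        max_strain = cfg$tensile$max_strain,
        n_points = cfg$tensile$n_points,
        noise_sd_N = cfg$tensile$noise_sd_N,
        seed = derive_seed(cfg$seed, paste0("tensile:", g, ":", r)))
      est <- estimate_modulus(compute_stress_strain(
        generate_tensile_record(params)),
        cfg$tensile$fit_lo_frac, cfg$tensile$fit_hi_frac)
      est$young_modulus_MPa
    }, 0)
    out[[g]] <- list(young_modulus_MPa_mean = mean(E),
                     young_modulus_MPa_sd = sd(E), n = length(E),
                     values = E)
    values[[g]] <- E
  }
  list(modulus = out, samples = values)
}

run_dsc_stage <- function(cfg) {
  out <- list(); values <- list()
  for (g in names(cfg$groups)) {
    td_true <- cfg$groups[[g]]$dsc$td_C
    td <- vapply(seq_len(cfg$dsc$n_replicates), function(r) {
      sd_rep <- derive_seed(cfg$seed, paste0("dsc:", g, ":", r))
      # biological replicate-to-replicate Td scatter, then instrument noise
      td_r <- with_seed_(derive_seed(sd_rep, "td"),
                         rnorm(1, td_true, cfg$dsc$replicate_td_sd_C))
      params <- thermogram_params(
        td_C = td_r, peak_width_C = cfg$dsc$peak_width_C,
        peak_depth_mW = cfg$dsc$peak_depth_mW,
        baseline_intercept_mW = cfg$dsc$baseline_intercept_mW,
        baseline_slope_mW_per_C = cfg$dsc$baseline_slope_mW_per_C,
        t_start_C = cfg$dsc$t_start_C, t_end_C = cfg$dsc$t_end_C,
        sampling_interval_C = cfg$dsc$sampling_interval_C,
        noise_sd_mW = cfg$dsc$noise_sd_mW, seed = sd_rep)
      detect_denaturation(generate_thermogram(params),
                          smooth_sigma_C = cfg$dsc$smooth_sigma_C)$td_C
    }, 0)
    out[[g]] <- list(td_C_mean = mean(td), td_C_sd = sd(td),
                     n = length(td), values = td)
    values[[g]] <- td
  }
  list(td = out, samples = values)
}

run_qpcr_stage <- function(cfg) {
  genes <- c(cfg$qpcr$housekeeping, names(group_template$qpcr))
  groups <- names(cfg$groups)
  eff <- matrix(0, length(groups), length(genes),
                dimnames = list(groups, genes))
  for (g in groups) {
    e <- cfg$groups[[g]]$qpcr
    for (gene in names(e)) if (gene %in% genes) eff[g, gene] <- e[[gene]]
  }
  params <- ct_table_params(
    genes = genes, housekeeping = cfg$qpcr$housekeeping, groups = groups,
    log2_effects = eff,
    replicates_per_group = cfg$qpcr$replicates_per_group,
    ct_noise_sd = cfg$qpcr$ct_noise_sd,
    seed = derive_seed(cfg$seed, "qpcr"))
  fc <- delta_delta_ct(generate_ct_table(params),
                       cfg$qpcr$housekeeping, cfg$qpcr$control_group)
  list(fold_change = fc)
}

pairwise_tests <- function(samples, references = c("control", "KC")) {
  res <- list()
  for (ref in intersect(references, names(samples)))
    for (g in setdiff(names(samples), ref)) {
      if (length(samples[[g]]) < 2 || length(samples[[ref]]) < 2) next
      tt <- tryCatch(two_sample_t(samples[[g]], samples[[ref]], "student"),
                     error = function(e) NULL)  # e.g. housekeeping gene
      if (is.null(tt)) next
      res[[paste0(g, "_vs_", ref)]] <-
        list(statistic = tt$statistic, df = tt$df, p = tt$p_two_sided)
    }
  res
}

anova_of <- function(samples) {
  ok <- samples[lengths(samples) >= 2]
  if (length(ok) < 2) return(NULL)
  an <- tryCatch(one_way_anova(unname(ok)), error = function(e) NULL)
  if (is.null(an)) return(NULL)  # degenerate endpoint (e.g. zero variation)
  list(F = an$statistic, df = an$df, p = an$p_two_sided)
}

#' Run the full analysis pipeline on synthetic study groups
#'
#' Executes, for every configured group and every requested stage, the
#' generate-then-measure chain: TEM fibril fields are rendered, segmented
#' and reduced to density and diameter summaries; tensile records are
#' reduced to Young's moduli; thermograms to denaturation temperatures; and
#' a Ct table to fold changes. Group comparisons (one-way ANOVA across all
#' groups plus pairwise Student t tests against the control and KC groups)
#' are attached per endpoint. All randomness derives from the single
#' configuration seed through named per-stage substreams, so an identical
#' configuration yields a byte-identical report.
#'
#' @param config A `pipeline_config` from [validate_config()] (or `NULL`
#'   for defaults with `seed`).
#' @param seed Seed used when `config` is `NULL`.
#' @param out_dir Optional directory; when given, `report.json` and
#'   per-stage CSV tables are written there.
#' @return The report, a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(config)) config <- validate_config(NULL, seed)
  if (inherits(config, "config_violations"))
    stop(paste(c("invalid pipeline configuration:", config$violations),
               collapse = "\n  "), call. = FALSE)
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(package = "stromaquant",
                 version = as.character(packageVersion("stromaquant")),
                 seed = config$seed, stages = config$stages,
                 groups = names(config$groups))
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  samples <- list()
  if ("tem" %in% config$stages) {
    tem <- run_stage("tem", function() run_tem_stage(config))
    report$density <- tem$density
    report$diameters <- tem$diameters
    report$stats$density <- list(
      pairwise = pairwise_tests(lapply(tem$samples, `[[`, "values")))
    report$stats$diameter <- list(
      pairwise = pairwise_tests(lapply(tem$samples, `[[`, "diameters_nm")))
  }
  if ("tensile" %in% config$stages) {
    tens <- run_stage("tensile", function() run_tensile_stage(config))
    report$modulus <- tens$modulus
    report$stats$modulus <- list(anova = anova_of(tens$samples),
                                 pairwise = pairwise_tests(tens$samples))
  }
  if ("dsc" %in% config$stages) {
    dsc <- run_stage("dsc", function() run_dsc_stage(config))
    report$td <- dsc$td
    report$stats$td <- list(anova = anova_of(dsc$samples),
                            pairwise = pairwise_tests(dsc$samples))
  }
  if ("qpcr" %in% config$stages) {
    qp <- run_stage("qpcr", function() run_qpcr_stage(config))
    fc <- qp$fold_change
    report$expression <- lapply(
      split(fc$by_group, fc$by_group$gene), function(d)
        stats::setNames(as.list(d$geo_mean_fold), d$group))
    l2 <- -fc$per_sample$ddct
    by_gene <- split(data.frame(group = fc$per_sample$group, l2 = l2),
                     fc$per_sample$gene)
    report$stats$expression <- lapply(by_gene, function(d) {
      s <- split(d$l2, d$group)
      list(anova = anova_of(s), pairwise = pairwise_tests(s))
    })
  }
  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` plus per-stage CSV tables (`density.csv`,
#' `modulus.csv`, `td.csv`, `expression.csv`) for whichever stages the
#' report contains.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  tab <- function(section, value_name) {
    do.call(rbind, lapply(names(report[[section]]), function(g) {
      v <- report[[section]][[g]][[value_name]]
      data.frame(group = g, value = v)
    }))
  }
  if (!is.null(report$density)) {
    d <- tab("density", "density_per_um2")
    names(d)[2] <- "density_per_um2"
    write.csv(d, file.path(out_dir, "density.csv"), row.names = FALSE)
  }
  if (!is.null(report$modulus)) {
    d <- tab("modulus", "values")
    names(d)[2] <- "young_modulus_MPa"
    write.csv(d, file.path(out_dir, "modulus.csv"), row.names = FALSE)
  }
  if (!is.null(report$td)) {
    d <- tab("td", "values")
    names(d)[2] <- "td_C"
    write.csv(d, file.path(out_dir, "td.csv"), row.names = FALSE)
  }
  if (!is.null(report$expression)) {
    rows <- do.call(rbind, lapply(names(report$expression), function(gene)
      data.frame(gene = gene, group = names(report$expression[[gene]]),
                 geo_mean_fold = unlist(report$expression[[gene]]))))
    write.csv(rows, file.path(out_dir, "expression.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> stromaquant %s, seed %s, stages: %s\n",
              x$version, x$seed, paste(x$stages, collapse = ", ")))
  if (!is.null(x$density)) {
    cat("  fibril density (fibrils/um^2):\n")
    for (g in names(x$density))
      cat(sprintf("    %-8s %6.2f\n", g, x$density[[g]]$density_per_um2))
  }
  if (!is.null(x$modulus)) {
    cat("  Young's modulus (MPa, mean +/- sd):\n")
    for (g in names(x$modulus))
      cat(sprintf("    %-8s %6.2f +/- %.2f\n", g,
                  x$modulus[[g]]$young_modulus_MPa_mean,
                  x$modulus[[g]]$young_modulus_MPa_sd))
  }
  if (!is.null(x$td)) {
    cat("  denaturation temperature (degrees C, mean +/- sd):\n")
    for (g in names(x$td))
      cat(sprintf("    %-8s %6.2f +/- %.2f\n", g, x$td[[g]]$td_C_mean,
                  x$td[[g]]$td_C_sd))
  }
  if (!is.null(x$expression)) {
    cat("  fold change (geometric mean, vs control):\n")
    for (gene in names(x$expression)) {
      v <- x$expression[[gene]]
      cat(sprintf("    %-6s %s\n", gene,
                  paste(sprintf("%s=%.2f", names(v), unlist(v)),
                        collapse = "  ")))
    }
  }
  invisible(x)
}
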