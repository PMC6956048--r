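#' Parameters for a synthetic uniaxial tensile record
#'
#' Encodes the constitutive law used to simulate a corneal strip pulled at
#' constant crosshead speed. Two laws are available: `linear`,
#' `sigma = E_linear * strain`, and `toe-exponential`,
#' `sigma = toe_amplitude * (exp(toe_rate * strain) - 1)`, the standard
#' J-shaped toe model for soft collagenous tissue. Load is stress times the
#' initial cross-section (engineering convention); displacement is strain
#' times gauge length; time follows from the constant displacement rate.
#'
#' @param model `"linear"` or `"toe-exponential"`.
#' @param E_linear Young's modulus of the linear law, MPa.
#' @param toe_amplitude,toe_rate Toe model parameters (MPa, dimensionless).
#' @param strip_width_mm Strip width, mm (default 5).
#' @param thickness_mm Strip thickness, mm.
#' @param gauge_length_mm Free length between clamps, mm.
#' @param displacement_rate_mm_s Crosshead speed, mm/s (default 0.1).
#' @param max_strain Final engineering strain, in (0, 1].
#' @param n_points Number of samples along the record.
#' @param noise_sd_N Additive load-cell noise SD, newtons.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `tensile_params`.
#' @export
tensile_params <- function(model = c("toe-exponential", "linear"),
                           E_linear = 5, toe_amplitude = 0.5, toe_rate = 8,
                           strip_width_mm = 5, thickness_mm = 0.4,
                           gauge_length_mm = 8,
                           displacement_rate_mm_s = 0.1,
                           max_strain = 0.3, n_points = 500L,
                           noise_sd_N = 0, seed = NULL) {
  model <- match.arg(model)
  for (nm in c("strip_width_mm", "thickness_mm", "gauge_length_mm",
               "displacement_rate_mm_s"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (max_strain <= 0 || max_strain > 1)
    stop("`max_strain` must be in (0, 1]", call. = FALSE)
  if (n_points < 3) stop("`n_points` must be >= 3", call. = FALSE)
  if (noise_sd_N < 0) stop("`noise_sd_N` must be >= 0", call. = FALSE)
  structure(list(model = model, E_linear = E_linear,
                 toe_amplitude = toe_amplitude, toe_rate = toe_rate,
                 strip_width_mm = strip_width_mm, thickness_mm = thickness_mm,
                 gauge_length_mm = gauge_length_mm,
                 displacement_rate_mm_s = displacement_rate_mm_s,
                 max_strain = max_strain, n_points = as.integer(n_points),
                 noise_sd_N = noise_sd_N, seed = seed),
            class = "tensile_params")
}

# Analytic stress (MPa) of a tensile_params law at given strains.
tensile_stress_law <- function(params, strain) {
  switch(params$model,
         "linear" = params$E_linear * strain,
         "toe-exponential" =
           params$toe_amplitude * (exp(params$toe_rate * strain) - 1))
}

# Analytic tangent modulus dsigma/dstrain (MPa).
tensile_tangent_law <- function(params, strain) {
  switch(params$model,
         "linear" = rep(params$E_linear, length(strain)),
         "toe-exponential" =
           params$toe_amplitude * params$toe_rate *
             exp(params$toe_rate * strain))
}

#' Generate a synthetic tensile record
#'
#' @param params A [tensile_params()] object.
#' @return A `tensile_record` (see [tensile_record()]) carrying columns
#'   `time_s`, `displacement_mm`, `load_N` plus the strip geometry.
#' @export
generate_tensile_record <- function(params) {
  stopifnot(inherits(params, "tensile_params"))
  strain <- seq(0, params$max_strain, length.out = params$n_points)
  stress <- tensile_stress_law(params, strain)            # MPa = N/mm^2
  load <- stress * params$strip_width_mm * params$thickness_mm
  displacement <- strain * params$gauge_length_mm
  time_s <- displacement / params$displacement_rate_mm_s
  load <- with_seed_(params$seed,
    load + rnorm(length(load), 0, params$noise_sd_N))
  tensile_record(time_s = time_s, displacement_mm = displacement,
                 load_N = load,
                 strip_width_mm = params$strip_width_mm,
                 thickness_mm = params$thickness_mm,
                 gauge_length_mm = params$gauge_length_mm)
}

#' Parameters for a synthetic DSC thermogram
#'
#' Models a heat-flow trace as a linear instrument baseline minus a Gaussian
#' endotherm (endotherm-down convention) centred on the collagen denaturation
#' temperature, plus white detector noise:
#' `hf(T) = intercept + slope * T - depth * exp(-(T - td)^2 / (2 width^2)) + noise`.
#'
#' @param td_C Denaturation (peak) temperature, degrees C; must lie inside
#'   the scanned range.
#' @param peak_width_C Gaussian sigma of the endotherm, degrees C.
#' @param peak_depth_mW Endotherm magnitude, mW.
#' @param baseline_intercept_mW,baseline_slope_mW_per_C Linear baseline.
#' @param t_start_C,t_end_C Scan range, degrees C (defaults 10 and 95).
#' @param heating_rate_C_min Heating rate, degrees C per minute (default 5);
#'   recorded as metadata.
#' @param sampling_interval_C Temperature grid spacing, degrees C.
#' @param noise_sd_mW Additive noise SD, mW.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `thermogram_params`.
#' @export
thermogram_params <- function(td_C = 66.8, peak_width_C = 2.5,
                              peak_depth_mW = 2,
                              baseline_intercept_mW = 0,
                              baseline_slope_mW_per_C = 0,
                              t_start_C = 10, t_end_C = 95,
                              heating_rate_C_min = 5,
                              sampling_interval_C = 0.1,
                              noise_sd_mW = 0.05, seed = NULL) {
  if (t_start_C >= t_end_C)
    stop("`t_start_C` must be below `t_end_C`", call. = FALSE)
  if (td_C <= t_start_C || td_C >= t_end_C)
    stop(sprintf("`td_C` = %.2f lies outside the scan range [%g, %g]",
                 td_C, t_start_C, t_end_C), call. = FALSE)
  stop_if_not_scalar_pos(peak_width_C, "peak_width_C")
  stop_if_not_scalar_pos(sampling_interval_C, "sampling_interval_C")
  stop_if_not_scalar_pos(heating_rate_C_min, "heating_rate_C_min")
  if (peak_depth_mW < 0 || noise_sd_mW < 0)
    stop("`peak_depth_mW` and `noise_sd_mW` must be >= 0", call. = FALSE)
  structure(list(td_C = td_C, peak_width_C = peak_width_C,
                 peak_depth_mW = peak_depth_mW,
                 baseline_intercept_mW = baseline_intercept_mW,
                 baseline_slope_mW_per_C = baseline_slope_mW_per_C,
                 t_start_C = t_start_C, t_end_C = t_end_C,
                 heating_rate_C_min = heating_rate_C_min,
                 sampling_interval_C = sampling_interval_C,
                 noise_sd_mW = noise_sd_mW, seed = seed),
            class = "thermogram_params")
}

#' Generate a synthetic DSC thermogram
#'
#' @param params A [thermogram_params()] object.
#' @return A `thermogram` (see [thermogram()]).
#' @export
generate_thermogram <- function(params) {
  stopifnot(inherits(params, "thermogram_params"))
  temp <- seq(params$t_start_C, params$t_end_C,
              by = params$sampling_interval_C)
  hf <- params$baseline_intercept_mW + params$baseline_slope_mW_per_C * temp -
    params$peak_depth_mW *
      exp(-(temp - params$td_C)^2 / (2 * params$peak_width_C^2))
  hf <- with_seed_(params$seed,
    hf + rnorm(length(hf), 0, params$noise_sd_mW))
  thermogram(temperature_C = temp, heat_flow_mW = hf)
}

#' Parameters for a synthetic qPCR Ct table
#'
#' Simulates threshold cycles as
#' `Ct(sample, gene) = baseline_ct[gene] - log2_effect[group, gene] + noise`,
#' so a positive log2 effect (upregulation) lowers Ct. The housekeeping gene
#' must carry a zero effect in every group so that normalization against it
#' is exact in expectation.
#'
#' @param genes Character vector of gene names, including the housekeeping
#'   gene.
#' @param housekeeping Name of the housekeeping gene.
#' @param groups Character vector of group labels; the first is taken as the
#'   control unless stated otherwise downstream.
#' @param log2_effects Numeric matrix (groups x genes) of log2 fold changes
#'   relative to control; missing rows/columns default to 0.
#' @param baseline_ct Named numeric vector of baseline Ct per gene; genes
#'   not named default to 25 cycles.
#' @param replicates_per_group Biological replicates per group (default 6).
#' @param ct_noise_sd Ct measurement noise SD, cycles.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `ct_table_params`.
#' @export
ct_table_params <- function(genes = c("Gapdh", "Tnfa", "Aldh", "Kera", "Bgn"),
                            housekeeping = "Gapdh",
                            groups = c("control", "KC"),
                            log2_effects = NULL,
                            baseline_ct = NULL,
                            replicates_per_group = 6L,
                            ct_noise_sd = 0.3, seed = NULL) {
  if (!housekeeping %in% genes)
    stop(sprintf("housekeeping gene '%s' is missing from `genes`",
                 housekeeping), call. = FALSE)
  if (replicates_per_group < 2)
    stop("`replicates_per_group` must be >= 2", call. = FALSE)
  if (ct_noise_sd < 0) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  eff <- matrix(0, length(groups), length(genes),
                dimnames = list(groups, genes))
  if (!is.null(log2_effects)) {
    le <- as.matrix(log2_effects)
    eff[rownames(le), colnames(le)] <- le
  }
  if (any(eff[, housekeeping] != 0))
    stop("the housekeeping gene must have log2 effect 0 in every group",
         call. = FALSE)
  bct <- stats::setNames(rep(25, length(genes)), genes)
  if (!is.null(baseline_ct)) bct[names(baseline_ct)] <- baseline_ct
  structure(list(genes = genes, housekeeping = housekeeping, groups = groups,
                 log2_effects = eff, baseline_ct = bct,
                 replicates_per_group = as.integer(replicates_per_group),
                 ct_noise_sd = ct_noise_sd, seed = seed),
            class = "ct_table_params")
}

#' Generate a synthetic qPCR Ct table
#'
#' @param params A [ct_table_params()] object.
#' @return A long-format data frame of class `ct_table` with columns
#'   `sample_id`, `group`, `gene`, `ct`.
#' @export
generate_ct_table <- function(params) {
  stopifnot(inherits(params, "ct_table_params"))
  grid <- expand.grid(rep = seq_len(params$replicates_per_group),
                      group = params$groups, gene = params$genes,
                      stringsAsFactors = FALSE)
  ct0 <- params$baseline_ct[grid$gene] -
    params$log2_effects[cbind(grid$group, grid$gene)]
  ct <- with_seed_(params$seed,
    ct0 + rnorm(nrow(grid), 0, params$ct_noise_sd))
  out <- data.frame(sample_id = sprintf("%s_%02d", grid$group, grid$rep),
                    group = grid$group, gene = grid$gene, ct = as.numeric(ct),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_table", "data.frame")
  out
}
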