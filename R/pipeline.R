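# End-to-end evaluation pipeline: a synthetic cohort is planned with the
# functional-sparing and standard techniques, every evaluation layer is
# run per patient, and cohort tables (dosimetry, NTCP, robustness,
# complexity, planned-vs-delivered deviations) are written with paired
# statistics, mirroring how a planning comparison study reports results.

#' Pipeline configuration
#'
#' @param out_dir output directory for the report tables.
#' @param n_patients cohort size.
#' @param seed master seed; every per-patient seed derives from it.
#' @param grid_shape,spacing_mm phantom grid (see [phantom_spec()]).
#' @param head_radius_mm,spine_length_mm phantom anatomy scale.
#' @param n_beams,n_cp_per_beam plan geometry per technique.
#' @param modulation_sparing,modulation_standard modulation levels of the
#'   two techniques (the sparing technique is the more modulated one).
#' @param mlc_sd_mm,gantry_sd_deg delivery-log error magnitudes.
#' @param registry_path NTCP parameter registry (default: shipped file).
#' @param age_range_years cohort age range (uniform draw per patient).
#' @param isodose_fraction fraction of the prescription used as the
#'   conformity/coverage isodose level.
#' @return object of class `evaluation_config`.
#' @export
evaluation_config <- function(out_dir = "results",
                              n_patients = 4, seed = 1L,
                              grid_shape = c(100, 100, 250),
                              spacing_mm = c(2, 2, 2),
                              head_radius_mm = 80,
                              spine_length_mm = 300,
                              n_beams = 3, n_cp_per_beam = 48,
                              modulation_sparing = 0.8,
                              modulation_standard = 0.3,
                              mlc_sd_mm = 0.5, gantry_sd_deg = 0.3,
                              registry_path = NULL,
                              age_range_years = c(3, 17),
                              isodose_fraction = 0.95) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  structure(as.list(environment()), class = "evaluation_config")
}

# Derived seeds stay below 2^31 regardless of the master seed's size.
patient_seed <- function(config, i, offset) {
  as.integer((as.numeric(config$seed) %% 1e6) * 1000 + i * 10 + offset)
}

#' Cohort paired comparison
#'
#' Mean and SD per arm, the paired t-test and the Wilcoxon signed-rank
#' test (normal approximation) on the paired differences. Degenerate
#' inputs (zero-variance differences) are flagged rather than producing
#' NaN: identical arms report p = 1, a constant non-zero shift reports
#' p = 0.
#'
#' @param a,b paired metric values of equal length >= 2.
#' @return one-row data.frame: n, mean/sd per arm, mean difference,
#'   `t_p`, `wilcoxon_p`, `degenerate`.
#' @export
cohort_compare <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  if (length(a) < 2) stop("paired tests need n >= 2")
  d <- a - b
  degenerate <- stats::sd(d) < .Machine$double.eps^0.5
  if (degenerate) {
    p_t <- p_w <- if (all(abs(d) < .Machine$double.eps^0.5)) 1 else 0
  } else {
    p_t <- stats::t.test(a, b, paired = TRUE)$p.value
    p_w <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  }
  data.frame(n = length(a), mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b), mean_diff = mean(d),
             t_p = p_t, wilcoxon_p = p_w, degenerate = degenerate)
}

# Per-patient dosimetric metric set (the planning-study comparison rows).
dosimetry_metrics <- function(dose, structures, prescription_Gy,
                              isodose_fraction) {
  dvhs <- lapply(structures, function(s) compute_dvh(dose, s))
  g <- function(s, m) dose_metric(dvhs[[s]], m)
  level <- prescription_Gy * isodose_fraction
  vt <- structure_volume_cc(structures$ptv)
  covered <- sum(dose$values[structures$ptv$mask] >= level) *
    voxel_volume_cc(dose)
  vref <- sum(dose$values >= level) * voxel_volume_cc(dose)
  c(ptv_D2 = g("ptv", "D2%"), ptv_D98 = g("ptv", "D98%"),
    ptv_D95 = g("ptv", "D95%"),
    ptv_HI = homogeneity_index(g("ptv", "D2%"), g("ptv", "D98%"),
                               g("ptv", "D50%")),
    ptv_CI = paddick_ci(vt, covered, vref),
    hippocampus_D003cc = g("hippocampus", "D0.03cc"),
    hippocampus_Dmin = g("hippocampus", "Dmin"),
    hippocampus_Dmean = g("hippocampus", "Dmean"),
    hypothalamus_Dmean = g("hypothalamus", "Dmean"),
    pituitary_Dmean = g("pituitary", "Dmean"),
    vertebrae_gradient = g("vertebrae", "gradient"),
    cochlea_Dmean = g("cochlea", "Dmean"),
    scalp_D50 = g("scalp", "D50%"))
}

# Per-patient radiobiological metric set.
ntcp_metrics <- function(dose, structures, recipe, age_years, registry) {
  dvhs <- lapply(structures[c("hippocampus", "hypothalamus", "pituitary",
                              "cochlea", "scalp")],
                 function(s) compute_dvh(dose, s))
  scheme <- fractionation_scheme(recipe$n_fractions,
                                 registry$hippocampus$alpha_beta_Gy)
  d40 <- dose_metric(dvhs$hippocampus, "D40%")
  hy50 <- dose_metric(dvhs$hypothalamus, "D50%")
  pi50 <- dose_metric(dvhs$pituitary, "D50%")
  co50 <- dose_metric(dvhs$cochlea, "D50%")
  sc_geud <- geud(dvhs$scalp, registry$scalp$n)
  ep <- registry$hpa
  c(hippocampus_D40 = d40,
    hippocampus_EQD2_D40 = eqd2(d40, scheme),
    hippocampus_NTCP_pct = 100 * hippocampal_ntcp(
      d40, scheme, registry$hippocampus$TD50_Gy, registry$hippocampus$m),
    hypothalamus_D50 = hy50, pituitary_D50 = pi50,
    hpa_NTCP_pct = 100 * endocrine_ntcp(
      hy50, pi50, age_years, ep$gamma, ep$const, ep$beta_age, ep$beta_age2,
      ep$beta_dose, ep$t_years),
    cochlea_D50 = co50,
    cochlea_NTCP_pct = 100 * cochlear_ntcp(co50, registry$cochlea$b0,
                                           registry$cochlea$b1),
    scalp_gEUD = sc_geud,
    scalp_NTCP_pct = 100 * scalp_ntcp(geud_Gy = sc_geud,
                                      TD50_Gy = registry$scalp$TD50_Gy,
                                      m = registry$scalp$m))
}

#' Run the full evaluation pipeline
#'
#' Generates the synthetic cohort (one phantom per patient, a
#' functional-sparing and a standard dose/plan/log per phantom), runs
#' every evaluation stage, and writes five report tables plus a JSON
#' provenance manifest into `config$out_dir`:
#' `dosimetry.csv`, `ntcp.csv`, `robustness.csv`, `complexity.csv`,
#' `delta_dvh.csv` and `manifest.json`. Outputs are a pure function of
#' the configuration; a rerun with the same config is byte-identical.
#'
#' @param config an [evaluation_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "evaluation_config"))
  reg_path <- config$registry_path
  if (is.null(reg_path))
    reg_path <- system.file("extdata", "ntcp_params.yaml", package = "csieval")
  if (!nzchar(reg_path) || !file.exists(reg_path))
    stop("model registry not found: ", reg_path)
  registry <- load_ntcp_registry(reg_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  modes <- c(sparing = "functional_sparing", standard = "standard")
  modul <- c(sparing = config$modulation_sparing,
             standard = config$modulation_standard)
  ages <- local_rng(config$seed, function()
    stats::runif(config$n_patients, config$age_range_years[1],
                 config$age_range_years[2]))

  dosim <- ntcp <- robust <- cplx <- ddvh <- list()
  for (i in seq_len(config$n_patients)) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
      head_radius_mm = config$head_radius_mm,
      spine_length_mm = config$spine_length_mm,
      seed = patient_seed(config, i, 0)))
    iso <- ph$geometry$head_centre_mm
    for (arm in names(modes)) {
      recipe <- dose_recipe(mode = modes[[arm]])
      dose <- generate_dose(ph, recipe, seed = patient_seed(config, i, 1))
      plan <- generate_plan(
        n_beams = config$n_beams, n_cp_per_beam = config$n_cp_per_beam,
        modulation_level = modul[[arm]],
        seed = patient_seed(config, i, 2))
      dlog <- generate_log(plan, config$mlc_sd_mm, config$gantry_sd_deg,
                           seed = patient_seed(config, i, 3))

      dm <- dosimetry_metrics(dose, ph$structures, recipe$prescription_Gy,
                              config$isodose_fraction)
      dosim[[length(dosim) + 1]] <- data.frame(
        patient = i, arm = arm, metric = names(dm), value = unname(dm))

      nm <- ntcp_metrics(dose, ph$structures, recipe, ages[i], registry)
      ntcp[[length(ntcp) + 1]] <- data.frame(
        patient = i, arm = arm, metric = names(nm), value = unname(nm))

      rs <- robustness_study(dose, ph$structures, isocenter_mm = iso)
      robust[[length(robust) + 1]] <- cbind(patient = i, arm = arm,
                                            rs$summary)

      cr <- aggregate_metrics(plan)
      cplx[[length(cplx) + 1]] <- cbind(patient = i, arm = arm,
                                        cr[cr$scope != "beam", ])

      delivered <- reconstruct_delivered_dose(dose, plan, dlog)
      dd <- delta_dvh(dose, delivered, ph$structures)
      lr <- log_rms(plan, dlog)
      dd$mlc_rms_mm <- lr$mlc_mm
      dd$gantry_rms_deg <- lr$gantry_deg
      ddvh[[length(ddvh) + 1]] <- cbind(patient = i, arm = arm, dd)
    }
  }

  paired_table <- function(long, keys) {
    out <- do.call(rbind, lapply(split(long, long[keys], drop = TRUE),
      function(df) {
        a <- df$value[df$arm == "sparing"][order(df$patient[df$arm == "sparing"])]
        b <- df$value[df$arm == "standard"][order(df$patient[df$arm == "standard"])]
        if (length(a) < 2)
          return(cbind(df[1, keys, drop = FALSE],
                       data.frame(n = 1, mean_a = a, sd_a = NA, mean_b = b,
                                  sd_b = NA, mean_diff = a - b, t_p = NA,
                                  wilcoxon_p = NA, degenerate = NA)))
        cbind(df[1, keys, drop = FALSE], cohort_compare(a, b))
      }))
    names(out)[names(out) == "mean_a"] <- "mean_sparing"
    names(out)[names(out) == "sd_a"] <- "sd_sparing"
    names(out)[names(out) == "mean_b"] <- "mean_standard"
    names(out)[names(out) == "sd_b"] <- "sd_standard"
    rownames(out) <- NULL
    out
  }

  dosim <- do.call(rbind, dosim)
  ntcp <- do.call(rbind, ntcp)
  robust <- do.call(rbind, robust)
  cplx <- do.call(rbind, cplx)
  ddvh <- do.call(rbind, ddvh)

  robust$metric_group <- paste(robust$structure, robust$group, sep = " ")
  rob_long <- data.frame(patient = robust$patient, arm = robust$arm,
                         metric = robust$metric_group,
                         value = robust$lambda_percent)
  cplx_long <- do.call(rbind, lapply(
    c("PI", "MCS", "SAS10", "MFA_cm2", "MLG_cm", "MLT_cm", "MU"),
    function(mm) data.frame(patient = cplx$patient, arm = cplx$arm,
                            metric = paste(cplx$id, mm), value = cplx[[mm]])))
  ddvh_long <- data.frame(patient = ddvh$patient, arm = ddvh$arm,
                          metric = paste(ddvh$structure, ddvh$metric),
                          value = ddvh$delta_Gy)

  tables <- list(
    dosimetry = paired_table(dosim, "metric"),
    ntcp = paired_table(ntcp, "metric"),
    robustness = paired_table(rob_long, "metric"),
    complexity = paired_table(cplx_long, "metric"),
    delta_dvh = paired_table(ddvh_long, "metric"))

  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files[nm] <- f
  }
  manifest <- list(
    package = "csieval",
    version = as.character(utils::packageVersion("csieval")),
    seed = config$seed, n_patients = config$n_patients,
    grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
    registry = reg_path,
    ages_years = ages,
    tables = list(
      dosimetry = list(file = files[["dosimetry"]],
                       producer = "compute_dvh/dose_metric/homogeneity_index/paddick_ci"),
      ntcp = list(file = files[["ntcp"]],
                  producer = "eqd2/hippocampal_ntcp/endocrine_ntcp/cochlear_ntcp/scalp_ntcp"),
      robustness = list(file = files[["robustness"]],
                        producer = "robustness_study/lambda_index"),
      complexity = list(file = files[["complexity"]],
                        producer = "aggregate_metrics"),
      delta_dvh = list(file = files[["delta_dvh"]],
                       producer = "reconstruct_delivered_dose/delta_dvh/log_rms")),
    status = "complete")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tables, list(manifest = manifest)))
}
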