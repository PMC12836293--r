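# Dose-volume histograms and dosimetric indices.
#
# DVHs are bin-free: the cumulative curve is built from the exact sorted
# in-structure voxel doses and every D_x% / D_cc metric is a linearly
# interpolated order statistic of that sample. This removes any binning
# tolerance from downstream metrics.

#' Compute a cumulative DVH
#'
#' @param dose a [dose_grid()].
#' @param structure a [structure_mask()] aligned to `dose`.
#' @return An object of class `dvh` with fields `doses` (sorted voxel
#'   doses, Gy), `dose_axis_Gy`, `volume_fraction` (fraction of the
#'   structure receiving at least each axis dose), `structure_name`,
#'   `total_volume_cc`.
#' @export
compute_dvh <- function(dose, structure) {
  d <- sort(structure_doses(dose, structure))
  n <- length(d)
  structure(
    list(doses = d,
         dose_axis_Gy = d,
         volume_fraction = (n - seq_len(n) + 1) / n,
         structure_name = structure$name,
         total_volume_cc = structure_volume_cc(structure)),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh '%s'> %.2f cc, mean %.2f Gy, range %.2f-%.2f Gy\n",
              x$structure_name, x$total_volume_cc, mean(x$doses),
              min(x$doses), max(x$doses)))
  invisible(x)
}

#' @export
as.data.frame.dvh <- function(x, ...) {
  data.frame(dose_Gy = x$dose_axis_Gy, volume_fraction = x$volume_fraction)
}

#' Build a DVH directly from a dose sample
#'
#' Constructor for tests and for dose distributions given as (dose,
#' relative volume) bins rather than grids; bins are expanded in
#' proportion to their volumes.
#'
#' @param doses numeric vector of voxel/bin doses (Gy).
#' @param structure_name label.
#' @param total_volume_cc total structure volume.
#' @return A `dvh`.
#' @export
dvh_from_doses <- function(doses, structure_name = "sample",
                           total_volume_cc = NA_real_) {
  d <- sort(as.numeric(doses))
  if (!length(d)) stop("empty dose sample")
  if (any(d < 0)) stop("doses must be non-negative")
  n <- length(d)
  structure(
    list(doses = d, dose_axis_Gy = d,
         volume_fraction = (n - seq_len(n) + 1) / n,
         structure_name = structure_name,
         total_volume_cc = total_volume_cc),
    class = "dvh"
  )
}

#' Dose metric specification
#'
#' @param kind one of `"D_percent"` (dose to the hottest `threshold`% of
#'   the volume), `"D_cc"` (dose to the hottest `threshold` cc),
#'   `"D_mean"`, `"D_min"`, `"D_max"`, `"V_Gy"` (% of volume receiving at
#'   least `threshold` Gy), `"gradient"` (D2% - D98%).
#' @param threshold percent volume, cc, or Gy as appropriate; ignored for
#'   kinds without a threshold.
#' @return An object of class `dose_metric_spec`.
#' @export
dose_metric_spec <- function(kind = c("D_percent", "D_cc", "D_mean", "D_min",
                                      "D_max", "V_Gy", "gradient"),
                             threshold = NA_real_) {
  kind <- match.arg(kind)
  if (kind %in% c("D_percent", "D_cc", "V_Gy")) {
    if (!is.finite(threshold)) stop("`threshold` required for kind ", kind)
    if (kind == "D_percent" && (threshold <= 0 || threshold > 100))
      stop("D_percent threshold must be in (0, 100]")
    if (kind != "D_percent" && threshold < 0)
      stop("threshold must be non-negative")
  }
  structure(list(kind = kind, threshold = threshold),
            class = "dose_metric_spec")
}

# Parse compact labels like "D95%", "D0.03cc", "Dmean", "V15Gy", "gradient".
parse_metric <- function(label) {
  if (inherits(label, "dose_metric_spec")) return(label)
  s <- gsub(" ", "", label)
  if (grepl("^D[0-9.]+%$", s))
    return(dose_metric_spec("D_percent", as.numeric(sub("^D([0-9.]+)%$", "\\1", s))))
  if (grepl("^D[0-9.]+cc$", s))
    return(dose_metric_spec("D_cc", as.numeric(sub("^D([0-9.]+)cc$", "\\1", s))))
  if (s %in% c("Dmean", "D_mean")) return(dose_metric_spec("D_mean"))
  if (s %in% c("Dmin", "D_min")) return(dose_metric_spec("D_min"))
  if (s %in% c("Dmax", "D_max")) return(dose_metric_spec("D_max"))
  if (grepl("^V[0-9.]+Gy$", s))
    return(dose_metric_spec("V_Gy", as.numeric(sub("^V([0-9.]+)Gy$", "\\1", s))))
  if (s %in% c("gradient", "D2%-D98%")) return(dose_metric_spec("gradient"))
  stop("cannot parse dose metric label: ", label)
}

#' Evaluate a dosimetric metric on a DVH
#'
#' `D_x%` is the smallest dose received by the hottest x% of the volume
#' (ICRU reading), obtained by linear interpolation between sorted voxel
#' doses; `D_cc` is the analogue on absolute volume; `V_xGy` is the
#' percent of volume receiving at least x Gy; `gradient` is D2% - D98%.
#'
#' @param dvh a `dvh`.
#' @param spec a [dose_metric_spec()] or a compact label such as
#'   `"D95%"`, `"D0.03cc"`, `"Dmean"`, `"V15Gy"`, `"gradient"`.
#' @return metric value (Gy, or % for `V_Gy`).
#' @export
dose_metric <- function(dvh, spec) {
  spec <- parse_metric(spec)
  d <- dvh$doses
  switch(spec$kind,
    D_percent = unname(stats::quantile(d, 1 - spec$threshold / 100, type = 7)),
    D_cc = {
      if (!is.finite(dvh$total_volume_cc))
        stop("D_cc needs a DVH with a known total volume")
      if (spec$threshold > dvh$total_volume_cc)
        stop(sprintf("D_cc threshold (%.3g cc) exceeds structure volume (%.3g cc)",
                     spec$threshold, dvh$total_volume_cc))
      p <- spec$threshold / dvh$total_volume_cc
      unname(stats::quantile(d, 1 - p, type = 7))
    },
    D_mean = mean(d),
    D_min = min(d),
    D_max = max(d),
    V_Gy = 100 * mean(d >= spec$threshold),
    gradient = unname(stats::quantile(d, 0.98, type = 7) -
                        stats::quantile(d, 0.02, type = 7))
  )
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`; 0 for a perfectly uniform target dose,
#' larger values indicate worse homogeneity.
#'
#' @param d2,d98,d50 near-maximum, near-minimum and median dose (Gy).
#' @return dimensionless HI.
#' @export
homogeneity_index <- function(d2, d98, d50) {
  if (any(d50 <= 0)) stop("D50% must be > 0")
  if (any(d2 < d98)) stop("D2% must be >= D98%")
  (d2 - d98) / d50
}

#' Paddick conformity index
#'
#' `CI = covered^2 / (target x isodose)` where `covered` is the target
#' volume receiving the prescription isodose. 1 means perfect conformity.
#'
#' @param target_volume_cc total target volume.
#' @param covered_target_volume_cc target volume covered by the
#'   prescription isodose.
#' @param prescription_isodose_volume_cc total prescription isodose volume.
#' @return CI in \[0, 1\].
#' @export
paddick_ci <- function(target_volume_cc, covered_target_volume_cc,
                       prescription_isodose_volume_cc) {
  if (target_volume_cc <= 0 || prescription_isodose_volume_cc <= 0)
    stop("target and isodose volumes must be > 0")
  if (covered_target_volume_cc >
      min(target_volume_cc, prescription_isodose_volume_cc) + 1e-9)
    stop("covered volume cannot exceed target or isodose volume")
  covered_target_volume_cc^2 /
    (target_volume_cc * prescription_isodose_volume_cc)
}

#' Goal sheet
#'
#' @param structure,metric,comparator,limit vectors of equal length:
#'   structure name, compact metric label (see [dose_metric()]),
#'   comparator (`"<="` or `">="`), and the limit value.
#' @return data.frame of class `goal_sheet`.
#' @export
goal_sheet <- function(structure, metric, comparator, limit) {
  if (!all(comparator %in% c("<=", ">=")))
    stop("comparator must be '<=' or '>='")
  if (any(limit <= 0)) stop("limits must be > 0")
  out <- data.frame(structure = structure, metric = metric,
                    comparator = comparator, limit = limit,
                    stringsAsFactors = FALSE)
  class(out) <- c("goal_sheet", "data.frame")
  out
}

#' Default CSI plan-evaluation goal sheet
#'
#' PTV coverage criteria plus the functional-organ constraints used for a
#' 23.4 Gy / 13-fraction craniospinal prescription: PTV D95 at
#' prescription, D2% cap, D98% floor, hippocampal near-max and minimum
#' dose, hypothalamus/pituitary mean, vertebral D2%-D98% gradient,
#' cochlear mean and scalp median. The `mode = "standard"` sheet carries
#' the PTV criteria only.
#'
#' @param mode `"functional_sparing"` or `"standard"`.
#' @param prescription_Gy prescription dose.
#' @return A [goal_sheet()].
#' @export
default_goal_sheet <- function(mode = c("functional_sparing", "standard"),
                               prescription_Gy = 23.4) {
  mode <- match.arg(mode)
  ptv <- goal_sheet(
    structure = c("ptv", "ptv", "ptv"),
    metric = c("D95%", "D2%", "D98%"),
    comparator = c(">=", "<=", ">="),
    limit = c(prescription_Gy, 25.7, 22))
  if (mode == "standard") return(ptv)
  oar <- goal_sheet(
    structure = c("hippocampus", "hippocampus", "hypothalamus", "pituitary",
                  "vertebrae", "cochlea", "scalp"),
    metric = c("D0.03cc", "Dmin", "Dmean", "Dmean",
               "gradient", "Dmean", "D50%"),
    comparator = c("<=", "<=", "<=", "<=", "<=", "<=", "<="),
    limit = c(16, 9, 16, 16, 5, 21, 19))
  out <- rbind(ptv, oar)
  class(out) <- c("goal_sheet", "data.frame")
  out
}

#' Evaluate a goal sheet against a dose distribution
#'
#' @param dose a [dose_grid()].
#' @param structures named list of [structure_mask()].
#' @param sheet a [goal_sheet()].
#' @return data.frame with one row per goal: achieved value, limit,
#'   comparator, `pass`, and `evaluated` (FALSE when the structure is
#'   missing -- reported, never silently skipped).
#' @export
evaluate_goals <- function(dose, structures, sheet) {
  stopifnot(inherits(sheet, "goal_sheet") || is.data.frame(sheet))
  n <- nrow(sheet)
  achieved <- rep(NA_real_, n)
  evaluated <- rep(FALSE, n)
  pass <- rep(NA, n)
  dvhs <- list()
  for (i in seq_len(n)) {
    snm <- sheet$structure[i]
    st <- structures[[snm]]
    if (is.null(st)) next
    if (is.null(dvhs[[snm]])) dvhs[[snm]] <- compute_dvh(dose, st)
    achieved[i] <- dose_metric(dvhs[[snm]], sheet$metric[i])
    evaluated[i] <- TRUE
    pass[i] <- if (sheet$comparator[i] == "<=")
      achieved[i] <= sheet$limit[i] else achieved[i] >= sheet$limit[i]
  }
  data.frame(structure = sheet$structure, metric = sheet$metric,
             comparator = sheet$comparator, limit = sheet$limit,
             achieved = achieved, pass = pass, evaluated = evaluated,
             stringsAsFactors = FALSE)
}
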