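# Quantification arithmetic for the bench assays accompanying the RIP-seq
# inference: competitive ELISA of free 8-oxoG, IP-efficiency scintillation,
# dot-blot dose linearity, reverse-transcription truncation, and
# densitometry loading normalization. All pure functions of their inputs.

.logit <- function(p) log(p / (1 - p))

#' Fit a competitive-ELISA standard curve
#'
#' In a competitive ELISA the bound-over-maximum-bound signal ratio B/B0
#' decreases with analyte concentration. The curve is linearized as
#' `logit(B/B0) = a + b * ln(conc)` and fitted by ordinary least squares
#' over the standards lying inside the configured linear range; within that
#' range the logit-log line and a four-parameter logistic coincide, and the
#' line has a closed-form inverse. The slope must be negative
#' (competition), otherwise an error is raised. Standards with B/B0 >= 1
#' are excluded with a warning.
#'
#' The sensitivity is the concentration at B/B0 = 0.80 and the midpoint
#' the concentration at B/B0 = 0.50 (`exp(-a/b)`).
#'
#' @param standards data.frame with columns `conc` (pg/ml, > 0) and
#'   `b_over_b0` in (0, 1.2]; B/B0 is computed upstream as mean bound over
#'   mean maximum bound of the replicate readings.
#' @param linear_range length-2 numeric, the assay's usable range in pg/ml
#'   (default `c(10.3, 3000)`).
#' @return `ox_standard_curve`: list with `a`, `b`, `linear_range`,
#'   `sensitivity_conc`, `midpoint_conc`, `standards` (points used).
#' @export
fit_standard_curve <- function(standards, linear_range = c(10.3, 3000)) {
  stopifnot(is.data.frame(standards),
            all(c("conc", "b_over_b0") %in% names(standards)),
            length(linear_range) == 2L, linear_range[1] < linear_range[2])
  s <- standards
  if (any(s$conc <= 0)) stop("standard concentrations must be > 0")
  if (any(s$b_over_b0 >= 1)) {
    warning("excluding ", sum(s$b_over_b0 >= 1),
            " standard(s) with B/B0 >= 1 (logit undefined)")
    s <- s[s$b_over_b0 < 1, , drop = FALSE]
  }
  if (any(s$b_over_b0 <= 0)) stop("B/B0 must be > 0")
  s <- s[s$conc >= linear_range[1] & s$conc <= linear_range[2], , drop = FALSE]
  if (length(unique(s$conc)) < 3L) {
    stop("need >= 3 distinct standard concentrations inside the linear range")
  }
  fit <- stats::lm(.logit(b_over_b0) ~ log(conc), data = s)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  if (b >= 0) stop("not a competitive curve: fitted slope is non-negative")
  curve <- structure(
    list(a = a, b = b, linear_range = as.numeric(linear_range),
         sensitivity_conc = exp((.logit(0.8) - a) / b),
         midpoint_conc = exp(-a / b),
         standards = s),
    class = "ox_standard_curve")
  stopifnot(curve$sensitivity_conc < curve$midpoint_conc)
  curve
}

#' Forward evaluation of a standard curve
#' @param curve `ox_standard_curve`.
#' @param conc concentration(s) in pg/ml.
#' @return predicted B/B0.
#' @export
curve_forward <- function(curve, conc) {
  stopifnot(all(conc > 0))
  stats::plogis(curve$a + curve$b * log(conc))
}

#' Interpolate a sample concentration from a standard curve
#'
#' Inverts the fitted logit-log line:
#' `conc = exp((logit(B/B0) - a) / b)`, then multiplies by the dilution
#' factor. The in-range flag refers to the pre-dilution (read-off)
#' concentration against the curve's linear range.
#'
#' @param curve `ox_standard_curve`.
#' @param b_over_b0 measured ratio(s), strictly inside (0, 1).
#' @param dilution_factor factor(s) the sample was diluted by (default 1).
#' @return data.frame `apparent_conc` (pg/ml, dilution-corrected) and
#'   `in_range`.
#' @export
interpolate_concentration <- function(curve, b_over_b0, dilution_factor = 1) {
  if (any(b_over_b0 <= 0 | b_over_b0 >= 1)) {
    stop("B/B0 must lie strictly in (0, 1) for interpolation")
  }
  raw <- exp((.logit(b_over_b0) - curve$a) / curve$b)
  data.frame(
    apparent_conc = raw * dilution_factor,
    in_range = raw >= curve$linear_range[1] & raw <= curve$linear_range[2])
}

#' Correct an apparent concentration for antibody cross-reactivity
#'
#' The assay antibody reacts with the RNA-form analyte at a relative
#' reactivity of `factor` (default 0.38). In `divide` mode (default) the
#' apparent concentration is divided by the factor — an antibody with 38%
#' relative reactivity under-reads the analyte; `multiply` mode applies the
#' factor the other way. The direction is exposed because kit protocols
#' state only the factor, and either mode is a constant relabeling of the
#' same measurements.
#'
#' @param conc apparent concentration(s).
#' @param factor cross-reactivity in (0, 1], default 0.38.
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return corrected concentration(s).
#' @export
correct_cross_reactivity <- function(conc, factor = 0.38,
                                     mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || factor <= 0 || factor > 1) {
    stop("cross-reactivity factor must lie in (0, 1]")
  }
  if (mode == "divide") conc / factor else conc * factor
}

#' Concordance between dilution estimates
#'
#' Replicate dilutions of one sample should interpolate to the same
#' concentration; the disparity is `100 * (max - min) / mean` and the
#' sample passes QC when it is below 20%.
#'
#' @param concs numeric vector of >= 2 per-dilution concentration
#'   estimates, all > 0.
#' @param max_disparity acceptance threshold in percent (default 20).
#' @return list `disparity_percent`, `qc_pass`.
#' @export
dilution_concordance <- function(concs, max_disparity = 20) {
  if (length(concs) < 2L) stop("need >= 2 dilution estimates")
  if (any(concs <= 0)) stop("concentrations must be > 0")
  disparity <- 100 * (max(concs) - min(concs)) / mean(concs)
  list(disparity_percent = disparity, qc_pass = disparity < max_disparity)
}

#' Convert a molar 8-oxoG concentration to mass per RNA input
#'
#' `pg/ug = nM * molar_mass * volume_per_rna`: a concentration of 1 nM
#' equals `molar_mass` pg/ml (for g/mol masses), and multiplying by the
#' assay volume per microgram of digested RNA yields pg of analyte per ug
#' of RNA. Defaults: the molar mass of 8-oxoguanosine (C10H13N5O6,
#' 299.24 g/mol) and 0.1505 ml of assay volume per ug RNA; both are
#' parameters of the assay setup, not constants.
#'
#' @param conc_nM molar concentration(s), nM, > 0.
#' @param molar_mass_g_per_mol analyte molar mass (default 299.24).
#' @param volume_per_rna_ml_per_ug assay volume per ug RNA (default 0.1505).
#' @return pg of analyte per ug of RNA.
#' @seealso [pg_per_ug_to_nm()] for the exact inverse.
#' @export
nm_to_pg_per_ug <- function(conc_nM, molar_mass_g_per_mol = 299.24,
                            volume_per_rna_ml_per_ug = 0.1505) {
  stopifnot(all(conc_nM > 0), molar_mass_g_per_mol > 0,
            volume_per_rna_ml_per_ug > 0)
  conc_nM * molar_mass_g_per_mol * volume_per_rna_ml_per_ug
}

#' @rdname nm_to_pg_per_ug
#' @param pg_per_ug mass of analyte per ug RNA, > 0.
#' @export
pg_per_ug_to_nm <- function(pg_per_ug, molar_mass_g_per_mol = 299.24,
                            volume_per_rna_ml_per_ug = 0.1505) {
  stopifnot(all(pg_per_ug > 0), molar_mass_g_per_mol > 0,
            volume_per_rna_ml_per_ug > 0)
  pg_per_ug / (molar_mass_g_per_mol * volume_per_rna_ml_per_ug)
}

#' Quantify a sample from ELISA readings
#'
#' Full competitive-ELISA sample quantification: interpolate each dilution
#' reading on the standard curve, correct for antibody cross-reactivity,
#' check dilution concordance, and convert the mean concentration to
#' pg per ug RNA and nM.
#'
#' @param curve `ox_standard_curve`.
#' @param readings data.frame with columns `b_over_b0` and `dilution`
#'   (dilution factor per reading).
#' @param cross_reactivity factor passed to [correct_cross_reactivity()].
#' @param mode cross-reactivity mode.
#' @param molar_mass_g_per_mol,volume_per_rna_ml_per_ug unit-conversion
#'   parameters, see [nm_to_pg_per_ug()].
#' @return `ox_elisa_quant`: list with `per_dilution` (data.frame
#'   `apparent_conc`, `in_range`, `corrected_conc`), `disparity_percent`,
#'   `qc_pass`, `conc_pg_ml`, `conc_nM`, `pg_per_ug_rna`.
#' @export
elisa_quantify <- function(curve, readings, cross_reactivity = 0.38,
                           mode = c("divide", "multiply"),
                           molar_mass_g_per_mol = 299.24,
                           volume_per_rna_ml_per_ug = 0.1505) {
  mode <- match.arg(mode)
  stopifnot(all(c("b_over_b0", "dilution") %in% names(readings)))
  interp <- interpolate_concentration(curve, readings$b_over_b0,
                                      readings$dilution)
  interp$corrected_conc <- correct_cross_reactivity(interp$apparent_conc,
                                                    cross_reactivity, mode)
  conc <- dilution_concordance(interp$corrected_conc)
  mean_conc <- mean(interp$corrected_conc)
  conc_nM <- mean_conc / molar_mass_g_per_mol
  structure(list(per_dilution = interp,
                 disparity_percent = conc$disparity_percent,
                 qc_pass = conc$qc_pass,
                 conc_pg_ml = mean_conc,
                 conc_nM = conc_nM,
                 pg_per_ug_rna = nm_to_pg_per_ug(conc_nM,
                                                 molar_mass_g_per_mol,
                                                 volume_per_rna_ml_per_ug)),
            class = "ox_elisa_quant")
}

#' Immunoprecipitation efficiency from scintillation counts
#'
#' `100 * (eluted - background) / (input - background)`, clipped to
#' `[0, 100]` with a flag when clipping occurred.
#'
#' @param eluted_counts counts recovered in the eluate, >= 0.
#' @param input_counts counts in the input, must exceed background.
#' @param background_counts no-antibody background (default 0).
#' @return list `percent`, `clipped`.
#' @export
ip_efficiency <- function(eluted_counts, input_counts, background_counts = 0) {
  stopifnot(eluted_counts >= 0, background_counts >= 0)
  if (input_counts <= background_counts) {
    stop("input counts must exceed background")
  }
  raw <- 100 * (eluted_counts - background_counts) /
    (input_counts - background_counts)
  list(percent = min(max(raw, 0), 100), clipped = raw < 0 || raw > 100)
}

#' Dose linearity of dot-blot binding signal
#'
#' OLS of binding signal on the number of oxidized marks per
#' oligonucleotide; a high R-squared indicates mark-count-proportional
#' binding (little sequence bias).
#'
#' @param marks_per_oligo integer vector (>= 3 points, not all equal).
#' @param signals positive numeric vector, same length.
#' @return list `slope`, `intercept`, `r_squared`.
#' @export
dotblot_linearity <- function(marks_per_oligo, signals) {
  stopifnot(length(marks_per_oligo) == length(signals),
            length(signals) >= 3L, all(signals > 0))
  if (length(unique(marks_per_oligo)) < 2L) {
    stop("marks_per_oligo is constant; slope undefined")
  }
  fit <- stats::lm(signals ~ marks_per_oligo)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((signals - mean(signals))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

#' Reverse-transcription truncation index
#'
#' Oxidized bases carrying a bulky adduct stop reverse transcription, so
#' oxidation depletes the distal (full-length) PCR product relative to the
#' proximal product. Per condition, the target's distal/proximal ratio is
#' normalized by the same ratio of an internal normalizer (e.g. GAPDH);
#' the oxidation index is the exposed over control normalized ratio, and a
#' transcript is called oxidized when the index falls below
#' `call_threshold`.
#'
#' @param intensities named list with elements `exposed` and `control`,
#'   each a named list/vector with `target_proximal`, `target_distal`,
#'   `norm_proximal`, `norm_distal`, all > 0.
#' @param call_threshold index below which oxidation is called
#'   (default 0.8).
#' @return `ox_truncation`: list with `ratio_exposed`, `ratio_control`
#'   (normalized distal/proximal), `oxidation_index`, `oxidized`.
#' @export
truncation_index <- function(intensities, call_threshold = 0.8) {
  ratio <- function(cond) {
    v <- intensities[[cond]]
    need <- c("target_proximal", "target_distal", "norm_proximal",
              "norm_distal")
    miss <- setdiff(need, names(v))
    if (length(miss)) stop("missing band(s) for ", cond, ": ",
                           paste(miss, collapse = ", "))
    bad <- need[unlist(v[need]) <= 0]
    if (length(bad)) stop("non-positive intensity for ", cond, " band(s): ",
                          paste(bad, collapse = ", "))
    (v[["target_distal"]] / v[["target_proximal"]]) /
      (v[["norm_distal"]] / v[["norm_proximal"]])
  }
  re <- ratio("exposed")
  rc <- ratio("control")
  idx <- re / rc
  structure(list(ratio_exposed = re, ratio_control = rc,
                 oxidation_index = idx, oxidized = idx < call_threshold),
            class = "ox_truncation")
}

#' Loading-control-normalized expression fold change
#'
#' Densitometry: each lane's target signal is divided by its loading
#' control (e.g. GAPDH), and the control-to-exposed ratio of these
#' normalized signals is the reported fold change (> 1 means lower target
#' protein in exposed cells).
#'
#' @param target_control,loading_control signals in the control lane, > 0.
#' @param target_exposed,loading_exposed signals in the exposed lane, > 0.
#' @return fold change (control over exposed) of normalized signal.
#' @export
loading_normalize <- function(target_control, loading_control,
                              target_exposed, loading_exposed) {
  vals <- c(target_control, loading_control, target_exposed, loading_exposed)
  if (any(vals <= 0)) stop("all signals must be > 0")
  (target_control / loading_control) / (target_exposed / loading_exposed)
}
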