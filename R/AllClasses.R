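#' @import methods
NULL

## Conversion between echo times declared in ms and relaxation rates in 1/s.
## This is the only place the factor appears; internal math uses it once.
.MS_PER_S <- 1000

#' Diffusion acquisition protocol
#'
#' Ordered schedule of diffusion sensitivity coefficients (b-values) for a
#' multi-b-value DWI acquisition. The segmented IVIM fit needs at least two
#' points on each side of the segment boundary, hence the minimum length of 4
#' and the requirement that a b = 0 measurement is present.
#'
#' @slot bvalues numeric, b-values in s/mm^2; non-negative, strictly
#'   increasing, containing 0.
#'
#' @seealso [defaultDiffusionProtocol()], [ivimSignal()]
#' @export
setClass("DiffusionProtocol", representation(bvalues = "numeric"))

setValidity("DiffusionProtocol", function(object) {
  b <- object@bvalues
  if (length(b) < 4L)
    return("bvalues: need at least 4 b-values (2 per fit segment)")
  if (anyNA(b) || any(b < 0))
    return("bvalues: must be non-negative and non-missing")
  if (any(diff(b) <= 0))
    return("bvalues: must be strictly increasing")
  if (b[1L] != 0)
    return("bvalues: must contain b = 0 as the first entry")
  TRUE
})

#' Multi-echo gradient-echo acquisition protocol
#'
#' Echo-time schedule for R2* relaxometry. Echo times are declared in
#' milliseconds, as printed on scanner protocols; fitted R2* is reported in
#' 1/s. The repetition time is carried as metadata only and never enters the
#' fit.
#'
#' @slot echo_times numeric, echo times in ms; positive, strictly increasing,
#'   length >= 3.
#' @slot repetition_time numeric(1), TR in ms (metadata).
#'
#' @seealso [defaultRelaxometryProtocol()], [greSignal()]
#' @export
setClass("RelaxometryProtocol",
         representation(echo_times = "numeric", repetition_time = "numeric"))

setValidity("RelaxometryProtocol", function(object) {
  te <- object@echo_times
  if (length(te) < 3L)
    return("echo_times: need at least 3 echoes")
  if (anyNA(te) || any(te <= 0))
    return("echo_times: must be positive and non-missing")
  if (any(diff(te) <= 0))
    return("echo_times: must be strictly increasing")
  if (length(object@repetition_time) != 1L || is.na(object@repetition_time) ||
      object@repetition_time <= 0)
    return("repetition_time: must be a single positive value (ms)")
  TRUE
})

#' Bi-exponential IVIM tissue parameters
#'
#' Per-voxel (or per-region) parameters of the intravoxel incoherent motion
#' signal model: the unattenuated signal S0, the true diffusion coefficient D
#' of water in tissue, the pseudo-diffusion coefficient D* attributed to
#' capillary blood motion, and the perfusion fraction f. D and D* are stored
#' in mm^2/s; display-unit conversion (1e-3 mm^2/s, percent) is a formatting
#' concern, see [displayUnits()].
#'
#' @slot S0 numeric(1), signal at b = 0, arbitrary units, > 0.
#' @slot D numeric(1), true diffusion coefficient, mm^2/s, > 0.
#' @slot Dstar numeric(1), pseudo-diffusion coefficient, mm^2/s, > D
#'   (identifiability of the two compartments).
#' @slot f numeric(1), perfusion fraction in [0, 1].
#'
#' @export
setClass("IVIMParams",
         representation(S0 = "numeric", D = "numeric", Dstar = "numeric",
                        f = "numeric"))

setValidity("IVIMParams", function(object) {
  for (nm in c("S0", "D", "Dstar", "f")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v)) return(paste0(nm, ": must be a single finite value"))
  }
  if (object@S0 <= 0) return("S0: must be > 0")
  if (object@D <= 0) return("D: must be > 0")
  if (object@Dstar <= object@D) return("Dstar: must exceed D")
  if (object@f < 0 || object@f > 1) return("f: must lie in [0, 1]")
  TRUE
})

#' Mono-exponential transverse decay parameters
#'
#' Signal model for multi-echo gradient-echo decay: SI(TE) = S0 exp(-R2* TE).
#' R2* is stored in 1/s; T2* = 1/R2* is derived on demand, never stored.
#'
#' @slot S0 numeric(1), extrapolated signal at TE = 0, > 0.
#' @slot R2star numeric(1), effective transverse relaxation rate, 1/s, >= 0.
#'
#' @export
setClass("MonoexpDecayParams",
         representation(S0 = "numeric", R2star = "numeric"))

setValidity("MonoexpDecayParams", function(object) {
  if (length(object@S0) != 1L || is.na(object@S0) || object@S0 <= 0)
    return("S0: must be a single value > 0")
  if (length(object@R2star) != 1L || is.na(object@R2star) || object@R2star < 0)
    return("R2star: must be a single value >= 0")
  TRUE
})

#' Noise specification for simulated signals
#'
#' Magnitude MRI noise is Rician: independent Gaussian noise on the two
#' quadrature channels followed by the modulus. A plain additive Gaussian
#' model and a noiseless mode are available for controlled tests.
#'
#' @slot model character(1), one of "none", "gaussian", "rician".
#' @slot sigma numeric(1), per-channel noise SD in signal units; ignored for
#'   model "none".
#' @slot seed integer(1) or NA; when set, [addNoise()] seeds its draw so a
#'   standalone call is reproducible.
#'
#' @export
setClass("NoiseSpec",
         representation(model = "character", sigma = "numeric",
                        seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (!object@model %in% c("none", "gaussian", "rician"))
    return("model: must be one of 'none', 'gaussian', 'rician'")
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
    return("sigma: must be a single value >= 0")
  TRUE
})

#' Tissue region parameterisation for the phantom
#'
#' Voxelwise truth parameters for one phantom region are drawn from
#' independent normals with these means and SDs, then clipped/redrawn into the
#' physical ranges of [IVIMParams-class] and [MonoexpDecayParams-class].
#' Quantities: S0 (a.u.), D and Dstar (mm^2/s), f (fraction), R2star (1/s).
#'
#' @slot mean named numeric with entries S0, D, Dstar, f, R2star.
#' @slot sd named numeric, same names, all >= 0.
#'
#' @export
setClass("RegionParams", representation(mean = "numeric", sd = "numeric"))

.REGION_QUANTITIES <- c("S0", "D", "Dstar", "f", "R2star")

setValidity("RegionParams", function(object) {
  for (sl in c("mean", "sd")) {
    v <- slot(object, sl)
    if (!all(.REGION_QUANTITIES %in% names(v)))
      return(paste0(sl, ": must name ", paste(.REGION_QUANTITIES, collapse = ", ")))
    if (anyNA(v[.REGION_QUANTITIES]))
      return(paste0(sl, ": contains missing values"))
  }
  if (any(object@sd[.REGION_QUANTITIES] < 0)) return("sd: must be >= 0")
  m <- object@mean
  if (m[["S0"]] <= 0 || m[["D"]] <= 0 || m[["f"]] < 0 || m[["f"]] > 1 ||
      m[["Dstar"]] <= m[["D"]] || m[["R2star"]] < 0)
    return("mean: region means must satisfy the tissue-parameter invariants")
  TRUE
})

#' Synthetic phantom geometry and tissue parameters
#'
#' An ellipsoidal "tumor" embedded in a rectangular grid of background
#' tissue, standing in for the imaged xenograft volume. Tumor tissue means
#' default to the baseline tumor values of the reference study
#' (D = 0.556e-3 mm^2/s, D* = 8.53e-3 mm^2/s, f = 0.1675, R2* = 24.74 /s).
#'
#' @slot grid integer(3), volume dimensions in voxels.
#' @slot center numeric(3), ellipsoid centre, 0-based voxel coordinates.
#' @slot semi_axes numeric(3), ellipsoid semi-axes in voxels, all > 0.
#' @slot tumor,background [RegionParams-class] for the two regions.
#'
#' @seealso [phantomSpec()], [generateIvimVolume()], [generateGreVolume()]
#' @export
setClass("PhantomSpec",
         representation(grid = "integer", center = "numeric",
                        semi_axes = "numeric", tumor = "RegionParams",
                        background = "RegionParams"))

setValidity("PhantomSpec", function(object) {
  if (length(object@grid) != 3L || any(object@grid < 1L))
    return("grid: must be 3 positive dimensions")
  if (length(object@center) != 3L || length(object@semi_axes) != 3L)
    return("center/semi_axes: must have length 3")
  if (any(object@semi_axes <= 0))
    return("semi_axes: must be strictly positive (degenerate ellipsoid)")
  if (any(object@center - object@semi_axes < -0.5) ||
      any(object@center + object@semi_axes > object@grid - 0.5))
    return("ellipsoid does not fit inside the grid")
  TRUE
})

#' Longitudinal study design
#'
#' The group-by-timepoint layout of the animal study together with the target
#' mean/SD for every measured quantity in every cell, from which synthetic
#' per-animal records are drawn. The default design is 4 treatment groups
#' (A saline control, B free drug, C low-dose nanoparticle, D full-dose
#' nanoparticle) x 4 time points (base, 1, 2, 3 weeks) with n = 8 animals per
#' group, and cell targets packaged from the reference study tables.
#'
#' @slot groups character, group labels.
#' @slot timepoints character, time point labels in chronological order.
#' @slot n_per_group integer(1), animals per group, >= 2.
#' @slot cell_targets data.frame with columns quantity, group, timepoint,
#'   mean, sd. Pathology quantities may be restricted to the final time point.
#'
#' @seealso [studyDesign()], [generateStudy()]
#' @export
setClass("StudyDesign",
         representation(groups = "character", timepoints = "character",
                        n_per_group = "integer", cell_targets = "data.frame"))

setValidity("StudyDesign", function(object) {
  if (length(object@groups) < 1L || anyDuplicated(object@groups))
    return("groups: must be distinct labels")
  if (length(object@timepoints) < 1L || anyDuplicated(object@timepoints))
    return("timepoints: must be distinct labels")
  if (object@n_per_group < 2L)
    return("n_per_group: must be >= 2")
  ct <- object@cell_targets
  need <- c("quantity", "group", "timepoint", "mean", "sd")
  if (!all(need %in% names(ct)))
    return(paste("cell_targets: must have columns", paste(need, collapse = ", ")))
  if (nrow(ct) > 0 && (anyNA(ct$mean) || anyNA(ct$sd) || any(ct$sd < 0)))
    return("cell_targets: means must be present and sd >= 0")
  TRUE
})

#' Segmented IVIM fit configuration
#'
#' @slot boundary numeric(1), b-value threshold splitting the low-b
#'   (perfusion-dominated) and high-b (diffusion-dominated) segments, s/mm^2.
#'   Default 200; membership of the boundary itself is governed by
#'   \code{highb_inclusive}.
#' @slot bounds_D,bounds_Dstar,bounds_f numeric(2) box constraints (mm^2/s,
#'   mm^2/s, dimensionless). The lower D* bound is additionally tied to the
#'   step-1 D estimate at fit time.
#' @slot max_iter integer(1), optimizer iteration cap.
#' @slot tol numeric(1), optimizer relative tolerance.
#' @slot step2_all_b logical(1); TRUE (default) fits the perfusion step on
#'   all b-values with D fixed, FALSE restricts it to the low-b segment only.
#' @slot highb_inclusive logical(1); FALSE (default) defines the high-b
#'   segment as b strictly above the boundary.
#'
#' @seealso [fitConfig()], [fitIvimVoxel()]
#' @export
setClass("FitConfig",
         representation(boundary = "numeric", bounds_D = "numeric",
                        bounds_Dstar = "numeric", bounds_f = "numeric",
                        max_iter = "integer", tol = "numeric",
                        step2_all_b = "logical", highb_inclusive = "logical"))

setValidity("FitConfig", function(object) {
  if (length(object@boundary) != 1L || object@boundary <= 0)
    return("boundary: must be a single positive b-value")
  for (nm in c("bounds_D", "bounds_Dstar", "bounds_f")) {
    v <- slot(object, nm)
    if (length(v) != 2L || v[1L] >= v[2L])
      return(paste0(nm, ": must be increasing (lower, upper)"))
  }
  if (object@max_iter < 1L) return("max_iter: must be >= 1")
  if (object@tol <= 0) return("tol: must be > 0")
  TRUE
})

#' R2* fit configuration
#'
#' @slot noise_floor numeric(1), absolute signal floor; echoes at or below
#'   max(noise_floor, tiny positive) are excluded before the log transform to
#'   keep the Rician floor from biasing R2* downward. Default 0 (keep all
#'   positive echoes).
#' @slot min_echoes integer(1), minimum usable echoes for a fit (>= 3).
#' @slot max_echoes integer(1) or NA, truncate the echo train to the first so
#'   many echoes before fitting.
#' @slot weighted logical(1); FALSE (default) is plain OLS on the log scale,
#'   TRUE weights by squared signal (variance-stabilising for log-transformed
#'   additive noise).
#'
#' @seealso [r2starConfig()], [fitR2starVoxel()]
#' @export
setClass("R2starConfig",
         representation(noise_floor = "numeric", min_echoes = "integer",
                        max_echoes = "integer", weighted = "logical"))

setValidity("R2starConfig", function(object) {
  if (object@noise_floor < 0) return("noise_floor: must be >= 0")
  if (object@min_echoes < 3L) return("min_echoes: must be >= 3")
  if (!is.na(object@max_echoes) && object@max_echoes < object@min_echoes)
    return("max_echoes: must be >= min_echoes")
  TRUE
})

#' Result of a voxelwise segmented IVIM fit
#'
#' @slot params [IVIMParams-class] estimates; meaningful only when
#'   \code{converged} is TRUE.
#' @slot rss numeric(1), residual sum of squares of the full bi-exponential
#'   model at the returned estimates.
#' @slot n_highb,n_lowb integer(1), points used in each segment.
#' @slot converged logical(1).
#' @slot boundary numeric(1), b-threshold used, s/mm^2.
#'
#' @export
setClass("IVIMFitResult",
         representation(params = "IVIMParams", rss = "numeric",
                        n_highb = "integer", n_lowb = "integer",
                        converged = "logical", boundary = "numeric"))

setValidity("IVIMFitResult", function(object) {
  if (length(object@rss) != 1L || is.na(object@rss) || object@rss < 0)
    return("rss: must be a single value >= 0")
  TRUE
})

#' Result of a voxelwise R2* fit
#'
#' @slot params [MonoexpDecayParams-class] estimates.
#' @slot r_squared numeric(1), goodness of the linear fit on the log scale;
#'   0 is reported (with \code{degenerate = TRUE}) when it is undefined.
#' @slot n_echoes_used integer(1).
#' @slot converged logical(1), FALSE when fewer than the minimum echoes were
#'   usable.
#' @slot degenerate logical(1), TRUE when the slope was clamped at 0 or the
#'   fit was otherwise degenerate (e.g. constant signal).
#'
#' @export
setClass("R2starFitResult",
         representation(params = "MonoexpDecayParams", r_squared = "numeric",
                        n_echoes_used = "integer", converged = "logical",
                        degenerate = "logical"))

setValidity("R2starFitResult", function(object) {
  r2 <- object@r_squared
  if (length(r2) != 1L || is.na(r2) || r2 < 0 || r2 > 1 + 1e-12)
    return("r_squared: must lie in [0, 1]")
  TRUE
})

#' One-way ANOVA result
#'
#' Classical fixed-effects between/within variance decomposition. An infinite
#' F (zero within-cell variance with unequal means) is flagged rather than
#' raised.
#'
#' @slot F numeric(1), variance ratio, >= 0 (may be Inf, see
#'   \code{infinite_F}).
#' @slot df_between,df_within integer(1).
#' @slot p numeric(1), upper-tail probability from the F distribution.
#' @slot ms_between,ms_within numeric(1), mean squares.
#' @slot infinite_F logical(1).
#'
#' @export
setClass("AnovaResult",
         representation(F = "numeric", df_between = "integer",
                        df_within = "integer", p = "numeric",
                        ms_between = "numeric", ms_within = "numeric",
                        infinite_F = "logical"))

setValidity("AnovaResult", function(object) {
  if (is.na(object@F) || object@F < 0) return("F: must be >= 0")
  if (object@df_between < 1L || object@df_within < 1L)
    return("degrees of freedom must be positive")
  if (is.na(object@p) || object@p < 0 || object@p > 1)
    return("p: must lie in [0, 1]")
  TRUE
})

#' Student-Newman-Keuls post hoc result
#'
#' @slot comparisons data.frame, one row per ordered pair of groups:
#'   group1, group2 (labels; group1 has the smaller sorted mean), r (range
#'   span of the comparison), q (studentized range statistic), q_crit
#'   (critical value at \code{alpha} for that span), reject (logical; FALSE
#'   either because q <= q_crit or because an enclosing non-rejection blocked
#'   the pair, see \code{blocked}).
#' @slot alpha numeric(1), familywise level per range step.
#' @slot df_within integer(1), error degrees of freedom from the ANOVA.
#'
#' @export
setClass("PosthocResult",
         representation(comparisons = "data.frame", alpha = "numeric",
                        df_within = "integer"))

setValidity("PosthocResult", function(object) {
  cmp <- object@comparisons
  need <- c("group1", "group2", "r", "q", "q_crit", "reject", "blocked")
  if (!all(need %in% names(cmp)))
    return(paste("comparisons: must have columns", paste(need, collapse = ", ")))
  bad <- !cmp$blocked & cmp$reject & !(cmp$q > cmp$q_crit)
  if (nrow(cmp) > 0 && any(bad, na.rm = TRUE))
    return("reject implies q > q_crit")
  TRUE
})

#' Pearson correlation with strength label
#'
#' Strength labels follow the convention of the reference study: |r| > 0.8 is
#' "high", 0.5 <= |r| <= 0.8 is "moderate", otherwise "weak".
#'
#' @slot r numeric(1) in [-1, 1].
#' @slot p numeric(1), two-sided p from the t transform on n - 2 df.
#' @slot n integer(1).
#' @slot strength character(1), one of "high", "moderate", "weak".
#'
#' @export
setClass("CorrelationResult",
         representation(r = "numeric", p = "numeric", n = "integer",
                        strength = "character"))

setValidity("CorrelationResult", function(object) {
  if (is.na(object@r) || abs(object@r) > 1 + 1e-12)
    return("r: must lie in [-1, 1]")
  if (!object@strength %in% c("high", "moderate", "weak"))
    return("strength: must be 'high', 'moderate' or 'weak'")
  TRUE
})
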