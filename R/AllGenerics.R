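#' @include AllClasses.R
NULL

#' b-values of a diffusion protocol
#' @param object a [DiffusionProtocol-class]
#' @return numeric vector of b-values, s/mm^2
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname bValues
#' @export
setMethod("bValues", "DiffusionProtocol", function(object) object@bvalues)

#' Echo times of a relaxometry protocol
#' @param object a [RelaxometryProtocol-class]
#' @return numeric vector of echo times, ms
#' @export
setGeneric("echoTimes", function(object) standardGeneric("echoTimes"))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "RelaxometryProtocol", function(object) object@echo_times)

#' Repetition time metadata of a relaxometry protocol
#' @param object a [RelaxometryProtocol-class]
#' @return TR in ms
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))

#' @rdname repetitionTime
#' @export
setMethod("repetitionTime", "RelaxometryProtocol",
          function(object) object@repetition_time)

#' Forward IVIM signal model
#'
#' Evaluates the bi-exponential intravoxel incoherent motion decay
#' \deqn{SI(b) = S0 [(1 - f) e^{-b D} + f e^{-b D^*}]}
#' at every b-value of the protocol. At b = 0 the two compartments sum to
#' S0 exactly; for large b D* the perfusion compartment has fully decayed and
#' the signal approaches the mono-exponential (1 - f) S0 exp(-b D).
#'
#' @param params an [IVIMParams-class]
#' @param protocol a [DiffusionProtocol-class]
#' @return numeric vector of signals (a.u.), one per b-value; strictly
#'   positive and non-increasing in b.
#' @examples
#' p <- ivimParams(S0 = 1000, D = 1.0e-3, Dstar = 10e-3, f = 0.2)
#' ivimSignal(p, diffusionProtocol(c(0, 100, 500, 1000)))
#' @export
setGeneric("ivimSignal", function(params, protocol) standardGeneric("ivimSignal"))

#' Forward gradient-echo decay model
#'
#' Evaluates SI(TE) = S0 exp(-R2* TE) at every echo time. Echo times are in
#' ms and R2* in 1/s; the unit conversion is internal.
#'
#' @param params a [MonoexpDecayParams-class]
#' @param protocol a [RelaxometryProtocol-class]
#' @return numeric vector of signals (a.u.), one per echo.
#' @examples
#' p <- monoexpDecayParams(S0 = 1000, R2star = 25)
#' greSignal(p, relaxometryProtocol(c(10, 20, 40)))
#' @export
setGeneric("greSignal", function(params, protocol) standardGeneric("greSignal"))

#' Extract the parameter estimates from a fit result
#' @param object an [IVIMFitResult-class] or [R2starFitResult-class]
#' @return the embedded parameter object
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname fitParams
#' @export
setMethod("fitParams", "IVIMFitResult", function(object) object@params)

#' @rdname fitParams
#' @export
setMethod("fitParams", "R2starFitResult", function(object) object@params)

#' Did a voxel fit converge?
#' @param object a fit result
#' @return logical(1)
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname isConverged
#' @export
setMethod("isConverged", "IVIMFitResult", function(object) object@converged)

#' @rdname isConverged
#' @export
setMethod("isConverged", "R2starFitResult", function(object) object@converged)

## ---- show methods -------------------------------------------------------

setMethod("show", "DiffusionProtocol", function(object) {
  b <- object@bvalues
  cat("DiffusionProtocol:", length(b), "b-values,",
      sprintf("%g..%g s/mm^2\n", min(b), max(b)))
})

setMethod("show", "RelaxometryProtocol", function(object) {
  te <- object@echo_times
  cat("RelaxometryProtocol:", length(te), "echoes,",
      sprintf("TE %g..%g ms, TR %g ms\n", min(te), max(te),
              object@repetition_time))
})

setMethod("show", "IVIMParams", function(object) {
  u <- displayUnits(object)
  cat(sprintf(
    "IVIMParams: S0 = %.4g, D = %.4g x 1e-3 mm^2/s, D* = %.4g x 1e-3 mm^2/s, f = %.4g%%\n",
    object@S0, u[["D"]], u[["Dstar"]], u[["f"]]))
})

setMethod("show", "MonoexpDecayParams", function(object) {
  cat(sprintf("MonoexpDecayParams: S0 = %.4g, R2* = %.4g /s (T2* = %.4g ms)\n",
              object@S0, object@R2star,
              if (object@R2star > 0) .MS_PER_S / object@R2star else Inf))
})

setMethod("show", "IVIMFitResult", function(object) {
  cat(sprintf("IVIMFitResult (%s): boundary %g s/mm^2, %d low-b + %d high-b points, rss %.4g\n",
              if (object@converged) "converged" else "NOT converged",
              object@boundary, object@n_lowb, object@n_highb, object@rss))
  if (object@converged) show(object@params)
})

setMethod("show", "R2starFitResult", function(object) {
  cat(sprintf("R2starFitResult (%s): %d echoes, R^2 = %.4f\n",
              if (object@converged) "converged" else "NOT converged",
              object@n_echoes_used, object@r_squared))
  if (object@converged) show(object@params)
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              object@df_between, object@df_within, object@F, object@p,
              if (object@infinite_F) " [infinite F: zero within-group variance]" else ""))
})

setMethod("show", "PosthocResult", function(object) {
  cat(sprintf("SNK post hoc at alpha = %g (%d comparisons, %d rejected)\n",
              object@alpha, nrow(object@comparisons),
              sum(object@comparisons$reject)))
  print(object@comparisons, row.names = FALSE)
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.4g): %s correlation\n",
              object@r, object@n, object@p, object@strength))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: grid %s, ellipsoid centre (%s), semi-axes (%s)\n",
              paste(object@grid, collapse = "x"),
              paste(object@center, collapse = ", "),
              paste(object@semi_axes, collapse = ", ")))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d groups x %d timepoints, n = %d per group, %d cell targets\n",
              length(object@groups), length(object@timepoints),
              object@n_per_group, nrow(object@cell_targets)))
})
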