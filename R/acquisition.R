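#' @include AllGenerics.R
NULL

#' Construct a diffusion protocol
#'
#' @param bvalues numeric vector of b-values in s/mm^2; must be non-negative,
#'   strictly increasing, start at 0 and have length >= 4.
#' @return a [DiffusionProtocol-class]
#' @examples
#' diffusionProtocol(c(0, 200, 600, 1000))
#' @export
diffusionProtocol <- function(bvalues) {
  new("DiffusionProtocol", bvalues = as.numeric(bvalues))
}

#' Construct a relaxometry protocol
#'
#' @param echo_times numeric vector of echo times in ms; positive, strictly
#'   increasing, length >= 3.
#' @param repetition_time TR in ms (metadata only).
#' @return a [RelaxometryProtocol-class]
#' @export
relaxometryProtocol <- function(echo_times, repetition_time = 160) {
  new("RelaxometryProtocol", echo_times = as.numeric(echo_times),
      repetition_time = as.numeric(repetition_time))
}

#' Construct IVIM tissue parameters
#'
#' @param S0 unattenuated signal, > 0 (a.u.).
#' @param D true diffusion coefficient, mm^2/s, > 0.
#' @param Dstar pseudo-diffusion coefficient, mm^2/s, > D.
#' @param f perfusion fraction in [0, 1].
#' @return an [IVIMParams-class]
#' @export
ivimParams <- function(S0, D, Dstar, f) {
  new("IVIMParams", S0 = as.numeric(S0), D = as.numeric(D),
      Dstar = as.numeric(Dstar), f = as.numeric(f))
}

#' Construct mono-exponential decay parameters
#'
#' @param S0 signal at TE = 0, > 0 (a.u.).
#' @param R2star transverse relaxation rate, 1/s, >= 0.
#' @return a [MonoexpDecayParams-class]
#' @export
monoexpDecayParams <- function(S0, R2star) {
  new("MonoexpDecayParams", S0 = as.numeric(S0), R2star = as.numeric(R2star))
}

#' @rdname ivimSignal
#' @export
setMethod("ivimSignal", signature("IVIMParams", "DiffusionProtocol"),
          function(params, protocol) {
  b <- protocol@bvalues
  params@S0 * ((1 - params@f) * exp(-b * params@D) +
               params@f * exp(-b * params@Dstar))
})

#' @rdname greSignal
#' @export
setMethod("greSignal", signature("MonoexpDecayParams", "RelaxometryProtocol"),
          function(params, protocol) {
  te_s <- protocol@echo_times / .MS_PER_S   # TE declared in ms, R2* in 1/s
  params@S0 * exp(-params@R2star * te_s)
})

#' Default acquisition protocols
#'
#' The 13-b-value diffusion schedule (0-1500 s/mm^2) and 16-echo
#' gradient-echo schedule (TE 3.4-92.1 ms, TR 160 ms) of the reference
#' preclinical study at 1.5 T.
#'
#' @return \code{defaultDiffusionProtocol}: a [DiffusionProtocol-class] of
#'   length 13; \code{defaultRelaxometryProtocol}: a
#'   [RelaxometryProtocol-class] of length 16; \code{defaultProtocols}: a
#'   list with elements \code{diffusion} and \code{relaxometry}.
#' @export
defaultDiffusionProtocol <- function() {
  diffusionProtocol(c(0, 25, 50, 75, 100, 150, 200, 400, 600, 800,
                      1000, 1200, 1500))
}

#' @rdname defaultDiffusionProtocol
#' @export
defaultRelaxometryProtocol <- function() {
  relaxometryProtocol(c(3.4, 9.3, 15.2, 21.2, 27.1, 33, 38.9, 44.8, 50.7,
                        56.6, 62.5, 68.5, 74.4, 80.3, 86.2, 92.1),
                      repetition_time = 160)
}

#' @rdname defaultDiffusionProtocol
#' @export
defaultProtocols <- function() {
  list(diffusion = defaultDiffusionProtocol(),
       relaxometry = defaultRelaxometryProtocol())
}

#' Convert fitted parameters to the display units of the study tables
#'
#' Internally D and D* are mm^2/s and f is a fraction; the tables print D and
#' D* in 1e-3 mm^2/s and f in percent. R2* is both stored and printed in 1/s.
#'
#' @param params an [IVIMParams-class] or a named numeric/list with entries
#'   among S0, D, Dstar, f, R2star (internal units).
#' @return named numeric in display units.
#' @export
displayUnits <- function(params) {
  if (is(params, "IVIMParams"))
    params <- c(S0 = params@S0, D = params@D, Dstar = params@Dstar,
                f = params@f)
  out <- unlist(params)
  if ("D" %in% names(out)) out[["D"]] <- out[["D"]] * 1e3
  if ("Dstar" %in% names(out)) out[["Dstar"]] <- out[["Dstar"]] * 1e3
  if ("f" %in% names(out)) out[["f"]] <- out[["f"]] * 100
  out
}

#' Read and write protocol sidecar files
#'
#' Protocols travel with their volumes as a plain-text JSON sidecar with the
#' schema \code{{"bvalues": [...], "echo_times_ms": [...], "tr_ms": x}}; a
#' sidecar may carry either or both protocols.
#'
#' @param diffusion a [DiffusionProtocol-class] or NULL.
#' @param relaxometry a [RelaxometryProtocol-class] or NULL.
#' @param path file path of the sidecar.
#' @return \code{readProtocol}: a list with elements \code{diffusion} and
#'   \code{relaxometry} (NULL when absent from the file).
#' @export
writeProtocol <- function(path, diffusion = NULL, relaxometry = NULL) {
  stopifnot(!is.null(diffusion) || !is.null(relaxometry))
  doc <- list()
  if (!is.null(diffusion)) {
    validObject(diffusion)
    doc$bvalues <- diffusion@bvalues
  }
  if (!is.null(relaxometry)) {
    validObject(relaxometry)
    doc$echo_times_ms <- relaxometry@echo_times
    doc$tr_ms <- relaxometry@repetition_time
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    diffusion = if (!is.null(doc$bvalues)) diffusionProtocol(doc$bvalues),
    relaxometry = if (!is.null(doc$echo_times_ms))
      relaxometryProtocol(doc$echo_times_ms,
                          repetition_time = if (!is.null(doc$tr_ms)) doc$tr_ms else 160)
  )
}
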