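#' @include AllGenerics.R
NULL

#' Construct a segmented-fit configuration
#'
#' Defaults follow the reference analysis: segment boundary 200 s/mm^2
#' (b >= 200 is the diffusion-dominated high-b segment, giving 7 of the 13
#' default b-values), D bounded in [1e-5, 5e-3] mm^2/s, D* in (D, 0.5]
#' mm^2/s, f in [0, 1], and the perfusion step fitted on all b-values with D
#' held fixed.
#'
#' @param boundary segment threshold, s/mm^2.
#' @param bounds_D,bounds_Dstar,bounds_f numeric(2) box constraints.
#' @param max_iter optimizer iteration cap.
#' @param tol optimizer relative tolerance.
#' @param step2_all_b logical; FALSE restricts the perfusion step to the
#'   low-b segment only (the strict variant, much noisier under measurement
#'   noise).
#' @param highb_inclusive logical; FALSE (default) takes the high-b segment
#'   as b strictly greater than the boundary, so b = 200 itself — where the
#'   perfusion compartment still contributes a few percent of signal — is
#'   left out of the diffusion fit. TRUE includes it.
#' @return a [FitConfig-class]
#' @export
fitConfig <- function(boundary = 200, bounds_D = c(1e-5, 5e-3),
                      bounds_Dstar = c(1e-4, 0.5), bounds_f = c(0, 1),
                      max_iter = 500L, tol = 1e-10, step2_all_b = TRUE,
                      highb_inclusive = FALSE) {
  new("FitConfig", boundary = as.numeric(boundary),
      bounds_D = as.numeric(bounds_D), bounds_Dstar = as.numeric(bounds_Dstar),
      bounds_f = as.numeric(bounds_f), max_iter = as.integer(max_iter),
      tol = as.numeric(tol), step2_all_b = as.logical(step2_all_b),
      highb_inclusive = as.logical(highb_inclusive))
}

.highbSel <- function(protocol, config) {
  if (config@highb_inclusive) protocol@bvalues >= config@boundary
  else protocol@bvalues > config@boundary
}

.checkBoundary <- function(protocol, config) {
  b <- protocol@bvalues
  if (sum(.highbSel(protocol, config)) < 2L || sum(b < config@boundary) < 2L)
    stop("boundary: need at least 2 b-values on each side of ",
         config@boundary, " s/mm^2")
}

#' Step 1: diffusion coefficient from the high-b segment
#'
#' In the high-b regime (b above the segment boundary) the pseudo-diffusion
#' compartment has decayed to a negligible level, so the signal is
#' mono-exponential and ln SI is linear in b with slope -D and intercept
#' ln[S0 (1 - f)]. Ordinary least squares on the log scale recovers both.
#'
#' @param signal numeric signal vector, one value per protocol b-value.
#' @param protocol a [DiffusionProtocol-class]
#' @param config a [FitConfig-class]
#' @return list with \code{D} (mm^2/s; raw slope estimate, may be <= 0 for
#'   non-decaying input), \code{intercept} (log scale), \code{n_used}, and
#'   \code{ok} (FALSE when fewer than 2 positive high-b points remained).
#' @export
fitMonoexpHighb <- function(signal, protocol, config = fitConfig()) {
  validObject(protocol); validObject(config)
  .checkBoundary(protocol, config)
  if (length(signal) != length(protocol@bvalues))
    stop("signal length must match the protocol")
  sel <- .highbSel(protocol, config)
  b <- protocol@bvalues[sel]; s <- signal[sel]
  pos <- s > 0
  if (!all(pos)) {
    warning("dropping ", sum(!pos), " non-positive high-b point(s)")
    b <- b[pos]; s <- s[pos]
  }
  if (length(s) < 2L)
    return(list(D = NA_real_, intercept = NA_real_, n_used = length(s),
                ok = FALSE))
  ls <- log(s)
  bc <- b - mean(b)
  slope <- sum(bc * ls) / sum(bc^2)
  list(D = -slope, intercept = mean(ls) - slope * mean(b),
       n_used = length(s), ok = TRUE)
}

## Full bi-exponential rss at fixed D with the scale S0 profiled out: for
## fixed (f, Dstar) the optimal S0 is linear least squares in closed form,
## so the nonlinear search runs over (f, Dstar) only.
.ivimProfile <- function(theta, b, s, D) {
  m <- (1 - theta[1L]) * exp(-b * D) + theta[1L] * exp(-b * theta[2L])
  S0 <- sum(s * m) / sum(m^2)
  list(S0 = S0, rss = sum((s - S0 * m)^2))
}

.ivimRss <- function(theta, b, s, D) .ivimProfile(theta, b, s, D)$rss

#' Step 2: perfusion fraction and pseudo-diffusion with D held fixed
#'
#' Box-constrained nonlinear least squares of the full bi-exponential model
#' in (f, D*, S0), with the true diffusion coefficient frozen at the step-1
#' estimate. The scale S0 is profiled out: at each candidate (f, D*) its
#' optimal value is linear least squares in closed form, so the search runs
#' over (f, D*) only, from the start f0 = 1 - exp(high-b intercept)/SI(0)
#' clipped to [0.01, 0.5] and D*0 = 10 D, plus a coarse D* multi-start. A
#' candidate pure-diffusion solution (f = 0) is evaluated as well and kept
#' when it attains an equal or lower residual, so zero perfusion is
#' recovered exactly.
#'
#' @param signal,protocol,config as [fitMonoexpHighb()].
#' @param D_fixed positive diffusion coefficient, mm^2/s.
#' @param init optional list(f, Dstar, S0) overriding the default start.
#' @return list with \code{f}, \code{Dstar}, \code{S0}, \code{rss} (over the
#'   fitted b-range), \code{n_used} and \code{converged}.
#' @export
fitPerfusion <- function(signal, protocol, D_fixed, config = fitConfig(),
                         init = NULL) {
  validObject(protocol); validObject(config)
  if (length(signal) != length(protocol@bvalues))
    stop("signal length must match the protocol")
  if (!is.finite(D_fixed) || D_fixed <= 0) stop("D_fixed: must be > 0")
  sel <- if (config@step2_all_b) rep(TRUE, length(signal))
         else protocol@bvalues < config@boundary
  b <- protocol@bvalues[sel]; s <- signal[sel]
  if (length(s) < 3L) stop("need at least 3 points for the perfusion fit")
  SI0 <- s[b == 0][1L]
  if (is.null(init)) {
    hb <- fitMonoexpHighb(signal, protocol, config)
    f0 <- if (hb$ok && SI0 > 0) 1 - exp(hb$intercept) / SI0 else 0.1
    init <- list(f = min(max(f0, 0.01), 0.5), Dstar = 10 * D_fixed,
                 S0 = max(SI0, .Machine$double.eps))
  }
  lower <- c(config@bounds_f[1L],
             max(D_fixed * (1 + 1e-9), config@bounds_Dstar[1L]))
  upper <- c(config@bounds_f[2L], config@bounds_Dstar[2L])
  start <- pmin(pmax(c(init$f, init$Dstar), lower), upper)
  opt <- stats::optim(start, .ivimRss, b = b, s = s, D = D_fixed,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = config@max_iter,
                                     factr = config@tol / .Machine$double.eps,
                                     parscale = c(0.1, 10 * D_fixed)))
  ## multi-start over a coarse D* ladder guards against the flat/multi-modal
  ## profile surface typical of perfusion fitting under noise
  for (Ds0 in c(3, 30, 100) * D_fixed) {
    if (Ds0 <= lower[2L] || Ds0 >= upper[2L]) next
    alt <- stats::optim(pmin(pmax(c(start[1L], Ds0), lower), upper),
                        .ivimRss, b = b, s = s, D = D_fixed,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = config@max_iter,
                                       factr = config@tol / .Machine$double.eps,
                                       parscale = c(0.1, 10 * D_fixed)))
    if (alt$value < opt$value) opt <- alt
  }
  ## pure-diffusion candidate: optimal scale against exp(-bD) in closed form
  w <- exp(-b * D_fixed)
  S0_mono <- sum(s * w) / sum(w^2)
  rss_mono <- sum((s - S0_mono * w)^2)
  if (S0_mono > 0 && rss_mono <= opt$value) {
    list(f = 0, Dstar = start[2L], S0 = S0_mono, rss = rss_mono,
         n_used = length(s), converged = TRUE)
  } else {
    prof <- .ivimProfile(opt$par, b, s, D_fixed)
    list(f = opt$par[1L], Dstar = opt$par[2L], S0 = prof$S0,
         rss = prof$rss, n_used = length(s),
         converged = opt$convergence == 0L)
  }
}

#' Segmented voxelwise IVIM fit
#'
#' The two-stage segmented inversion of the bi-exponential IVIM model:
#' step 1 estimates D by log-linear least squares on the diffusion-dominated
#' high-b segment (b >= boundary, where pseudo-diffusion is negligible);
#' step 2 estimates f, D* and the scale S0 by box-constrained nonlinear least
#' squares with D frozen. Running the diffusion step first makes the
#' perfusion step well-posed.
#'
#' @param signal numeric vector, one value per protocol b-value.
#' @param protocol a [DiffusionProtocol-class]
#' @param config a [FitConfig-class]
#' @return an [IVIMFitResult-class]; a failure (all-zero signal, degenerate
#'   segment) is returned with \code{converged = FALSE}, never raised.
#' @examples
#' prot <- defaultDiffusionProtocol()
#' truth <- ivimParams(S0 = 1000, D = 0.556e-3, Dstar = 8.53e-3, f = 0.1675)
#' fitIvimVoxel(ivimSignal(truth, prot), prot)
#' @export
fitIvimVoxel <- function(signal, protocol, config = fitConfig()) {
  validObject(protocol); validObject(config)
  if (length(signal) != length(protocol@bvalues))
    stop("signal length must match the protocol")
  n_high <- sum(.highbSel(protocol, config))
  n_low <- sum(protocol@bvalues < config@boundary)
  failure <- function() new("IVIMFitResult",
    params = ivimParams(1, 1e-6, 1e-3, 0), rss = 0,
    n_highb = as.integer(n_high), n_lowb = as.integer(n_low),
    converged = FALSE, boundary = config@boundary)
  if (all(signal <= 0) || anyNA(signal)) return(failure())
  hb <- tryCatch(fitMonoexpHighb(signal, protocol, config),
                 warning = function(w) {
                   suppressWarnings(fitMonoexpHighb(signal, protocol, config))
                 })
  if (!hb$ok) return(failure())
  D_fixed <- min(max(hb$D, config@bounds_D[1L]), config@bounds_D[2L])
  pf <- fitPerfusion(signal, protocol, D_fixed, config,
                     init = list(
                       f = min(max(1 - exp(hb$intercept) / max(signal[1L], .Machine$double.eps),
                                   0.01), 0.5),
                       Dstar = 10 * D_fixed,
                       S0 = max(signal[1L], .Machine$double.eps)))
  ## rss of the returned parameters over the full protocol
  b <- protocol@bvalues
  model <- pf$S0 * ((1 - pf$f) * exp(-b * D_fixed) + pf$f * exp(-b * pf$Dstar))
  params <- tryCatch(ivimParams(pf$S0, D_fixed, pf$Dstar, pf$f),
                     error = function(e) NULL)
  if (is.null(params)) return(failure())
  new("IVIMFitResult", params = params, rss = sum((signal - model)^2),
      n_highb = as.integer(hb$n_used), n_lowb = as.integer(n_low),
      converged = isTRUE(pf$converged), boundary = config@boundary)
}

#' Voxelwise IVIM parameter maps
#'
#' Applies [fitIvimVoxel()] to every voxel of a 4D multi-b-value volume
#' inside a mask.
#'
#' @param volume4d numeric 4D array (x, y, z, b).
#' @param mask logical/numeric 3D array on the same spatial grid; must select
#'   at least one voxel.
#' @param protocol a [DiffusionProtocol-class] matching the 4th dimension.
#' @param config a [FitConfig-class]
#' @return list of 3D arrays \code{D}, \code{Dstar}, \code{f}, \code{S0},
#'   \code{rss}, \code{converged}; voxels outside the mask carry NaN (the
#'   on-disk missing-value sentinel).
#' @export
fitIvimMap <- function(volume4d, mask, protocol, config = fitConfig()) {
  validObject(protocol)
  d <- dim(volume4d)
  if (length(d) != 4L || d[4L] != length(protocol@bvalues))
    stop("volume4d: 4th dimension must match the protocol length")
  if (!identical(dim(mask), d[1:3]))
    stop("mask: spatial grid must match the volume")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask: selects no voxels")
  nvox <- prod(d[1:3])
  mat <- matrix(volume4d, nrow = nvox)
  maps <- list(D = NaN, Dstar = NaN, f = NaN, S0 = NaN, rss = NaN,
               converged = NaN)
  maps <- lapply(maps, function(x) array(NaN, dim = d[1:3]))
  for (i in idx) {
    fit <- fitIvimVoxel(mat[i, ], protocol, config)
    p <- fit@params
    maps$D[i] <- p@D; maps$Dstar[i] <- p@Dstar; maps$f[i] <- p@f
    maps$S0[i] <- p@S0; maps$rss[i] <- fit@rss
    maps$converged[i] <- as.numeric(fit@converged)
  }
  maps
}
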