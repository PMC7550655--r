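#' @include AllGenerics.R
NULL

#' Construct an R2* fit configuration
#'
#' @param noise_floor absolute signal floor (a.u.); echoes at or below it are
#'   excluded before the log transform. At high R2* the late echoes of a
#'   16-echo train (TE up to ~92 ms) sit near the Rician floor, which biases
#'   a log-linear fit downward; a floor of about 3 background SDs removes
#'   them. Default 0 (keep all positive echoes).
#' @param min_echoes minimum usable echoes (>= 3).
#' @param max_echoes optional truncation of the echo train (NA = use all).
#' @param weighted TRUE weights the log-scale regression by squared signal.
#' @return an [R2starConfig-class]
#' @export
r2starConfig <- function(noise_floor = 0, min_echoes = 3L,
                         max_echoes = NA_integer_, weighted = FALSE) {
  new("R2starConfig", noise_floor = as.numeric(noise_floor),
      min_echoes = as.integer(min_echoes),
      max_echoes = as.integer(max_echoes), weighted = as.logical(weighted))
}

#' Voxelwise R2* estimation by log-linear fitting
#'
#' Ordinary (or signal-weighted) least squares of ln SI on TE: the slope is
#' -R2* and the intercept ln S0. Echo times are declared in ms; R2* is
#' reported in 1/s. Negative slopes (non-decaying input) are clamped to
#' R2* = 0 and flagged degenerate.
#'
#' @param signal numeric vector, one value per protocol echo.
#' @param protocol a [RelaxometryProtocol-class]
#' @param config an [R2starConfig-class]
#' @return an [R2starFitResult-class]; fewer than \code{min_echoes} usable
#'   echoes give a flagged failure result, not an error.
#' @examples
#' prot <- defaultRelaxometryProtocol()
#' fitR2starVoxel(greSignal(monoexpDecayParams(1000, 24.74), prot), prot)
#' @export
fitR2starVoxel <- function(signal, protocol, config = r2starConfig()) {
  validObject(protocol); validObject(config)
  te <- protocol@echo_times
  if (length(signal) != length(te))
    stop("signal length must match the protocol")
  if (!is.na(config@max_echoes)) {
    keep <- seq_len(min(config@max_echoes, length(te)))
    te <- te[keep]; signal <- signal[keep]
  }
  floor_ <- max(config@noise_floor, .Machine$double.xmin)
  use <- is.finite(signal) & signal > floor_
  te_s <- te[use] / .MS_PER_S
  s <- signal[use]
  n <- length(s)
  failure <- new("R2starFitResult", params = monoexpDecayParams(1, 0),
                 r_squared = 0, n_echoes_used = as.integer(n),
                 converged = FALSE, degenerate = TRUE)
  if (n < config@min_echoes) return(failure)
  y <- log(s)
  w <- if (config@weighted) s^2 else rep(1, n)
  xm <- sum(w * te_s) / sum(w); ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (te_s - xm)^2)
  if (sxx == 0) return(failure)
  slope <- sum(w * (te_s - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  syy <- sum(w * (y - ym)^2)
  degenerate <- FALSE
  r2 <- if (syy > 0) {
    sse <- sum(w * (y - (intercept + slope * te_s))^2)
    max(0, min(1, 1 - sse / syy))
  } else {
    degenerate <- TRUE   # constant signal: R^2 undefined, reported 0
    0
  }
  R2star <- -slope
  if (R2star < 0) { R2star <- 0; degenerate <- TRUE }
  new("R2starFitResult",
      params = monoexpDecayParams(exp(intercept), R2star),
      r_squared = r2, n_echoes_used = as.integer(n), converged = TRUE,
      degenerate = degenerate)
}

#' Voxelwise R2* map
#'
#' Applies [fitR2starVoxel()] to every voxel of a 4D multi-echo volume inside
#' a mask.
#'
#' @param volume4d numeric 4D array (x, y, z, echo).
#' @param mask logical/numeric 3D array; must select at least one voxel.
#' @param protocol a [RelaxometryProtocol-class] matching the 4th dimension.
#' @param config an [R2starConfig-class]
#' @return list of 3D arrays \code{R2star} (1/s), \code{S0},
#'   \code{r_squared}, \code{converged}; NaN outside the mask.
#' @export
fitR2starMap <- function(volume4d, mask, protocol, config = r2starConfig()) {
  validObject(protocol)
  d <- dim(volume4d)
  if (length(d) != 4L || d[4L] != length(protocol@echo_times))
    stop("volume4d: 4th dimension must match the protocol length")
  if (!identical(dim(mask), d[1:3]))
    stop("mask: spatial grid must match the volume")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask: selects no voxels")
  mat <- matrix(volume4d, nrow = prod(d[1:3]))
  maps <- lapply(1:4, function(i) array(NaN, dim = d[1:3]))
  names(maps) <- c("R2star", "S0", "r_squared", "converged")
  for (i in idx) {
    fit <- fitR2starVoxel(mat[i, ], protocol, config)
    maps$R2star[i] <- fit@params@R2star
    maps$S0[i] <- fit@params@S0
    maps$r_squared[i] <- fit@r_squared
    maps$converged[i] <- as.numeric(fit@converged)
  }
  maps
}
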