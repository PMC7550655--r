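#' @include AllGenerics.R
NULL

#' Construct a noise specification
#'
#' @param model "none", "gaussian" or "rician".
#' @param sigma per-channel noise SD in signal units. The default of 20
#'   gives b = 0 SNR 50 against the default tumor S0 of 1000, a typical
#'   preclinical DWI operating point.
#' @param seed optional integer; when given, [addNoise()] seeds the RNG before
#'   drawing so a standalone call is reproducible.
#' @return a [NoiseSpec-class]
#' @export
noiseSpec <- function(model = c("rician", "gaussian", "none"), sigma = 20,
                      seed = NA_integer_) {
  model <- match.arg(model)
  new("NoiseSpec", model = model, sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' Construct region tissue parameters
#'
#' @param mean,sd named numerics with entries S0 (a.u.), D (mm^2/s),
#'   Dstar (mm^2/s), f (fraction), R2star (1/s).
#' @return a [RegionParams-class]
#' @export
regionParams <- function(mean, sd) {
  new("RegionParams", mean = unlist(mean)[.REGION_QUANTITIES],
      sd = unlist(sd)[.REGION_QUANTITIES])
}

#' Default tumor and background tissue parameters
#'
#' Tumor means are the baseline tumor values of the reference study
#' (D = 0.556e-3 mm^2/s, D* = 8.53e-3 mm^2/s, f = 16.75%, R2* = 24.74 /s)
#' with the corresponding baseline SDs taken as voxelwise heterogeneity;
#' background emulates non-tumor soft tissue (higher D, low perfusion).
#'
#' @return a [RegionParams-class]
#' @export
defaultTumorParams <- function() {
  regionParams(
    mean = c(S0 = 1000, D = 0.556e-3, Dstar = 8.53e-3, f = 0.1675,
             R2star = 24.74),
    sd = c(S0 = 20, D = 0.024e-3, Dstar = 0.57e-3, f = 0.0095, R2star = 0.61))
}

#' @rdname defaultTumorParams
#' @export
defaultBackgroundParams <- function() {
  regionParams(
    mean = c(S0 = 600, D = 1.1e-3, Dstar = 6e-3, f = 0.05, R2star = 30),
    sd = c(S0 = 15, D = 0.05e-3, Dstar = 0.4e-3, f = 0.01, R2star = 1.2))
}

#' Construct a phantom specification
#'
#' The default geometry is a 24 x 24 x 12 grid with an ellipsoidal tumor of
#' semi-axes (6, 6, 4) voxels (about 600 tumor voxels), comparable to an
#' 8-10 mm xenograft at preclinical DWI resolution.
#'
#' @param grid integer(3) volume dimensions.
#' @param center numeric(3) ellipsoid centre, 0-based voxel coordinates.
#' @param semi_axes numeric(3) ellipsoid semi-axes, voxels.
#' @param tumor,background [RegionParams-class] for the two regions.
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(grid = c(24L, 24L, 12L),
                        center = (grid - 1) / 2,
                        semi_axes = c(6, 6, 4),
                        tumor = defaultTumorParams(),
                        background = defaultBackgroundParams()) {
  new("PhantomSpec", grid = as.integer(grid), center = as.numeric(center),
      semi_axes = as.numeric(semi_axes), tumor = tumor,
      background = background)
}

#' Ellipsoid region-of-interest mask of a phantom
#'
#' @param spec a [PhantomSpec-class]
#' @return logical 3D array, TRUE for voxels whose 0-based centre lies inside
#'   the ellipsoid.
#' @export
ellipsoidMask <- function(spec) {
  validObject(spec)
  d <- spec@grid
  x <- (seq_len(d[1L]) - 1 - spec@center[1L]) / spec@semi_axes[1L]
  y <- (seq_len(d[2L]) - 1 - spec@center[2L]) / spec@semi_axes[2L]
  z <- (seq_len(d[3L]) - 1 - spec@center[3L]) / spec@semi_axes[3L]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(r2 <= 1, dim = d)
}

#' Add measurement noise to a signal
#'
#' Gaussian noise adds one N(0, sigma^2) deviate per sample. Rician noise
#' models magnitude MRI: sqrt((s + e1)^2 + e2^2) with independent N(0,
#' sigma^2) deviates on the two quadrature channels, which biases low-SNR
#' signals towards the Rayleigh floor sigma*sqrt(pi/2).
#'
#' @param signal numeric vector or array of non-negative signals.
#' @param spec a [NoiseSpec-class]; if its seed is set the RNG is seeded
#'   first, otherwise the current RNG stream is used.
#' @return noisy signal, same shape as the input.
#' @export
addNoise <- function(signal, spec) {
  validObject(spec)
  if (any(signal < 0, na.rm = TRUE))
    stop("signal: must be non-negative")
  if (spec@model == "none" || spec@sigma == 0) return(signal)
  if (!is.na(spec@seed)) set.seed(spec@seed)
  n <- length(signal)
  out <- switch(spec@model,
    gaussian = signal + stats::rnorm(n, 0, spec@sigma),
    rician = sqrt((signal + stats::rnorm(n, 0, spec@sigma))^2 +
                  stats::rnorm(n, 0, spec@sigma)^2))
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

## Draw one truth field (n voxels) for a region. Each quantity is an
## independent normal clipped to the physical range; Dstar > D is enforced by
## redrawing Dstar (up to 100 times per voxel, then clamped just above D with
## a warning), mirroring the tissue-parameter invariants.
.drawRegionField <- function(n, region) {
  m <- region@mean; s <- region@sd
  draw <- function(q, lower = -Inf, upper = Inf) {
    x <- stats::rnorm(n, m[[q]], s[[q]])
    bad <- which(x < lower | x > upper)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      x[bad] <- stats::rnorm(length(bad), m[[q]], s[[q]])
      bad <- which(x < lower | x > upper)
      tries <- tries + 1L
    }
    if (length(bad)) {
      warning("clamping ", length(bad), " draws of ", q, " to physical range")
      x[bad] <- pmin(pmax(x[bad], lower), upper)
    }
    x
  }
  eps <- .Machine$double.eps
  S0 <- draw("S0", lower = eps)
  D <- draw("D", lower = eps)
  f <- draw("f", lower = 0, upper = 1)
  R2star <- draw("R2star", lower = 0)
  Dstar <- stats::rnorm(n, m[["Dstar"]], s[["Dstar"]])
  bad <- which(Dstar <= D)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    Dstar[bad] <- stats::rnorm(length(bad), m[["Dstar"]], s[["Dstar"]])
    bad <- which(Dstar <= D)
    tries <- tries + 1L
  }
  if (length(bad)) {
    warning("clamping ", length(bad), " Dstar draws above D")
    Dstar[bad] <- D[bad] * (1 + 1e-6)
  }
  list(S0 = S0, D = D, Dstar = Dstar, f = f, R2star = R2star)
}

## Shared scaffolding of the two volume generators: truth fields over the
## grid (tumor field inside the ellipsoid, background outside) plus mask.
.phantomTruth <- function(spec, seed) {
  validObject(spec)
  set.seed(as.integer(seed))
  mask <- ellipsoidMask(spec)
  n <- prod(spec@grid)
  idx <- which(mask)
  tumor <- .drawRegionField(length(idx), spec@tumor)
  bg <- .drawRegionField(n - length(idx), spec@background)
  fields <- lapply(.REGION_QUANTITIES, function(q) {
    x <- numeric(n)
    x[idx] <- tumor[[q]]
    x[-idx] <- bg[[q]]
    array(x, dim = spec@grid)
  })
  names(fields) <- .REGION_QUANTITIES
  list(fields = fields, mask = mask)
}

#' Generate a synthetic multi-b-value diffusion volume
#'
#' Draws voxelwise IVIM truth parameters for an ellipsoidal tumor embedded in
#' background tissue, evaluates the bi-exponential forward model at every
#' b-value, and applies measurement noise. The result is a pure function of
#' (spec, protocol, noise, seed).
#'
#' @param spec a [PhantomSpec-class]
#' @param protocol a [DiffusionProtocol-class]
#' @param noise a [NoiseSpec-class]; its seed slot is ignored here, the
#'   \code{seed} argument governs both the truth draw and the noise draw.
#' @param seed integer seed.
#' @return list with \code{volume} (4D array, grid x b-values), \code{truth}
#'   (list of 3D arrays S0, D, Dstar, f), and \code{mask} (logical 3D array
#'   marking the tumor ellipsoid).
#' @examples
#' ph <- generateIvimVolume(phantomSpec(), defaultDiffusionProtocol(),
#'                          noiseSpec("none", 0), seed = 1)
#' dim(ph$volume)
#' @export
generateIvimVolume <- function(spec, protocol, noise = noiseSpec(), seed = 1L) {
  validObject(protocol)
  tr <- .phantomTruth(spec, seed)
  b <- protocol@bvalues
  S0 <- as.vector(tr$fields$S0); D <- as.vector(tr$fields$D)
  Ds <- as.vector(tr$fields$Dstar); f <- as.vector(tr$fields$f)
  sig <- S0 * ((1 - f) * exp(-outer(D, b)) + f * exp(-outer(Ds, b)))
  vol <- array(addNoise(sig, .currentStreamNoise(noise)),
               dim = c(spec@grid, length(b)))
  list(volume = vol, truth = tr$fields[c("S0", "D", "Dstar", "f")],
       mask = tr$mask)
}

#' Generate a synthetic multi-echo gradient-echo volume
#'
#' As [generateIvimVolume()], with the mono-exponential R2* decay as the
#' forward model.
#'
#' @inheritParams generateIvimVolume
#' @param protocol a [RelaxometryProtocol-class]
#' @return list with \code{volume} (4D array, grid x echoes), \code{truth}
#'   (list with 3D arrays S0 and R2star), and \code{mask}.
#' @export
generateGreVolume <- function(spec, protocol, noise = noiseSpec(), seed = 1L) {
  validObject(protocol)
  tr <- .phantomTruth(spec, seed)
  te_s <- protocol@echo_times / .MS_PER_S
  S0 <- as.vector(tr$fields$S0); R2 <- as.vector(tr$fields$R2star)
  sig <- S0 * exp(-outer(R2, te_s))
  vol <- array(addNoise(sig, .currentStreamNoise(noise)),
               dim = c(spec@grid, length(te_s)))
  list(volume = vol, truth = tr$fields[c("S0", "R2star")], mask = tr$mask)
}

## noise spec with the seed stripped: volume generators run truth + noise in
## one seeded stream so the pair (spec, seed) fully determines the output
.currentStreamNoise <- function(noise) {
  new("NoiseSpec", model = noise@model, sigma = noise@sigma,
      seed = NA_integer_)
}

#' Construct a longitudinal study design
#'
#' @param groups,timepoints character labels; defaults follow the reference
#'   study (groups A-D; base plus weeks 1-3).
#' @param n_per_group animals per group (default 8).
#' @param cell_targets data.frame (quantity, group, timepoint, mean, sd) of
#'   target summary cells in table display units; defaults to the packaged
#'   reference study cells ([referenceCellTargets()]).
#' @return a [StudyDesign-class]
#' @export
studyDesign <- function(groups = c("A", "B", "C", "D"),
                        timepoints = c("base", "week1", "week2", "week3"),
                        n_per_group = 8L,
                        cell_targets = referenceCellTargets()) {
  new("StudyDesign", groups = as.character(groups),
      timepoints = as.character(timepoints),
      n_per_group = as.integer(n_per_group),
      cell_targets = as.data.frame(cell_targets))
}

## physical ranges of study quantities on the table (display) scale
.QUANTITY_RANGE <- list(
  volume = c(0, Inf), D = c(0, Inf), Dstar = c(0, Inf), f = c(0, 100),
  R2star = c(0, Inf), HIF1a = c(0, 100), Ki67 = c(0, 100),
  TUNEL = c(0, 100), PTEN = c(0, 100))

#' Generate a synthetic longitudinal study table
#'
#' Draws one value per animal, time point and quantity from
#' Normal(cell mean, cell SD), clipped to the quantity's physical range
#' (redraw up to 100 times, then clamp with a warning). Quantities reported
#' only at some time points (e.g. pathology at sacrifice) yield records only
#' where a cell target exists.
#'
#' @param design a [StudyDesign-class]
#' @param seed integer seed.
#' @return long-format data.frame with columns animal_id, group, timepoint,
#'   quantity, value (table display units).
#' @seealso [widenStudy()], [longitudinalSummary()]
#' @export
generateStudy <- function(design, seed = 1L) {
  validObject(design)
  ct <- design@cell_targets
  miss <- !(ct$group %in% design@groups & ct$timepoint %in% design@timepoints)
  if (any(miss))
    stop("cell_targets reference unknown group/timepoint: ",
         paste(unique(paste(ct$group[miss], ct$timepoint[miss])), collapse = ", "))
  set.seed(as.integer(seed))
  n <- design@n_per_group
  ## fixed ordering: groups, then timepoints, then quantities as listed
  ct <- ct[order(match(ct$group, design@groups),
                 match(ct$timepoint, design@timepoints),
                 match(ct$quantity, unique(ct$quantity))), ]
  out <- lapply(seq_len(nrow(ct)), function(i) {
    rng <- .QUANTITY_RANGE[[ct$quantity[i]]]
    if (is.null(rng)) rng <- c(-Inf, Inf)
    x <- stats::rnorm(n, ct$mean[i], ct$sd[i])
    bad <- which(x < rng[1L] | x > rng[2L])
    tries <- 0L
    while (length(bad) && tries < 100L) {
      x[bad] <- stats::rnorm(length(bad), ct$mean[i], ct$sd[i])
      bad <- which(x < rng[1L] | x > rng[2L])
      tries <- tries + 1L
    }
    if (length(bad)) {
      warning("clamping ", length(bad), " draws of ", ct$quantity[i])
      x[bad] <- pmin(pmax(x[bad], rng[1L]), rng[2L])
    }
    data.frame(animal_id = paste0(ct$group[i], "_", seq_len(n)),
               group = ct$group[i], timepoint = ct$timepoint[i],
               quantity = ct$quantity[i], value = x,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pivot a long study table to one record per animal and time point
#'
#' @param records long-format study table as from [generateStudy()].
#' @return data.frame with columns animal_id, group, timepoint and one column
#'   per quantity (NA where not measured).
#' @export
widenStudy <- function(records) {
  stopifnot(all(c("animal_id", "group", "timepoint", "quantity", "value")
                %in% names(records)))
  wide <- stats::reshape(records, direction = "wide",
                         idvar = c("animal_id", "group", "timepoint"),
                         timevar = "quantity")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
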