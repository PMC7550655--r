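## Packaged summary tables of the reference xenograft study (A549 lung-cancer
## model, 4 groups x 4 time points, n = 8): caliper tumor volumes, ROI-mean
## quantitative MRI parameters, and final-time-point pathology staining rates,
## each as printed mean/sd cells plus the printed one-way ANOVA F values.
## Fixture integrity is enforced by md5 checksum at load.

.FIXTURE_MD5 <- c(
  table1_tumor_volumes.csv   = "12cf3bf4f2458d8668415615628c11ee",
  table2_mri_parameters.csv  = "3c26baa0208545980c225801f569e253",
  table3_pathology.csv       = "cd575ae9ac318291be205c4744819e1c",
  printed_F_values.csv       = "20e2e3802fee2ed11a42493580b4cc3b"
)

.fixturePath <- function(file) {
  path <- system.file("extdata", file, package = "tumorQMRI")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.FIXTURE_MD5[[file]])))
    stop("fixture integrity check failed for ", file,
         " (md5 ", got, ", expected ", .FIXTURE_MD5[[file]], ")")
  path
}

#' Reference study summary tables
#'
#' Loads the packaged mean/SD/n summary cells of the reference xenograft
#' treatment study: caliper tumor volumes (mm^3) per group and time point,
#' ROI-mean quantitative MRI parameters (D and D* in 1e-3 mm^2/s, f in
#' percent, R2* in 1/s), and percent-positive pathology staining rates
#' (HIF-1a, Ki-67, TUNEL, PTEN) at the final time point, together with the
#' printed one-way ANOVA F values. Values are in the tables' display units.
#' File integrity is checked by md5 at load.
#'
#' @return a list with data.frames \code{volumes}, \code{mri},
#'   \code{pathology} (columns quantity, group, timepoint, mean, sd, n) and
#'   \code{printed_F} (columns table, scope, quantity, group, F).
#' @examples
#' tabs <- referenceTables()
#' subset(tabs$volumes, group == "A" & timepoint == "week3")
#' @export
referenceTables <- function() {
  rd <- function(f) utils::read.csv(.fixturePath(f), stringsAsFactors = FALSE)
  list(volumes = rd("table1_tumor_volumes.csv"),
       mri = rd("table2_mri_parameters.csv"),
       pathology = rd("table3_pathology.csv"),
       printed_F = rd("printed_F_values.csv"))
}

#' Recompute the reference study's printed statistics from its summary cells
#'
#' For every printed one-way ANOVA F value (volume, each MRI parameter within
#' each group across time; each pathology marker across groups at the final
#' time point), recomputes F from the printed mean/SD cells with n = 8 via
#' [anovaFromSummary()], and recomputes the week-3 tumor inhibition rates of
#' the three treatment groups from the week-3 volume means via
#' [inhibitionRate()]. Residual deviation reflects only the rounding of the
#' printed cells.
#'
#' @param tol_F relative tolerance on F for the pass flag (default 0.01).
#' @param tol_F_near_null wider relative tolerance applied to near-null rows
#'   (printed F < 1), where a small F amplifies input rounding; default 0.05.
#' @return data.frame with one row per printed number: columns statistic,
#'   quantity, group, recomputed, printed, rel_dev, pass.
#' @examples
#' rep <- reproduceTables()
#' subset(rep, statistic == "inhibition_rate")
#' @export
reproduceTables <- function(tol_F = 0.01, tol_F_near_null = 0.05) {
  tabs <- referenceTables()
  cells <- rbind(tabs$volumes, tabs$mri, tabs$pathology)
  pf <- tabs$printed_F

  rows <- lapply(seq_len(nrow(pf)), function(i) {
    if (pf$scope[i] == "time-within-group") {
      cc <- cells[cells$quantity == pf$quantity[i] & cells$group == pf$group[i], ]
    } else {
      cc <- cells[cells$quantity == pf$quantity[i], ]
    }
    fit <- anovaFromSummary(cc)
    tol <- if (pf$F[i] < 1) tol_F_near_null else tol_F
    rel <- abs(fit@F - pf$F[i]) / pf$F[i]
    grp <- if (is.na(pf$group[i])) "all" else as.character(pf$group[i])
    data.frame(statistic = "F", quantity = pf$quantity[i],
               group = grp, recomputed = fit@F,
               printed = pf$F[i], rel_dev = rel, pass = rel <= tol,
               stringsAsFactors = FALSE)
  })

  wk3 <- tabs$volumes[tabs$volumes$timepoint == "week3", ]
  v_ctrl <- wk3$mean[wk3$group == "A"]
  inh <- lapply(c("B", "C", "D"), function(g) {
    rate <- inhibitionRate(v_ctrl, wk3$mean[wk3$group == g])
    printed <- c(B = 23.8, C = 27.1, D = 47.4)[[g]]
    data.frame(statistic = "inhibition_rate", quantity = "volume", group = g,
               recomputed = rate, printed = printed,
               rel_dev = abs(rate - printed) / printed,
               pass = round(rate, 1) == printed, stringsAsFactors = FALSE)
  })

  do.call(rbind, c(rows, inh))
}

#' Cell targets for the default synthetic study design
#'
#' The reference tables reshaped into the \code{cell_targets} layout of
#' [StudyDesign-class] (quantity, group, timepoint, mean, sd).
#'
#' @return data.frame of cell targets in table display units.
#' @export
referenceCellTargets <- function() {
  tabs <- referenceTables()
  ct <- rbind(tabs$volumes, tabs$mri, tabs$pathology)
  ct[c("quantity", "group", "timepoint", "mean", "sd")]
}
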