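# Field-comparison statistics and injury-threshold assessment.

#' Correlation score between two paired fields
#'
#' A 0-100 rating combining shape, slope and magnitude sub-scores of the
#' paired element-wise fields: shape = max(Pearson r, 0); slope score =
#' max(1 - |m - 1|, 0); magnitude score = ratio of smaller to larger peak
#' absolute value. Default weights 0.5 / 0.25 / 0.25. The method is
#' pluggable via [compare_fields()].
#'
#' @param a,b paired numeric fields on the same elements
#' @param weights weights of the shape, slope and magnitude sub-scores
#' @return score in [0, 100]
#' @export
correlation_score <- function(a, b, weights = c(0.5, 0.25, 0.25)) {
  r <- suppressWarnings(cor(a, b))
  if (is.na(r)) r <- 0
  m <- sum(a * b) / sum(a * a)
  shape <- max(r, 0)
  slope <- max(1 - abs(m - 1), 0)
  pa <- max(abs(a)); pb <- max(abs(b))
  mag <- if (max(pa, pb) == 0) 1 else min(pa, pb) / max(pa, pb)
  100 * sum(weights * c(shape, slope, mag)) / sum(weights)
}

#' Compare two element-wise metric fields
#'
#' Pearson correlation `r`, least-squares regression slope `m` of `b` on
#' `a` (through the origin of the cloud), and correlation score `CS`.
#' The difference is flagged statistically significant when
#' `r < 0.90`, or `m` outside (0.9, 1.1), or `CS < 86`.
#'
#' @param a base field
#' @param b variant field (same element count and ordering)
#' @param cs_method function `(a, b) -> score in [0, 100]`
#' @return object of class `comparison_stats` with r, m, CS,
#'   significant_difference
#' @export
compare_fields <- function(a, b, cs_method = correlation_score) {
  if (length(a) != length(b))
    stop("fields differ in element count (", length(a), " vs ", length(b), ")")
  va <- stats::var(a); vb <- stats::var(b)
  r <- if (va == 0 || vb == 0) NA_real_ else cor(a, b)
  # least-squares slope of b on a through the data cloud
  m <- if (sum(a^2) == 0) NA_real_ else sum(a * b) / sum(a^2)
  cs <- cs_method(a, b)
  sig <- isTRUE(is.na(r)) || r < 0.90 || is.na(m) || m <= 0.9 || m >= 1.1 ||
    cs < 86
  structure(list(r = r, m = m, CS = cs,
                 significant_difference = sig,
                 zero_variance = (va == 0 || vb == 0)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("comparison: r = %.4f, m = %.4f, CS = %.2f -> %s\n",
              x$r, x$m, x$CS,
              if (x$significant_difference) "significantly different"
              else "not significantly different"))
  invisible(x)
}

#' Injury thresholds
#'
#' Axonal tensile strain onset thresholds of 18% and 13% (diffuse axonal
#' injury), and a shear stress tolerance of 7.8 kPa (50% probability of
#' mild TBI). Maximum principal strain stands in for axonal strain.
#'
#' @return named list of thresholds
#' @export
injury_thresholds <- function() {
  list(axonal_strain_18 = 0.18, axonal_strain_13 = 0.13,
       shear_stress = 7.8e3)
}

#' Assess brain injury-threshold exceedance of a run
#'
#' Compares element-wise peak MPS against the 13% and 18% axonal-strain
#' thresholds and peak von Mises stress against 7.8 kPa, separately for
#' the head-rotation window and the deceleration-dwell window (split at
#' the drive's impact-pulse start).
#'
#' @param history a `fieldhistory`
#' @param region region to assess (default brain)
#' @param thresholds threshold list, see [injury_thresholds()]
#' @return object of class `injury_assessment`: per-criterion, per-phase
#'   exceedance flags, peak values, and exceeded area fractions
#' @export
assess_injury <- function(history, region = "brain",
                          thresholds = injury_thresholds()) {
  idx <- region_elements(history$mesh, region)
  split_t <- if (!is.null(history$drive)) history$drive$t_pulse else Inf
  ar <- history$mesh$elem_area[idx]
  # per-phase element-wise peaks from the saved frames (the running peak
  # tracker only records the single global peak time per element, which
  # would hide an exceedance in the earlier, weaker phase)
  phase_peaks <- function(sel) {
    mps <- vm <- rep(0, length(idx))
    for (i in sel) {
      mps <- pmax(mps, principal_strains(
        history$F_frames[idx, , i, drop = TRUE])[, 1])
      vm <- pmax(vm, von_mises(history$stress_frames[idx, , i, drop = TRUE]))
    }
    list(mps = mps, vm = vm)
  }
  rot <- phase_peaks(which(history$times < split_t))
  dec <- phase_peaks(which(history$times >= split_t))
  mps_all <- history$peaks[idx, 2]
  vm_all <- history$peaks[idx, 3]
  t_mps <- history$peak_times[idx, 2]
  t_vm <- history$peak_times[idx, 3]
  crit <- function(val, tm, rot_val, dec_val, thr) {
    hit <- val >= thr
    list(exceeded = any(hit),
         exceeded_rotation = any(rot_val >= thr),
         exceeded_dwell = any(dec_val >= thr),
         peak = max(val),
         peak_rotation = max(rot_val), peak_dwell = max(dec_val),
         area_fraction = sum(ar[hit]) / sum(ar),
         first_time = if (any(hit)) min(tm[hit]) else NA_real_)
  }
  structure(list(
    axonal_strain_18 = crit(mps_all, t_mps, rot$mps, dec$mps,
                            thresholds$axonal_strain_18),
    axonal_strain_13 = crit(mps_all, t_mps, rot$mps, dec$mps,
                            thresholds$axonal_strain_13),
    shear_stress = crit(vm_all, t_vm, rot$vm, dec$vm,
                        thresholds$shear_stress),
    region = region, thresholds = thresholds
  ), class = "injury_assessment")
}

#' @export
print.injury_assessment <- function(x, ...) {
  cat("injury assessment (", x$region, "):\n", sep = "")
  for (nm in c("axonal_strain_18", "axonal_strain_13", "shear_stress")) {
    cc <- x[[nm]]
    cat(sprintf("  %-18s peak %.4g  exceeded: %s (rotation %s, decel-dwell %s)\n",
                nm, cc$peak, cc$exceeded, cc$exceeded_rotation,
                cc$exceeded_dwell))
  }
  invisible(x)
}
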