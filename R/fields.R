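# Post-processing of deformation histories into scalar injury metrics.
#
# Strain measure: logarithmic (true) strain from the deformation
# gradient. MSS is the engineering maximum shear, eps1 - eps2 (so for
# incompressible uniaxial stretch MSS = 2 MPS). von Mises stress uses the
# full plane-strain stress including the out-of-plane normal component.

#' In-plane principal logarithmic strains of a saved frame
#'
#' @param F_frame E x 4 matrix of deformation gradients (xx, xy, yx, yy)
#' @return E x 2 matrix, ordered eps1 >= eps2 (out-of-plane strain is 0)
#' @export
principal_strains <- function(F_frame) {
  F11 <- F_frame[, 1]; F12 <- F_frame[, 2]
  F21 <- F_frame[, 3]; F22 <- F_frame[, 4]
  C11 <- F11^2 + F21^2
  C22 <- F12^2 + F22^2
  C12 <- F11 * F12 + F21 * F22
  disc <- sqrt(((C11 - C22) / 2)^2 + C12^2)
  l1 <- pmax((C11 + C22) / 2 + disc, 1e-12)
  l2 <- pmax((C11 + C22) / 2 - disc, 1e-12)
  cbind(eps1 = 0.5 * log(l1), eps2 = 0.5 * log(l2))
}

#' Maximum shear strain per element
#'
#' Engineering maximum shear, the difference of in-plane principal
#' logarithmic strains.
#'
#' @param F_frame E x 4 deformation-gradient matrix
#' @return numeric vector (dimensionless, >= 0)
#' @export
max_shear_strain <- function(F_frame) {
  ps <- principal_strains(F_frame)
  unname(ps[, 1] - ps[, 2])
}

#' von Mises stress per element
#'
#' Second-deviatoric-invariant form using all three normal components of
#' the plane-strain Cauchy stress.
#'
#' @param stress_frame E x 4 stress matrix (xx, yy, xy, zz), Pa
#' @return numeric vector, Pa
#' @export
von_mises <- function(stress_frame) {
  sxx <- stress_frame[, 1]; syy <- stress_frame[, 2]
  sxy <- stress_frame[, 3]; szz <- stress_frame[, 4]
  sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) + 3 * sxy^2)
}

# element indices of a region (quads-then-triangles ordering)
region_elements <- function(mesh, region) {
  idx <- which(mesh$elem_region %in% region)
  if (!length(idx)) stop("no elements in region '", region, "'")
  idx
}

#' Element-wise peak metric field over a run
#'
#' Running maxima tracked by the solver at sub-frame resolution.
#'
#' @param history a `fieldhistory`
#' @param metric one of `"MSS"`, `"MPS"`, `"VM"`
#' @param region optional region restriction (e.g. `"brain"`)
#' @return numeric vector over the (restricted) elements
#' @export
peak_field <- function(history, metric = c("MSS", "MPS", "VM"),
                       region = NULL) {
  metric <- match.arg(metric)
  col <- match(metric, c("MSS", "MPS", "VM"))
  v <- history$peaks[, col]
  if (!is.null(region)) v <- v[region_elements(history$mesh, region)]
  v
}

#' Area fraction of a region meeting a metric rule
#'
#' Fraction of region area whose peak metric satisfies `rule` (a
#' threshold with `above = TRUE/FALSE`), or a binned decomposition when
#' `breaks` is given (fractions sum to 1).
#'
#' @param history a `fieldhistory`
#' @param metric `"MSS"`, `"MPS"` or `"VM"`
#' @param region region name
#' @param threshold scalar threshold (ignored if `breaks` given)
#' @param above count elements at or above the threshold?
#' @param breaks optional bin edges covering the data range
#' @return scalar fraction in [0, 1], or named vector of bin fractions
#' @export
area_fraction <- function(history, metric = "MSS", region = "brain",
                          threshold = NULL, above = TRUE, breaks = NULL) {
  idx <- region_elements(history$mesh, region)
  v <- peak_field(history, metric)[idx]
  ar <- history$mesh$elem_area[idx]
  tot <- sum(ar)
  if (!is.null(breaks)) {
    bin <- cut(v, breaks = breaks, include.lowest = TRUE)
    out <- tapply(ar, bin, sum, default = 0) / tot
    out[is.na(out)] <- 0
    return(out)
  }
  stopifnot(!is.null(threshold))
  sel <- if (above) v >= threshold else v < threshold
  sum(ar[sel]) / tot
}

#' Peak metric report for a region
#'
#' Region-wise peak MSS, MPS and von Mises stress with occurrence times
#' and attribution to the head-rotation versus deceleration-dwell phase
#' (split at the impact-pulse start of the drive, when available).
#'
#' @param history a `fieldhistory`
#' @param region region name (default brain)
#' @return data.frame with metric, peak, time, phase
#' @export
peak_report <- function(history, region = "brain") {
  idx <- region_elements(history$mesh, region)
  split_t <- if (!is.null(history$drive)) history$drive$t_pulse else Inf
  out <- lapply(1:3, function(k) {
    pk <- history$peaks[idx, k]
    e_star <- which.max(pk)
    tm <- history$peak_times[idx, k][e_star]
    data.frame(metric = c("MSS", "MPS", "VM")[k],
               peak = pk[e_star], time = tm,
               phase = if (tm < split_t) "rotation" else "deceleration-dwell")
  })
  do.call(rbind, out)
}

#' Per-frame region peak trace of a metric
#'
#' Maximum of the metric over a region at every saved frame (used for
#' dwell-relaxation and multi-cycle diagnostics).
#'
#' @param history a `fieldhistory`
#' @param metric `"MSS"`, `"MPS"` or `"VM"`
#' @param region region name
#' @return data.frame with t and value
#' @export
metric_trace <- function(history, metric = "VM", region = "brain") {
  idx <- region_elements(history$mesh, region)
  nf <- length(history$times)
  val <- vapply(seq_len(nf), function(i) {
    if (metric == "VM") {
      max(von_mises(history$stress_frames[idx, , i, drop = TRUE]))
    } else if (metric == "MSS") {
      max(max_shear_strain(history$F_frames[idx, , i, drop = TRUE]))
    } else {
      max(principal_strains(history$F_frames[idx, , i, drop = TRUE])[, 1])
    }
  }, numeric(1))
  data.frame(t = history$times, value = val)
}
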