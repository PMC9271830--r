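#' Surface regularity
#'
#' Ratio of the tumor volume to the volume of the sphere having the tumor's
#' surface area: \code{S_R = 6 sqrt(pi) TV / TS^(3/2)}. Equals 1 for a
#' sphere (isoperimetric equality) and decreases as the surface roughens;
#' scale invariant.
#'
#' @param TV tumor volume (mm^3), positive.
#' @param TS tumor outer surface area (mm^2), positive.
#' @return S_R in (0, 1] (up to surface-estimation tolerance).
#' @export
surface_regularity <- function(TV, TS) {
  stopifnot(TV > 0, TS > 0)
  6 * sqrt(pi) * TV / TS^1.5
}

#' Surface factor
#'
#' The equivalent-sphere area ratio \code{TS_eq / TS}; algebraically
#' \code{S_F = S_R^(2/3)}, so the two regularity measures are equivalent
#' descriptions.
#'
#' @param S_R a [surface_regularity()] value.
#' @return S_F.
#' @export
surface_factor <- function(S_R) {
  stopifnot(S_R > 0)
  S_R^(2 / 3)
}

#' Contrast-region regularity
#'
#' The same isoperimetric ratio evaluated on the contrast-enhancing region,
#' whose surface area includes both outer and inner (cavity) components.
#' For a solid lesion \code{S_C = S_R}; contrast-free cores push S_C below
#' S_R, which is the basis of the S_C/S_R discriminator.
#'
#' @param TV_C contrast-region volume.
#' @param TS_C contrast-region total surface area (inner + outer).
#' @return S_C.
#' @export
contrast_regularity <- function(TV_C, TS_C) {
  stopifnot(TV_C > 0, TS_C > 0)
  6 * sqrt(pi) * TV_C / TS_C^1.5
}

#' Shape correction factor and fractional anisotropy from PCA axes
#'
#' \code{f_shape} is the volume of the PCA ellipsoid divided by the volume
#' of the sphere with the same surface area as that ellipsoid (ellipsoid
#' area by the Thomsen approximation, p = 1.6075, max error ~1%); it
#' isolates how much of a low S_R is mere elongation rather than surface
#' roughness. FA is the normalized axis dispersion: 0 for an isotropic
#' cloud, 1 in the maximally elongated limit.
#'
#' @param axes semi-axes \code{lambda1 >= lambda2 >= lambda3}, positive
#'   (from [pca_ellipsoid()]).
#' @return list with \code{f_shape} and \code{FA}.
#' @export
shape_correction <- function(axes) {
  stopifnot(length(axes) == 3, all(axes > 0))
  l <- sort(axes, decreasing = TRUE)
  V_ell <- 4 / 3 * pi * prod(l)
  p <- 1.6075
  S_ell <- 4 * pi * (((l[1] * l[2])^p + (l[1] * l[3])^p + (l[2] * l[3])^p) / 3)^(1 / p)
  r_eq <- sqrt(S_ell / (4 * pi))
  V_sph <- 4 / 3 * pi * r_eq^3
  FA <- sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[1] - l[3])^2) /
    sqrt(2 * (l[1]^2 + l[2]^2 + l[3]^2))
  list(f_shape = V_ell / V_sph, FA = FA)
}

#' Shape-corrected surface regularity
#'
#' \code{S_R* = S_R / f_shape}: divides out the purely ellipsoidal part of
#' the irregularity so that a smooth elongated lesion scores ~1.
#'
#' @param S_R a [surface_regularity()] value.
#' @param f_shape from [shape_correction()].
#' @return S_R*.
#' @export
corrected_regularity <- function(S_R, f_shape) {
  stopifnot(f_shape > 0)
  S_R / f_shape
}

#' All regularity measures of a labeled tumor
#'
#' Convenience wrapper: computes [surface_measures()], [pca_ellipsoid()]
#' and assembles S_R, S_F, S_C, S_C/S_R, FA, f_shape and S_R*.
#'
#' @param labels integer label array.
#' @param tumor_label,contrast_label,spacing as in [surface_measures()].
#' @param interface optionally a precomputed [extract_interface()] result.
#' @return list of all measures plus the underlying \code{measures}.
#' @export
regularity_measures <- function(labels, tumor_label = c(1L, 2L),
                                contrast_label = NULL, spacing = c(1, 1, 1),
                                interface = NULL) {
  sm <- surface_measures(labels, tumor_label, contrast_label, spacing)
  if (is.null(interface))
    interface <- extract_interface(labels, tumor_label, min_points = 10L,
                                   spacing = spacing)
  S_R <- surface_regularity(sm$TV, sm$TS)
  S_C <- contrast_regularity(sm$TV_C, sm$TS_C)
  pe <- pca_ellipsoid(interface)
  shp <- shape_correction(pe$axes)
  list(S_R = S_R, S_F = surface_factor(S_R), S_C = S_C,
       ratio_SC_SR = S_C / S_R, FA = shp$FA, f_shape = shp$f_shape,
       S_R_star = corrected_regularity(S_R, shp$f_shape),
       measures = sm, axes = pe$axes)
}
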