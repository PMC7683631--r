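#' Sphere volume from diameter
#'
#' Volume in millilitres of a sphere with the given diameter in millimetres.
#' The largest image-quality phantom sphere (37 mm inner diameter) has a
#' volume of 26.52 mL.
#'
#' @param diameter_mm Sphere diameter in mm.
#' @return Volume in mL.
#' @export
#' @examples
#' sphere_volume_ml(37) # 26.52 mL
sphere_volume_ml <- function(diameter_mm) {
  stopifnot(is.numeric(diameter_mm))
  (pi / 6) * diameter_mm^3 / 1000
}

#' Equivalent sphere diameter from volume
#'
#' Diameter in millimetres of the sphere with the given volume in
#' millilitres; the "equivalent diameter" conventionally quoted for lesions.
#'
#' @param volume_ml Volume in mL.
#' @return Diameter in mm.
#' @export
#' @examples
#' sphere_diameter_mm(sphere_volume_ml(22)) # 22
sphere_diameter_mm <- function(volume_ml) {
  stopifnot(is.numeric(volume_ml))
  (6000 * volume_ml / pi)^(1 / 3)
}

#' Activity unit conversions
#'
#' Convert injected activity between megabecquerel and millicurie
#' (1 mCi = 37 MBq).
#'
#' @param mbq Activity in MBq.
#' @param mci Activity in mCi.
#' @return Converted activity.
#' @export
mbq_to_mci <- function(mbq) mbq / 37

#' @rdname mbq_to_mci
#' @export
mci_to_mbq <- function(mci) mci * 37
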