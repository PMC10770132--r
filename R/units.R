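# Centralised unit conversions. Coordinates are carried in Angstrom
# throughout; curvature is reported in nm^-1 (H) and nm^-2 (K), forces in
# kJ mol^-1 nm^-1, restraint constants in kJ mol^-1 nm^-2.

#' Unit conversion helpers
#'
#' Internal coordinates are Angstrom; curvature and force quantities follow
#' the conventions of the coarse-grained membrane literature (nm-based).
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @keywords internal
#' @name units
NULL

#' @rdname units
ang_to_nm <- function(x) x / 10

#' @rdname units
nm_to_ang <- function(x) x * 10

# curvature 1/Angstrom -> 1/nm
curv_ang_to_nm <- function(x) x * 10

# Gaussian curvature 1/Angstrom^2 -> 1/nm^2
gauss_ang_to_nm <- function(x) x * 100
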