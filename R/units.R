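#' Unit conventions
#'
#' All lengths are handled internally in millimetres and all times in hours.
#' Diffusion coefficients are accepted in um^2/h at every public interface and
#' converted once, here, to mm^2/h for the solvers. Imaging sessions are labelled
#' in days post-implantation; the solvers work in hours.
#'
#' @name units
NULL

#' Convert a diffusion coefficient from um^2/h to mm^2/h
#'
#' @param D_um2h diffusion coefficient in um^2/h.
#' @return diffusion coefficient in mm^2/h (factor 1e-6).
#' @export
um2h_to_mm2h <- function(D_um2h) D_um2h * 1e-6

#' Convert days post-implantation to hours
#'
#' Day d corresponds to t = 24 * d hours; every module uses this conversion.
#'
#' @param day numeric vector of days.
#' @return hours.
#' @export
day_to_hours <- function(day) 24 * day

#' Convert hours to days post-implantation
#' @param hours numeric vector of hours.
#' @return days.
#' @export
hours_to_day <- function(hours) hours / 24
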