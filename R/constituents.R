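#' Standard tidal constituents
#'
#' Astronomical periods of the principal diurnal and semi-diurnal tidal
#' constituents (Darwin symbols). The four carrying most energy in the
#' hotspot region — O1, K1 (diurnal) and M2, S2 (semi-diurnal) — are the
#' package default; the longer list supports extended fits. No nodal or
#' satellite corrections are applied.
#'
#' @param names Constituent names to return; default the energetic four.
#' @return Tibble with `constituent`, `period_h`, `omega_rad_h` (angular
#'   frequency in rad h^-1).
#' @examples
#' tidal_constituents()
#' tidal_constituents(c("M2", "K1", "P1"))
#' @export
tidal_constituents <- function(names = c("O1", "K1", "M2", "S2")) {
  periods <- c(
    M2 = 12.4206012, S2 = 12.0000000, N2 = 12.6583475, K2 = 11.9672361,
    K1 = 23.9344697, O1 = 25.8193417, P1 = 24.0658902, Q1 = 26.8683567,
    MF = 327.8599387, MM = 661.3111655
  )
  unknown <- setdiff(names, names(periods))
  if (length(unknown)) {
    rlang::abort(paste0("unknown tidal constituent(s): ",
                        paste(unknown, collapse = ", ")))
  }
  tibble::tibble(
    constituent = names,
    period_h = unname(periods[names]),
    omega_rad_h = 2 * pi / unname(periods[names])
  )
}
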