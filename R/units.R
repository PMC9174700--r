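#' Unit conversions
#'
#' Canonical internal units are Torr for partial oxygen pressure, Gy for
#' dose and ns for time. Oxygen availability quoted as a percentage of one
#' atmosphere converts with 100% = 760 Torr, so atmospheric 20% oxygen is
#' 152 Torr. Instantaneous (within-pulse) dose rates are carried in cGy/ns;
#' 1 cGy/ns equals 1e7 Gy/s.
#'
#' @param percent oxygen availability in percent of one atmosphere.
#' @param torr partial oxygen pressure in Torr (1 Torr is about 1 mmHg).
#' @param rate_cgy_ns instantaneous dose rate in cGy per ns.
#' @param rate_gy_s mean dose rate in Gy per s.
#' @return the converted quantity, vectorised over the input.
#' @examples
#' torr_from_percent(20)    # 152 Torr
#' gy_s_from_cgy_ns(1)      # 1e7 Gy/s
#' @name units
NULL

#' @rdname units
#' @export
torr_from_percent <- function(percent) {
  if (any(percent < 0)) stop_domain("oxygen percentage must be >= 0")
  percent / 100 * 760
}

#' @rdname units
#' @export
percent_from_torr <- function(torr) {
  if (any(torr < 0)) stop_domain("pO2 must be >= 0")
  torr / 760 * 100
}

#' @rdname units
#' @export
gy_s_from_cgy_ns <- function(rate_cgy_ns) rate_cgy_ns * 1e7

#' @rdname units
#' @export
cgy_ns_from_gy_s <- function(rate_gy_s) rate_gy_s / 1e7
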