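# In-silico MSRE-PCR: methylation-sensitive restriction digestion of GATC
# duplex sites followed by amplicon-presence prediction. MboI cuts only fully
# unmethylated GATC, DpnI only fully (duplex) methylated GATC, Bsp143I cuts
# regardless of methylation state; hemimethylated sites are refractory to
# both MboI and DpnI. An amplicon is detected iff no cut falls between the
# primers (an undigested positive control always amplifies).

MSRE_ENZYMES <- c("none", "MboI", "DpnI", "Bsp143I")

#' Describe the duplex methylation state of GATC sites
#'
#' @param position 0-based positions of the G of each GATC duplex (plus
#'   strand).
#' @param plus_methylated,minus_methylated Logical vectors: is the adenine on
#'   the plus / minus strand methylated?
#' @return Data.frame of site states.
#' @export
gatc_site_states <- function(position, plus_methylated, minus_methylated) {
  stopifnot(length(position) == length(plus_methylated),
            length(position) == length(minus_methylated))
  data.frame(position = as.integer(position),
             plus_methylated = as.logical(plus_methylated),
             minus_methylated = as.logical(minus_methylated))
}

#' Digest GATC sites with a methylation-sensitive enzyme
#'
#' @param sites Data.frame from [gatc_site_states()].
#' @param enzyme One of \code{"none"}, \code{"MboI"}, \code{"DpnI"},
#'   \code{"Bsp143I"}.
#' @return Sorted integer vector of cut positions.
#' @export
digest <- function(sites, enzyme) {
  if (!enzyme %in% MSRE_ENZYMES) {
    stop("unknown enzyme '", enzyme, "'; expected one of ",
         paste(MSRE_ENZYMES, collapse = ", "))
  }
  cut <- switch(enzyme,
                none = rep(FALSE, nrow(sites)),
                MboI = !sites$plus_methylated & !sites$minus_methylated,
                DpnI = sites$plus_methylated & sites$minus_methylated,
                Bsp143I = rep(TRUE, nrow(sites)))
  sort(sites$position[cut])
}

#' Predict amplicon presence after digestion
#'
#' The amplicon is detected iff no cut position lies strictly between the 3'
#' end of the forward primer and the 5' start of the reverse primer.
#'
#' @param forward_primer_end 0-based position of the forward primer 3' end.
#' @param reverse_primer_start 0-based position of the reverse primer start.
#' @param cuts Integer vector of cut positions.
#' @return Logical scalar.
#' @export
predict_amplicon <- function(forward_primer_end, reverse_primer_start, cuts) {
  stopifnot(forward_primer_end < reverse_primer_start)
  !any(cuts > forward_primer_end & cuts < reverse_primer_start)
}

#' Run the four-enzyme MSRE-PCR panel
#'
#' The truth table of amplicon presence for the undigested control and the
#' three enzymes, for the GATC sites lying between the primers.
#'
#' @param sites Data.frame from [gatc_site_states()].
#' @param forward_primer_end,reverse_primer_start Primer bounds, 0-based.
#' @return Named logical vector over \code{c("none", "MboI", "DpnI",
#'   "Bsp143I")}.
#' @export
msre_panel <- function(sites, forward_primer_end, reverse_primer_start) {
  between <- sites$position > forward_primer_end &
    sites$position < reverse_primer_start
  if (!any(between)) stop("no GATC site between the primers")
  vapply(MSRE_ENZYMES, function(e) {
    predict_amplicon(forward_primer_end, reverse_primer_start, digest(sites, e))
  }, logical(1))
}
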