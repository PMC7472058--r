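#' Activity class taxonomy
#'
#' The five movement-behaviour classes used throughout the package, in the
#' fixed order used for every confusion matrix and report: sedentary
#' (\code{SED}), light activities and games (\code{LIGHT_AG}), moderate to
#' vigorous activities and games (\code{MV_AG}), walking (\code{WALK}) and
#' running (\code{RUN}).
#'
#' @return Character vector of the five class codes, in canonical order.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("SED", "LIGHT_AG", "MV_AG", "WALK", "RUN")
}

#' Event codes accepted in direct-observation logs
#'
#' The five activity classes plus \code{OUT_OF_VIEW}, the code observers use
#' when the child is not visible on camera.
#'
#' @return Character vector of the six valid event codes.
#' @export
event_codes <- function() {
  c(activity_classes(), "OUT_OF_VIEW")
}

# Sentinel for samples not covered by any observation event.  Distinct from
# OUT_OF_VIEW: a gap in the log, not an observed occlusion.
UNLABELED <- "UNLABELED"

# Sentinel window label for windows with no usable strict-majority class.
EXCLUDED <- "EXCLUDED"

#' Accelerometer placements
#'
#' @return Character vector of recognised sensor placements. \code{hip_wrist}
#'   denotes feature fusion of the two single placements.
#' @export
placements <- function() {
  c("hip", "wrist", "hip_wrist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
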