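#' Default study-region boundary
#'
#' Rectangular boundary of the Longitudinal Range Gorge Region of southwest
#' China from its published bounding coordinates: 95.79-106.12 degrees E,
#' 21.15-30.60 degrees N.
#'
#' @return a `polygon_set` with one rectangle.
#' @examples
#' bb <- ps_bbox(lrgr_boundary())
#' bb["east"] - bb["west"]   # longitudinal span, degrees
#' @export
lrgr_boundary <- function() {
  ps_rect(west = 95.79, south = 21.15, east = 106.12, north = 30.60)
}
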