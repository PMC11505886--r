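#' Synthetic 2-D scalp channel layout
#'
#' Places `n_channels` electrode positions on the unit disk with a
#' sunflower (phyllotaxis) spiral, which covers the scalp evenly for any
#' channel count, and assigns each position to a named scalp region.
#' Coordinates use +y = anterior (nasion), +x = right. The layout stands in
#' for a 10-10 style montage: region-level statements ("left-frontal",
#' "occipital") are made against these named regions, not a specific cap
#' file.
#'
#' Regions: `frontal-left` / `frontal-right` (y >= 0.3), `central`
#' (|y| < 0.3), `parietal` (-0.6 < y <= -0.3), `occipital` (y <= -0.6).
#'
#' @param n_channels Number of electrodes (>= 8).
#' @return A data.frame with columns `label`, `x`, `y`, `region`.
#' @export
channel_layout <- function(n_channels) {
  if (n_channels < 8) stop("too few channels to express topographies")
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_channels) * 0.95
  th <- i * golden
  x <- r * cos(th)
  y <- r * sin(th)
  region <- ifelse(y >= 0.3, ifelse(x < 0, "frontal-left", "frontal-right"),
            ifelse(y > -0.3, "central",
            ifelse(y > -0.6, "parietal", "occipital")))
  prefix <- c("frontal-left" = "FL", "frontal-right" = "FR",
              "central" = "C", "parietal" = "P", "occipital" = "O")[region]
  idx <- stats::ave(seq_along(region), region, FUN = seq_along)
  data.frame(label = sprintf("%s%02d", prefix, idx), x = x, y = y,
             region = region, stringsAsFactors = FALSE)
}

#' Channels belonging to given scalp regions
#'
#' @param layout A layout from [channel_layout()].
#' @param regions Character vector of region names.
#' @return Integer indices of channels in those regions.
#' @export
region_channels <- function(layout, regions) {
  which(layout$region %in% regions)
}
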