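# Shared angle/geometry helpers.
#
# Image convention throughout: coordinates are (y, x) with y increasing
# downward, so "up" is the negative-y direction. Headings are compass-style
# bearings of the center->snout vector: 0 deg = up, 90 deg = image right,
# increasing clockwise on screen.

# wrap an angle (deg) into (-180, 180]
wrap180 <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

# bearing (deg) of displacement (dy, dx); 0 = up (-y), clockwise positive
bearing_deg <- function(dy, dx) {
  atan2(dx, -dy) * 180 / pi
}

# unit (y, x) displacement for a bearing in degrees
bearing_unit <- function(deg) {
  r <- deg * pi / 180
  cbind(y = -cos(r), x = sin(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
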