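# Brute-force pixel-centre rasterization oracle: loops over every pixel
# and applies the documented predicate (centre within the circle,
# boundary inclusive with 1e-12 relative tolerance). Independent of the
# package's vectorised rasterizer.
oracleCirclePixels <- function(centers, diameters, dpi, widthPx,
                               heightPx) {
  pitch <- 25400 / dpi
  r2 <- (diameters / (2 * pitch))^2 * (1 + 1e-12)
  mask <- matrix(FALSE, heightPx, widthPx)
  for (y in 0:(heightPx - 1)) {
    for (x in 0:(widthPx - 1)) {
      for (k in seq_len(nrow(centers))) {
        if ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= r2[k]) {
          mask[y + 1, x + 1] <- TRUE
          break
        }
      }
    }
  }
  mask
}

oraclePixelCount <- function(cx, cy, diameter, dpi, widthPx, heightPx) {
  sum(oracleCirclePixels(cbind(cx, cy), diameter, dpi, widthPx, heightPx))
}

# closed-form droplet volume under a constant power-law model, written
# out from first principles (sphere volume of SF * A^b, um^3 -> uL)
closedFormVolume <- function(areaUm2, sf = 1.06, b = 0.455) {
  (pi / 6) * (sf * areaUm2^b)^3 * 1e-9
}
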