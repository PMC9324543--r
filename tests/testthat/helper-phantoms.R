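# Shared fixtures, built in code at test time.

# Small flat-band phantom: curves at rows 40 and 120, 0.1 mm/px.
flat_phantom <- function(angle = 30, noise = 0, seed = 1,
                         gaps = list()) {
  generate_phantom(phantom_spec(
    width_px = 256L, height_px = 200L, pixel_spacing_mm = 0.1,
    superficial_curve = c(40, 0, 0), deep_curve = c(120, 0, 0),
    fascicle_angle_deg = angle, aponeurosis_gap_columns = gaps,
    noise_level = noise, seed = seed))
}

# Mid-size phantom with configurable geometry, used by recovery tests.
gcm_phantom <- function(angle = 20, thickness_px = 200, slope = 0, quad = 0,
                        noise = 0.2, seed = 3, width = 480L, height = 420L) {
  y0 <- 50
  generate_phantom(phantom_spec(
    width_px = width, height_px = height, pixel_spacing_mm = 0.1,
    superficial_curve = c(y0, slope, quad),
    deep_curve = c(y0 + thickness_px, slope, quad),
    fascicle_angle_deg = angle, fascicle_spacing_px = 18L,
    noise_level = noise, seed = seed))
}

# Brute-force flood fill (4/8-connectivity) used as the component oracle.
flood_fill_count <- function(m, connectivity = 8) {
  m <- m != 0
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8)
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  count <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1) %% h) + 1; c <- ((cur - 1) %/% h) + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          i2 <- (c2 - 1) * h + r2
          if (m[i2] && !seen[i2]) { seen[i2] <- TRUE; queue <- c(queue, i2) }
        }
      }
    }
  }
  count
}

# Shannon entropy of an 8-bit histogram, for the CLAHE flatness check.
hist_entropy <- function(v) {
  p <- tabulate(round(v) + 1L, nbins = 256L)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}
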