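# Small two-group design for fast unit tests.
tiny_design <- function(noise = 0.08, batch_sd = 0.15, loading_sd = 0.05,
                        effect_treated_A = 1.5, n_blots = 2L, seed = 1L, ...) {
  groups <- c(normal = 4L, treated = 4L)
  proteins <- c("A", "B", "GAPDH")
  eff <- matrix(1, 2, 3, dimnames = list(names(groups), proteins))
  eff["treated", "A"] <- effect_treated_A
  nsd <- matrix(noise, 2, 3, dimnames = list(names(groups), proteins))
  synthetic_design(groups = groups, proteins = proteins,
                   loading_control = "GAPDH", reference_group = "normal",
                   effect = eff, noise_sd = nsd, n_blots = n_blots,
                   batch_sd = batch_sd, loading_sd = loading_sd,
                   seed = seed, ...)
}

# Independent brute-force densitometry oracle: plain double loop over pixels,
# deliberately naive so it shares no code path with quantify_band().
oracle_density <- function(image, roi, background) {
  total <- 0
  for (dy in seq_len(roi$height)) {
    for (dx in seq_len(roi$width)) {
      v <- image[roi$y0 + dy, roi$x0 + dx] - background
      if (v > 0) total <- total + v
    }
  }
  total / roi$width
}

# Random non-degenerate ROI placed fully inside an image with room for the
# background frame.
random_roi <- function(image, margin = 3L, max_w = 12L, max_h = 8L) {
  w <- sample(1:max_w, 1)
  h <- sample(1:max_h, 1)
  x0 <- sample(margin:(ncol(image) - w - margin), 1)
  y0 <- sample(margin:(nrow(image) - h - margin), 1)
  band_roi("B1", "p", "L01", x0, y0, w, h)
}
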