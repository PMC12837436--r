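# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / base fitting routines, never the package's vectorized
# paths.

# per-pixel triple-interval membership loop (blue precedence)
naive_classify_counts <- function(image, ts) {
  h <- dim(image)[1]; w <- dim(image)[2]
  counts <- c(blue = 0L, pink = 0L, other = 0L)
  in_box <- function(px, box) {
    all(px >= box["low", ] & px <= box["high", ])
  }
  map <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      px <- image[i, j, ]
      if (in_box(px, ts$blue_box)) {
        counts["blue"] <- counts["blue"] + 1L; map[i, j] <- 2L
      } else if (in_box(px, ts$pink_box)) {
        counts["pink"] <- counts["pink"] + 1L; map[i, j] <- 1L
      } else {
        counts["other"] <- counts["other"] + 1L
      }
    }
  }
  list(counts = counts, map = map)
}

# naive per-label pixel counting
naive_label_areas <- function(mask, spacing_row, spacing_col) {
  out <- numeric(0)
  for (code in sort(unique(as.vector(mask)))) {
    if (code == 0) next
    n <- 0L
    for (v in as.vector(mask)) if (v == code) n <- n + 1L
    out[as.character(code)] <- n * spacing_row * spacing_col
  }
  out
}

# random 8-bit RGB image
random_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# pure-class pixel patches drawn from the synthetic color model
model_patch <- function(n, center, sd, label) {
  px <- sapply(1:3, function(ch) {
    pmin(255, pmax(0, round(center[ch] + rnorm(n, 0, sd))))
  })
  list(pixels = matrix(px, ncol = 3), label = label)
}
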