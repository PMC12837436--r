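#' Classify pixels of a Perls-stained section into blue / pink / other
#'
#' Implements the "blue/pink analysis": every pixel of an 8-bit RGB image of a
#' Perls Prussian-blue + eosin stained section is assigned to exactly one of
#' three classes by axis-aligned box membership in RGB space — `blue` (ferric
#' iron pigment), `pink` (eosin-stained tissue) or `other` (background,
#' artefacts, out-of-box colors). A pixel lying inside both boxes is assigned
#' `blue`: the assay's analyte is iron, so the iron class takes precedence.
#'
#' @param image an 8-bit RGB image: a `height x width x 3` numeric array with
#'   integer values in 0--255 (as returned by [read_image()]).
#' @param thresholds an [rgb_threshold_set()]; defaults to
#'   [default_thresholds()].
#' @param tissue_mask optional logical (or 0/1) matrix of the image's height
#'   and width; pixels where it is `FALSE` are excluded from the class map and
#'   from all counts.
#'
#' @return A list of class `pixel_classification` with elements
#'   \describe{
#'     \item{class_map}{integer matrix, `0` = other, `1` = pink, `2` = blue,
#'       `NA` = masked out.}
#'     \item{counts}{a `pixel_class_counts` object (`blue`, `pink`, `other`,
#'       `total`); `total` equals the number of unmasked pixels.}
#'     \item{thresholds_used}{the threshold set applied.}
#'   }
#' @export
classify_pixels <- function(image, thresholds = default_thresholds(),
                            tissue_mask = NULL) {
  check_rgb_image(image)
  stopifnot(inherits(thresholds, "rgb_threshold_set"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!is.null(tissue_mask)) {
    if (!identical(dim(tissue_mask), c(h, w))) {
      stop("tissue_mask dimensions must match the image", call. = FALSE)
    }
    keep <- as.logical(tissue_mask)
    dim(keep) <- c(h, w)
  } else {
    keep <- NULL
  }

  in_box <- function(box) {
    m <- image[, , 1] >= box["low", "R"] & image[, , 1] <= box["high", "R"] &
         image[, , 2] >= box["low", "G"] & image[, , 2] <= box["high", "G"] &
         image[, , 3] >= box["low", "B"] & image[, , 3] <= box["high", "B"]
    m
  }
  blue <- in_box(thresholds$blue_box)
  pink <- in_box(thresholds$pink_box) & !blue  # blue precedence on overlap

  class_map <- matrix(0L, h, w)
  class_map[pink] <- 1L
  class_map[blue] <- 2L
  if (!is.null(keep)) class_map[!keep] <- NA_integer_

  counts <- pixel_class_counts(
    blue = sum(class_map == 2L, na.rm = TRUE),
    pink = sum(class_map == 1L, na.rm = TRUE),
    other = sum(class_map == 0L, na.rm = TRUE)
  )
  structure(list(class_map = class_map, counts = counts,
                 thresholds_used = thresholds),
            class = "pixel_classification")
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be a height x width x 3 RGB array", call. = FALSE)
  }
  if (any(image < 0) || any(image > 255) || any(image != floor(image))) {
    stop("image must hold 8-bit channel values (integers in 0-255)",
         call. = FALSE)
  }
  invisible(image)
}

#' Pixel class counts
#'
#' Tallies of classified pixels. `total = blue + pink + other` by
#' construction, i.e. the number of (unmasked) pixels considered.
#'
#' @param blue,pink,other non-negative integer counts.
#' @return An object of class `pixel_class_counts`.
#' @export
pixel_class_counts <- function(blue, pink, other) {
  for (v in list(blue, pink, other)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      stop("counts must be single non-negative integers", call. = FALSE)
    }
  }
  structure(list(blue = as.integer(blue), pink = as.integer(pink),
                 other = as.integer(other),
                 total = as.integer(blue + pink + other)),
            class = "pixel_class_counts")
}

#' Blue/pink iron-deposition ratio
#'
#' The quantitative readout of the stain analysis: the number of blue
#' (iron-stained) pixels divided by the number of blue plus pink pixels.
#' Background and other out-of-box pixels never enter numerator or
#' denominator, so the ratio measures iron-deposition area as a fraction of
#' recognized tissue area.
#'
#' @param counts a `pixel_class_counts` object (or the `$counts` of a
#'   [classify_pixels()] result).
#' @param image_id identifier carried into the result.
#' @param thresholds_used optional `rgb_threshold_set` recorded alongside.
#' @return A `stain_ratio_result` list: `counts`, `ratio` (in `[0, 1]`),
#'   `image_id`, `thresholds_used`.
#' @export
blue_pink_ratio <- function(counts, image_id = NA_character_,
                            thresholds_used = NULL) {
  if (inherits(counts, "pixel_classification")) {
    if (is.null(thresholds_used)) thresholds_used <- counts$thresholds_used
    counts <- counts$counts
  }
  stopifnot(inherits(counts, "pixel_class_counts"))
  denom <- counts$blue + counts$pink
  if (denom == 0L) {
    stop("undefined blue/pink ratio: no blue or pink pixels recognized ",
         "(image contains no classifiable tissue)", call. = FALSE)
  }
  structure(list(counts = counts, ratio = counts$blue / denom,
                 image_id = image_id, thresholds_used = thresholds_used),
            class = "stain_ratio_result")
}

#' @export
print.stain_ratio_result <- function(x, ...) {
  cat(sprintf("blue/pink stain ratio: %.6g  (blue %d / [blue %d + pink %d])\n",
              x$ratio, x$counts$blue, x$counts$blue, x$counts$pink))
  if (!is.na(x$image_id)) cat("  image:", x$image_id, "\n")
  if (!is.null(x$thresholds_used)) {
    cat("  thresholds:", x$thresholds_used$name, "\n")
  }
  invisible(x)
}

#' Calibrate threshold boxes from annotated pure-class patches
#'
#' Grid search for the pair of RGB boxes maximizing balanced per-class pixel
#' accuracy on annotated patches, mirroring the empirical threshold-adjustment
#' workflow the blue/pink analysis was built around. Each candidate box is a
#' combination of per-channel `(low, high)` bounds from `grid`; the blue and
#' pink boxes are searched independently (one-vs-rest on the patch pixels),
#' which is exact because class precedence only matters on overlap. Ties are
#' broken by earliest grid ordering, so the result is deterministic for a
#' fixed grid.
#'
#' @param patches a list of annotated patches; each element is a list with
#'   `pixels` (an `n x 3` matrix of 8-bit RGB rows, or an RGB array that will
#'   be flattened) and `label` (`"blue"`, `"pink"` or `"other"`).
#' @param grid a list with elements `low` and `high`: candidate bound values
#'   (vectors in 0--255) tried for every channel. Defaults to a coarse
#'   32-level grid.
#' @return A calibrated [rgb_threshold_set()].
#' @export
calibrate_thresholds <- function(patches,
                                 grid = list(low = seq(0, 224, by = 32),
                                             high = seq(31, 255, by = 32))) {
  labels <- vapply(patches, function(p) p$label, character(1))
  if (!all(labels %in% c("blue", "pink", "other"))) {
    stop("patch labels must be 'blue', 'pink' or 'other'", call. = FALSE)
  }
  for (cls in c("blue", "pink")) {
    if (!any(labels == cls)) {
      stop("calibration requires at least one '", cls, "' patch",
           call. = FALSE)
    }
  }
  if (!length(grid$low) || !length(grid$high) ||
      any(grid$low < 0) || any(grid$high > 255)) {
    stop("degenerate search grid", call. = FALSE)
  }
  px <- do.call(rbind, lapply(patches, function(p) {
    m <- p$pixels
    if (is.array(m) && length(dim(m)) == 3L) m <- matrix(m, ncol = 3)
    m
  }))
  lab <- rep(labels, vapply(patches, function(p) {
    m <- p$pixels
    if (is.array(m) && length(dim(m)) == 3L) prod(dim(m)[1:2]) else nrow(m)
  }, integer(1)))

  best_box_for <- function(cls) {
    pos <- lab == cls
    # per-channel bound pairs scored jointly: exhaustive over the grid,
    # channel memberships precomputed once per candidate bound
    cand <- expand.grid(low = grid$low, high = grid$high)
    cand <- cand[cand$low <= cand$high, , drop = FALSE]
    ch_member <- lapply(1:3, function(ch) {
      vapply(seq_len(nrow(cand)), function(i) {
        px[, ch] >= cand$low[i] & px[, ch] <= cand$high[i]
      }, logical(nrow(px)))
    })
    best <- NULL; best_score <- -Inf
    for (i in seq_len(nrow(cand))) {
      mi <- ch_member[[1]][, i]
      if (!any(mi[pos])) next  # box misses the class entirely on channel R
      for (j in seq_len(nrow(cand))) {
        mj <- mi & ch_member[[2]][, j]
        if (!any(mj[pos])) next
        for (k in seq_len(nrow(cand))) {
          inside <- mj & ch_member[[3]][, k]
          sens <- mean(inside[pos])
          spec <- if (any(!pos)) mean(!inside[!pos]) else 1
          score <- (sens + spec) / 2
          if (score > best_score + 1e-12) {
            best_score <- score
            best <- c(cand$low[i], cand$high[i], cand$low[j], cand$high[j],
                      cand$low[k], cand$high[k])
          }
        }
      }
    }
    if (is.null(best)) stop("calibration failed: empty class coverage",
                            call. = FALSE)
    best
  }

  rgb_threshold_set(best_box_for("blue"), best_box_for("pink"),
                    name = "calibrated", provenance = "calibrated")
}

#' Run the stain analysis over a batch of images
#'
#' Applies one threshold set to every image of a batch (the between-group
#' comparison requires batch-level threshold consistency) and returns one row
#' per image. A per-image threshold override is possible but must be explicit.
#'
#' @param paths character vector of PNG/TIFF image paths.
#' @param thresholds the batch [rgb_threshold_set()].
#' @param overrides optional named list mapping an image path to its own
#'   `rgb_threshold_set` (explicit per-image override).
#' @return A data.frame with columns `image_id`, `blue`, `pink`, `other`,
#'   `total`, `ratio`, `thresholds`. An image whose ratio is undefined (no
#'   blue or pink pixels) gets `ratio = NA` with a warning.
#' @export
stain_batch <- function(paths, thresholds = default_thresholds(),
                        overrides = NULL) {
  rows <- lapply(paths, function(p) {
    ts <- if (!is.null(overrides) && !is.null(overrides[[p]])) {
      overrides[[p]]
    } else {
      thresholds
    }
    cl <- classify_pixels(read_image(p), ts)
    ratio <- tryCatch(blue_pink_ratio(cl$counts)$ratio, error = function(e) {
      warning("image '", basename(p), "': ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    data.frame(image_id = basename(p), blue = cl$counts$blue,
               pink = cl$counts$pink, other = cl$counts$other,
               total = cl$counts$total, ratio = ratio,
               thresholds = ts$name, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
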