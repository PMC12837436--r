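#' RGB threshold sets for blue/pink stain classification
#'
#' An `rgb_threshold_set` holds one axis-aligned box per stain class in RGB
#' space: an inclusive `(low, high)` interval per channel for the Prussian-blue
#' (ferric iron) class and one for the eosin-pink (tissue) class. A pixel
#' belongs to a class when all three of its channel values fall inside the
#' class box; bounds are inclusive on both ends.
#'
#' @param blue_box,pink_box 2x3 numeric matrices, rows `low`/`high`, columns
#'   `R`/`G`/`B`, all values in 0--255 with `low <= high` per channel. A plain
#'   length-6 vector `(Rlo, Rhi, Glo, Ghi, Blo, Bhi)` is also accepted.
#' @param name free-text label for the set.
#' @param provenance `"default"` or `"calibrated"`.
#'
#' @return An object of class `rgb_threshold_set`.
#' @seealso [default_thresholds()], [classify_pixels()], [read_thresholds()]
#' @export
rgb_threshold_set <- function(blue_box, pink_box, name = "unnamed",
                              provenance = c("default", "calibrated")) {
  provenance <- match.arg(provenance)
  obj <- structure(
    list(blue_box = as_channel_box(blue_box),
         pink_box = as_channel_box(pink_box),
         name = as.character(name)[1],
         provenance = provenance),
    class = "rgb_threshold_set"
  )
  validate_threshold_set(obj)
  obj
}

as_channel_box <- function(x) {
  if (is.numeric(x) && length(x) == 6L && is.null(dim(x))) {
    x <- matrix(x, nrow = 2, ncol = 3,
                dimnames = list(c("low", "high"), c("R", "G", "B")))
  }
  if (!is.matrix(x) || !all(dim(x) == c(2, 3))) {
    stop("a channel box must be a 2x3 matrix (low/high rows, R/G/B columns)",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(c("low", "high"), c("R", "G", "B"))
  x
}

validate_threshold_set <- function(ts) {
  for (nm in c("blue_box", "pink_box")) {
    b <- ts[[nm]]
    if (any(b < 0) || any(b > 255)) {
      stop(sprintf("%s: all bounds must lie in [0, 255]", nm), call. = FALSE)
    }
    if (any(b["low", ] > b["high", ])) {
      stop(sprintf("%s: low bound exceeds high bound", nm), call. = FALSE)
    }
  }
  invisible(ts)
}

#' Default blue/pink threshold set
#'
#' The study this pipeline models determined its RGB thresholds empirically
#' and never published the values, so the package ships a documented stand-in:
#' the blue box admits low-red / low-to-mid-green / high-blue pixels
#' (Prussian-blue pigment) and the pink box admits high-red / mid-green /
#' mid-blue pixels (eosin counterstain). Near-white background falls outside
#' both boxes. Every quantitative result records the threshold set used, so a
#' calibrated replacement (see [calibrate_thresholds()]) can be swapped in
#' batch-wide.
#'
#' @return An `rgb_threshold_set` named `"phhquant-default"`.
#' @export
default_thresholds <- function() {
  rgb_threshold_set(
    blue_box = matrix(c(0, 120,   0, 130, 120, 255), 2, 3),
    pink_box = matrix(c(150, 255, 60, 210, 100, 220), 2, 3),
    name = "phhquant-default",
    provenance = "default"
  )
}

#' @export
print.rgb_threshold_set <- function(x, ...) {
  cat(sprintf("RGB threshold set '%s' (%s)\n", x$name, x$provenance))
  fmt <- function(b) paste(sprintf("%s:[%g,%g]", colnames(b), b["low", ],
                                   b["high", ]), collapse = " ")
  cat("  blue_box:", fmt(x$blue_box), "\n")
  cat("  pink_box:", fmt(x$pink_box), "\n")
  invisible(x)
}

#' Read / write threshold sets as JSON
#'
#' Threshold sets serialize to a small JSON config with explicit per-channel
#' bounds and round-trip losslessly.
#'
#' @param ts an `rgb_threshold_set`.
#' @param path file path of the JSON config.
#' @return `write_thresholds()` returns `path` invisibly; `read_thresholds()`
#'   returns an `rgb_threshold_set`.
#' @export
write_thresholds <- function(ts, path) {
  stopifnot(inherits(ts, "rgb_threshold_set"))
  box_list <- function(b) list(R = unname(b[, "R"]), G = unname(b[, "G"]),
                               B = unname(b[, "B"]))
  jsonlite::write_json(
    list(name = ts$name, provenance = ts$provenance,
         blue_box = box_list(ts$blue_box), pink_box = box_list(ts$pink_box)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "provenance", "blue_box", "pink_box")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("threshold config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unbox <- function(b) matrix(c(b$R, b$G, b$B), nrow = 2, ncol = 3)
  rgb_threshold_set(unbox(j$blue_box), unbox(j$pink_box),
                    name = j$name, provenance = j$provenance)
}
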