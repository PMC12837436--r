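#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path image file; format by extension (`.png`, `.tif`, `.tiff`).
#' @return `height x width x 3` array of integers in 0--255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = FALSE),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    stop("grayscale image: 8-bit RGB input required", call. = FALSE)
  }
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L) {
    stop("expected 3 channels, found ", dim(img)[3], call. = FALSE)
  }
  # readers return [0,1]; recover 8-bit levels and reject deeper data
  v <- img * 255
  if (max(abs(v - round(v))) > 1e-6) {
    stop("image is not 8-bit per channel; convert to 8-bit RGB first",
         call. = FALSE)
  }
  array(as.numeric(round(v)), dim = dim(v))
}

#' Write an 8-bit RGB image
#'
#' @param image `height x width x 3` array, integers 0--255.
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @return `path` invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write a class map as an indexed PNG
#'
#' Class codes are stored directly as 8-bit gray levels: 0 = other,
#' 1 = pink, 2 = blue (masked pixels fall back to 0).
#'
#' @param class_map integer matrix from [classify_pixels()].
#' @param path output PNG path.
#' @return `path` invisibly.
#' @export
write_class_map <- function(class_map, path) {
  m <- class_map
  m[is.na(m)] <- 0L
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read / write a long-format longitudinal volume table
#'
#' CSV dialect: comma-separated, UTF-8, header required, `.` decimal.
#' Required columns: `group`, `subject_id`, `day`, `volume_mL`. Missing
#' visits are simply absent rows and stay absent. Unknown group labels pass
#' through — grouping is data-driven.
#'
#' @param path CSV file path.
#' @return `read_long_table()`: typed data.frame
#'   `(group, subject_id, day, volume_mL)`.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("group", "subject_id", "day", "volume_mL")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("long table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$group <- as.character(df$group)
  df$subject_id <- as.character(df$subject_id)
  df$day <- as.integer(df$day)
  df$volume_mL <- as.numeric(df$volume_mL)
  df[, need]
}

#' @rdname read_long_table
#' @param table long-format data.frame to write.
#' @export
write_long_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a slice-area CSV
#'
#' Columns: `subject_id`, `day`, `slice_index`, `compartment`, `area_mm2`,
#' `thickness_mm` (units fixed at mm2 / mm; volumes are reported in mL).
#'
#' @param path CSV file path.
#' @return Validated slice-area data.frame.
#' @export
read_slice_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject_id", "day", "slice_index", "compartment", "area_mm2",
            "thickness_mm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("slice table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  slice_area_records(df$subject_id, df$day, df$slice_index, df$compartment,
                     df$area_mm2, df$thickness_mm)
}

#' Write a JSON run manifest
#'
#' Every CLI run emits a manifest sufficient to reproduce it: the
#' subcommand, its configuration, the seed, input paths with MD5 digests,
#' and package/R versions.
#'
#' @param path output JSON path.
#' @param subcommand CLI subcommand name.
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (digested).
#' @param seed integer seed or `NULL`.
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, subcommand, config = list(),
                           inputs = character(), seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    versions = list(phhquant = as.character(utils::packageVersion("phhquant")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
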