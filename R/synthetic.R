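# Seeded generators emulating the study's raw materials: stained sections
# with known class fractions, ellipsoid ventricle phantoms with analytic
# volumes, and four-group longitudinal cohorts. Every generator is a pure
# function of its spec + seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Largest-remainder integer allocation
#'
#' Splits `total` into integer counts proportional to `fractions` (which may
#' sum to less than 1; the remainder is the last, implicit share). Floors
#' every share, then hands the leftover units to the largest fractional
#' remainders, ties broken by position. Used to turn target class fractions
#' into exact pixel counts.
#'
#' @param total integer total to allocate.
#' @param fractions numeric vector of shares, each in `[0, 1]`, sum ≤ 1.
#' @return Integer vector of length `length(fractions) + 1` summing to
#'   `total`; the last element is the implicit remainder share.
#' @export
largest_remainder <- function(total, fractions) {
  stopifnot(all(fractions >= 0), sum(fractions) <= 1 + 1e-12)
  shares <- c(fractions, max(0, 1 - sum(fractions))) * total
  base <- floor(shares)
  left <- round(total - sum(base))
  frac <- shares - base
  if (left > 0) {
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Specification for a synthetic stained-section image
#'
#' Describes an image with three color populations — Prussian-blue stain,
#' eosin-pink tissue, and background — at controlled mixing fractions and
#' per-channel Gaussian color jitter. Default color centers sit inside the
#' default threshold boxes of [default_thresholds()], so classification of a
#' zero-jitter image recovers the generated counts exactly.
#'
#' @param width,height image size in pixels.
#' @param blue_fraction,pink_fraction target class fractions, in `[0, 1]`
#'   with sum ≤ 1; the remainder is background.
#' @param blue_center,pink_center,background_color RGB triples (0--255).
#' @param jitter_sd per-channel Gaussian color spread in 8-bit units.
#' @param layout `"RANDOM_PIXELS"` (classes scattered uniformly) or
#'   `"BLOBS"` (blue as a compact blob inside a compact tissue region).
#' @param seed integer RNG seed.
#' @return A list of class `stain_image_spec`.
#' @export
stain_image_spec <- function(width = 100, height = 100,
                             blue_fraction = 0.03, pink_fraction = 0.9,
                             blue_center = c(60, 70, 180),
                             pink_center = c(230, 150, 180),
                             background_color = c(245, 245, 245),
                             jitter_sd = 0,
                             layout = c("RANDOM_PIXELS", "BLOBS"),
                             seed = 1L) {
  layout <- match.arg(layout)
  if (blue_fraction < 0 || pink_fraction < 0 ||
      blue_fraction + pink_fraction > 1 + 1e-12) {
    stop("class fractions must be in [0, 1] with sum at most 1",
         call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be non-negative", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 blue_fraction = blue_fraction,
                 pink_fraction = pink_fraction,
                 blue_center = blue_center, pink_center = pink_center,
                 background_color = background_color,
                 jitter_sd = jitter_sd, layout = layout,
                 seed = as.integer(seed)),
            class = "stain_image_spec")
}

#' Generate a synthetic stained-section image with ground truth
#'
#' Pixel classes are allocated exactly (largest-remainder rounding of the
#' target fractions), placed per the layout, and colored by sampling each
#' channel from a Gaussian around the class center (sd = `jitter_sd`),
#' rounded and clamped to `[0, 255]`. Identical spec and seed give a
#' bit-identical image.
#'
#' @param spec a [stain_image_spec()].
#' @return A list: `image` (height x width x 3 array, 0--255 integers),
#'   `counts` (ground-truth [pixel_class_counts()]), `class_map` (generated
#'   classes: 0 background, 1 pink, 2 blue), `spec`.
#' @export
make_stain_image <- function(spec) {
  stopifnot(inherits(spec, "stain_image_spec"))
  n <- spec$width * spec$height
  alloc <- largest_remainder(n, c(spec$blue_fraction, spec$pink_fraction))
  n_blue <- alloc[1]; n_pink <- alloc[2]
  with_seed(spec$seed, {
    if (spec$layout == "RANDOM_PIXELS") {
      ord <- sample.int(n)
    } else {
      # compact tissue disc around a random center, blue blob inside it
      rows <- rep(seq_len(spec$height), times = spec$width)
      cols <- rep(seq_len(spec$width), each = spec$height)
      c_tissue <- c(stats::runif(1, 0.35, 0.65) * spec$height,
                    stats::runif(1, 0.35, 0.65) * spec$width)
      d_tissue <- (rows - c_tissue[1])^2 + (cols - c_tissue[2])^2
      tissue_ord <- order(d_tissue, seq_len(n))
      inner <- tissue_ord[seq_len(n_blue + n_pink)]
      c_blue <- c(rows[inner[1]], cols[inner[1]])
      d_blue <- (rows[inner] - c_blue[1])^2 + (cols[inner] - c_blue[2])^2
      ord <- c(inner[order(d_blue, seq_along(inner))],
               tissue_ord[-seq_len(n_blue + n_pink)])
    }
    class_vec <- integer(n)                     # 0 = background
    class_vec[ord[seq_len(n_blue)]] <- 2L       # blue
    if (n_pink > 0) class_vec[ord[n_blue + seq_len(n_pink)]] <- 1L
    centers <- rbind(spec$background_color, spec$pink_center,
                     spec$blue_center)
    img <- array(0, dim = c(spec$height, spec$width, 3))
    for (ch in 1:3) {
      mu <- centers[class_vec + 1L, ch]
      v <- if (spec$jitter_sd > 0) {
        mu + stats::rnorm(n, 0, spec$jitter_sd)
      } else {
        mu
      }
      img[, , ch] <- pmin(255, pmax(0, round(v)))
    }
  })
  class_map <- matrix(class_vec, spec$height, spec$width)
  list(image = img,
       counts = pixel_class_counts(blue = n_blue, pink = n_pink,
                                   other = n - n_blue - n_pink),
       class_map = class_map, spec = spec)
}

#' Ellipsoid ventricle phantom as a stack of label masks
#'
#' Rasterizes an axis-aligned ellipsoid (semi-axes `a`, `b` in-plane, `c`
#' through-plane, in mm) into per-slice label masks at the given pixel
#' spacing, sliced at the given thickness; each slice is the cross-section
#' at its mid-plane. All voxels are labeled `LATERAL_L`. The analytic volume
#' `4/3 pi a b c` is returned for comparison with the Cavalieri estimate.
#'
#' @param semi_axes numeric length-3 `(a, b, c)` in mm; `c` is along the
#'   slicing axis.
#' @param pixel_spacing in-plane spacing, mm per pixel edge (default 0.02).
#' @param thickness slice thickness in mm.
#' @return A list: `masks` (list of integer matrices, one per slice),
#'   `thickness_mm`, `pixel_spacing_mm`, `analytic_volume_mL`,
#'   `compartment`.
#' @export
make_ventricle_stack <- function(semi_axes, pixel_spacing = 0.02,
                                 thickness = 0.1) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes >= 0),
            pixel_spacing > 0, thickness > 0)
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  analytic_mL <- 4 / 3 * pi * a * b * cc / 1000
  if (any(semi_axes == 0)) {
    return(list(masks = list(), thickness_mm = thickness,
                pixel_spacing_mm = pixel_spacing,
                analytic_volume_mL = 0, compartment = "LATERAL_L"))
  }
  if (thickness > min(semi_axes)) {
    warning("slice thickness exceeds the smallest semi-axis; ",
            "the phantom is under-resolved", call. = FALSE)
  }
  n_slices <- ceiling(2 * cc / thickness)
  z <- -n_slices * thickness / 2 + (seq_len(n_slices) - 0.5) * thickness
  nx <- ceiling(2 * a / pixel_spacing) + 2L
  ny <- ceiling(2 * b / pixel_spacing) + 2L
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_spacing
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_spacing
  code <- compartments()[["LATERAL_L"]]
  masks <- lapply(z, function(zk) {
    shrink <- 1 - (zk / cc)^2
    m <- matrix(0L, ny, nx)
    if (shrink > 0) {
      az <- a * sqrt(shrink); bz <- b * sqrt(shrink)
      inside <- outer(ys^2 / bz^2, xs^2 / az^2, `+`) <= 1
      m[inside] <- code
    }
    m
  })
  list(masks = masks, thickness_mm = thickness,
       pixel_spacing_mm = pixel_spacing,
       analytic_volume_mL = analytic_mL, compartment = "LATERAL_L")
}

#' Slice-area records from a phantom stack
#'
#' Convenience bridge from [make_ventricle_stack()] masks to the tabular
#' slice-area representation consumed by [volume_from_areas()].
#'
#' @param stack result of [make_ventricle_stack()].
#' @param subject_id,day identifiers stamped on every record.
#' @return data.frame of slice-area records (non-empty compartments only).
#' @export
stack_to_records <- function(stack, subject_id = "phantom", day = 0L) {
  rows <- lapply(seq_along(stack$masks), function(i) {
    areas <- area_from_mask(stack$masks[[i]], stack$pixel_spacing_mm)
    areas <- areas[areas > 0]
    if (!length(areas)) return(NULL)
    data.frame(subject_id = subject_id, day = as.integer(day),
               slice_index = i - 1L, compartment = names(areas),
               area_mm2 = unname(areas), thickness_mm = stack$thickness_mm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- slice_area_records(character(), integer(), integer(),
                              character(), numeric(), numeric())
  }
  out
}

#' Reference group-mean volume trajectories
#'
#' The per-day mean ventricular CSF volumes (mL) of the four induction
#' groups of the neonatal rat IVH cohort this pipeline models — saline
#' control, hemoglobin, ferric iron, and lysed red blood cells — at
#' postnatal days 5, 12, 19 and 26. These are the default generating means
#' of [cohort_spec()] and the worked-example input of the trend analysis.
#'
#' @return data.frame `(group, day, mean_volume_mL)` with groups `control`,
#'   `Hb`, `iron`, `L-RBC`.
#' @export
reference_cohort_means <- function() {
  days <- c(5L, 12L, 19L, 26L)
  data.frame(
    group = rep(c("control", "Hb", "iron", "L-RBC"), each = 4),
    day = rep(days, 4),
    mean_volume_mL = c(0.01208, 0.005668, 0.0105, 0.0115,
                       0.007613, 0.03797, 0.03839, 0.02312,
                       0.04906, 0.2462, 0.5019, 0.9695,
                       0.04934, 0.1970, 0.2635, 0.3760),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic longitudinal cohort
#'
#' Describes a multi-group cohort whose per-subject volumes are drawn from a
#' log-normal distribution around per-group, per-day generating means —
#' log-normal for positive support and the right-skew typical of volume
#' data. The default spread is a coefficient of variation of 1.13, the mean
#' of the CVs recoverable from the reported day-26 SEMs of the modeled
#' cohort. Optional dropout emulates death from severe hydrocephalus:
#' after a subject's drawn volume exceeds a threshold, each later visit is
#' missing with the given probability (missing rows, never imputed).
#'
#' @param means data.frame `(group, day, mean_volume_mL)`; defaults to
#'   [reference_cohort_means()].
#' @param n_per_group named integer vector of subjects per group; defaults
#'   to the modeled cohort sizes (control 20, Hb 25, iron 49, L-RBC 41).
#' @param cv between-subject coefficient of variation at every group-day
#'   (spread ≥ 0; 0 gives the noise-free limit).
#' @param dropout `NULL`, or `list(threshold_mL =, prob =)`.
#' @param seed integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(means = reference_cohort_means(),
                        n_per_group = c(control = 20L, Hb = 25L,
                                        iron = 49L, `L-RBC` = 41L),
                        cv = 1.13, dropout = NULL, seed = 1L) {
  stopifnot(all(c("group", "day", "mean_volume_mL") %in% names(means)))
  if (cv < 0) stop("spread (cv) must be non-negative", call. = FALSE)
  if (any(n_per_group < 1L)) stop("need at least one subject per group",
                                  call. = FALSE)
  if (!all(names(n_per_group) %in% unique(means$group))) {
    stop("n_per_group names must match groups in `means`", call. = FALSE)
  }
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout),
              all(c("threshold_mL", "prob") %in% names(dropout)))
  }
  structure(list(means = means, n_per_group = n_per_group, cv = cv,
                 dropout = dropout, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws every subject's trajectory day by day: volume at a visit is
#' log-normal with expectation equal to the group-day generating mean and
#' the spec's CV. With dropout enabled, once a drawn volume exceeds the
#' threshold the subject dies before each subsequent visit with the given
#' probability, and all visits after death are absent from the table.
#'
#' @param spec a [cohort_spec()].
#' @return Long-format data.frame `(group, subject_id, day, volume_mL)`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sdlog <- sqrt(log(1 + spec$cv^2))
  days <- sort(unique(spec$means$day))
  mu <- function(g, d) {
    spec$means$mean_volume_mL[spec$means$group == g & spec$means$day == d]
  }
  with_seed(spec$seed, {
    rows <- list()
    for (g in names(spec$n_per_group)) {
      for (s in seq_len(spec$n_per_group[[g]])) {
        sid <- sprintf("%s_%02d", g, s)
        exceeded <- FALSE
        for (d in days) {
          if (exceeded && !is.null(spec$dropout) &&
              stats::runif(1) < spec$dropout$prob) {
            break  # death before this visit; later rows stay absent
          }
          m <- mu(g, d)
          v <- if (spec$cv == 0) m else {
            stats::rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, subject_id = sid, day = as.integer(d),
            volume_mL = v, stringsAsFactors = FALSE)
          if (!is.null(spec$dropout) && v > spec$dropout$threshold_mL) {
            exceeded <- TRUE
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
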