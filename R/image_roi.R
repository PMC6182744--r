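#' Construct a validated grayscale image slice
#'
#' Wraps a 2-D intensity matrix (arbitrary scanner units) with basic geometry
#' checks. Intensities must be finite and non-negative; images smaller than
#' 8x8 pixels are rejected as they cannot support the texture operators.
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_spacing_mm optional length-2 numeric, per-axis spacing in mm.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_spacing_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("image must be at least 8x8 pixels")
  if (any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_spacing_mm = pixel_spacing_mm),
    class = "gray_image"
  )
}

#' Construct a region-of-interest mask
#'
#' @param mask logical matrix, `TRUE` inside the ROI; must be congruent with
#'   the image it annotates and contain at least 64 in-ROI pixels.
#' @param region_label one of `"medial_tibia"`, `"medial_femur"`.
#' @param image optional `gray_image` to validate congruence against.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, region_label = c("medial_tibia", "medial_femur"),
                     image = NULL) {
  region_label <- match.arg(region_label)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (sum(mask) < 64L)
    stop("ROI must contain at least 64 pixels")
  if (!is.null(image) && !identical(dim(mask), dim(image$pixels)))
    stop("geometry error: mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ",
         paste(dim(image$pixels), collapse = "x"))
  structure(list(mask = mask, region_label = region_label), class = "roi_mask")
}

#' Assemble one knee/timepoint series of slices with per-region masks
#'
#' The analysis uses the five most central coronal slices; shorter series are
#' rejected unless `allow_short = TRUE`, in which case a warning is issued and
#' the series proceeds with a `short_series` flag.
#'
#' @param slices list, one element per slice; each element a list with
#'   components `image` (`gray_image`) and `masks` (named list of `roi_mask`
#'   with entries `medial_tibia` and `medial_femur`).
#' @param n_expected expected slice count (default 5).
#' @param allow_short proceed with fewer than `n_expected` slices.
#' @return an object of class `slice_series`.
#' @export
slice_series <- function(slices, n_expected = 5L, allow_short = FALSE) {
  if (length(slices) == 0L) stop("empty slice series")
  dims <- lapply(slices, function(s) dim(s$image$pixels))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("geometry error: slices do not share dimensions")
  for (s in slices) {
    if (!all(c("medial_tibia", "medial_femur") %in% names(s$masks)))
      stop("input error: each slice needs medial_tibia and medial_femur masks")
    for (m in s$masks) {
      if (!identical(dim(m$mask), dim(s$image$pixels)))
        stop("geometry error: mask shape does not match image shape")
    }
  }
  short <- length(slices) < n_expected
  if (short && !allow_short)
    stop("input error: expected ", n_expected, " slices, got ", length(slices))
  if (short)
    warning("short slice series: ", length(slices), " of ", n_expected,
            " slices; proceeding")
  structure(list(slices = slices, n_slices = length(slices),
                 short_series = short),
            class = "slice_series")
}

#' Read a grayscale image from PNG or NIfTI
#'
#' PNG files are read with the `png` package (values rescaled to their native
#' integer range); `.nii`/`.nii.gz` files require the `RNifti` package. For
#' 3-D NIfTI volumes a single slice must be selected by `slice_index`.
#'
#' @param path file path.
#' @param slice_index slice to extract from a 3-D volume (ignored for 2-D).
#' @return a `gray_image`.
#' @export
read_gray_image <- function(path, slice_index = NULL) {
  gray_image(.read_pixels(path, slice_index))
}

#' Read an ROI mask (nonzero pixels are in-ROI)
#'
#' @inheritParams read_gray_image
#' @param region_label region the mask delineates.
#' @return an `roi_mask`.
#' @export
read_roi_mask <- function(path, region_label, slice_index = NULL) {
  px <- .read_pixels(path, slice_index)
  roi_mask(px > 0, region_label = region_label)
}

.read_pixels <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]  # collapse grayscale-as-RGB
    # readPNG rescales to [0,1]; restore 16-bit integer units
    return(round(a * 65535))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI files")
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) == 3L) {
      if (is.null(slice_index)) stop("slice_index required for 3-D volume")
      a <- a[, , slice_index]
    }
    return(a)
  }
  stop("unsupported image format: ", path)
}

#' Load a slice series from a file manifest
#'
#' The manifest is a data frame (or CSV path) with columns `subject_id`,
#' `timepoint`, `slice_index`, `region`, `image_path`, `mask_path`. Rows for
#' one (subject, timepoint) are loaded into a `slice_series`; the two region
#' masks for a slice must reference the same image.
#'
#' @param manifest data frame or path to the manifest CSV.
#' @param subject_id,timepoint keys selecting the series to load.
#' @param n_expected,allow_short passed to [slice_series()].
#' @return a `slice_series`.
#' @export
load_slice_series <- function(manifest, subject_id, timepoint,
                              n_expected = 5L, allow_short = FALSE) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  rows <- manifest[manifest$subject_id == subject_id &
                   manifest$timepoint == timepoint, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("input error: no manifest rows for ", subject_id, "/", timepoint)
  slices <- lapply(sort(unique(rows$slice_index)), function(k) {
    sub <- rows[rows$slice_index == k, , drop = FALSE]
    img <- read_gray_image(sub$image_path[1L])
    masks <- lapply(seq_len(nrow(sub)), function(r) {
      m <- read_roi_mask(sub$mask_path[r], region_label = sub$region[r])
      if (!identical(dim(m$mask), dim(img$pixels)))
        stop("geometry error: mask ", sub$mask_path[r],
             " does not match image ", sub$image_path[1L])
      m
    })
    names(masks) <- sub$region
    list(image = img, masks = masks)
  })
  slice_series(slices, n_expected = n_expected, allow_short = allow_short)
}

#' Quantize in-mask intensities to 2^bits grey levels
#'
#' Linear min-max binning of the in-ROI intensities into `2^bits` equal-width
#' bins labelled `1..2^bits`: the in-mask minimum maps to level 1 and the
#' maximum to the top level (bins are half-open with the top edge closed).
#' This makes downstream texture features invariant to positive affine
#' rescaling of the ROI intensities. A `"sigma"` normalization alternative
#' clips to mean +/- 3 SD before binning.
#'
#' @param image a `gray_image` (or bare numeric matrix).
#' @param mask an `roi_mask` (or bare logical matrix).
#' @param bits bits per pixel, 4 (gradient) or 6 (GLCM/RLM).
#' @param normalization `"minmax"` (default) or `"sigma"` (+/- 3 SD window).
#' @return an object of class `quantized_roi` with components `grid` (integer
#'   matrix, `NA` outside the mask), `levels` (in-mask levels), `bits`,
#'   `n_levels`, `mask`, and `degenerate` (TRUE when the ROI is constant, in
#'   which case every pixel maps to level 1).
#' @export
quantize <- function(image, mask, bits, normalization = c("minmax", "sigma")) {
  normalization <- match.arg(normalization)
  if (!bits %in% c(4L, 6L)) stop("bits must be 4 or 6")
  px <- if (inherits(image, "gray_image")) image$pixels else image
  mk <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(px), dim(mk)))
    stop("geometry error: mask shape does not match image shape")
  n_levels <- as.integer(2^bits)
  x <- px[mk]
  if (normalization == "sigma") {
    mu <- mean(x); s <- sd(x)
    lo <- mu - 3 * s; hi <- mu + 3 * s
    x <- pmin(pmax(x, lo), hi)
  } else {
    lo <- min(x); hi <- max(x)
  }
  degenerate <- hi <= lo
  if (degenerate) {
    lev <- rep(1L, length(x))
  } else {
    # half-open bins [lo, hi), top edge closed so max -> top level
    lev <- pmin(floor((x - lo) / (hi - lo) * n_levels), n_levels - 1L) + 1L
    lev <- as.integer(lev)
  }
  grid <- matrix(NA_integer_, nrow(px), ncol(px))
  grid[mk] <- lev
  structure(list(grid = grid, levels = lev, bits = as.integer(bits),
                 n_levels = n_levels, mask = mk, degenerate = degenerate),
            class = "quantized_roi")
}
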