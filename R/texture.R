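# Texture feature classes: grey-level histogram, absolute gradient,
# run-length matrix (RLM) and grey-level co-occurrence matrix (GLCM).
# Conventions: grey levels are 1-based (1..2^bits); GLCM accumulation is
# symmetric; pixel pairs and runs must lie wholly in-mask (mask gaps break
# runs and invalidate pairs); per-feature averaging over directions/offsets.

# canonical direction set as (row, col) steps; 0 deg = horizontal,
# 90 deg = vertical, 45/135 deg = the two diagonals
.texture_directions <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

# population central moments; excess kurtosis; sd==0 => skew/kurt 0, flagged
.moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  v <- sum(d^2) / n
  if (v <= 0) {
    return(list(mean = mu, variance = 0, skewness = 0, kurtosis = 0,
                degenerate = TRUE))
  }
  s <- sqrt(v)
  list(mean = mu, variance = v,
       skewness = sum(d^3) / n / s^3,
       kurtosis = sum(d^4) / n / v^2 - 3,
       degenerate = FALSE)
}

#' Grey-level histogram features
#'
#' First- to fourth-order descriptors of the in-ROI intensity distribution:
#' mean, population variance, skewness and excess kurtosis. By default the
#' raw (unquantized) in-mask intensities are min-max normalized to \[0, 1\]
#' before the moments are taken, so the features are invariant to positive
#' affine intensity rescaling; `normalize = "none"` computes the moments on
#' the values as given.
#'
#' @param x numeric vector of in-ROI pixel intensities (or a `quantized_roi`,
#'   whose level vector is used).
#' @param normalize `"minmax"` or `"none"`.
#' @return named list: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `degenerate` (TRUE when the ROI is constant; skewness/kurtosis are then
#'   reported as 0).
#' @export
histogram_features <- function(x, normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  if (inherits(x, "quantized_roi")) x <- x$levels
  if (length(x) < 2L) stop("need at least 2 pixels")
  if (normalize == "minmax") {
    lo <- min(x); hi <- max(x)
    x <- if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
  }
  .moments(x)
}

#' Absolute gradient features
#'
#' Gradient magnitude by central differences on the 4-neighbourhood of the
#' 4-bit quantized ROI: for each interior pixel (all four neighbours
#' in-mask), `G = sqrt((I(i+1,j)-I(i-1,j))^2 + (I(i,j+1)-I(i,j-1))^2)`.
#' Features are the mean, population variance, skewness and excess kurtosis
#' of G over interior pixels, plus the fraction of interior pixels with
#' nonzero gradient.
#'
#' @param image `gray_image` or numeric matrix.
#' @param mask `roi_mask` or logical matrix.
#' @param bits quantization depth (default 4).
#' @param normalization passed to [quantize()].
#' @return named list: `gr_mean`, `gr_variance`, `gr_skewness`,
#'   `gr_kurtosis`, `gr_nonzeros`, `degenerate`.
#' @export
gradient_features <- function(image, mask, bits = 4L,
                              normalization = "minmax") {
  q <- quantize(image, mask, bits = bits, normalization = normalization)
  g <- q$grid
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3L || nc < 3L) stop("ROI too thin for gradient")
  core <- g[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  up    <- g[1:(nr - 2), 2:(nc - 1), drop = FALSE]
  down  <- g[3:nr,       2:(nc - 1), drop = FALSE]
  left  <- g[2:(nr - 1), 1:(nc - 2), drop = FALSE]
  right <- g[2:(nr - 1), 3:nc,       drop = FALSE]
  interior <- !is.na(core) & !is.na(up) & !is.na(down) &
              !is.na(left) & !is.na(right)
  if (!any(interior)) stop("ROI too thin for gradient")
  G <- sqrt((down[interior] - up[interior])^2 +
            (right[interior] - left[interior])^2)
  m <- .moments(G)
  list(gr_mean = m$mean, gr_variance = m$variance, gr_skewness = m$skewness,
       gr_kurtosis = m$kurtosis, gr_nonzeros = mean(G > 0),
       degenerate = m$degenerate)
}

# in-mask level pairs at (dr, dc): two columns (level_a, level_b)
.level_pairs <- function(grid, dr, dc) {
  nr <- nrow(grid); nc <- ncol(grid)
  r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
  c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
  if (r_lo > r_hi || c_lo > c_hi)
    return(matrix(integer(0), ncol = 2L))
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  a <- grid[r1, c1, drop = FALSE]
  b <- grid[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a[ok], b[ok])
}

#' Compute a grey-level co-occurrence matrix
#'
#' Counts pairs of in-mask grey levels at a given direction and pixel offset,
#' accumulated symmetrically (each pair contributes to both orientations), and
#' normalizes to probabilities.
#'
#' @param q a `quantized_roi` (6-bit by convention).
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param offset pixel offset, 1..5.
#' @return an object of class `glcm` with `counts`, `probabilities` (both
#'   `n_levels x n_levels`), `direction`, `offset`, `n_pairs`; or `NULL` when
#'   the configuration admits no valid pair (skipped configuration).
#' @export
compute_glcm <- function(q, direction, offset) {
  stopifnot(inherits(q, "quantized_roi"))
  dirs <- .texture_directions()
  key <- as.character(direction)
  if (!key %in% names(dirs)) stop("direction must be one of 0, 45, 90, 135")
  if (!offset %in% 1:5) stop("offset must be in 1..5")
  step <- dirs[[key]] * as.integer(offset)
  pr <- .level_pairs(q$grid, step[1L], step[2L])
  if (nrow(pr) == 0L) return(NULL)
  L <- q$n_levels
  counts <- matrix(tabulate((pr[, 1L] - 1L) * L + pr[, 2L], nbins = L * L),
                   L, L, byrow = TRUE)
  counts <- counts + t(counts)  # symmetric accumulation
  structure(list(counts = counts, probabilities = counts / sum(counts),
                 direction = direction, offset = offset,
                 n_pairs = sum(counts)),
            class = "glcm")
}

# per-n_levels constant structure for the Haralick features (level vector,
# squared level differences, inverse-difference weights, and the groupings of
# the p_{x+y} / p_{x-y} marginals), cached by matrix size
.glcm_cache_env <- new.env(parent = emptyenv())
.glcm_cache <- function(L) {
  key <- as.character(L)
  v <- .glcm_cache_env[[key]]
  if (!is.null(v)) return(v)
  i <- matrix(seq_len(L), L, L); j <- t(i)
  d2 <- (i - j)^2
  # the p_{x+y} / p_{x-y} marginals are group sums over the anti-diagonal /
  # diagonal bands; cache the band-sorted cell permutation and the group end
  # positions so each marginal is one indexed cumsum
  grp_sum <- function(g) {
    ord <- order(g)
    ends <- cumsum(tabulate(g - min(g) + 1L, nbins = max(g) - min(g) + 1L))
    list(ord = ord, ends = ends)
  }
  v <- list(lv = seq_len(L), d2 = d2, idmw = 1 / (1 + d2),
            sums = grp_sum(as.vector(i + j)),
            diffs = grp_sum(as.vector(abs(i - j))))
  assign(key, v, envir = .glcm_cache_env)
  v
}

#' Haralick features of a co-occurrence matrix
#'
#' Computes angular second moment, contrast, correlation, sum of squares,
#' inverse difference moment, sum average, sum entropy, entropy and difference
#' entropy from a normalized GLCM. Entropies use the natural logarithm with
#' the convention `0 * log(0) = 0`. A GLCM whose marginal standard deviations
#' vanish (single occupied level) has undefined correlation, reported as 0
#' with the `degenerate` flag set.
#'
#' @param g a `glcm` object.
#' @return named list of the nine features plus `degenerate`.
#' @export
glcm_features <- function(g) {
  p <- g$probabilities
  L <- nrow(p)
  cc <- .glcm_cache(L)
  px <- rowSums(p); py <- colSums(p)
  lv <- cc$lv
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  ent_of <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  # diagonal-band marginals p_{x+y} (k = 2..2L) and p_{x-y} (k = 0..L-1)
  band_sums <- function(gs) diff(c(0, cumsum(p[gs$ord])[gs$ends]))
  psum <- band_sums(cc$sums)
  pdiff <- band_sums(cc$diffs)
  degenerate <- (sx * sy) <= 0
  list(
    asm = sum(p * p),
    contrast = sum(cc$d2 * p),
    correlation = if (degenerate) 0 else
      drop((lv - mux) %*% p %*% (lv - muy)) / (sx * sy),
    sum_of_squares = sum((lv - mux)^2 * px),
    inverse_difference_moment = sum(cc$idmw * p),
    sum_average = sum((2:(2 * L)) * psum),
    sum_entropy = ent_of(psum),
    entropy = ent_of(p),
    difference_entropy = ent_of(pdiff),
    degenerate = degenerate
  )
}

# linear pixel indices tracing every scan line of a direction, with 0 as a
# line separator; cached by grid shape so each call is one lookup
.scan_index_env <- new.env(parent = emptyenv())
.scan_index <- function(nr, nc, direction) {
  key <- paste(nr, nc, direction)
  v <- .scan_index_env[[key]]
  if (!is.null(v)) return(v)
  idx <- seq_len(nr * nc)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  lines <- switch(as.character(direction),
    `0`   = split(idx, rows),          # along a row, by column
    `90`  = split(idx, cols),          # along a column, by row
    # 45 deg: anti-diagonals (constant row+col), traversed up-right
    `45`  = split(idx, rows + cols),
    # 135 deg: main diagonals (constant col-row), traversed down-right
    `135` = split(idx, cols - rows),
    stop("direction must be one of 0, 45, 90, 135"))
  v <- unlist(lapply(lines, function(x) c(x, 0L)), use.names = FALSE)
  assign(key, v, envir = .scan_index_env)
  v
}

#' Compute a run-length matrix
#'
#' Counts maximal runs of equal grey level along in-mask collinear segments in
#' one direction; out-of-mask pixels terminate runs. Every in-mask pixel
#' belongs to exactly one maximal run, so `sum(r * p(i, r)) = n_pixels`.
#'
#' @param q a `quantized_roi`.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @return an object of class `rlm` with `counts` (levels x run length),
#'   `total_runs`, `n_pixels`, `direction`.
#' @export
compute_rlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_roi"))
  idx <- .scan_index(nrow(q$grid), ncol(q$grid), direction)
  v <- rep(NA_integer_, length(idx))
  nz <- idx > 0L
  v[nz] <- q$grid[idx[nz]]
  r <- rle(v)
  keep <- !is.na(r$values)
  levs <- r$values[keep]; lens <- r$lengths[keep]
  n_pixels <- sum(!is.na(q$grid))
  L <- q$n_levels
  max_len <- max(lens)
  counts <- matrix(tabulate((levs - 1L) * max_len + lens,
                            nbins = L * max_len),
                   nrow = L, byrow = TRUE)
  structure(list(counts = counts, total_runs = sum(counts),
                 n_pixels = n_pixels, direction = direction),
            class = "rlm")
}

#' Run-length features (Galloway set)
#'
#' Short-run emphasis, long-run emphasis, grey-level nonuniformity, run-length
#' nonuniformity, and the fraction of the ROI occupied by runs (total runs /
#' total pixels).
#'
#' @param r an `rlm` object.
#' @return named list of the five features.
#' @export
rlm_features <- function(r) {
  p <- r$counts
  C <- r$total_runs
  if (C < 1) stop("empty run-length matrix")
  rl <- col(p)
  list(
    short_run_emphasis = sum(p / rl^2) / C,
    long_run_emphasis = sum(p * rl^2) / C,
    grey_level_nonuniformity = sum(rowSums(p)^2) / C,
    run_length_nonuniformity = sum(colSums(p)^2) / C,
    fraction_in_runs = C / r$n_pixels
  )
}

#' Average a feature over direction/offset configurations
#'
#' RLM features are averaged over 4 directions and GLCM features over the 20
#' direction-by-offset combinations, per slice. Configurations that admitted
#' no valid pairs contribute `NA` and are dropped from the mean; if every
#' configuration was skipped the result is `NA`.
#'
#' @param values numeric vector of per-configuration feature values.
#' @return scalar mean over the valid configurations.
#' @export
aggregate_feature <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Default texture feature registry
#'
#' Nineteen features spanning the four classes, always including the
#' landmark features mean, variance, gradient mean, gradient variance,
#' contrast, angular second moment and entropy. The full computable superset
#' (`full = TRUE`) has 23 names.
#'
#' @param full return the 23-name superset instead of the 19-name default.
#' @return character vector of feature names.
#' @export
texture_registry <- function(full = FALSE) {
  hist4 <- c("mean", "variance", "skewness", "kurtosis")
  grad5 <- c("gr_mean", "gr_variance", "gr_skewness", "gr_kurtosis",
             "gr_nonzeros")
  rlm5 <- c("short_run_emphasis", "long_run_emphasis",
            "grey_level_nonuniformity", "run_length_nonuniformity",
            "fraction_in_runs")
  glcm9 <- c("asm", "contrast", "correlation", "sum_of_squares",
             "inverse_difference_moment", "sum_average", "sum_entropy",
             "entropy", "difference_entropy")
  if (full) return(c(hist4, grad5, rlm5, glcm9))
  c(hist4, c("gr_mean", "gr_variance", "gr_nonzeros"), rlm5,
    c("asm", "contrast", "correlation", "inverse_difference_moment",
      "sum_average", "sum_entropy", "entropy"))
}

#' Texture configuration
#'
#' @param bits_gradient bits/pixel for gradient features (default 4).
#' @param bits_cooccurrence bits/pixel for GLCM and RLM (default 6).
#' @param offsets GLCM pixel offsets (default 1..5).
#' @param directions directions in degrees (default 0, 45, 90, 135).
#' @param registry feature names to report (default [texture_registry()]).
#' @param normalization intensity normalization before quantization.
#' @param glcm_log log base is natural; kept for provenance echo.
#' @return a list of class `texture_config`.
#' @export
texture_config <- function(bits_gradient = 4L, bits_cooccurrence = 6L,
                           offsets = 1:5, directions = c(0, 45, 90, 135),
                           registry = texture_registry(),
                           normalization = "minmax", glcm_log = "natural") {
  structure(list(bits_gradient = bits_gradient,
                 bits_cooccurrence = bits_cooccurrence,
                 offsets = offsets, directions = directions,
                 registry = registry, normalization = normalization,
                 glcm_log = glcm_log),
            class = "texture_config")
}

#' All texture features for one ROI on one slice
#'
#' Computes the histogram features on raw in-mask intensities, gradient
#' features on the 4-bit quantization, and the direction/offset-averaged RLM
#' and GLCM features on the 6-bit quantization.
#'
#' @param image `gray_image` or numeric matrix.
#' @param mask `roi_mask` or logical matrix.
#' @param config a [texture_config()].
#' @return named numeric vector over `config$registry`.
#' @export
slice_features <- function(image, mask, config = texture_config()) {
  px <- if (inherits(image, "gray_image")) image$pixels else image
  mk <- if (inherits(mask, "roi_mask")) mask$mask else mask
  out <- list()
  h <- histogram_features(px[mk])
  out[c("mean", "variance", "skewness", "kurtosis")] <-
    h[c("mean", "variance", "skewness", "kurtosis")]
  g <- gradient_features(px, mk, bits = config$bits_gradient,
                         normalization = config$normalization)
  out[c("gr_mean", "gr_variance", "gr_skewness", "gr_kurtosis",
        "gr_nonzeros")] <-
    g[c("gr_mean", "gr_variance", "gr_skewness", "gr_kurtosis",
        "gr_nonzeros")]
  q6 <- quantize(px, mk, bits = config$bits_cooccurrence,
                 normalization = config$normalization)
  rlm_names <- c("short_run_emphasis", "long_run_emphasis",
                 "grey_level_nonuniformity", "run_length_nonuniformity",
                 "fraction_in_runs")
  rvals <- sapply(config$directions, function(d) {
    unlist(rlm_features(compute_rlm(q6, d))[rlm_names])
  })
  out[rlm_names] <- apply(matrix(rvals, nrow = length(rlm_names)), 1,
                          aggregate_feature)
  glcm_names <- c("asm", "contrast", "correlation", "sum_of_squares",
                  "inverse_difference_moment", "sum_average", "sum_entropy",
                  "entropy", "difference_entropy")
  cfgs <- expand.grid(direction = config$directions, offset = config$offsets)
  gvals <- apply(cfgs, 1, function(cf) {
    gm <- compute_glcm(q6, cf[["direction"]], cf[["offset"]])
    if (is.null(gm)) return(rep(NA_real_, length(glcm_names)))
    unlist(glcm_features(gm)[glcm_names])
  })
  out[glcm_names] <- apply(matrix(gvals, nrow = length(glcm_names)), 1,
                           aggregate_feature)
  unlist(out)[config$registry]
}

#' Per-region summary features for a slice series
#'
#' Computes [slice_features()] for each slice and region and averages over
#' slices (slices with a missing feature are dropped from that feature's
#' mean).
#'
#' @param series a `slice_series`.
#' @param config a [texture_config()].
#' @param regions regions to compute (default both).
#' @return named list of per-region named feature vectors
#'   (`medial_tibia`, `medial_femur`).
#' @export
series_features <- function(series, config = texture_config(),
                            regions = c("medial_tibia", "medial_femur")) {
  stopifnot(inherits(series, "slice_series"))
  out <- lapply(regions, function(rg) {
    per_slice <- sapply(series$slices, function(s) {
      slice_features(s$image, s$masks[[rg]], config)
    })
    per_slice <- matrix(per_slice, nrow = length(config$registry),
                        dimnames = list(config$registry, NULL))
    apply(per_slice, 1, aggregate_feature)
  })
  names(out) <- regions
  out
}

#' Assemble the subject-level feature table
#'
#' @param records list; each element a list with `subject_id`, `region`
#'   (`medial_tibia`/`medial_femur`), `timepoint` (`initial`/`followup`) and
#'   `features` (named numeric vector over a common registry).
#' @return data frame with key columns `subject_id`, `region`, `timepoint`
#'   followed by one column per feature; class `feature_table`. Duplicate
#'   keys are an error.
#' @export
build_feature_table <- function(records) {
  keys <- vapply(records, function(r)
    paste(r$subject_id, r$region, r$timepoint, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("input error: duplicate (subject, region, timepoint) keys")
  feats <- do.call(rbind, lapply(records, function(r) r$features))
  df <- data.frame(
    subject_id = vapply(records, function(r) as.character(r$subject_id),
                        character(1)),
    region = vapply(records, function(r) r$region, character(1)),
    timepoint = vapply(records, function(r) r$timepoint, character(1)),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(feats))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read a feature table written to CSV
#'
#' Restores the `feature_table` class on a table previously written with
#' `write.csv` (key columns `subject_id`, `region`, `timepoint` first).
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region", "timepoint")
  if (!all(need %in% names(df)))
    stop("input error: feature table needs columns ",
         paste(need, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Follow-up minus initial change rows of a feature table
#'
#' @param ft a `feature_table`.
#' @return data frame keyed by `subject_id`, `region` with per-feature change
#'   values; subjects lacking either timepoint in a region are omitted.
#' @export
feature_changes <- function(ft) {
  fcols <- setdiff(names(ft), c("subject_id", "region", "timepoint"))
  ini <- ft[ft$timepoint == "initial", , drop = FALSE]
  fup <- ft[ft$timepoint == "followup", , drop = FALSE]
  key <- function(d) paste(d$subject_id, d$region, sep = "|")
  common <- intersect(key(ini), key(fup))
  ini <- ini[match(common, key(ini)), , drop = FALSE]
  fup <- fup[match(common, key(fup)), , drop = FALSE]
  out <- ini[, c("subject_id", "region")]
  out[fcols] <- fup[fcols] - ini[fcols]
  rownames(out) <- NULL
  out
}

#' Design matrix for one region/timebase dataset
#'
#' Builds the subject-by-feature matrix for the tibial, femoral or combined
#' dataset at the initial timepoint or as 12-18-month change. Combined
#' datasets carry `T_`/`F_` column prefixes.
#'
#' @param ft a `feature_table`.
#' @param region `"tibial"`, `"femoral"` or `"combined"`.
#' @param timebase `"initial"` or `"change"`.
#' @return numeric matrix with subject ids as row names.
#' @export
dataset_matrix <- function(ft, region = c("tibial", "femoral", "combined"),
                           timebase = c("initial", "change")) {
  region <- match.arg(region)
  timebase <- match.arg(timebase)
  fcols <- setdiff(names(ft), c("subject_id", "region", "timepoint"))
  base <- if (timebase == "initial") {
    ft[ft$timepoint == "initial", c("subject_id", "region", fcols)]
  } else {
    feature_changes(ft)
  }
  pick <- function(lbl) {
    d <- base[base$region == lbl, , drop = FALSE]
    m <- as.matrix(d[, fcols, drop = FALSE])
    rownames(m) <- d$subject_id
    m
  }
  if (region == "tibial") return(pick("medial_tibia"))
  if (region == "femoral") return(pick("medial_femur"))
  tt <- pick("medial_tibia"); ff <- pick("medial_femur")
  common <- intersect(rownames(tt), rownames(ff))
  tt <- tt[common, , drop = FALSE]; ff <- ff[common, , drop = FALSE]
  colnames(tt) <- paste0("T_", colnames(tt))
  colnames(ff) <- paste0("F_", colnames(ff))
  cbind(tt, ff)
}
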