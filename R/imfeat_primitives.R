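# Low-level image operations: illumination correction, thresholding,
# labeling, morphometry. Matrices are (row, col) with origin top-left.

#' Gaussian blur
#'
#' @param img numeric matrix.
#' @param sigma Gaussian sigma in px.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  .cpp_gaussian_blur(img, sigma)
}

#' Flat-field illumination correction
#'
#' Divides the image by a smooth flat-field estimate (large-kernel Gaussian
#' of the image itself) and rescales to preserve the original mean.
#'
#' @param img numeric matrix, non-negative.
#' @param sigma flat-field smoothing sigma; default an eighth of the
#'   smaller image dimension.
#' @return corrected matrix.
#' @export
correct_illumination <- function(img, sigma = min(dim(img)) / 8) {
  stopifnot(is.matrix(img))
  m <- mean(img)
  if (m <= 0) {
    warning("constant-zero image: illumination correction is a no-op")
    return(img)
  }
  flat <- .cpp_gaussian_blur(img, sigma)
  out <- img / pmax(flat, 1e-12)
  out * (m / mean(out))
}

#' Otsu threshold
#'
#' Maximizes between-class variance on a 256-bin histogram.
#'
#' @param x numeric vector or matrix of pixel values.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) return(hi)  # degenerate: everything background
  nb <- 256L
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * nb) + 1L, 1L), nb),
                nbins = nb)
  w <- h / sum(h)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  # ties across an empty valley: take the middle of the plateau
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-10))
  k <- best[ceiling(length(best) / 2)]
  lo + k * (hi - lo) / nb
}

#' Pooled per-plate automatic threshold
#'
#' Emulates per-plate empirically-determined intensity thresholds,
#' reproducibly: Otsu on a pooled pixel sample from all fields of a plate.
#'
#' @param images list of numeric matrices (same channel, one plate).
#' @param sample_px pixels sampled per image (deterministic stride).
#' @return scalar threshold.
#' @export
plate_threshold <- function(images, sample_px = 20000L) {
  stopifnot(length(images) >= 1)
  pool <- unlist(lapply(images, function(im) {
    v <- as.numeric(im)
    if (length(v) > sample_px)
      v <- v[seq(1L, length(v), length.out = sample_px)]
    v
  }))
  otsu_threshold(pool)
}

#' Threshold-and-label segmentation of one channel
#'
#' Connected components (8-connectivity) above an intensity threshold,
#' minimum-size filtered. An all-background image yields an empty mask.
#'
#' @param img numeric matrix.
#' @param threshold numeric threshold, or `"otsu"` for a per-image Otsu.
#' @param min_size minimum object area in px.
#' @return integer label matrix (0 = background, labels 1..n contiguous).
#' @export
segment_channel <- function(img, threshold = "otsu", min_size = 10L) {
  th <- if (identical(threshold, "otsu")) otsu_threshold(img)
        else as.numeric(threshold)
  mask <- img > th
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  lab <- .cpp_label(mask)
  filter_labels(lab, min_size)
}

#' Drop small objects and relabel contiguously
#'
#' @param lab integer label matrix.
#' @param min_size minimum area in px.
#' @return relabeled matrix.
#' @export
filter_labels <- function(lab, min_size = 1L) {
  n <- max(lab)
  if (n == 0) return(lab)
  sz <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(sz >= min_size)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# Crofton perimeter (4 directions) on a logical mask: histogram of 2x2
# pixel configurations weighted by intercept coefficients. Close to the
# true contour length for smooth objects and ~2L for thin lines.
.crofton_coefs <- c(0, pi / 4 * (1 + 1 / sqrt(2)), pi / (4 * sqrt(2)),
                    pi / (2 * sqrt(2)), 0, pi / 4 * (1 + 1 / sqrt(2)), 0,
                    pi / (4 * sqrt(2)), pi / 4, pi / 2,
                    pi / (4 * sqrt(2)), pi / (4 * sqrt(2)), pi / 4,
                    pi / 2, 0, 0)

.perimeter_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(0L, nr + 2, nc + 2)
  pm[2:(nr + 1), 2:(nc + 1)] <- mask * 1L
  ctr <- seq_len(nr + 1)
  ctc <- seq_len(nc + 1)
  xf <- pm[ctr, ctc] + 4L * pm[ctr, ctc + 1] +
    2L * pm[ctr + 1, ctc] + 8L * pm[ctr + 1, ctc + 1]
  h <- tabulate(xf + 1L, nbins = 16)
  sum(.crofton_coefs * h)
}

#' Per-object morphometry and intensity statistics
#'
#' For each labeled object: area, perimeter, form factor `4*pi*A/P^2`,
#' compactness `A/(pi*r_max^2)` with `r_max` the maximum centroid-to-border
#' distance, eccentricity and aspect ratio from second central moments,
#' extent (area / bounding-box area), centroid, and the mean/total of every
#' supplied intensity channel over the object pixels.
#'
#' @param lab integer label matrix.
#' @param intensities named list of numeric matrices (same size as `lab`).
#' @return data.frame, one row per object.
#' @export
region_props <- function(lab, intensities = list()) {
  n <- max(lab)
  cols <- c("label", "area", "perimeter", "form_factor", "compactness",
            "eccentricity", "aspect_ratio", "extent", "cy", "cx")
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    for (ch in names(intensities))
      out[[paste0(ch, "_mean")]] <- out[[paste0(ch, "_total")]] <- numeric(0)
    return(out)
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  ys <- (idx - 1) %% nrow(lab) + 1
  xs <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(lv, nbins = n)
  cy <- vapply(split(ys, lv), mean, 0)[as.character(seq_len(n))]
  cx <- vapply(split(xs, lv), mean, 0)[as.character(seq_len(n))]
  out <- data.frame(label = seq_len(n), area = area, perimeter = NA_real_,
                    form_factor = NA_real_, compactness = NA_real_,
                    eccentricity = NA_real_, aspect_ratio = NA_real_,
                    extent = NA_real_, cy = cy, cx = cx)
  sy <- split(ys, lv); sx <- split(xs, lv)
  for (i in seq_len(n)) {
    oy <- sy[[as.character(i)]]; ox <- sx[[as.character(i)]]
    y0 <- min(oy); x0 <- min(ox)
    m <- matrix(FALSE, max(oy) - y0 + 1, max(ox) - x0 + 1)
    m[cbind(oy - y0 + 1, ox - x0 + 1)] <- TRUE
    P <- .perimeter_mask(m)
    out$perimeter[i] <- P
    out$form_factor[i] <- if (P > 0) min(4 * pi * area[i] / P^2, 1 + 1e-6)
                          else NA_real_
    dy <- oy - cy[i]; dx <- ox - cx[i]
    r_max <- sqrt(max(dy^2 + dx^2)) + 0.5
    out$compactness[i] <- area[i] / (pi * r_max^2)
    mu20 <- mean(dy^2) + 1 / 12; mu02 <- mean(dx^2) + 1 / 12
    mu11 <- mean(dy * dx)
    tr <- mu20 + mu02
    dt <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (tr + dt) / 2; l2 <- max((tr - dt) / 2, 1e-12)
    out$eccentricity[i] <- sqrt(max(0, 1 - l2 / l1))
    out$aspect_ratio[i] <- sqrt(l1 / l2)
    out$extent[i] <- area[i] / (nrow(m) * ncol(m))
  }
  for (ch in names(intensities)) {
    v <- intensities[[ch]][idx]
    tot <- vapply(split(v, lv), sum, 0)[as.character(seq_len(n))]
    out[[paste0(ch, "_mean")]] <- tot / area
    out[[paste0(ch, "_total")]] <- tot
  }
  rownames(out) <- NULL
  out
}

#' Segment mitochondrial puncta
#'
#' Rolling-ball background subtraction (grayscale opening with a
#' ball-topped structuring element), white top-hat with a disc, then a
#' robust threshold (median + 6 MAD of the top-hat image) and a minimum
#' area filter. Returns labeled puncta; a blank field with a smooth
#' gradient yields no objects.
#'
#' @param img numeric matrix (TMRM channel).
#' @param ball_radius rolling-ball radius in px (default 15).
#' @param tophat_radius top-hat disc radius in px (default 5).
#' @param min_area minimum punctum area in px (default 4).
#' @return integer label matrix.
#' @export
segment_mitochondria <- function(img, ball_radius = 15L, tophat_radius = 5L,
                                 min_area = 4L) {
  if (ball_radius <= 0 || tophat_radius <= 0)
    stop("radii must be positive")
  if (ball_radius <= tophat_radius)
    stop("ball_radius must exceed tophat_radius")
  bg <- .cpp_gray_open(img, as.integer(ball_radius), TRUE, 1.0)
  sub <- pmax(img - bg, 0)
  th_img <- sub - .cpp_gray_open(sub, as.integer(tophat_radius), FALSE, 0)
  cut <- median(th_img) + 6 * mad(th_img)
  mask <- th_img > pmax(cut, 1e-9)
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  filter_labels(.cpp_label(mask), min_area)
}

#' Granularity: intensity fraction removed by a grayscale opening
#'
#' @param img numeric matrix.
#' @param radius disc radius in px.
#' @return scalar in \[0, 1\].
#' @export
granularity <- function(img, radius) {
  s <- sum(img)
  if (s <= 0) return(0)
  op <- .cpp_gray_open(img, as.integer(radius), FALSE, 0)
  max(0, (s - sum(op)) / s)
}

#' Skeletonize a neurite mask
#'
#' Zhang-Suen thinning to a one-pixel skeleton. Branch points are skeleton
#' pixels with three or more skeleton neighbors (adjacent branch pixels
#' are merged into one junction); end points have exactly one neighbor.
#'
#' @param mask logical matrix (neurite mask, somata already excluded).
#' @param prune iterations of end-point pruning applied after thinning to
#'   suppress short spur artifacts (each iteration removes the terminal
#'   pixel of every branch; spurs shorter than `prune` px vanish).
#' @return list: `skeleton` (logical matrix, pruned), `n_branch_points`,
#'   `n_end_points`, `total_length` (skeleton pixel count),
#'   `branch_xy`/`end_xy` coordinate matrices.
#' @export
skeletonize_neurites <- function(mask, prune = 4L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask))
    return(list(skeleton = mask, n_branch_points = 0L, n_end_points = 0L,
                total_length = 0L,
                branch_xy = matrix(0, 0, 2), end_xy = matrix(0, 0, 2)))
  sk <- .cpp_thin(mask)
  nr <- nrow(sk); nc <- ncol(sk)
  neighbor_count <- function(s) {
    pm <- matrix(FALSE, nr + 2, nc + 2)
    pm[2:(nr + 1), 2:(nc + 1)] <- s
    nb <- matrix(0L, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- nb + pm[2:(nr + 1) + dy, 2:(nc + 1) + dx]
    }
    nb
  }
  for (i in seq_len(prune)) {
    nb <- neighbor_count(sk)
    tips <- sk & nb == 1
    if (!any(tips)) break
    sk[tips] <- FALSE
  }
  nb <- neighbor_count(sk)
  branch_mask <- sk & nb >= 3
  # merge junction pixels within ~2 px into one junction
  dil <- branch_mask
  for (dy in -1:1) for (dx in -1:1) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    dil <- dil | branch_mask[ys, xs]
  }
  blab_d <- .cpp_label(dil)
  blab <- blab_d * branch_mask
  n_branch <- length(unique(blab[blab > 0]))
  ends <- which(sk & nb == 1, arr.ind = TRUE)
  bxy <- if (n_branch > 0) {
    rp <- region_props(filter_labels(blab, 1L))
    cbind(rp$cy, rp$cx)
  } else matrix(0, 0, 2)
  list(skeleton = sk, n_branch_points = as.integer(n_branch),
       n_end_points = nrow(ends), total_length = sum(sk),
       branch_xy = bxy, end_xy = ends)
}

#' Marker-positivity calls for segmented cells
#'
#' A cell is positive when its mean soma intensity in the marker channel
#' exceeds the threshold; with `threshold = NULL` an automatic (Otsu)
#' threshold over the supplied intensities is used. Degenerate intensity
#' distributions (range below `min_range`) yield all-negative calls.
#'
#' @param marker_means numeric vector of per-cell mean marker intensities.
#' @param threshold numeric or NULL for automatic.
#' @param min_range minimum intensity range for an automatic call.
#' @return logical vector of positivity flags.
#' @export
classify_cells <- function(marker_means, threshold = NULL,
                           min_range = 1e-6) {
  if (length(marker_means) == 0) return(logical(0))
  if (is.null(threshold)) {
    if (diff(range(marker_means)) < min_range)
      return(rep(FALSE, length(marker_means)))
    threshold <- otsu_threshold(marker_means)
  }
  marker_means > threshold
}
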