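# Synthetic multi-channel field rendering.
#
# Fields are rendered from an explicit object-level truth: nuclei as
# smoothed elliptical blobs, somata as discs around a subset of nuclei
# carrying the marker intensities, neurites as piecewise-linear trees with
# a known branch count, and (mitochondrial panel) small high-intensity
# puncta on a smooth background gradient. Photon noise is Poisson. The
# rendering is deliberately cartoon-like: it supports round-trip testing
# of the segmentation code, not photorealism.

#' Optical / rendering parameters for synthetic fields
#'
#' @param field_size image side length in pixels.
#' @param background per-channel additive background level (counts).
#' @param nucleus_radius mean nucleus radius (px).
#' @param soma_radius mean soma radius (px).
#' @param mito_radius mean mitochondrial punctum radius (px).
#' @param lyso_radius mean lysosome radius (px).
#' @param blur_sigma Gaussian PSF sigma (px).
#' @param margin placement margin from the field border (px); default
#'   2.5 x soma_radius. Increase it when whole neurite trees must stay
#'   in frame.
#' @param gradient_amp amplitude of the smooth background gradient
#'   (fraction of background; mitochondrial panel).
#' @return object of class `optics_params`.
#' @export
optics_params <- function(field_size = 192L, background = 100,
                          nucleus_radius = 4, soma_radius = 5.5,
                          mito_radius = 1.6, lyso_radius = 1.4,
                          blur_sigma = 0.8, gradient_amp = 1.5,
                          margin = NULL) {
  stopifnot(field_size >= 32)
  margin <- margin %||% (2.5 * soma_radius)
  structure(as.list(environment()), class = "optics_params")
}

#' Object-level truth for one synthetic field
#'
#' @param panel staining panel.
#' @param n_nuclei nuclei to place.
#' @param th_fraction fraction of cells that are TH+ (panel A).
#' @param map2_fraction fraction of cells that are MAP2+ / neurite-bearing.
#' @param branches_per_cell side branches per neurite tree.
#' @param n_mito mitochondrial puncta (mitochondrial panel).
#' @param n_lyso lysosomal puncta (LAMP1 panel).
#' @param intensity named amplitudes per channel above background.
#' @return object of class `field_truth` (counts only; positions are drawn
#'   at render time and recorded in the render result).
#' @export
field_truth <- function(panel = "panelA", n_nuclei = 50, th_fraction = 0.4,
                        map2_fraction = 0.65, branches_per_cell = 2L,
                        n_mito = 250L, n_lyso = 150L,
                        intensity = NULL) {
  panel <- match.arg(panel, PANELS)
  def <- c(Hoechst = 1500, aSyn = 800, TH = 1000, MAP2 = 1200,
           calcein = 1100, TMRM = 900, LAMP1 = 700)
  intensity <- modifyList(as.list(def[panel_channels(panel)]),
                          as.list(intensity %||% list()))
  structure(list(panel = panel, n_nuclei = as.integer(n_nuclei),
                 th_fraction = th_fraction, map2_fraction = map2_fraction,
                 branches_per_cell = as.integer(branches_per_cell),
                 n_mito = as.integer(n_mito), n_lyso = as.integer(n_lyso),
                 intensity = intensity), class = "field_truth")
}

# additive elliptical blob with Gaussian profile
.add_blob <- function(img, y0, x0, ry, rx, theta, amp) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(max(ry, rx) * 2.2)
  ylo <- max(1, floor(y0 - r)); yhi <- min(nr, ceiling(y0 + r))
  xlo <- max(1, floor(x0 - r)); xhi <- min(nc, ceiling(x0 + r))
  if (yhi < ylo || xhi < xlo) return(img)
  ys <- ylo:yhi
  xs <- xlo:xhi
  dy <- outer(ys - y0, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - x0)
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  d2 <- (u / ry)^2 + (v / rx)^2
  # near-flat top, soft shoulder: recovers area ~ pi*ry*rx on thresholding
  img[ys, xs] <- img[ys, xs] + amp / (1 + exp(8 * (sqrt(d2) - 1)))
  img
}

# stamp a line segment of given half-width by sampling along its length
.add_segment <- function(img, y1, x1, y2, x2, halfwidth, amp) {
  len <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  for (i in seq_len(n))
    img <- .add_blob(img, y1 + t[i] * (y2 - y1), x1 + t[i] * (x2 - x1),
                     halfwidth, halfwidth, 0, amp / 3)
  img
}

# place n centers with a minimum pairwise distance by rejection sampling
.place_centers <- function(n, size, min_dist, margin, max_tries = 4000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  k <- 0L
  for (t in seq_len(max_tries)) {
    cand <- runif(2, margin, size - margin)
    if (k == 0L ||
        min((pts[seq_len(k), 1] - cand[1])^2 +
            (pts[seq_len(k), 2] - cand[2])^2) >= min_dist^2) {
      k <- k + 1L
      pts[k, ] <- cand
      if (k == n) return(pts)
    }
  }
  stop("field capacity error: could not place ", n,
       " objects at min distance ", min_dist, " in a ", size, "px field")
}

#' Render one synthetic field
#'
#' @param truth a [field_truth()].
#' @param optics an [optics_params()].
#' @param seed integer seed; rendering is deterministic given it.
#' @param noise add Poisson photon noise (default TRUE).
#' @return list with `images` (named list of numeric matrices, one per
#'   channel) and `truth` (the input truth augmented with exact placed
#'   object counts and positions).
#' @export
render_field <- function(truth, optics = optics_params(), seed = 1L,
                         noise = TRUE) {
  chans <- panel_channels(truth$panel)
  if (length(chans) < 2) stop("panel must define at least 2 channels")
  sz <- optics$field_size
  with_seed(seed, "render", {
    imgs <- lapply(chans, function(ch) matrix(0, sz, sz))
    names(imgs) <- chans

    nuc <- .place_centers(truth$n_nuclei, sz,
                          min_dist = 3.2 * optics$nucleus_radius,
                          margin = optics$margin)
    n_cells <- nrow(nuc)
    th_pos <- rep(FALSE, n_cells)
    map2_pos <- rep(FALSE, n_cells)
    if (n_cells > 0) {
      th_pos[sample.int(n_cells, round(truth$th_fraction * n_cells))] <- TRUE
      map2_pos[sample.int(n_cells,
                          round(truth$map2_fraction * n_cells))] <- TRUE
    }

    # nuclei
    for (i in seq_len(n_cells)) {
      ry <- optics$nucleus_radius * runif(1, 0.85, 1.15)
      rx <- optics$nucleus_radius * runif(1, 0.7, 1.0)
      imgs$Hoechst <- .add_blob(imgs$Hoechst, nuc[i, 1], nuc[i, 2], ry, rx,
                                runif(1, 0, pi),
                                truth$intensity$Hoechst * runif(1, .8, 1.2))
    }

    # somata with marker intensities
    soma_ch <- intersect(c("aSyn", "TH", "MAP2", "calcein"), chans)
    n_branch_total <- 0L
    n_agg_total <- 0L
    for (i in seq_len(n_cells)) {
      rs <- optics$soma_radius * runif(1, 0.85, 1.15)
      for (ch in soma_ch) {
        amp <- truth$intensity[[ch]] * runif(1, 0.85, 1.15)
        if (ch == "TH" && !th_pos[i]) amp <- amp * 0.08
        if (ch == "MAP2" && !map2_pos[i]) amp <- amp * 0.08
        imgs[[ch]] <- .add_blob(imgs[[ch]], nuc[i, 1], nuc[i, 2], rs, rs,
                                0, amp)
      }
      # punctate aSyn aggregates (pS129-like) inside the soma
      if ("aSyn" %in% chans) {
        n_agg <- rpois(1, 2)
        for (a in seq_len(n_agg)) {
          off <- runif(2, -0.5, 0.5) * rs
          imgs$aSyn <- .add_blob(imgs$aSyn, nuc[i, 1] + off[1],
                                 nuc[i, 2] + off[2], 1.3, 1.3, 0,
                                 truth$intensity$aSyn * 2)
        }
        n_agg_total <- n_agg_total + n_agg
      }
      # neurite tree on the MAP2 channel (and TH for TH+ cells)
      if ("MAP2" %in% chans && map2_pos[i]) {
        ang <- runif(1, 0, 2 * pi)
        trunk_len <- runif(1, 30, 38)
        y2 <- nuc[i, 1] + trunk_len * sin(ang)
        x2 <- nuc[i, 2] + trunk_len * cos(ang)
        amp <- truth$intensity$MAP2 * 0.9
        imgs$MAP2 <- .add_segment(imgs$MAP2, nuc[i, 1], nuc[i, 2], y2, x2,
                                  0.8, amp)
        nb <- truth$branches_per_cell
        if (nb > 0) {
          at <- seq(0.5, 0.85, length.out = nb)
          for (b in seq_len(nb)) {
            by <- nuc[i, 1] + at[b] * trunk_len * sin(ang)
            bx <- nuc[i, 2] + at[b] * trunk_len * cos(ang)
            bang <- ang + (-1)^b * runif(1, 0.9, 1.4)
            blen <- runif(1, 12, 18)
            ey <- by + blen * sin(bang)
            ex <- bx + blen * cos(bang)
            imgs$MAP2 <- .add_segment(imgs$MAP2, by, bx, ey, ex, 0.8, amp)
            # ground truth counts only junctions actually rendered in
            # frame (trunk end and branch tip may leave the field)
            inside <- function(y, x) y > 3 && y < sz - 3 && x > 3 &&
              x < sz - 3
            if (inside(by, bx) && inside(ey, ex))
              n_branch_total <- n_branch_total + 1L
          }
        }
      }
    }

    # mitochondrial puncta on a smooth gradient (TMRM channel)
    mito <- NULL
    if ("TMRM" %in% chans && truth$n_mito > 0) {
      ramp <- outer(seq(0, 1, length.out = sz), seq(0.3, 1, length.out = sz))
      imgs$TMRM <- imgs$TMRM + optics$background * optics$gradient_amp * ramp
      mito <- .place_centers(truth$n_mito, sz,
                             min_dist = 5 * optics$mito_radius, margin = 4)
      for (i in seq_len(truth$n_mito)) {
        el <- runif(1, 1, 2.2)
        imgs$TMRM <- .add_blob(imgs$TMRM, mito[i, 1], mito[i, 2],
                               optics$mito_radius * el, optics$mito_radius,
                               runif(1, 0, pi),
                               truth$intensity$TMRM * runif(1, 0.7, 1.3))
      }
    }

    # lysosomal puncta (LAMP1 channel)
    lyso <- NULL
    if ("LAMP1" %in% chans && truth$n_lyso > 0) {
      lyso <- .place_centers(truth$n_lyso, sz,
                             min_dist = 4 * optics$lyso_radius, margin = 4)
      for (i in seq_len(truth$n_lyso))
        imgs$LAMP1 <- .add_blob(imgs$LAMP1, lyso[i, 1], lyso[i, 2],
                                optics$lyso_radius, optics$lyso_radius, 0,
                                truth$intensity$LAMP1 * runif(1, 0.8, 1.2))
    }

    for (ch in chans) {
      img <- .cpp_gaussian_blur(imgs[[ch]] + optics$background,
                                optics$blur_sigma)
      if (noise)
        img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img))
      imgs[[ch]] <- pmin(img, 65535)
    }

    placed <- truth
    placed$nuclei_centers <- nuc
    placed$th_pos <- th_pos
    placed$map2_pos <- map2_pos
    placed$n_branch_points <- n_branch_total
    placed$n_aggregates <- n_agg_total
    placed$mito_centers <- mito
    placed$lyso_centers <- lyso
    list(images = imgs, truth = placed)
  })
}

#' Render a well's fields to TIFF files
#'
#' Files follow the pattern `{plate}_{well}_F{field}_C{channel}.tiff`.
#'
#' @param truth a [field_truth()].
#' @param dir output directory (created if needed).
#' @param plate_id,well identifiers used in filenames.
#' @param n_fields number of fields to render.
#' @param optics an [optics_params()].
#' @param seed integer seed.
#' @return data.frame listing the written files and per-field truth
#'   (as an attribute `truth`).
#' @export
render_well <- function(truth, dir, plate_id = "P1", well = "B02",
                        n_fields = 9L, optics = optics_params(),
                        seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- panel_channels(truth$panel)
  rows <- list()
  truths <- list()
  for (f in seq_len(n_fields)) {
    fr <- render_field(truth, optics,
                       seed = child_seed(seed, paste(plate_id, well, f)))
    truths[[f]] <- fr$truth
    for (ci in seq_along(chans)) {
      fn <- sprintf("%s_%s_F%d_C%d.tiff", plate_id, well, f, ci)
      write_tiff(fr$images[[ci]], file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(
        plate_id = plate_id, well = well, field = f, channel = chans[ci],
        file = fn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truths
  out
}
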