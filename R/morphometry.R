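#' Read a grayscale micrograph
#'
#' Reads a TIFF or PNG micrograph, converting RGB to luminance, and attaches
#' the pixel-size calibration. Intensities are scaled to \[0, 1\].
#'
#' @param path Image file path.
#' @param pixel_size Micrometres per pixel.
#' @param source_id Identifier recorded in downstream diameter samples;
#'   defaults to the file name.
#' @return An object of class `micrograph`: list with `pixels` (numeric
#'   matrix, rows x cols), `pixel_size`, `source_id`.
#' @export
read_micrograph <- function(path, pixel_size, source_id = basename(path)) {
  stop_if_not_scalar_positive(pixel_size, "pixel_size")
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != 0L) {
    img <- EBImage::channel(img, "luminance")
  }
  px <- EBImage::imageData(img)
  if (length(base::dim(px)) > 2L) px <- px[, , 1L]
  micrograph(t(px), pixel_size, source_id)
}

#' Construct a micrograph object from a pixel matrix
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\], rows x cols.
#' @param pixel_size Micrometres per pixel.
#' @param source_id Identifier carried into diameter samples.
#' @return A `micrograph` object.
#' @export
micrograph <- function(pixels, pixel_size, source_id = "micrograph") {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 3L, ncol(pixels) >= 3L)
  stop_if_not_scalar_positive(pixel_size, "pixel_size")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 source_id = as.character(source_id)),
            class = "micrograph")
}

#' Binarize a micrograph (step 1)
#'
#' Optionally smooths with a Gaussian filter, applies a global Otsu
#' threshold, and keeps the *dark* side as foreground (stained objects are
#' dark on a bright background). Connected components (8-connectivity)
#' smaller than `min_object_px` are removed. Holes are deliberately not
#' filled so that unstained ghost lumina stay out of the foreground.
#'
#' @param m A `micrograph` (or plain numeric matrix in \[0, 1\]).
#' @param smoothing_sigma Gaussian sigma in pixels; 0 disables smoothing.
#' @param min_object_px Minimum component area kept, in pixels.
#' @return Logical matrix, `TRUE` = stained foreground.
#' @export
binarize <- function(m, smoothing_sigma = 1, min_object_px = 30) {
  px <- if (inherits(m, "micrograph")) m$pixels else m
  stopifnot(is.matrix(px), min_object_px >= 0, smoothing_sigma >= 0)
  if (max(px) > 1 || min(px) < 0) px <- (px - min(px)) / max(1e-12, diff(range(px)))
  if (diff(range(px)) < 1e-9) {
    warning("constant-intensity image: returning empty mask")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  if (smoothing_sigma > 0) {
    px <- EBImage::imageData(EBImage::gblur(EBImage::Image(px), smoothing_sigma))
  }
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(px, 0), 1)))
  mask <- px < thr
  if (min_object_px > 0 && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Outline foreground objects (step 2)
#'
#' Marks every foreground pixel that is 8-adjacent to background; pixels on
#' the image border count the outside as background, so border-touching
#' objects are outlined along the border.
#'
#' @param mask Logical foreground matrix.
#' @return Logical matrix of outline pixels.
#' @export
outline <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(mask)
  interior <- erode_3x3(mask)
  mask & !interior
}

#' Skeletonize foreground objects (step 3)
#'
#' Thins each foreground object to a 1-pixel-wide, 8-connected medial
#' skeleton using Zhang-Suen iterative thinning, which preserves the
#' topology of each component.
#'
#' @param mask Logical foreground matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  sk <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- zhang_suen_candidates(sk, step)
      if (any(del)) {
        sk[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk
}

# One Zhang-Suen sub-iteration: pixels satisfying the classic deletion
# conditions (2<=B<=6 neighbours, exactly one 0->1 transition around the
# 8-neighbourhood, and the step-specific background constraints).
zhang_suen_candidates <- function(sk, step) {
  s <- function(dr, dc) shift_matrix(sk, dr, dc, fill = FALSE)
  # clockwise from north: P2..P9
  p2 <- s(-1, 0); p3 <- s(-1, 1); p4 <- s(0, 1); p5 <- s(1, 1)
  p6 <- s(1, 0); p7 <- s(1, -1); p8 <- s(0, -1); p9 <- s(-1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  if (step == 1) {
    cond <- (!p2 | !p4 | !p6) & (!p4 | !p6 | !p8)
  } else {
    cond <- (!p2 | !p4 | !p8) & (!p2 | !p6 | !p8)
  }
  sk & b >= 2 & b <= 6 & a == 1 & cond
}

#' Remove skeleton intersections (step 4)
#'
#' Deletes every skeleton pixel with three or more skeleton neighbours
#' (8-connectivity), repeating until none remain so that only simple paths
#' survive; isolated pixels are then dropped. Crossing or branching hyphae
#' therefore break into separate unbranched centre-line segments, keeping
#' the orthogonal width measurement well defined.
#'
#' @param s Logical skeleton matrix.
#' @return Logical skeleton matrix with only simple paths.
#' @export
prune_intersections <- function(s) {
  stopifnot(is.logical(s), is.matrix(s))
  repeat {
    nb <- neighbor_count(s)
    junction <- s & nb >= 3L
    if (!any(junction)) break
    s[junction] <- FALSE
  }
  nb <- neighbor_count(s)
  s[s & nb == 0L] <- FALSE
  s
}

#' Fragment skeleton paths (step 6, cutting)
#'
#' Traces each simple skeleton path and cuts it into consecutive fragments
#' of `fragment_len` pixels. A terminal remainder of at least 3 pixels
#' becomes its own fragment; a shorter remainder is merged into the
#' previous fragment. Paths shorter than 3 pixels yield no fragment.
#'
#' @param s Logical skeleton matrix; must already be free of intersections
#'   (see [prune_intersections()]).
#' @param fragment_len Target fragment length in pixels (>= 3).
#' @return List of fragments; each is a list with `pixels` (n x 2 matrix of
#'   (row, col)), `center` (numeric length-2), `orientation` (unit vector,
#'   endpoint to endpoint) and `fragment_id`.
#' @export
fragment_skeleton <- function(s, fragment_len = 7) {
  stopifnot(is.logical(s), is.matrix(s), fragment_len >= 3)
  paths <- trace_paths(s)
  frags <- list()
  fid <- 0L
  for (p in paths) {
    n <- nrow(p)
    if (n < 3L) next
    k <- n %/% fragment_len
    r <- n - k * fragment_len
    if (k == 0L) {
      lens <- n
    } else {
      lens <- rep(fragment_len, k)
      if (r >= 3L) lens <- c(lens, r) else lens[k] <- lens[k] + r
    }
    start <- 1L
    for (len in lens) {
      pix <- p[start:(start + len - 1L), , drop = FALSE]
      start <- start + len
      fid <- fid + 1L
      o <- pix[nrow(pix), ] - pix[1L, ]
      o <- o / sqrt(sum(o^2))
      frags[[fid]] <- list(
        pixels = pix,
        center = as.numeric(pix[ceiling(nrow(pix) / 2), ]),
        orientation = as.numeric(o),
        fragment_id = fid
      )
    }
  }
  frags
}

# Order the pixels of each simple path (max degree 2). Cycles are opened at
# an arbitrary pixel.
trace_paths <- function(s) {
  idx <- which(s, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  key <- function(r, c) paste(r, c)
  alive <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(idx))) assign(key(idx[i, 1], idx[i, 2]), TRUE, alive)
  nb <- neighbor_count(s)
  if (any(nb[s] > 2L)) {
    stop("skeleton has junction pixels; run prune_intersections() first",
         call. = FALSE)
  }
  offs <- cbind(
    rep(-1:1, each = 3), rep(-1:1, times = 3)
  )
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  live_neighbors <- function(r, c) {
    out <- NULL
    for (i in 1:8) {
      r2 <- r + offs[i, 1]; c2 <- c + offs[i, 2]
      if (exists(key(r2, c2), alive, inherits = FALSE)) {
        out <- rbind(out, c(r2, c2))
      }
    }
    out
  }
  # endpoints first so open paths are traced end-to-end
  degrees <- nb[cbind(idx[, 1], idx[, 2])]
  order_idx <- order(degrees)
  paths <- list()
  for (i in order_idx) {
    r <- idx[i, 1]; c <- idx[i, 2]
    if (!exists(key(r, c), alive, inherits = FALSE)) next
    path <- matrix(c(r, c), 1L, 2L)
    rm(list = key(r, c), envir = alive)
    repeat {
      nxt <- live_neighbors(path[nrow(path), 1], path[nrow(path), 2])
      if (is.null(nxt)) break
      path <- rbind(path, nxt[1L, ])
      rm(list = key(nxt[1L, 1], nxt[1L, 2]), envir = alive)
    }
    # if we started mid-path (cycle opened or interior start), extend backwards
    repeat {
      prv <- live_neighbors(path[1L, 1], path[1L, 2])
      if (is.null(prv)) break
      path <- rbind(prv[1L, ], path)
      rm(list = key(prv[1L, 1], prv[1L, 2]), envir = alive)
    }
    paths[[length(paths) + 1L]] <- unname(path)
  }
  paths
}

#' Measure hyphal diameters orthogonally to skeleton fragments (steps 5-6)
#'
#' From the centre of each fragment, casts two rays along the +/- normal to
#' the fragment orientation in 0.25-pixel steps until the first background
#' crossing. The diameter is the sum of the two ray lengths times the pixel
#' size. Samples are discarded when the fragment centre is not on
#' foreground, a ray exits the image before hitting background, or the
#' measured diameter exceeds `max_diameter` (such samples are typically
#' blob or crossing artifacts).
#'
#' @param fragments List of fragments from [fragment_skeleton()].
#' @param mask Logical foreground mask the fragments were derived from.
#' @param pixel_size Micrometres per pixel.
#' @param max_diameter Maximum accepted diameter in micrometres.
#' @param source_id Identifier copied into the output.
#' @return Data frame with columns `fragment_id`, `row`, `col`,
#'   `diameter_um`, `source_id`; one row per accepted fragment.
#' @export
measure_diameters <- function(fragments, mask, pixel_size,
                              max_diameter = 10, source_id = "micrograph") {
  stopifnot(is.logical(mask), is.matrix(mask))
  stop_if_not_scalar_positive(pixel_size, "pixel_size")
  out <- vector("list", length(fragments))
  n_off <- 0L
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    ctr <- f$center
    cr <- round(ctr[1L]); cc <- round(ctr[2L])
    if (cr < 1 || cr > nrow(mask) || cc < 1 || cc > ncol(mask) ||
        !mask[cr, cc]) {
      n_off <- n_off + 1L
      next
    }
    normal <- c(-f$orientation[2L], f$orientation[1L])
    d_pos <- ray_to_background(ctr, normal, mask)
    d_neg <- ray_to_background(ctr, -normal, mask)
    if (is.na(d_pos) || is.na(d_neg)) next
    diameter <- (d_pos + d_neg) * pixel_size
    if (diameter > max_diameter) next
    out[[i]] <- data.frame(
      fragment_id = f$fragment_id, row = ctr[1L], col = ctr[2L],
      diameter_um = diameter, source_id = source_id
    )
  }
  if (n_off > 0) {
    warning(sprintf("%d fragment centre(s) not on foreground; discarded", n_off))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(fragment_id = integer(0), row = numeric(0),
                      col = numeric(0), diameter_um = numeric(0),
                      source_id = character(0)))
  }
  do.call(rbind, out)
}

# Distance from `start` along unit `dir` to the first background crossing,
# sampled in 0.25 px steps; NA if the ray leaves the image first.
ray_to_background <- function(start, dir, mask, step = 0.25) {
  t <- 0
  max_t <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  while (t <= max_t) {
    t <- t + step
    r <- round(start[1L] + t * dir[1L])
    c <- round(start[2L] + t * dir[2L])
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) return(NA_real_)
    if (!mask[r, c]) return(t)
  }
  NA_real_
}

#' Kernel density summary of a diameter sample
#'
#' Gaussian kernel density of pooled hyphal diameters on a regular grid
#' over \[0, `grid_max`\], renormalized to integrate to 1 on the grid, plus
#' the thin/thick population split at `split_threshold`: the fraction of
#' hyphal width samples below the threshold estimates the thin
#' (secondary-growth) population share.
#'
#' @param samples Numeric vector of diameters in micrometres, or a data
#'   frame with a `diameter_um` column.
#' @param bandwidth Kernel bandwidth in micrometres, or `"silverman"` for
#'   Silverman's rule of thumb.
#' @param grid_max Upper grid limit in micrometres.
#' @param split_threshold Thin/thick split in micrometres.
#' @param n_grid Number of grid points.
#' @return Object of class `diameter_distribution`: list with `grid`,
#'   `density`, `bandwidth`, `n_samples`, `thin_fraction`,
#'   `thick_fraction`, `split_threshold`.
#' @export
diameter_density <- function(samples, bandwidth = "silverman", grid_max = 6,
                             split_threshold = 2, n_grid = 512L) {
  d <- if (is.data.frame(samples)) samples$diameter_um else samples
  d <- as.numeric(d)
  if (length(d) < 2L) {
    stop("need at least 2 diameter samples; pool more micrographs",
         call. = FALSE)
  }
  stopifnot(all(d > 0))
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(d) else bandwidth
  stop_if_not_scalar_positive(bw, "bandwidth")
  dens <- stats::density(d, bw = bw, from = 0, to = grid_max, n = n_grid)
  # renormalize on the truncated grid (trapezoid rule)
  dx <- diff(dens$x[1:2])
  area <- sum((dens$y[-1] + dens$y[-n_grid]) / 2) * dx
  y <- dens$y / area
  thin <- mean(d < split_threshold)
  structure(list(
    grid = dens$x, density = y, bandwidth = bw, n_samples = length(d),
    thin_fraction = thin, thick_fraction = 1 - thin,
    split_threshold = split_threshold
  ), class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  cat(sprintf(
    "<diameter_distribution> n = %d, bw = %.3g um, thin (< %.2g um) = %.3f, thick = %.3f\n",
    x$n_samples, x$bandwidth, x$split_threshold, x$thin_fraction,
    x$thick_fraction
  ))
  invisible(x)
}

#' Default morphometry configuration
#'
#' @param pixel_size Micrometres per pixel.
#' @param smoothing_sigma Gaussian smoothing sigma (px) for binarization.
#' @param min_object_px Minimum object area kept (px).
#' @param fragment_len Skeleton fragment length (px).
#' @param max_diameter Maximum accepted diameter (um).
#' @param split_threshold Thin/thick split (um).
#' @param kde_bandwidth KDE bandwidth (um) or `"silverman"`.
#' @return Named list of parameters.
#' @export
morphometry_config <- function(pixel_size = 0.2, smoothing_sigma = 1,
                               min_object_px = 30, fragment_len = 7,
                               max_diameter = 10, split_threshold = 2,
                               kde_bandwidth = "silverman") {
  list(pixel_size = pixel_size, smoothing_sigma = smoothing_sigma,
       min_object_px = min_object_px, fragment_len = fragment_len,
       max_diameter = max_diameter, split_threshold = split_threshold,
       kde_bandwidth = kde_bandwidth)
}

#' Run the six-step diameter pipeline on one micrograph
#'
#' Binarize, outline, skeletonize, prune intersections, fragment and
#' measure; returns the per-image diameter samples.
#'
#' @param m A `micrograph` object (or numeric matrix; then
#'   `config$pixel_size` is used).
#' @param config Parameters from [morphometry_config()].
#' @return Data frame of diameter samples (see [measure_diameters()]).
#' @export
measure_micrograph <- function(m, config = morphometry_config()) {
  if (!inherits(m, "micrograph")) {
    m <- micrograph(m, config$pixel_size)
  }
  mask <- binarize(m, config$smoothing_sigma, config$min_object_px)
  sk <- prune_intersections(skeletonize(mask))
  frags <- fragment_skeleton(sk, config$fragment_len)
  measure_diameters(frags, mask, m$pixel_size, config$max_diameter,
                    source_id = m$source_id)
}

#' Process a batch of micrographs and pool diameter samples
#'
#' Runs the full pipeline per image and pools the diameter samples, the way
#' sets of micrographs taken from one culture sample are analyzed together.
#' Unreadable files are skipped with a warning; if every input fails, an
#' error is raised.
#'
#' @param inputs Character vector of image paths, or a list of `micrograph`
#'   objects / numeric matrices.
#' @param config Parameters from [morphometry_config()].
#' @return List with `samples` (pooled data frame) and `counts` (named
#'   integer vector of per-image sample counts).
#' @export
process_micrograph_batch <- function(inputs, config = morphometry_config()) {
  if (length(inputs) == 0L) {
    return(list(samples = data.frame(
      fragment_id = integer(0), row = numeric(0), col = numeric(0),
      diameter_um = numeric(0), source_id = character(0)
    ), counts = integer(0)))
  }
  if (is.character(inputs)) inputs <- as.list(inputs)
  pools <- list()
  counts <- integer(length(inputs))
  names(counts) <- vapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) basename(x)
    else if (inherits(x, "micrograph")) x$source_id
    else sprintf("micrograph_%d", i)
  }, character(1))
  n_fail <- 0L
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    res <- tryCatch({
      m <- if (is.character(x)) {
        read_micrograph(x, config$pixel_size)
      } else if (inherits(x, "micrograph")) x else {
        micrograph(x, config$pixel_size, names(counts)[i])
      }
      measure_micrograph(m, config)
    }, error = function(e) {
      warning(sprintf("skipping input %d (%s): %s", i, names(counts)[i],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    counts[i] <- nrow(res)
    pools[[length(pools) + 1L]] <- res
  }
  if (n_fail == length(inputs)) {
    stop("all inputs failed to process", call. = FALSE)
  }
  samples <- if (length(pools)) do.call(rbind, pools) else data.frame(
    fragment_id = integer(0), row = numeric(0), col = numeric(0),
    diameter_um = numeric(0), source_id = character(0)
  )
  list(samples = samples, counts = counts)
}
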