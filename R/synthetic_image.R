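#' Generate a synthetic micrograph of stained mycelium
#'
#' Renders a bright-field-like grayscale image of tubular hyphae whose true
#' diameters are drawn from a normal mixture, emulating Lactophenol-blue
#' stained dispersed mycelium: stained tubes are dark ribbons of constant
#' width along smooth random paths on a bright background, while a fraction
#' of tubes are rendered as empty "ghosts" -- two thin dark cell-wall lines
#' with an unstained lumen, the morphological signature of hyphal
#' compartments that lost their cytoplasm during carbon starvation.
#'
#' The returned bundle carries the ground truth needed to validate the
#' morphometry pipeline: per-tube diameters and population labels, and a
#' `truth_mask` that covers stained tubes only (ghosts contribute nothing,
#' so a stain-polarity-based analysis must exclude them).
#'
#' @param n_tubes Number of tubes to render.
#' @param populations Data frame (or list coercible to one) with columns
#'   `mean`, `sd` (diameter in micrometres) and `weight`; weights must sum
#'   to 1. Defaults to the two populations seen under carbon starvation:
#'   thick exponential-growth hyphae (3.0 +/- 0.3 um) and thin secondary
#'   hyphae (1.0 +/- 0.15 um), equally weighted.
#' @param empty_ghost_fraction Fraction of tubes rendered as unstained
#'   ghosts (outline only).
#' @param pixel_size Micrometres per pixel (calibration; must be supplied
#'   to match the imaging setup, default 0.2).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise;
#'   the image is clipped to \[0, 1\] afterwards.
#' @param seed Integer seed; identical arguments and seed give a
#'   bit-identical bundle.
#' @param dim Image dimensions `c(rows, cols)` in pixels.
#' @param tube_length_um Approximate centre-line length of each tube.
#' @return An object of class `mycelium_bundle`: a list with elements
#'   `image` (numeric matrix in \[0,1\]), `pixel_size`, `tubes` (data frame
#'   `tube_id`, `population_id`, `true_diameter_um`, `ghost`), `paths`
#'   (list of n x 2 matrices of (row, col) centre-line points) and
#'   `truth_mask` (logical matrix of stained foreground).
#' @export
generate_mycelium_image <- function(n_tubes,
                                    populations = data.frame(
                                      mean = c(3.0, 1.0),
                                      sd = c(0.3, 0.15),
                                      weight = c(0.5, 0.5)
                                    ),
                                    empty_ghost_fraction = 0,
                                    pixel_size = 0.2,
                                    noise_sd = 0.02,
                                    seed = 1L,
                                    dim = c(800L, 800L),
                                    tube_length_um = 30) {
  stopifnot(is.numeric(n_tubes), length(n_tubes) == 1L, n_tubes >= 0)
  populations <- as.data.frame(populations)
  stopifnot(all(c("mean", "sd", "weight") %in% names(populations)))
  if (abs(sum(populations$weight) - 1) > 1e-8) {
    stop("population weights must sum to 1", call. = FALSE)
  }
  if (any(populations$mean <= 0) || any(populations$sd <= 0)) {
    stop("population means and sds must be positive", call. = FALSE)
  }
  stop_if_not_scalar_positive(pixel_size, "pixel_size")
  stopifnot(empty_ghost_fraction >= 0, empty_ghost_fraction <= 1,
            noise_sd >= 0, length(dim) == 2L, all(dim >= 16L))

  nr <- as.integer(dim[1L]); nc <- as.integer(dim[2L])
  max_diam_px <- max(populations$mean + 4 * populations$sd) / pixel_size
  if (min(nr, nc) < max_diam_px + 8) {
    stop("image too small to hold the widest tube", call. = FALSE)
  }

  bundle <- with_seed(seed, {
    # stained cytoplasm is strongly dark; unstained ghost walls are only
    # faintly visible (no stain), so thresholding excludes them
    bg <- 0.9; fg <- 0.2; wall_fg <- 0.6
    image <- matrix(bg, nr, nc)
    truth_mask <- matrix(FALSE, nr, nc)
    tubes <- data.frame(
      tube_id = integer(0), population_id = integer(0),
      true_diameter_um = numeric(0), ghost = logical(0)
    )
    paths <- list()
    if (n_tubes > 0) {
      pop_id <- sample.int(nrow(populations), n_tubes, replace = TRUE,
                           prob = populations$weight)
      diam <- rnorm(n_tubes, populations$mean[pop_id], populations$sd[pop_id])
      # truncate at a tenth of the population mean: diameters must be > 0
      diam <- pmax(diam, 0.1 * populations$mean[pop_id])
      paths <- lapply(seq_len(n_tubes), function(i) {
        random_tube_path(nr, nc, margin = diam[i] / pixel_size / 2 + 3,
                         n_steps = round(tube_length_um / pixel_size))
      })
      # ghost flags are drawn last, so fixtures differing only in
      # empty_ghost_fraction share identical tube geometry at equal seed
      n_ghost <- round(empty_ghost_fraction * n_tubes)
      ghost <- rep(FALSE, n_tubes)
      if (n_ghost > 0) ghost[sample.int(n_tubes, n_ghost)] <- TRUE
      dark <- matrix(FALSE, nr, nc)   # stained pixels
      walls <- matrix(FALSE, nr, nc)  # faint unstained ghost walls
      for (i in seq_len(n_tubes)) {
        tube_mask <- rasterize_tube(paths[[i]], diam[i] / pixel_size / 2,
                                    nr, nc)
        if (ghost[i]) {
          walls <- walls | (tube_mask & !erode_3x3(tube_mask))
        } else {
          dark <- dark | tube_mask
          truth_mask <- truth_mask | tube_mask
        }
      }
      image[walls] <- wall_fg
      image[dark] <- fg
      tubes <- data.frame(
        tube_id = seq_len(n_tubes), population_id = pop_id,
        true_diameter_um = diam, ghost = ghost
      )
    }
    if (noise_sd > 0) {
      image <- image + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      image <- pmin(pmax(image, 0), 1)
    }
    list(image = image, pixel_size = pixel_size, tubes = tubes,
         paths = paths, truth_mask = truth_mask)
  })
  structure(bundle, class = "mycelium_bundle")
}

# Smooth random centre-line: random start and heading, small per-step
# angular jitter (bounded curvature). The heading is reflected at the
# frame border (mirror in the wall) so tube placement stays spatially
# uniform across the frame.
random_tube_path <- function(nr, nc, margin, n_steps, step = 1, jitter_sd = 0.06) {
  r <- runif(1, margin + 1, nr - margin)
  c <- runif(1, margin + 1, nc - margin)
  theta <- runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- c(r, c)
  for (k in seq_len(n_steps)) {
    theta <- theta + rnorm(1, 0, jitter_sd)
    r2 <- r + step * sin(theta)
    c2 <- c + step * cos(theta)
    if (r2 < margin + 1 || r2 > nr - margin) {
      theta <- -theta
      r2 <- r + step * sin(theta)
    }
    if (c2 < margin + 1 || c2 > nc - margin) {
      theta <- pi - theta
      c2 <- c + step * cos(theta)
    }
    r <- r2; c <- c2
    pts[k + 1L, ] <- c(r, c)
  }
  pts
}

# Pixels whose centre lies within `radius_px` of the (densely resampled)
# centre line. Distances are computed against path points spaced 0.5 px
# apart, restricted to the tube's bounding box.
rasterize_tube <- function(path, radius_px, nr, nc) {
  dense <- densify_path(path, spacing = 0.5)
  r0 <- max(1L, floor(min(dense[, 1L]) - radius_px - 1))
  r1 <- min(nr, ceiling(max(dense[, 1L]) + radius_px + 1))
  c0 <- max(1L, floor(min(dense[, 2L]) - radius_px - 1))
  c1 <- min(nc, ceiling(max(dense[, 2L]) + radius_px + 1))
  rows <- r0:r1; cols <- c0:c1
  mask <- matrix(FALSE, nr, nc)
  # chunk over path points to bound memory
  dmin <- matrix(Inf, length(rows), length(cols))
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  idx <- seq_len(nrow(dense))
  for (chunk in split(idx, ceiling(idx / 200))) {
    for (j in chunk) {
      d2 <- (rr - dense[j, 1L])^2 + (cc - dense[j, 2L])^2
      dmin <- pmin(dmin, d2)
    }
  }
  mask[rows, cols] <- dmin <= radius_px^2
  mask
}

densify_path <- function(path, spacing = 0.5) {
  seg <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  out <- list(path[1L, , drop = FALSE])
  for (i in seq_along(seg)) {
    n <- max(1L, ceiling(seg[i] / spacing))
    t <- seq_len(n) / n
    out[[i + 1L]] <- cbind(
      path[i, 1L] + t * (path[i + 1L, 1L] - path[i, 1L]),
      path[i, 2L] + t * (path[i + 1L, 2L] - path[i, 2L])
    )
  }
  do.call(rbind, out)
}

# 3x3 (8-connected) binary erosion with FALSE padding.
erode_3x3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_matrix(mask, dr, dc, fill = FALSE)
  }
  out
}

#' @export
print.mycelium_bundle <- function(x, ...) {
  cat(sprintf(
    "<mycelium_bundle> %d x %d px @ %.3g um/px, %d tubes (%d ghosts), %d stained px\n",
    nrow(x$image), ncol(x$image), x$pixel_size, nrow(x$tubes),
    sum(x$tubes$ghost), sum(x$truth_mask)
  ))
  invisible(x)
}

#' Write a synthetic micrograph bundle to disk
#'
#' Writes the image as an 8-bit grayscale TIFF or PNG (chosen by the file
#' extension) and the per-tube ground truth as a TSV
#' (`tube_id`, `population_id`, `true_diameter_um`, `ghost`).
#'
#' @param bundle A `mycelium_bundle`.
#' @param image_file Output image path (`.tif` or `.png`).
#' @param truth_file Output TSV path for the tube table (optional).
#' @return Invisibly, `image_file`.
#' @export
write_image_bundle <- function(bundle, image_file, truth_file = NULL) {
  stopifnot(inherits(bundle, "mycelium_bundle"))
  # EBImage images are column-major x,y; transpose so the written raster
  # matches the (row, col) orientation used throughout.
  EBImage::writeImage(EBImage::Image(t(bundle$image)), image_file,
                      bits.per.sample = 8L)
  if (!is.null(truth_file)) {
    write.table(bundle$tubes, truth_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(image_file)
}
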