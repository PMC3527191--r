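test_that("binarize handles degenerate and analytic inputs", {
  expect_warning(m <- binarize(matrix(0.5, 20, 20)), "constant")
  expect_false(any(m))

  # dark disk of radius 10 px on bright background: area within 5% of pi r^2
  nr <- 64
  img <- matrix(0.9, nr, nr)
  rr <- row(img) - 32; cc <- col(img) - 32
  img[rr^2 + cc^2 <= 100] <- 0.2
  mask <- binarize(img, smoothing_sigma = 0, min_object_px = 10)
  expect_lt(abs(sum(mask) - pi * 100) / (pi * 100), 0.05)
})

test_that("binarize recovers the generator truth mask up to a 1-px band", {
  b <- generate_mycelium_image(8, noise_sd = 0, seed = 21, dim = c(256, 256))
  mask <- binarize(b$image, smoothing_sigma = 0, min_object_px = 0)
  mismatch <- xor(mask, b$truth_mask)
  # mismatches may only sit within 1 px of the truth boundary
  boundary <- outline(b$truth_mask) |
    (b$truth_mask == FALSE &
       mycostarve:::neighbor_count(b$truth_mask) > 0)
  expect_true(all(!mismatch | boundary))
})

test_that("small components are removed and holes are not filled", {
  img <- matrix(0.9, 40, 40)
  img[5:6, 5:6] <- 0.2            # 4-px speck
  img[15:30, 15:30] <- 0.2        # big square ...
  img[20:25, 20:25] <- 0.9        # ... with a bright hole (ghost lumen)
  mask <- binarize(img, smoothing_sigma = 0, min_object_px = 10)
  expect_false(mask[5, 5])
  expect_true(mask[15, 15])
  expect_false(mask[22, 22])      # the hole must remain background
})

test_that("outline marks boundary pixels exactly", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(outline(empty), empty)

  sq <- matrix(FALSE, 20, 20)
  sq[6:15, 6:15] <- TRUE
  expect_equal(sum(outline(sq)), 36)   # perimeter ring of a 10x10 square

  # random blobs: outline == mask minus its 3x3 erosion
  set.seed(1)
  blob <- matrix(runif(900) < 0.4, 30, 30)
  ero <- blob
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ero <- ero & mycostarve:::shift_matrix(blob, dr, dc, fill = FALSE)
  }
  expect_equal(outline(blob), blob & !ero)
})

test_that("skeletonize is idempotent on thin lines and finds the midline", {
  thin <- matrix(FALSE, 20, 40)
  thin[10, 5:35] <- TRUE
  expect_equal(skeletonize(thin), thin)

  rib <- ribbon_mask(40, 120, r0 = 20, w = 15, c_from = 5, c_to = 115)
  sk <- skeletonize(rib)
  pos <- which(sk, arr.ind = TRUE)
  # away from the ends, the skeleton sits within 1 px of the midline
  interior <- pos[pos[, 2] > 20 & pos[, 2] < 100, , drop = FALSE]
  expect_gt(nrow(interior), 0)
  expect_true(all(abs(interior[, 1] - 20) <= 1))
})

test_that("crossing ribbons produce a junction pixel", {
  plus <- ribbon_mask(60, 60, r0 = 30, w = 9) |
    t(ribbon_mask(60, 60, r0 = 30, w = 9))
  sk <- skeletonize(plus)
  expect_true(any(mycostarve:::neighbor_count(sk)[sk] >= 3))
})

test_that("prune_intersections leaves only simple paths", {
  path <- matrix(FALSE, 10, 20)
  path[5, 3:17] <- TRUE
  expect_equal(prune_intersections(path), path)

  expect_equal(prune_intersections(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))

  plus <- matrix(FALSE, 21, 21)
  plus[11, 2:20] <- TRUE
  plus[2:20, 11] <- TRUE
  pruned <- prune_intersections(plus)
  expect_true(all(mycostarve:::neighbor_count(pruned)[pruned] <= 2))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pruned * 1)))
  expect_equal(max(lab), 4)   # four disjoint arms remain
})

test_that("pruning guarantee holds over random synthetic images", {
  for (i in 1:100) {
    b <- generate_mycelium_image(4, seed = 1000 + i, dim = c(96, 96),
                                 noise_sd = 0, tube_length_um = 10)
    sk <- prune_intersections(skeletonize(b$truth_mask))
    if (any(sk)) {
      expect_true(all(mycostarve:::neighbor_count(sk)[sk] <= 2))
    }
  }
})

test_that("fragment_skeleton follows the stated remainder rule", {
  path10 <- matrix(FALSE, 5, 14)
  path10[3, 3:12] <- TRUE
  f <- fragment_skeleton(path10, fragment_len = 5)
  expect_length(f, 2)
  expect_equal(vapply(f, function(x) nrow(x$pixels), integer(1)), c(5L, 5L))

  path12 <- matrix(FALSE, 5, 16)
  path12[3, 3:14] <- TRUE
  f <- fragment_skeleton(path12, fragment_len = 5)
  expect_equal(vapply(f, function(x) nrow(x$pixels), integer(1)), c(5L, 7L))

  path2 <- matrix(FALSE, 5, 6)
  path2[3, 3:4] <- TRUE
  expect_length(fragment_skeleton(path2, fragment_len = 5), 0)

  # orientation is the normalized endpoint-to-endpoint vector
  expect_equal(f[[1]]$orientation, c(0, 1))
})

test_that("measure_diameters matches the known ribbon width", {
  rib <- ribbon_mask(40, 160, r0 = 20, w = 11, c_from = 5, c_to = 155)
  sk <- prune_intersections(skeletonize(rib))
  frags <- fragment_skeleton(sk, 7)
  s <- measure_diameters(frags, rib, pixel_size = 0.2)
  expect_gt(nrow(s), 5)
  expect_lt(abs(mean(s$diameter_um) - 2.2), 0.2)
})

test_that("rays that exit the image discard the sample", {
  # vertical ribbon touching top and bottom: normals exit left/right are
  # fine, but a ribbon along the border with rays leaving must not emit
  rib <- matrix(TRUE, 20, 5)  # foreground slab at the left edge
  frag <- list(list(pixels = cbind(8:12, 3), center = c(10, 3),
                    orientation = c(1, 0), fragment_id = 1L))
  # normal is horizontal; the ray toward column 0 exits the image
  s <- measure_diameters(frag, rib, pixel_size = 0.2)
  expect_equal(nrow(s), 0)
})

test_that("ray-cast diameters agree with the distance transform on straight tubes", {
  for (w in 3:25) {
    rib <- ribbon_mask(60, 200, r0 = 30, w = w, c_from = 5, c_to = 195)
    sk <- prune_intersections(skeletonize(rib))
    frags <- fragment_skeleton(sk, 7)
    s <- measure_diameters(frags, rib, pixel_size = 1, max_diameter = 60)
    expect_gt(nrow(s), 0)
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(rib * 1)))
    oracle <- 2 * dm[cbind(round(s$row), round(s$col))]
    expect_true(all(abs(s$diameter_um - oracle) <= 1 + 1e-9))
  }
})

test_that("diameter_density normalizes and splits populations", {
  expect_error(diameter_density(2.0), "at least 2")

  d <- diameter_density(rep(2.0, 50) + rnorm(50, 0, 1e-4), bandwidth = 0.05)
  expect_lt(abs(d$grid[which.max(d$density)] - 2.0), 0.05)

  set.seed(7)
  mix <- c(rnorm(400, 1, 0.15), rnorm(400, 3, 0.3))
  d <- diameter_density(mix, split_threshold = 2)
  dx <- diff(d$grid[1:2])
  area <- sum((d$density[-1] + d$density[-length(d$density)]) / 2) * dx
  expect_lt(abs(area - 1), 1e-6)
  expect_lt(abs(d$thin_fraction - 0.5), 0.05)
  loc <- which(diff(sign(diff(d$density))) == -2) + 1
  modes <- sort(d$grid[loc][order(d$density[loc], decreasing = TRUE)][1:2])
  expect_lt(abs(modes[1] - 1), 0.2)
  expect_lt(abs(modes[2] - 3), 0.2)
})

test_that("unstained ghosts leave the diameter distribution unchanged", {
  pops <- data.frame(mean = c(3, 1), sd = c(0.3, 0.15), weight = c(0.5, 0.5))
  s_plain <- s_ghost <- NULL
  for (i in 1:3) {
    b1 <- generate_mycelium_image(40, populations = pops, seed = 300 + i,
                                  dim = c(512, 512))
    b2 <- generate_mycelium_image(40, populations = pops,
                                  empty_ghost_fraction = 0.5,
                                  seed = 300 + i, dim = c(512, 512))
    # equal seeds share tube geometry; the ghost arm stains half of them
    expect_identical(b1$tubes$true_diameter_um, b2$tubes$true_diameter_um)
    s_plain <- c(s_plain,
                 measure_micrograph(micrograph(b1$image, 0.2))$diameter_um)
    s_ghost <- c(s_ghost,
                 measure_micrograph(micrograph(b2$image, 0.2))$diameter_um)
  }
  ks <- suppressWarnings(stats::ks.test(s_plain, s_ghost))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("batch processing pools deterministically and tolerates failures", {
  expect_equal(nrow(process_micrograph_batch(list())$samples), 0)

  b <- generate_mycelium_image(6, seed = 31, dim = c(160, 160))
  m <- micrograph(b$image, b$pixel_size, "rep")
  out <- process_micrograph_batch(list(m, m))
  expect_equal(out$counts[[1]], out$counts[[2]])
  half <- out$samples[out$samples$source_id == "rep", ]
  expect_equal(sort(half$diameter_um[seq_len(out$counts[[1]])]),
               sort(half$diameter_um[out$counts[[1]] + seq_len(out$counts[[2]])]))

  w <- capture_warnings(
    out2 <- process_micrograph_batch(list("no/such/file.tif", m))
  )
  expect_true(any(grepl("skipping", w)))
  expect_equal(unname(out2$counts[2]), unname(out$counts[1]))
  expect_error(
    suppressWarnings(process_micrograph_batch(list("a.tif", "b.tif"))),
    "all inputs failed"
  )
})
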