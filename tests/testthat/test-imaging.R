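test_that("pixel/micron conversions are mutually consistent", {
  expect_equal(px_to_um(3), 0.96)
  expect_equal(px_to_um(5), 1.6)
  expect_equal(px_to_um(10), 3.2)
  expect_equal(um_to_px(px_to_um(7)), 7)
  expect_equal(px_to_um(5, pixel_size_nm = 100), 0.5)
})

test_that("maximum projection is the element-wise max across planes", {
  a <- matrix(1:6, 2, 3)
  expect_identical(max_project(list(a)), a)
  b <- matrix(6:1, 2, 3)
  pr <- max_project(list(a, b))
  expect_true(all(pr >= a) && all(pr >= b))
  withr::with_seed(21, {
    st <- array(stats::runif(5 * 4 * 3), c(5, 4, 3))
    expect_equal(max_project(st), pmax(st[, , 1], st[, , 2], st[, , 3]))
  })
  expect_error(max_project(list(a, matrix(0, 3, 3))), "shape")
  expect_error(max_project(list()), "at least one")
})

test_that("nuclear segmentation retains non-border nuclei of real size", {
  nuc <- data.frame(cx = c(20, 60, 100, 60, 2),
                    cy = c(30, 30, 30, 80, 110),
                    radius = c(10, 10, 10, 10, 10))
  img <- render_nuclei(nuc, dim = c(120, 120))
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$nuclei), 5)
  expect_equal(sum(seg$nuclei$retained), 4)
  expect_equal(sum(seg$nuclei$touches_border), 1)
  # blank image -> no nuclei, not an error
  blank <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(blank$nuclei), 0)
})

test_that("segmentation recovers the planted non-border count per field", {
  withr::with_seed(22, {
    for (f in 1:10) {
      k <- sample(2:5, 1)
      cx <- stats::runif(k, 25, 95)
      cy <- stats::runif(k, 25, 95)
      # enforce separation so planted count is unambiguous
      ok <- rep(TRUE, k)
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        if (sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) < 24)
          ok[j] <- FALSE
      nuc <- data.frame(cx = cx[ok], cy = cy[ok], radius = 10)
      img <- render_nuclei(nuc, dim = c(120, 120))
      seg <- segment_nuclei(img)
      expect_equal(sum(seg$nuclei$retained), nrow(nuc))
    }
  })
})

test_that("spot detection picks brightest pixels with the (y, x) tie rule", {
  img <- matrix(0, 20, 20)
  img[5, 7] <- 10          # (x=7, y=5)
  img[15, 3] <- 8
  sp <- detect_spots(img, matrix(TRUE, 20, 20), min_intensity = 1)
  expect_equal(sp$x_px, c(7, 3))
  expect_equal(sp$y_px, c(5, 15))
  # two equal-intensity adjacent pixels -> smaller (y, x) wins
  img2 <- matrix(0, 10, 10)
  img2[4, 6] <- 5
  img2[4, 7] <- 5
  sp2 <- detect_spots(img2, matrix(TRUE, 10, 10), min_intensity = 1,
                      min_separation = 2)
  expect_equal(nrow(sp2), 1)
  expect_equal(c(sp2$x_px, sp2$y_px), c(6, 4))
})

test_that("planted rendered spots are detected within one pixel", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- sample(2:4, 1)
      truth <- data.frame(x_px = stats::runif(n, 8, 32),
                          y_px = stats::runif(n, 8, 32))
      # enforce separation
      keep <- rep(TRUE, n)
      if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (sqrt((truth$x_px[i] - truth$x_px[j])^2 +
                   (truth$y_px[i] - truth$y_px[j])^2) < 6) keep[j] <- FALSE
      truth <- truth[keep, ]
      img <- render_spots(truth, dim = c(40, 40), sigma = 1.2)
      sp <- detect_spots(img, matrix(TRUE, 40, 40), min_intensity = 100,
                         min_separation = 4)
      expect_equal(nrow(sp), nrow(truth))
      for (i in seq_len(nrow(truth))) {
        d <- sqrt((sp$x_px - truth$x_px[i])^2 + (sp$y_px - truth$y_px[i])^2)
        expect_lte(min(d), sqrt(2))
      }
    }
  })
})

test_that("per-spot minimum distances match geometry and the oracle", {
  cell <- data.frame(cell_id = 1,
                     channel = c("RNU1", "VGOI", "VGOI", "CB"),
                     x_px = c(0, 3, 7, 1),
                     y_px = c(0, 4, 7, 0))
  d <- spot_distances(cell)
  expect_equal(d$d_gene, 5)  # 3-4-5 triangle, nearer of the two VGOI
  expect_equal(d$d_cb, 1)
  # second VGOI farther away never wins the minimum
  cell2 <- rbind(cell, data.frame(cell_id = 1, channel = "VGOI",
                                  x_px = 0, y_px = 2))
  expect_equal(spot_distances(cell2)$d_gene, 2)
  # random tables vs all-pairs brute force
  withr::with_seed(24, {
    for (rep in 1:20) {
      R <- cbind(stats::runif(sample(1:3, 1), 0, 50),
                 stats::runif(1, 0, 50))
      R <- matrix(stats::runif(2 * sample(1:3, 1), 0, 50), ncol = 2)
      V <- matrix(stats::runif(2 * sample(1:3, 1), 0, 50), ncol = 2)
      C <- matrix(stats::runif(2 * sample(1:3, 1), 0, 50), ncol = 2)
      tab <- data.frame(
        cell_id = 1,
        channel = rep(c("RNU1", "VGOI", "CB"),
                      c(nrow(R), nrow(V), nrow(C))),
        x_px = c(R[, 1], V[, 1], C[, 1]),
        y_px = c(R[, 2], V[, 2], C[, 2]))
      got <- spot_distances(tab)
      want <- bf_min_distances(R, V, C)
      expect_equal(got$d_gene, unname(want[, "d_gene"]))
      expect_equal(got$d_cb, unname(want[, "d_cb"]))
      expect_equal(got$d_cb_vgoi, unname(want[, "d_cb_vgoi"]))
    }
  })
})

test_that("spot classification matches the threshold definitions", {
  cl <- classify_rnu1_spot(c(2, 2, 3.5, 3, 4), c(4, 6, 1, 5, 4),
                           c(9, 9, 3, 5, 2))
  expect_equal(as.character(cl$label),
               c("CB_dependent", "CB_independent", "none",
                 "CB_dependent", "none"))
  # bridging is an orthogonal flag
  expect_equal(cl$bridging, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # exactly one pair label applies for any distance pair
  withr::with_seed(25, {
    d <- classify_rnu1_spot(stats::runif(200, 0, 8),
                            stats::runif(200, 0, 8),
                            stats::runif(200, 0, 8))
    expect_true(all(table(d$label) >= 0))
    expect_equal(sum(is.na(d$label)), 0)
  })
})

test_that("interaction frequencies respect eligibility", {
  spots <- rbind(
    data.frame(cell_id = 1, channel = c("RNU1", "VGOI", "CB"),
               x_px = c(0, 1, 2), y_px = c(0, 0, 0)),
    data.frame(cell_id = 2, channel = c("RNU1", "VGOI", "CB"),
               x_px = c(0, 2, 40), y_px = c(0, 0, 0)),
    data.frame(cell_id = 3, channel = c("RNU1", "VGOI"),  # no CB
               x_px = c(0, 1), y_px = c(0, 0)))
  an <- classify_cells(spots)
  expect_setequal(an$eligible_cells, c(1, 2))
  expect_equal(an$ineligible$cell_id, 3)
  f <- interaction_frequency(an, "any_pair")
  expect_equal(f$percent, 100)
  expect_equal(f$n_cells, 2)
  fd <- interaction_frequency(an, "CB_dependent")
  expect_equal(fd$percent, 50)
  # no eligible cells -> undefined, reported
  f0 <- interaction_frequency(classify_cells(spots[spots$cell_id == 3, ]),
                              "any_pair")
  expect_true(is.na(f0$percent))
})

test_that("gene-pair frequencies are symmetric under channel swap", {
  m <- cell_population_model(n_cells = 150, p_dep = 0.4, p_indep = 0.2)
  sim <- simulate_cell_spots(m, seed = 9)
  f1 <- interaction_frequency(classify_cells(sim$spots), "any_pair")
  sw <- sim$spots
  sw$channel <- c(RNU1 = "VGOI", VGOI = "RNU1", CB = "CB")[sw$channel]
  f2 <- interaction_frequency(classify_cells(sw), "any_pair")
  expect_equal(f1$percent, f2$percent)
})

test_that("locus position scoring matches the disc geometry", {
  mask <- matrix(FALSE, 41, 41)
  yy <- row(mask); xx <- col(mask)
  mask[(xx - 21)^2 + (yy - 21)^2 <= 15^2] <- TRUE
  expect_equal(locus_position_class(21, 21, mask, edge_width = 3),
               "interior")
  expect_equal(locus_position_class(2, 2, mask, edge_width = 3),
               "exterior")
  expect_equal(locus_position_class(21, 21 - 15, mask, edge_width = 3),
               "periphery")
  # analytic oracle: distance to the circle of radius 15; points within
  # ~1.5 px of the decision boundary are skipped (the pixelated rim sits
  # up to ~1 px off the ideal circle)
  withr::with_seed(26, {
    checked <- 0
    for (rep in 1:60) {
      x <- stats::runif(1, 3, 39); y <- stats::runif(1, 3, 39)
      r <- sqrt((x - 21)^2 + (y - 21)^2)
      if (abs(abs(r - 15) - 3) < 1.5) next
      want <- if (abs(r - 15) < 3) "periphery"
      else if (r < 15) "interior" else "exterior"
      expect_equal(locus_position_class(x, y, mask, edge_width = 3), want)
      checked <- checked + 1
    }
    expect_gt(checked, 20)
  })
})
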