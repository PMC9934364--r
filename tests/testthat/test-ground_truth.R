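test_that("cell moments match closed forms for degenerate and solid shapes", {
  lab <- matrix(0L, 5, 5)
  lab[3, 3] <- 1L
  cm <- cell_moments(lab, 1)
  expect_equal(cm$area, 1)
  expect_equal(cm$M, matrix(0, 2, 2))

  # axis-aligned solid rectangle, width w (x/cols), height h (y/rows):
  # discrete variance of 0..n-1 is (n^2 - 1) / 12
  w <- 7
  h <- 4
  lab <- matrix(0L, 12, 12)
  lab[3 + seq_len(h), 2 + seq_len(w)] <- 2L
  cm <- cell_moments(lab, 2)
  expect_equal(cm$area, w * h)
  expect_equal(cm$M, diag(c((w^2 - 1) / 12, (h^2 - 1) / 12)), tolerance = 1e-12)

  expect_error(cell_moments(lab, 99), "not present")
})

test_that("rasterized ellipse moments recover the continuous a^2/4, b^2/4", {
  for (ab in list(c(20, 10), c(15, 12))) {
    lab <- rasterize_ellipse(ab[1], ab[2], theta = 0)
    ev <- eigen(cell_moments(lab, 1)$M, symmetric = TRUE)$values
    expect_lt(abs(ev[1] - ab[1]^2 / 4) / (ab[1]^2 / 4), 0.03)
    expect_lt(abs(ev[2] - ab[2]^2 / 4) / (ab[2]^2 / 4), 0.03)
  }
})

test_that("window shape recovers a tilted ellipse's axes and orientation", {
  lab <- rasterize_ellipse(20, 10, theta = pi / 3, size = 64)
  st <- window_shape(lab)
  expect_lt(abs(st$L / 2 - 20) / 20, 0.05)
  expect_lt(abs(st$l / 2 - 10) / 10, 0.05)
  expect_lt(abs(fold_pi(st$alpha - pi / 3)), 0.05)
  expect_false(st$degenerate)
})

test_that("a circular cell yields equal axes and a flagged orientation", {
  lab <- rasterize_ellipse(10, 10, size = 32)
  st <- window_shape(lab)
  expect_equal(st$L, st$l, tolerance = 1e-9)
  expect_true(st$degenerate)
  expect_equal(st$alpha, 0)
})

test_that("window shape is invariant under 180-degree rotation and equivariant under 90", {
  lab <- rasterize_ellipse(18, 9, theta = 0.4, size = 56)
  st <- window_shape(lab)
  rot180 <- lab[rev(seq_len(nrow(lab))), rev(seq_len(ncol(lab)))]
  st180 <- window_shape(rot180)
  expect_equal(st180$L, st$L, tolerance = 1e-9)
  expect_equal(st180$l, st$l, tolerance = 1e-9)
  expect_equal(st180$alpha, st$alpha, tolerance = 1e-9)

  # 90-degree CCW-in-matrix rotation maps alpha -> alpha + pi/2 (mod pi)
  rot90 <- t(lab)[rev(seq_len(ncol(lab))), ]
  st90 <- window_shape(rot90)
  expect_gt(st$L / st$l, 1.3)
  expect_lt(abs(fold_pi(st90$alpha - (st$alpha + pi / 2))), 0.05)
  expect_equal(st90$L, st$L, tolerance = 1e-6)
})

test_that("window shape agrees with the naive pixel-loop oracle to 1e-9", {
  set.seed(5)
  n_checked <- 0
  for (s in 1:10) {
    tis <- generate_tissue(tissue_spec(
      image_height = 96, image_width = 96, mean_cell_area = 300,
      stretch_factor = runif(1, 1, 2.5), seed = 1000 + s
    ))
    for (k in 1:5) {
      win <- data.frame(
        row = sample(0:(96 - 48), 1), col = sample(0:(96 - 48), 1), size = 48
      )
      ours <- window_shape(tis$labels, win)
      ref <- naive_window_shape(tis$labels, win)
      expect_equal(ours$L, ref$L, tolerance = 1e-9)
      expect_equal(ours$l, ref$l, tolerance = 1e-9)
      expect_lt(abs(fold_pi(ours$alpha - ref$alpha)), 1e-9)
      expect_equal(ours$n_cells, ref$n_cells)
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 50)
})

test_that("area weighting matches the naive oracle too and differs from cell weighting", {
  tis <- generate_tissue(tissue_spec(seed = 31, stretch_factor = 1.8,
                                     orientation_mode = "random"))
  win <- data.frame(row = 10, col = 10, size = 64)
  ours <- window_shape(tis$labels, win, weighting = "area")
  ref <- naive_window_shape(tis$labels, win, weighting = "area")
  expect_equal(ours$L, ref$L, tolerance = 1e-9)
  expect_lt(abs(fold_pi(ours$alpha - ref$alpha)), 1e-9)
  percell <- window_shape(tis$labels, win, weighting = "cell")
  expect_false(isTRUE(all.equal(ours$L, percell$L)))
})

test_that("upsampling labels 2x doubles both axes within 2 percent", {
  tis <- generate_tissue(tissue_spec(seed = 12, stretch_factor = 1.5,
                                     orientation_mode = "constant",
                                     alpha0 = 1))
  st <- window_shape(tis$labels)
  up <- tis$labels[rep(seq_len(128), each = 2), rep(seq_len(128), each = 2)]
  st2 <- window_shape(up)
  expect_lt(abs(st2$L / st$L - 2), 0.02 * 2)
  expect_lt(abs(st2$l / st$l - 2), 0.02 * 2)
})

test_that("tiling lays half-open windows with clamped trailing origins", {
  w1 <- tile_image(c(128, 128), 128, 0.25)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$row, w1$col), c(0, 0))

  w2 <- tile_image(c(256, 256), 128, 0)
  expect_equal(nrow(w2), 4)
  expect_setequal(unique(w2$row), c(0, 128))
  expect_setequal(unique(w2$col), c(0, 128))

  # stride 96; last window clamped to 352 - 128 = 224
  w3 <- tile_image(c(352, 352), 128, 0.25)
  expect_equal(nrow(w3), 16)
  expect_equal(unique(w3$row), c(0, 96, 192, 224))
  expect_equal(unique(w3$col), c(0, 96, 192, 224))
  # row-major order
  expect_equal(w3$row, rep(c(0, 96, 192, 224), each = 4))

  # full coverage: every pixel of an odd-sized image is inside some window
  w4 <- tile_image(c(200, 167), 64, 0.3)
  covered_rows <- sort(unique(unlist(
    Map(function(r) r + 1:64, w4$row)
  )))
  expect_equal(covered_rows, 1:200)
  expect_error(tile_image(c(100, 100), 128), "exceeds")
})

test_that("anisotropy is L/l - 1", {
  expect_equal(anisotropy(10, 10), 0)
  expect_equal(anisotropy(20, 10), 1)
  expect_equal(anisotropy(3, 2), 0.5)
  expect_error(anisotropy(3, 0), "undefined")
  st <- window_shape(rasterize_ellipse(20, 10, size = 64))
  expect_equal(anisotropy(st), st$L / st$l - 1)
})

test_that("per-window target tables carry the documented columns", {
  tis <- generate_tissue(tissue_spec(
    image_height = 192, image_width = 160, seed = 4
  ))
  tab <- window_targets(tis$labels, tile = 128, overlap = 0.25)
  expect_equal(
    names(tab),
    c("tile_id", "row", "col", "L", "l", "alpha", "anisotropy", "n_cells")
  )
  expect_equal(tab$tile_id, seq_len(nrow(tab)) - 1L)
  expect_equal(tab$anisotropy, tab$L / tab$l - 1)
})

test_that("degenerate windows raise the documented errors", {
  lab <- matrix(0L, 64, 64)
  expect_error(window_shape(lab), "no cell pixels")
  lab[1, 1] <- 1L
  expect_error(
    window_shape(lab, data.frame(row = 60, col = 60, size = 128)),
    "does not fit"
  )
})
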