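# Independent brute-force oracles and shared fixtures.

# naive double-loop implementation of the window-averaged shape, kept
# deliberately independent of the package internals (base eigen(), explicit
# per-pixel sums)
naive_window_shape <- function(labels, window = NULL, weighting = "cell",
                               min_inside = 0.5) {
  if (!is.null(window)) {
    sub <- labels[
      window$row + seq_len(window$size),
      window$col + seq_len(window$size),
      drop = FALSE
    ]
    totals <- table(labels[labels > 0])
  } else {
    sub <- labels
    totals <- NULL
  }
  ids <- sort(unique(sub[sub > 0]))
  mats <- list()
  wts <- numeric(0)
  for (id in ids) {
    xs <- c()
    ys <- c()
    for (r in seq_len(nrow(sub))) {
      for (cc in seq_len(ncol(sub))) {
        if (sub[r, cc] == id) {
          xs <- c(xs, cc - 1)
          ys <- c(ys, r - 1)
        }
      }
    }
    if (!is.null(totals)) {
      frac <- length(xs) / as.numeric(totals[as.character(id)])
      if (frac < min_inside) next
    }
    mx <- mean(xs)
    my <- mean(ys)
    M <- matrix(0, 2, 2)
    for (i in seq_along(xs)) {
      d <- c(xs[i] - mx, ys[i] - my)
      M <- M + d %o% d
    }
    M <- M / length(xs)
    mats[[length(mats) + 1]] <- M
    wts <- c(wts, if (weighting == "cell") 1 else length(xs))
  }
  wts <- wts / sum(wts)
  Mbar <- Reduce(`+`, Map(`*`, mats, wts))
  e <- eigen(Mbar, symmetric = TRUE)
  v <- e$vectors[, 1]
  list(
    L = 4 * sqrt(e$values[1]), l = 4 * sqrt(max(e$values[2], 0)),
    alpha = atan2(v[2], v[1]) %% pi, n_cells = length(mats)
  )
}

# solid rasterized ellipse with semi-axes (a, b) at angle theta, as a label
# image with a single cell of ID 1 on background 0
rasterize_ellipse <- function(a, b, theta = 0, size = ceiling(2.6 * a)) {
  ctr <- (size - 1) / 2
  lab <- matrix(0L, size, size)
  for (r in seq_len(size)) {
    for (cc in seq_len(size)) {
      dx <- (cc - 1) - ctr
      dy <- (r - 1) - ctr
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      if ((u / a)^2 + (v / b)^2 <= 1) lab[r, cc] <- 1L
    }
  }
  lab
}

# fold an angular difference into [-pi/2, pi/2); independent of the package
fold_pi <- function(d) ((d + pi / 2) %% pi) - pi / 2

# memoized fixtures shared across test files (tests run in one session)
.fixtures <- new.env(parent = emptyenv())

# small 32x32-tile dataset for fast training tests
small_dataset <- function(n, seed, stretch_range = c(1, 2.5)) {
  key <- sprintf("small_%d_%d_%s", n, seed, paste(stretch_range, collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_dataset(
      tissue_spec(seed = seed, mean_cell_area = 40),
      n,
      tile_size = 32, stretch_range = stretch_range
    )
  }
  .fixtures[[key]]
}

# The headline parameter-recovery fixture: the optimized 3-conv architecture
# trained on 2,000 synthetic 128x128 tiles and evaluated on 400 held-out
# tiles. Trained once and reused by several tests.
headline_fixture <- function() {
  if (is.null(.fixtures$headline)) {
    train_ds <- make_dataset(tissue_spec(seed = 20260920), 2000,
      tile_size = 128
    )
    test_ds <- make_dataset(tissue_spec(seed = 77003), 400, tile_size = 128)
    arch <- arch_spec(list(c(8, 5), c(64, 9), c(128, 3)))
    cfg <- train_config(max_epochs = 15L, patience = 14L, seed = 20260920)
    fit <- final_retrain(arch, train_ds, cfg)
    .fixtures$headline <- list(
      model = fit$model, scaler = fit$scaler,
      train_ds = train_ds, test_ds = test_ds
    )
  }
  .fixtures$headline
}
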