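#' Enumerate an architecture search space
#'
#' Full Cartesian product of per-layer filter-count and kernel-size choices,
#' in a fixed deterministic order. The reference spaces are: 1 layer with
#' filters {2,...,64} x sizes {3,...,11} (30 models), 2 layers over the same
#' per-layer choices (900 models), and 3 layers with filters {8,...,128}
#' (15,625 models, explored with Hyperband rather than exhaustively).
#'
#' @param n_layers Number of convolutional blocks.
#' @param filter_choices Filter counts allowed per layer.
#' @param size_choices Kernel sizes allowed per layer.
#' @param n_outputs,input_size Passed through to [arch_spec()].
#' @return List of `arch_spec`s of length
#'   `(length(filter_choices) * length(size_choices))^n_layers`.
#' @export
enumerate_space <- function(n_layers,
                            filter_choices = c(2, 4, 8, 16, 32, 64),
                            size_choices = c(3, 5, 7, 9, 11),
                            n_outputs = 4L, input_size = 128L) {
  stopifnot(n_layers >= 1)
  cols <- list()
  for (i in seq_len(n_layers)) {
    cols[[paste0("n", i)]] <- as.integer(filter_choices)
    cols[[paste0("k", i)]] <- as.integer(size_choices)
  }
  grid <- do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(r) {
    blocks <- matrix(as.integer(grid[r, ]), ncol = 2, byrow = TRUE)
    arch_spec(blocks, n_outputs = n_outputs, input_size = input_size)
  })
}

# flatten a space into the persistable table skeleton
space_table <- function(space) {
  n_layers <- nrow(space[[1]]$blocks)
  tab <- do.call(rbind, lapply(space, function(a) {
    v <- as.vector(t(a$blocks))
    names(v) <- as.vector(rbind(
      paste0("n", seq_len(n_layers)), paste0("k", seq_len(n_layers))
    ))
    as.data.frame(as.list(v))
  }))
  tab$key <- vapply(space, arch_key, character(1))
  tab$trainable <- vapply(space, function(a) count_params(a)$trainable,
    numeric(1)
  )
  tab
}

#' Exhaustive cross-validated grid search
#'
#' Runs [cross_validate()] on every architecture of the space and tabulates
#' the scores. Results can be persisted to CSV; an interrupted search resumes
#' from the persisted table, recomputing only the missing rows.
#'
#' @param space List of `arch_spec`s, e.g. from [enumerate_space()].
#' @param ds Training `tile_dataset`.
#' @param config A [train_config()].
#' @param folds CV folds (default 5).
#' @param persist Optional CSV path for checkpointing/resuming.
#' @return An object of class `search_result`: `table` (one row per
#'   architecture, sorted ascending by `mae_mean`, ties broken by fewer
#'   trainable parameters then by key), and `best` (the winning `arch_spec`).
#' @export
grid_search <- function(space, ds, config = train_config(), folds = 5L,
                        persist = NULL) {
  stopifnot(length(space) >= 1)
  tab <- space_table(space)
  tab$mae_mean <- NA_real_
  tab$mae_L <- NA_real_
  tab$mae_l <- NA_real_
  tab$mae_orient <- NA_real_
  tab$status <- "pending"
  if (!is.null(persist) && file.exists(persist)) {
    old <- utils::read.csv(persist, stringsAsFactors = FALSE)
    hit <- match(tab$key, old$key)
    ok <- !is.na(hit) & old$status[hit] == "done"
    for (col in c("mae_mean", "mae_L", "mae_l", "mae_orient", "status")) {
      tab[[col]][ok] <- old[[col]][hit[ok]]
    }
  }
  for (i in seq_len(nrow(tab))) {
    if (tab$status[i] == "done") next
    sc <- cross_validate(space[[i]], ds, config, folds)
    tab$mae_mean[i] <- sc$mean_encoded_mae
    tab$mae_L[i] <- sc$means[["mae_L"]]
    tab$mae_l[i] <- sc$means[["mae_l"]]
    tab$mae_orient[i] <- sc$means[["mae_alpha"]]
    tab$status[i] <- "done"
    if (!is.null(persist)) {
      utils::write.csv(tab, persist, row.names = FALSE)
    }
  }
  ord <- order(tab$mae_mean, tab$trainable, tab$key)
  structure(
    list(table = tab[ord, ], best = space[[ord[1]]], space = space),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("architecture search over", nrow(x$table), "models; best:\n  ")
  print(x$best)
  invisible(x)
}

#' Pooled pivot table of a 2-layer grid search
#'
#' Mean MAE over all models sharing the same per-layer kernel sizes
#' (`what = "sizes"`) or the same per-layer filter counts
#' (`what = "filters"`).
#'
#' @param result A `search_result` over a 2-layer space.
#' @param what `"filters"` or `"sizes"`.
#' @return A matrix of pooled mean MAEs (rows: layer 1, columns: layer 2).
#' @export
pooled_pivot <- function(result, what = c("filters", "sizes")) {
  what <- match.arg(what)
  tab <- result$table
  v <- if (what == "filters") c("n1", "n2") else c("k1", "k2")
  stopifnot(all(v %in% names(tab)))
  agg <- stats::aggregate(tab$mae_mean, by = tab[v], FUN = mean)
  r <- sort(unique(agg[[1]]))
  c_ <- sort(unique(agg[[2]]))
  m <- matrix(NA_real_, length(r), length(c_), dimnames = list(r, c_))
  m[cbind(match(agg[[1]], r), match(agg[[2]], c_))] <- agg$x
  m
}

#' Successive halving over a fixed candidate set
#'
#' Allocates a per-candidate budget `r`, evaluates all candidates, keeps the
#' best `1/eta` fraction (floor, at least one), multiplies the budget by
#' `eta`, and repeats until one rung remains. Evaluations are delegated to
#' `evaluator(arch, budget)`, which must return a loss (lower is better), so
#' the schedule can be tested against hand-simulated traces with injected
#' losses.
#'
#' @param candidates List of `arch_spec`s.
#' @param evaluator `function(arch, budget) -> loss`.
#' @param r Initial per-candidate budget (epochs).
#' @param eta Reduction factor (2 = keep the best half).
#' @param max_budget Budget cap per candidate.
#' @return A list with `trace` (data frame: rung, key, budget, loss, kept)
#'   and `best` (list with `arch`, `loss`, `budget`).
#' @export
successive_halving <- function(candidates, evaluator, r, eta = 2,
                               max_budget = Inf) {
  stopifnot(length(candidates) >= 1, r >= 1)
  keys <- vapply(candidates, arch_key, character(1))
  alive <- seq_along(candidates)
  rung <- 0L
  budget <- min(r, max_budget)
  trace <- list()
  repeat {
    losses <- vapply(
      alive, function(i) evaluator(candidates[[i]], budget), numeric(1)
    )
    ord <- order(losses, keys[alive]) # deterministic tie-break on key
    n_keep <- if (length(alive) == 1) 0L else max(1L, length(alive) %/% eta)
    kept <- rep(FALSE, length(alive))
    if (n_keep > 0 && budget < max_budget) kept[ord[seq_len(n_keep)]] <- TRUE
    trace[[length(trace) + 1]] <- data.frame(
      rung = rung, key = keys[alive], budget = budget, loss = losses,
      kept = kept
    )
    if (!any(kept)) {
      best_i <- alive[ord[1]]
      return(list(
        trace = do.call(rbind, trace),
        best = list(
          arch = candidates[[best_i]],
          loss = losses[ord[1]], budget = budget
        )
      ))
    }
    alive <- alive[kept]
    rung <- rung + 1L
    budget <- min(budget * eta, max_budget)
  }
}

#' Hyperband architecture search with cross-validated losses
#'
#' Hyperband grid-searches over the successive-halving trade-off between the
#' number of sampled configurations `n` and the per-configuration budget:
#' brackets run from many-configurations/small-budget to
#' few-configurations/full-budget. Here each evaluation is a cross-validated
#' training: the loss of a candidate at a rung is the validation MSE averaged
#' over `folds` models trained to that rung's epoch budget. The incumbent
#' best model is tracked continuously, so the search can be stopped early.
#'
#' Evaluations are cached by (architecture, budget) within a run; a bracket
#' whose candidate set has a single member is evaluated directly at the full
#' budget.
#'
#' @param space List of candidate `arch_spec`s.
#' @param ds Training `tile_dataset` (ignored when `evaluator` is given).
#' @param config A [train_config()]; its `max_epochs` is overridden per rung.
#' @param max_epochs Full per-candidate budget R (default 40).
#' @param eta Halving factor (default 2, i.e. keep the best half).
#' @param folds CV folds per evaluation.
#' @param iterations Number of Hyperband iterations (default 1).
#' @param seed Seed for candidate sampling.
#' @param evaluator Optional `function(arch, budget) -> loss` replacing the
#'   cross-validated training (used by tests and by resumed searches).
#' @return An object of class `hyperband_result`: `best` (arch, loss,
#'   budget), `brackets` (list of successive-halving traces),
#'   `evaluations` (data frame of all (key, budget, loss) evaluated) and
#'   `total_budget` (sum of epoch budgets handed to the evaluator).
#' @export
hyperband <- function(space, ds = NULL, config = train_config(),
                      max_epochs = 40L, eta = 2, folds = 5L,
                      iterations = 1L, seed = config$seed,
                      evaluator = NULL) {
  if (length(space) == 0) stop("empty search space")
  if (is.null(evaluator)) {
    stopifnot(inherits(ds, "tile_dataset"))
    evaluator <- function(arch, budget) {
      cfg <- config
      cfg$max_epochs <- as.integer(max(1, budget))
      cfg$patience <- min(cfg$patience, cfg$max_epochs - 1L)
      cross_validate(arch, ds, cfg, folds)$mean_mse
    }
  }
  cache <- new.env(parent = emptyenv())
  evals <- list()
  total_budget <- 0
  cached_eval <- function(arch, budget) {
    key <- paste0(arch_key(arch), "@", budget)
    if (!is.null(cache[[key]])) return(cache[[key]])
    loss <- evaluator(arch, budget)
    cache[[key]] <- loss
    total_budget <<- total_budget + budget
    evals[[length(evals) + 1]] <<- data.frame(
      key = arch_key(arch), budget = budget, loss = loss
    )
    loss
  }

  s_max <- floor(log(max_epochs) / log(eta))
  best <- NULL
  brackets <- list()
  set.seed(seed)
  for (it in seq_len(iterations)) {
    for (s in s_max:0) {
      n <- ceiling((s_max + 1) / (s + 1) * eta^s)
      r <- max(1, ceiling(max_epochs * eta^(-s)))
      idx <- if (n >= length(space)) {
        sample(seq_along(space)) # all of them, permuted
      } else {
        sample(seq_along(space), n)
      }
      cands <- space[idx]
      sh <- if (length(cands) == 1) {
        loss <- cached_eval(cands[[1]], max_epochs)
        list(
          trace = data.frame(
            rung = 0L, key = arch_key(cands[[1]]), budget = max_epochs,
            loss = loss, kept = FALSE
          ),
          best = list(arch = cands[[1]], loss = loss, budget = max_epochs)
        )
      } else {
        successive_halving(cands, cached_eval, r, eta, max_budget = max_epochs)
      }
      brackets[[length(brackets) + 1]] <- sh$trace
      cand <- sh$best
      if (is.null(best) || cand$budget > best$budget ||
        (cand$budget == best$budget && cand$loss < best$loss)) {
        best <- cand
      }
    }
  }
  structure(
    list(
      best = best, brackets = brackets,
      evaluations = do.call(rbind, evals), total_budget = total_budget,
      max_epochs = max_epochs, eta = eta
    ),
    class = "hyperband_result"
  )
}

#' @export
print.hyperband_result <- function(x, ...) {
  cat(sprintf(
    "Hyperband over %d evaluations (total budget %g epochs); best @%g:\n  ",
    nrow(x$evaluations), x$total_budget, x$best$budget
  ))
  print(x$best$arch)
  invisible(x)
}

#' Decision-tree meta-analysis of architecture vs performance
#'
#' Fits a depth-capped regression tree predicting a model's cross-validated
#' MAE from its architecture integers (n1, k1, n2, k2, ...), reports the
#' normalized feature importances and the Pearson correlation of each
#' parameter with the MAE (negative r: increasing the parameter reduces the
#' MAE). The table is split 70/30 into train/held-out by default.
#'
#' @param table Data frame with architecture columns (`n1`, `k1`, ...) and a
#'   `mae_mean` (or `mae`) column; typically `search_result$table`.
#' @param split Training fraction.
#' @param seed Seed for the split.
#' @param max_depth Tree depth cap (default 16; splits minimize squared
#'   error, no pruning, surrogates disabled so importances reflect primary
#'   splits only).
#' @return An object of class `meta_model`: the `rpart` fit, `importance`
#'   (named, sums to 1), `pearson` (named), `train_idx` and `test_pred`
#'   (data frame of held-out truth and prediction).
#' @export
fit_meta_tree <- function(table, split = 0.7, seed = 1L, max_depth = 16L) {
  target <- if ("mae_mean" %in% names(table)) "mae_mean" else "mae"
  stopifnot(target %in% names(table))
  feats <- grep("^[nk][0-9]+$", names(table), value = TRUE)
  stopifnot(length(feats) >= 1)
  y <- table[[target]]
  if (stats::sd(y) == 0) {
    stop("constant MAE target: feature importance is undefined")
  }
  set.seed(seed)
  n <- nrow(table)
  tr <- sort(sample(n, round(split * n)))
  te <- setdiff(seq_len(n), tr)
  dat <- table[, c(feats, target)]
  names(dat)[ncol(dat)] <- "mae"
  fit <- rpart::rpart(
    mae ~ ., data = dat[tr, ],
    method = "anova",
    control = rpart::rpart.control(
      maxdepth = max_depth, cp = 0, minsplit = 2, minbucket = 1,
      xval = 0, maxsurrogate = 0, usesurrogate = 0, maxcompete = 0
    )
  )
  imp <- rep(0, length(feats))
  names(imp) <- feats
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  imp <- imp / sum(imp)
  pearson <- vapply(feats, function(f) stats::cor(table[[f]], y), numeric(1))
  pred <- if (length(te)) stats::predict(fit, dat[te, ]) else numeric(0)
  structure(
    list(
      model = fit, importance = imp, pearson = pearson,
      train_idx = tr,
      test_pred = data.frame(truth = y[te], pred = pred),
      train_pred = data.frame(truth = y[tr], pred = stats::predict(
        fit, dat[tr, ]
      ))
    ),
    class = "meta_model"
  )
}

#' @export
print.meta_model <- function(x, ...) {
  cat("architecture meta-tree; feature importance:\n")
  print(round(x$importance, 3))
  cat("Pearson r vs MAE:\n")
  print(round(x$pearson, 3))
  invisible(x)
}
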