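test_that("the conv/pool stack flattens a 5-s window to 768 nodes", {
  for (ch in c(22, 20)) {
    tr <- conv_stack_output_shape(ch, 640)
    expect_equal(unname(tr["flatten_dim"]), 768L)
    expect_equal(unname(tr["channel_extent"]), 3L)
    expect_equal(unname(tr["time_extent"]), 1L)
  }
})

test_that("insufficient extents raise a shape error naming the block", {
  # 8 channels survive the 5x5 block (8 rows) but not the final 3x3 block
  expect_error(conv_stack_output_shape(8, 640), "block 6")
  expect_error(conv_stack_output_shape(22, 64), "block")
})

test_that("shape trace matches instantiated models over random valid shapes", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      ch <- sample(12:30, 1); sa <- sample(c(320, 640, 960), 1)
      tr <- tryCatch(conv_stack_output_shape(ch, sa), error = function(e) NULL)
      if (is.null(tr)) next
      m <- build_model(ch, sa, seed = rep)
      expect_equal(ncol(m$params$dense[[1]]$W), unname(tr["flatten_dim"]))
    }
  })
})

test_that("parameter count matches the hand-computed value at 22 channels", {
  # conv (no bias, batchnorm scale+shift): 80 + 1600 + 10368 + 43200 +
  # 307456 + 295424; dense: 768*128+128 + 128*32+32 + 32+1 = 102593
  m <- build_model(22, 640, seed = 1)
  expect_equal(count_parameters(m), 760721L)
  # conv parameters are channel-count invariant; dense follow the flatten
  m20 <- build_model(20, 640, seed = 1)
  expect_equal(count_parameters(m20), 760721L)
})

test_that("initialization is seeded and forward outputs are probabilities", {
  a <- build_model(12, 640, seed = 9)
  b <- build_model(12, 640, seed = 9)
  expect_identical(a$params, b$params)
  c <- build_model(12, 640, seed = 10)
  expect_false(identical(a$params$conv[[1]]$W, c$params$conv[[1]]$W))
  ws <- window_set(withr::with_seed(1, array(rnorm(5 * 12 * 640),
                                             c(5, 12, 640))),
                   c(1L, 0L, 1L, 0L, 1L), rep("p", 5), rep(1L, 5), 128, 5)
  p <- predict_proba(a, ws)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict_proba(a, ws))      # deterministic inference
  expect_identical(p[1:3], predict_proba(a, subset_windows(ws, 1:3)))
})

test_that("analytic gradients match central finite differences", {
  spec <- cnn_spec(list(
    list(maps = 3L, kh = 1L, kw = 3L, ph = 1L, pw = 2L, dropout = 0),
    list(maps = 4L, kh = 2L, kw = 3L, ph = 2L, pw = 2L, dropout = 0)),
    dense_units = c(5L))
  withr::with_seed(42, {
    n <- 6; ch <- 4; sa <- 20
    X <- array(rnorm(n * ch * sa), c(ch, sa, n))
    y <- rep(c(0, 1), 3)
    m <- build_model(ch, sa, spec, seed = 7)
    g <- seizcal:::.cnn_loss_grad(m$params, X, y)
    fd <- function(mutate) {
      eps <- 1e-3
      (seizcal:::.cnn_loss_grad(mutate(m$params, eps), X, y)$loss -
         seizcal:::.cnn_loss_grad(mutate(m$params, -eps), X, y)$loss) /
        (2 * eps)
    }
    for (b in 1:2) for (k in 1:3) {
      i <- sample(length(m$params$conv[[b]]$W), 1)
      an <- g$conv[[b]]$W[i]
      nu <- fd(function(p, e) { p$conv[[b]]$W[i] <- p$conv[[b]]$W[i] + e; p })
      expect_equal(an, nu, tolerance = 0.02)
    }
    for (d in seq_along(m$params$dense)) {
      i <- sample(length(m$params$dense[[d]]$W), 1)
      an <- g$dense[[d]]$W[i]
      nu <- fd(function(p, e) { p$dense[[d]]$W[i] <- p$dense[[d]]$W[i] + e; p })
      expect_equal(an, nu, tolerance = 0.02)
    }
  })
})

test_that("training learns a separable task and rejects degenerate input", {
  withr::with_seed(33, {
    n <- 80; ch <- 12
    X <- array(rnorm(n * ch * 640), c(n, ch, 640))
    y <- rep(c(0L, 1L), each = n / 2)
    X[y == 1, , ] <- X[y == 1, , ] + 0.5
    ws <- window_set(X, y, rep("p", n), rep(1L, n), 128, 5)
    cfg <- train_config(learning_rate = 1e-3, batch_size = 32,
                        max_epochs = 3, early_stop_patience = 0, seed = 2)
    m <- train_model(build_model(ch, 640, seed = 2), ws, cfg)
    expect_true(m$trained)
    expect_equal(nrow(m$history), 3)
    expect_lt(m$history$train_loss[3], m$history$train_loss[1])
    expect_gt(mean((predict_proba(m, ws) > 0.5) == y), 0.9)
    ws1 <- subset_windows(ws, y == 1)
    expect_error(train_model(build_model(ch, 640, seed = 2), ws1,
                             cfg), "single class")
  })
})

test_that("label-shuffled training stays at chance on held-out windows", {
  withr::with_seed(34, {
    n <- 120; ch <- 12
    X <- array(rnorm(n * ch * 640), c(n, ch, 640))
    y <- sample(rep(c(0L, 1L), each = n / 2))
    tr <- window_set(X[1:80, , ], y[1:80], rep("p", 80), rep(1L, 80), 128, 5)
    te <- window_set(X[81:n, , ], y[81:n], rep("p", 40), rep(1L, 40), 128, 5)
    cfg <- train_config(learning_rate = 1e-3, batch_size = 32,
                        max_epochs = 2, early_stop_patience = 0, seed = 3)
    m <- train_model(build_model(ch, 640, seed = 3), tr, cfg)
    acc <- mean((predict_proba(m, te) > 0.5) == te$labels)
    expect_gt(acc, 0.25); expect_lt(acc, 0.75)
  })
})

test_that("early stopping halts after patience epochs without improvement", {
  withr::with_seed(35, {
    n <- 60; ch <- 4
    spec <- cnn_spec(list(
      list(maps = 4L, kh = 1L, kw = 3L, ph = 1L, pw = 2L, dropout = 0.2)),
      dense_units = c(8L))
    X <- array(rnorm(n * ch * 64), c(n, ch, 64))
    y <- sample(c(0L, 1L), n, replace = TRUE)       # unlearnable noise
    ws <- window_set(X, y, rep("p", n), rep(1L, n), 128, 0.5)
    cfg <- train_config(learning_rate = 5e-2, batch_size = 16,
                        max_epochs = 50, early_stop_patience = 2,
                        validation_fraction = 0.2, seed = 4)
    m <- train_model(build_model(ch, 64, spec, seed = 4), ws, cfg)
    expect_lt(nrow(m$history), 50)
  })
})

test_that("fine-tuning starts from the checkpoint and never mutates it", {
  withr::with_seed(36, {
    n <- 40; ch <- 12
    X <- array(rnorm(n * ch * 640), c(n, ch, 640))
    y <- rep(c(0L, 1L), n / 2)
    ws <- window_set(X, y, rep("p", n), rep(1L, n), 128, 5)
    cfg <- train_config(learning_rate = 1e-3, batch_size = 20,
                        max_epochs = 1, early_stop_patience = 0,
                        fine_tune_max_epochs = 2, seed = 5)
    m <- train_model(build_model(ch, 640, seed = 5), ws, cfg)
    snapshot <- m$params
    cfg0 <- cfg; cfg0$fine_tune_max_epochs <- 0L
    same <- fine_tune(m, ws, cfg0)
    expect_identical(predict_proba(same, ws), predict_proba(m, ws))
    tuned <- fine_tune(m, ws, cfg)
    expect_identical(m$params, snapshot)           # checkpoint untouched
    expect_false(identical(tuned$params$dense[[1]]$W,
                           m$params$dense[[1]]$W))
    expect_error(fine_tune(build_model(ch, 640, seed = 1), ws, cfg),
                 "trained")
    empty <- subset_windows(ws, integer(0))
    expect_error(fine_tune(m, empty, cfg), "empty calibration")
  })
})

test_that("checkpoints survive a JSON round-trip", {
  withr::with_seed(37, {
    m <- build_model(12, 640, seed = 6)
    m$trained <- TRUE
    path <- withr::local_tempfile(fileext = ".json")
    save_checkpoint(m, path)
    back <- load_checkpoint(path)
    ws <- window_set(array(rnorm(3 * 12 * 640), c(3, 12, 640)),
                     c(0L, 1L, 0L), rep("p", 3), rep(1L, 3), 128, 5)
    expect_equal(predict_proba(back, ws), predict_proba(m, ws),
                 tolerance = 1e-6)
  })
})
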