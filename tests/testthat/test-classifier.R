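test_that("datasets carry 2 positives per run and concatenate channels", {
  sy <- synthetic_averaged(n_runs = 60)
  ds <- build_dataset(sy$avg, sy$session, "P8")
  expect_equal(nrow(ds$x), 720)
  expect_equal(sum(ds$y == 1), 120)
  expect_equal(ncol(ds$x), 250)
  expect_true(all(tapply(ds$y, ds$info$run_index, sum) == 2))

  sy4 <- synthetic_averaged(n_runs = 2,
                            channels = c("Cz", "CP1", "CP2", "P7", "P3",
                                         "Pz", "P4", "P8", "O1", "Oz", "O2"))
  ds4 <- build_dataset(sy4$avg, sy4$session, "Group4")
  expect_equal(ncol(ds4$x), 2750)
  expect_error(build_dataset(sy$avg, sy$session, "F2"),
               class = "channel_error")
})

test_that("forward pass matches a hand computation of the network formula", {
  # 2 inputs, 1 hidden unit, worked by hand:
  # a = w2 * tanh(w11 x1 + w12 x2 + b1) + b2; score = 1/(1+exp(-a))
  model <- structure(list(d = 2L, M = 1L,
                          W1 = matrix(c(0.3, -0.2), 1, 2), b1 = 0.1,
                          w2 = 0.8, b2 = -0.05),
                     class = "ann_model")
  x <- c(1.5, -2.0)
  a <- 0.8 * tanh(0.3 * 1.5 + (-0.2) * (-2.0) + 0.1) - 0.05
  expect_equal(ann_forward(model, x), 1 / (1 + exp(-a)), tolerance = 1e-12)

  zero <- ann_init(4, 3, seed = 1)
  zero$W1[] <- 0; zero$b1[] <- 0; zero$w2[] <- 0; zero$b2 <- 0
  expect_equal(ann_forward(zero, matrix(rnorm(8), 2)), c(0.5, 0.5))

  set.seed(2)
  m <- ann_init(6, 4, seed = 3)
  s <- ann_forward(m, matrix(rnorm(60) * 100, 10))
  expect_true(all(s > 0 & s < 1))
  expect_error(ann_forward(m, matrix(1, 1, 5)), class = "shape_error")
})

test_that("cross-entropy matches the closed form and direct formula", {
  expect_equal(cross_entropy(rep(0.5, 8), rep(c(0, 1), 4)), log(2))
  y <- c(1, 0, 1, 1, 0)
  p <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  expect_lt(cross_entropy(p, y), 1e-10)
  set.seed(4)
  m <- ann_init(5, 3, seed = 5)
  x <- matrix(rnorm(40), 8)
  yy <- rbinom(8, 1, 0.5)
  ph <- ann_forward(m, x)
  direct <- -mean(yy * log(ph) + (1 - yy) * log(1 - ph))
  expect_equal(ann_loss(m, x, yy), direct, tolerance = 1e-12)
  expect_error(cross_entropy(numeric(0), numeric(0)), class = "empty_data")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(6)
  model <- ann_init(7, 4, seed = 7)
  x <- matrix(rnorm(15 * 7), 15)
  y <- rbinom(15, 1, 0.4)
  g <- speller3d:::ann_gradients(model, x, y)
  eps <- 1e-6
  check <- function(field, idx) {
    m1 <- model; m2 <- model
    m1[[field]][idx] <- m1[[field]][idx] + eps
    m2[[field]][idx] <- m2[[field]][idx] - eps
    num <- (ann_loss(m1, x, y) - ann_loss(m2, x, y)) / (2 * eps)
    expect_equal(g[[field]][idx], num, tolerance = 1e-6)
  }
  for (idx in c(1, 9, 20)) check("W1", idx)
  for (idx in 1:4) { check("b1", idx); check("w2", idx) }
  check("b2", 1)
})

test_that("training separates separable data and fails gracefully", {
  set.seed(8)
  n <- 400; d <- 10
  x <- rbind(matrix(rnorm(n / 2 * d, 2), n / 2),
             matrix(rnorm(n / 2 * d, -2), n / 2))
  y <- rep(c(1, 0), each = n / 2)
  idx <- sample(n)
  x <- x[idx, ]; y <- y[idx]
  cfg <- train_config(max_epochs = 200, seed = 9)
  model <- train_ann(x[1:280, ], y[1:280], x[281:340, ], y[281:340], cfg,
                     seed = 9)
  acc <- mean(as.numeric(ann_forward(model, x[341:400, ]) > 0.5) ==
                y[341:400])
  expect_gte(acc, 0.99)
  # descent property
  h <- attr(model, "history")
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])

  # permuted labels give chance-level accuracy
  yp <- sample(y)
  mp <- train_ann(x[1:280, ], yp[1:280], x[281:340, ], yp[281:340], cfg,
                  seed = 10)
  accp <- mean(as.numeric(ann_forward(mp, x[341:400, ]) > 0.5) ==
                 yp[341:400])
  expect_gt(accp, 0.3)
  expect_lt(accp, 0.7)

  expect_error(train_ann(x[1:10, ], rep(1, 10), config = cfg),
               class = "degenerate_data")
})

test_that("stratified splits preserve class balance and training is seeded", {
  y <- rep(c(1, 0), c(120, 600))
  set.seed(11)
  parts <- speller3d:::stratified_split(y, c(0.7, 0.15, 0.15))
  expect_length(unique(unlist(parts)), 720)
  frac <- vapply(parts, function(p) mean(y[p] == 1), 0)
  expect_true(all(abs(frac - 120 / 720) < 1.5 / min(lengths(parts))))

  set.seed(12)
  x <- matrix(rnorm(60 * 5), 60)
  yy <- rep(0:1, 30)
  cfg <- train_config(max_epochs = 50, seed = 13)
  m1 <- train_ann(x, yy, config = cfg, seed = 13)
  m2 <- train_ann(x, yy, config = cfg, seed = 13)
  expect_identical(m1$W1, m2$W1)
  # prediction invariant to sample order
  ord <- sample(60)
  expect_equal(ann_forward(m1, x[ord, ]), ann_forward(m1, x)[ord])
})

test_that("repeated-split detection is perfect on noise-free features", {
  sy <- synthetic_averaged(n_runs = 12)
  ds <- build_dataset(sy$avg, sy$session, "P8")
  res <- evaluate_detection(ds, train_config(n_repeats = 3,
                                             max_epochs = 150, seed = 14))
  expect_equal(res$per_repeat$accuracy, rep(100, 3))
  expect_true(all(res$per_repeat$accuracy >= 0 &
                    res$per_repeat$accuracy <= 100))
  expect_equal(res$mean_accuracy, 100)
})

test_that("model JSON serialization round-trips", {
  m <- ann_init(6, 3, seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_json(m, path)
  back <- read_ann_json(path)
  expect_equal(back$W1, m$W1, tolerance = 1e-12)
  expect_equal(back$w2, m$w2, tolerance = 1e-12)
  x <- matrix(rnorm(12), 2)
  expect_equal(ann_forward(back, x), ann_forward(m, x), tolerance = 1e-10)
})
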