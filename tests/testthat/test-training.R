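test_that("cyclical learning rate hits its landmark values", {
  spec <- cyclical_lr_spec(1e-5, 1e-3, cycle_length = 100)
  expect_equal(cyclical_lr(0, spec), 1e-3)               # cos 0 = 1
  expect_equal(cyclical_lr(100, spec), 1e-5)             # cos pi = -1
  expect_equal(cyclical_lr(50, spec), (1e-5 + 1e-3) / 2) # cos pi/2 = 0
  expect_equal(cyclical_lr(50, spec), 5.05e-4)
  # restart just after the cycle boundary
  expect_gt(cyclical_lr(100.001, spec), 0.999e-3)
  expect_error(cyclical_lr(-1, spec), ">= 0")
  expect_error(cyclical_lr(1, cyclical_lr_spec(1e-5, 1e-3)), "cycle_length")
  expect_error(cyclical_lr_spec(0, 1e-3), "lr_min")
})

test_that("schedule matches an independent evaluation on random specs", {
  set.seed(1)
  for (k in 1:1000) {
    lr_min <- 10^runif(1, -6, -4)
    lr_max <- lr_min * 10^runif(1, 0, 3)
    tmax <- sample(1:500, 1)
    t <- runif(1, 0, 5 * tmax)
    spec <- cyclical_lr_spec(lr_min, lr_max, tmax)
    # independent re-implementation: cosine of the within-cycle position
    tc <- t %% tmax
    if (tc == 0 && t > 0) tc <- tmax
    want <- lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(tc / tmax * pi))
    got <- cyclical_lr(t, spec)
    expect_lt(abs(got - want) / want, 1e-12)
    # bounds and periodicity
    expect_gte(got, lr_min)
    expect_lte(got, lr_max)
    expect_equal(cyclical_lr(t + tmax, spec), got, tolerance = 1e-12)
  }
})

test_that("triangular mode oscillates linearly between the bounds", {
  spec <- cyclical_lr_spec(1e-4, 1e-3, cycle_length = 10)
  expect_equal(cyclical_lr(0, spec, mode = "triangular"), 1e-4)
  expect_equal(cyclical_lr(5, spec, mode = "triangular"), 1e-3)
  expect_equal(cyclical_lr(2.5, spec, mode = "triangular"),
               1e-4 + 0.5 * 9e-4)
})

test_that("progressive stages nest and split epochs evenly", {
  groups <- paste0("block", 1:4)
  one <- build_stages(groups, 1, 50)
  expect_length(one, 1)
  expect_setequal(one[[1]]$trainable, c(groups, "head"))
  four <- build_stages(groups, 4, 50)
  expect_equal(vapply(four, `[[`, numeric(1), "epochs"), c(12, 12, 12, 14))
  expect_setequal(four[[1]]$trainable, c("block4", "head"))
  # nestedness verified by a pairwise subset scan
  for (cfg in list(c(4, 2), c(4, 3), c(3, 3), c(5, 4))) {
    st <- build_stages(paste0("g", seq_len(cfg[1])), cfg[2], 20)
    for (s in seq_len(length(st) - 1)) {
      expect_true(all(st[[s]]$trainable %in% st[[s + 1]]$trainable))
    }
    expect_equal(sum(vapply(st, `[[`, numeric(1), "epochs")), 20)
  }
  expect_error(build_stages(character(0), 1, 10), "empty")
  expect_error(build_stages(groups, 5, 10), "n_stages")
})

test_that("a degenerate schedule records a constant learning rate", {
  cl <- fixture_clouds(n = 60, seed = 1)
  fit <- train_classifier(
    cl$x, cl$y,
    plan = train_plan(total_epochs = 2,
                      lr_spec = cyclical_lr_spec(1e-3, 1e-3)),
    seed = 0)
  expect_true(all(fit$history$lr == 1e-3))
})

test_that("frozen layer parameters are bit-identical across a stage", {
  cl <- fixture_clouds(n = 60, seed = 2)
  model <- mlp_model(ncol(cl$x), hidden = c(8, 8), seed = 1)
  plan <- train_plan(total_epochs = 2, n_stages = 2, dropout_rate = 0)
  # stage 1 trains block2 + head only; run it alone and compare block1
  stages <- build_stages(model$layer_groups, 2, 2)
  plan1 <- train_plan(total_epochs = 1, dropout_rate = 0,
                      stages = stages[1])
  fit1 <- train_classifier(cl$x, cl$y, plan = plan1, model = model,
                           seed = 3)
  expect_identical(fit1$model$params$block1, model$params$block1)
  expect_false(identical(fit1$model$params$block2, model$params$block2))
  expect_false(identical(fit1$model$params$head, model$params$head))
})

test_that("recorded learning rates equal the scheduler output exactly", {
  cl <- fixture_clouds(n = 100, seed = 3)
  spec <- cyclical_lr_spec(1e-4, 1e-2, cycle_length = 7)
  fit <- train_classifier(cl$x, cl$y,
                          plan = train_plan(total_epochs = 3,
                                            batch_size = 16,
                                            lr_spec = spec),
                          seed = 1)
  iters <- length(fit$history$lr)
  expect_equal(iters, 3 * ceiling(100 / 16))
  expect_identical(fit$history$lr,
                   vapply(seq_len(iters) - 1, cyclical_lr, numeric(1),
                          spec = spec))
})

test_that("training separates the two-cloud fixture like the glm oracle", {
  cl <- fixture_clouds(n = 400, d = 5, sep = 4, seed = 0)
  std <- fit_standardizer(cl$x)
  xs <- apply_standardizer(cl$x, std)
  fit <- train_classifier(
    xs, cl$y,
    plan = train_plan(total_epochs = 10,
                      lr_spec = cyclical_lr_spec(1e-4, 1e-2)),
    seed = 0)
  acc <- mean((predict_proba(fit$model, xs) >= 0.5) == cl$y)
  expect_gte(acc, 0.95)
  # logistic-regression oracle reaches the same bound on the same data
  glm_fit <- suppressWarnings(
    glm(y ~ ., data = data.frame(y = cl$y, xs), family = binomial))
  glm_acc <- mean((predict(glm_fit, type = "response") >= 0.5) == cl$y)
  expect_gte(glm_acc, 0.95)
})

test_that("training is seed-deterministic and validates labels", {
  cl <- fixture_clouds(n = 80, seed = 5)
  f1 <- train_classifier(cl$x, cl$y,
                         plan = train_plan(total_epochs = 3), seed = 9)
  f2 <- train_classifier(cl$x, cl$y,
                         plan = train_plan(total_epochs = 3), seed = 9)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$epochs, f2$history$epochs)
  expect_error(train_classifier(cl$x, cl$y * 3,
                                plan = train_plan(total_epochs = 1)),
               "binary")
})

test_that("history CSV export has one schedule-matching row per iteration", {
  cl <- fixture_clouds(n = 64, seed = 7)
  fit <- train_classifier(cl$x, cl$y,
                          plan = train_plan(total_epochs = 2), seed = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_train_history(fit$history, path)
  h <- read.csv(path)
  expect_equal(names(h), c("iteration", "epoch", "stage", "lr",
                           "train_loss", "val_loss", "train_acc",
                           "val_acc"))
  expect_equal(nrow(h), length(fit$history$lr))
  expect_equal(h$lr, fit$history$lr, tolerance = 1e-12)  # CSV float text
})

test_that("predictions are probabilities and duplicate rows agree", {
  cl <- fixture_clouds(n = 80, seed = 6)
  fit <- train_classifier(cl$x, cl$y,
                          plan = train_plan(total_epochs = 3), seed = 0)
  p <- predict_proba(fit$model, cl$x)
  expect_true(all(p >= 0 & p <= 1))
  dup <- predict_proba(fit$model, cl$x[c(1, 1, 2), ])
  expect_identical(dup[1], dup[2])
  unfitted <- mlp_model(5)
  expect_error(predict_proba(unfitted, cl$x), "not fitted")
})
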