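sphere_space <- function() {
  search_space(ss_continuous("x", -5, 5), ss_continuous("y", -5, 5))
}
sphere_fitness <- function(a) -(a$x^2 + a$y^2)

test_that("swarm initialization is seeded, bounded and scored", {
  space <- sphere_space()
  cfg <- swarm_config(swarm_size = 5, seed = 11)
  s1 <- withr::with_seed(11, init_swarm(space, cfg, sphere_fitness))
  s2 <- withr::with_seed(11, init_swarm(space, cfg, sphere_fitness))
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$positions >= 0 & s1$positions <= 1))
  expect_equal(s1$evaluations, 5)
  expect_true(all(is.finite(s1$fitness)))
  # decoded values respect the bounds
  for (i in 1:5) {
    a <- decode_position(s1$positions[i, ], space)
    expect_true(a$x >= -5 && a$x <= 5)
  }
})

test_that("log-scale decoding spans the orders of magnitude", {
  space <- search_space(ss_continuous("lr", 1e-5, 1e-3, scale = "log"))
  u <- withr::with_seed(1, runif(1000))
  vals <- vapply(u, function(v) decode_position(v, space)$lr, numeric(1))
  expect_lt(min(vals), 2e-5)       # within a factor 2 of the lower bound
  expect_gt(max(vals), 5e-4)       # within a factor 2 of the upper bound
  # roughly uniform in log: the median sits near the geometric mean
  expect_gt(median(vals), 3e-5)
  expect_lt(median(vals), 3e-4)
})

test_that("decode/encode round-trips and discrete snapping", {
  space <- default_search_space()
  a <- list(lr_min = 3e-5, lr_max = 2e-3, batch_size = 32L, n_layers = 2L,
            layer_width = 16L, dropout = 0.3)
  u <- encode_assignment(a, space)
  back <- decode_position(u, space)
  expect_equal(back$lr_min, a$lr_min, tolerance = 1e-12)
  expect_equal(back$dropout, a$dropout, tolerance = 1e-12)
  expect_identical(back$batch_size, 32L)
  # every discrete value survives the round trip
  for (bs in c(16L, 32L, 64L)) {
    a$batch_size <- bs
    expect_identical(decode_position(encode_assignment(a, space),
                                     space)$batch_size, bs)
  }
  # any continuous coordinate decodes onto the allowed set
  one_dim <- search_space(ss_discrete("batch_size", c(16L, 32L, 64L)))
  for (u1 in seq(0, 1, by = 0.05)) {
    expect_true(decode_position(u1, one_dim)$batch_size %in%
                  c(16L, 32L, 64L))
  }
})

test_that("movement limits behave as the update equation dictates", {
  xi <- c(0.2, 0.8); xj <- c(0.6, 0.4)
  full <- withr::with_seed(1, move_bug(xi, xj, swarm_config(
    beta0 = 1, gamma = 0, alpha = 0)))
  expect_equal(full, xj)
  none <- withr::with_seed(1, move_bug(xi, xj, swarm_config(
    beta0 = 0, gamma = 0, alpha = 0)))
  expect_equal(none, xi)
  # attraction annihilated by strong absorption over distance 0.5
  far <- withr::with_seed(1, move_bug(c(0, 0), c(0.5, 0), swarm_config(
    beta0 = 1, gamma = 1e6, alpha = 0)))
  expect_lt(sum(abs(far - c(0, 0))), 1e-10)
})

test_that("a generation step keeps only improvements", {
  space <- sphere_space()
  cfg <- swarm_config(swarm_size = 10, seed = 2)
  withr::with_seed(2, {
    swarm <- init_swarm(space, cfg, sphere_fitness)
    before <- swarm$fitness
    dist_before <- mean(sqrt(rowSums((swarm$positions - 0.5)^2)))
    stepped <- step_generation(swarm, sphere_fitness, space, cfg)
    expect_true(all(stepped$fitness >= before))
    dist_after <- mean(sqrt(rowSums((stepped$positions - 0.5)^2)))
    expect_lte(dist_after, dist_before)
  })
  # single-bug swarm has no brighter partner
  lone <- structure(list(positions = matrix(0.3, 1, 2), fitness = -1,
                         evaluations = 1), class = "swarm")
  lone2 <- step_generation(lone, sphere_fitness, space,
                           swarm_config(seed = 1))
  expect_identical(lone2$positions, lone$positions)
})

test_that("the optimizer recovers the sphere optimum", {
  res <- optimize_swarm(sphere_fitness, sphere_space(),
                        swarm_config(swarm_size = 20, generations = 50,
                                     seed = 0))
  expect_lt(sqrt(res$best_assignment$x^2 + res$best_assignment$y^2), 0.1)
  expect_gte(res$best_fitness, -0.01)
  expect_true(all(diff(res$trace$best_fitness) >= 0))
  # budget accounting: <= N + N (N-1) G evaluations
  expect_lte(max(res$trace$evaluations),
             20 + 20 * 19 * nrow(res$trace))
})

test_that("one motionless generation returns the initial argmax", {
  space <- sphere_space()
  cfg <- swarm_config(swarm_size = 12, generations = 1, beta0 = 0,
                      alpha = 0, seed = 4)
  res <- optimize_swarm(sphere_fitness, space, cfg)
  init <- withr::with_seed(4, init_swarm(space, cfg, sphere_fitness))
  best <- which.max(init$fitness)
  expect_equal(res$best_fitness, max(init$fitness))
  expect_equal(res$best_position, init$positions[best, ])
})

test_that("failing evaluations degrade gracefully", {
  bad <- function(a) stop("boom")
  expect_error(
    suppressWarnings(optimize_swarm(bad, sphere_space(),
                                    swarm_config(swarm_size = 3,
                                                 generations = 1))),
    "all initial fitness")
  flaky <- function(a) if (a$x > 0) -abs(a$x) else stop("neg")
  res <- suppressWarnings(
    optimize_swarm(flaky, sphere_space(),
                   swarm_config(swarm_size = 6, generations = 3,
                                seed = 5)))
  expect_true(is.finite(res$best_fitness))
})

test_that("swarm runs are fully reproducible", {
  cfg <- swarm_config(swarm_size = 8, generations = 5, seed = 21)
  r1 <- optimize_swarm(sphere_fitness, sphere_space(), cfg)
  r2 <- optimize_swarm(sphere_fitness, sphere_space(), cfg)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$trace, r2$trace)
})

test_that("plan tuning respects bounds and beats random search", {
  cl <- fixture_clouds(n = 400, d = 5, sep = 4, seed = 0)
  std <- fit_standardizer(cl$x)
  xs <- apply_standardizer(cl$x, std)
  idx <- rep(c(TRUE, FALSE), 200)
  cfg <- swarm_config(swarm_size = 8, generations = 3, seed = 3)
  tuned <- tune_train_plan(xs[idx, ], cl$y[idx], xs[!idx, ], cl$y[!idx],
                           config = cfg, proxy_epochs = 3,
                           total_epochs = 10)
  expect_s3_class(tuned$plan, "train_plan")
  expect_true(tuned$plan$batch_size %in% c(16L, 32L, 64L))
  expect_gte(tuned$plan$dropout_rate, 0.1)
  expect_lte(tuned$plan$dropout_rate, 0.5)
  expect_gte(tuned$plan$lr_spec$lr_min, 1e-6)
  expect_lte(tuned$plan$lr_spec$lr_max, 1e-2)
  expect_equal(tuned$plan$total_epochs, 10L)
  # determinism end to end
  tuned2 <- tune_train_plan(xs[idx, ], cl$y[idx], xs[!idx, ], cl$y[!idx],
                            config = cfg, proxy_epochs = 3,
                            total_epochs = 10)
  expect_identical(tuned$assignment, tuned2$assignment)
  # paired comparison against random search at the same evaluation budget
  budget <- max(tuned$trace$evaluations)
  space <- default_search_space()
  rand_acc <- withr::with_seed(13, {
    vapply(1:5, function(r) {
      best <- -Inf
      for (b in seq_len(budget)) {
        a <- decode_position(runif(length(space)), space)
        fit <- train_classifier(
          xs[idx, ], cl$y[idx],
          plan = train_plan(total_epochs = 3,
                            batch_size = a$batch_size,
                            dropout_rate = a$dropout,
                            lr_spec = cyclical_lr_spec(a$lr_min, a$lr_max)),
          model = mlp_model(ncol(xs), hidden = rep(a$layer_width,
                                                   a$n_layers),
                            seed = b),
          seed = b)
        acc <- mean((predict_proba(fit$model, xs[!idx, ]) >= 0.5) ==
                      cl$y[!idx])
        best <- max(best, acc)
      }
      best
    }, numeric(1))
  })
  expect_gte(tuned$fitness, median(rand_acc) - 1e-9)
})
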