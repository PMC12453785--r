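# Firebug/firefly swarm optimization: a seeded black-box maximizer over
# mixed hyperparameter spaces. Candidates live in unit-cube internal
# coordinates; dimmer candidates move toward brighter ones with
# distance-attenuated attraction plus a random perturbation, and a move is
# kept only when it strictly improves fitness (greedy retention).

#' Continuous search dimension
#' @param name Dimension name.
#' @param low,high Bounds, `low < high`.
#' @param scale `"linear"` or `"log"` (log-uniform decoding).
#' @return A search-dimension object.
#' @export
ss_continuous <- function(name, low, high, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (low >= high) stop("need low < high", call. = FALSE)
  if (scale == "log" && low <= 0) {
    stop("log-scale dimensions need low > 0", call. = FALSE)
  }
  structure(list(name = name, type = "continuous", low = low, high = high,
                 scale = scale), class = "search_dim")
}

#' Discrete search dimension
#' @param name Dimension name.
#' @param values Non-empty vector of ordered allowed values.
#' @return A search-dimension object.
#' @export
ss_discrete <- function(name, values) {
  if (length(values) == 0) stop("discrete set is empty", call. = FALSE)
  structure(list(name = name, type = "discrete", values = values),
            class = "search_dim")
}

#' Assemble a search space
#' @param ... `search_dim` objects from [ss_continuous()] / [ss_discrete()].
#' @return A `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  stopifnot(length(dims) >= 1,
            all(vapply(dims, inherits, logical(1), "search_dim")))
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, class = "search_space")
}

#' Default hyperparameter search space
#'
#' Learning-rate bounds on a log scale, batch size in {16, 32, 64}, the
#' number of hidden layer groups, their width (the network-capacity
#' analogue of a filter size), and dropout in [0.1, 0.5].
#' @return A `search_space`.
#' @export
default_search_space <- function() {
  search_space(
    ss_continuous("lr_min", 1e-6, 1e-4, scale = "log"),
    ss_continuous("lr_max", 1e-4, 1e-2, scale = "log"),
    ss_discrete("batch_size", c(16L, 32L, 64L)),
    ss_discrete("n_layers", c(1L, 2L, 3L)),
    ss_discrete("layer_width", c(8L, 16L, 32L)),
    ss_continuous("dropout", 0.1, 0.5))
}

# unit-cube coordinate -> hyperparameter value
decode_dim <- function(dim, u) {
  u <- clip(u, 0, 1)
  if (dim$type == "continuous") {
    if (dim$scale == "log") {
      exp(log(dim$low) + u * (log(dim$high) - log(dim$low)))
    } else {
      dim$low + u * (dim$high - dim$low)
    }
  } else {
    k <- length(dim$values)
    dim$values[[if (k == 1) 1 else round(u * (k - 1)) + 1]]
  }
}

encode_dim <- function(dim, value) {
  if (dim$type == "continuous") {
    if (dim$scale == "log") {
      (log(value) - log(dim$low)) / (log(dim$high) - log(dim$low))
    } else {
      (value - dim$low) / (dim$high - dim$low)
    }
  } else {
    k <- length(dim$values)
    if (k == 1) 0.5 else (match(value, dim$values) - 1) / (k - 1)
  }
}

#' Decode a unit-cube position into a hyperparameter assignment
#' @param position Numeric vector in [0, 1]^d.
#' @param space A `search_space`.
#' @return Named list of decoded values.
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "search_space"),
            length(position) == length(space))
  stats::setNames(lapply(seq_along(space), function(k) {
    decode_dim(space[[k]], position[k])
  }), names(space))
}

#' Encode a hyperparameter assignment into unit-cube coordinates
#' @param assignment Named list of values.
#' @param space A `search_space`.
#' @return Numeric vector in [0, 1]^d.
#' @export
encode_assignment <- function(assignment, space) {
  vapply(seq_along(space), function(k) {
    encode_dim(space[[k]], assignment[[names(space)[k]]])
  }, numeric(1))
}

#' Swarm configuration
#' @param swarm_size Number of candidates `N >= 2`.
#' @param generations Maximum generations `G_max >= 1`.
#' @param beta0 Attractiveness at zero distance.
#' @param gamma Absorption coefficient (distance attenuation, unit-cube
#'   scale).
#' @param alpha Randomization weight.
#' @param seed Master seed for the run.
#' @return A `swarm_config`.
#' @export
swarm_config <- function(swarm_size = 15, generations = 20, beta0 = 1,
                         gamma = 1, alpha = 0.1, seed = 0) {
  stopifnot(swarm_size >= 2, generations >= 1,
            beta0 >= 0, gamma >= 0, alpha >= 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 generations = as.integer(generations),
                 beta0 = beta0, gamma = gamma, alpha = alpha,
                 seed = as.integer(seed)),
            class = "swarm_config")
}

safe_fitness <- function(fitness_fn, assignment) {
  out <- tryCatch(fitness_fn(assignment), error = function(e) {
    warning("fitness evaluation failed: ", conditionMessage(e),
            call. = FALSE)
    -Inf
  })
  if (is.na(out)) out <- -Inf
  out
}

#' Initialize a swarm
#'
#' Positions are i.i.d. uniform on the unit cube (seeded through the
#' enclosing optimizer); each is decoded and scored once. A failing
#' fitness function marks the candidate with fitness `-Inf`.
#'
#' @param space A `search_space`.
#' @param config A `swarm_config`.
#' @param fitness_fn Function of a decoded assignment returning a scalar
#'   fitness to maximize.
#' @return A `swarm`: list with `positions` (N x d matrix), `fitness`,
#'   `evaluations`.
#' @export
init_swarm <- function(space, config, fitness_fn) {
  n <- config$swarm_size
  d <- length(space)
  pos <- matrix(stats::runif(n * d), n, d)
  fit <- vapply(seq_len(n), function(i) {
    safe_fitness(fitness_fn, decode_position(pos[i, ], space))
  }, numeric(1))
  structure(list(positions = pos, fitness = fit, evaluations = n),
            class = "swarm")
}

#' Move one candidate toward a brighter one
#'
#' `x_i' = x_i + beta0 * exp(-gamma * r_ij^2) * (x_j - x_i) + alpha *
#' delta_i` with `r_ij` the Euclidean distance in unit-cube coordinates
#' and `delta_i` i.i.d. U(-0.5, 0.5) per dimension; the result is clipped
#' to [0, 1].
#'
#' @param x_i,x_j Positions (the mover and the attractor).
#' @param config A `swarm_config`.
#' @return New position for the mover.
#' @export
move_bug <- function(x_i, x_j, config) {
  r2 <- sum((x_j - x_i)^2)
  delta <- stats::runif(length(x_i), -0.5, 0.5)
  clip(x_i + config$beta0 * exp(-config$gamma * r2) * (x_j - x_i) +
         config$alpha * delta, 0, 1)
}

#' Advance the swarm by one generation
#'
#' Pairwise pass: each candidate is moved toward every brighter partner it
#' encounters, re-evaluated, and the move is kept only when fitness
#' strictly improves, so per-candidate fitness is monotone non-decreasing.
#' With `literal_rule = TRUE` the comparison is reversed (the brighter
#' candidate moves toward the dimmer), provided for compatibility.
#'
#' @param swarm A `swarm`.
#' @param fitness_fn Fitness function over decoded assignments.
#' @param space A `search_space`.
#' @param config A `swarm_config`.
#' @param literal_rule Reverse the attraction inequality?
#' @return The updated `swarm`.
#' @export
step_generation <- function(swarm, fitness_fn, space, config,
                            literal_rule = FALSE) {
  n <- nrow(swarm$positions)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      attracted <- if (literal_rule) {
        swarm$fitness[i] > swarm$fitness[j]
      } else {
        swarm$fitness[j] > swarm$fitness[i]
      }
      if (!attracted) next
      cand <- move_bug(swarm$positions[i, ], swarm$positions[j, ], config)
      f_new <- safe_fitness(fitness_fn, decode_position(cand, space))
      swarm$evaluations <- swarm$evaluations + 1
      if (f_new > swarm$fitness[i]) {
        swarm$positions[i, ] <- cand
        swarm$fitness[i] <- f_new
      }
    }
  }
  swarm
}

#' Run the swarm optimizer
#'
#' Runs up to `generations` generations, stopping early when the best
#' fitness has improved by less than 1e-9 for 10 consecutive generations.
#' All randomness derives from `config$seed`.
#'
#' @param fitness_fn Function of a decoded assignment, returning the
#'   fitness to maximize.
#' @param space A `search_space`.
#' @param config A `swarm_config`.
#' @param literal_rule See [step_generation()].
#' @return List: `best_assignment`, `best_fitness`, `best_position`, and a
#'   per-generation `trace` data.frame
#'   (`generation,best_fitness,mean_fitness,evaluations`).
#' @export
optimize_swarm <- function(fitness_fn, space, config = swarm_config(),
                           literal_rule = FALSE) {
  stopifnot(inherits(space, "search_space"),
            inherits(config, "swarm_config"))
  withr::with_seed(config$seed, {
    swarm <- init_swarm(space, config, fitness_fn)
    if (all(!is.finite(swarm$fitness))) {
      stop("all initial fitness evaluations failed", call. = FALSE)
    }
    best_idx <- which.max(swarm$fitness)
    best_fit <- swarm$fitness[best_idx]
    best_pos <- swarm$positions[best_idx, ]
    stall <- 0
    rows <- vector("list", config$generations)
    for (g in seq_len(config$generations)) {
      swarm <- step_generation(swarm, fitness_fn, space, config,
                               literal_rule = literal_rule)
      gen_best <- max(swarm$fitness)
      if (gen_best > best_fit + 1e-9) {
        stall <- 0
      } else {
        stall <- stall + 1
      }
      if (gen_best > best_fit) {
        best_idx <- which.max(swarm$fitness)
        best_fit <- swarm$fitness[best_idx]
        best_pos <- swarm$positions[best_idx, ]
      }
      rows[[g]] <- data.frame(
        generation = g, best_fitness = best_fit,
        mean_fitness = mean(swarm$fitness[is.finite(swarm$fitness)]),
        evaluations = swarm$evaluations)
      if (stall >= 10) break
    }
    list(best_assignment = decode_position(best_pos, space),
         best_fitness = best_fit, best_position = best_pos,
         trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  })
}

#' Tune a training plan by swarm search
#'
#' Fitness of a candidate assignment is the validation accuracy of a short
#' proxy training run (a small, fixed epoch budget) with the decoded
#' hyperparameters; the returned plan is rebuilt from the best assignment
#' with the full epoch budget. Diverging proxy runs score `-Inf`. Fully
#' deterministic for a fixed `config$seed`.
#'
#' @param x_train,y_train Training features/labels (already standardized).
#' @param x_val,y_val Validation features/labels for the fitness.
#' @param space A `search_space`; defaults to [default_search_space()].
#' @param config A `swarm_config`.
#' @param proxy_epochs Epochs per fitness evaluation.
#' @param total_epochs Epoch budget of the returned plan.
#' @return List: `plan` (a [train_plan()]), `hidden` (tuned layer widths),
#'   `assignment`, `fitness`, `trace`.
#' @export
tune_train_plan <- function(x_train, y_train, x_val, y_val,
                            space = default_search_space(),
                            config = swarm_config(), proxy_epochs = 5,
                            total_epochs = 50) {
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  counter <- 0
  as_plan <- function(a, epochs) {
    train_plan(total_epochs = epochs,
               batch_size = if (is.null(a$batch_size)) 32L else a$batch_size,
               dropout_rate = if (is.null(a$dropout)) 0.3 else a$dropout,
               lr_spec = cyclical_lr_spec(
                 lr_min = if (is.null(a$lr_min)) 1e-5 else a$lr_min,
                 lr_max = if (is.null(a$lr_max)) 1e-3 else a$lr_max))
  }
  as_hidden <- function(a) {
    n <- if (is.null(a$n_layers)) 2L else a$n_layers
    w <- if (is.null(a$layer_width)) 16L else a$layer_width
    rep(as.integer(w), n)
  }
  fitness_fn <- function(a) {
    counter <<- counter + 1
    # fixed proxy seed: fitness is a pure, reproducible function of the
    # decoded assignment
    eval_seed <- (abs(as.numeric(config$seed)) * 131) %%
      (.Machine$integer.max - 1)
    fit <- train_classifier(
      x_train, y_train, plan = as_plan(a, proxy_epochs),
      model = mlp_model(ncol(x_train), hidden = as_hidden(a),
                        seed = eval_seed),
      seed = eval_seed)
    mean((predict_proba(fit$model, x_val) >= 0.5) ==
           labels_to_binary(y_val))
  }
  res <- optimize_swarm(fitness_fn, space, config)
  list(plan = as_plan(res$best_assignment, total_epochs),
       hidden = as_hidden(res$best_assignment),
       assignment = res$best_assignment,
       fitness = res$best_fitness,
       trace = res$trace)
}
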