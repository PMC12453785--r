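# Progressive cyclical training: staged layer unfreezing driven by a
# cosine-with-warm-restarts learning-rate schedule, over a small MLP
# classifier with named layer groups.

#' Cyclical learning-rate specification
#'
#' Defaults are the study configuration: bounds 1e-5 and 1e-3. When
#' `cycle_length` is `NULL` the trainer sets it to 10 epochs' worth of
#' iterations.
#'
#' @param lr_min,lr_max Learning-rate bounds, `0 < lr_min <= lr_max`.
#' @param cycle_length Iterations per cycle (`T_max`), or `NULL`.
#' @return A `cyclical_lr_spec`.
#' @export
cyclical_lr_spec <- function(lr_min = 1e-5, lr_max = 1e-3,
                             cycle_length = NULL) {
  if (lr_min <= 0 || lr_max < lr_min) {
    stop("need 0 < lr_min <= lr_max", call. = FALSE)
  }
  if (!is.null(cycle_length) && cycle_length <= 0) {
    stop("cycle_length must be positive", call. = FALSE)
  }
  structure(list(lr_min = lr_min, lr_max = lr_max,
                 cycle_length = cycle_length),
            class = "cyclical_lr_spec")
}

#' Cyclical learning rate at iteration t
#'
#' Cosine annealing with warm restarts:
#' `LR(t) = LR_min + (LR_max - LR_min)/2 * (1 + cos(pi * T_cur / T_max))`
#' with `T_cur` the position within the current cycle. The schedule starts
#' each cycle at `LR_max`, reaches `LR_min` at the cycle end, and restarts.
#' `mode = "triangular"` gives a linear up-then-down oscillation over the
#' same bounds instead.
#'
#' @param t Iteration (scalar or vector), `t >= 0`.
#' @param spec A [cyclical_lr_spec()] with a set `cycle_length`.
#' @param mode `"cosine"` (default) or `"triangular"`.
#' @return Learning rate(s) in `[lr_min, lr_max]`.
#' @export
cyclical_lr <- function(t, spec, mode = c("cosine", "triangular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cyclical_lr_spec"))
  tmax <- spec$cycle_length
  if (is.null(tmax) || tmax == 0) {
    stop("cycle_length (T_max) must be set and nonzero", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tcur <- t - floor(t / tmax) * tmax
  tcur[t > 0 & tcur == 0] <- tmax  # cycle end hits LR_min before restarting
  if (mode == "cosine") {
    spec$lr_min + 0.5 * (spec$lr_max - spec$lr_min) *
      (1 + cos(pi * tcur / tmax))
  } else {
    frac <- tcur / tmax
    spec$lr_min + (spec$lr_max - spec$lr_min) * (1 - abs(2 * frac - 1))
  }
}

#' Build a progressive unfreezing schedule
#'
#' The final stage always trains every group; earlier stages freeze the
#' early groups, so stage k of K trains the head plus the last
#' `n_groups - K + k` groups. Trainable sets are therefore nested and
#' non-decreasing. Epochs are divided as evenly as possible with the
#' remainder going to the final stage.
#'
#' @param layer_groups Character vector of layer-group names in forward
#'   order (excluding the head).
#' @param n_stages Number of stages, `1 <= n_stages <= length(layer_groups)`.
#' @param total_epochs Total epochs to distribute.
#' @param head Name of the always-trainable output group.
#' @return List of stages: `stage_index`, `trainable` (group names),
#'   `epochs`.
#' @export
build_stages <- function(layer_groups, n_stages, total_epochs,
                         head = "head") {
  if (length(layer_groups) == 0) stop("empty layer list", call. = FALSE)
  if (n_stages < 1 || n_stages > length(layer_groups)) {
    stop("need 1 <= n_stages <= number of layer groups", call. = FALSE)
  }
  k <- length(layer_groups)
  per <- rep(total_epochs %/% n_stages, n_stages)
  per[n_stages] <- per[n_stages] + total_epochs %% n_stages
  lapply(seq_len(n_stages), function(s) {
    n_open <- k - n_stages + s
    list(stage_index = s,
         trainable = c(layer_groups[(k - n_open + 1):k], head),
         epochs = per[s])
  })
}

#' Training plan
#'
#' Bundles the progressive stages, the cyclical learning-rate spec and the
#' optimization hyperparameters. Defaults follow the study configuration:
#' 50 epochs, batch size 32, dropout 0.3, binary cross-entropy loss, Adam
#' base optimizer with its step size overridden by the schedule.
#'
#' @param total_epochs Total training epochs.
#' @param batch_size Minibatch size.
#' @param dropout_rate Dropout probability on hidden activations.
#' @param lr_spec A [cyclical_lr_spec()].
#' @param n_stages Number of progressive stages, or `NULL` for one stage
#'   per layer group.
#' @param stages Explicit stage list from [build_stages()], or `NULL` to
#'   build at fit time from the model's groups.
#' @param lr_mode Schedule shape, `"cosine"` or `"triangular"`.
#' @return A `train_plan`.
#' @export
train_plan <- function(total_epochs = 50, batch_size = 32,
                       dropout_rate = 0.3, lr_spec = cyclical_lr_spec(),
                       n_stages = NULL, stages = NULL,
                       lr_mode = "cosine") {
  if (!is.null(stages)) {
    tot <- sum(vapply(stages, `[[`, numeric(1), "epochs"))
    if (tot != total_epochs) {
      stop("stage epochs must sum to total_epochs", call. = FALSE)
    }
  }
  stopifnot(total_epochs >= 1, batch_size >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, lr_spec = lr_spec,
                 n_stages = n_stages, stages = stages, lr_mode = lr_mode,
                 loss = "binary_cross_entropy"),
            class = "train_plan")
}

#' A multilayer perceptron with named layer groups
#'
#' Hidden layers are ReLU groups named `block1`, `block2`, ...; the
#' sigmoid output layer is the group `head`. The grouping is what the
#' progressive schedule freezes and unfreezes.
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed Seed for He-scaled weight initialization.
#' @return An `mlp_model`.
#' @export
mlp_model <- function(input_dim, hidden = c(32, 16), seed = 0) {
  stopifnot(input_dim >= 1)
  dims <- c(input_dim, hidden, 1L)
  names_all <- c(paste0("block", seq_along(hidden)), "head")
  params <- withr::with_seed(as.integer(seed), {
    stats::setNames(lapply(seq_along(names_all), function(l) {
      fan_in <- dims[l]
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1],
                                   sd = sqrt(2 / fan_in)),
                      dims[l], dims[l + 1]),
           b = rep(0, dims[l + 1]))
    }), names_all)
  })
  structure(list(params = params,
                 layer_groups = setdiff(names_all, "head"),
                 hidden = hidden, input_dim = as.integer(input_dim),
                 fitted = FALSE),
            class = "mlp_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; returns activations for backprop when keep = TRUE.
mlp_forward <- function(model, x, dropout_rate = 0, keep = FALSE) {
  groups <- c(model$layer_groups, "head")
  acts <- list(x)
  masks <- list()
  h <- x
  for (g in groups) {
    p <- model$params[[g]]
    z <- h %*% p$W + matrix(p$b, nrow(h), length(p$b), byrow = TRUE)
    if (g == "head") {
      h <- sigmoid(z)
    } else {
      h <- pmax(z, 0)
      if (dropout_rate > 0) {
        m <- matrix(stats::runif(length(h)) >= dropout_rate,
                    nrow(h), ncol(h)) / (1 - dropout_rate)
        h <- h * m
        masks[[g]] <- m
      }
    }
    acts[[length(acts) + 1]] <- h
  }
  if (keep) list(prob = h[, 1], acts = acts, masks = masks) else h[, 1]
}

bce_loss <- function(p, y) {
  p <- clip(p, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

labels_to_binary <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("benign", "malignant"))) {
    stop("labels must be binary (0/1 or benign/malignant)", call. = FALSE)
  }
  as.numeric(y == "malignant")
}

#' Train a classifier with progressive cyclical scheduling
#'
#' Minibatch Adam on binary cross-entropy, with the optimizer step size
#' overridden at every iteration by [cyclical_lr()] and parameter updates
#' restricted to the current progressive stage's trainable groups (frozen
#' groups stay bit-identical across a stage). Fully seeded: the shuffling,
#' dropout masks and initialization derive from `seed`.
#'
#' @param x Feature matrix (standardize it first; see
#'   [fit_standardizer()]).
#' @param y Binary labels (0/1 or benign/malignant; malignant = 1).
#' @param plan A [train_plan()].
#' @param model An `mlp_model`, or `NULL` to create one sized to `x`.
#' @param seed Master seed for the run.
#' @param x_val,y_val Optional validation split for per-epoch metrics.
#' @return List with `model` (fitted) and `history` (per-iteration `lr`,
#'   per-epoch data.frame, stage boundaries).
#' @export
train_classifier <- function(x, y, plan = train_plan(), model = NULL,
                             seed = 0, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(plan, "train_plan"))
  x <- as.matrix(x)
  y <- labels_to_binary(y)
  if (is.null(model)) model <- mlp_model(ncol(x), seed = seed)
  stopifnot(inherits(model, "mlp_model"))
  yv <- if (!is.null(y_val)) labels_to_binary(y_val) else NULL
  n <- nrow(x)
  iters_per_epoch <- max(1L, ceiling(n / plan$batch_size))
  lr_spec <- plan$lr_spec
  if (is.null(lr_spec$cycle_length)) {
    lr_spec$cycle_length <- iters_per_epoch * 10
  }
  stages <- plan$stages
  if (is.null(stages)) {
    ns <- if (is.null(plan$n_stages)) length(model$layer_groups) else
      plan$n_stages
    stages <- build_stages(model$layer_groups, ns, plan$total_epochs)
  }
  groups <- c(model$layer_groups, "head")
  adam <- lapply(model$params, function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0, t = 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  lr_trace <- numeric(0)
  epoch_rows <- list()
  stage_bounds <- integer(0)
  t_iter <- 0
  epoch_global <- 0
  withr::with_seed(as.integer(seed), {
    for (st in stages) {
      stage_bounds <- c(stage_bounds, epoch_global + 1L)
      trainable <- st$trainable
      for (ep in seq_len(st$epochs)) {
        epoch_global <- epoch_global + 1
        perm <- sample.int(n)
        for (bstart in seq(1, n, by = plan$batch_size)) {
          idx <- perm[bstart:min(n, bstart + plan$batch_size - 1)]
          xb <- x[idx, , drop = FALSE]
          yb <- y[idx]
          fw <- mlp_forward(model, xb, dropout_rate = plan$dropout_rate,
                            keep = TRUE)
          loss <- bce_loss(fw$prob, yb)
          if (!is.finite(loss)) {
            stop("NaN/Inf loss at iteration ", t_iter,
                 "; try smaller learning rates", call. = FALSE)
          }
          lr <- cyclical_lr(t_iter, lr_spec, mode = plan$lr_mode)
          lr_trace <- c(lr_trace, lr)
          # backprop
          nb <- length(idx)
          delta <- matrix((fw$prob - yb) / nb, nb, 1)  # dL/dz at the head
          for (li in rev(seq_along(groups))) {
            g <- groups[li]
            h_in <- fw$acts[[li]]
            gW <- crossprod(h_in, delta)
            gb <- colSums(delta)
            if (li > 1) {
              delta_prev <- delta %*% t(model$params[[g]]$W)
              a_prev <- fw$acts[[li]]
              delta_prev <- delta_prev * (a_prev > 0)
              if (!is.null(fw$masks[[groups[li - 1]]])) {
                delta_prev <- delta_prev * fw$masks[[groups[li - 1]]]
              }
              delta <- delta_prev
            }
            if (g %in% trainable) {
              a <- adam[[g]]
              a$t <- a$t + 1
              a$mW <- beta1 * a$mW + (1 - beta1) * gW
              a$vW <- beta2 * a$vW + (1 - beta2) * gW^2
              a$mb <- beta1 * a$mb + (1 - beta1) * gb
              a$vb <- beta2 * a$vb + (1 - beta2) * gb^2
              mhW <- a$mW / (1 - beta1^a$t)
              vhW <- a$vW / (1 - beta2^a$t)
              mhb <- a$mb / (1 - beta1^a$t)
              vhb <- a$vb / (1 - beta2^a$t)
              model$params[[g]]$W <- model$params[[g]]$W -
                lr * mhW / (sqrt(vhW) + aeps)
              model$params[[g]]$b <- model$params[[g]]$b -
                lr * mhb / (sqrt(vhb) + aeps)
              adam[[g]] <- a
            }
          }
          t_iter <- t_iter + 1
        }
        p_tr <- mlp_forward(model, x)
        row <- data.frame(epoch = epoch_global, stage = st$stage_index,
                          train_loss = bce_loss(p_tr, y),
                          train_acc = mean((p_tr >= 0.5) == y),
                          val_loss = NA_real_, val_acc = NA_real_)
        if (!is.null(x_val)) {
          p_va <- mlp_forward(model, as.matrix(x_val))
          row$val_loss <- bce_loss(p_va, yv)
          row$val_acc <- mean((p_va >= 0.5) == yv)
        }
        epoch_rows[[length(epoch_rows) + 1]] <- row
      }
    }
  })
  model$fitted <- TRUE
  list(model = model,
       history = list(lr = lr_trace,
                      epochs = do.call(rbind, epoch_rows),
                      stage_boundaries = stage_bounds,
                      lr_spec = lr_spec))
}

#' Export a training history as CSV
#'
#' One row per iteration with columns
#' `iteration,epoch,stage,lr,train_loss,val_loss,train_acc,val_acc`;
#' per-epoch metrics repeat across the epoch's iterations.
#'
#' @param history The `history` element returned by [train_classifier()].
#' @param path Output CSV path.
#' @export
write_train_history <- function(history, path) {
  ep <- history$epochs
  n_ep <- nrow(ep)
  iters <- length(history$lr)
  per_ep <- iters / n_ep
  epoch_of <- rep(ep$epoch, each = per_ep)[seq_len(iters)]
  idx <- match(epoch_of, ep$epoch)
  out <- data.frame(iteration = seq_len(iters) - 1L,
                    epoch = epoch_of,
                    stage = ep$stage[idx],
                    lr = history$lr,
                    train_loss = ep$train_loss[idx],
                    val_loss = ep$val_loss[idx],
                    train_acc = ep$train_acc[idx],
                    val_acc = ep$val_acc[idx])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Predict malignancy probabilities
#' @param model A fitted `mlp_model`.
#' @param x Feature matrix on the training feature scale.
#' @return Probabilities in [0, 1], one per row; deterministic (no
#'   dropout at inference).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (!isTRUE(model$fitted)) stop("model is not fitted", call. = FALSE)
  mlp_forward(model, as.matrix(x))
}
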