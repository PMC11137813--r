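#' Train the feedforward network mapping features to pair parameters
#'
#' A fully connected network inverts the three reduced-model features
#' (mean Fe-O2-O1 angle, effective well depth epsilon_f, effective length
#' sigma_f) into the four two-site parameters (epsilon1, sigma1, epsilon2,
#' sigma2). Architecture: four fully connected layers (3 -> 64 -> 64 ->
#' 64 -> 4) with rectified-linear transformations between layers except
#' before the output; trained with Adam at learning rate 5e-4 for 2001
#' epochs under a mean-squared-error loss. Features and targets are
#' z-scored on the training partition (mixed-magnitude targets train
#' poorly unscaled); the normalization statistics are stored with the
#' model. Minibatches (default 512, reshuffled every epoch) are a protocol
#' choice recorded in the model.
#'
#' @param db Featurized database ([featurize_database()]); rows with
#'   `converged == FALSE` are dropped with a message.
#' @param train_frac Training fraction (default 0.8).
#' @param epochs Training epochs (default 2001).
#' @param lr Adam learning rate (default 5e-4).
#' @param hidden Hidden-layer widths (default `c(64, 64, 64)`).
#' @param batch_size Minibatch size.
#' @param seed Seed for the split, initialization and shuffling.
#' @return An object of class `fnn_model`: weights, normalization
#'   statistics, per-output train/test RMSE (original units), loss
#'   history and the split. `tidy()`/`glance()` methods report the RMSEs.
#' @export
train_fnn <- function(db, train_frac = 0.8, epochs = 2001, lr = 5e-4,
                      hidden = c(64, 64, 64), batch_size = 512, seed = 1) {
  feat_cols <- c("mean_angle", "epsilon_f", "sigma_f")
  targ_cols <- c("epsilon1", "sigma1", "epsilon2", "sigma2")
  stopifnot(all(c(feat_cols, targ_cols) %in% names(db)))
  if ("converged" %in% names(db) && any(!db$converged)) {
    message("dropping ", sum(!db$converged), " non-converged record(s)")
    db <- db[db$converged, ]
  }
  set.seed(seed)
  if (!"partition" %in% names(db)) db <- partition_database(db, train_frac)
  tr <- db$partition == "train"
  X <- as.matrix(db[, feat_cols]); Y <- as.matrix(db[, targ_cols])
  mu_x <- colMeans(X[tr, ]); sd_x <- apply(X[tr, ], 2, sd)
  mu_y <- colMeans(Y[tr, ]); sd_y <- apply(Y[tr, ], 2, sd)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, "/")

  sizes <- c(length(feat_cols), hidden, length(targ_cols))
  L <- length(sizes) - 1L
  init_layer <- function(fin, fout) {
    s <- 1 / sqrt(fin)
    list(W = matrix(runif(fin * fout, -s, s), fin, fout),
         b = runif(fout, -s, s))
  }
  layers <- purrr::map(seq_len(L), ~init_layer(sizes[.x], sizes[.x + 1]))
  mom <- purrr::map(layers, ~list(mW = .x$W * 0, vW = .x$W * 0,
                                  mb = .x$b * 0, vb = .x$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8

  forward <- function(X, layers) {
    acts <- vector("list", L + 1L)
    acts[[1]] <- X
    for (l in seq_len(L)) {
      z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
      acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    acts
  }

  Xtr <- Xs[tr, , drop = FALSE]; Ytr <- Ys[tr, , drop = FALSE]
  n_tr <- nrow(Xtr)
  bs <- min(batch_size, n_tr)
  loss_hist <- numeric(epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    for (b0 in seq(1, n_tr, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1L, n_tr)]
      xb <- Xtr[idx, , drop = FALSE]; yb <- Ytr[idx, , drop = FALSE]
      acts <- forward(xb, layers)
      pred <- acts[[L + 1]]
      err <- pred - yb
      ep_loss <- ep_loss + sum(err^2)
      delta <- 2 * err / (length(err))        # d(MSE)/d(pred)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        m <- mom[[l]]
        m$mW <- beta1 * m$mW + (1 - beta1) * gW
        m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
        m$mb <- beta1 * m$mb + (1 - beta1) * gb
        m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
        mW_hat <- m$mW / (1 - beta1^step); vW_hat <- m$vW / (1 - beta2^step)
        mb_hat <- m$mb / (1 - beta1^step); vb_hat <- m$vb / (1 - beta2^step)
        layers[[l]]$W <- layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps_adam)
        layers[[l]]$b <- layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps_adam)
        mom[[l]] <- m
      }
    }
    loss_hist[ep] <- ep_loss / (n_tr * length(targ_cols))
    if (!is.finite(loss_hist[ep]))
      stop("training loss diverged (NaN) at epoch ", ep, call. = FALSE)
  }

  rmse_part <- function(part) {
    pred_s <- forward(Xs[part, , drop = FALSE], layers)[[L + 1]]
    pred <- sweep(sweep(pred_s, 2, sd_y, "*"), 2, mu_y, "+")
    sqrt(colMeans((pred - Y[part, , drop = FALSE])^2))
  }
  rmse <- tibble::tibble(
    output = targ_cols,
    train_rmse = rmse_part(which(tr)),
    test_rmse = rmse_part(which(!tr)))

  structure(list(layers = layers, sizes = sizes,
                 norm = list(mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y),
                 feature_names = feat_cols, target_names = targ_cols,
                 feature_range = apply(X[tr, ], 2, range),
                 rmse = rmse, loss = loss_hist,
                 config = list(epochs = epochs, lr = lr, hidden = hidden,
                               batch_size = bs, seed = seed,
                               n_train = sum(tr), n_test = sum(!tr)),
                 forward = NULL), class = "fnn_model")
}

fnn_forward <- function(model, X) {
  L <- length(model$layers)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$layers[[l]]$W, 2, model$layers[[l]]$b, "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  a
}

#' @export
print.fnn_model <- function(x, ...) {
  cat(sprintf("<fnn_model> %s | %d train / %d test | final loss %.4g\n",
              paste(x$sizes, collapse = " -> "),
              x$config$n_train, x$config$n_test, tail(x$loss, 1)))
  print(x$rmse)
  invisible(x)
}

#' @method tidy fnn_model
#' @export
tidy.fnn_model <- function(x, ...) x$rmse

#' @method glance fnn_model
#' @export
glance.fnn_model <- function(x, ...) {
  tibble::tibble(epochs = x$config$epochs, lr = x$config$lr,
                 n_train = x$config$n_train, n_test = x$config$n_test,
                 final_loss = tail(x$loss, 1),
                 mean_test_rmse = mean(x$rmse$test_rmse))
}

#' @export
predict.fnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  Xs <- sweep(sweep(X, 2, object$norm$mu_x), 2, object$norm$sd_x, "/")
  pred_s <- fnn_forward(object, Xs)
  pred <- sweep(sweep(pred_s, 2, object$norm$sd_y, "*"), 2, object$norm$mu_y, "+")
  out <- tibble::as_tibble(as.data.frame(pred))
  names(out) <- object$target_names
  rng <- object$feature_range
  out$extrapolated <- vapply(seq_len(nrow(X)), function(i) {
    any(X[i, ] < rng[1, ] | X[i, ] > rng[2, ])
  }, logical(1))
  out
}

#' Invert target features into a two-site parameter set
#'
#' Single forward pass through a trained network. Well depths are
#' returned in the signed (negative) convention of coordination parameter
#' tables; a target outside the training feature ranges is flagged as an
#' extrapolation (prediction quality there is bounded by the model's test
#' RMSE at best).
#'
#' @param model A trained [train_fnn()] model.
#' @param features A one-row tibble (or named list) with `mean_angle`,
#'   `epsilon_f`, `sigma_f`.
#' @return A tibble `epsilon1`, `sigma1`, `epsilon2`, `sigma2` (epsilons
#'   negative, kcal/mol; sigmas Angstrom) plus `extrapolated`.
#' @export
invert_features <- function(model, features) {
  stopifnot(inherits(model, "fnn_model"))
  pred <- predict(model, tibble::as_tibble(features))
  pred$epsilon1 <- -abs(pred$epsilon1)
  pred$epsilon2 <- -abs(pred$epsilon2)
  pred
}

#' Serialize / restore a trained network
#'
#' Plain-JSON container holding the architecture, weights and
#' normalization statistics, so a trained model can be archived with a
#' run's outputs and reloaded without reference to the training session.
#'
#' @param model A `fnn_model`.
#' @param path Output path (JSON).
#' @return `write_fnn` returns `path` invisibly; `read_fnn` the restored
#'   model.
#' @export
write_fnn <- function(model, path) {
  payload <- list(
    sizes = model$sizes,
    layers = purrr::map(model$layers, ~list(W = .x$W, b = .x$b)),
    norm = model$norm,
    feature_names = model$feature_names, target_names = model$target_names,
    feature_range = model$feature_range,
    rmse = model$rmse, config = model$config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fnn
#' @export
read_fnn <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  layers <- purrr::map(seq_along(p$layers$W), function(l) {
    list(W = p$layers$W[[l]], b = as.numeric(p$layers$b[[l]]))
  })
  structure(list(layers = layers, sizes = as.numeric(p$sizes),
                 norm = purrr::map(p$norm, unlist),
                 feature_names = p$feature_names, target_names = p$target_names,
                 feature_range = p$feature_range,
                 rmse = tibble::as_tibble(p$rmse),
                 loss = NULL, config = p$config), class = "fnn_model")
}
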