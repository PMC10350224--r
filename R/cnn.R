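#' Configuration for the tile classification network
#'
#' Training hyperparameters follow the triage training protocol: batch size
#' 32, an 80/20 train/validation split, and early stopping that monitors the
#' validation accuracy with a patience of 10 epochs, keeping the
#' best-validation-accuracy checkpoint. Architecture defaults (number of
#' blocks, filters, learning rate, input size) are package choices and fully
#' configurable.
#'
#' @param n_blocks Number of convolution blocks; each block is a 3x3
#'   convolution + ReLU + 2x2 max-pool that halves the spatial size.
#' @param filters Integer vector of length `n_blocks`: output channels per
#'   block.
#' @param input_size Side of the square network input, pixels; tile MIPs are
#'   resized (area-average) to this size. Must be divisible by
#'   `2^n_blocks`.
#' @param batch_size Minibatch size.
#' @param train_fraction Fraction of the dataset used for training (rest is
#'   validation).
#' @param patience_epochs Early-stopping patience on validation accuracy.
#' @param max_epochs Hard epoch cap.
#' @param learning_rate Adam learning rate.
#' @param probability_threshold Default decision threshold on the predicted
#'   probability of "informative".
#' @param seed Default training seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_blocks = 3L, filters = c(8L, 16L, 32L),
                              input_size = 32L, batch_size = 32L,
                              train_fraction = 0.8, patience_epochs = 10L,
                              max_epochs = 50L, learning_rate = 1e-3,
                              probability_threshold = 0.5, seed = 1L) {
  n_blocks <- chk_count(n_blocks, "n_blocks")
  if (length(filters) != n_blocks || any(filters < 1))
    stop("`filters` must give one positive channel count per block",
         call. = FALSE)
  input_size <- chk_count(input_size, "input_size")
  if (input_size %% 2L^n_blocks != 0L)
    stop(sprintf("input_size (%d) must be divisible by 2^n_blocks (%d)",
                 input_size, 2L^n_blocks), call. = FALSE)
  batch_size <- chk_count(batch_size, "batch_size")
  chk_num(train_fraction, "train_fraction", lower = 0, upper = 1,
          strict_lower = TRUE)
  patience_epochs <- chk_count(patience_epochs, "patience_epochs")
  max_epochs <- chk_count(max_epochs, "max_epochs")
  chk_num(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  chk_num(probability_threshold, "probability_threshold", lower = 0,
          upper = 1)
  structure(
    list(n_blocks = n_blocks, filters = as.integer(filters),
         input_size = input_size, batch_size = batch_size,
         train_fraction = train_fraction,
         patience_epochs = patience_epochs, max_epochs = max_epochs,
         learning_rate = learning_rate,
         probability_threshold = probability_threshold, seed = seed),
    class = "classifier_config"
  )
}

# ---- input preparation -----------------------------------------------------

# Area-average resampling matrix mapping `from` samples onto `to` samples.
resize_matrix <- function(from, to) {
  A <- matrix(0, to, from)
  scale <- from / to
  for (i in seq_len(to)) {
    a <- (i - 1) * scale
    b <- i * scale
    js <- floor(a):min(ceiling(b) - 1, from - 1)
    w <- pmin(js + 1, b) - pmax(js, a)
    A[i, js + 1] <- w / sum(w)
  }
  A
}

# Tile (3D stack or 2D MIP) -> normalized input_size x input_size matrix.
# Normalization: 1st-99th percentile scaling, clipped to [0, 1].
prepare_tile_input <- function(tile, input_size) {
  m <- if (is.matrix(tile)) tile else mip(tile, axis = 3L)
  if (nrow(m) != input_size || ncol(m) != input_size) {
    Ar <- resize_matrix(nrow(m), input_size)
    Ac <- resize_matrix(ncol(m), input_size)
    m <- Ar %*% m %*% t(Ac)
  }
  q <- stats::quantile(m, c(0.01, 0.99), names = FALSE)
  if (q[2] > q[1]) {
    m <- (m - q[1]) / (q[2] - q[1])
    m[m < 0] <- 0
    m[m > 1] <- 1
  } else {
    m[] <- 0
  }
  m
}

# Stack a list of tiles into the network input array [H, W, 1, N].
prepare_inputs <- function(tiles, input_size) {
  n <- length(tiles)
  X <- array(0, dim = c(input_size, input_size, 1L, n))
  for (i in seq_len(n))
    X[, , 1L, i] <- prepare_tile_input(tiles[[i]], input_size)
  X
}

# ---- layers ----------------------------------------------------------------

# 3x3 same-padding convolution forward.
# X [H, W, Cin, B], W_mat [9*Cin, Cout] -> list(Y [H, W, Cout, B], cols)
conv3x3_forward <- function(X, W_mat, bias) {
  d <- dim(X); H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- ncol(W_mat)
  Xp <- array(0, dim = c(H + 2L, W + 2L, Cin, B))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  cols <- array(0, dim = c(H, W, B, 9L * Cin))
  s <- 0L
  for (dj in 0:2) for (di in 0:2) {
    sub <- Xp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    cols[, , , s * Cin + seq_len(Cin)] <- aperm(sub, c(1, 2, 4, 3))
    s <- s + 1L
  }
  dim(cols) <- c(H * W * B, 9L * Cin)
  Y <- cols %*% W_mat
  Y <- sweep(Y, 2L, bias, "+")
  dim(Y) <- c(H, W, B, Cout)
  list(Y = aperm(Y, c(1, 2, 4, 3)), cols = cols)
}

# Backward pass of conv3x3. dY [H, W, Cout, B].
conv3x3_backward <- function(dY, cols, W_mat, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]; Cin <- in_dim[3]; B <- in_dim[4]
  Cout <- ncol(W_mat)
  dYm <- aperm(dY, c(1, 2, 4, 3))
  dim(dYm) <- c(H * W * B, Cout)
  dW <- crossprod(cols, dYm)
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, W_mat)  # [H*W*B, 9*Cin]
  dim(dcols) <- c(H, W, B, 9L * Cin)
  dXp <- array(0, dim = c(H + 2L, W + 2L, Cin, B))
  s <- 0L
  for (dj in 0:2) for (di in 0:2) {
    piece <- dcols[, , , s * Cin + seq_len(Cin), drop = FALSE]
    dim(piece) <- c(H, W, B, Cin)
    dXp[di + seq_len(H), dj + seq_len(W), , ] <-
      dXp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] +
      aperm(piece, c(1, 2, 4, 3))
    s <- s + 1L
  }
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW, db = db)
}

# 2x2 max-pool; records the argmax quadrant for the backward pass.
maxpool2_forward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  q <- list(X[i1, j1, , , drop = FALSE], X[i2, j1, , , drop = FALSE],
            X[i1, j2, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
  best <- q[[1]]
  idx <- array(1L, dim = dim(best))
  for (k in 2:4) {
    upd <- q[[k]] > best
    best[upd] <- q[[k]][upd]
    idx[upd] <- k
  }
  list(Y = best, idx = idx)
}

maxpool2_backward <- function(dY, idx, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]
  dX <- array(0, dim = in_dim)
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  route <- function(k, ii, jj) {
    m <- idx == k
    g <- array(0, dim = dim(dY))
    g[m] <- dY[m]
    dX[ii, jj, , ] <<- g
  }
  route(1L, i1, j1); route(2L, i2, j1); route(3L, i1, j2); route(4L, i2, j2)
  dX
}

# ---- model -----------------------------------------------------------------

init_params <- function(config, seed) {
  set.seed(derive_seed(seed, 5L))
  params <- list()
  cin <- 1L
  for (b in seq_len(config$n_blocks)) {
    cout <- config$filters[b]
    fan_in <- 9L * cin
    params[[paste0("W", b)]] <-
      matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
    params[[paste0("b", b)]] <- numeric(cout)
    cin <- cout
  }
  params$Wd <- matrix(stats::rnorm(cin, 0, sqrt(1 / cin)), cin, 1L)
  params$bd <- 0
  params
}

count_params <- function(params)
  sum(vapply(params, length, 1L))

# Forward pass. Returns logits and (optionally) the caches for backprop.
cnn_forward <- function(params, X, n_blocks, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", n_blocks) else NULL
  A <- X
  for (b in seq_len(n_blocks)) {
    cv <- conv3x3_forward(A, params[[paste0("W", b)]],
                          params[[paste0("b", b)]])
    relu_mask <- cv$Y > 0
    R <- cv$Y * relu_mask
    mp <- maxpool2_forward(R)
    if (keep_cache)
      caches[[b]] <- list(cols = cv$cols, relu_mask = relu_mask,
                          in_dim = dim(A), relu_dim = dim(R),
                          pool_idx = mp$idx)
    A <- mp$Y
  }
  d <- dim(A)  # [h, w, C, B]
  feat_mat <- matrix(A, d[1] * d[2], d[3] * d[4])
  gap <- matrix(colMeans(feat_mat), d[3], d[4])  # [C, B]
  logits <- as.numeric(crossprod(gap, params$Wd) + params$bd)
  list(logits = logits, gap = gap, feat_dim = d, caches = caches)
}

cnn_backward <- function(params, fwd, dlogits, n_blocks) {
  grads <- list()
  d <- fwd$feat_dim
  grads$Wd <- fwd$gap %*% matrix(dlogits, ncol = 1)
  grads$bd <- sum(dlogits)
  dgap <- params$Wd %*% matrix(dlogits, nrow = 1)  # [C, B]
  # broadcast back over the pooled spatial positions
  dA <- array(0, dim = d)
  per <- 1 / (d[1] * d[2])
  dA[] <- rep(as.numeric(dgap), each = d[1] * d[2]) * per
  for (b in rev(seq_len(n_blocks))) {
    cache <- fwd$caches[[b]]
    dR <- maxpool2_backward(dA, cache$pool_idx, cache$relu_dim)
    dR <- dR * cache$relu_mask
    bk <- conv3x3_backward(dR, cache$cols, params[[paste0("W", b)]],
                           cache$in_dim)
    grads[[paste0("W", b)]] <- bk$dW
    grads[[paste0("b", b)]] <- bk$db
    dA <- bk$dX
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Build an untrained tile classification network
#'
#' The network is `n_blocks` of (3x3 convolution, ReLU, 2x2 max-pool) — each
#' block halves the spatial size — followed by global average pooling and a
#' single sigmoid output giving the probability that the tile is
#' informative.
#'
#' @param config A [classifier_config()].
#' @param input_shape Spatial input size `(rows, cols)`; must be square and
#'   divisible by `2^n_blocks`. Defaults to the config's `input_size`.
#' @param seed Seed for the parameter initialization.
#' @return An object of class `tile_cnn` (untrained): parameters, config,
#'   `n_params`, `final_feature_size`.
#' @examples
#' m <- build_classifier(classifier_config(n_blocks = 4L,
#'                                         filters = c(16L, 32L, 64L, 128L),
#'                                         input_size = 128L))
#' m$final_feature_size  # 8
#' @export
build_classifier <- function(config = classifier_config(),
                             input_shape = NULL, seed = config$seed) {
  stopifnot(inherits(config, "classifier_config"))
  if (!is.null(input_shape)) {
    input_shape <- as.integer(input_shape)
    if (length(input_shape) == 1L) input_shape <- rep(input_shape, 2L)
    if (input_shape[1] != input_shape[2])
      stop("network input must be square", call. = FALSE)
    if (input_shape[1] %% 2L^config$n_blocks != 0L)
      stop(sprintf("input size %d is not divisible by 2^%d",
                   input_shape[1], config$n_blocks), call. = FALSE)
    config$input_size <- input_shape[1]
  }
  params <- init_params(config, seed)
  structure(
    list(params = params, config = config, trained = FALSE,
         n_params = count_params(params),
         final_feature_size = as.integer(config$input_size %/% 2^config$n_blocks),
         log = NULL, best_epoch = NA_integer_,
         best_val_accuracy = NA_real_),
    class = "tile_cnn"
  )
}

#' @export
print.tile_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Tile classifier: %d conv blocks (%s filters), input %dx%d, %d parameters\n",
    cfg$n_blocks, paste(cfg$filters, collapse = "/"),
    cfg$input_size, cfg$input_size, x$n_params))
  if (x$trained)
    cat(sprintf("  trained: best validation accuracy %.4f at epoch %d\n",
                x$best_val_accuracy, x$best_epoch))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.tile_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("Training log (last rows):\n")
    print(utils::tail(object$log, 5))
  }
  invisible(object)
}

eval_batches <- function(params, X, y, n_blocks, batch_size) {
  n <- length(y)
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    f <- cnn_forward(params, X[, , , idx, drop = FALSE], n_blocks)
    p <- sigmoid(f$logits)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss <- loss - sum(y[idx] * log(p) + (1 - y[idx]) * log(1 - p))
    correct <- correct + sum((p >= 0.5) == (y[idx] == 1))
  }
  c(loss = loss / n, accuracy = correct / n)
}

#' Train the tile classification network
#'
#' Deterministic 80/20 train/validation split (per seed), minibatch Adam on
#' binary cross-entropy, early stopping on validation accuracy with the
#' configured patience, returning the parameters of the
#' best-validation-accuracy epoch. A per-epoch log (epoch, train loss, train
#' accuracy, validation loss, validation accuracy) is kept and optionally
#' written as CSV; improving checkpoints can be saved to a directory.
#'
#' @param dataset A balanced, labelled [make_tile_dataset()].
#' @param config A [classifier_config()].
#' @param seed Training seed (split, shuffling, initialization).
#' @param log_file Optional CSV path for the training log.
#' @param checkpoint_dir Optional directory; the model state at each epoch
#'   that improves the validation accuracy is saved there.
#' @param verbose Print per-epoch progress.
#' @return A trained `tile_cnn`; fields `log`, `best_epoch`,
#'   `best_val_accuracy`, `split` (the train/validation indices).
#' @export
train_classifier <- function(dataset, config = classifier_config(),
                             seed = config$seed, log_file = NULL,
                             checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "tile_dataset"),
            inherits(config, "classifier_config"))
  y <- dataset$labels
  if (length(unique(y)) < 2L)
    stop("dataset is degenerate: both classes are required for training",
         call. = FALSE)
  n <- length(y)
  set.seed(derive_seed(seed, 6L))
  perm <- sample.int(n)
  n_train <- floor(config$train_fraction * n)
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[(n_train + 1L):n]

  X <- prepare_inputs(dataset$tiles, config$input_size)
  Xtr <- X[, , , train_idx, drop = FALSE]
  ytr <- y[train_idx]
  Xva <- X[, , , val_idx, drop = FALSE]
  yva <- y[val_idx]
  rm(X)

  params <- init_params(config, seed)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  t_step <- 0L
  nb <- config$n_blocks
  bs <- config$batch_size

  log_rows <- list()
  best_val <- -Inf
  best_params <- params
  best_epoch <- 0L
  since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(seed, 1000L + epoch))
    ord <- sample.int(n_train)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n_train, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_train)]
      xb <- Xtr[, , , idx, drop = FALSE]
      yb <- ytr[idx]
      fwd <- cnn_forward(params, xb, nb, keep_cache = TRUE)
      p <- sigmoid(fwd$logits)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(pc) + (1 - yb) * log(1 - pc))
      ep_correct <- ep_correct + sum((p >= 0.5) == (yb == 1))
      dlogits <- (p - yb) / length(yb)
      grads <- cnn_backward(params, fwd, dlogits, nb)
      t_step <- t_step + 1L
      corr <- sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      for (nm in names(params)) {
        g <- grads[[nm]]
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] - lr * corr * m[[nm]] /
          (sqrt(v[[nm]]) + eps)
      }
    }
    val <- eval_batches(params, Xva, yva, nb, bs)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = ep_loss / n_train,
      train_accuracy = ep_correct / n_train,
      val_loss = unname(val["loss"]),
      val_accuracy = unname(val["accuracy"]))
    if (verbose)
      message(sprintf("epoch %d: train acc %.4f, val acc %.4f",
                      epoch, ep_correct / n_train, val["accuracy"]))
    if (val["accuracy"] > best_val) {
      best_val <- unname(val["accuracy"])
      best_params <- params
      best_epoch <- epoch
      since_best <- 0L
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(list(params = params, epoch = epoch,
                     val_accuracy = best_val),
                file.path(checkpoint_dir,
                          sprintf("checkpoint_epoch%03d.rds", epoch)))
      }
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience_epochs) break
    }
  }

  log_df <- do.call(rbind, log_rows)
  if (!is.null(log_file))
    utils::write.csv(log_df, log_file, row.names = FALSE)

  structure(
    list(params = best_params, config = config, trained = TRUE,
         n_params = count_params(best_params),
         final_feature_size = as.integer(config$input_size %/% 2^config$n_blocks),
         log = log_df, best_epoch = best_epoch,
         best_val_accuracy = best_val,
         split = list(train = train_idx, validation = val_idx),
         seed = seed),
    class = "tile_cnn"
  )
}

#' Predict informative-tile probabilities
#'
#' @param object A trained `tile_cnn`.
#' @param tiles A `tile_dataset` or list of tiles (3D arrays or 2D MIPs).
#' @param threshold Decision threshold; probabilities are clamped to
#'   `[1e-12, 1 - 1e-12]` and a tile is labelled informative iff
#'   `probability >= threshold`, so `threshold = 0` labels everything
#'   informative and `threshold = 1` nothing.
#' @param ... Unused.
#' @return A data frame of class `triage_result`: `id`, `score`
#'   (probability), `label`.
#' @export
predict.tile_cnn <- function(object, tiles,
                             threshold = object$config$probability_threshold,
                             ...) {
  if (!object$trained)
    warning("predicting with an untrained classifier", call. = FALSE)
  tl <- if (inherits(tiles, "tile_dataset")) tiles$tiles else tiles
  if (!is.list(tl)) tl <- list(tl)
  X <- prepare_inputs(tl, object$config$input_size)
  n <- length(tl)
  probs <- numeric(n)
  bs <- object$config$batch_size
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    f <- cnn_forward(object$params, X[, , , idx, drop = FALSE],
                     object$config$n_blocks)
    probs[idx] <- sigmoid(f$logits)
  }
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  out <- data.frame(
    id = seq_len(n), score = probs,
    label = ifelse(probs >= threshold, "informative", "non-informative"))
  class(out) <- c("triage_result", class(out))
  out
}
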