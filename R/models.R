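#' Stratified train/validation/test split
#'
#' Overall sizes follow the fixed rounding rule: train gets
#' `floor(f_train * n)` items, validation `round-half-up(f_val * n)`, test
#' the remainder (at the default 70/15/15 fractions a 90-item dataset splits
#' 63/14/13). Within each split, classes are allocated by largest-remainder
#' quotas, keeping per-class counts within one item of exact
#' proportionality.
#'
#' @param labels integer/factor vector of class labels, every class with at
#'   least 3 items.
#' @param fractions numeric length 3 summing to 1 (train, val, test).
#' @param seed integer seed for the per-class shuffles.
#' @return Object of class `dataset_split`: list with integer index vectors
#'   `train`, `val`, `test` (disjoint, union = all items), plus `fractions`,
#'   `seed`.
#' @export
stratified_split <- function(labels, fractions = c(0.70, 0.15, 0.15),
                             seed = 42L) {
  if (abs(sum(fractions)) - 1 > 1e-9 || length(fractions) != 3) {
    stop("`fractions` must be 3 numbers summing to 1")
  }
  labels <- as.integer(as.factor(labels))
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < 3)) {
    stop(sprintf("stratification needs >= 3 items per class (class %s has %d)",
                 names(tab)[which.min(tab)], min(tab)))
  }
  eps <- 1e-9 # guards floor() against binary representation of 0.70 * n
  n_train <- floor(fractions[1] * n + eps)
  n_val <- floor(fractions[2] * n + 0.5 + eps) # round half up
  n_test <- n - n_train - n_val
  classes <- as.integer(names(tab))
  nc <- as.integer(tab)
  quota <- function(total, already_taken) {
    # largest-remainder allocation of `total` among classes, capped by what
    # remains per class
    remaining <- nc - already_taken
    q <- total * nc / n
    base <- pmin(floor(q), remaining)
    short <- total - sum(base)
    if (short > 0) {
      pref <- order(q - floor(q), decreasing = TRUE)
      for (cl in pref) {
        if (short == 0) break
        add <- min(short, remaining[cl] - base[cl])
        base[cl] <- base[cl] + add
        short <- short - add
      }
    }
    base
  }
  tr_c <- quota(n_train, rep(0L, length(nc)))
  va_c <- quota(n_val, tr_c)
  te_c <- nc - tr_c - va_c
  train <- val <- test <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- sample(which(labels == classes[ci]))
      train <- c(train, idx[seq_len(tr_c[ci])])
      val <- c(val, idx[seq_len(va_c[ci]) + tr_c[ci]])
      test <- c(test, idx[seq_len(te_c[ci]) + tr_c[ci] + va_c[ci]])
    }
  })
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 fractions = fractions, seed = seed),
            class = "dataset_split")
}

#' Stratified k-fold partition
#'
#' Each item appears in exactly one test fold; folds are class-balanced by
#' cycling shuffled per-class indices over the folds.
#'
#' @param labels class labels, `length(labels) >= k`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` folds, each `list(train=, test=)` index vectors.
#' @export
kfold_split <- function(labels, k = 5L, seed = 42L) {
  labels <- as.integer(as.factor(labels))
  n <- length(labels)
  if (k > n) stop("`k` exceeds the number of items")
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# nearest-neighbor / block-average resize of an H x W (xC) array
.resize_array <- function(x, out_h, out_w) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h == out_h && w == out_w) return(x)
  if (h %% out_h == 0 && w %% out_w == 0) {
    fh <- h %/% out_h; fw <- w %/% out_w
    pool1 <- function(m) {
      m2 <- rowsum(m, rep(seq_len(out_h), each = fh))
      t(rowsum(t(m2), rep(seq_len(out_w), each = fw))) / (fh * fw)
    }
    if (length(d) == 2) return(pool1(x))
    out <- array(0, c(out_h, out_w, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- pool1(x[, , ch])
    return(out)
  }
  ri <- pmin(pmax(round(seq(1, h, length.out = out_h)), 1), h)
  ci <- pmin(pmax(round(seq(1, w, length.out = out_w)), 1), w)
  if (length(d) == 2) x[ri, ci] else x[ri, ci, , drop = FALSE]
}

#' Random augmentation of one image
#'
#' Independent draws from the current RNG: rotation angle uniform in
#' +/- 15 degrees (nearest-neighbor resampling, reflective fill),
#' horizontal and vertical flips each with probability 1/2, a
#' multiplicative brightness factor uniform in `[0.8, 1.2]` (clipped to the
#' 8-bit range), and center zoom uniform in `[0.9, 1.1]`
#' (crop / reflect-pad). Output shape always equals input shape.
#'
#' @param image [rgb_image] or numeric H x W (x C) array in `[0, 255]`.
#' @param seed optional seed; by default the surrounding RNG stream is used
#'   (so training epochs draw fresh augmentations reproducibly).
#' @return augmented object of the same type and shape.
#' @export
augment <- function(image, seed = NULL) {
  was_rgb <- inherits(image, "rgb_image")
  x <- if (was_rgb) array(as.numeric(image), dim(image)) else image
  draw <- function() {
    list(angle = stats::runif(1, -15, 15) * pi / 180,
         flip_h = stats::runif(1) < 0.5,
         flip_v = stats::runif(1) < 0.5,
         brightness = stats::runif(1, 0.8, 1.2),
         zoom = stats::runif(1, 0.9, 1.1))
  }
  pars <- if (is.null(seed)) draw() else with_seed(seed, draw())
  x <- .apply_augment(x, pars)
  if (was_rgb) rgb_image(x) else x
}

# geometric part only (no brightness/clip); used on prepared model inputs
.apply_geometric <- function(x, pars) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w) - cy
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ca <- cos(-pars$angle); sa <- sin(-pars$angle)
  ry <- (rows * ca - cols * sa) / pars$zoom + cy
  rx <- (rows * sa + cols * ca) / pars$zoom + cx
  ri <- .reflect_index(as.integer(round(ry)), h)
  ci <- .reflect_index(as.integer(round(rx)), w)
  gather <- function(m) matrix(m[cbind(as.vector(ri), as.vector(ci))], h, w)
  if (length(d) == 3) {
    for (ch in seq_len(d[3])) x[, , ch] <- gather(x[, , ch])
  } else x <- gather(x)
  if (pars$flip_h) x <- if (length(d) == 3) x[, w:1, , drop = FALSE] else x[, w:1]
  if (pars$flip_v) x <- if (length(d) == 3) x[h:1, , , drop = FALSE] else x[h:1, ]
  x
}

# deterministic geometric + photometric transform given drawn parameters
.apply_augment <- function(x, pars) {
  pmin(pmax(.apply_geometric(x, pars) * pars$brightness, 0), 255)
}

#' Categorical cross-entropy loss
#'
#' `-(1/N) * sum_ij y_ij log p_ij` with probabilities clipped to
#' `[1e-12, 1]`.
#'
#' @param y one-hot N x C matrix.
#' @param p probability N x C matrix, rows summing to 1.
#' @return mean loss (natural log).
#' @export
categorical_crossentropy <- function(y, p) {
  if (!identical(dim(y), dim(p))) stop("`y` and `p` shapes differ")
  p <- pmin(pmax(p, 1e-12), 1)
  -mean(rowSums(y * log(p)))
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.onehot <- function(y, C) {
  m <- matrix(0, length(y), C)
  m[cbind(seq_along(y), y)] <- 1
  m
}

.he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# ---- convolution primitives (channels-last, 3x3, pad 1, stride 1) ----

.kernel_offsets <- expand.grid(dr = -1:1, dc = -1:1)[, c("dr", "dc")]

.pad_hw <- function(x, p = 1L) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

.im2col <- function(x) { # x: H x W x C -> (H*W) x (9*C)
  d <- dim(x)
  pad <- .pad_hw(x)
  cols <- vector("list", 9L)
  for (o in 1:9) {
    dr <- .kernel_offsets$dr[o]; dc <- .kernel_offsets$dc[o]
    sl <- pad[1 + dr + seq_len(d[1]), 1 + dc + seq_len(d[2]), , drop = FALSE]
    dim(sl) <- c(d[1] * d[2], d[3])
    cols[[o]] <- sl
  }
  do.call(cbind, cols)
}

.col2im <- function(dcols, h, w, C) { # inverse scatter-add of .im2col
  pad <- array(0, c(h + 2, w + 2, C))
  for (o in 1:9) {
    dr <- .kernel_offsets$dr[o]; dc <- .kernel_offsets$dc[o]
    blk <- dcols[, (o - 1) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(h, w, C)
    rr <- 1 + dr + seq_len(h); cc <- 1 + dc + seq_len(w)
    pad[rr, cc, ] <- pad[rr, cc, ] + blk
  }
  pad[1 + seq_len(h), 1 + seq_len(w), , drop = FALSE]
}

.conv_fwd <- function(x, W, b) {
  d <- dim(x)
  Xc <- .im2col(x)
  Y <- Xc %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = array(Y, c(d[1], d[2], ncol(W))), Xc = Xc)
}

.conv_bwd <- function(dout, cache_Xc, W, h, w, C_in) {
  dY <- dout
  dim(dY) <- c(h * w, ncol(W))
  list(dW = crossprod(cache_Xc, dY), db = colSums(dY),
       dx = .col2im(dY %*% t(W), h, w, C_in))
}

.pool_fwd <- function(x) { # 2x2 max pool, stride 2
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  q <- list(x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE],
            x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE],
            x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE],
            q4 = x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE])
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  which_q <- 1L * (q[[1]] == out)
  which_q[which_q == 0 & q[[2]] == out] <- 2L
  which_q[which_q == 0 & q[[3]] == out] <- 3L
  which_q[which_q == 0] <- 4L
  list(out = out, which = which_q, in_dim = d)
}

.pool_bwd <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  sel <- list(list(seq(1, d[1], 2), seq(1, d[2], 2)),
              list(seq(2, d[1], 2), seq(1, d[2], 2)),
              list(seq(1, d[1], 2), seq(2, d[2], 2)),
              list(seq(2, d[1], 2), seq(2, d[2], 2)))
  for (qi in 1:4) {
    mask <- (cache$which == qi) * dout
    dx[sel[[qi]][[1]], sel[[qi]][[2]], ] <- dx[sel[[qi]][[1]], sel[[qi]][[2]], ] + mask
  }
  dx
}

# ---- model construction ----

#' Build a burn-depth classifier
#'
#' Three architectures over the 3 burn-depth classes:
#' \describe{
#'   \item{cnn}{three 3x3 convolution blocks (32, 64, 128 filters, ReLU,
#'     2x2 max-pool), dropout 0.25, a 128-unit dense layer and a 3-way
#'     softmax; consumes the L,u,v planes stacked as 3 channels, resized to
#'     `input_size` (architecture default 224).}
#'   \item{fnn}{dense stack (32, 16 hidden units, ReLU) on the 10-value
#'     texture feature vector, softmax output.}
#'   \item{rnn}{vanilla tanh recurrence over the rows of the
#'     `input_size x input_size` downsampled L plane (one row per timestep),
#'     64 hidden units, softmax on the final hidden state.}
#' }
#' Weights use seeded He-normal initialization; the forward pass on any
#' batch returns rows summing to 1.
#'
#' @param kind `"cnn"`, `"fnn"` or `"rnn"`.
#' @param input_size square input side for cnn/rnn (must be divisible by 8
#'   for the cnn).
#' @param n_classes output classes (default 3).
#' @param seed integer seed for initialization.
#' @return Object of class `burn_model`.
#' @export
build_model <- function(kind = c("cnn", "fnn", "rnn"), input_size = 224L,
                        n_classes = 3L, seed = 42L) {
  kind <- match.arg(kind)
  S <- as.integer(input_size)
  params <- with_seed(seed, switch(kind,
    cnn = {
      if (S %% 8L != 0L) stop("cnn `input_size` must be divisible by 8")
      flat <- (S %/% 8L)^2 * 128L
      list(W1 = .he_init(27, 32), b1 = numeric(32),
           W2 = .he_init(288, 64), b2 = numeric(64),
           W3 = .he_init(576, 128), b3 = numeric(128),
           W4 = .he_init(flat, 128), b4 = numeric(128),
           W5 = .he_init(128, n_classes), b5 = numeric(n_classes))
    },
    fnn = list(W1 = .he_init(10, 32), b1 = numeric(32),
               W2 = .he_init(32, 16), b2 = numeric(16),
               W3 = .he_init(16, n_classes), b3 = numeric(n_classes)),
    rnn = list(Wxh = .he_init(S, 64), Whh = .he_init(64, 64, fan_in = 64),
               bh = numeric(64),
               Why = .he_init(64, n_classes), by = numeric(n_classes))
  ))
  structure(list(kind = kind, input_size = S, n_classes = as.integer(n_classes),
                 params = params, seed = as.integer(seed),
                 feature_center = NULL, feature_scale = NULL),
            class = "burn_model")
}

#' @export
print.burn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<burn_model %s, input %d, %d classes, %d parameters>\n",
              x$kind, x$input_size, x$n_classes, np))
  invisible(x)
}

# forward pass for a single cnn sample; returns logits + caches
.cnn_forward1 <- function(p, x, drop_mask = NULL) {
  c1 <- .conv_fwd(x, p$W1, p$b1); a1 <- pmax(c1$out, 0)
  p1 <- .pool_fwd(a1)
  c2 <- .conv_fwd(p1$out, p$W2, p$b2); a2 <- pmax(c2$out, 0)
  p2 <- .pool_fwd(a2)
  c3 <- .conv_fwd(p2$out, p$W3, p$b3); a3 <- pmax(c3$out, 0)
  p3 <- .pool_fwd(a3)
  flat <- as.vector(p3$out)
  if (!is.null(drop_mask)) flat <- flat * drop_mask
  z4 <- as.vector(flat %*% p$W4) + p$b4
  a4 <- pmax(z4, 0)
  logits <- as.vector(a4 %*% p$W5) + p$b5
  list(logits = logits, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
       c3 = c3, a3 = a3, p3 = p3, flat = flat, a4 = a4, x = x)
}

.cnn_backward1 <- function(p, fw, dlogits, drop_mask = NULL) {
  g <- list()
  g$W5 <- outer(fw$a4, dlogits); g$b5 <- dlogits
  da4 <- as.vector(p$W5 %*% dlogits) * (fw$a4 > 0)
  g$W4 <- outer(fw$flat, da4); g$b4 <- da4
  dflat <- as.vector(p$W4 %*% da4)
  if (!is.null(drop_mask)) dflat <- dflat * drop_mask
  d3 <- dim(fw$p3$out)
  dp3 <- array(dflat, d3)
  da3 <- .pool_bwd(dp3, fw$p3) * (fw$a3 > 0)
  b3 <- .conv_bwd(da3, fw$c3$Xc, p$W3, dim(fw$a3)[1], dim(fw$a3)[2], 64L)
  g$W3 <- b3$dW; g$b3 <- b3$db
  da2 <- .pool_bwd(b3$dx, fw$p2) * (fw$a2 > 0)
  b2 <- .conv_bwd(da2, fw$c2$Xc, p$W2, dim(fw$a2)[1], dim(fw$a2)[2], 32L)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- .pool_bwd(b2$dx, fw$p1) * (fw$a1 > 0)
  b1 <- .conv_bwd(da1, fw$c1$Xc, p$W1, dim(fw$a1)[1], dim(fw$a1)[2], 3L)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

.fnn_forward <- function(p, X) {
  z1 <- sweep(X %*% p$W1, 2, p$b1, "+"); a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% p$W2, 2, p$b2, "+"); a2 <- pmax(z2, 0)
  logits <- sweep(a2 %*% p$W3, 2, p$b3, "+")
  list(logits = logits, X = X, a1 = a1, a2 = a2)
}

.fnn_backward <- function(p, fw, dlogits) {
  g <- list()
  g$W3 <- crossprod(fw$a2, dlogits); g$b3 <- colSums(dlogits)
  da2 <- (dlogits %*% t(p$W3)) * (fw$a2 > 0)
  g$W2 <- crossprod(fw$a1, da2); g$b2 <- colSums(da2)
  da1 <- (da2 %*% t(p$W2)) * (fw$a1 > 0)
  g$W1 <- crossprod(fw$X, da1); g$b1 <- colSums(da1)
  g
}

.rnn_forward1 <- function(p, x) { # x: T x F matrix of row-sequences
  T_ <- nrow(x)
  H <- matrix(0, T_ + 1, ncol(p$Whh))
  for (t in seq_len(T_)) {
    H[t + 1, ] <- tanh(x[t, ] %*% p$Wxh + H[t, ] %*% p$Whh + p$bh)
  }
  logits <- as.vector(H[T_ + 1, ] %*% p$Why) + p$by
  list(logits = logits, H = H, x = x)
}

.rnn_backward1 <- function(p, fw, dlogits) {
  T_ <- nrow(fw$x)
  g <- list(Wxh = 0 * p$Wxh, Whh = 0 * p$Whh, bh = 0 * p$bh,
            Why = outer(fw$H[T_ + 1, ], dlogits), by = dlogits)
  dh <- as.vector(p$Why %*% dlogits)
  for (t in rev(seq_len(T_))) {
    dz <- dh * (1 - fw$H[t + 1, ]^2)
    g$Wxh <- g$Wxh + outer(fw$x[t, ], dz)
    g$Whh <- g$Whh + outer(fw$H[t, ], dz)
    g$bh <- g$bh + dz
    dh <- as.vector(p$Whh %*% dz)
  }
  g
}

# model inputs from a phantom dataset, per architecture
#' Prepare classifier inputs from a phantom dataset
#'
#' cnn: L,u,v planes (scaled to roughly unit range) resized to the model
#' input size, per-sample `S x S x 3` arrays. fnn: the 10-value
#' [feature_vector] per sample. rnn: the resized L plane as a row-sequence
#' matrix.
#'
#' @param dataset [generate_dataset] result.
#' @param kind `"cnn"`, `"fnn"` or `"rnn"`.
#' @param input_size square side for cnn/rnn inputs.
#' @param G,d texture parameters for fnn features.
#' @return list of per-sample inputs (fnn: a single N x 10 matrix).
#' @export
prepare_inputs <- function(dataset, kind, input_size = 32L, G = 8L, d = 1L) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (kind == "fnn") {
    ft <- dataset_features(dataset, G = G, d = d)
    return(as.matrix(ft[, grep("^src_", names(ft))]))
  }
  lapply(dataset$phantoms, function(ph) {
    rgb_small <- .resize_array(array(as.numeric(ph$image), dim(ph$image)),
                               input_size, input_size)
    luv <- rgb_to_luv(rgb_image(rgb_small))
    if (kind == "cnn") {
      x <- array(0, c(input_size, input_size, 3L))
      x[, , 1] <- luv$L / 100; x[, , 2] <- luv$u / 100; x[, , 3] <- luv$v / 100
      x
    } else {
      luv$L / 100
    }
  })
}

#' Training configuration
#'
#' @param epochs training epochs (protocol default 50).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param augment apply random [augment] draws to cnn/rnn training images
#'   each epoch.
#' @param seed integer seed covering shuffling, dropout and augmentation.
#' @param dropout dropout rate on the cnn flattened features.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, lr = 1e-3, batch_size = 8L,
                         augment = TRUE, seed = 42L, dropout = 0.25) {
  stopifnot(epochs >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), augment = augment,
                 seed = as.integer(seed), dropout = dropout),
            class = "train_config")
}

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# augmentation of prepared cnn/rnn inputs: geometric transform on all
# planes, brightness on the luminance plane only (clipped to its [0,1] range)
.augment_input <- function(x, kind) {
  pars <- list(angle = stats::runif(1, -15, 15) * pi / 180,
               flip_h = stats::runif(1) < 0.5,
               flip_v = stats::runif(1) < 0.5,
               brightness = stats::runif(1, 0.8, 1.2),
               zoom = stats::runif(1, 0.9, 1.1))
  x <- .apply_geometric(x, pars)
  if (kind == "cnn") {
    x[, , 1] <- pmin(pmax(x[, , 1] * pars$brightness, 0), 1)
  } else {
    x <- pmin(pmax(x * pars$brightness, 0), 1)
  }
  x
}

#' Train a burn-depth classifier
#'
#' Minimizes categorical cross-entropy with Adam on shuffled minibatches;
#' images are re-augmented every epoch when enabled. Fully deterministic in
#' `cfg$seed`. FNN inputs are standardized with statistics of the training
#' set, stored in the model.
#'
#' @param model [build_model] result.
#' @param inputs [prepare_inputs] result for the matching `kind`.
#' @param labels integer class labels (1-based) for all samples.
#' @param split [stratified_split] result; `split$train` trains, `split$val`
#'   (if nonempty) is monitored.
#' @param cfg [train_config].
#' @return trained `burn_model` with a `history` data.frame (epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, inputs, labels, split, cfg = train_config()) {
  stopifnot(inherits(model, "burn_model"))
  C <- model$n_classes
  p <- model$params
  kind <- model$kind
  if (kind == "fnn") {
    mu <- colMeans(inputs[split$train, , drop = FALSE])
    sd_ <- apply(inputs[split$train, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    model$feature_center <- mu
    model$feature_scale <- sd_
    X <- sweep(sweep(inputs, 2, mu), 2, sd_, "/")
  }
  adam <- .adam_new(p)
  hist_rows <- vector("list", cfg$epochs)
  keep <- 1 - cfg$dropout
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample(split$train)
      ep_loss <- 0; ep_hits <- 0
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      for (bt in batches) {
        if (kind == "fnn") {
          fw <- .fnn_forward(p, X[bt, , drop = FALSE])
          probs <- .softmax(fw$logits)
          yh <- .onehot(labels[bt], C)
          ep_loss <- ep_loss + categorical_crossentropy(yh, probs) * length(bt)
          ep_hits <- ep_hits + sum(max.col(probs, "first") == labels[bt])
          grads <- .fnn_backward(p, fw, (probs - yh) / length(bt))
          if (anyNA(grads$W1)) stop(sprintf("training diverged at epoch %d", ep))
        } else {
          grads <- NULL
          for (i in bt) {
            x <- inputs[[i]]
            if (cfg$augment) x <- .augment_input(x, kind)
            if (kind == "cnn") {
              dm <- (stats::runif(nrow(p$W4)) < keep) / keep
              fw <- .cnn_forward1(p, x, drop_mask = dm)
            } else {
              fw <- .rnn_forward1(p, x)
            }
            probs <- .softmax(matrix(fw$logits, 1))
            yh <- .onehot(labels[i], C)
            ep_loss <- ep_loss + categorical_crossentropy(yh, probs)
            ep_hits <- ep_hits + (which.max(probs) == labels[i])
            dl <- as.vector(probs - yh) / length(bt)
            gi <- if (kind == "cnn") .cnn_backward1(p, fw, dl, drop_mask = dm)
                  else .rnn_backward1(p, fw, dl)
            grads <- if (is.null(grads)) gi
                     else Map(`+`, grads, gi)
          }
          if (anyNA(grads[[1]])) stop(sprintf("training diverged at epoch %d", ep))
        }
        st <- .adam_step(p, grads, adam, cfg$lr)
        p <- st$params; adam <- st$state
      }
      n_tr <- length(idx)
      row <- data.frame(epoch = ep, train_loss = ep_loss / n_tr,
                        train_acc = ep_hits / n_tr,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (length(split$val) > 0) {
        model$params <- p
        ev <- .predict_probs(model, inputs, split$val,
                             X_std = if (kind == "fnn") X else NULL)
        yv <- .onehot(labels[split$val], C)
        row$val_loss <- categorical_crossentropy(yv, ev)
        row$val_acc <- mean(max.col(ev, "first") == labels[split$val])
      }
      hist_rows[[ep]] <- row
    }
  })
  model$params <- p
  model$history <- do.call(rbind, hist_rows)
  model
}

.predict_probs <- function(model, inputs, idx, X_std = NULL) {
  p <- model$params
  if (model$kind == "fnn") {
    X <- if (!is.null(X_std)) X_std[idx, , drop = FALSE] else
      sweep(sweep(inputs[idx, , drop = FALSE], 2, model$feature_center),
            2, model$feature_scale, "/")
    return(.softmax(.fnn_forward(p, X)$logits))
  }
  out <- matrix(0, length(idx), model$n_classes)
  for (k in seq_along(idx)) {
    fw <- if (model$kind == "cnn") .cnn_forward1(p, inputs[[idx[k]]])
          else .rnn_forward1(p, inputs[[idx[k]]])
    out[k, ] <- .softmax(matrix(fw$logits, 1))
  }
  out
}

#' Class probabilities for a set of samples
#'
#' @param model trained [build_model].
#' @param inputs [prepare_inputs] result.
#' @param idx indices to score (default all).
#' @return N x n_classes probability matrix (rows sum to 1).
#' @export
predict_model <- function(model, inputs,
                          idx = if (is.matrix(inputs)) seq_len(nrow(inputs))
                                else seq_along(inputs)) {
  .predict_probs(model, inputs, idx)
}

#' Classification metrics
#'
#' Confusion matrix (rows = truth, columns = prediction), accuracy,
#' per-class precision / recall / F1, and their macro (unweighted) and
#' weighted (support-weighted) averages. A class absent from both truth and
#' prediction gets zero metrics and is flagged.
#'
#' @param truth integer labels (1-based).
#' @param pred integer predicted labels, same length.
#' @param n_classes class count.
#' @return Object of class `eval_metrics`: list with `confusion`,
#'   `accuracy`, `per_class` (data.frame), `macro`, `weighted`,
#'   `absent_classes`.
#' @export
evaluate_predictions <- function(truth, pred, n_classes = max(truth, pred)) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  C <- n_classes
  conf <- matrix(0L, C, C)
  for (i in seq_along(truth)) {
    conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  }
  tp <- diag(conf)
  support <- rowSums(conf)
  predn <- colSums(conf)
  prec <- ifelse(predn > 0, tp / predn, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  absent <- which(support == 0 & predn == 0)
  w <- support / sum(support)
  structure(list(
    confusion = conf,
    accuracy = sum(tp) / sum(conf),
    per_class = data.frame(class = seq_len(C), precision = prec,
                           recall = rec, f1 = f1, support = support),
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted = c(precision = sum(w * prec), recall = sum(w * rec),
                 f1 = sum(w * f1)),
    absent_classes = absent
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-F1 %.4f | weighted-F1 %.4f\n",
              x$accuracy, x$macro[["f1"]], x$weighted[["f1"]]))
  print(x$confusion)
  invisible(x)
}

#' Collapse three burn-depth classes to binary severity
#'
#' Maps class labels 1 (superficial) and 2 (dermal) to severity 1
#' ("at most dermal") and class 3 (deep) to severity 2, so three-class
#' predictions can be scored as a binary deep-vs-rest problem.
#'
#' @param labels integer labels in 1..3.
#' @return integer labels in 1..2.
#' @export
collapse_severity <- function(labels) {
  if (any(!labels %in% 1:3)) stop("labels must lie in 1..3")
  ifelse(labels == 3, 2L, 1L)
}

#' Evaluate a trained model on held-out samples
#'
#' @param model trained [build_model].
#' @param inputs [prepare_inputs] result.
#' @param labels integer labels for all samples.
#' @param idx indices of the held-out items.
#' @return [evaluate_predictions] result.
#' @export
evaluate_model <- function(model, inputs, labels, idx) {
  probs <- .predict_probs(model, inputs, idx)
  evaluate_predictions(labels[idx], max.col(probs, "first"),
                       n_classes = model$n_classes)
}
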