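# Classifier backend for visual identification.
#
# The backend contract: `fit(X, y, ...)` on feature rows with integer class
# labels, and `predict(X)` returning one probability row per image, rows
# summing to 1.  Any backend honouring the contract (e.g. a CNN) can be
# plugged into the accumulation machinery; the reference backend shipped
# here is a gradient-trained linear softmax on 16x16 down-sampled crops --
# deterministic given its seed and fast enough for batch pipelines without
# a GPU.

#' Down-sample a grayscale image by block averaging
#'
#' @param img numeric matrix.
#' @param size target side length (square output).
#' @return `size` x `size` matrix.
#' @export
downsample_image <- function(img, size = 16) {
  h <- nrow(img); w <- ncol(img)
  ri <- ceiling(seq_len(h) / (h / size))
  ci <- ceiling(seq_len(w) / (w / size))
  acc <- rowsum(img, ri)
  acc <- t(rowsum(t(acc), ci))
  cnt <- outer(tabulate(ri, size), tabulate(ci, size))
  acc / cnt
}

# image (0..255) -> feature vector in [-1, 1]
crop_features <- function(img, size = 16) {
  as.vector(downsample_image(img, size)) / 127.5 - 1
}

#' Linear softmax backend
#'
#' Multinomial logistic regression trained by full-batch Adam on the
#' categorical focal loss (focusing parameter `gamma`).  Training stops when
#' any of the usual criteria fires: the epoch budget is reached, validation
#' accuracy plateaus (< 1e-3 improvement over five epochs), validation loss
#' rises for five consecutive epochs while training loss falls (overfitting),
#' or training accuracy hits 1.  Optional augmentation shifts training crops
#' by one pixel in x.  All randomness (validation split, balancing,
#' augmentation) flows from `seed`; refitting with identical inputs is
#' bit-identical.
#'
#' @param n_classes number of identities.
#' @param input_size side length of the (square) down-sampled input crop.
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param gamma focal-loss focusing parameter.
#' @return object of class `btx_backend` (an environment) with functions
#'   `fit(X, y, max_epochs, validation_split, reset, augment)`, `predict(X)`,
#'   `get_state()`, `set_state(s)`.
#' @export
backend_linear <- function(n_classes, input_size = 32, seed = 1,
                           lr = 0.02, gamma = 2) {
  be <- new.env(parent = emptyenv())
  be$n_classes <- as.integer(n_classes)
  be$input_size <- as.integer(input_size)
  be$seed <- as.integer(seed)
  be$n_feat <- be$input_size^2 + 1L
  be$W <- matrix(0, be$n_feat, be$n_classes)
  be$mu <- rep(0, be$input_size^2)
  be$fit_count <- 0L

  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  be$predict <- function(X) {
    X <- cbind(sweep(X, 2, be$mu), 1)
    P <- softmax(X %*% be$W)
    colnames(P) <- seq_len(be$n_classes) - 1L
    P
  }
  be$get_state <- function() list(W = be$W, mu = be$mu)
  be$set_state <- function(s) { be$W <- s$W; be$mu <- s$mu; invisible(NULL) }

  # x-shift augmentation on flattened size x size crops
  shift_x <- function(X, k) {
    if (k == 0) return(X)
    s <- be$input_size
    A <- array(t(X), c(s, s, nrow(X)))   # [row, col, img]
    B <- array(-1, dim(A))               # background value after scaling
    if (k > 0) B[, (k + 1):s, ] <- A[, 1:(s - k), , drop = FALSE]
    else B[, 1:(s + k), ] <- A[, (1 - k):s, , drop = FALSE]
    t(matrix(B, s * s, nrow(X)))
  }

  be$fit <- function(X, y, max_epochs = 150, validation_split = 0.2,
                     reset = TRUE, augment = TRUE) {
    stopifnot(nrow(X) == length(y))
    y <- as.integer(y)                   # classes 0..n_classes-1
    be$fit_count <- be$fit_count + 1L
    with_seed(derive_seed(be$seed, 31L, be$fit_count), {
      n <- nrow(X)
      if (validation_split > 0 && n >= 10) {
        # stratified split, one fifth per class to validation
        val <- unlist(lapply(split(seq_len(n), y), function(ix)
          sample(ix, max(1, floor(length(ix) * validation_split)))))
      } else val <- integer(0)
      tr <- setdiff(seq_len(n), val)
      Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
      Xv <- X[val, , drop = FALSE]; yv <- y[val]
      if (reset) be$W <- matrix(0, be$n_feat, be$n_classes)
      # centring the features improves the conditioning of the problem
      be$mu <- colMeans(Xt)
      Xt <- sweep(Xt, 2, be$mu)
      M <- V <- matrix(0, be$n_feat, be$n_classes)
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      hist <- vector("list", max_epochs)
      stop_reason <- "max_epochs"
      Yt <- matrix(0, length(yt), be$n_classes)
      Yt[cbind(seq_along(yt), yt + 1L)] <- 1
      for (ep in seq_len(max_epochs)) {
        Xa <- if (augment) shift_x(Xt, sample(-1:1, 1)) else Xt
        Xa1 <- cbind(Xa, 1)
        P <- softmax(Xa1 %*% be$W)
        pt <- P[cbind(seq_along(yt), yt + 1L)]
        pt <- pmax(pt, 1e-12)
        # focal loss and its gradient w.r.t. the logits
        floss <- mean(-(1 - pt)^gamma * log(pt))
        dLdp <- gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
        G <- (P - Yt) * (-dLdp * pt) / length(yt)   # chain rule via p_t
        grad <- t(Xa1) %*% G
        M <- b1 * M + (1 - b1) * grad
        V <- b2 * V + (1 - b2) * grad^2
        mh <- M / (1 - b1^ep); vh <- V / (1 - b2^ep)
        be$W <- be$W - lr * mh / (sqrt(vh) + eps)
        tr_acc <- mean(max.col(P) == yt + 1L)
        if (length(val)) {
          Pv <- be$predict(Xv)
          pv <- pmax(Pv[cbind(seq_along(yv), yv + 1L)], 1e-12)
          val_loss <- mean(-(1 - pv)^gamma * log(pv))
          val_acc <- mean(max.col(Pv) == yv + 1L)
        } else { val_loss <- floss; val_acc <- tr_acc }
        hist[[ep]] <- c(epoch = ep, train_loss = floss, train_acc = tr_acc,
                        val_loss = val_loss, val_acc = val_acc)
        if (tr_acc >= 1 && ep >= 5) { stop_reason <- "train_accuracy_1"; break }
        if (ep >= 10) {
          h <- do.call(rbind, hist[(ep - 5):ep])
          # a plateau only counts once per-class accuracy is already high
          if (h[1, "val_acc"] >= 0.9 &&
              max(h[, "val_acc"]) - h[1, "val_acc"] < 1e-3 &&
              h[1, "val_acc"] >= h[nrow(h), "val_acc"]) {
            stop_reason <- "plateau"; break
          }
          vl <- h[, "val_loss"]; tl <- h[, "train_loss"]
          if (all(diff(vl) > 0) && all(diff(tl) < 0)) {
            stop_reason <- "overfitting"; break
          }
        }
      }
      hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
      list(history = hist, stop_reason = stop_reason,
           val_acc = hist$val_acc[nrow(hist)],
           epochs = nrow(hist))
    })
  }
  class(be) <- "btx_backend"
  be
}

#' @export
print.btx_backend <- function(x, ...) {
  cat(sprintf("<linear softmax backend: %d classes, %dx%d input>\n",
              x$n_classes, x$input_size, x$input_size))
  invisible(x)
}
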