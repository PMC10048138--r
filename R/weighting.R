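# Median-frequency class balancing and the pixel-wise weighted
# cross-entropy loss it feeds.

#' Median-frequency class weights
#'
#' For class frequencies `F` returns `W_i = median(F) / F_i`. Classes rarer
#' than the median get weights above one, common classes below one; for an
#' even number of classes the harmonic mean of the two weights whose source
#' frequencies straddle the median is exactly one. Only relative frequencies
#' matter: rescaling `F` by a constant leaves the weights unchanged.
#'
#' @param f numeric vector of class frequencies, all strictly positive.
#' @return object of class `class_weights` (a numeric vector).
#' @export
median_frequency_weights <- function(f) {
  if (any(!is.finite(f)) || any(f < 0))
    stop("median_frequency_weights: frequencies must be finite and non-negative")
  if (any(f == 0))
    stop("median_frequency_weights: zero frequency for a class; drop the class ",
         "or floor its frequency before weighting")
  w <- stats::median(f) / f
  structure(as.numeric(w), class = "class_weights")
}

#' Pixel-wise weighted softmax cross-entropy
#'
#' Mean over all pixels of `W_label * (-log softmax(scores)_label)`. The
#' normalisation is by the total pixel count, not by the sum of weights, so
#' the loss scale (and hence learning-rate semantics) is independent of the
#' weight vector's scale. With unit weights this is the ordinary multi-class
#' cross-entropy.
#'
#' @param scores `H x W x C` (or `H x W x C x N`) array of class scores.
#' @param labels `H x W` (or `H x W x N`) integer grid of codes in
#'   `[0, C - 1]`.
#' @param weights a `class_weights` vector from [median_frequency_weights()] (or any positive numeric of
#'   length C).
#' @return non-negative scalar loss.
#' @export
weighted_pixel_loss <- function(scores, labels, weights) {
  wce_loss_grad(scores, labels, weights, want_grad = FALSE)$loss
}

# shared implementation: loss and (optionally) gradient wrt scores
wce_loss_grad <- function(scores, labels, weights, want_grad = TRUE) {
  d <- dim(scores)
  if (length(d) == 3) dim(scores) <- c(d[1], d[2], d[3], 1L)
  d <- dim(scores)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (any(!is.finite(scores))) stop("weighted_pixel_loss: non-finite scores")
  lab <- as.integer(labels)
  if (any(lab < 0 | lab >= C)) stop("weighted_pixel_loss: label outside [0, C)")

  s <- aperm(scores, c(1, 2, 4, 3))       # H, W, N, C
  dim(s) <- c(H * W * N, C)
  m <- do.call(pmax, c(lapply(seq_len(C), function(j) s[, j])))
  p <- exp(s - m)
  p <- p / rowSums(p)
  npix <- H * W * N
  idx <- cbind(seq_len(npix), lab + 1L)
  wl <- as.numeric(weights)[lab + 1L]
  loss <- sum(wl * -log(pmax(p[idx], 1e-300))) / npix
  if (!want_grad) return(list(loss = loss))

  g <- p * wl
  g[idx] <- g[idx] - wl
  g <- g / npix
  dim(g) <- c(H, W, N, C)
  g <- aperm(g, c(1, 2, 4, 3))
  list(loss = loss, grad = g)
}
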