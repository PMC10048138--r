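# Atrous (dilated) convolution and the atrous-spatial-pyramid-pooling block.

#' Atrous (dilated) convolution of a signal or image
#'
#' Correlates `f` with `w` sampling the input with gaps of `k - 1` positions
#' between taps (`h_i = sum_n f_{i + k*n} w_n`, taps centred on the output
#' position), under zero same-padding, along one axis for a vector input or
#' both axes for a matrix input. With `k = 1` this reverts to a conventional
#' convolution. Equivalent to convolving with the kernel obtained by
#' inserting `k - 1` zeros between the taps of `w`.
#'
#' @param f numeric vector or matrix.
#' @param w odd-length numeric vector (1-D) or odd-sized matrix (2-D) of
#'   filter taps.
#' @param k dilation rate, integer >= 1.
#' @return object of the same shape as `f`.
#' @export
atrous_conv <- function(f, w, k = 1L) {
  if (k < 1) stop("atrous_conv: dilation rate k must be >= 1")
  k <- as.integer(k)
  if (is.null(dim(f))) {
    n <- length(w)
    if (n %% 2 == 0) stop("atrous_conv: filter length must be odd")
    half <- (n - 1L) %/% 2L
    out <- numeric(length(f))
    for (t in seq_len(n)) {
      off <- (t - 1L - half) * k
      src <- seq_along(f) + off
      ok <- src >= 1 & src <= length(f)
      out[ok] <- out[ok] + f[src[ok]] * w[t]
    }
    return(out)
  }
  if (any(dim(w) %% 2 == 0)) stop("atrous_conv: filter sides must be odd")
  x <- array(f, dim = c(dim(f), 1L, 1L))
  ww <- array(w, dim = c(dim(w), 1L, 1L))
  pad <- k * (dim(w)[1] - 1L) %/% 2L
  y <- cpp_conv2d_fwd(x, ww, NULL, 1L, pad, k, 1L)
  matrix(y, dim(f)[1], dim(f)[2])
}

#' Effective receptive field of a dilated kernel
#'
#' Span in pixels covered by an `n`-tap kernel at dilation `k`:
#' `n + (n - 1) (k - 1)`.
#'
#' @param n odd kernel size.
#' @param k dilation rate >= 1.
#' @return span in pixels.
#' @export
effective_receptive_field <- function(n, k) {
  if (n %% 2 == 0) stop("effective_receptive_field: even kernel sizes unsupported")
  if (k < 1) stop("effective_receptive_field: k must be >= 1")
  n + (n - 1) * (k - 1)
}

#' ASPP block specification
#'
#' Four parallel branches — a 1x1 convolution and three 3x3 atrous
#' convolutions at rates `k`, `2k`, `3k` — each followed by batch
#' normalisation and rectification; outputs are concatenated along channels
#' and fused by a 1x1 projection back to `branch_channels`.
#'
#' @param in_channels channels of the incoming high-level feature map.
#' @param branch_channels channels of each branch (default 256).
#' @param base_rate base dilation rate `k` (default 6, giving rates 6/12/18).
#' @return object of class `aspp_spec` with the derived `rates`.
#' @export
aspp_spec <- function(in_channels, branch_channels = 256L, base_rate = 6L) {
  if (base_rate < 1) stop("aspp_spec: base_rate must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 base_rate = as.integer(base_rate),
                 rates = as.integer(base_rate * c(1L, 2L, 3L))),
            class = "aspp_spec")
}

#' Build the ASPP module
#' @param spec an [aspp_spec].
#' @return an `nn_module` mapping `[H, W, in_channels, N]` to
#'   `[H, W, branch_channels, N]`; fields `$rates` and `$branches` expose the
#'   branch structure.
#' @export
build_aspp <- function(spec) {
  cb <- spec$branch_channels
  branches <- c(list(conv_bn_relu(spec$in_channels, cb, 1L)),
                lapply(spec$rates, function(r)
                  conv_bn_relu(spec$in_channels, cb, 3L, dilation = r)))
  m <- mod_seq(mod_parallel_concat(branches),
               conv_bn_relu(4L * cb, cb, 1L))
  m$rates <- spec$rates
  m$branches <- branches
  m$spec <- spec
  m
}
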