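# Full segmentation network: backbone -> ASPP -> decoder.
# The decoder up-samples the ASPP output x4, concatenates it with
# 1x1-projected low-level features, refines with two 3x3 convolutions and
# projects to per-class scores at input resolution.

#' Assemble a segmentation network from a model specification
#'
#' Pipeline: backbone (low tap at stride 4, high output at stride 16) ->
#' ASPP on the high-level features -> bilinear up-sample x4 -> concatenate
#' with projected low-level features -> two 3x3 conv-BN-ReLU blocks -> 1x1
#' convolution to `n_classes` score maps -> bilinear up-sample x4 back to
#' input resolution. The three named variants are `"mi-resnet50"` ->
#' MI-ResNet50-AC, `"mi-resnet18"` -> MI-ResNet18-AC, `"mi-mobilenetv2"` ->
#' MI-MobileNet-AC.
#'
#' When `width_multiplier < 1` the ASPP branch and decoder widths are thinned
#' by the same factor as the backbone.
#'
#' @param spec a [model_spec].
#' @param seed optional integer; when given, parameter initialisation
#'   (variance-scaling fan-in) is drawn under this seed so builds are
#'   reproducible.
#' @return object of class `segmentation_model` (an `nn_module`).
#' @export
build_myinet <- function(spec, seed = NULL) {
  builder <- function() {
    eps <- spec$width_multiplier
    backbone <- build_backbone(spec)
    cb <- scale_ch(256L, eps)
    aspp <- build_aspp(aspp_spec(backbone$high_channels, cb, spec$atrous_base_rate))
    c_low <- scale_ch(48L, eps)
    low_proj <- conv_bn_relu(backbone$low_channels, c_low, 1L)
    refine <- mod_seq(conv_bn_relu(c_low + cb, cb, 3L),
                      conv_bn_relu(cb, cb, 3L))
    head <- mod_conv(cb, spec$n_classes, 1L, bias = TRUE)
    up4a <- mod_bilinear(scale = 4)
    up4b <- mod_bilinear(scale = 4)

    m <- mod_new("segmentation_model")
    m$children <- list(backbone, aspp, low_proj, refine, head, up4a, up4b)
    m$spec <- spec
    m$backbone <- backbone
    m$aspp <- aspp
    m$forward <- function(x, training) {
      d <- dim(x)
      if (d[1] != d[2]) stop("model: input must be square")
      m$orig_hw <- d[1:2]
      delta <- spec$resolution_multiplier
      m$resized <- FALSE
      if (delta < 1) {
        side <- max(16L, as.integer(round(d[1] * delta / 16)) * 16L)
        if (side != d[1]) {
          x <- cpp_bilinear_fwd(x, side, side)
          m$resized <- TRUE
          d <- dim(x)
        }
      }
      if (d[1] %% spec$output_stride != 0)
        stop(sprintf("model: input side %d not divisible by the output stride %d",
                     d[1], spec$output_stride))
      feats <- backbone$forward(x, training)
      ctx <- aspp$forward(feats$high, training)
      ctx_up <- up4a$forward(ctx, training)
      low <- low_proj$forward(feats$low, training)
      m$split_c <- c(dim(ctx_up)[3], dim(low)[3])
      z <- array(0, dim = c(dim(low)[1], dim(low)[2],
                            sum(m$split_c), dim(low)[4]))
      z[, , seq_len(m$split_c[1]), ] <- ctx_up
      z[, , m$split_c[1] + seq_len(m$split_c[2]), ] <- low
      z <- refine$forward(z, training)
      scores <- head$forward(z, training)
      scores <- up4b$forward(scores, training)
      if (m$resized) scores <- cpp_bilinear_fwd(scores, m$orig_hw[1], m$orig_hw[2])
      m$net_hw <- d[1:2]
      scores
    }
    m$backward <- function(gy) {
      if (m$resized) gy <- cpp_bilinear_bwd(gy, m$net_hw[1], m$net_hw[2])
      g <- up4b$backward(gy)
      g <- head$backward(g)
      g <- refine$backward(g)
      g_ctx <- g[, , seq_len(m$split_c[1]), , drop = FALSE]
      g_low <- g[, , m$split_c[1] + seq_len(m$split_c[2]), , drop = FALSE]
      g_low <- low_proj$backward(g_low)
      g_ctx <- up4a$backward(g_ctx)
      g_ctx <- aspp$backward(g_ctx)
      backbone$backward(list(low = g_low, high = g_ctx))
    }
    class(m) <- c("segmentation_model", class(m))
    m
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

#' The three named model variants
#'
#' Convenience wrapper: `"MI-ResNet50-AC"`, `"MI-ResNet18-AC"` and
#' `"MI-MobileNet-AC"` map onto the corresponding backbone specification.
#'
#' @param name variant name (case-insensitive).
#' @param ... passed on to [model_spec].
#' @param seed optional initialisation seed, see [build_myinet].
#' @return a `segmentation_model`.
#' @export
build_variant <- function(name, ..., seed = NULL) {
  bk <- switch(tolower(name),
               "mi-resnet50-ac" = "mi-resnet50",
               "mi-resnet18-ac" = "mi-resnet18",
               "mi-mobilenet-ac" = "mi-mobilenetv2",
               stop("unknown variant ", name))
  build_myinet(model_spec(backbone = bk, ...), seed = seed)
}

#' Per-pixel class scores for an image
#' @param model a `segmentation_model`.
#' @param image numeric matrix in `[0, 1]` (side divisible by 16).
#' @return `H x W x n_classes` score array.
#' @export
predict_scores <- function(model, image) {
  if (any(!is.finite(image))) stop("predict_scores: non-finite input")
  y <- nn_forward(model, image, training = FALSE)
  array(y, dim = dim(y)[1:3])
}

#' Segment an image into class labels
#'
#' Per-pixel argmax of the class scores; ties break toward the lowest class
#' code. Invariant to positive rescaling of the scores.
#'
#' @param model a `segmentation_model`.
#' @param image numeric matrix (square, side divisible by 16, finite).
#' @return integer label matrix of the same shape as `image`.
#' @export
segment <- function(model, image) {
  s <- predict_scores(model, image)
  scores_to_labels(s)
}

#' Argmax labels from a score array (lowest-index tie-break)
#' @param scores `H x W x C` array.
#' @return integer `H x W` matrix of 0-based codes.
#' @export
scores_to_labels <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Per-pixel softmax probabilities from a score array
#' @param scores `H x W x C` array.
#' @return array of the same shape; probabilities sum to one per pixel.
#' @export
scores_to_probs <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  m <- exp(m - apply(m, 1, max))
  m <- m / rowSums(m)
  array(m, dim = d)
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("segmentation model | backbone %s | %d classes | k = %d | %s parameters\n",
              x$spec$backbone, x$spec$n_classes, x$spec$atrous_base_rate,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Architecture summary: stage shapes and parameter counts
#'
#' Runs a forward pass on a blank image and reports the tap shapes, the ASPP
#' rates, the parameter count, and the depthwise-separable cost of a
#' representative block in both the plain two-term form (`D_k = 1`) and the
#' kernel-corrected form (`D_k = 3`).
#'
#' @param model a `segmentation_model`.
#' @param input_size square input side (default 64).
#' @return invisibly, a list of the printed quantities.
#' @export
describe_model <- function(model, input_size = 64L) {
  x <- matrix(0, input_size, input_size)
  feats <- nn_forward(model$backbone, x)
  out <- nn_forward(model, x)
  eps <- model$spec$width_multiplier
  cost_plain <- dsc_cost(64, 64, input_size / 16, d_k = 1, eps = eps)
  cost_kernel <- dsc_cost(64, 64, input_size / 16, d_k = 3, eps = eps)
  info <- list(backbone = model$spec$backbone,
               input = c(input_size, input_size),
               low_tap = dim(feats$low)[1:3],
               high_tap = dim(feats$high)[1:3],
               aspp_rates = model$aspp$rates,
               output = dim(out)[1:3],
               n_params = count_params(model),
               dsc_cost_printed_form = cost_plain,
               dsc_cost_kernel_corrected = cost_kernel)
  cat(sprintf("backbone: %s\n", info$backbone))
  cat(sprintf("input %dx%d -> low tap %s | high tap %s | output %s\n",
              input_size, input_size,
              paste(info$low_tap, collapse = "x"),
              paste(info$high_tap, collapse = "x"),
              paste(info$output, collapse = "x")))
  cat(sprintf("ASPP rates: %s\n", paste(info$aspp_rates, collapse = ", ")))
  cat(sprintf("parameters: %s\n", format(info$n_params, big.mark = ",")))
  cat(sprintf("reference DSC cost (64->64 ch, %dpx map): %g (two-term form), %g (kernel-corrected)\n",
              input_size / 16, cost_plain, cost_kernel))
  invisible(info)
}
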