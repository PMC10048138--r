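# Feature extractors: MI-ResNet (18/50) and MI-MobileNetV2, each exposing a
# low-level tap at stride 4 and a high-level output at stride 16 (the final
# stage trades stride for dilation so spatial context is not collapsed).

#' Architecture specification
#'
#' @param backbone one of `"mi-resnet18"`, `"mi-resnet50"`,
#'   `"mi-mobilenetv2"`.
#' @param n_classes number of output classes (default 4).
#' @param atrous_base_rate base dilation rate `k` of the ASPP branches
#'   (rates `k`, `2k`, `3k`; default 6).
#' @param width_multiplier factor in (0, 1] uniformly thinning every stage's
#'   channel count (native to MobileNet; honoured for the ResNets too as a
#'   desk-scale convenience).
#' @param resolution_multiplier factor in (0, 1] applied to the input image
#'   size before the network consumes it.
#' @param output_stride ratio of input size to the deepest feature map
#'   (fixed at 16).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(backbone = c("mi-resnet18", "mi-resnet50", "mi-mobilenetv2"),
                       n_classes = 4L, atrous_base_rate = 6L,
                       width_multiplier = 1, resolution_multiplier = 1,
                       output_stride = 16L) {
  backbone <- match.arg(backbone)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("model_spec: width_multiplier must be in (0, 1]")
  if (resolution_multiplier <= 0 || resolution_multiplier > 1)
    stop("model_spec: resolution_multiplier must be in (0, 1]")
  if (n_classes < 2) stop("model_spec: n_classes must be >= 2")
  if (output_stride != 16) stop("model_spec: only output stride 16 is supported")
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 atrous_base_rate = as.integer(atrous_base_rate),
                 width_multiplier = width_multiplier,
                 resolution_multiplier = resolution_multiplier,
                 output_stride = as.integer(output_stride)),
            class = "model_spec")
}

scale_ch <- function(c, eps) max(1L, as.integer(round(c * eps)))

#' Residual block (basic, two 3x3 convolutions)
#'
#' `y = relu(H(x) + shortcut(x))` where `H` is conv-BN-relu-conv-BN; the
#' shortcut is the identity when shapes allow, a 1x1 projection otherwise.
#' With the transform branch zeroed and an identity shortcut the block is the
#' identity on non-negative inputs; dropping the shortcut would reduce it to
#' a plain convolution cascade.
#'
#' @param cin,cout input/output channels.
#' @param stride 1 or 2.
#' @param dilation dilation of the 3x3 convolutions.
#' @return an `nn_module`; field `$main` is the transform branch,
#'   `$shortcut` is `NULL` for an identity skip.
#' @export
residual_block <- function(cin, cout, stride = 1L, dilation = 1L) {
  main <- mod_seq(mod_conv(cin, cout, 3L, stride, dilation), mod_bn(cout),
                  mod_relu(),
                  mod_conv(cout, cout, 3L, 1L, dilation), mod_bn(cout))
  shortcut <- NULL
  if (stride != 1L || cin != cout)
    shortcut <- mod_seq(mod_conv(cin, cout, 1L, stride), mod_bn(cout))
  m <- mod_add(main, shortcut, relu_after = TRUE)
  m$main <- main; m$shortcut <- shortcut
  m
}

# ResNet bottleneck (1x1 reduce / 3x3 / 1x1 expand), expansion 4
resnet_bottleneck <- function(cin, cmid, stride = 1L, dilation = 1L) {
  cout <- cmid * 4L
  main <- mod_seq(mod_conv(cin, cmid, 1L), mod_bn(cmid), mod_relu(),
                  mod_conv(cmid, cmid, 3L, stride, dilation), mod_bn(cmid), mod_relu(),
                  mod_conv(cmid, cout, 1L), mod_bn(cout))
  shortcut <- NULL
  if (stride != 1L || cin != cout)
    shortcut <- mod_seq(mod_conv(cin, cout, 1L, stride), mod_bn(cout))
  m <- mod_add(main, shortcut, relu_after = TRUE)
  m$main <- main; m$shortcut <- shortcut
  m$cout <- cout
  m
}

backbone_module <- function(name, stem, stages, low_channels, high_channels) {
  m <- mod_new(paste0("backbone_", name))
  m$children <- c(list(stem), stages)
  m$backbone_name <- name
  m$low_channels <- low_channels
  m$high_channels <- high_channels
  m$forward <- function(x, training) {
    x <- stem$forward(x, training)
    x <- stages[[1]]$forward(x, training)
    low <- x
    for (st in stages[-1]) x <- st$forward(x, training)
    list(low = low, high = x)
  }
  m$backward <- function(gy) {  # gy = list(low, high)
    g <- gy$high
    for (st in rev(stages[-1])) g <- st$backward(g)
    g <- g + gy$low
    g <- stages[[1]]$backward(g)
    stem$backward(g)
  }
  m
}

#' Build an MI-ResNet feature extractor
#'
#' 18-layer variant: two-convolution basic blocks; 50-layer variant:
#' 1x1/3x3/1x1 bottlenecks. Stages sit at strides 4, 8 and 16; the final
#' stage uses dilation 2 instead of stride so the output stride stays 16.
#' The low-level tap is taken after the first residual stage (stride 4).
#'
#' @param spec a [model_spec] with a ResNet backbone.
#' @return backbone `nn_module`; `nn_forward` returns
#'   `list(low =, high =)` feature arrays.
#' @export
build_resnet <- function(spec) {
  if (!spec$backbone %in% c("mi-resnet18", "mi-resnet50"))
    stop("build_resnet: unsupported backbone ", spec$backbone)
  eps <- spec$width_multiplier
  base <- vapply(c(64L, 64L, 128L, 256L, 512L), scale_ch, integer(1), eps = eps)
  stem <- mod_seq(mod_conv(1L, base[1], 7L, 2L, pad = 3L), mod_bn(base[1]),
                  mod_relu(), mod_maxpool(3L, 2L, 1L))
  if (spec$backbone == "mi-resnet18") {
    nblocks <- c(2L, 2L, 2L, 2L)
    make <- function(cin, cmid, n, stride, dilation) {
      blocks <- list(residual_block(cin, cmid, stride, dilation))
      for (i in seq_len(n - 1))
        blocks <- c(blocks, list(residual_block(cmid, cmid, 1L, dilation)))
      list(mod = do.call(mod_seq, blocks), cout = cmid)
    }
  } else {
    nblocks <- c(3L, 4L, 6L, 3L)
    make <- function(cin, cmid, n, stride, dilation) {
      blocks <- list(resnet_bottleneck(cin, cmid, stride, dilation))
      for (i in seq_len(n - 1))
        blocks <- c(blocks, list(resnet_bottleneck(cmid * 4L, cmid, 1L, dilation)))
      list(mod = do.call(mod_seq, blocks), cout = cmid * 4L)
    }
  }
  s1 <- make(base[1], base[2], nblocks[1], 1L, 1L)
  s2 <- make(s1$cout, base[3], nblocks[2], 2L, 1L)
  s3 <- make(s2$cout, base[4], nblocks[3], 2L, 1L)
  s4 <- make(s3$cout, base[5], nblocks[4], 1L, 2L)  # dilated, keeps stride 16
  backbone_module(spec$backbone, stem, list(s1$mod, s2$mod, s3$mod, s4$mod),
                  s1$cout, s4$cout)
}

#' Depthwise separable convolution block
#'
#' Per-channel 3x3 depthwise convolution, then a 1x1 pointwise convolution to
#' `cout`, each followed by batch normalisation and rectification.
#'
#' @param cin,cout input/output channels.
#' @param stride,dilation of the depthwise stage.
#' @return an `nn_module`; after a forward pass `$multiply_count()` reports
#'   the number of scalar multiplications the two convolution stages
#'   performed per sample.
#' @export
depthwise_separable_conv <- function(cin, cout, stride = 1L, dilation = 1L) {
  dw <- mod_conv(cin, cin, 3L, stride, dilation, groups = cin)
  pw <- mod_conv(cin, cout, 1L)
  m <- mod_seq(dw, mod_bn(cin), mod_relu(), pw, mod_bn(cout), mod_relu())
  m$multiply_count <- function() dw$last_multiplies + pw$last_multiplies
  m
}

#' Computation cost of one depthwise separable convolution
#'
#' Multiply count `eps*D_I * D_k^2 * (delta*D_F)^2 +
#' eps*D_I * eps*D_O * (delta*D_F)^2` with channel counts rounded to the
#' nearest integer (at least 1) after applying the width multiplier. With
#' `D_k = 1` this is the plain two-term product form often quoted for the
#' width/resolution-multiplier analysis; `D_k = 3` gives the kernel-corrected
#' count for the 3x3 depthwise filters actually used. Reports should print
#' both rather than silently picking one.
#'
#' @param d_i,d_o input/output channel counts.
#' @param d_f spatial size of the square feature map.
#' @param d_k depthwise kernel size (1 for the printed form, 3 for the
#'   kernel-corrected count).
#' @param eps width multiplier in (0, 1].
#' @param delta resolution multiplier in (0, 1].
#' @return multiply count (numeric).
#' @export
dsc_cost <- function(d_i, d_o, d_f, d_k = 1, eps = 1, delta = 1) {
  if (any(c(d_i, d_o, d_f, d_k) <= 0)) stop("dsc_cost: arguments must be positive")
  if (eps <= 0 || eps > 1 || delta <= 0 || delta > 1)
    stop("dsc_cost: multipliers must be in (0, 1]")
  ci <- max(1, round(eps * d_i))
  co <- max(1, round(eps * d_o))
  f2 <- (delta * d_f)^2
  ci * d_k^2 * f2 + ci * co * f2
}

#' Inverted-residual bottleneck block (MobileNetV2)
#'
#' 1x1 expansion with capped rectification (ReLU6), 3x3 depthwise
#' convolution, then a linear 1x1 projection (no non-linearity). The additive
#' skip is present exactly when `stride = 1` and `cin = cout`.
#'
#' @param cin,cout input/output channels.
#' @param expansion expansion factor of the hidden layer.
#' @param stride 1 or 2.
#' @param dilation dilation of the depthwise stage.
#' @return an `nn_module`; field `$main` is the transform branch.
#' @export
bottleneck_block <- function(cin, cout, expansion = 6L, stride = 1L, dilation = 1L) {
  if (!stride %in% c(1L, 2L)) stop("bottleneck_block: stride must be 1 or 2")
  hid <- cin * expansion
  layers <- list()
  if (expansion != 1L)
    layers <- c(layers, list(mod_conv(cin, hid, 1L), mod_bn(hid), mod_relu(6)))
  layers <- c(layers,
              list(mod_conv(hid, hid, 3L, stride, dilation, groups = hid),
                   mod_bn(hid), mod_relu(6),
                   mod_conv(hid, cout, 1L), mod_bn(cout)))
  main <- do.call(mod_seq, layers)
  if (stride == 1L && cin == cout) {
    m <- mod_add(main, NULL, relu_after = FALSE)
  } else {
    m <- mod_new("bottleneck_noskip")
    m$children <- list(main)
    m$forward <- function(x, training) main$forward(x, training)
    m$backward <- function(gy) main$backward(gy)
  }
  m$main <- main
  m
}

# MobileNetV2 stage table: expansion, channels, repeats, stride, dilation.
mobilenet_stages <- function() list(
  c(1L, 16L, 1L, 1L, 1L),
  c(6L, 24L, 2L, 2L, 1L),   # stride-4 stage -> low-level tap
  c(6L, 32L, 3L, 2L, 1L),
  c(6L, 64L, 4L, 2L, 1L),
  c(6L, 96L, 3L, 1L, 1L),
  c(6L, 160L, 3L, 1L, 2L),  # dilated instead of a further stride
  c(6L, 320L, 1L, 1L, 2L))

#' Build an MI-MobileNetV2 feature extractor
#'
#' Standard MobileNetV2 stage layout with the width multiplier applied to
#' every stage's channel count (rounded, minimum 1); late stages use dilated
#' depthwise convolutions so the output stride is 16. Low-level tap at the
#' stride-4 stage. The resolution multiplier is applied by the surrounding
#' model as an input-resize factor, not here.
#'
#' @param spec a [model_spec] with `backbone = "mi-mobilenetv2"`.
#' @return backbone `nn_module` as in [build_resnet].
#' @export
build_mobilenetv2 <- function(spec) {
  if (spec$backbone != "mi-mobilenetv2")
    stop("build_mobilenetv2: wrong backbone ", spec$backbone)
  eps <- spec$width_multiplier
  c_stem <- scale_ch(32L, eps)
  stem <- mod_seq(mod_conv(1L, c_stem, 3L, 2L), mod_bn(c_stem), mod_relu(6))
  cin <- c_stem
  blocks_before_tap <- list()
  blocks_after <- list()
  low_channels <- NULL
  for (i in seq_along(mobilenet_stages())) {
    st <- mobilenet_stages()[[i]]
    cout <- scale_ch(st[2], eps)
    for (r in seq_len(st[3])) {
      blk <- bottleneck_block(cin, cout, st[1], if (r == 1) st[4] else 1L, st[5])
      if (i <= 2) blocks_before_tap <- c(blocks_before_tap, list(blk))
      else blocks_after <- c(blocks_after, list(blk))
      cin <- cout
    }
    if (i == 2) low_channels <- cout
  }
  backbone_module("mi-mobilenetv2", stem,
                  list(do.call(mod_seq, blocks_before_tap),
                       do.call(mod_seq, blocks_after)),
                  low_channels, cin)
}

build_backbone <- function(spec) {
  switch(spec$backbone,
         "mi-resnet18" = ,
         "mi-resnet50" = build_resnet(spec),
         "mi-mobilenetv2" = build_mobilenetv2(spec))
}
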