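# Minimal CNN layer library with explicit forward/backward passes.
# Tensors are plain R arrays laid out [H, W, C, N]; all heavy lifting
# (convolution, pooling, bilinear resampling) is done in compiled code.

new_param <- function(dim, init = c("he", "ones", "zeros"), fan_in = NULL) {
  init <- match.arg(init)
  n <- prod(dim)
  v <- switch(init,
    he    = stats::rnorm(n, sd = sqrt(2 / fan_in)),
    ones  = rep(1, n),
    zeros = rep(0, n))
  e <- new.env(parent = emptyenv())
  e$value <- array(v, dim = dim)
  e$grad <- array(0, dim = dim)
  e
}

mod_new <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$children <- list()
  m$params_local <- list()
  class(m) <- "nn_module"
  m
}

#' Collect the parameter tensors of a network module
#'
#' Walks the module tree and returns the flat list of parameter
#' environments (each holding `$value` and `$grad` arrays).
#'
#' @param m an `nn_module`.
#' @return list of parameter environments.
#' @export
mod_params <- function(m) {
  out <- m$params_local
  for (ch in m$children) out <- c(out, mod_params(ch))
  out
}

#' Total number of trainable parameters in a module
#' @param m an `nn_module`.
#' @return integer count.
#' @export
count_params <- function(m) {
  sum(vapply(mod_params(m), function(p) length(p$value), numeric(1)))
}

#' Zero every parameter tensor of a module (in place)
#'
#' Useful for contract checks: a residual block whose transform branch is
#' zeroed must act as the identity.
#' @param m an `nn_module`.
#' @return the module, invisibly.
#' @export
zero_params <- function(m) {
  for (p in mod_params(m)) p$value[] <- 0
  invisible(m)
}

zero_grads <- function(m) {
  for (p in mod_params(m)) p$grad[] <- 0
  invisible(m)
}

#' Run a module forward
#' @param m an `nn_module`.
#' @param x input array `[H, W, C, N]` (a matrix is promoted to `[H, W, 1, 1]`).
#' @param training logical; batch-norm layers use batch statistics and cache
#'   intermediates for the backward pass when `TRUE`.
#' @return output array.
#' @export
nn_forward <- function(m, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  m$forward(x, training)
}

#' Back-propagate through a module
#' @param m an `nn_module` that has been run forward with `training = TRUE`.
#' @param gy gradient of the loss with respect to the module output.
#' @return gradient with respect to the module input; parameter gradients are
#'   accumulated into each parameter's `$grad`.
#' @export
nn_backward <- function(m, gy) m$backward(gy)

as_nchw_dims <- function(x) dim(x)

# repeat a per-channel vector so that plain elementwise arithmetic
# broadcasts it over [H, W, C, N] (R recycles over the batch dim)
bc_channel <- function(v, d) rep(v, each = d[1] * d[2])

channel_sums <- function(x) {
  d <- dim(x)
  m <- colSums(x, dims = 2)          # C x N
  if (is.null(dim(m))) m <- matrix(m, d[3], d[4])
  rowSums(m)
}

# ---- convolution ----------------------------------------------------------

mod_conv <- function(cin, cout, k, stride = 1L, dilation = 1L, groups = 1L,
                     bias = FALSE, pad = NULL) {
  m <- mod_new("conv")
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L   # 'same' for odd k
  m$k <- as.integer(k); m$stride <- as.integer(stride)
  m$pad <- as.integer(pad); m$dilation <- as.integer(dilation)
  m$groups <- as.integer(groups)
  fan_in <- k * k * cin / groups
  m$params_local$w <- new_param(c(k, k, cin %/% groups, cout), "he", fan_in = fan_in)
  if (bias) m$params_local$b <- new_param(cout, "zeros")
  m$last_multiplies <- NA_real_
  m$forward <- function(x, training) {
    m$x <- if (training) x else NULL
    d <- dim(x)
    y <- cpp_conv2d_fwd(x, m$params_local$w$value,
                        if (bias) m$params_local$b$value else NULL,
                        m$stride, m$pad, m$dilation, m$groups)
    dy <- dim(y)
    # exact number of scalar products performed by the GEMMs (per sample)
    m$last_multiplies <- (k * k * cin / m$groups) * dy[1] * dy[2] * cout
    y
  }
  m$backward <- function(gy) {
    r <- cpp_conv2d_bwd(m$x, m$params_local$w$value, gy,
                        m$stride, m$pad, m$dilation, m$groups, TRUE, bias)
    m$params_local$w$grad <- m$params_local$w$grad + r$gw
    if (bias) m$params_local$b$grad <- m$params_local$b$grad + r$gb
    m$x <- NULL
    r$gx
  }
  m
}

# ---- batch normalisation --------------------------------------------------

mod_bn <- function(c, eps = 1e-5, momentum = 0.1, gamma_init = "ones") {
  m <- mod_new("bn")
  m$params_local$gamma <- new_param(c, gamma_init)
  m$params_local$beta <- new_param(c, "zeros")
  m$running_mean <- rep(0, c)
  m$running_var <- rep(1, c)
  m$eps <- eps
  m$momentum <- momentum
  m$forward <- function(x, training) {
    d <- dim(x)
    nelem <- d[1] * d[2] * d[4]
    if (training) {
      mu <- channel_sums(x) / nelem
      xc <- x - bc_channel(mu, d)
      v <- channel_sums(xc * xc) / nelem
      ivar <- 1 / sqrt(v + m$eps)
      xhat <- xc * bc_channel(ivar, d)
      m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
      m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
      m$xhat <- xhat; m$ivar <- ivar; m$nelem <- nelem
    } else {
      ivar <- 1 / sqrt(m$running_var + m$eps)
      xhat <- (x - bc_channel(m$running_mean, d)) * bc_channel(ivar, d)
    }
    xhat * bc_channel(m$params_local$gamma$value, d) +
      bc_channel(m$params_local$beta$value, d)
  }
  m$backward <- function(gy) {
    d <- dim(gy)
    dgamma <- channel_sums(gy * m$xhat)
    dbeta <- channel_sums(gy)
    m$params_local$gamma$grad <- m$params_local$gamma$grad + dgamma
    m$params_local$beta$grad <- m$params_local$beta$grad + dbeta
    coef <- m$params_local$gamma$value * m$ivar / m$nelem
    gx <- bc_channel(coef, d) *
      (m$nelem * gy - bc_channel(dbeta, d) - m$xhat * bc_channel(dgamma, d))
    m$xhat <- NULL
    gx
  }
  m
}

# ---- activations ----------------------------------------------------------

mod_relu <- function(cap = Inf) {
  m <- mod_new(if (is.finite(cap)) "relu6" else "relu")
  m$forward <- function(x, training) {
    y <- pmin(pmax(x, 0), cap)
    dim(y) <- dim(x)
    if (training) m$mask <- (x > 0) & (x < cap)
    y
  }
  m$backward <- function(gy) {
    gx <- gy * m$mask
    dim(gx) <- dim(gy)
    m$mask <- NULL
    gx
  }
  m
}

# ---- pooling / resampling -------------------------------------------------

mod_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  m <- mod_new("maxpool")
  m$forward <- function(x, training) {
    r <- cpp_maxpool_fwd(x, k, stride, pad)
    if (training) { m$idx <- r$idx; m$xdim <- dim(x) }
    r$y
  }
  m$backward <- function(gy) {
    gx <- cpp_maxpool_bwd(gy, m$idx, m$xdim)
    m$idx <- NULL
    gx
  }
  m
}

mod_bilinear <- function(scale = NULL, out_hw = NULL) {
  m <- mod_new("bilinear")
  m$forward <- function(x, training) {
    d <- dim(x)
    hw <- if (!is.null(out_hw)) out_hw else round(d[1:2] * scale)
    m$in_hw <- d[1:2]
    cpp_bilinear_fwd(x, as.integer(hw[1]), as.integer(hw[2]))
  }
  m$backward <- function(gy) cpp_bilinear_bwd(gy, m$in_hw[1], m$in_hw[2])
  m
}

# ---- composition ----------------------------------------------------------

mod_seq <- function(...) {
  m <- mod_new("seq")
  m$children <- list(...)
  m$forward <- function(x, training) {
    for (ch in m$children) x <- ch$forward(x, training)
    x
  }
  m$backward <- function(gy) {
    for (ch in rev(m$children)) gy <- ch$backward(gy)
    gy
  }
  m
}

# elementwise sum of a main branch and a shortcut, optional trailing ReLU
mod_add <- function(main, shortcut = NULL, relu_after = TRUE) {
  m <- mod_new("add")
  m$children <- if (is.null(shortcut)) list(main) else list(main, shortcut)
  act <- if (relu_after) mod_relu() else NULL
  if (!is.null(act)) m$children <- c(m$children, list(act))
  m$forward <- function(x, training) {
    y <- main$forward(x, training)
    y <- y + (if (is.null(shortcut)) x else shortcut$forward(x, training))
    if (!is.null(act)) y <- act$forward(y, training)
    y
  }
  m$backward <- function(gy) {
    if (!is.null(act)) gy <- act$backward(gy)
    gx <- main$backward(gy)
    gx + (if (is.null(shortcut)) gy else shortcut$backward(gy))
  }
  m
}

# channel-wise concatenation of parallel branches fed the same input
mod_parallel_concat <- function(branches) {
  m <- mod_new("concat")
  m$children <- branches
  m$forward <- function(x, training) {
    ys <- lapply(m$children, function(b) b$forward(x, training))
    m$splits <- vapply(ys, function(y) dim(y)[3], numeric(1))
    d <- dim(ys[[1]])
    out <- array(0, dim = c(d[1], d[2], sum(m$splits), d[4]))
    at <- 0
    for (y in ys) {
      cc <- dim(y)[3]
      out[, , at + seq_len(cc), ] <- y
      at <- at + cc
    }
    out
  }
  m$backward <- function(gy) {
    at <- 0
    gx <- NULL
    for (i in seq_along(m$children)) {
      cc <- m$splits[i]
      g <- gy[, , at + seq_len(cc), , drop = FALSE]
      at <- at + cc
      gi <- m$children[[i]]$backward(g)
      gx <- if (is.null(gx)) gi else gx + gi
    }
    gx
  }
  m
}

conv_bn_relu <- function(cin, cout, k, stride = 1L, dilation = 1L,
                         groups = 1L, cap = Inf) {
  mod_seq(mod_conv(cin, cout, k, stride, dilation, groups),
          mod_bn(cout), mod_relu(cap))
}

collect_bn <- function(m) {
  out <- if (m$type == "bn") list(m) else list()
  for (ch in m$children) out <- c(out, collect_bn(ch))
  out
}

#' Finalize batch-norm statistics with a population pass
#'
#' Replaces every batch-norm layer's running mean/variance with the
#' statistics of one full forward pass over the supplied batch (typically
#' the whole training split), so that evaluation-mode inference uses
#' population rather than exponentially smoothed estimates.
#'
#' @param model an `nn_module`.
#' @param pixels input array `[H, W, C, N]` covering the reference data.
#' @return the module, invisibly.
#' @export
finalize_bn_stats <- function(model, pixels) {
  bns <- collect_bn(model)
  old <- lapply(bns, function(b) b$momentum)
  for (b in bns) b$momentum <- 1
  on.exit(for (i in seq_along(bns)) bns[[i]]$momentum <- old[[i]])
  invisible(nn_forward(model, pixels, training = TRUE))
  for (b in bns) { b$xhat <- NULL; b$ivar <- NULL }
  invisible(model)
}

# ---- optimiser ------------------------------------------------------------

sgd_step <- function(params, lr, momentum = 0.9) {
  for (p in params) {
    if (is.null(p$mom)) p$mom <- array(0, dim = dim(p$grad))
    p$mom <- momentum * p$mom + p$grad
    p$value <- p$value - lr * p$mom
    p$grad[] <- 0
  }
  invisible(NULL)
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}

# full model state: parameters plus batch-norm running statistics
snapshot_state <- function(model) {
  list(params = snapshot_params(mod_params(model)),
       bn = lapply(collect_bn(model),
                   function(b) list(m = b$running_mean, v = b$running_var)))
}

restore_state <- function(model, snap) {
  restore_params(mod_params(model), snap$params)
  bns <- collect_bn(model)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- snap$bn[[i]]$m
    bns[[i]]$running_var <- snap$bn[[i]]$v
  }
  invisible(model)
}
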