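# shared fixtures: small phantoms and width-reduced models keep tests quick

tiny_params <- function(size = 64L, ...) phantom_params(image_size = size, ...)

tiny_model <- function(backbone = "mi-resnet18", eps = 0.125, seed = 1L, ...) {
  build_myinet(model_spec(backbone = backbone, width_multiplier = eps, ...),
               seed = seed)
}

random_labels <- function(h, w, n_classes = 4L) {
  matrix(sample.int(n_classes, h * w, replace = TRUE) - 1L, h, w)
}

# brute-force per-pixel metric oracles (independent of the implementation)
brute_confusion <- function(gt, pred, n) {
  P <- matrix(0, n, n)
  for (i in seq_along(gt)) P[gt[i] + 1, pred[i] + 1] <- P[gt[i] + 1, pred[i] + 1] + 1
  P
}

brute_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    nb <- c(if (r > 1) mask[r - 1, c] else FALSE,
            if (r < h) mask[r + 1, c] else FALSE,
            if (c > 1) mask[r, c - 1] else FALSE,
            if (c < w) mask[r, c + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

brute_bf_pr <- function(bp, bg, tol) {
  mind <- function(z, set) {
    if (nrow(set) == 0) return(Inf)
    min(sqrt((set[, 1] - z[1])^2 + (set[, 2] - z[2])^2))
  }
  p <- if (nrow(bp) == 0) 0 else
    mean(vapply(seq_len(nrow(bp)), function(i) mind(bp[i, ], bg) < tol, logical(1)))
  r <- if (nrow(bg) == 0) 0 else
    mean(vapply(seq_len(nrow(bg)), function(i) mind(bg[i, ], bp) < tol, logical(1)))
  c(p, r)
}
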