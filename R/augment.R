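# Training-time geometric augmentation: random rotation (0-360 degrees) and
# random scaling (0.9-1.1). Pixels are interpolated bilinearly, labels with
# nearest-neighbour; exposed regions are filled with background intensity
# and label 0. Augmentation is meant for the training split only.

# inverse-map sampling shared by rotation and scaling
warp_labeled_image <- function(li, map_fun, fill = NULL) {
  h <- nrow(li$pixels); w <- ncol(li$pixels)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  src <- map_fun(rows - cy, cols - cx)   # list(dr, dc) source offsets
  sr <- src$dr + cy
  sc <- src$dc + cx

  if (is.null(fill)) {
    bgpix <- li$pixels[li$labels == 0L]
    fill <- if (length(bgpix)) mean(bgpix) else 0
  }

  # bilinear for intensities
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gather <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v <- matrix(fill, h, w)
    v[ok] <- li$pixels[cbind(rr[ok], cc[ok])]
    v
  }
  pix <- gather(r0, c0) * (1 - fr) * (1 - fc) +
    gather(r0 + 1, c0) * fr * (1 - fc) +
    gather(r0, c0 + 1) * (1 - fr) * fc +
    gather(r0 + 1, c0 + 1) * fr * fc

  # nearest-neighbour for labels
  rn <- round(sr); cn <- round(sc)
  ok <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
  lab <- matrix(0L, h, w)
  lab[ok] <- li$labels[cbind(rn[ok], cn[ok])]

  out <- labeled_image(pmin(pmax(pix, 0), 1), lab, li$patient_id, li$slice_index)
  attr(out, "geometry") <- attr(li, "geometry")
  out
}

#' Random rotation of a labelled image
#'
#' Rotates pixels (bilinear) and labels (nearest-neighbour) jointly about the
#' image centre by an angle drawn uniformly from `[0, 360)` degrees; the
#' canvas size is preserved and exposed corners are filled with the mean
#' background intensity and label 0.
#'
#' @param li a [labeled_image].
#' @param angle optional fixed angle in degrees (overrides the random draw).
#' @return the rotated [labeled_image].
#' @export
random_rotation <- function(li, angle = NULL) {
  if (is.null(angle)) angle <- stats::runif(1, 0, 360)
  th <- angle * pi / 180
  if (angle %% 360 == 0) return(li)
  warp_labeled_image(li, function(dr, dc) {
    list(dr = dc * sin(th) + dr * cos(th),
         dc = dc * cos(th) - dr * sin(th))
  })
}

#' Random scaling of a labelled image
#'
#' Resamples about the image centre with a factor drawn uniformly from
#' `[0.9, 1.1]`; the output keeps the input size (implicit centre-crop for
#' factors above 1, background padding below 1).
#'
#' @param li a [labeled_image].
#' @param factor optional fixed scaling factor.
#' @return the rescaled [labeled_image].
#' @export
random_scale <- function(li, factor = NULL) {
  if (is.null(factor)) factor <- stats::runif(1, 0.9, 1.1)
  if (factor == 1) return(li)
  warp_labeled_image(li, function(dr, dc) {
    list(dr = dr / factor, dc = dc / factor)
  })
}

#' Apply the training augmentation pipeline to one image
#' @param li a [labeled_image].
#' @return augmented [labeled_image].
#' @export
augment_image <- function(li) random_scale(random_rotation(li))
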