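# Synthetic short-axis LGE-CMR phantom: concentric cardiac geometry with
# pixel-perfect 4-class ground truth (0 background, 1 blood, 2 muscle, 3 LGE).

CLASS_CODES <- c(background = 0L, blood = 1L, muscle = 2L, lge = 3L)

#' Parameters of the synthetic cardiac phantom
#'
#' Geometry is drawn in pixels relative to `image_size`; intensities live in
#' `[0, 1]`. Defaults emulate the qualitative structure of clinical short-axis
#' late-gadolinium-enhancement slices: a bright blood pool, a nulled (dark)
#' myocardial annulus, a hyperintense scar wedge whose intensity is close to
#' blood, an optional dark microvascular-obstruction core that is *labelled*
#' LGE, a slow linear background shading and additive Gaussian noise. Pixel
#' counts under the defaults are severely imbalanced in the order
#' background > blood > muscle > LGE.
#'
#' @param image_size side of the square image in pixels (default 256).
#' @param center_jitter maximal displacement of the heart centre from the
#'   image centre, pixels.
#' @param blood_radius_range range of the blood-pool radius, pixels.
#' @param myocardium_thickness_range range of the myocardial wall thickness,
#'   pixels.
#' @param lge_angular_extent_range angular width of the scar wedge, degrees;
#'   `c(0, 0)` disables LGE entirely.
#' @param lge_center_angle_range direction of the wedge centre, degrees.
#' @param lge_transmurality_range fraction of the wall thickness the scar
#'   penetrates, in (0, 1].
#' @param mvo_probability probability that a scar carries a dark MVO core.
#' @param mvo_radius_fraction MVO core radius as a fraction of half the scar's
#'   radial depth.
#' @param tissue_intensity_means named means for background, blood, muscle,
#'   lge and mvo tissue.
#' @param tissue_intensity_sds per-slice jitter of the tissue means.
#' @param background_gradient_amplitude amplitude of the linear shading ramp.
#' @param noise_sd standard deviation of the additive pixel noise.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256L,
                           center_jitter = 0.05 * image_size,
                           blood_radius_range = c(0.15, 0.21) * image_size,
                           myocardium_thickness_range = c(0.05, 0.075) * image_size,
                           lge_angular_extent_range = c(40, 140),
                           lge_center_angle_range = c(0, 360),
                           lge_transmurality_range = c(0.4, 1.0),
                           mvo_probability = 0.15,
                           mvo_radius_fraction = 0.4,
                           tissue_intensity_means = c(background = 0.20, blood = 0.70,
                                                      muscle = 0.35, lge = 0.75,
                                                      mvo = 0.25),
                           tissue_intensity_sds = c(background = 0.02, blood = 0.03,
                                                    muscle = 0.03, lge = 0.03,
                                                    mvo = 0.02),
                           background_gradient_amplitude = 0.05,
                           noise_sd = 0.03) {
  p <- list(image_size = as.integer(image_size), center_jitter = center_jitter,
            blood_radius_range = blood_radius_range,
            myocardium_thickness_range = myocardium_thickness_range,
            lge_angular_extent_range = lge_angular_extent_range,
            lge_center_angle_range = lge_center_angle_range,
            lge_transmurality_range = lge_transmurality_range,
            mvo_probability = mvo_probability,
            mvo_radius_fraction = mvo_radius_fraction,
            tissue_intensity_means = tissue_intensity_means,
            tissue_intensity_sds = tissue_intensity_sds,
            background_gradient_amplitude = background_gradient_amplitude,
            noise_sd = noise_sd)
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  stopifnot(p$image_size >= 16)
  if (max(p$blood_radius_range) + max(p$myocardium_thickness_range) +
      p$center_jitter > p$image_size / 2)
    stop("phantom_params: blood radius + wall thickness (+ jitter) must fit inside image_size/2")
  fr <- c(p$mvo_probability, p$mvo_radius_fraction, p$lge_transmurality_range)
  if (any(fr < 0 | fr > 1)) stop("phantom_params: probabilities and fractions must lie in [0, 1]")
  m <- p$tissue_intensity_means
  if (!(m["muscle"] < m["blood"] && m["muscle"] < m["lge"]))
    stop("phantom_params: muscle must be hypointense relative to blood and LGE")
  invisible(p)
}

#' A labelled image: grayscale slice plus per-pixel class mask
#'
#' @param pixels numeric `H x W` matrix in `[0, 1]`.
#' @param labels integer `H x W` matrix with codes 0 = background, 1 = blood,
#'   2 = muscle, 3 = LGE.
#' @param patient_id opaque identifier.
#' @param slice_index integer slice number.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, labels, patient_id = "p0", slice_index = 1L) {
  stopifnot(is.matrix(pixels), is.matrix(labels),
            all(dim(pixels) == dim(labels)))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 0:3)) stop("labeled_image: labels must be in {0, 1, 2, 3}")
  structure(list(pixels = pixels, labels = labels,
                 patient_id = patient_id, slice_index = as.integer(slice_index)),
            class = "labeled_image")
}

# run expr under a local, fully restored RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derived stream seed for entity (patient, slice) under a master seed;
# kept below 2^31 - 1
child_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 48271 + a * 30269 + b * 1013) %% 2147483629)
}

runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

# sample one geometry/intensity realisation from the parameter ranges
sample_phantom_draw <- function(params) {
  s <- params$image_size
  list(
    cx = (s + 1) / 2 + stats::runif(1, -1, 1) * params$center_jitter,
    cy = (s + 1) / 2 + stats::runif(1, -1, 1) * params$center_jitter,
    r_blood = runif1(params$blood_radius_range),
    thickness = runif1(params$myocardium_thickness_range),
    lge_extent = runif1(params$lge_angular_extent_range),
    lge_angle = runif1(params$lge_center_angle_range),
    transmurality = runif1(params$lge_transmurality_range),
    has_mvo = stats::runif(1) < params$mvo_probability,
    grad_angle = stats::runif(1, 0, 2 * pi),
    means = params$tissue_intensity_means +
      stats::rnorm(5) * params$tissue_intensity_sds
  )
}

render_phantom <- function(params, draw, noise_seeded = TRUE) {
  s <- params$image_size
  xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  dx <- xs - draw$cx
  dy <- ys - draw$cy
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360

  labels <- matrix(0L, s, s)
  labels[r <= draw$r_blood + draw$thickness] <- CLASS_CODES[["muscle"]]
  labels[r <= draw$r_blood] <- CLASS_CODES[["blood"]]

  ang_dist <- abs(((theta - draw$lge_angle + 180) %% 360) - 180)
  in_wedge <- ang_dist <= draw$lge_extent / 2 & draw$lge_extent > 0
  scar_depth <- draw$transmurality * draw$thickness
  scar <- in_wedge & r > draw$r_blood & r <= draw$r_blood + scar_depth
  labels[scar] <- CLASS_CODES[["lge"]]

  mvo <- matrix(FALSE, s, s)
  if (draw$has_mvo && any(scar)) {
    mr <- draw$r_blood + scar_depth / 2
    ma <- draw$lge_angle * pi / 180
    mcx <- draw$cx + mr * cos(ma)
    mcy <- draw$cy + mr * sin(ma)
    mrad <- params$mvo_radius_fraction * scar_depth / 2
    mvo <- scar & ((xs - mcx)^2 + (ys - mcy)^2 <= mrad^2)
    labels[mvo] <- CLASS_CODES[["lge"]]  # MVO is merged into the LGE class
  }

  mu <- draw$means
  pix <- matrix(mu[["background"]], s, s)
  pix[labels == CLASS_CODES[["blood"]]] <- mu[["blood"]]
  pix[labels == CLASS_CODES[["muscle"]]] <- mu[["muscle"]]
  pix[labels == CLASS_CODES[["lge"]]] <- mu[["lge"]]
  pix[mvo] <- mu[["mvo"]]

  ramp <- (dx * cos(draw$grad_angle) + dy * sin(draw$grad_angle)) / s
  pix <- pix + params$background_gradient_amplitude * ramp
  if (noise_seeded && params$noise_sd > 0)
    pix <- pix + stats::rnorm(s * s, sd = params$noise_sd)
  pix <- pmin(pmax(pix, 0), 1)
  list(pixels = pix, labels = labels)
}

#' Generate one synthetic LGE-CMR slice with exact ground truth
#'
#' Draws a phantom realisation (centre, radii, wedge, intensities) from the
#' parameter ranges, renders intensity and label grids and returns them as a
#' [labeled_image]. The sampled geometry is attached as attribute
#' `"geometry"` so tests can recompute labels from polar coordinates.
#' Identical `(params, seed)` give bit-identical output.
#'
#' @param params a [phantom_params] object.
#' @param seed integer seed for this slice.
#' @param patient_id,slice_index metadata stored on the image.
#' @return a [labeled_image].
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L,
                             patient_id = "p0", slice_index = 1L) {
  validate_phantom_params(params)
  res <- with_seed(seed, {
    draw <- sample_phantom_draw(params)
    c(render_phantom(params, draw), list(draw = draw))
  })
  li <- labeled_image(res$pixels, res$labels, patient_id, slice_index)
  attr(li, "geometry") <- res$draw
  li
}

#' Generate a patient-grouped phantom cohort with 60/20/20 splits
#'
#' Patient-level geometry and intensity parameters are drawn once per patient
#' and jittered per slice, so slices of one patient correlate; the train /
#' validation / test assignment is by patient (largest-remainder rounding of
#' the 60/20/20 fractions), so no patient leaks across splits.
#'
#' @param n_patients number of patients (>= 5 so all splits are non-empty).
#' @param slices_per_patient slices generated per patient.
#' @param params a [phantom_params] object.
#' @param seed master seed; all randomness is derived from it.
#' @param fractions patient-count fractions for train/validation/test
#'   (default 60/20/20); a zero fraction disables that split.
#' @return object of class `cohort`: `$images` (list of [labeled_image]) and
#'   `$split_assignment` (named character vector patient -> split).
#' @export
generate_cohort <- function(n_patients, slices_per_patient = 3L,
                            params = phantom_params(), seed = 1L,
                            fractions = c(train = 0.6, validation = 0.2,
                                          test = 0.2)) {
  if (n_patients < 5)
    stop("generate_cohort: need at least 5 patients to form three non-empty splits")
  validate_phantom_params(params)
  pids <- sprintf("patient%03d", seq_len(n_patients))

  images <- vector("list", n_patients * slices_per_patient)
  k <- 0
  for (i in seq_len(n_patients)) {
    base <- with_seed(child_seed(seed, i), sample_phantom_draw(params))
    for (j in seq_len(slices_per_patient)) {
      res <- with_seed(child_seed(seed, i, j), {
        d <- base
        s <- params$image_size
        d$cx <- d$cx + stats::rnorm(1, sd = 0.01 * s)
        d$cy <- d$cy + stats::rnorm(1, sd = 0.01 * s)
        d$r_blood <- d$r_blood * stats::runif(1, 0.95, 1.05)
        d$thickness <- d$thickness * stats::runif(1, 0.95, 1.05)
        d$lge_extent <- max(0, d$lge_extent * stats::runif(1, 0.9, 1.1))
        d$means <- d$means + stats::rnorm(5, sd = 0.01)
        c(render_phantom(params, d), list(draw = d))
      })
      k <- k + 1
      li <- labeled_image(res$pixels, res$labels, pids[i], j)
      attr(li, "geometry") <- res$draw
      images[[k]] <- li
    }
  }

  split <- assign_splits(pids, seed, fractions)
  structure(list(images = images, split_assignment = split), class = "cohort")
}

# largest-remainder assignment by patient, order shuffled by seed
assign_splits <- function(pids, seed,
                          frac = c(train = 0.6, validation = 0.2, test = 0.2)) {
  n <- length(pids)
  frac <- frac / sum(frac)
  base <- floor(frac * n)
  rem <- frac * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  base[frac > 0] <- pmax(base[frac > 0], 1L)  # non-empty splits, feasible for n >= 5
  while (sum(base) > n) {  # re-trim if the floor forced extras
    i <- which.max(base)
    base[i] <- base[i] - 1L
  }
  ord <- with_seed(child_seed(seed, 999983L), sample.int(n))
  split <- rep(names(base), times = base)
  stats::setNames(split[order(ord)], pids)
}

#' Images belonging to one split of a cohort
#' @param cohort a `cohort`.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @return list of [labeled_image].
#' @export
cohort_split <- function(cohort, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  keep <- names(cohort$split_assignment)[cohort$split_assignment == split]
  Filter(function(li) li$patient_id %in% keep, cohort$images)
}

#' Empirical class frequencies over a set of labelled images
#'
#' Returns the pixel share of each class, F_i = N_i / sum(N), pooled over all
#' supplied images; frequencies sum to one.
#'
#' @param images list of [labeled_image] (or bare label matrices).
#' @param n_classes number of classes (default 4).
#' @return numeric vector of length `n_classes`.
#' @export
class_frequencies <- function(images, n_classes = 4L) {
  if (inherits(images, "labeled_image")) images <- list(images)
  if (length(images) == 0) stop("class_frequencies: no images supplied")
  counts <- rep(0, n_classes)
  for (im in images) {
    lab <- if (inherits(im, "labeled_image")) im$labels else im
    if (any(lab >= n_classes | lab < 0))
      stop("class_frequencies: label outside [0, n_classes)")
    counts <- counts + tabulate(as.integer(lab) + 1L, nbins = n_classes)
  }
  counts / sum(counts)
}
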