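#' Generate a feature table with planted informative channels
#'
#' Emulates the pooled-feature stage of the pipeline with known ground truth:
#' every channel is Gaussian noise, except `k_informative` channels (drawn
#' uniformly without replacement) whose class-1 mean is shifted by
#' `effect_size * noise_sd`. The identities of the informative channels are
#' returned so selection recovery can be scored exactly.
#'
#' Defaults mirror the study conditions of the corneal-ulcer application:
#' 712 samples and 512 candidate maps (the width of the late residual
#' layers). Signal sparsity and strength have no published analogue, so the
#' defaults plant a moderately sparse, unit-strength signal.
#'
#' @param n_samples number of samples (images).
#' @param n_channels number of feature maps `w`.
#' @param k_informative number of class-predictive channels (`<= n_channels`).
#' @param effect_size class-mean shift of informative channels, in units of
#'   `noise_sd`. `0` plants no signal.
#' @param noise_sd standard deviation of the channel noise (> 0).
#' @param class_balance probability that a sample is class 1, in (0, 1).
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return A [feature_table()] tibble with an extra `informative_channels`
#'   attribute (sorted 1-based channel ids); retrieve it with
#'   [informative_channels()].
#' @export
#' @examples
#' ft <- planted_features(n_samples = 60, n_channels = 8, k_informative = 2,
#'                        effect_size = 3, seed = 1)
#' informative_channels(ft)
planted_features <- function(n_samples = 712, n_channels = 512,
                             k_informative = 32, effect_size = 1,
                             noise_sd = 1, class_balance = 0.5,
                             seed = NULL) {
  stopifnot(n_samples >= 2, n_channels >= 1,
            k_informative >= 0, k_informative <= n_channels,
            effect_size >= 0, noise_sd > 0,
            class_balance > 0, class_balance < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  labels <- rbinom(n_samples, 1L, class_balance)
  if (length(unique(labels)) < 2L) {
    abort("degenerate design: generated labels contain a single class; increase n_samples.")
  }
  informative <- sort(sample.int(n_channels, k_informative))
  x <- matrix(rnorm(n_samples * n_channels, 0, noise_sd),
              n_samples, n_channels)
  if (k_informative > 0 && effect_size > 0) {
    x[labels == 1L, informative] <-
      x[labels == 1L, informative] + effect_size * noise_sd
  }
  out <- feature_table(x, labels)
  attr(out, "informative_channels") <- informative
  out
}

#' @rdname planted_features
#' @param table a table produced by [planted_features()].
#' @export
informative_channels <- function(table) {
  attr(table, "informative_channels")
}

#' Generate toy stained-eye images with and without a lesion
#'
#' Produces small grayscale images (replicated to 3 channels so any RGB
#' backbone accepts them) of a textured circular disc resembling a
#' fluorescein-stained cornea. Class-1 images additionally contain one
#' bright, smooth-edged lesion blob placed uniformly at random so that it
#' fits inside the disc; class-0 images have no blob. With
#' `lesion_intensity = 0` the two classes are pixelwise identically
#' distributed.
#'
#' @param n_samples number of images; labels alternate 0/1 so both classes
#'   are always present.
#' @param image_size side length in pixels (square images).
#' @param lesion_intensity peak added intensity of the lesion blob, on the
#'   [0, 1] pixel scale.
#' @param lesion_radius_range length-2 interval (pixels) from which each
#'   lesion radius is drawn uniformly.
#' @param background_texture_sd standard deviation of the Gaussian texture
#'   added inside the disc.
#' @param seed integer seed for reproducibility.
#' @param dir optional directory: images are written as PNG under
#'   `class_0/` and `class_1/` subfolders (the layout [load_image_folder()]
#'   reads).
#' @return A list with `images` (list of `image_size x image_size x 3`
#'   arrays in [0, 1]), `labels` (integer 0/1), and `files` (paths, or NULL).
#' @export
#' @examples
#' toys <- toy_images(n_samples = 4, image_size = 48, seed = 1)
#' range(toys$images[[1]])
toy_images <- function(n_samples = 20, image_size = 64,
                       lesion_intensity = 0.6,
                       lesion_radius_range = c(5, 10),
                       background_texture_sd = 0.05,
                       seed = NULL, dir = NULL) {
  stopifnot(n_samples >= 2, length(lesion_radius_range) == 2,
            lesion_radius_range[1] > 0,
            lesion_radius_range[1] <= lesion_radius_range[2],
            lesion_intensity >= 0, background_texture_sd >= 0)
  disc_radius <- 0.45 * image_size
  if (max(lesion_radius_range) >= disc_radius) {
    abort("image_size too small: the largest lesion cannot fit inside the corneal disc.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  labels <- rep(c(0L, 1L), length.out = n_samples)

  centre <- (image_size + 1) / 2
  xy <- expand.grid(i = seq_len(image_size), j = seq_len(image_size))
  d_centre <- sqrt((xy$i - centre)^2 + (xy$j - centre)^2)
  disc <- matrix(d_centre <= disc_radius, image_size, image_size)

  images <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    img <- matrix(0.05, image_size, image_size)
    img[disc] <- 0.35 + rnorm(sum(disc), 0, background_texture_sd)
    # lesion placement is drawn for every sample so the RNG stream (and
    # hence the background texture) is class-independent
    r <- runif(1, lesion_radius_range[1], lesion_radius_range[2])
    theta <- runif(1, 0, 2 * pi)
    rho <- runif(1, 0, disc_radius - r)
    ci <- centre + rho * cos(theta)
    cj <- centre + rho * sin(theta)
    if (labels[s] == 1L && lesion_intensity > 0) {
      d_les <- sqrt((xy$i - ci)^2 + (xy$j - cj)^2)
      blob <- matrix(exp(-(d_les / (0.6 * r))^2), image_size, image_size)
      img <- img + lesion_intensity * blob
    }
    img <- pmin(pmax(img, 0), 1)
    images[[s]] <- array(rep(img, 3), c(image_size, image_size, 3))
  }

  files <- NULL
  if (!is.null(dir)) {
    files <- write_toy_images(images, labels, dir)
  }
  list(images = images, labels = labels, files = files)
}

#' Write toy images to the per-class folder layout
#'
#' @param images list of H x W x 3 arrays in [0, 1].
#' @param labels integer 0/1 vector, one per image.
#' @param dir output directory; `class_0/` and `class_1/` are created.
#' @return invisibly, the vector of written file paths.
#' @export
write_toy_images <- function(images, labels, dir) {
  stopifnot(length(images) == length(labels))
  for (cl in c(0, 1)) {
    dir.create(file.path(dir, paste0("class_", cl)),
               recursive = TRUE, showWarnings = FALSE)
  }
  files <- character(length(images))
  for (s in seq_along(images)) {
    files[s] <- file.path(dir, paste0("class_", labels[s]),
                          sprintf("img_%04d.png", s))
    EBImage::writeImage(
      EBImage::Image(aperm(images[[s]], c(2, 1, 3)), colormode = "Color"),
      files[s]
    )
  }
  invisible(files)
}
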