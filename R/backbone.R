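# ResNet-18 layer graph, weights, forward pass and per-map mean pooling.
#
# The enumeration covers every tensor-producing operation from the first
# convolution through the final global pooling inclusive -- convolutions,
# batch normalizations, ReLUs, the max pool, and each residual elementwise
# sum -- and excludes the input and the classification head (fully-connected,
# softmax, output). That convention yields 67 candidate layers for ResNet-18
# at the 224 x 224 x 3 reference input, with per-shape subtotals
# 3 x (112,112,64), 15 x (56,56,64), 16 x (28,28,128), 16 x (14,14,256),
# 16 x (7,7,512) and 1 x (1,1,512).

STAGE_WIDTH <- c(`2` = 64L, `3` = 128L, `4` = 256L, `5` = 512L)
STAGE_SPACE <- c(`2` = 56L, `3` = 28L, `4` = 14L, `5` = 7L)

# ordered op plan; each entry: name, op, input(s), conv geometry
resnet18_plan <- function() {
  plan <- list(
    list(name = "conv1", op = "conv", input = ".input",
         k = 7L, stride = 2L, pad = 3L, cin = 3L, cout = 64L),
    list(name = "bn_conv1", op = "bn", input = "conv1", channels = 64L),
    list(name = "conv1_relu", op = "relu", input = "bn_conv1"),
    list(name = "pool1", op = "maxpool", input = "conv1_relu")
  )
  block_in <- "pool1"
  in_ch <- 64L
  for (s in 2:5) {
    width <- STAGE_WIDTH[[as.character(s)]]
    for (blk in c("a", "b")) {
      p <- paste0(s, blk)
      downsample <- s > 2 && blk == "a"
      stride <- if (downsample) 2L else 1L
      plan <- c(plan, list(
        list(name = sprintf("res%s_branch2a", p), op = "conv", input = block_in,
             k = 3L, stride = stride, pad = 1L, cin = in_ch, cout = width)
      ))
      if (downsample) {
        plan <- c(plan, list(
          list(name = sprintf("res%s_branch1", p), op = "conv", input = block_in,
               k = 1L, stride = 2L, pad = 0L, cin = in_ch, cout = width),
          list(name = sprintf("bn%s_branch1", p), op = "bn",
               input = sprintf("res%s_branch1", p), channels = width)
        ))
      }
      shortcut <- if (downsample) sprintf("bn%s_branch1", p) else block_in
      plan <- c(plan, list(
        list(name = sprintf("bn%s_branch2a", p), op = "bn",
             input = sprintf("res%s_branch2a", p), channels = width),
        list(name = sprintf("res%s_branch2a_relu", p), op = "relu",
             input = sprintf("bn%s_branch2a", p)),
        list(name = sprintf("res%s_branch2b", p), op = "conv",
             input = sprintf("res%s_branch2a_relu", p),
             k = 3L, stride = 1L, pad = 1L, cin = width, cout = width),
        list(name = sprintf("bn%s_branch2b", p), op = "bn",
             input = sprintf("res%s_branch2b", p), channels = width),
        list(name = sprintf("res%s", p), op = "add",
             input = c(sprintf("bn%s_branch2b", p), shortcut)),
        list(name = sprintf("res%s_relu", p), op = "relu",
             input = sprintf("res%s", p))
      ))
      block_in <- sprintf("res%s_relu", p)
      in_ch <- width
    }
  }
  c(plan, list(list(name = "pool5", op = "gap", input = "res5b_relu")))
}

#' Enumerate the candidate layers of a backbone
#'
#' Lists, in network order, every intermediate output whose feature maps can
#' be pooled and classified: each convolution, batch normalization, ReLU,
#' pooling and residual elementwise-sum output from the first convolution
#' through the final global average pool. The input and the
#' fully-connected/softmax/output head are excluded. For ResNet-18 this
#' gives 67 layers.
#'
#' @param backbone_id backbone identifier; only `"resnet18"` is available.
#' @param input_size reference square input size in pixels (default 224).
#' @return A tibble with one row per layer: `index` (1-based sweep position),
#'   `name`, `height`, `width`, `channels`, and `n_attributes`
#'   (`height * width * channels`).
#' @export
#' @examples
#' layers <- enumerate_layers()
#' nrow(layers)                       # 67
#' layers[layers$name == "pool5", ]   # 1 x 1 x 512
enumerate_layers <- function(backbone_id = "resnet18", input_size = 224) {
  if (!identical(backbone_id, "resnet18")) {
    abort(sprintf("unknown backbone_id '%s' (available: resnet18)", backbone_id))
  }
  plan <- resnet18_plan()
  space <- floor((input_size + 2 * 3 - 7) / 2) + 1  # conv1 output side
  shape_of <- function(entry) {
    nm <- entry$name
    if (nm %in% c("conv1", "bn_conv1", "conv1_relu")) {
      return(c(space, space, 64L))
    }
    if (nm == "pool1") {
      return(c(floor((space + 2 - 3) / 2) + 1, floor((space + 2 - 3) / 2) + 1, 64L))
    }
    if (nm == "pool5") return(c(1L, 1L, 512L))
    s <- as.integer(substr(sub("^(res|bn)", "", nm), 1, 1))
    side <- as.integer(round(STAGE_SPACE[[as.character(s)]] * input_size / 224))
    c(side, side, STAGE_WIDTH[[as.character(s)]])
  }
  shapes <- t(vapply(plan, shape_of, numeric(3)))
  tibble::tibble(
    index = seq_along(plan),
    name = vapply(plan, `[[`, character(1), "name"),
    height = as.integer(shapes[, 1]),
    width = as.integer(shapes[, 2]),
    channels = as.integer(shapes[, 3]),
    n_attributes = as.integer(shapes[, 1] * shapes[, 2] * shapes[, 3])
  )
}

#' Total activation count for layers of a given output shape
#'
#' @param layers a tibble from [enumerate_layers()] (possibly filtered).
#' @param shape length-3 integer vector `c(height, width, channels)`.
#' @return `(number of layers with that shape) * height * width * channels`.
#' @export
#' @examples
#' count_layer_attributes(enumerate_layers(), c(7, 7, 512))  # 401408
count_layer_attributes <- function(layers, shape) {
  stopifnot(length(shape) == 3)
  if (NROW(layers) == 0) return(0L)
  hits <- layers$height == shape[1] & layers$width == shape[2] &
    layers$channels == shape[3]
  sum(hits) * prod(shape)
}

#' Random (He-initialized) ResNet-18 weights
#'
#' Builds a full, deterministic weight set for the forward pass without any
#' pretrained download: convolution kernels are drawn from
#' `N(0, 2 / fan_in)` and batch-norm layers start at identity
#' (`gamma = 1, beta = 0`, running mean 0, variance 1). A list with the same
#' structure (named `$w` arrays for convolutions; `$gamma/$beta/$mean/$var`
#' for batch norms) holding converted pretrained parameters can be passed
#' anywhere these weights are accepted.
#'
#' @param seed integer seed; the same seed always yields bit-identical weights.
#' @return Named list of parameter sets, one per parameterized layer.
#' @export
resnet18_weights <- function(seed = 1) {
  withr::local_seed(seed)
  weights <- list()
  for (entry in resnet18_plan()) {
    if (entry$op == "conv") {
      fan_in <- entry$k * entry$k * entry$cin
      weights[[entry$name]] <- list(
        w = array(rnorm(fan_in * entry$cout, sd = sqrt(2 / fan_in)),
                  c(entry$k, entry$k, entry$cin, entry$cout))
      )
    } else if (entry$op == "bn") {
      n <- entry$channels
      weights[[entry$name]] <- list(gamma = rep(1, n), beta = rep(0, n),
                                    mean = rep(0, n), var = rep(1, n))
    }
  }
  attr(weights, "backbone") <- "resnet18"
  attr(weights, "seed") <- seed
  weights
}

#' Raw activation tensor of one layer for one image
#'
#' Runs the forward pass up to (and including) the named layer and returns
#' the full activation stack, for inspection or independent recomputation of
#' pooled descriptors.
#'
#' @param image anything [preprocess_image()] accepts (path, EBImage Image,
#'   or numeric array).
#' @param layer layer name (see [enumerate_layers()]) or a one-row subset of
#'   the enumeration.
#' @param weights a weight list from [resnet18_weights()].
#' @return Numeric array `height x width x channels`.
#' @export
layer_activation <- function(image, layer, weights = resnet18_weights()) {
  layer <- layer_name_of(layer)
  x <- preprocess_image(image)
  resnet18_forward(x, weights, upto = layer)
}

layer_name_of <- function(layer) {
  if (is.character(layer)) return(layer)
  if (is.data.frame(layer)) return(layer$name[[1]])
  if (is.list(layer) && !is.null(layer$name)) return(layer$name[[1]])
  abort("`layer` must be a layer name or a row of enumerate_layers().")
}

resnet18_forward <- function(x, weights, upto) {
  acts <- new.env(parent = emptyenv())
  assign(".input", x, envir = acts)
  for (entry in resnet18_plan()) {
    value <- switch(entry$op,
      conv = conv2d(get(entry$input, acts), weights[[entry$name]]$w,
                    stride = entry$stride, pad = entry$pad),
      bn = batchnorm(get(entry$input, acts), weights[[entry$name]]),
      relu = relu(get(entry$input, acts)),
      maxpool = maxpool2d(get(entry$input, acts)),
      add = get(entry$input[1], acts) + get(entry$input[2], acts),
      gap = global_avgpool(get(entry$input, acts))
    )
    assign(entry$name, value, envir = acts)
    if (entry$name == upto) return(value)
  }
  abort(sprintf("layer '%s' is not part of the resnet18 enumeration.", upto))
}

#' Preprocess an image for the backbone
#'
#' Decodes (if given a path), converts to height x width x 3, resizes with
#' bilinear interpolation to the reference input size, scales to [0, 1] and
#' standardizes each channel with the canonical ImageNet statistics
#' (means 0.485/0.456/0.406, SDs 0.229/0.224/0.225). Grayscale inputs are
#' replicated across the three channels.
#'
#' @param image file path (PNG/JPG), EBImage `Image`, or numeric array
#'   (H x W, or H x W x C) with values in [0, 1] or [0, 255].
#' @param size target side length (default 224).
#' @return `size x size x 3` numeric array.
#' @export
preprocess_image <- function(image, size = 224) {
  if (is.character(image)) image <- EBImage::readImage(image)
  if (inherits(image, "Image")) {
    image <- EBImage::resize(image, w = size, h = size)
    a <- as.array(image)
    # EBImage stores (x, y, c); transpose to (row = y, col = x, c)
    a <- if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else {
    a <- as.array(image)
    if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    if (max(a) > 1.5) a <- a / 255
    img <- EBImage::Image(aperm(a, c(2, 1, 3)),
                          colormode = if (dim(a)[3] == 3) "Color" else "Grayscale")
    a <- as.array(EBImage::resize(img, w = size, h = size))
    a <- if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  if (dim(a)[3] == 1) a <- array(rep(a, 3), c(dim(a)[1:2], 3))
  a <- pmin(pmax(a, 0), 1)
  means <- c(0.485, 0.456, 0.406)
  sds <- c(0.229, 0.224, 0.225)
  for (c in 1:3) a[, , c] <- (a[, , c] - means[c]) / sds[c]
  a
}

#' Reduce an activation tensor to per-map means
#'
#' The pooled descriptor of a layer: each a x b feature map becomes its
#' arithmetic mean, giving one scalar per channel.
#'
#' @param tensor numeric array `height x width x channels`.
#' @return numeric vector of length `channels`.
#' @export
#' @examples
#' pool_feature_maps(array(c(1, 3, 2, 4), c(2, 2, 1)))  # 2.5
pool_feature_maps <- function(tensor) {
  d <- dim(tensor)
  colMeans(matrix(tensor, d[1] * d[2], d[3]))
}

#' List images stored in per-class subfolders
#'
#' Reads the `class_0/`, `class_1/` layout (any two `class_*` folders, in
#' sorted order, are mapped to labels 0 and 1).
#'
#' @param dir directory containing the class subfolders.
#' @return tibble with columns `file` and `label`.
#' @export
load_image_folder <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE))
  classes <- classes[grepl("class_", basename(classes))]
  if (length(classes) != 2) {
    abort(sprintf("expected exactly two class_* subfolders under '%s'.", dir))
  }
  rows <- purrr::map2_dfr(classes, c(0L, 1L), function(d, lab) {
    files <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    tibble::tibble(file = files, label = lab)
  })
  if (nrow(rows) == 0) abort(sprintf("no images found under '%s'.", dir))
  rows
}

#' Extract pooled features of one layer for a set of images
#'
#' For every image, runs the backbone forward to the requested layer and
#' records the spatial mean of each feature map, yielding one row of the
#' feature table per image.
#'
#' @param images one of: a directory with `class_0/`, `class_1/` subfolders;
#'   a tibble from [load_image_folder()]; a list as returned by
#'   [toy_images()]; or a list of arrays (then `labels` must be given).
#' @param layer layer name or a row of [enumerate_layers()].
#' @param weights weight list ([resnet18_weights()] by default).
#' @param labels 0/1 labels, required only when `images` is a bare list of
#'   arrays.
#' @return A [feature_table()] with one column per feature map of the layer
#'   and a `label` column; the `layer` attribute records provenance.
#' @export
extract_layer_features <- function(images, layer,
                                   weights = resnet18_weights(),
                                   labels = NULL) {
  layer <- layer_name_of(layer)
  enum <- enumerate_layers()
  spec <- enum[enum$name == layer, ]
  if (nrow(spec) != 1) abort(sprintf("unknown layer '%s'.", layer))

  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    images <- load_image_folder(images)
  }
  if (is.data.frame(images)) {
    labels <- images$label
    images <- as.list(images$file)
  } else if (is.list(images) && !is.null(images$images)) {
    labels <- images$labels
    images <- images$images
  }
  if (is.null(labels)) abort("`labels` are required for a bare image list.")
  if (length(images) == 0) abort("no images to extract from.")

  rows <- t(vapply(images, function(img) {
    pool_feature_maps(resnet18_forward(preprocess_image(img), weights,
                                       upto = layer))
  }, numeric(spec$channels)))
  feature_table(rows, labels, layer = as.list(spec))
}
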