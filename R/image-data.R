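# Image-folder reading, stratified splitting, and augmentation.

#' Load a class-subdirectory image folder
#'
#' Enumerates an image folder laid out one subdirectory per class (the
#' single-cell cytology convention): class names are the subdirectory names
#' sorted lexicographically, items are enumerated deterministically (sorted
#' file names). Files are referenced, not decoded; use [read_images()] to
#' materialize pixel data.
#'
#' @param root_path Directory with >= 2 class subdirectories, each holding
#'   >= 1 image file (PNG/JPEG/BMP/TIFF).
#' @return A `cell_image_set` tibble with columns `id`, `file`, `class_name`,
#'   `class_index`, and attribute `class_names`.
#' @export
load_image_folder <- function(root_path) {
  if (!dir.exists(root_path))
    abort_data(sprintf("image folder '%s' does not exist", root_path))
  dirs <- sort(list.dirs(root_path, recursive = FALSE, full.names = TRUE))
  if (length(dirs) < 2L)
    abort_data(sprintf(
      "image folder '%s' needs >= 2 class subdirectories, found %d",
      root_path, length(dirs)))
  exts <- "\\.(png|jpg|jpeg|bmp|tif|tiff)$"
  rows <- vector("list", length(dirs))
  for (ci in seq_along(dirs)) {
    files <- sort(list.files(dirs[ci], pattern = exts, ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      abort_data(sprintf("class directory '%s' contains no image files",
                         dirs[ci]))
    cls <- basename(dirs[ci])
    rows[[ci]] <- tibble::tibble(
      id = sub(exts, "", basename(files), ignore.case = TRUE),
      file = files, class_name = cls, class_index = ci)
  }
  ds <- dplyr::bind_rows(rows)
  attr(ds, "class_names") <- basename(dirs)
  class(ds) <- c("cell_image_set", class(ds))
  ds
}

#' Materialize image pixel data for a dataset
#'
#' Reads every referenced file into an `(H, W, 3)` array in `[0, 1]`
#' (grayscale inputs are replicated to 3 channels). Unreadable files raise a
#' warning and are skipped (dropped from the result).
#'
#' @param dataset A `cell_image_set` with a `file` column.
#' @param size Optional target side length; images are resized (bilinear).
#' @return The dataset with an `image` list-column.
#' @export
read_images <- function(dataset, size = NULL) {
  imgs <- vector("list", nrow(dataset))
  ok <- rep(TRUE, nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    im <- tryCatch(EBImage::readImage(dataset$file[i]), error = function(e) NULL)
    if (is.null(im)) {
      warn(sprintf("skipping unreadable image file '%s'", dataset$file[i]))
      ok[i] <- FALSE
      next
    }
    a <- as.array(im)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1L) a <- array(a, c(dim(a)[1:2], 3L))
    if (!is.null(size) && !all(dim(a)[1:2] == size))
      a <- as.array(EBImage::resize(EBImage::Image(a, colormode = "Color"),
                                    w = size, h = size))
    imgs[[i]] <- pmin(pmax(a, 0), 1)
  }
  out <- dataset[ok, ]
  out$image <- imgs[ok]
  out
}

#' Stratified train/validation/test split
#'
#' Assigns every item to one of `train`, `val`, `test`, stratified within
#' class at the given ratios (default 3:1:1) by largest-remainder
#' apportionment, so per-class proportions are exact up to integer rounding.
#' Randomization is at the item level within class, seeded.
#'
#' @param dataset A `cell_image_set`.
#' @param ratios Length-3 positive weights for train/val/test; default
#'   `c(3, 1, 1)`.
#' @param seed Integer seed.
#' @return The dataset with a `split` column (factor train/val/test).
#' @export
split_dataset <- function(dataset, ratios = c(3, 1, 1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0))
    abort_config("ratios must be 3 positive weights")
  p <- ratios / sum(ratios)
  splits <- factor(rep(NA_character_, nrow(dataset)),
                   levels = c("train", "val", "test"))
  for (ci in sort(unique(dataset$class_index))) {
    idx <- which(dataset$class_index == ci)
    n <- length(idx)
    if (n < 5L)
      abort_data(sprintf(
        "class '%s' has only %d items; at least 5 are needed for a 3:1:1 split",
        dataset$class_name[idx[1]], n))
    base <- floor(n * p)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- n * p - base
      extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    perm <- with_seed(derive_seed(seed, paste0("split-", ci)), sample(idx))
    splits[perm] <- rep(c("train", "val", "test"), times = base)
  }
  dataset$split <- splits
  dataset
}

#' Write a split manifest CSV
#'
#' @param dataset A split `cell_image_set`.
#' @param path Output CSV path (columns filename, class, split).
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(dataset, path) {
  utils::write.csv(
    data.frame(filename = ifelse(is.na(dataset$file), dataset$id,
                                 basename(dataset$file)),
               class = dataset$class_name, split = as.character(dataset$split)),
    path, row.names = FALSE)
  invisible(path)
}

#' Augmentation policy
#'
#' The train-time augmentation set: random crop scaling, horizontal flip,
#' mirror (vertical) flip, and rotation. Magnitude defaults are conventional
#' mild settings; validation/test images get resize-only normalization.
#'
#' @param crop_scale_range Area-fraction interval of the random crop, a
#'   subset of `(0, 1]`. `c(1, 1)` disables cropping.
#' @param rotation_degrees Maximum absolute rotation; 0 disables.
#' @param horizontal_flip_p,vertical_flip_p Flip probabilities in `[0, 1]`.
#' @param output_size Side length of the output image.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(crop_scale_range = c(0.7, 1.0),
                           rotation_degrees = 15,
                           horizontal_flip_p = 0.5, vertical_flip_p = 0.5,
                           output_size = 64L) {
  if (any(crop_scale_range <= 0) || any(crop_scale_range > 1) ||
      crop_scale_range[1] > crop_scale_range[2])
    abort_config("crop_scale_range must be an interval inside (0, 1]")
  for (pp in c(horizontal_flip_p, vertical_flip_p))
    if (pp < 0 || pp > 1) abort_config("flip probabilities must lie in [0, 1]")
  if (rotation_degrees < 0) abort_config("rotation_degrees must be >= 0")
  structure(list(crop_scale_range = crop_scale_range,
                 rotation_degrees = rotation_degrees,
                 horizontal_flip_p = horizontal_flip_p,
                 vertical_flip_p = vertical_flip_p,
                 output_size = as.integer(output_size)),
            class = "augment_policy")
}

resize_image <- function(image, size) {
  if (all(dim(image)[1:2] == size)) return(image)
  a <- as.array(EBImage::resize(EBImage::Image(image, colormode = "Color"),
                                w = size, h = size))
  pmin(pmax(a, 0), 1)
}

#' Augment one image
#'
#' Applies, in order: random rotation, random area-scaled crop, random
#' horizontal and vertical flips, and a resize to the policy's output size.
#' The all-off policy (`crop_scale_range = c(1, 1)`, 0 degrees, flip
#' probabilities 0) reduces exactly to resize-only. Deterministic per
#' `rng_seed`; pixel values stay in `[0, 1]`.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param policy An [augment_policy()].
#' @param rng_seed Integer seed.
#' @return `(output_size, output_size, 3)` array.
#' @export
augment <- function(image, policy = augment_policy(), rng_seed = 1L) {
  with_seed(rng_seed, {
    img <- image
    S <- dim(img)[1]
    if (policy$rotation_degrees > 0) {
      ang <- runif(1, -policy$rotation_degrees, policy$rotation_degrees)
      bg <- stats::median(img[c(1, S), c(1, dim(img)[2]), 1])
      im <- EBImage::rotate(EBImage::Image(img, colormode = "Color"), ang,
                            output.dim = dim(img)[1:2], bg.col = bg)
      img <- pmin(pmax(as.array(im), 0), 1)
    }
    cs <- policy$crop_scale_range
    if (cs[1] < 1 || cs[2] < 1) {
      scale <- runif(1, cs[1], cs[2])
      side <- max(2L, round(dim(img)[1] * sqrt(scale)))
      if (side < dim(img)[1]) {
        r0 <- sample.int(dim(img)[1] - side + 1L, 1L)
        c0 <- sample.int(dim(img)[2] - side + 1L, 1L)
        img <- img[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE]
      }
    }
    if (policy$horizontal_flip_p > 0 && runif(1) < policy$horizontal_flip_p)
      img <- img[, dim(img)[2]:1, , drop = FALSE]
    if (policy$vertical_flip_p > 0 && runif(1) < policy$vertical_flip_p)
      img <- img[dim(img)[1]:1, , , drop = FALSE]
    resize_image(img, policy$output_size)
  })
}

# ---- batch assembly ---------------------------------------------------------

#' Per-channel normalization statistics of the training split
#'
#' @param dataset A `cell_image_set` with `image` and (optionally) `split`
#'   columns; when a split is present only training images contribute.
#' @return List with `mean` and `sd` (length 3 each).
#' @export
norm_stats <- function(dataset) {
  imgs <- dataset$image
  if (!is.null(dataset$split)) imgs <- imgs[dataset$split == "train"]
  acc_m <- c(0, 0, 0); acc_s <- c(0, 0, 0); n <- 0
  for (im in imgs) {
    for (ch in 1:3) {
      acc_m[ch] <- acc_m[ch] + sum(im[, , ch])
      acc_s[ch] <- acc_s[ch] + sum(im[, , ch]^2)
    }
    n <- n + prod(dim(im)[1:2])
  }
  m <- acc_m / n
  v <- acc_s / n - m^2
  list(mean = m, sd = sqrt(pmax(v, 1e-8)))
}

# Stack a list of (H, W, 3) images into a channel-first (3, H, W, N) batch,
# optionally normalized per channel.
as_image_batch <- function(images, stats = NULL) {
  d <- dim(images[[1]])
  x <- array(0, c(3L, d[1], d[2], length(images)))
  for (i in seq_along(images)) x[, , , i] <- aperm(images[[i]], c(3L, 1L, 2L))
  if (!is.null(stats)) x <- (x - stats$mean) / stats$sd
  x
}
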