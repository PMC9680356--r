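# Synthetic single-cell image generator.
#
# Renders grayscale (replicated to 3 channels) single-cell images: a filled
# cytoplasm whose boundary is a radially perturbed ellipse, an interior
# nucleus disk, radial intra-cytoplasm texture, and i.i.d. Gaussian intensity
# noise clipped to [0, 1]. The five default classes follow the morphology
# axes that separate cervical cell types — nucleus size, nucleo-cytoplasmic
# ratio, boundary irregularity, and texture — ordered by increasing N/C
# ratio to mimic the normal-to-abnormal gradient.

#' Class morphology parameters
#'
#' Per-class parameter ranges of the synthetic renderer. Radii are fractions
#' of the image side; intensities are mean grayscale levels in `[0, 1]`.
#'
#' @param name Class name.
#' @param nucleus_radius_range Length-2 numeric, nucleus radius range.
#' @param cytoplasm_radius_range Length-2 numeric, cytoplasm radius range;
#'   its minimum must exceed the nucleus maximum (nucleus stays inside).
#' @param boundary_irregularity Amplitude of the radial boundary
#'   perturbation (0 = smooth ellipse).
#' @param nucleus_intensity,cytoplasm_intensity Mean grayscale levels.
#' @param texture_grain Spatial frequency (cycles across the cytoplasm
#'   radius) of the radial texture.
#' @return A `class_morphology` list.
#' @export
class_morphology <- function(name, nucleus_radius_range, cytoplasm_radius_range,
                             boundary_irregularity = 0.1,
                             nucleus_intensity = 0.3, cytoplasm_intensity = 0.6,
                             texture_grain = 4) {
  m <- list(name = as.character(name),
            nucleus_radius_range = as.numeric(nucleus_radius_range),
            cytoplasm_radius_range = as.numeric(cytoplasm_radius_range),
            boundary_irregularity = boundary_irregularity,
            nucleus_intensity = nucleus_intensity,
            cytoplasm_intensity = cytoplasm_intensity,
            texture_grain = texture_grain)
  validate_morphology(m)
  structure(m, class = "class_morphology")
}

validate_morphology <- function(m) {
  chk_range <- function(r, field) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[2] < r[1] ||
        r[2] >= 0.5)
      abort_config(sprintf("invalid %s: must be 0 < min <= max < 0.5", field))
  }
  chk_range(m$nucleus_radius_range, "nucleus_radius_range")
  chk_range(m$cytoplasm_radius_range, "cytoplasm_radius_range")
  if (max(m$nucleus_radius_range) >= min(m$cytoplasm_radius_range))
    abort_config(
      "nucleus_radius_range: maximum must be below cytoplasm_radius_range minimum")
  for (field in c("nucleus_intensity", "cytoplasm_intensity")) {
    v <- m[[field]]
    if (!is.finite(v) || v < 0 || v > 1)
      abort_config(sprintf("invalid %s: must lie in [0, 1]", field))
  }
  if (m$boundary_irregularity < 0 || m$boundary_irregularity > 1)
    abort_config("invalid boundary_irregularity: must lie in [0, 1]")
  if (m$texture_grain < 0) abort_config("invalid texture_grain: must be >= 0")
  invisible(m)
}

#' Default five-class cell morphologies
#'
#' The built-in class parameter sets, ordered by increasing
#' nucleo-cytoplasmic ratio to mimic the normal-to-abnormal morphology
#' gradient of cervical cell types; classes also differ in boundary
#' irregularity and texture frequency.
#'
#' @return List of five [class_morphology()] objects.
#' @export
default_cell_classes <- function() {
  list(
    class_morphology("superficial_intermediate",
                     c(0.05, 0.08), c(0.32, 0.42), 0.05, 0.25, 0.75, 2),
    class_morphology("parabasal",
                     c(0.10, 0.13), c(0.28, 0.34), 0.05, 0.30, 0.65, 3),
    class_morphology("metaplastic",
                     c(0.13, 0.16), c(0.26, 0.32), 0.10, 0.30, 0.60, 5),
    class_morphology("koilocytotic",
                     c(0.16, 0.20), c(0.26, 0.32), 0.20, 0.35, 0.55, 7),
    class_morphology("dyskeratotic",
                     c(0.20, 0.24), c(0.27, 0.33), 0.30, 0.40, 0.50, 10)
  )
}

#' Synthetic dataset specification
#'
#' @param image_size Pixels per (square) side, at least 16. Default 64.
#' @param classes List of [class_morphology()] objects (2 to 10 classes);
#'   default: the five built-in cell classes ordered by increasing
#'   nucleo-cytoplasmic ratio.
#' @param noise_sd Additive Gaussian intensity-noise standard deviation in
#'   `[0, 1]` intensity units.
#' @param background_level Background intensity in `[0, 1]`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_size = 64L, classes = default_cell_classes(),
                           noise_sd = 0.03, background_level = 0.08) {
  if (image_size < 16) abort_config("image_size must be >= 16")
  if (length(classes) < 2L || length(classes) > 10L)
    abort_config("between 2 and 10 classes are supported")
  lapply(classes, validate_morphology)
  nms <- vapply(classes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort_config("class names must be distinct")
  sig <- vapply(classes, function(m)
    paste(unlist(m[-1]), collapse = ","), character(1))
  if (anyDuplicated(sig))
    abort_config("default class parameter sets must be pairwise distinct")
  for (v in c(noise_sd, background_level))
    if (!is.finite(v) || v < 0 || v > 1)
      abort_config("noise_sd and background_level must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size), classes = classes,
                 noise_sd = noise_sd, background_level = background_level),
            class = "synthetic_spec")
}

#' Render one synthetic cell image
#'
#' Draws a single cell: a cytoplasm region bounded by a radially perturbed
#' circle, an interior nucleus disk, radial texture inside the cytoplasm, and
#' clipped Gaussian intensity noise. Identical `(class_morph, rng_seed,
#' renderer settings)` give bit-identical images.
#'
#' @param class_morph A [class_morphology()].
#' @param rng_seed Integer seed; the image is a pure function of it.
#' @param image_size Side length in pixels.
#' @param noise_sd,background_level Renderer-level intensity settings.
#' @param center_jitter Maximum cell-center offset as a fraction of the image
#'   side (0 centers the cell exactly).
#' @return `(image_size, image_size, 3)` array in `[0, 1]` (grayscale
#'   replicated to 3 channels), with attributes `nucleus_mask`,
#'   `cytoplasm_mask` (logical matrices) and `radii` (`r_n`, `r_c` in
#'   pixels).
#' @export
render_cell <- function(class_morph, rng_seed, image_size = 64L,
                        noise_sd = 0.03, background_level = 0.08,
                        center_jitter = 0.04) {
  validate_morphology(class_morph)
  S <- as.integer(image_size)
  with_seed(rng_seed, {
    m <- class_morph
    r_n <- runif(1, m$nucleus_radius_range[1], m$nucleus_radius_range[2]) * S
    r_c <- runif(1, m$cytoplasm_radius_range[1], m$cytoplasm_radius_range[2]) * S
    cx <- runif(1, -center_jitter, center_jitter) * S
    cy <- runif(1, -center_jitter, center_jitter) * S
    # boundary perturbation: random-phase low-order harmonics, even in theta
    # when the phases vanish; amplitude scaled by boundary_irregularity
    n_harm <- 3L
    amp <- runif(n_harm, 0.3, 1)
    amp <- amp / sum(amp)
    ph <- runif(n_harm, 0, 2 * pi) * (m$boundary_irregularity > 0)
    ks <- 2L + seq_len(n_harm)
    tex_phase <- runif(1, 0, 2 * pi)
    coord <- seq_len(S) - (S + 1) / 2
    xx <- matrix(coord, S, S) - cx          # rows
    yy <- matrix(coord, S, S, byrow = TRUE) - cy
    rr <- sqrt(xx^2 + yy^2)
    th <- atan2(yy, xx)
    pert <- 0
    for (j in seq_len(n_harm)) pert <- pert + amp[j] * cos(ks[j] * th + ph[j])
    r_bound <- r_c * (1 + m$boundary_irregularity * pert)
    cyt_mask <- rr <= r_bound
    nuc_mask <- rr <= r_n
    img <- matrix(background_level, S, S)
    # radial texture: rotationally symmetric, frequency set by texture_grain
    tex <- 0.06 * sin(2 * pi * m$texture_grain * rr / r_c + tex_phase)
    img[cyt_mask] <- m$cytoplasm_intensity + tex[cyt_mask]
    # soft intensity falloff towards the cytoplasm rim
    rim <- cyt_mask & (rr > 0.85 * r_bound)
    img[rim] <- img[rim] - 0.08
    img[nuc_mask] <- m$nucleus_intensity +
      0.03 * sin(2 * pi * 2 * rr[nuc_mask] / max(r_n, 1))
    if (noise_sd > 0) img <- img + matrix(rnorm(S * S, sd = noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)
    out <- array(img, c(S, S, 3L))
    attr(out, "nucleus_mask") <- nuc_mask
    attr(out, "cytoplasm_mask") <- cyt_mask
    attr(out, "radii") <- c(r_n = r_n, r_c = r_c)
    out
  })
}

#' Generate a labeled synthetic dataset
#'
#' Renders `n_per_class` images for every class of the spec. The result is a
#' pure function of `(spec, n_per_class, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_per_class Images per class (>= 1).
#' @param seed Integer master seed; each image gets a derived child seed.
#' @return A `cell_image_set`: a tibble with columns `id`, `file` (`NA` until
#'   written), `class_name`, `class_index`, `image` (list of arrays), `seed`,
#'   and attributes `class_names` and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), n_per_class = 10L,
                             seed = 1L) {
  if (n_per_class < 1) abort_config("n_per_class must be >= 1")
  rows <- list()
  k <- 0L
  for (ci in seq_along(spec$classes)) {
    m <- spec$classes[[ci]]
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- derive_seed(seed, sprintf("img-%d-%d", ci, i))
      img <- render_cell(m, s, image_size = spec$image_size,
                         noise_sd = spec$noise_sd,
                         background_level = spec$background_level)
      attributes(img) <- list(dim = dim(img))   # drop mask attrs
      rows[[k]] <- tibble::tibble(
        id = sprintf("%s_%04d", m$name, i), file = NA_character_,
        class_name = m$name, class_index = ci,
        image = list(img), seed = s)
    }
  }
  ds <- dplyr::bind_rows(rows)
  attr(ds, "class_names") <- vapply(spec$classes, `[[`, character(1), "name")
  attr(ds, "spec") <- spec
  class(ds) <- c("cell_image_set", class(ds))
  ds
}

#' Write a dataset to the class-subdirectory image-folder layout
#'
#' Writes one PNG per image under `root/<class_name>/`, identical to the
#' layout expected for real cytology folders, plus a `manifest.csv`
#' (filename, class_name, class_index, seed).
#'
#' @param dataset A `cell_image_set` with an `image` list-column.
#' @param root Output directory (created if needed).
#' @return The dataset tibble with its `file` column filled, invisibly.
#' @export
write_image_folder <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    cls <- dataset$class_name[i]
    dir.create(file.path(root, cls), showWarnings = FALSE)
    f <- file.path(root, cls, paste0(dataset$id[i], ".png"))
    EBImage::writeImage(EBImage::Image(dataset$image[[i]], colormode = "Color"),
                        f, type = "png", bits.per.sample = 8L)
    files[i] <- f
  }
  out <- dataset
  out$file <- files
  manifest <- data.frame(filename = basename(files),
                         class_name = dataset$class_name,
                         class_index = dataset$class_index,
                         seed = dataset$seed)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
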