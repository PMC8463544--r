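# Seeded multi-label phantom image corpora.
#
# Real chest-radiograph / head-CT corpora are emulated by a shared background
# phantom (a centred ellipse standing in for the anatomy) plus one localized
# geometric primitive per finding label. Because every label's information is
# spatially localized at a known position, downstream attribution maps have a
# ground truth and classifier separability is controlled by a single contrast
# parameter.

#' Specification of the phantom image generator
#'
#' @param resolution Image side length in pixels; a power of two, >= 8.
#' @param label_names Character vector of finding names. Defaults to
#'   `finding_1 ... finding_n` when `n_labels` is given instead.
#' @param n_labels Number of finding labels (used when `label_names` missing).
#' @param lesion_descriptors Optional list (one per label) with fields
#'   `type` ("blob", "ring", "line" or "texture"), `center` (fractions of the
#'   image side), `extent` (fraction of the image side) and `contrast`
#'   (additive intensity in image units, images live in [0,1]). When omitted,
#'   blobs are placed on a circle around the phantom centre.
#' @param contrast Default additive lesion contrast used for auto-placed
#'   descriptors (default 0.35).
#' @param background Named list with `axes` (two fractions, ellipse semi-axes)
#'   and `intensity`.
#' @param noise_sigma Additive Gaussian pixel noise standard deviation
#'   (default 0.05).
#' @param images_per_patient Number of consecutive images sharing a patient id
#'   (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(resolution = 32,
                         label_names = NULL,
                         n_labels = 3,
                         lesion_descriptors = NULL,
                         contrast = 0.35,
                         background = list(axes = c(0.42, 0.36), intensity = 0.45),
                         noise_sigma = 0.05,
                         images_per_patient = 1) {
  check_that(is_power_of_two(resolution) && resolution >= 8,
             "resolution must be a power of two >= 8")
  if (is.null(label_names)) label_names <- paste0("finding_", seq_len(n_labels))
  L <- length(label_names)
  check_that(L >= 1, "need at least one label")
  if (is.null(lesion_descriptors)) {
    ang <- 2 * pi * (seq_len(L) - 1) / L
    lesion_descriptors <- lapply(seq_len(L), function(k) {
      list(type = "blob",
           center = c(0.5 + 0.26 * cos(ang[k]), 0.5 + 0.26 * sin(ang[k])),
           extent = 0.11,
           contrast = contrast)
    })
  }
  check_that(length(lesion_descriptors) == L,
             "every label needs exactly one lesion descriptor")
  for (d in lesion_descriptors) {
    check_that(d$type %in% c("blob", "ring", "line", "texture"),
               "unknown lesion type: ", d$type)
    check_that(is.finite(d$contrast), "lesion contrast must be finite")
  }
  check_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  check_that(images_per_patient >= 1, "images_per_patient must be positive")
  structure(list(resolution = as.integer(resolution),
                 label_names = label_names,
                 lesion_descriptors = lesion_descriptors,
                 background = background,
                 noise_sigma = noise_sigma,
                 images_per_patient = as.integer(images_per_patient)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d px, %d labels (%s), noise sd %.3g, %d image(s)/patient\n",
              x$resolution, x$resolution, length(x$label_names),
              paste(x$label_names, collapse = ", "),
              x$noise_sigma, x$images_per_patient))
  invisible(x)
}

# pixel-centre coordinate grids as fractions of the side
.coord_grid <- function(res) {
  u <- (seq_len(res) - 0.5) / res
  list(x = matrix(u, res, res, byrow = FALSE),   # row index -> x
       y = matrix(u, res, res, byrow = TRUE))    # col index -> y
}

# logical mask of the pixels a descriptor covers
lesion_mask <- function(desc, res) {
  g <- .coord_grid(res)
  dx <- g$x - desc$center[1]
  dy <- g$y - desc$center[2]
  r <- desc$extent
  switch(desc$type,
         blob = dx^2 + dy^2 <= r^2,
         ring = {
           rr <- dx^2 + dy^2
           rr <= r^2 & rr >= (0.55 * r)^2
         },
         line = {
           ang <- desc$angle %||% (pi / 4)
           d_perp <- abs(-sin(ang) * dx + cos(ang) * dy)
           d_par <- abs(cos(ang) * dx + sin(ang) * dy)
           d_perp <= 0.22 * r & d_par <= r
         },
         texture = abs(dx) <= r & abs(dy) <= r)
}

# additive intensity pattern of a descriptor (0 outside its mask)
lesion_pattern <- function(desc, res) {
  m <- lesion_mask(desc, res)
  pat <- matrix(0, res, res)
  if (desc$type == "texture") {
    idx <- outer(seq_len(res), seq_len(res),
                 function(i, j) (i %/% 2 + j %/% 2) %% 2)
    pat[m] <- desc$contrast * (2 * idx[m] - 1) # +/- checkerboard, mean ~ 0
  } else {
    pat[m] <- desc$contrast
  }
  pat
}

background_phantom <- function(spec) {
  res <- spec$resolution
  g <- .coord_grid(res)
  ax <- spec$background$axes
  inside <- ((g$x - 0.5) / ax[1])^2 + ((g$y - 0.5) / ax[2])^2 <= 1
  img <- matrix(0, res, res)
  img[inside] <- spec$background$intensity
  img
}

#' Render one phantom image for a multi-hot label vector
#'
#' Deterministic in `(labels, spec, seed)`: the background phantom is always
#' present, each positive label adds its geometric primitive at its fixed
#' descriptor location, and seeded Gaussian noise is added last. Pixel values
#' are clipped to [0,1].
#'
#' @param labels Multi-hot 0/1 vector, one entry per `spec$label_names`.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the pixel noise.
#' @return A `resolution x resolution` matrix in [0,1].
#' @export
generate_image <- function(labels, spec, seed = 0L) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  check_that(length(labels) == length(spec$label_names),
             "labels length (", length(labels), ") does not match spec (",
             length(spec$label_names), ")")
  check_that(all(labels %in% c(0, 1)), "labels must be binary")
  img <- background_phantom(spec)
  for (k in which(labels == 1)) {
    img <- img + lesion_pattern(spec$lesion_descriptors[[k]], spec$resolution)
  }
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                                        nrow(img), ncol(img)))
  }
  pmin(pmax(img, 0), 1)
}

#' A list of distinct label combinations ("classes")
#'
#' Each class is one unique multi-hot vector over the finding labels, mirroring
#' the class-as-label-combination design of multi-label imaging benchmarks.
#'
#' @param combinations 0/1 matrix, one row per class.
#' @param label_names Optional character vector naming the columns.
#' @return Object of class `class_list`.
#' @export
class_list <- function(combinations, label_names = NULL) {
  combinations <- as.matrix(combinations)
  storage.mode(combinations) <- "integer"
  check_that(nrow(combinations) >= 1, "ClassList must not be empty")
  check_that(all(combinations %in% c(0L, 1L)), "combinations must be binary")
  check_that(!anyDuplicated(combo_key(combinations)),
             "class combinations must be distinct")
  if (!is.null(label_names)) {
    check_that(ncol(combinations) == length(label_names),
               "combination length must equal number of labels")
    colnames(combinations) <- label_names
  }
  structure(list(combinations = combinations), class = "class_list")
}

#' Default class list: no-finding, singletons, then pairs
#'
#' Deterministic enumeration of `n_classes` distinct combinations over
#' `n_labels` labels, ordered by number of positive labels then
#' lexicographically, optionally starting with the all-zero "no finding"
#' class.
#'
#' @param n_labels Number of binary labels.
#' @param n_classes Number of classes requested.
#' @param include_no_finding Include the all-zero combination first.
#' @return A [class_list()].
#' @export
default_class_list <- function(n_labels, n_classes, include_no_finding = TRUE) {
  combos <- list()
  if (include_no_finding) combos <- list(integer(n_labels))
  for (k in 1:n_labels) {
    for (set in utils::combn(n_labels, k, simplify = FALSE)) {
      v <- integer(n_labels); v[set] <- 1L
      combos <- c(combos, list(v))
      if (length(combos) >= n_classes) break
    }
    if (length(combos) >= n_classes) break
  }
  check_that(length(combos) >= n_classes,
             "not enough distinct combinations for ", n_classes, " classes")
  class_list(do.call(rbind, combos[seq_len(n_classes)]))
}

#' Generate a seeded multi-label phantom dataset
#'
#' Emits exactly `per_class` images for every class in `classes`, assigns
#' patient ids in consecutive blocks of `spec$images_per_patient` (a patient
#' never spans classes), and splits patients into train/validation/test folds
#' within class strata.
#'
#' @param spec A [phantom_spec()].
#' @param classes A [class_list()].
#' @param per_class Images per class (>= 1).
#' @param fold_fractions Train/val/test fractions summing to 1.
#' @param seed Integer master seed.
#' @return A `dataset_store`.
#' @export
generate_dataset <- function(spec, classes, per_class,
                             fold_fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  check_that(inherits(classes, "class_list"), "classes must be a class_list")
  check_that(per_class >= 1, "per_class must be >= 1")
  check_that(abs(sum(fold_fractions) - 1) < 1e-8, "fold fractions must sum to 1")
  K <- nrow(classes$combinations)
  L <- length(spec$label_names)
  check_that(ncol(classes$combinations) == L,
             "class combinations must have one entry per label")
  n <- K * per_class
  labels <- classes$combinations[rep(seq_len(K), each = per_class), , drop = FALSE]
  colnames(labels) <- spec$label_names
  ipp <- spec$images_per_patient
  # patient blocks are formed within a class so no patient spans classes
  patient_of <- unlist(lapply(seq_len(K), function(k) {
    (k - 1) * ceiling(per_class / ipp) + rep(seq_len(ceiling(per_class / ipp)),
                                             each = ipp)[seq_len(per_class)]
  }))
  images <- array(0, c(n, spec$resolution, spec$resolution))
  for (i in seq_len(n)) {
    images[i, , ] <- generate_image(labels[i, ], spec, fanout_seed(seed, i))
  }
  store <- new_dataset_store(images = images, labels = labels,
                             label_names = spec$label_names,
                             image_id = sprintf("img%06d", seq_len(n)),
                             patient_id = sprintf("pat%06d", patient_of),
                             fold = rep("unassigned", n),
                             origin = "real",
                             resolution = spec$resolution)
  stratified_patient_split(store, fold_fractions, seed = fanout_seed(seed, 0L))
}
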