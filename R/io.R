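# On-disk DatasetStore layout:
#   dir/images/<image_id>.pgm   8-bit grayscale, plain-text PGM (P2)
#   dir/labels.csv              image_id, patient_id, fold, origin, one 0/1
#                               column per label
#   dir/spec.json               label_names, resolution, origin
# PGM/CSV/JSON keep the store plain-text end to end.

write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # row-major pixel order as PGM requires
  writeLines(apply(v, 1, paste, collapse = " "), con)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  check_that(toks[1] == "P2", "only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  check_that(length(vals) == w * h, "corrupt PGM: wrong pixel count")
  matrix(vals, h, w, byrow = TRUE) / maxval
}

#' Write a dataset store to a directory
#'
#' @param store A `dataset_store`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset_store <- function(store, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(store_size(store))) {
    write_pgm(store$images[i, , ],
              file.path(dir, "images", paste0(store$image_id[i], ".pgm")))
  }
  df <- data.frame(image_id = store$image_id, patient_id = store$patient_id,
                   fold = store$fold, origin = store$origin,
                   check.names = FALSE)
  lab <- as.data.frame(store$labels)
  names(lab) <- store$label_names
  utils::write.csv(cbind(df, lab), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(label_names = store$label_names,
                            resolution = store$resolution,
                            origin = store$origin),
                       file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset store from a directory
#'
#' @param dir Directory written by [write_dataset_store()].
#' @return A `dataset_store`.
#' @export
read_dataset_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "labels.csv"), check.names = FALSE)
  n <- nrow(tab)
  res <- as.integer(meta$resolution)
  images <- array(0, c(n, res, res))
  for (i in seq_len(n)) {
    images[i, , ] <- read_pgm(file.path(dir, "images",
                                        paste0(tab$image_id[i], ".pgm")))
  }
  new_dataset_store(images = images,
                    labels = as.matrix(tab[, meta$label_names, drop = FALSE]),
                    label_names = meta$label_names,
                    image_id = tab$image_id, patient_id = tab$patient_id,
                    fold = tab$fold, origin = meta$origin %||% "real",
                    resolution = res)
}
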