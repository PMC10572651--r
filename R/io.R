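# Disk formats: 8-bit grayscale PNG slices and cohort manifests.

#' Write / read a slice as 8-bit grayscale PNG
#'
#' Intensities in [0, 1] map to 0..255 by round-half-up; reading maps back
#' by division by 255.
#'
#' @param image A \code{slice_image}.
#' @param path Output file.
#' @export
write_slice_png <- function(image, path) {
  q <- floor(image$pixels * 255 + 0.5) / 255
  png::writePNG(q, path)
  invisible(path)
}

#' @rdname write_slice_png
#' @param case_id Identifier for the restored slice.
#' @param slice_thickness_mm Thickness metadata for the restored slice.
#' @export
read_slice_png <- function(path, case_id = basename(path),
                           slice_thickness_mm = 1.25) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  slice_image(px, slice_thickness_mm, case_id)
}

#' Write a cohort to disk
#'
#' Produces PNG slices plus two UTF-8 CSVs: \code{manifest.csv} with
#' columns \code{case_id,label,split,client_id,px_file} and
#' \code{features.csv} with the eight named feature columns.
#'
#' @param cohort An \code{fl_cohort}.
#' @param dir Output directory (created if missing).
#' @param split Optional named character vector (case id to
#'   \code{"train"}/\code{"test"}).
#' @param client_of Optional named vector (case id to client id).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL, client_of = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "slices")
  dir.create(img_dir, showWarnings = FALSE)
  ids <- cohort_ids(cohort)
  files <- file.path("slices", paste0(ids, ".png"))
  for (i in seq_along(cohort$cases))
    write_slice_png(cohort$cases[[i]]$image, file.path(dir, files[i]))
  manifest <- data.frame(
    case_id = ids,
    label = cohort_labels(cohort),
    split = if (is.null(split)) "" else unname(split[ids]),
    client_id = if (is.null(client_of)) "" else unname(client_of[ids]),
    px_file = files)
  con <- file(file.path(dir, "manifest.csv"), open = "wb")
  utils::write.csv(manifest, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  feats <- cohort_features(cohort)
  fdf <- data.frame(case_id = ids, feats$x, row.names = NULL)
  con <- file(file.path(dir, "features.csv"), open = "wb")
  utils::write.csv(fdf, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  invisible(dir)
}

#' Read a cohort written by \code{write_cohort}
#'
#' Slices are re-read from PNG and features re-extracted, so the invariant
#' that stored features equal \code{extract_features(image)} holds after a
#' round trip (features shift only by the 8-bit quantization).
#'
#' @param dir Cohort directory.
#' @return An \code{fl_cohort}.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_slice_png(file.path(dir, manifest$px_file[i]),
                          case_id = manifest$case_id[i])
    labeled_case(img, manifest$label[i])
  })
  counts <- table(factor(manifest$label, class_labels()))
  structure(list(cases = cases, seed = NA_integer_,
                 class_counts = stats::setNames(as.integer(counts),
                                                class_labels())),
            class = "fl_cohort")
}
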