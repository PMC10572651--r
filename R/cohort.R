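# Synthetic CT-like nodule cohort: slice generation, RoI feature extraction,
# cohort assembly and stratified splitting.

#' Admissible class labels, in declared order
#'
#' The three-way labeling used throughout: \code{normal} (no positive region
#' of interest), \code{benign} (a positive RoI with a smooth, non-expanding
#' boundary) and \code{malignant} (a positive RoI with active, irregular
#' growth).
#'
#' @return Character vector \code{c("normal", "benign", "malignant")}.
#' @export
class_labels <- function() c("normal", "benign", "malignant")

#' Names of the eight RoI features, in declared order
#'
#' The feature vector is the concatenation of the physical attribute group
#' Pa (density, mass, orientation, weight) and the digital attribute group
#' Pd (pixel_ratio, growth_pattern, pixel_intensity, expansion_density).
#'
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  c("density", "mass", "orientation", "weight",
    "pixel_ratio", "growth_pattern", "pixel_intensity", "expansion_density")
}

#' @rdname feature_names
#' @export
pa_names <- function() feature_names()[1:4]

#' @rdname feature_names
#' @export
pd_names <- function() feature_names()[5:8]

#' Default generator settings for synthetic slices
#'
#' Controls the appearance of the three classes. Background is Gaussian
#' noise (mean 0.2, sd 0.05, clipped to [0, 1]); the RoI foreground
#' threshold of 0.45 sits five background standard deviations above the
#' background mean, so normal slices have an empty RoI with overwhelming
#' probability. Benign nodules are disks with a smooth boundary
#' (spiculation amplitude 0); malignant nodules are larger, brighter and
#' spiculated: the boundary radius follows
#' r(theta) = r0 * (1 + a * sum_k sin(k * theta + phi_k))
#' over the configured harmonics k, clamped below at half a pixel.
#' The binary nodule mask is softened with a Gaussian blur of the stated
#' sigma (pixels) before compositing over the background.
#'
#' @param img_size Image side length in pixels (square slices).
#' @return A list of generator settings, class \code{"gen_params"}.
#' @export
default_gen_params <- function(img_size = 64L) {
  gp <- list(
    img_size = as.integer(img_size),
    slice_thickness_mm = 1.25,
    background_mean = 0.2,
    background_sd = 0.05,
    foreground_threshold = 0.45,
    edge_blur_sd = 1,
    benign = list(radius_range = c(3, 6), core_intensity = 0.6,
                  spiculation_amplitude = 0, harmonics = integer(0)),
    malignant = list(radius_range = c(5, 9), core_intensity = 0.8,
                     spiculation_amplitude = 0.35, harmonics = c(3L, 5L, 7L))
  )
  class(gp) <- "gen_params"
  validate_gen_params(gp)
  gp
}

validate_gen_params <- function(gp) {
  if (gp$img_size < 16L) stop("img_size must be at least 16")
  for (cls in c("benign", "malignant")) {
    p <- gp[[cls]]
    if (length(p$radius_range) != 2L || diff(p$radius_range) < 0)
      stop(cls, ": radius_range must be an ordered pair")
    if (p$spiculation_amplitude < 0)
      stop(cls, ": spiculation_amplitude must be nonnegative")
    rmax <- p$radius_range[2] * (1 + p$spiculation_amplitude * length(p$harmonics))
    if (2 * rmax + 4 > gp$img_size)
      stop(cls, ": maximum RoI extent (", round(2 * rmax, 1),
           " px) does not fit in a ", gp$img_size, "-px image")
  }
  invisible(gp)
}

#' Construct a slice image
#'
#' @param pixels Numeric matrix of intensities in [0, 1], at least 16 x 16.
#' @param slice_thickness_mm Slice thickness metadata (mm).
#' @param case_id Opaque case identifier.
#' @return An object of class \code{"slice_image"}.
#' @export
slice_image <- function(pixels, slice_thickness_mm = 1.25, case_id = "case") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("slice must be at least 16 x 16 pixels")
  if (any(!is.finite(pixels)))
    stop("pixel intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]")
  structure(list(pixels = pixels,
                 slice_thickness_mm = slice_thickness_mm,
                 case_id = as.character(case_id)),
            class = "slice_image")
}

#' Generate one labeled synthetic slice
#'
#' Draws from the current RNG stream (seed with \code{set.seed} upstream for
#' reproducibility). Normal slices are background noise only; benign and
#' malignant slices carry one nodule whose radius, boundary phases and
#' position are drawn from the class settings in \code{gen_params}.
#'
#' @param label One of \code{class_labels()}.
#' @param gen_params Generator settings, see \code{\link{default_gen_params}}.
#' @param case_id Identifier stored on the slice.
#' @return A \code{labeled_case}: list with \code{image}, \code{label} and
#'   the extracted 8-element \code{features} vector.
#' @export
generate_case <- function(label, gen_params = default_gen_params(),
                          case_id = "case") {
  if (!(is.character(label) && length(label) == 1L && label %in% class_labels()))
    stop("unknown class label: ", paste(label, collapse = ","))
  validate_gen_params(gen_params)
  sz <- gen_params$img_size
  px <- matrix(stats::rnorm(sz * sz, gen_params$background_mean,
                            gen_params$background_sd), sz, sz)
  px <- pmin(pmax(px, 0), 1)
  if (label != "normal") {
    p <- gen_params[[label]]
    r0 <- stats::runif(1, p$radius_range[1], p$radius_range[2])
    k <- p$harmonics
    a <- p$spiculation_amplitude
    phases <- if (length(k)) stats::runif(length(k), 0, 2 * pi) else numeric(0)
    rmax <- r0 * (1 + a * length(k))
    slack <- sz / 2 - rmax - 2
    ctr <- sz / 2 + stats::runif(2, -max(slack, 0), max(slack, 0))
    rowd <- row(px) - ctr[1]
    cold <- col(px) - ctr[2]
    theta <- atan2(cold, rowd)
    rtheta <- if (length(k)) {
      dev <- sapply(seq_along(k), function(i) sin(k[i] * theta + phases[i]))
      r0 * (1 + a * rowSums(matrix(dev, ncol = length(k))))
    } else rep(r0, length(theta))
    rtheta <- pmax(rtheta, 0.5)
    mask <- matrix(sqrt(rowd^2 + cold^2) <= rtheta, sz, sz)
    soft <- EBImage::gblur(mask * 1, sigma = gen_params$edge_blur_sd)
    px <- pmin(pmax(pmax(px, soft * p$core_intensity), 0), 1)
  }
  img <- slice_image(px, gen_params$slice_thickness_mm, case_id)
  labeled_case(img, label,
               threshold = gen_params$foreground_threshold)
}

#' @rdname generate_case
#' @param image A \code{slice_image}.
#' @param threshold Foreground threshold for RoI detection.
#' @export
labeled_case <- function(image, label, threshold = 0.45) {
  structure(list(image = image, label = label,
                 features = extract_features(image, threshold = threshold)),
            class = "labeled_case")
}

# Crack-edge count of a binary mask: number of exposed pixel edges.
# The Cauchy-Crofton corrected perimeter (crack * pi / 4) is unbiased for
# isotropically oriented boundaries and exact for digitized disks in the
# large-radius limit.
crack_perimeter <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  up    <- rbind(0L, m[-h, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], 0L)
  left  <- cbind(0L, m[, -w, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], 0L)
  cracks <- sum(m & !up) + sum(m & !down) + sum(m & !left) + sum(m & !right)
  cracks * pi / 4
}

shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out | shift_mask(m, dr, dc)
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out & shift_mask(m, dr, dc)
  out
}

#' Extract the eight-element Pa/Pd feature vector from a slice
#'
#' The region of interest (RoI) is the largest connected component of
#' pixels strictly above the foreground threshold. An empty RoI yields the
#' all-zero vector. Otherwise:
#' \itemize{
#'   \item \code{density}: mean RoI intensity.
#'   \item \code{mass}: density times RoI area (pixel-intensity units).
#'   \item \code{orientation}: principal-axis angle of the RoI from its
#'     central second moments, in radians in [-pi/2, pi/2]; defined as 0
#'     when the axes are degenerate (rotationally symmetric mask).
#'   \item \code{weight}: (RoI area / image area) times density.
#'   \item \code{pixel_ratio}: RoI area / image area.
#'   \item \code{growth_pattern}: boundary irregularity
#'     perimeter^2 / (4 pi area), floored at 1 (the disk bound) for a
#'     non-empty RoI; perimeter is the Cauchy-Crofton corrected crack-edge
#'     length of the mask.
#'   \item \code{pixel_intensity}: maximum RoI intensity.
#'   \item \code{expansion_density}: mean absolute radial intensity
#'     gradient over the one-pixel boundary band of the RoI.
#' }
#'
#' @param image A \code{slice_image} (or bare numeric matrix in [0, 1]).
#' @param threshold Foreground threshold; default 0.45.
#' @return Named numeric vector of length 8 in \code{feature_names()} order.
#' @export
extract_features <- function(image, threshold = 0.45) {
  px <- if (inherits(image, "slice_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) stop("image must carry a numeric pixel matrix")
  if (any(!is.finite(px))) stop("pixel intensities must be finite")
  zero <- stats::setNames(numeric(8), feature_names())
  fg <- px > threshold
  if (!any(fg)) return(zero)
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  roi <- lab == which.max(tab)
  area <- sum(roi)
  vals <- px[roi]
  density <- mean(vals)
  pixel_ratio <- area / length(px)
  idx <- which(roi, arr.ind = TRUE)
  yc <- idx[, 1] - mean(idx[, 1])
  xc <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(xc^2); mu02 <- mean(yc^2); mu11 <- mean(xc * yc)
  orientation <- if (sqrt((2 * mu11)^2 + (mu20 - mu02)^2) < 1e-9) 0 else
    0.5 * atan2(2 * mu11, mu20 - mu02)
  perim <- crack_perimeter(roi)
  growth <- max(1, perim^2 / (4 * pi * area))
  band <- dilate3(roi) & !erode3(roi)
  h <- nrow(px); w <- ncol(px)
  gy <- (rbind(px[-1, , drop = FALSE], px[h, ]) -
         rbind(px[1, ], px[-h, , drop = FALSE])) / 2
  gx <- (cbind(px[, -1, drop = FALSE], px[, w]) -
         cbind(px[, 1], px[, -w, drop = FALSE])) / 2
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  bidx <- which(band, arr.ind = TRUE)
  dy <- bidx[, 1] - cy; dx <- bidx[, 2] - cx
  nrm <- pmax(sqrt(dy^2 + dx^2), 1e-12)
  gr <- gy[band] * (dy / nrm) + gx[band] * (dx / nrm)
  expansion <- mean(abs(gr))
  stats::setNames(
    c(density, density * area, orientation, pixel_ratio * density,
      pixel_ratio, growth, max(vals), expansion),
    feature_names())
}

# Largest-remainder apportionment of n among proportions; ties broken in
# declared label order.
largest_remainder <- function(n, props) {
  q <- n * props
  base <- floor(q)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    extra <- order(-(q - base), seq_along(q))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labeled synthetic cohort
#'
#' Class counts follow largest-remainder rounding of
#' \code{n_cases * class_mix} (ties broken in label order); case order is
#' shuffled by the seed. Bit-for-bit reproducible for identical arguments.
#'
#' @param n_cases Number of cases (at least 3).
#' @param class_mix Proportions over the three labels, summing to 1.
#' @param gen_params Generator settings.
#' @param seed Integer seed.
#' @return An object of class \code{"fl_cohort"}: list with \code{cases},
#'   \code{seed} and \code{class_counts}.
#' @export
generate_cohort <- function(n_cases, class_mix = rep(1 / 3, 3),
                            gen_params = default_gen_params(), seed = 1L) {
  if (n_cases < 3) stop("n_cases must be at least 3")
  if (length(class_mix) != 3L) stop("class_mix must have three entries")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  counts <- largest_remainder(n_cases, class_mix)
  labels <- rep(class_labels(), counts)
  cases <- with_seed(seed, {
    out <- lapply(seq_along(labels), function(i)
      generate_case(labels[i], gen_params,
                    case_id = sprintf("case_%04d", i)))
    out[sample.int(length(out))]
  })
  structure(list(cases = cases, seed = as.integer(seed),
                 class_counts = stats::setNames(counts, class_labels())),
            class = "fl_cohort")
}

#' @export
print.fl_cohort <- function(x, ...) {
  cat("Synthetic nodule cohort:", length(x$cases), "cases (seed", x$seed, ")\n")
  print(x$class_counts)
  invisible(x)
}

cohort_labels <- function(cohort) {
  vapply(cohort$cases, function(cs) cs$label, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort$cases, function(cs) cs$image$case_id, character(1))
}

#' Feature matrix and labels of a cohort
#'
#' @param cohort An \code{fl_cohort} (or plain list of labeled cases).
#' @return List with \code{x} (n x 8 matrix, rownames = case ids) and
#'   \code{y} (character labels).
#' @export
cohort_features <- function(cohort) {
  cases <- if (inherits(cohort, "fl_cohort")) cohort$cases else cohort
  x <- t(vapply(cases, function(cs) cs$features, numeric(8)))
  colnames(x) <- feature_names()
  rownames(x) <- vapply(cases, function(cs) cs$image$case_id, character(1))
  list(x = x, y = vapply(cases, function(cs) cs$label, character(1)))
}

#' Stratified train/test split of a cohort
#'
#' Per class, the train count is \code{round(train_fraction * class count)}
#' (round-half-even, as base R rounds); membership is drawn by the seed.
#' Subsets are disjoint and their union is the cohort.
#'
#' @param cohort An \code{fl_cohort}.
#' @param train_fraction Fraction in (0, 1); default 0.6.
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test}, each an \code{fl_cohort}.
#' @export
split_cohort <- function(cohort, train_fraction = 0.6, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  labs <- cohort_labels(cohort)
  tab <- table(factor(labs, levels = class_labels()))
  if (any(tab < 2)) stop("every class needs at least 2 cases to stratify")
  train_idx <- with_seed(seed, {
    unlist(lapply(class_labels(), function(cl) {
      members <- which(labs == cl)
      k <- round(train_fraction * length(members))
      k <- min(max(k, 1L), length(members) - 1L)
      sort(sample(members, k))
    }))
  })
  train_idx <- sort(train_idx)
  subset_of <- function(idx) {
    cc <- table(factor(labs[idx], levels = class_labels()))
    structure(list(cases = cohort$cases[idx], seed = cohort$seed,
                   class_counts = stats::setNames(as.integer(cc), class_labels())),
              class = "fl_cohort")
  }
  list(train = subset_of(train_idx),
       test = subset_of(setdiff(seq_along(cohort$cases), train_idx)))
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
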