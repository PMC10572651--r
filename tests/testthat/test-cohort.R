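# Synthetic cohort generation and Pa/Pd feature extraction.

test_that("normal slices carry no positive RoI and all-zero features", {
  set.seed(7)
  case <- generate_case("normal")
  expect_identical(unname(case$features), rep(0, 8))
  set.seed(123)
  for (i in 1:20)
    expect_true(all(generate_case("normal")$features == 0))
})

test_that("benign boundaries are near-circular, malignant more irregular", {
  set.seed(1)
  benign <- generate_case("benign")
  expect_gte(benign$features[["growth_pattern"]], 1.0)
  expect_lte(benign$features[["growth_pattern"]], 1.15)
  set.seed(1)
  malignant <- generate_case("malignant")
  expect_gt(malignant$features[["growth_pattern"]],
            benign$features[["growth_pattern"]])
  expect_gt(malignant$features[["pixel_intensity"]],
            benign$features[["pixel_intensity"]])
})

test_that("feature extraction matches direct arithmetic on a square mask", {
  img <- square_slice(side = 10L, intensity = 0.8)
  f <- extract_features(img)
  expect_equal(f[["pixel_ratio"]], 100 / 4096)
  expect_equal(f[["density"]], 0.8)
  expect_equal(f[["pixel_intensity"]], 0.8)
  expect_equal(f[["mass"]], 0.8 * 100)
  expect_equal(f[["weight"]], 100 / 4096 * 0.8)
  # brute-force boundary count: exposed 4-neighbor edges of the mask
  mask <- img$pixels > 0.45
  cracks <- 0L
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr <- r + d[1]; nc <- cc + d[2]
      out <- nr < 1 || nr > nrow(mask) || nc < 1 || nc > ncol(mask) ||
        !mask[nr, nc]
      if (out) cracks <- cracks + 1L
    }
  }
  perim <- cracks * pi / 4
  expect_equal(f[["growth_pattern"]], max(1, perim^2 / (4 * pi * 100)))
  # a square is 4-fold symmetric: degenerate principal axes map to 0
  expect_identical(f[["orientation"]], 0)
})

test_that("rotation preserves area within rasterization error", {
  size <- 64L
  f0 <- extract_features(square_slice(side = 10L))
  # square of side 10 rotated 45 degrees; off-lattice center so boundary
  # pixels are not all exact ties
  dx <- row(matrix(0, size, size)) - 32.3
  dy <- col(matrix(0, size, size)) - 32.7
  u <- (dx + dy) / sqrt(2); v <- (dx - dy) / sqrt(2)
  rot <- matrix(0, size, size)
  rot[abs(u) <= 5 & abs(v) <= 5] <- 0.8
  f45 <- extract_features(slice_image(rot, case_id = "rot"))
  expect_lt(abs(f45[["pixel_ratio"]] - f0[["pixel_ratio"]]) / f0[["pixel_ratio"]],
            0.10)
  # an elongated rectangle rotated 45 degrees has a well-defined axis
  rect <- matrix(0, size, size)
  rect[abs(u) <= 8 & abs(v) <= 3] <- 0.8
  fr <- extract_features(slice_image(rect, case_id = "rect"))
  expect_equal(abs(fr[["orientation"]]), pi / 4, tolerance = 0.05)
})

test_that("feature extraction is pure and rejects bad input", {
  img <- square_slice()
  expect_identical(extract_features(img), extract_features(img))
  expect_identical(unname(extract_features(matrix(0, 64, 64))), rep(0, 8))
  bad <- matrix(0.1, 64, 64); bad[5, 5] <- NA
  expect_error(extract_features(bad), "finite")
  expect_error(generate_case("tumor"), "unknown class label")
  gp <- default_gen_params()
  gp$malignant$radius_range <- c(20, 30)
  expect_error(validate_gen_params(gp), "does not fit")
})

test_that("cohort class counts follow largest-remainder rounding", {
  cohort <- generate_cohort(50, seed = 42)
  expect_identical(unname(cohort$class_counts), c(17L, 17L, 16L))
  expect_length(cohort$cases, 50)
  tiny <- generate_cohort(3, seed = 0)
  expect_identical(unname(tiny$class_counts), c(1L, 1L, 1L))
  expect_error(generate_cohort(10, class_mix = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("cohort generation is bit-for-bit reproducible", {
  a <- generate_cohort(12, seed = 42)
  b <- generate_cohort(12, seed = 42)
  expect_identical(cohort_ids(a), cohort_ids(b))
  expect_identical(cohort_features(a), cohort_features(b))
  expect_identical(a$cases[[3]]$image$pixels, b$cases[[3]]$image$pixels)
})

test_that("stratified split hits the prescribed per-class sizes", {
  cohort <- make_stub_cohort(rep(class_labels(), c(17, 17, 16)))
  sp <- split_cohort(cohort, 0.6, seed = 1)
  expect_identical(unname(sp$train$class_counts), c(10L, 10L, 10L))
  expect_length(sp$train$cases, 30)
  expect_length(sp$test$cases, 20)
  sp2 <- split_cohort(cohort, 0.6, seed = 1)
  expect_identical(cohort_ids(sp$train), cohort_ids(sp2$train))
  expect_error(split_cohort(make_stub_cohort(c("normal", "benign", "malignant")),
                            0.6), "at least 2")
  expect_error(split_cohort(cohort, 1.2), "strictly between")
})

test_that("split is a partition: cover, disjointness, conservation", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(9:60, 1)
    labels <- sample(class_labels(), n, replace = TRUE)
    while (any(table(factor(labels, class_labels())) < 2))
      labels <- sample(class_labels(), n, replace = TRUE)
    cohort <- make_stub_cohort(labels)
    sp <- split_cohort(cohort, runif(1, 0.3, 0.8), seed = i)
    tr <- cohort_ids(sp$train); te <- cohort_ids(sp$test)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), cohort_ids(cohort))
    expect_identical(length(tr) + length(te), length(cohort$cases))
  }
})

test_that("malignant growth pattern stochastically dominates benign", {
  set.seed(11)
  feats <- lapply(class_labels(), function(cl)
    t(replicate(200, generate_case(cl)$features)))
  names(feats) <- class_labels()
  expect_true(all(feats$normal == 0))
  expect_true(all(feats$benign[, "pixel_ratio"] > 0))
  expect_true(all(feats$malignant[, "pixel_ratio"] > 0))
  p <- stats::wilcox.test(feats$malignant[, "growth_pattern"],
                          feats$benign[, "growth_pattern"],
                          alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.01)
})
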