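# Shared fixtures, built in code at test time.

# A cohort without images: enough structure for split / partition tests.
make_stub_cohort <- function(labels) {
  cases <- lapply(seq_along(labels), function(i) {
    structure(list(image = list(case_id = sprintf("stub_%04d", i)),
                   label = labels[i],
                   features = stats::setNames(numeric(8), feature_names())),
              class = "labeled_case")
  })
  counts <- table(factor(labels, class_labels()))
  structure(list(cases = cases, seed = 0L,
                 class_counts = stats::setNames(as.integer(counts),
                                                class_labels())),
            class = "fl_cohort")
}

# Memoized medium cohort shared across heavier tests.
.shared <- new.env()
shared_cohort <- function() {
  if (is.null(.shared$cohort))
    .shared$cohort <- generate_cohort(90, seed = 5L)
  .shared$cohort
}

# Slice with a filled axis-aligned square at a given intensity.
square_slice <- function(side = 10L, intensity = 0.8, size = 64L,
                         at = 25L) {
  px <- matrix(0, size, size)
  px[at:(at + side - 1L), at:(at + side - 1L)] <- intensity
  slice_image(px, case_id = "square")
}

# Random parameter vector for a default architecture.
random_params <- function(seed) {
  arch <- mlp_architecture()
  with_seed_test(seed, mlp_params(stats::rnorm(n_params(arch)), arch))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Hand-built MLP that classifies perfectly from either attribute group:
# unit 1 fires on (density + pixel_intensity)/2, unit 2 on
# (mass + growth_pattern)/2, with inputs crafted one-hot per class.
perfect_pair_model <- function() {
  arch <- mlp_architecture(8L, 16L)
  W1 <- matrix(0, 8, 16); b1 <- numeric(16)
  W1[1, 1] <- 0.5; W1[7, 1] <- 0.5; b1[1] <- -0.2
  W1[2, 2] <- 0.5; W1[6, 2] <- 0.5; b1[2] <- -0.2
  W2 <- matrix(0, 16, 3); b2 <- numeric(3)
  W2[1, 2] <- 10; W2[2, 3] <- 10
  mlp_params(c(as.numeric(W1), b1, as.numeric(W2), b2), arch)
}

# Calibration data matching perfect_pair_model: benign marks features 1 and
# 7, malignant marks features 2 and 6, normal is all-zero.
perfect_pair_data <- function(per_class = 4L) {
  y <- rep(class_labels(), each = per_class)
  x <- matrix(0, length(y), 8, dimnames = list(NULL, feature_names()))
  x[y == "benign", c(1, 7)] <- 1
  x[y == "malignant", c(2, 6)] <- 1
  list(x = x, y = y)
}
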