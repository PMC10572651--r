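# Confusion-matrix metrics, the published-table fixtures, and the two
# experiment harnesses (centralized vs decentralized; node scaling).

#' Build a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted, both in
#' \code{class_labels()} order (the layout of the published training and
#' testing tables).
#'
#' @param truth,pred Equal-length label vectors.
#' @return Integer 3x3 matrix of class \code{"confusion_matrix3"}.
#' @export
confusion_matrix3 <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (!length(truth)) stop("need at least one case")
  lv <- class_labels()
  if (!all(truth %in% lv) || !all(pred %in% lv))
    stop("labels must be one of: ", paste(lv, collapse = ", "))
  m <- table(factor(truth, lv), factor(pred, lv))
  cm <- matrix(as.integer(m), 3, 3, dimnames = list(true = lv, predicted = lv))
  structure(cm, class = c("confusion_matrix3", "matrix"))
}

as_confusion_matrix3 <- function(cells) {
  cells <- matrix(as.integer(round(cells)), 3, 3,
                  dimnames = list(true = class_labels(),
                                  predicted = class_labels()))
  if (any(cells < 0)) stop("confusion counts must be nonnegative")
  structure(cells, class = c("confusion_matrix3", "matrix"))
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  m <- unclass(x)
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a 3-class confusion matrix
#'
#' Accuracy is trace over grand total. Per class, sensitivity is the
#' row-normalized diagonal TP/(TP+FN); specificity is one-vs-rest
#' TN/(TN+FP). Macro values are unweighted means over the classes; a class
#' with a zero denominator yields NA, is flagged, and is excluded from the
#' macro mean.
#'
#' @param cm A \code{confusion_matrix3} (or plain 3x3 count matrix).
#' @return Object of class \code{"metrics_report"}: \code{accuracy},
#'   \code{sensitivity_macro}, \code{specificity_macro}, a
#'   \code{per_class} data frame, and \code{undefined} flags.
#' @export
cm_metrics <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || !all(dim(m) == c(3, 3))) stop("expected a 3x3 matrix")
  if (any(m < 0)) stop("counts must be nonnegative")
  total <- sum(m)
  if (total < 1) stop("confusion matrix is empty")
  tp <- diag(m)
  rowt <- rowSums(m)
  colt <- colSums(m)
  sens <- ifelse(rowt > 0, tp / rowt, NA_real_)
  fp <- colt - tp
  tn <- total - rowt - colt + tp
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  macro <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(
    accuracy = sum(tp) / total,
    sensitivity_macro = macro(sens),
    specificity_macro = macro(spec),
    per_class = data.frame(class = class_labels(), sensitivity = sens,
                           specificity = spec, row.names = NULL),
    undefined = list(sensitivity = class_labels()[is.na(sens)],
                     specificity = class_labels()[is.na(spec)])),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro sensitivity %.4f | macro specificity %.4f\n",
              x$accuracy, x$sensitivity_macro, x$specificity_macro))
  print(x$per_class)
  invisible(x)
}

# Grand totals of the transcribed published tables; used as a transcription
# checksum by the loader.
paper_table_totals <- c(T1_train = 96L, T1_test = 65L,
                        T2_train = 106L, T2_test = 90L)

#' Load a published confusion-table fixture
#'
#' Returns the printed cell counts of the centralized (T1) or
#' decentralized/federated (T2) training and testing tables, transcribed
#' into \code{inst/extdata/paper_confusion_tables.csv}. Row totals and the
#' grand total are validated against the printed values (a grand-total
#' mismatch is rejected as a corrupted fixture). The printed column totals
#' are attached as attribute \code{"printed_col_totals"}; note the T2
#' testing table as published carries an internally inconsistent first
#' column total (printed 19 where the cells sum to 34).
#'
#' @param table_id One of \code{"T1_train"}, \code{"T1_test"},
#'   \code{"T2_train"}, \code{"T2_test"}.
#' @return A \code{confusion_matrix3} with attributes
#'   \code{printed_row_totals} and \code{printed_col_totals}.
#' @export
load_paper_table <- function(table_id = c("T1_train", "T1_test",
                                          "T2_train", "T2_test")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", "paper_confusion_tables.csv",
                      package = "fedlung", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$table_id == table_id, ]
  rows <- tab[match(class_labels(), tab$true_class), ]
  cells <- as.matrix(rows[, c("normal", "benign", "malignant")])
  cm <- as_confusion_matrix3(cells)
  if (sum(cm) != paper_table_totals[[table_id]])
    stop("fixture checksum mismatch for ", table_id)
  if (!all(rowSums(cm) == rows$printed_total))
    stop("fixture row totals disagree with printed totals for ", table_id)
  ct <- tab[tab$true_class == "printed_column_total", ]
  attr(cm, "printed_row_totals") <- rows$printed_total
  attr(cm, "printed_col_totals") <-
    stats::setNames(as.integer(ct[, c("normal", "benign", "malignant")]),
                    class_labels())
  cm
}

#' Write a confusion matrix as CSV with Total row and column
#'
#' @param cm A \code{confusion_matrix3}.
#' @param path Output file.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- unclass(cm)
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  df <- data.frame(true_class = rownames(m), m, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df <- df[df$true_class %in% class_labels(), ]
  as_confusion_matrix3(as.matrix(df[, class_labels()]))
}

#' Compare centralized and decentralized (federated) training
#'
#' Generates one synthetic cohort, splits it, and trains both arms on the
#' identical data: the centralized arm is a single model on the pooled
#' client training pool; the decentralized arm is the federated pipeline
#' with the same seeds. Both are evaluated on the shared test split.
#'
#' @param n_cases Cohort size (default 300).
#' @param class_mix Class proportions.
#' @param gen_params Generator settings.
#' @param train_fraction Train share of the split (default 0.6).
#' @param n_clients,n_routers,rounds,cfg,policy,scheme,skew_alpha Federation
#'   settings, see \code{\link{run_federation}}.
#' @param cohort_seed,split_seed,init_seed,train_seed,partition_seed Seeds.
#' @return List of class \code{"cd_comparison"} with \code{centralized}
#'   and \code{decentralized} (each a \code{report} plus confusion
#'   matrix \code{cm}), and the absolute accuracy \code{gap}.
#' @export
compare_centralized_decentralized <- function(
    n_cases = 300L, class_mix = rep(1 / 3, 3),
    gen_params = default_gen_params(), train_fraction = 0.6,
    n_clients = 5L, n_routers = ceiling(sqrt(n_clients)), rounds = 30L,
    cfg = training_config(), policy = dnt_policy("off"),
    scheme = "iid", skew_alpha = 0.5,
    cohort_seed = 42L, split_seed = 7L, init_seed = 11L,
    train_seed = 101L, partition_seed = 21L) {
  cohort <- generate_cohort(n_cases, class_mix, gen_params, seed = cohort_seed)
  sp <- split_cohort(cohort, train_fraction, seed = split_seed)
  fed <- run_federation(sp$train, sp$test, n_clients = n_clients,
                        n_routers = n_routers, rounds = rounds, cfg = cfg,
                        policy = policy, scheme = scheme,
                        skew_alpha = skew_alpha, init_seed = init_seed,
                        train_seed = train_seed, partition_seed = partition_seed)
  cen <- train_centralized(sp$train, rounds = rounds, cfg = cfg,
                           init_seed = init_seed, train_seed = train_seed,
                           calib_seed = partition_seed + 1L)
  tf <- cohort_features(sp$test)
  eval_arm <- function(params, stats_) {
    pred <- predict(params, standardize_features(tf$x, stats_))$label
    cm <- confusion_matrix3(tf$y, pred)
    list(cm = cm, report = cm_metrics(cm))
  }
  cen_arm <- eval_arm(cen$params, cen$stats)
  dec_arm <- eval_arm(fed$global_params, fed$stats)
  structure(list(centralized = cen_arm, decentralized = dec_arm,
                 gap = abs(cen_arm$report$accuracy - dec_arm$report$accuracy),
                 federation = fed),
            class = "cd_comparison")
}

#' @export
print.cd_comparison <- function(x, ...) {
  cat(sprintf("centralized accuracy %.4f | decentralized accuracy %.4f | gap %.4f\n",
              x$centralized$report$accuracy, x$decentralized$report$accuracy,
              x$gap))
  invisible(x)
}

#' Node-scaling experiment
#'
#' Runs one federated experiment per node count. Because a fixed small
#' cohort spread over many clients leaves untrainable shards, the cohort
#' size scales with the node count: \code{n * per_node_min} cases per run
#' (default 12 per node). Router count is
#' \code{ceiling(sqrt(n))}. Deterministic per seed.
#'
#' @param counts Increasing node counts; default the published ladder
#'   \code{c(5, 10, 20, 40, 80, 160)}.
#' @param per_node_min Cases generated per node (default 12).
#' @param rounds Federated rounds per run (default 10).
#' @param cfg,policy,gen_params As in \code{\link{run_federation}}.
#' @param seed Master seed; per-run seeds derive from it and the count.
#' @return Data frame of class \code{"scaling_result"} with one row per
#'   count: \code{n_nodes}, \code{accuracy}, \code{sensitivity_macro},
#'   \code{specificity_macro}, \code{n_cases}.
#' @export
node_scaling <- function(counts = c(5L, 10L, 20L, 40L, 80L, 160L),
                         per_node_min = 12L, rounds = 10L,
                         cfg = training_config(), policy = dnt_policy("off"),
                         gen_params = default_gen_params(), seed = 1L) {
  if (!length(counts)) stop("counts must be non-empty")
  if (is.unsorted(counts, strictly = TRUE)) stop("counts must be increasing")
  rows <- lapply(seq_along(counts), function(i) {
    n <- as.integer(counts[i])
    n_cases <- n * as.integer(per_node_min)
    cohort <- generate_cohort(n_cases, seed = seed + i,
                              gen_params = gen_params)
    sp <- split_cohort(cohort, 0.6, seed = seed + 100L + i)
    fed <- run_federation(sp$train, sp$test, n_clients = n,
                          rounds = rounds, cfg = cfg, policy = policy,
                          init_seed = seed + 200L + i,
                          train_seed = seed + 300L + i,
                          partition_seed = seed + 400L + i)
    tf <- cohort_features(sp$test)
    pred <- predict(fed$global_params,
                    standardize_features(tf$x, fed$stats))$label
    rep_ <- cm_metrics(confusion_matrix3(tf$y, pred))
    data.frame(n_nodes = n, accuracy = rep_$accuracy,
               sensitivity_macro = rep_$sensitivity_macro,
               specificity_macro = rep_$specificity_macro,
               n_cases = n_cases)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scaling_result", "data.frame")
  out
}

#' Write a scaling result as CSV
#'
#' @param x A \code{scaling_result}.
#' @param path Output file.
#' @export
write_scaling_csv <- function(x, path) {
  utils::write.csv(x[, c("n_nodes", "accuracy", "sensitivity_macro",
                         "specificity_macro")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report A \code{metrics_report}.
#' @param path Output file.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         sensitivity_macro = report$sensitivity_macro,
         specificity_macro = report$specificity_macro,
         per_class = report$per_class),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
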