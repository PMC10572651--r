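# Distributed Network Thresholding (DNT) and hierarchical federated
# averaging: per-client validation scoring split by the Pa and Pd feature
# groups, an append-only validation matrix R, threshold-based client
# admission, and two-stage (router, then central) weighted parameter
# averaging.

#' Score a client model on the calibration set
#'
#' The validation score splits the held-out accuracy by attribute group:
#' \code{v_pa} is the accuracy when the digital (Pd) coordinates are
#' zero-masked (on the standardized scale, i.e. mean-imputed) and only the
#' physical attributes inform the prediction; \code{v_pd} is symmetric;
#' \code{v} is their mean.
#'
#' @param params Client \code{mlp_params}.
#' @param calib_x Standardized calibration feature matrix (8 columns in
#'   \code{feature_names()} order).
#' @param calib_y Calibration labels.
#' @return Object of class \code{"validation_score"}: list with
#'   \code{v_pa}, \code{v_pd}, \code{v}, all in [0, 1] and
#'   \code{v == (v_pa + v_pd) / 2} exactly.
#' @export
client_validation_score <- function(params, calib_x, calib_y) {
  if (is.null(nrow(calib_x)) || nrow(calib_x) < 1L)
    stop("calibration set must be non-empty")
  if (length(unique(calib_y)) < 2L)
    stop("calibration set must contain at least two classes")
  acc_on <- function(x) mean(predict(params, x)$label == calib_y)
  pa_idx <- match(pa_names(), feature_names())
  pd_idx <- match(pd_names(), feature_names())
  xa <- calib_x; xa[, pd_idx] <- 0
  xd <- calib_x; xd[, pa_idx] <- 0
  v_pa <- acc_on(xa)
  v_pd <- acc_on(xd)
  structure(list(v_pa = v_pa, v_pd = v_pd, v = (v_pa + v_pd) / 2),
            class = "validation_score")
}

#' Create an empty validation matrix R
#'
#' R records, per round and client, the DNT validation scores. Rows are
#' append-only; a client absent from a round is a missing entry (NA), not
#' a zero score.
#'
#' @param client_ids Integer client ids (columns of R).
#' @return Object of class \code{"validation_matrix"}.
#' @export
new_validation_matrix <- function(client_ids) {
  cn <- paste0("client_", client_ids)
  empty <- matrix(numeric(0), 0, length(client_ids), dimnames = list(NULL, cn))
  structure(list(v = empty, v_pa = empty, v_pd = empty,
                 rounds = integer(0), client_ids = as.integer(client_ids)),
            class = "validation_matrix")
}

#' Append one round of scores to the validation matrix
#'
#' @param R A \code{validation_matrix}.
#' @param round Round index; must exceed all recorded rounds.
#' @param scores Named list (names = client ids) of
#'   \code{validation_score}s; clients missing from the list get NA.
#' @return The extended matrix; prior rows are untouched.
#' @export
update_validation_matrix <- function(R, round, scores) {
  round <- as.integer(round)
  if (length(R$rounds) && round <= max(R$rounds))
    stop("round index ", round, " already recorded; rounds must increase")
  take <- function(field) {
    row <- rep(NA_real_, length(R$client_ids))
    pos <- match(as.integer(names(scores)), R$client_ids)
    row[pos] <- vapply(scores, function(s) s[[field]], numeric(1))
    row
  }
  for (field in c("v", "v_pa", "v_pd")) {
    R[[field]] <- rbind(R[[field]], take(field))
    rownames(R[[field]]) <- paste0("round_", c(R$rounds, round))
  }
  R$rounds <- c(R$rounds, round)
  R
}

#' Write the validation matrix as CSV
#'
#' One row per round; cells hold the combined score \code{v}, or the
#' \code{v_pa;v_pd;v} triple when \code{detailed = TRUE}.
#'
#' @param R A \code{validation_matrix}.
#' @param path Output file.
#' @param detailed Write the score triple instead of \code{v} alone.
#' @export
write_validation_matrix <- function(R, path, detailed = FALSE) {
  cells <- if (detailed) {
    matrix(sprintf("%.6g;%.6g;%.6g", R$v_pa, R$v_pd, R$v),
           nrow(R$v), ncol(R$v))
  } else matrix(sprintf("%.6g", R$v), nrow(R$v), ncol(R$v))
  cells[is.na(R$v)] <- ""
  df <- data.frame(round = R$rounds, cells)
  names(df) <- c("round", colnames(R$v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Client-admission policy for Distributed Network Thresholding
#'
#' @param mode \code{"off"} (admit everyone), \code{"absolute"} (admit
#'   clients with \code{v >= tau}) or \code{"robust"} (admit clients with
#'   \code{v >= median(v) - z * MAD(v)}, MAD unscaled).
#' @param tau Absolute cutoff on the combined score.
#' @param z Robust MAD multiplier (>= 0).
#' @return List of class \code{"dnt_policy"}.
#' @export
dnt_policy <- function(mode = c("off", "absolute", "robust"),
                       tau = 0.5, z = 2) {
  mode <- match.arg(mode)
  if (z < 0) stop("z must be nonnegative")
  structure(list(mode = mode, tau = tau, z = z), class = "dnt_policy")
}

#' Apply the DNT admission policy to one round of scores
#'
#' The admission boundary is inclusive. If the rule would admit no client,
#' the single highest-scoring client is admitted instead and the round is
#' flagged (attribute \code{"fallback"}).
#'
#' @param scores Named list (names = client ids) of
#'   \code{validation_score}s.
#' @param policy A \code{\link{dnt_policy}}.
#' @return Integer vector of admitted client ids, with attribute
#'   \code{fallback} (logical).
#' @export
dnt_admit <- function(scores, policy) {
  if (!length(scores)) stop("need at least one score")
  ids <- as.integer(names(scores))
  v <- vapply(scores, function(s) s$v, numeric(1))
  keep <- switch(policy$mode,
    off = rep(TRUE, length(v)),
    absolute = v >= policy$tau,
    robust = {
      med <- stats::median(v)
      mad_u <- stats::median(abs(v - med))
      v >= med - policy$z * mad_u
    })
  fallback <- !any(keep)
  if (fallback) keep <- seq_along(v) == which.max(v)
  structure(sort(ids[keep]), fallback = fallback)
}

#' Weighted average of model parameters (federated averaging)
#'
#' Coordinate-wise weighted mean of the flat parameter vectors,
#' \code{sum(w_i x_i) / sum(w_i)}.
#'
#' @param params_list List of \code{mlp_params} sharing one architecture.
#' @param weights Nonnegative weights, positive sum.
#' @return The averaged \code{mlp_params}.
#' @export
weighted_average <- function(params_list, weights) {
  if (!length(params_list)) stop("nothing to average")
  if (length(weights) != length(params_list))
    stop("one weight per parameter set required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must have positive sum")
  ref <- params_list[[1L]]$arch
  for (p in params_list)
    if (!identical(layer_dims(p$arch), layer_dims(ref)))
      stop("architecture mismatch across parameter sets")
  mat <- vapply(params_list, function(p) p$flat,
                numeric(length(params_list[[1L]]$flat)))
  # normalize first so a single model (or weights summing to 1) passes
  # through exactly
  wn <- weights / sum(weights)
  flat <- as.numeric(matrix(mat, ncol = length(params_list)) %*% wn)
  mlp_params(flat, ref)
}

#' Two-stage hierarchical aggregation
#'
#' Each routing server averages its admitted clients with shard-size
#' weights; the central server averages the router aggregates with weights
#' equal to the admitted shard mass under each router. Routers with no
#' admitted client contribute nothing. With every client admitted this
#' equals the flat weighted mean over all clients (associativity of
#' weighted means).
#'
#' @param topology An \code{fl_topology}.
#' @param client_params Named list (names = client ids) of
#'   \code{mlp_params}.
#' @param client_weights Named numeric (names = client ids), typically
#'   shard sizes.
#' @param admitted Integer vector of admitted client ids.
#' @return The central aggregate, an \code{mlp_params}.
#' @export
hierarchical_aggregate <- function(topology, client_params, client_weights,
                                   admitted) {
  router_aggs <- list()
  router_mass <- numeric(0)
  for (r in topology$routers) {
    ids <- intersect(r$client_ids, admitted)
    if (!length(ids)) next
    key <- as.character(ids)
    w <- as.numeric(client_weights[key])
    router_aggs[[length(router_aggs) + 1L]] <-
      weighted_average(client_params[key], w)
    router_mass <- c(router_mass, sum(w))
  }
  if (!length(router_aggs))
    stop("no admitted client under any router")
  weighted_average(router_aggs, router_mass)
}

#' One federated round
#'
#' Every client trains from the current global parameters on its shard
#' (shared per-round training seed, so identically sharded clients follow
#' identical trajectories), is scored on the central calibration set,
#' passes through DNT admission, and the admitted models are aggregated
#' router-wise then centrally. R gains one row.
#'
#' @param state List with \code{round_index}, \code{global_params},
#'   \code{R} (validation matrix).
#' @param topology An \code{fl_topology} with shards filled.
#' @param shard_data Named list per client id: list with standardized
#'   \code{x} and labels \code{y}.
#' @param cfg Base \code{\link{training_config}}; its seed is replaced by
#'   \code{train_seed + round_index}.
#' @param policy A \code{\link{dnt_policy}}.
#' @param calib Calibration list with standardized \code{x} and \code{y}.
#' @param train_seed Base training seed.
#' @return Updated state; also carries \code{admitted}, \code{fallback}
#'   and the round's \code{scores}.
#' @export
run_round <- function(state, topology, shard_data, cfg, policy, calib,
                      train_seed = cfg$seed) {
  rnd <- state$round_index + 1L
  round_cfg <- cfg
  round_cfg$seed <- as.integer(train_seed + rnd)
  ids <- client_ids_of(topology)
  client_params <- list()
  scores <- list()
  weights <- numeric(0)
  for (i in ids) {
    sd_i <- shard_data[[as.character(i)]]
    trained <- train_local(state$global_params, sd_i$x, sd_i$y, round_cfg)
    client_params[[as.character(i)]] <- trained
    scores[[as.character(i)]] <- client_validation_score(trained, calib$x, calib$y)
    weights[as.character(i)] <- nrow(sd_i$x)
  }
  admitted <- dnt_admit(scores, policy)
  global <- hierarchical_aggregate(topology, client_params, weights, admitted)
  state$R <- update_validation_matrix(state$R, rnd, scores)
  state$round_index <- rnd
  state$global_params <- global
  state$admitted <- as.integer(admitted)
  state$fallback <- isTRUE(attr(admitted, "fallback"))
  state$scores <- scores
  state
}

# Stratified carve-out of a fraction of cases, by class; returns indices.
stratified_indices <- function(labels, fraction, seed) {
  with_seed(seed, {
    sort(unlist(lapply(unique(labels), function(cl) {
      members <- which(labels == cl)
      k <- max(1L, round(fraction * length(members)))
      sample(members, min(k, length(members)))
    })))
  })
}

#' Run a full federated experiment
#'
#' Pipeline: a stratified calibration share of the training split is held
#' at the central server for DNT scoring; standardization statistics are
#' computed once on the pooled remaining training features and broadcast;
#' the remaining cases are partitioned across clients; then
#' \code{rounds} federated rounds are executed, tracking held-out test
#' accuracy when a test split is supplied.
#'
#' @param train Training \code{fl_cohort}.
#' @param test Optional test \code{fl_cohort} for per-round metrics.
#' @param n_clients,n_routers Topology size; routers default to
#'   \code{ceiling(sqrt(n_clients))}.
#' @param rounds Number of federated rounds (>= 1).
#' @param cfg A \code{\link{training_config}} (per-round local epochs).
#' @param policy A \code{\link{dnt_policy}}.
#' @param scheme,skew_alpha Partitioning scheme, see
#'   \code{\link{partition_cases}}.
#' @param init_seed,train_seed,partition_seed,calib_seed Component seeds.
#' @param calib_fraction Stratified share of the training split held out
#'   centrally for DNT scoring (default 0.2).
#' @param corrupt_clients Integer ids of clients whose shard labels are
#'   shuffled (adversarial-client simulation; empty by default).
#' @return Object of class \code{"federation_result"}: final
#'   \code{global_params}, the validation matrix \code{R}, per-round
#'   \code{history} (test accuracy, admitted count, fallback flag,
#'   aggregate norm), the \code{topology}, standardization \code{stats}
#'   and the seeds used.
#' @export
run_federation <- function(train, test = NULL, n_clients = 5L,
                           n_routers = ceiling(sqrt(n_clients)),
                           rounds = 30L, cfg = training_config(),
                           policy = dnt_policy("off"),
                           scheme = "iid", skew_alpha = 0.5,
                           init_seed = 11L, train_seed = 101L,
                           partition_seed = 21L, calib_seed = partition_seed + 1L,
                           calib_fraction = 0.2,
                           corrupt_clients = integer(0)) {
  if (rounds < 1L) stop("rounds must be at least 1")
  feats <- cohort_features(train)
  calib_idx <- stratified_indices(feats$y, calib_fraction, calib_seed)
  pool_idx <- setdiff(seq_along(feats$y), calib_idx)
  stats_ <- feature_stats(feats$x[pool_idx, , drop = FALSE])
  xs <- standardize_features(feats$x, stats_)
  calib <- list(x = xs[calib_idx, , drop = FALSE], y = feats$y[calib_idx])
  topology <- build_topology(n_clients, n_routers)
  topology <- partition_cases(rownames(feats$x)[pool_idx], feats$y[pool_idx],
                              topology, scheme = scheme,
                              skew_alpha = skew_alpha, seed = partition_seed)
  shard_data <- list()
  for (cl in topology$clients) {
    # canonical row order (cohort position) so trajectories depend only on
    # shard membership, not on partition shuffle order
    pos <- sort(match(cl$shard, rownames(feats$x)))
    y <- feats$y[pos]
    if (cl$client_id %in% corrupt_clients)
      y <- with_seed(train_seed + 7919L + cl$client_id, sample(y))
    shard_data[[as.character(cl$client_id)]] <-
      list(x = xs[pos, , drop = FALSE], y = y)
  }
  arch <- mlp_architecture(input_dim = ncol(feats$x))
  state <- list(round_index = 0L,
                global_params = init_params(arch, init_seed),
                R = new_validation_matrix(client_ids_of(topology)))
  test_xy <- if (!is.null(test)) {
    tf <- cohort_features(test)
    list(x = standardize_features(tf$x, stats_), y = tf$y)
  }
  history <- data.frame()
  for (r in seq_len(rounds)) {
    state <- run_round(state, topology, shard_data, cfg, policy, calib,
                       train_seed = train_seed)
    acc <- if (!is.null(test_xy))
      mean(predict(state$global_params, test_xy$x)$label == test_xy$y)
    else NA_real_
    history <- rbind(history, data.frame(
      round = r, test_accuracy = acc,
      n_admitted = length(state$admitted),
      fallback = state$fallback,
      aggregate_norm = sqrt(sum(state$global_params$flat^2))))
  }
  structure(list(global_params = state$global_params, R = state$R,
                 history = history, topology = topology, stats = stats_,
                 admitted_final = state$admitted,
                 seeds = list(init = init_seed, train = train_seed,
                              partition = partition_seed, calib = calib_seed),
                 test = test_xy),
            class = "federation_result")
}

#' @export
print.federation_result <- function(x, ...) {
  cat("Federation result:", nrow(x$history), "rounds,",
      length(x$topology$clients), "clients\n")
  if (!all(is.na(x$history$test_accuracy)))
    cat("final test accuracy:",
        round(utils::tail(x$history$test_accuracy, 1), 4), "\n")
  invisible(x)
}

#' Centralized reference training
#'
#' Trains one model on the pooled client training pool (the training split
#' minus the central calibration carve-out), using the same
#' initialization and per-round seeds as the federated pipeline, so that a
#' one-client federation with admission off is bit-identical to this
#' baseline.
#'
#' @inheritParams run_federation
#' @return List with \code{params}, standardization \code{stats} and the
#'   pooled training size \code{n_pool}.
#' @export
train_centralized <- function(train, rounds = 30L, cfg = training_config(),
                              init_seed = 11L, train_seed = 101L,
                              calib_seed = 22L, calib_fraction = 0.2) {
  feats <- cohort_features(train)
  calib_idx <- stratified_indices(feats$y, calib_fraction, calib_seed)
  pool_idx <- setdiff(seq_along(feats$y), calib_idx)
  stats_ <- feature_stats(feats$x[pool_idx, , drop = FALSE])
  x <- standardize_features(feats$x[pool_idx, , drop = FALSE], stats_)
  y <- feats$y[pool_idx]
  arch <- mlp_architecture(input_dim = ncol(x))
  params <- init_params(arch, init_seed)
  for (r in seq_len(rounds)) {
    round_cfg <- cfg
    round_cfg$seed <- as.integer(train_seed + r)
    params <- train_local(params, x, y, round_cfg)
  }
  list(params = params, stats = stats_, n_pool = length(pool_idx))
}
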