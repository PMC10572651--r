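# Distributed Network Thresholding and hierarchical federated averaging.

score_list <- function(v) {
  out <- lapply(v, function(vi)
    structure(list(v_pa = vi, v_pd = vi, v = vi), class = "validation_score"))
  names(out) <- as.character(seq_along(v) - 1L)
  out
}

test_that("validation scores split by attribute group and average exactly", {
  d <- perfect_pair_data()
  zero_model <- mlp_params(numeric(n_params(mlp_architecture())),
                           mlp_architecture())
  s <- client_validation_score(zero_model, d$x, d$y)
  # all-zero weights always predict the first label; balanced 3-way set
  expect_equal(s$v_pa, 1 / 3)
  expect_equal(s$v_pd, 1 / 3)
  expect_equal(s$v, 1 / 3)
  perfect <- perfect_pair_model()
  sp <- client_validation_score(perfect, d$x, d$y)
  expect_identical(c(sp$v_pa, sp$v_pd, sp$v), c(1, 1, 1))
  for (i in 1:100) {
    s <- client_validation_score(random_params(i), d$x, d$y)
    expect_identical(s$v, (s$v_pa + s$v_pd) / 2)
    expect_true(s$v >= 0 && s$v <= 1)
  }
  expect_error(client_validation_score(perfect, d$x[0, , drop = FALSE],
                                       character(0)), "non-empty")
  expect_error(client_validation_score(perfect, d$x[1:2, ], c("normal", "normal")),
               "two classes")
})

test_that("validation matrix is append-only with NA for absentees", {
  R <- new_validation_matrix(0:2)
  R <- update_validation_matrix(R, 0, score_list(c(0.5, 0.6, 0.7)))
  partial <- score_list(c(0.4, 0.8, 0.9))[c("0", "2")]
  R <- update_validation_matrix(R, 1, partial)
  expect_identical(nrow(R$v), 2L)
  expect_identical(R$v[1, ], c(client_0 = 0.5, client_1 = 0.6, client_2 = 0.7))
  expect_true(is.na(R$v[2, "client_1"]))
  expect_identical(R$v[2, "client_2"], 0.9)
  expect_error(update_validation_matrix(R, 0, score_list(0.5)), "increase")
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_matrix(R, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), 2L)
  expect_true(is.na(df$client_1[2]))
})

test_that("admission policies and the keep-best fallback", {
  s <- score_list(c(0.9, 0.8, 0.2))
  expect_identical(as.integer(dnt_admit(s, dnt_policy("absolute", tau = 0.5))),
                   c(0L, 1L))
  expect_identical(as.integer(dnt_admit(s, dnt_policy("off"))), 0:2)
  eq <- score_list(rep(0.42, 4))
  expect_identical(as.integer(dnt_admit(eq, dnt_policy("robust", z = 0))), 0:3)
  fb <- dnt_admit(s, dnt_policy("absolute", tau = 0.95))
  expect_identical(as.integer(fb), 0L)
  expect_true(attr(fb, "fallback"))
})

test_that("absolute-mode admission is non-increasing in tau", {
  set.seed(12)
  for (i in 1:50) {
    s <- score_list(runif(sample(2:10, 1)))
    taus <- sort(runif(5))
    prev <- NULL
    for (tau in taus) {
      adm <- as.integer(dnt_admit(s, dnt_policy("absolute", tau = tau)))
      if (!is.null(prev)) expect_true(all(adm %in% prev))
      prev <- adm
    }
  }
})

test_that("weighted averaging matches an independent oracle", {
  arch <- mlp_architecture()
  one <- random_params(3)
  expect_identical(weighted_average(list(one), 5)$flat, one$flat)
  zeros <- mlp_params(numeric(n_params(arch)), arch)
  ones <- mlp_params(rep(1, n_params(arch)), arch)
  expect_equal(weighted_average(list(zeros, ones), c(1, 1))$flat,
               rep(0.5, n_params(arch)))
  set.seed(2)
  for (rep_i in 1:10) {
    ps <- lapply(1:7, function(i) random_params(100 * rep_i + i))
    w <- runif(7)
    got <- weighted_average(ps, w)$flat
    # brute-force sum, coded independently of the implementation
    acc <- numeric(n_params(arch))
    for (i in 1:7) acc <- acc + w[i] * ps[[i]]$flat
    expect_equal(got, acc / sum(w), tolerance = 1e-12)
  }
  expect_error(weighted_average(list(zeros, ones), c(0, 0)), "positive sum")
  small <- init_params(mlp_architecture(8, 4), 1)
  expect_error(weighted_average(list(zeros, small), c(1, 1)), "mismatch")
})

test_that("aggregation is linear in the parameters", {
  ps <- lapply(1:4, random_params)
  w <- c(2, 1, 3, 5)
  base <- weighted_average(ps, w)$flat
  scaled <- lapply(ps, function(p) mlp_params(3 * p$flat, p$arch))
  expect_equal(weighted_average(scaled, w)$flat, 3 * base, tolerance = 1e-12)
})

test_that("hierarchical aggregation equals the flat weighted mean when all admit", {
  set.seed(21)
  for (i in 1:15) {
    nc <- sample(2:12, 1)
    topo <- build_topology(nc, sample(seq_len(nc), 1))
    ps <- lapply(seq_len(nc), function(j) random_params(1000 * i + j))
    names(ps) <- as.character(0:(nc - 1))
    w <- stats::setNames(sample(1:20, nc, replace = TRUE), names(ps))
    hier <- hierarchical_aggregate(topo, ps, w, 0:(nc - 1))
    flat <- weighted_average(ps, as.numeric(w))
    expect_equal(hier$flat, flat$flat, tolerance = 1e-10)
  }
})

test_that("routers without admitted clients contribute nothing", {
  topo <- build_topology(4, 2)  # routers {0,2} and {1,3}
  ps <- lapply(1:4, random_params)
  names(ps) <- as.character(0:3)
  w <- stats::setNames(c(3, 1, 2, 4), names(ps))
  only_r0 <- hierarchical_aggregate(topo, ps, w, c(0L, 2L))
  expect_equal(only_r0$flat,
               weighted_average(ps[c("0", "2")], c(3, 2))$flat,
               tolerance = 1e-12)
  expect_error(hierarchical_aggregate(topo, ps, w, integer(0)), "no admitted")
})

test_that("a one-client round reduces to plain local training", {
  cohort <- shared_cohort()
  feats <- cohort_features(cohort)
  stats_ <- feature_stats(feats$x)
  xs <- standardize_features(feats$x, stats_)
  calib <- list(x = xs[1:20, ], y = feats$y[1:20])
  shard <- list(x = xs[21:60, ], y = feats$y[21:60])
  topo <- build_topology(1, 1)
  topo$clients[[1]]$shard <- rownames(shard$x)
  cfg <- training_config(epochs = 15)
  state <- list(round_index = 0L,
                global_params = init_params(mlp_architecture(), 5),
                R = new_validation_matrix(0L))
  out <- run_round(state, topo, list("0" = shard), cfg, dnt_policy("off"),
                   calib, train_seed = 100L)
  direct_cfg <- cfg
  direct_cfg$seed <- 101L
  direct <- train_local(state$global_params, shard$x, shard$y, direct_cfg)
  expect_identical(out$global_params$flat, direct$flat)
  expect_identical(nrow(out$R$v), 1L)
})

test_that("identically sharded clients collapse to a single trajectory", {
  cohort <- shared_cohort()
  feats <- cohort_features(cohort)
  xs <- standardize_features(feats$x, feature_stats(feats$x))
  shard <- list(x = xs[1:30, ], y = feats$y[1:30])
  calib <- list(x = xs[31:60, ], y = feats$y[31:60])
  topo <- build_topology(4, 2)
  for (i in 1:4) topo$clients[[i]]$shard <- rownames(shard$x)
  shards <- stats::setNames(rep(list(shard), 4), as.character(0:3))
  state <- list(round_index = 0L,
                global_params = init_params(mlp_architecture(), 2),
                R = new_validation_matrix(0:3))
  out <- run_round(state, topo, shards, training_config(epochs = 10),
                   dnt_policy("off"), calib, train_seed = 7L)
  single_cfg <- training_config(epochs = 10)
  single_cfg$seed <- 8L
  single <- train_local(state$global_params, shard$x, shard$y, single_cfg)
  expect_equal(out$global_params$flat, single$flat, tolerance = 1e-10)
})

test_that("federation runs are reproducible end to end", {
  cohort <- shared_cohort()
  sp <- split_cohort(cohort, 0.6, seed = 3)
  args <- list(train = sp$train, test = sp$test, n_clients = 3L, rounds = 2L,
               cfg = training_config(epochs = 8), policy = dnt_policy("off"),
               init_seed = 1L, train_seed = 2L, partition_seed = 3L)
  a <- do.call(run_federation, args)
  b <- do.call(run_federation, args)
  expect_identical(a$global_params$flat, b$global_params$flat)
  expect_identical(a$history, b$history)
  expect_identical(a$R$v, b$R$v)
})
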