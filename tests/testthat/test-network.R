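test_that("Gaussian response has the right shape and closed-form values", {
  x <- rnorm(84); cen <- rnorm(84)
  expect_equal(hidden_response(x, x, 2), 1.0)
  # half-activation at distance sigma * sqrt(2 ln 2)
  sigma <- 1.7
  d <- sigma * sqrt(2 * log(2))
  cen2 <- x; cen2[1] <- x[1] + d
  expect_equal(hidden_response(x, cen2, sigma), 0.5)
  # strictly decreasing in distance
  resp <- sapply(seq(0, 10, by = 0.5), function(dd) {
    c2 <- x; c2[1] <- x[1] + dd
    hidden_response(x, c2, sigma)
  })
  expect_true(all(diff(resp) < 0))
  expect_error(hidden_response(x, cen, 0), "state error")
})

test_that("winner equals the argmax oracle and handles ties and emptiness", {
  set.seed(1)
  cfg <- train_config(seed = 1)
  st <- new_net(cfg)
  x <- encode_stem(parse_form("1 s I N"))
  expect_true(is.na(winner(st, x)$index))
  # 100 random units: winner matches a brute-force response scan
  m <- 100
  st$centers <- matrix(rnorm(84 * m), 84, m)
  st$widths <- runif(m, 0.5, 5)
  st$W_hidden <- matrix(0, 97, m)
  st$local_error <- numeric(m); st$last_active <- integer(m)
  resp <- sapply(seq_len(m), function(u)
    hidden_response(x, st$centers[, u], st$widths[u]))
  w <- winner(st, x)
  expect_equal(w$index, which.max(resp))
  expect_equal(w$activation, max(resp))
  # exact tie broken by lowest index
  st$centers[, 5] <- st$centers[, 2]; st$widths[5] <- st$widths[2]
  resp5 <- hidden_response(x, st$centers[, 2], st$widths[2])
  if (resp5 > max(resp[-c(2, 5)])) expect_equal(winner(st, x)$index, 2L)
})

test_that("forward pass matches a brute-force double loop", {
  cfg <- train_config(theta = 0.5)
  set.seed(2)
  for (rep in 1:20) {
    n_in <- 5; n_out <- 5
    st <- structure(list(
      W_direct = matrix(rnorm(n_out * n_in), n_out, n_in),
      W_hidden = matrix(rnorm(n_out), n_out, 1),
      centers = matrix(rnorm(n_in), n_in, 1),
      widths = 1.5, local_error = 0, last_active = 0L, token = 0L,
      win_means = numeric(0), cur_sum = 0, cur_n = 0L), class = "ncm_state")
    x <- sample(c(-1, 0, 1), n_in, replace = TRUE)
    fw <- net_forward(st, x, cfg)
    a_h <- hidden_response(x, st$centers[, 1], st$widths[1])
    brute <- sapply(seq_len(n_out), function(o)
      sum(st$W_direct[o, ] * x) + st$W_hidden[o, 1] * a_h)
    expect_equal(fw$net, brute, tolerance = 1e-12)
  }
  # zero weights give all-zero output; empty layer leaves the direct path
  st0 <- new_net(train_config(init_w = 0))
  x <- encode_stem(parse_form("1 s I N"))
  expect_true(all(net_forward(st0, x, cfg)$output == 0))
  expect_equal(net_forward(st0, x, cfg)$indirect, numeric(97))
})

test_that("a correct output produces no update; centers move toward inputs", {
  cfg <- train_config(seed = 3)
  set.seed(3)
  st <- new_net(cfg)
  x <- encode_stem(parse_form("1 s I N"))
  y <- net_forward(st, x, cfg)$output  # target equal to current decision
  st2 <- train_step(st, x, y, cfg)
  expect_equal(st2$W_direct, st$W_direct)
  # repeated presentation of one pattern does not increase its error
  y_real <- encode_past(regular_past(parse_form("1 s I N")))
  err_of <- function(s) sum(abs(y_real - net_forward(s, x, cfg)$output))
  s <- st
  errs <- numeric(30)
  for (k in 1:30) { s <- train_step(s, x, y_real, cfg); errs[k] <- err_of(s) }
  expect_lte(errs[30], errs[1])
  expect_equal(errs[30], 0)
  # winner's center moves a step eta_center toward the input
  s$centers <- matrix(rnorm(84), 84, 1)
  s$widths <- 2; s$local_error <- 0; s$last_active <- 0L
  s$W_hidden <- matrix(0, 97, 1)
  d0 <- sqrt(sum((s$centers[, 1] - x)^2))
  s2 <- train_step(s, x, y_real, cfg)
  d1 <- sqrt(sum((s2$centers[, 1] - x)^2))
  expect_equal(d1, (1 - cfg$eta_center) * d0)
})

test_that("growth fires on a flat error history and inserts 3 units at the max-error center", {
  cfg <- train_config(seed = 4)
  set.seed(4)
  st <- new_net(cfg)
  st$centers <- matrix(rnorm(84 * 3), 84, 3)
  st$widths <- rep(2, 3)
  st$W_hidden <- matrix(0, 97, 3)
  st$local_error <- c(1, 10, 2)   # unit 2 is the donor
  st$last_active <- rep(0L, 3)
  x <- encode_stem(parse_form("1 s I N"))
  # strictly improving error: no insertion
  st$win_means <- c(4, 3, 2, 1)
  expect_equal(pastnet:::n_units(maybe_grow(st, cfg, x)), 3)
  # flat error: exactly insert_k units appear, centered near the donor
  st$win_means <- c(2, 2, 2, 2)
  st2 <- maybe_grow(st, cfg, x)
  expect_equal(pastnet:::n_units(st2), 6)
  for (u in 4:6)
    expect_lt(max(abs(st2$centers[, u] - st$centers[, 2])), 0.1)
  expect_equal(st2$local_error[2], 0)  # donor counter reset
  expect_equal(st2$win_means, numeric(0))
  # new units inherit the donor's width
  expect_equal(st2$widths[4:6], rep(st$widths[2], 3))
  # bootstrap from an empty layer inserts at the current input
  st0 <- new_net(cfg)
  st0$win_means <- c(2, 2, 2, 2)
  st3 <- maybe_grow(st0, cfg, x)
  expect_equal(pastnet:::n_units(st3), 3)
  expect_lt(max(abs(st3$centers[, 1] - x)), 0.1)
})

test_that("pruning removes exactly the stale units", {
  cfg <- train_config()
  set.seed(5)
  st <- new_net(cfg)
  st$centers <- matrix(rnorm(84 * 3), 84, 3)
  st$widths <- rep(2, 3)
  st$W_hidden <- matrix(rnorm(97 * 3), 97, 3)
  st$local_error <- 1:3
  st$token <- 60000L
  # inactivity 5,000 / 29,999 / 30,001: only the third reaches the cutoff
  st$last_active <- c(55000L, 30001L, 29999L)
  st2 <- prune_units(st, cfg)
  expect_equal(pastnet:::n_units(st2), 2)
  expect_equal(st2$local_error, c(1, 2))
  expect_true(all(st2$token - st2$last_active < cfg$prune_T))
  # inactivity of exactly prune_T is pruned too
  st$last_active <- c(55000L, 30000L, 31000L)
  expect_equal(pastnet:::n_units(prune_units(st, cfg)), 2)
  # a unit that keeps winning is never pruned
  st$last_active <- rep(st$token, 3)
  expect_equal(pastnet:::n_units(prune_units(st, cfg)), 3)
})

test_that("accuracy scores exact ternary matches and ignores unit order", {
  cfg <- train_config(init_w = 0)
  corp <- small_corpus(seed = 5, n = 60)
  set.seed(6)
  st <- new_net(cfg)
  expect_equal(accuracy(st, corp, cfg), 0)  # zero net never matches a verb
  # constructed exact solution on a 2-verb toy with orthogonal inputs
  x1 <- numeric(84); x1[1:12] <- rep(c(1, -1), 6)
  x2 <- numeric(84); x2[51:60] <- rep(c(-1, 1), 5)
  y1 <- sample(c(-1, 0, 1), 97, replace = TRUE)
  y2 <- sample(c(-1, 0, 1), 97, replace = TRUE)
  toy <- list(X = cbind(x1, x2), Y = cbind(y1, y2))
  W <- y1 %o% x1 / sum(x1^2) + y2 %o% x2 / sum(x2^2)
  stW <- st; stW$W_direct <- W
  expect_equal(accuracy(stW, toy, cfg), 1)
  # accuracy invariant under permutation of hidden units
  fx <- trained_fixture()
  st <- fx$fit$state
  perm <- sample(pastnet:::n_units(st))
  stp <- st
  stp$W_hidden <- st$W_hidden[, perm, drop = FALSE]
  stp$centers <- st$centers[, perm, drop = FALSE]
  stp$widths <- st$widths[perm]
  stp$local_error <- st$local_error[perm]
  stp$last_active <- st$last_active[perm]
  expect_equal(accuracy(stp, fx$corpus, fx$cfg),
               accuracy(st, fx$corpus, fx$cfg))
})

test_that("the compiled and R engines produce identical trajectories", {
  corp <- small_corpus()
  cfg <- train_config(seed = 11, checkpoint_interval = 50000L)
  fc <- train_network(corp, 150000, cfg, engine = "cpp")
  fr <- train_network(corp, 150000, cfg, engine = "R")
  expect_equal(pastnet:::n_units(fc$state), pastnet:::n_units(fr$state))
  expect_equal(fc$state$W_direct, fr$state$W_direct, tolerance = 1e-10)
  expect_equal(fc$state$W_hidden, fr$state$W_hidden, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fc$state$centers, fr$state$centers, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fc$state$widths, fr$state$widths)
  expect_equal(fc$events, fr$events)
  expect_equal(fc$record, fr$record, tolerance = 1e-8)
})

test_that("training is deterministic given the seed", {
  corp <- small_corpus()
  cfg <- train_config(seed = 21)
  f1 <- train_network(corp, 100000, cfg, record = FALSE)
  f2 <- train_network(corp, 100000, cfg, record = FALSE)
  expect_identical(f1$state$W_direct, f2$state$W_direct)
  expect_identical(f1$state$W_hidden, f2$state$W_hidden)
  expect_equal(train_network(corp, 0, cfg)$state$token, 0)
})

test_that("lesions remove the requested pathway material", {
  fx <- trained_fixture()
  st <- fx$fit$state
  # fraction 0: identical behaviour
  l0 <- lesion(st, "direct", 0, seed = 1)
  expect_equal(l0$W_direct, st$W_direct)
  # full indirect lesion: behaviour equals the direct pathway alone
  l1 <- lesion(st, "indirect", 1, seed = 1)
  expect_equal(pastnet:::n_units(l1), 0)
  x <- encode_stem(fx$corpus$stem_forms[[1]])
  expect_equal(net_forward(l1, x, fx$cfg)$net,
               as.numeric(st$W_direct %*% x))
  # half direct lesion zeroes about half of the weights
  lh <- lesion(st, "direct", 0.5, seed = 2)
  expect_equal(sum(lh$W_direct == 0), round(0.5 * length(st$W_direct)))
})
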