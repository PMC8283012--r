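test_that("Mann-Whitney U matches pairwise counting and wilcox.test", {
  set.seed(10)
  # exhaustive pairwise-count oracle for small samples, with and without ties
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:6, n1, replace = TRUE)  # replacement forces ties
    b <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney(a, b)
    expect_equal(res$U, brute_U(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE,
                                              exact = FALSE))
    expect_equal(res$U, unname(wt$statistic))
    expect_equal(res$p, wt$p.value, tolerance = 1e-10)
  }
  # identical samples: z = 0, p = 1
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p, 1, tolerance = 1e-6)
  # all values tied across both samples
  res <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(res$z, 0); expect_equal(res$p, 1)
  # swapping sample labels negates z
  a <- rnorm(12); b <- rnorm(15) + 1
  expect_equal(mann_whitney(a, b)$z, -mann_whitney(b, a)$z)
  # mean ranks: the textbook example with full separation
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$mean_rank_a, 2); expect_equal(res$mean_rank_b, 5)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("correlation table matches the textbook formula", {
  d <- data.frame(past_freq = c(1, 2, 3, 4), friends = c(2, 2, 2, 2),
                  enemies = c(4, 3, 2, 1), complexity = c(1, 3, 2, 4))
  y <- 2 * d$past_freq + 3
  r <- corr_table(d, y)
  expect_equal(unname(r["past_freq"]), 1)           # exact affine function
  expect_true(is.na(r["friends"]))                  # zero variance
  expect_equal(unname(r["enemies"]), -1)
  # hand computation on a printed 4-point toy
  hand <- sum(scale(d$complexity) * scale(y)) / 3
  expect_equal(unname(r["complexity"]), hand)
  expect_error(corr_table(d[1:2, ], y[1:2]), "at least 3")
})

test_that("mixed model recovers known coefficients within 2 SE", {
  set.seed(12)
  n_verb <- 500; n_net <- 3
  verb <- rep(seq_len(n_verb), n_net)
  network <- rep(seq_len(n_net), each = n_verb)
  freq <- rep(rexp(n_verb), n_net)
  friends <- rep(rpois(n_verb, 3), n_net)
  enemies <- rep(rpois(n_verb, 2), n_net)
  complexity <- rep(sample(2:7, n_verb, replace = TRUE), n_net)
  u_verb <- rep(rnorm(n_verb, 0, 0.5), n_net)
  u_net <- rep(rnorm(n_net, 0, 0.3), each = n_verb)
  y <- 2 * scale(freq)[, 1] - 1 * scale(enemies)[, 1] + u_verb + u_net +
    rnorm(n_verb * n_net, 0, 0.7)
  d <- data.frame(id = verb, network = network, past_freq = freq,
                  friends = friends, enemies = enemies,
                  complexity = complexity, indirect = y,
                  class = "regular")
  fit <- fit_pathway_model(d, "indirect")
  expect_lt(abs(fit$beta["past_freq"] - 2), 2 * fit$se["past_freq"])
  expect_lt(abs(fit$beta["enemies"] + 1), 2 * fit$se["enemies"])
  expect_lt(abs(fit$beta["friends"]), 2 * fit$se["friends"])
  expect_gt(fit$r2, 0.3)
  # standardisation contract: affine predictor transforms leave beta unchanged
  d2 <- d; d2$past_freq <- 100 * d2$past_freq - 7
  fit2 <- fit_pathway_model(d2, "indirect")
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
})

test_that("null augmentation adds nothing; collinearity is an error", {
  set.seed(13)
  n_verb <- 300
  d <- data.frame(id = rep(seq_len(n_verb), 2),
                  network = rep(1:2, each = n_verb),
                  past_freq = rep(rexp(n_verb), 2),
                  friends = rep(rpois(n_verb, 3), 2),
                  enemies = rep(rpois(n_verb, 2), 2),
                  complexity = rep(sample(2:7, n_verb, TRUE), 2))
  d$indirect <- 1.5 * scale(d$past_freq)[, 1] + rnorm(2 * n_verb)
  # regularity assigned independently of y: no improvement expected
  d$class <- rep(sample(c("regular", "irregular"), n_verb, TRUE), 2)
  fit <- fit_pathway_model(d, "indirect", include_regularity = TRUE)
  expect_gt(fit$lrt_p, 0.05)
  expect_lt(abs(fit$delta_r2), 0.01)
  # a duplicated predictor triggers the collinearity error
  d$friends <- d$enemies
  expect_error(fit_pathway_model(d, "indirect"), "collinear")
})

test_that("typicality ranks by activation ratio with stable ties", {
  prof <- data.frame(id = sprintf("v%02d", 1:8),
                     class = rep(c("regular", "irregular"), each = 4),
                     subtype = c(rep("none", 4), rep("vowel_change", 4)),
                     ratio = c(0.9, 0.8, 0.7, 0.6, 0.2, 0.3, 0.4, 0.5))
  t_reg <- typicality(prof, "regular", k = 2)
  expect_equal(t_reg$most_typical$id, c("v01", "v02"))   # highest ratio
  expect_equal(t_reg$least_typical$id, c("v04", "v03"))  # lowest, worst first
  t_irr <- typicality(prof, "irregular", k = 2)
  expect_equal(t_irr$most_typical$id, c("v05", "v06"))   # lowest ratio
  expect_equal(t_irr$least_typical$id, c("v08", "v07"))
  # k = class size returns the whole class; lists disjoint when 2k <= size
  t_all <- typicality(prof, "regular", k = 4)
  expect_setequal(t_all$most_typical$id, prof$id[1:4])
  expect_length(intersect(t_reg$most_typical$id, t_reg$least_typical$id), 0)
  expect_warning(typicality(prof, "irregular", k = 10), "truncating")
})

test_that("matched subsets pair nearest complexity and rerun group tests", {
  set.seed(14)
  prof <- data.frame(
    id = sprintf("v%02d", 1:12),
    class = c(rep("regular", 8), rep("irregular", 4)),
    complexity = c(2, 3, 3, 4, 5, 6, 6, 7, 2, 3, 4, 6),
    direct = rnorm(12, 100, 10), indirect = rnorm(12, 10, 2))
  m <- matched_subset(prof)
  expect_equal(nrow(m$pairs), 4)        # min class size
  # perfectly matchable keys give equal complexity across classes
  expect_equal(sort(m$pairs$key_regular), sort(m$pairs$key_irregular))
  expect_s3_class(m$direct_test, "mw_test")
  expect_equal(m$direct_test$n_a, 4)
  expect_error(matched_subset(prof[prof$class == "regular", ]), "nonempty")
})
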