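test_that("regular past applies -ed allomorphy by final segment", {
  inv <- default_inventory()
  # voiceless non-alveolar final consonant -> /t/
  p <- regular_past(parse_form("1 l U k"), inv)
  expect_null(p$suffix_v); expect_equal(p$suffix_c, "t")
  # voiced final -> /d/
  p <- regular_past(parse_form("1 s I N"), inv)
  expect_equal(p$suffix_c, "d")
  # vowel-final -> /d/
  p <- regular_past(parse_form("1 s t e"), inv)
  expect_equal(p$suffix_c, "d")
  # final alveolar stop -> syllabic allomorph, V and C slots both filled
  p <- regular_past(parse_form("1 n i d"), inv)
  expect_equal(p$suffix_v, "I"); expect_equal(p$suffix_c, "d")
})

test_that("irregular subtypes produce the intended past shapes", {
  inv <- default_inventory()
  stem <- parse_form("1 s I N")
  expect_equal(deparse_form(irregular_past(stem, "no_change", inv = inv)$form),
               deparse_form(stem))
  vc <- irregular_past(stem, "vowel_change", new_vowel = "&", inv = inv)
  expect_equal(deparse_form(vc$form), "1 s & N")
  expect_null(vc$suffix_c)
  vcs <- irregular_past(stem, "vowel_change_suffix", new_vowel = "E",
                        inv = inv)
  expect_equal(vcs$suffix_c, "d")  # voiced final segment takes /d/
  # suppletive pasts share little encoded material with the stem on average
  set.seed(31)
  overlap <- replicate(40, {
    sup <- irregular_past(stem, "suppletive", inv = inv)
    x <- encode_stem(stem, inv); y <- encode_stem(sup$form, inv)
    nz <- x != 0 | y != 0
    mean(x[nz] == y[nz])
  })
  expect_lt(mean(overlap), 0.5)
})

test_that("generated corpora hit the class structure targets deterministically", {
  cfg <- corpus_config(n_types = 200, seed = 3)
  corp <- generate_corpus(cfg)
  s <- corpus_summary(corp)
  expect_equal(s$n_types, 200)
  # type fraction within one type of the target
  expect_lte(abs(s$n_irregular - round(cfg$irregular_type_frac * 200)), 1)
  # token fraction within 5 percentage points of the target
  expect_lt(abs(s$token_frac_irregular - 100 * cfg$irregular_token_frac), 5)
  # irregular token share exceeds irregular type share
  expect_gt(s$token_frac_irregular, s$type_frac_irregular)
  # homophone exclusion: unique stems
  expect_equal(anyDuplicated(corp$entries$stem), 0L)
  # determinism
  corp2 <- generate_corpus(cfg)
  expect_identical(corp$entries, corp2$entries)
  # infeasible token share at small n is rejected
  expect_error(generate_corpus(corpus_config(n_types = 60, seed = 1)),
               "config error")
})

test_that("all-regular corpora are supported", {
  corp <- generate_corpus(corpus_config(n_types = 50, irregular_type_frac = 0,
                                        irregular_token_frac = 0, seed = 2))
  expect_true(all(corp$entries$class == "regular"))
  s <- corpus_summary(corp)
  expect_equal(s$type_frac_irregular, 0)
  expect_equal(s$token_frac_irregular, 0)
})

test_that("friend/enemy counts match a brute-force pairwise oracle", {
  corp <- small_corpus(seed = 7)
  e <- corp$entries
  stem_r <- vapply(corp$stem_forms, rime, "")
  past_r <- vapply(corp$past_forms, pastnet:::past_rime, "")
  n <- nrow(e)
  for (i in sample.int(n, 30)) {
    fr <- sum(stem_r == stem_r[i] & past_r == past_r[i]) - 1L
    en <- sum(stem_r == stem_r[i] & past_r != past_r[i])
    expect_equal(e$friends[i], fr)
    expect_equal(e$enemies[i], en)
    # friends + enemies = rime-mates - 1
    expect_equal(e$friends[i] + e$enemies[i], sum(stem_r == stem_r[i]) - 1L)
  }
})

test_that("friendship and enmity are symmetric relations", {
  corp <- small_corpus(seed = 13)
  stem_r <- vapply(corp$stem_forms, rime, "")
  past_r <- vapply(corp$past_forms, pastnet:::past_rime, "")
  n <- length(stem_r)
  friend <- outer(stem_r, stem_r, "==") & outer(past_r, past_r, "==")
  enemy <- outer(stem_r, stem_r, "==") & !outer(past_r, past_r, "==")
  expect_true(isSymmetric(friend))
  expect_true(isSymmetric(enemy))
  # two verbs sharing a rime family with the same transformation are friends
  diag(friend) <- FALSE
  expect_equal(corp$entries$friends, rowSums(friend))
  expect_equal(corp$entries$enemies, rowSums(enemy))
})

test_that("token stream sampling follows the frequency weights", {
  # single-verb corpus: the stream is that verb repeated
  corp <- small_corpus(seed = 5)
  one <- corp
  one$entries <- one$entries[1, ]
  one$stem_forms <- one$stem_forms[1]
  one$past_forms <- one$past_forms[1]
  expect_true(all(sample_stream(one, 50, seed = 1) == 1L))
  # 2:1 weights converge to a 2:1 empirical ratio
  two <- corp
  two$entries <- two$entries[1:2, ]
  two$entries$past_freq <- c(2, 1)
  s <- sample_stream(two, 3e4, seed = 2)
  expect_lt(abs(mean(s == 1L) - 2 / 3), 0.02)
  # uniform weights pass a chi-square uniformity test
  unif <- corp
  unif$entries$past_freq <- rep(1, nrow(unif$entries))
  s <- sample_stream(unif, 1e5, seed = 3)
  p <- chisq.test(tabulate(s, nrow(unif$entries)))$p.value
  expect_gt(p, 0.001)
  # determinism
  expect_identical(sample_stream(corp, 1000, seed = 4),
                   sample_stream(corp, 1000, seed = 4))
})

test_that("summary fractions agree with hand computation", {
  # the reference corpus arithmetic: 111 irregulars among 1,271 types
  expect_equal(round(100 * 111 / 1271, 2), 8.73)
  corp <- small_corpus(seed = 5)
  toy <- corp
  toy$entries <- toy$entries[1:5, ]
  toy$entries$class <- c("irregular", "regular", "regular", "irregular",
                         "regular")
  toy$entries$past_freq <- c(4, 3, 1, 1, 1)
  s <- corpus_summary(toy)
  expect_equal(s$type_frac_irregular, 40)
  expect_equal(s$token_frac_irregular, 50)
  expect_error(corpus_summary(structure(list(entries = toy$entries[0, ]),
                                        class = "verb_corpus")), "empty")
})

test_that("corpus CSV round-trips forms and statistics", {
  corp <- small_corpus(seed = 5, n = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, path)
  expect_match(readLines(path, n = 1), "seed: 5")
  back <- read_corpus(path)
  expect_equal(back$entries, corp$entries)
  expect_equal(vapply(back$stem_forms, deparse_form, ""),
               vapply(corp$stem_forms, deparse_form, ""))
  expect_equal(vapply(back$past_forms, pastnet:::deparse_past, ""),
               vapply(corp$past_forms, pastnet:::deparse_past, ""))
})
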