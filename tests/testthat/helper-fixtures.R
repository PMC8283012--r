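# Shared fixtures and independent oracles.

# a feasible small corpus for fast tests (token-share target reachable at n=120)
small_corpus <- function(seed = 5, n = 120) {
  generate_corpus(corpus_config(n_types = n, irregular_type_frac = 0.12,
                                irregular_token_frac = 0.35, seed = seed))
}

# one small trained network, computed once per test run
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corp <- small_corpus()
      cfg <- train_config(seed = 11, checkpoint_interval = 100000L)
      fit <- train_network(corp, 8e5, cfg)
      cache <<- list(corpus = corp, fit = fit, cfg = cfg)
    }
    cache
  }
})

# brute-force double-loop pathway activations (independent of the package's
# vectorised implementations)
brute_direct <- function(W, x) {
  s <- 0
  for (o in seq_len(nrow(W))) for (i in seq_len(ncol(W)))
    s <- s + abs(W[o, i] * x[i])
  s
}

brute_indirect <- function(w_col, a_h) {
  s <- 0
  for (o in seq_along(w_col)) s <- s + abs(w_col[o] * a_h)
  s
}

# Mann-Whitney U by exhaustive pairwise counting (the definitional form)
brute_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# random legal verb form built directly from the inventory tables
random_form_oracle <- function(inv, bisyllabic = FALSE) {
  cons <- inventory_symbols(inv, "consonant")
  vows <- inventory_symbols(inv, "vowel")
  syl <- function(stress) syllable(stress,
                                   onset = sample(cons, sample(0:3, 1)),
                                   nucleus = sample(vows, 1),
                                   coda = sample(cons, sample(0:2, 1)))
  if (bisyllabic) verb_form(syl(0L), syl(1L)) else verb_form(syl(1L))
}
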