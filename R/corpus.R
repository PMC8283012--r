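#' Configuration for the synthetic verb corpus generator
#'
#' The generator emulates the statistical structure of a realistic English
#' past-tense training set: a Zipf-Mandelbrot token-frequency distribution
#' over verb types, a small fraction of irregular types carrying a much
#' larger fraction of tokens (defaults: 8.73\% of types, 46\% of tokens),
#' rime families that create friend/enemy neighbourhoods, regular
#' \emph{-ed} allomorphy, and phonological complexity variation with
#' regulars slightly more complex on average.
#'
#' @param n_types Number of verb types (default 1271).
#' @param irregular_type_frac Target fraction of irregular types
#'   (default 111/1271).
#' @param irregular_token_frac Target fraction of tokens that are irregular
#'   (default 0.46), achieved by biasing irregulars toward high-frequency
#'   ranks.
#' @param zipf_exponent Exponent of the Zipf-Mandelbrot law (default 1).
#' @param zipf_offset Rank offset of the Zipf-Mandelbrot law (default 2.7).
#' @param mean_family_size Mean number of verbs per stem-rime family
#'   (default 6).
#' @param subtype_mix Named numeric mixture over irregular subtypes
#'   \code{no_change}, \code{vowel_change}, \code{vowel_change_suffix}
#'   (the "pseudo-regulars"), \code{suppletive}.
#' @param p_bisyllabic_regular,p_bisyllabic_irregular Probability that a
#'   regular/irregular stem is bisyllabic. Regulars default higher, making
#'   them phonologically more complex on average.
#' @param seed Integer seed; the corpus is fully deterministic given the
#'   seed.
#' @return A list of class \code{corpus_config}.
#' @export
corpus_config <- function(n_types = 1271L,
                          irregular_type_frac = 111 / 1271,
                          irregular_token_frac = 0.46,
                          zipf_exponent = 1,
                          zipf_offset = 2.7,
                          mean_family_size = 6,
                          subtype_mix = c(no_change = 0.15,
                                          vowel_change = 0.45,
                                          vowel_change_suffix = 0.30,
                                          suppletive = 0.10),
                          p_bisyllabic_regular = 0.45,
                          p_bisyllabic_irregular = 0.2,
                          seed = 1L) {
  if (n_types < 10L) stop("config error: n_types must be >= 10")
  if (irregular_type_frac < 0 || irregular_type_frac >= 1)
    stop("config error: irregular_type_frac must be in [0,1)")
  if (irregular_token_frac < 0 || irregular_token_frac >= 1)
    stop("config error: irregular_token_frac must be in [0,1)")
  stopifnot(abs(sum(subtype_mix) - 1) < 1e-8)
  structure(list(n_types = as.integer(n_types),
                 irregular_type_frac = irregular_type_frac,
                 irregular_token_frac = irregular_token_frac,
                 zipf_exponent = zipf_exponent,
                 zipf_offset = zipf_offset,
                 mean_family_size = mean_family_size,
                 subtype_mix = subtype_mix,
                 p_bisyllabic_regular = p_bisyllabic_regular,
                 p_bisyllabic_irregular = p_bisyllabic_irregular,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Regular past tense of a stem
#'
#' Applies the \emph{-ed} allomorphy rule: the syllabic allomorph (vowel +
#' /d/) after a stem-final alveolar stop, voiceless /t/ after a voiceless
#' final consonant, /d/ otherwise (including vowel-final stems).
#'
#' @param stem A \code{verb_form}.
#' @param inv A \code{phoneme_inventory}.
#' @return A \code{verb_past}.
#' @export
regular_past <- function(stem, inv = default_inventory()) {
  fin <- final_segment(stem)
  if (isTRUE(inv$alveolar_stop[[fin]]))
    verb_past(stem, suffix_v = "I", suffix_c = "d")
  else if (!inv$voiced[[fin]])
    verb_past(stem, suffix_c = "t")
  else
    verb_past(stem, suffix_c = "d")
}

final_segment <- function(form) {
  syls <- form[!vapply(form, is_empty_syllable, TRUE)]
  fin <- syls[[length(syls)]]
  if (length(fin$coda)) fin$coda[length(fin$coda)] else fin$nucleus
}

#' Irregular past tense of a stem
#'
#' Generates an irregular past according to the subtype: \code{no_change}
#' returns the stem itself; \code{vowel_change} replaces the final-syllable
#' nucleus (consistently within a rime family, so family members become
#' friends); \code{vowel_change_suffix} additionally adds a dental /t/ or
#' /d/ suffix (the "pseudo-regular" pattern, e.g. sleep-slept);
#' \code{suppletive} produces an unrelated random legal form.
#'
#' @param stem A \code{verb_form}.
#' @param subtype One of \code{"no_change"}, \code{"vowel_change"},
#'   \code{"vowel_change_suffix"}, \code{"suppletive"}.
#' @param new_vowel Replacement nucleus for the vowel-change subtypes.
#' @param inv A \code{phoneme_inventory}.
#' @return A \code{verb_past}. The suppletive subtype consumes random
#'   numbers from the current RNG stream.
#' @export
irregular_past <- function(stem, subtype, new_vowel = NULL,
                           inv = default_inventory()) {
  subtype <- match.arg(subtype, c("no_change", "vowel_change",
                                  "vowel_change_suffix", "suppletive"))
  if (subtype == "no_change") return(verb_past(stem))
  if (subtype == "suppletive") {
    form <- random_stem(inv, bisyllabic = stats::runif(1) < 0.3)
    return(verb_past(form))
  }
  if (is.null(new_vowel)) stop("vowel-change subtypes require new_vowel")
  syls <- unclass(stem)
  last_real <- max(which(!vapply(syls, is_empty_syllable, TRUE)))
  s <- syls[[last_real]]
  syls[[last_real]] <- syllable(s$stress, s$onset, new_vowel, s$coda)
  form <- verb_form(syls)
  if (subtype == "vowel_change") return(verb_past(form))
  fin <- final_segment(form)
  verb_past(form, suffix_c = if (inv$voiced[[fin]]) "d" else "t")
}

# Random legal stem; consumes the current RNG stream.
random_stem <- function(inv, bisyllabic = FALSE,
                        onset_probs = c(0.25, 0.5, 0.2, 0.05),
                        rime_key = NULL) {
  cons <- inventory_symbols(inv, "consonant")
  vows <- inventory_symbols(inv, "vowel")
  final_onset_n <- sample(0:3, 1, prob = onset_probs)
  if (is.null(rime_key)) {
    nucleus <- sample(vows, 1)
    coda <- sample(cons, sample(0:2, 1, prob = c(0.25, 0.5, 0.25)))
  } else {
    parts <- strsplit(rime_key, "+", fixed = TRUE)[[1]]
    nucleus <- parts[1]
    coda <- if (length(parts) > 1 && nzchar(parts[2]))
      strsplit(parts[2], " ")[[1]] else character()
  }
  # keep every stem at least two segments long
  if (!bisyllabic && final_onset_n == 0L && !length(coda)) final_onset_n <- 1L
  fin <- syllable(1L, sample(cons, final_onset_n), nucleus, coda)
  if (!bisyllabic) return(verb_form(fin))
  first <- syllable(0L, sample(cons, sample(0:2, 1, prob = c(0.2, 0.6, 0.2))),
                    sample(vows, 1), character())
  verb_form(first, fin)
}

# Deterministic rank set for irregulars: stride-spread over frequency ranks,
# binary-searched so the realized token share hits the target.
choose_irregular_ranks <- function(w, n_irr, target, tol = 0.02) {
  n <- length(w)
  if (n_irr == 0L) return(integer())
  share <- function(ranks) sum(w[ranks]) / sum(w)
  ranks_for <- function(g) {
    r <- unique(pmin(n, round(1 + (seq_len(n_irr) - 1) * g)))
    i <- 1L
    while (length(r) < n_irr) {       # fill collisions with unused ranks
      if (!(i %in% r)) r <- c(r, i)
      i <- i + 1L
    }
    sort(r)
  }
  g_lo <- 1; g_hi <- (n - 1) / max(1, n_irr - 1)
  s_max <- share(ranks_for(g_lo)); s_min <- share(ranks_for(g_hi))
  if (target > s_max + 0.05)
    stop("config error: irregular token fraction ", target,
         " unreachable (max attainable ", round(s_max, 3), ")")
  if (target < s_min - 0.05)
    stop("config error: irregular token fraction ", target,
         " unreachable (min attainable ", round(s_min, 3), ")")
  for (it in 1:60) {
    g <- (g_lo + g_hi) / 2
    s <- share(ranks_for(g))
    if (s > target) g_lo <- g else g_hi <- g
  }
  ranks_for((g_lo + g_hi) / 2)
}

#' Generate a synthetic verb corpus
#'
#' Builds an artificial verb lexicon whose statistics emulate a realistic
#' English past-tense training corpus: Zipf-Mandelbrot token frequencies,
#' irregulars concentrated at high-frequency ranks so that a small type
#' fraction carries a large token fraction, stems drawn from shared rime
#' families (creating friends and enemies), homophone exclusion, and
#' per-verb predictor statistics (frequency, friends, enemies, phonological
#' complexity, final-alveolar flag).
#'
#' @param cfg A \code{corpus_config}.
#' @param inv A \code{phoneme_inventory}.
#' @return An object of class \code{verb_corpus}: a list with
#'   \item{entries}{data frame with one row per verb type: \code{id},
#'     \code{stem}, \code{past} (string notations), \code{class},
#'     \code{subtype}, \code{past_freq} (normalised token weight),
#'     \code{friends}, \code{enemies}, \code{complexity},
#'     \code{final_alveolar}}
#'   \item{stem_forms, past_forms}{parallel lists of \code{verb_form} /
#'     \code{verb_past} objects}
#'   \item{config}{the generating configuration}
#' @export
generate_corpus <- function(cfg = corpus_config(), inv = default_inventory()) {
  set.seed(cfg$seed)
  n <- cfg$n_types
  n_irr <- as.integer(round(cfg$irregular_type_frac * n))

  ranks <- seq_len(n)
  w <- 1 / (ranks + cfg$zipf_offset)^cfg$zipf_exponent
  irr_ranks <- choose_irregular_ranks(w, n_irr, cfg$irregular_token_frac)
  is_irr <- ranks %in% irr_ranks

  # rime families with unique keys
  vows <- inventory_symbols(inv, "vowel")
  cons <- inventory_symbols(inv, "consonant")
  k <- max(2L, ceiling(n / cfg$mean_family_size))
  fam_keys <- character(0)
  while (length(fam_keys) < k) {
    nuc <- sample(vows, 1)
    coda <- sample(cons, sample(0:2, 1, prob = c(0.2, 0.55, 0.25)))
    key <- paste0(nuc, "+", paste(coda, collapse = " "))
    if (!key %in% fam_keys) fam_keys <- c(fam_keys, key)
  }
  # geometric family sizes, shuffled over ranks
  fam_w <- stats::rgeom(k, prob = 1 / cfg$mean_family_size) + 1
  family <- sample(rep.int(seq_len(k), ceiling(n * fam_w / sum(fam_w)) + 1L))[seq_len(n)]

  # per-family irregular subtype and vowel-change target
  subtypes <- names(cfg$subtype_mix)
  fam_subtype <- sample(subtypes, k, replace = TRUE, prob = cfg$subtype_mix)
  fam_new_vowel <- vapply(seq_len(k), function(f) {
    nuc <- strsplit(fam_keys[f], "+", fixed = TRUE)[[1]][1]
    sample(setdiff(vows, nuc), 1)
  }, "")

  stems <- vector("list", n)
  pasts <- vector("list", n)
  subtype <- rep("none", n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in ranks) {
    f <- family[i]
    irr <- is_irr[i]
    p_bi <- if (irr) cfg$p_bisyllabic_irregular else cfg$p_bisyllabic_regular
    onset_probs <- if (irr) c(0.3, 0.5, 0.15, 0.05) else c(0.15, 0.45, 0.28, 0.12)
    ok <- FALSE
    for (try in 1:500) {
      stem <- random_stem(inv, bisyllabic = stats::runif(1) < p_bi,
                          onset_probs = onset_probs, rime_key = fam_keys[f])
      key <- deparse_form(stem)
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; ok <- TRUE; break }
    }
    if (!ok) stop("config error: could not generate ", n,
                  " distinct stems; reduce n_types or enlarge the inventory")
    stems[[i]] <- stem
    if (irr) {
      subtype[i] <- fam_subtype[f]
      pasts[[i]] <- irregular_past(stem, fam_subtype[f],
                                   new_vowel = fam_new_vowel[f], inv = inv)
    } else {
      pasts[[i]] <- regular_past(stem, inv)
    }
  }

  entries <- data.frame(
    id = paste0("v", formatC(ranks, width = nchar(n), flag = "0")),
    stem = vapply(stems, deparse_form, ""),
    past = vapply(pasts, deparse_past, ""),
    class = ifelse(is_irr, "irregular", "regular"),
    subtype = subtype,
    past_freq = w / sum(w),
    friends = NA_integer_,
    enemies = NA_integer_,
    complexity = vapply(stems, stem_complexity, 0L),
    final_alveolar = vapply(stems, function(s)
      isTRUE(inv$alveolar_stop[[final_segment(s)]]), TRUE),
    stringsAsFactors = FALSE
  )
  corp <- structure(list(entries = entries, stem_forms = stems,
                         past_forms = pasts, config = cfg, inventory = inv),
                    class = "verb_corpus")
  compute_neighbors(corp)
}

stem_complexity <- function(form) {
  sum(vapply(form, function(s) {
    if (is_empty_syllable(s)) 0L
    else length(s$onset) + 1L + length(s$coda)
  }, 0L))
}

deparse_past <- function(p) {
  base <- deparse_form(p$form)
  if (is.null(p$suffix_c)) base
  else paste(base, "++", paste(c(p$suffix_v, p$suffix_c), collapse = " "))
}

parse_past <- function(x, inv = default_inventory()) {
  parts <- strsplit(x, "++", fixed = TRUE)[[1]]
  form <- parse_form(trimws(parts[1]), inv)
  if (length(parts) == 1L) return(verb_past(form))
  toks <- strsplit(trimws(parts[2]), "\\s+")[[1]]
  if (length(toks) == 2L) verb_past(form, suffix_v = toks[1], suffix_c = toks[2])
  else verb_past(form, suffix_c = toks[1])
}

#' Fill in friend and enemy counts
#'
#' A friend of a verb is another verb with the same stem rime and the same
#' past-tense rime (e.g. the sing-sang / ring-rang pattern); an enemy shares
#' the stem rime but has a different past-tense rime (sing-sang vs.
#' bring-brought).
#'
#' @param corpus A \code{verb_corpus}.
#' @return The corpus with \code{friends} and \code{enemies} columns filled.
#' @export
compute_neighbors <- function(corpus) {
  stem_r <- vapply(corpus$stem_forms, rime, "")
  past_r <- vapply(corpus$past_forms, past_rime, "")
  both <- paste(stem_r, past_r, sep = "  ")
  n_stem <- table(stem_r)
  n_both <- table(both)
  corpus$entries$friends <- as.integer(n_both[both] - 1L)
  corpus$entries$enemies <- as.integer(n_stem[stem_r] - n_both[both])
  corpus
}

#' Sample a frequency-weighted token stream
#'
#' Draws verb tokens i.i.d. from the corpus according to the normalised
#' past-tense frequencies, reproducibly given the seed.
#'
#' @param corpus A \code{verb_corpus}.
#' @param n_tokens Number of tokens to draw.
#' @param seed Integer seed.
#' @return Integer vector of verb row indices into \code{corpus$entries}.
#' @export
sample_stream <- function(corpus, n_tokens, seed = 1L) {
  set.seed(seed)
  w <- corpus$entries$past_freq
  sample.int(nrow(corpus$entries), n_tokens, replace = TRUE, prob = w / sum(w))
}

#' Summary statistics of a corpus
#'
#' @param corpus A \code{verb_corpus}.
#' @return A list with irregular type and token percentages (computed from
#'   entry counts and normalised token weights) and complexity/frequency
#'   summaries per class.
#' @export
corpus_summary <- function(corpus) {
  e <- corpus$entries
  if (!nrow(e)) stop("empty corpus")
  irr <- e$class == "irregular"
  w <- e$past_freq / sum(e$past_freq)
  list(
    n_types = nrow(e),
    n_irregular = sum(irr),
    type_frac_irregular = 100 * mean(irr),
    token_frac_irregular = 100 * sum(w[irr]),
    complexity_by_class = tapply(e$complexity, e$class, mean),
    mean_freq_by_class = tapply(w, e$class, mean)
  )
}

#' Encode a corpus into input/target matrices
#'
#' @param corpus A \code{verb_corpus}.
#' @return A list with \code{X} (84 x n stem encodings, the input
#'   activations) and \code{Y} (97 x n past-tense target encodings).
#' @export
encode_corpus <- function(corpus) {
  inv <- corpus$inventory
  X <- vapply(corpus$stem_forms, encode_stem, numeric(STEM_LEN), inv = inv)
  Y <- vapply(corpus$past_forms, encode_past, numeric(PAST_LEN), inv = inv)
  list(X = X, Y = Y)
}

#' Write / read a corpus as CSV
#'
#' The CSV holds the entry table with the generator seed recorded in a
#' header comment; forms are stored in the package's string notation.
#'
#' @param corpus A \code{verb_corpus}.
#' @param path File path.
#' @return \code{read_corpus} returns a \code{verb_corpus} (with forms
#'   re-parsed); \code{write_corpus} returns \code{path} invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pastnet corpus; seed: ", corpus$config$seed), con)
  utils::write.csv(corpus$entries, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @param inv A \code{phoneme_inventory}.
#' @export
read_corpus <- function(path, inv = default_inventory()) {
  entries <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stems <- lapply(entries$stem, parse_form, inv = inv)
  pasts <- lapply(entries$past, parse_past, inv = inv)
  structure(list(entries = entries, stem_forms = stems, past_forms = pasts,
                 config = NULL, inventory = inv),
            class = "verb_corpus")
}

#' @export
print.verb_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat("verb_corpus:", s$n_types, "types,", s$n_irregular, "irregular (",
      sprintf("%.2f%% of types, %.2f%% of tokens", s$type_frac_irregular,
              s$token_frac_irregular), ")\n")
  invisible(x)
}
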