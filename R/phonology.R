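#' @useDynLib pastnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Slot layout of one encoded syllable (42 positions):
#   1       stress (0/1)
#   2-22    onset: 3 consonant slots x 7 features, right-justified at the vowel
#   23-28   nucleus: 1 vowel slot x 6 features
#   29-42   coda: 2 consonant slots x 7 features, left-justified after the vowel
SYL_LEN <- 42L
STEM_LEN <- 84L
SUFFIX_LEN <- 13L
PAST_LEN <- 97L

#' Construct a syllable
#'
#' A syllable follows the xCCCVCC template: a stress marker, up to three
#' onset consonants, one vowel nucleus, and up to two coda consonants. The
#' all-empty padding syllable (used for the second syllable of monosyllabic
#' verbs) has stress 0 and no segments.
#'
#' @param stress 0 or 1.
#' @param onset Character vector of 0-3 consonant symbols.
#' @param nucleus A single vowel symbol, or \code{NULL} for the padding
#'   syllable.
#' @param coda Character vector of 0-2 consonant symbols.
#' @return A list of class \code{syllable}.
#' @export
syllable <- function(stress = 0L, onset = character(), nucleus = NULL,
                     coda = character()) {
  if (length(onset) > 3L) stop("template overflow: more than 3 onset consonants")
  if (length(coda) > 2L) stop("template overflow: more than 2 coda consonants")
  if (!stress %in% c(0L, 1L)) stop("stress must be 0 or 1")
  if (is.null(nucleus) && (length(onset) || length(coda) || stress != 0L))
    stop("a syllable without a nucleus must be the all-empty padding syllable")
  structure(list(stress = as.integer(stress), onset = as.character(onset),
                 nucleus = nucleus, coda = as.character(coda)),
            class = "syllable")
}

empty_syllable <- function() syllable()

is_empty_syllable <- function(s) is.null(s$nucleus)

#' Construct a verb form
#'
#' A verb form is a sequence of one or two syllables.
#'
#' @param ... \code{syllable} objects (or a single list of them).
#' @return A list of class \code{verb_form}.
#' @export
verb_form <- function(...) {
  syls <- list(...)
  if (length(syls) == 1L && !inherits(syls[[1]], "syllable")) syls <- syls[[1]]
  if (length(syls) < 1L || length(syls) > 2L)
    stop("unsupported form: verbs must have 1 or 2 syllables")
  structure(syls, class = "verb_form")
}

n_syllables <- function(v) sum(!vapply(v, is_empty_syllable, TRUE))

#' Parse a verb form from its string notation
#'
#' Syllables are separated by \code{"|"}; within a syllable, tokens are
#' space-separated with the stress mark (0 or 1) first, e.g. \code{"1 s I N"}
#' for a stressed monosyllable or \code{"0 r i | 1 p l e"} for a bisyllable.
#'
#' @param x A single string.
#' @param inv A \code{phoneme_inventory} used to classify symbols.
#' @return A \code{verb_form}.
#' @export
parse_form <- function(x, inv = default_inventory()) {
  syl_strs <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  syls <- lapply(syl_strs, function(s) {
    toks <- strsplit(s, "\\s+")[[1]]
    stress <- suppressWarnings(as.integer(toks[1]))
    if (is.na(stress)) stop("syllable must start with a stress mark: ", s)
    segs <- toks[-1]
    unknown <- setdiff(segs, names(inv$class))
    if (length(unknown))
      stop("unknown phoneme symbol(s): ", paste(unknown, collapse = ", "))
    vpos <- which(inv$class[segs] == "vowel")
    if (length(vpos) != 1L) stop("syllable must contain exactly one vowel: ", s)
    syllable(stress, onset = segs[seq_len(vpos - 1L)], nucleus = segs[vpos],
             coda = if (vpos < length(segs)) segs[(vpos + 1L):length(segs)]
                    else character())
  })
  verb_form(syls)
}

#' Deparse a verb form to its string notation
#' @param v A \code{verb_form}.
#' @return A single string.
#' @export
deparse_form <- function(v) {
  paste(vapply(v[!vapply(v, is_empty_syllable, TRUE)], function(s) {
    paste(c(s$stress, s$onset, s$nucleus, s$coda), collapse = " ")
  }, ""), collapse = " | ")
}

#' Encode one syllable into the 42-position template vector
#'
#' Lays the syllable into the xCCCVCC feature template: 1 stress position,
#' 3x7 onset features (consonants right-justified against the vowel), 6
#' nucleus features, and 2x7 coda features (left-justified after the vowel).
#' Empty phoneme slots are all-zero.
#'
#' @param s A \code{syllable}.
#' @param inv A \code{phoneme_inventory}.
#' @return Numeric vector of length 42 with entries in \{-1, 0, +1\}.
#' @export
encode_syllable <- function(s, inv = default_inventory()) {
  out <- numeric(SYL_LEN)
  if (is_empty_syllable(s)) return(out)
  lookup <- function(sym, cls) {
    if (!sym %in% names(inv$class)) stop("unknown phoneme symbol: ", sym)
    if (inv$class[[sym]] != cls)
      stop("symbol '", sym, "' is not a ", cls)
    inv$features[[sym]]
  }
  out[1] <- s$stress
  k <- length(s$onset)
  if (k > 3L) stop("template overflow: more than 3 onset consonants")
  for (j in seq_len(k)) {            # right-justify: last onset C sits in slot 3
    slot <- 3L - k + j
    out[2L + (slot - 1L) * 7L + 1:7 - 1L] <- lookup(s$onset[j], "consonant")
  }
  out[23:28] <- lookup(s$nucleus, "vowel")
  k <- length(s$coda)
  if (k > 2L) stop("template overflow: more than 2 coda consonants")
  for (j in seq_len(k)) {            # left-justify: first coda C sits in slot 1
    out[29L + (j - 1L) * 7L + 1:7 - 1L] <- lookup(s$coda[j], "consonant")
  }
  out
}

#' Encode a verb stem into the 84-position input vector
#'
#' Concatenates the template encodings of the two syllable frames.
#' Monosyllabic stems occupy the first frame; the second is the all-zero
#' padding syllable.
#'
#' @param v A \code{verb_form} (1 or 2 syllables).
#' @param inv A \code{phoneme_inventory}.
#' @return Numeric vector of length 84.
#' @export
encode_stem <- function(v, inv = default_inventory()) {
  if (!inherits(v, "verb_form")) stop("expected a verb_form")
  if (length(v) > 2L) stop("unsupported form: more than 2 syllables")
  s1 <- encode_syllable(v[[1]], inv)
  s2 <- if (length(v) >= 2L) encode_syllable(v[[2]], inv) else numeric(SYL_LEN)
  c(s1, s2)
}

#' Construct a past-tense form
#'
#' A past form is template material in the same 84-position stem layout plus
#' an optional VC suffix (6 vowel + 7 consonant features). The dental
#' allomorphs /t/ and /d/ fill only the suffix consonant slot; the syllabic
#' allomorph (after alveolar stops) fills both.
#'
#' @param form A \code{verb_form} holding the stem-template material of the
#'   past form.
#' @param suffix_v A vowel symbol or \code{NULL}.
#' @param suffix_c A consonant symbol or \code{NULL}.
#' @return A list of class \code{verb_past}.
#' @export
verb_past <- function(form, suffix_v = NULL, suffix_c = NULL) {
  if (!is.null(suffix_v) && is.null(suffix_c))
    stop("a suffix vowel requires a suffix consonant")
  structure(list(form = form, suffix_v = suffix_v, suffix_c = suffix_c),
            class = "verb_past")
}

#' Encode a past-tense form into the 97-position target vector
#'
#' The first 84 positions hold the stem-template material of the past form;
#' positions 85-97 hold the VC suffix (zero when the past is formed without
#' suffixation).
#'
#' @param p A \code{verb_past}.
#' @param inv A \code{phoneme_inventory}.
#' @return Numeric vector of length 97.
#' @export
encode_past <- function(p, inv = default_inventory()) {
  if (!inherits(p, "verb_past")) stop("expected a verb_past")
  suf <- numeric(SUFFIX_LEN)
  if (!is.null(p$suffix_v)) {
    if (inv$class[[p$suffix_v]] != "vowel") stop("suffix_v must be a vowel")
    suf[1:6] <- inv$features[[p$suffix_v]]
  }
  if (!is.null(p$suffix_c)) {
    if (inv$class[[p$suffix_c]] != "consonant")
      stop("suffix_c must be a consonant")
    suf[7:13] <- inv$features[[p$suffix_c]]
  }
  c(encode_stem(p$form, inv), suf)
}

#' Decode an 84-position stem vector back to a verb form
#'
#' Inverse of \code{\link{encode_stem}} for vectors produced by it; used to
#' verify that encoding is injective on a corpus.
#'
#' @param x Numeric vector of length 84.
#' @param inv A \code{phoneme_inventory}.
#' @return A \code{verb_form}.
#' @export
decode_stem <- function(x, inv = default_inventory()) {
  stopifnot(length(x) == STEM_LEN)
  con_key <- vapply(inv$features[inv$class == "consonant"], paste, "",
                    collapse = ",")
  vow_key <- vapply(inv$features[inv$class == "vowel"], paste, "",
                    collapse = ",")
  match_sym <- function(v, keys) {
    hit <- names(keys)[keys == paste(v, collapse = ",")]
    if (!length(hit)) stop("no phoneme matches features ",
                           paste(v, collapse = ","))
    hit[1]
  }
  decode_syl <- function(sv) {
    if (all(sv == 0)) return(empty_syllable())
    onset <- character()
    for (slot in 1:3) {
      seg <- sv[2L + (slot - 1L) * 7L + 0:6]
      if (any(seg != 0)) onset <- c(onset, match_sym(seg, con_key))
    }
    nucleus <- match_sym(sv[23:28], vow_key)
    coda <- character()
    for (slot in 1:2) {
      seg <- sv[29L + (slot - 1L) * 7L + 0:6]
      if (any(seg != 0)) coda <- c(coda, match_sym(seg, con_key))
    }
    syllable(as.integer(sv[1]), onset, nucleus, coda)
  }
  s1 <- decode_syl(x[1:42])
  s2 <- decode_syl(x[43:84])
  if (is_empty_syllable(s2)) verb_form(s1) else verb_form(s1, s2)
}

#' Count active input units
#'
#' Number of nonzero positions of an encoded stem; used to normalise direct
#' pathway activation for phonological complexity (more phonemes means more
#' active input units under the distributed encoding).
#'
#' @param x Numeric vector (an \code{EncodedStem}).
#' @return Integer count.
#' @export
active_input_count <- function(x) sum(x != 0)

#' Rime of a verb form
#'
#' The rime is the vowel nucleus plus coda of the final (non-padding)
#' syllable, returned as a comparable key string. Friend/enemy neighbourhood
#' structure is defined over stem and past-tense rimes.
#'
#' @param v A \code{verb_form} or \code{verb_past}.
#' @return A single string key, e.g. \code{"I+N"}.
#' @export
rime <- function(v) {
  if (inherits(v, "verb_past")) return(past_rime(v))
  syls <- v[!vapply(v, is_empty_syllable, TRUE)]
  if (!length(syls)) stop("malformed form: no syllable with a nucleus")
  fin <- syls[[length(syls)]]
  if (is.null(fin$nucleus)) stop("malformed form: final syllable lacks a nucleus")
  paste0(fin$nucleus, "+", paste(fin$coda, collapse = " "))
}

# Past-tense rime: the syllabic allomorph adds a syllable whose rime is the
# suffix itself; the dental allomorphs extend the final coda.
past_rime <- function(p) {
  if (!is.null(p$suffix_v)) return(paste0(p$suffix_v, "+", p$suffix_c))
  syls <- p$form[!vapply(p$form, is_empty_syllable, TRUE)]
  fin <- syls[[length(syls)]]
  coda <- c(fin$coda, p$suffix_c)
  paste0(fin$nucleus, "+", paste(coda, collapse = " "))
}
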