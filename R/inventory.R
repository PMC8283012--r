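#' Load a phoneme feature inventory
#'
#' Reads a phoneme inventory from a CSV file mapping phoneme symbols to
#' binary articulatory feature vectors: 7 features per consonant and 6 per
#' vowel, each feature coded \code{+1} (present) or \code{-1} (absent).
#' The packaged default inventory covers 24 consonants and 13 vowels with
#' ASCII stand-ins for non-ASCII IPA symbols (see the file header comments).
#'
#' @param path Path to the inventory CSV. Defaults to the inventory shipped
#'   with the package.
#' @return An object of class \code{phoneme_inventory}: a list with elements
#'   \item{features}{named list of numeric feature vectors (length 7 for
#'     consonants, 6 for vowels), entries in \{-1, +1\}}
#'   \item{class}{named character vector, \code{"consonant"} or \code{"vowel"}}
#'   \item{voiced}{named logical vector}
#'   \item{alveolar_stop}{named logical vector, \code{TRUE} for the alveolar
#'     stops /t/ and /d/ that condition the syllabic past-tense allomorph}
#' @export
load_inventory <- function(path = system.file("extdata", "phoneme_features.csv",
                                              package = "pastnet")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "class", "voiced", "alveolar_stop") %in% names(tab)))
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, paste0("f", 1:7)])
    if (tab$class[i] == "vowel") v <- v[1:6]
    v
  })
  names(feats) <- tab$symbol
  inv <- structure(list(
    features      = feats,
    class         = stats::setNames(tab$class, tab$symbol),
    voiced        = stats::setNames(tab$voiced == 1, tab$symbol),
    alveolar_stop = stats::setNames(tab$alveolar_stop == 1, tab$symbol)
  ), class = "phoneme_inventory")
  validate_inventory(inv)
  inv
}

#' @keywords internal
validate_inventory <- function(inv) {
  for (s in names(inv$features)) {
    v <- inv$features[[s]]
    len <- if (inv$class[[s]] == "consonant") 7L else 6L
    if (length(v) != len)
      stop("feature vector for '", s, "' has length ", length(v),
           ", expected ", len)
    if (!all(v %in% c(-1, 1)))
      stop("feature vector for '", s, "' has entries outside {-1,+1}")
  }
  for (cl in c("consonant", "vowel")) {
    syms <- names(inv$class)[inv$class == cl]
    key <- vapply(inv$features[syms], paste, "", collapse = ",")
    if (anyDuplicated(key))
      stop("duplicate feature vectors within class ", cl, ": ",
           paste(syms[duplicated(key)], collapse = ", "))
  }
  invisible(inv)
}

#' Symbols of an inventory by class
#' @param inv A \code{phoneme_inventory}.
#' @param class \code{"consonant"} or \code{"vowel"}.
#' @return Character vector of symbols.
#' @export
inventory_symbols <- function(inv, class = c("consonant", "vowel")) {
  class <- match.arg(class)
  names(inv$class)[inv$class == class]
}

#' The packaged default inventory (cached)
#' @return A \code{phoneme_inventory}.
#' @export
default_inventory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_inventory()
    cache
  }
})
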