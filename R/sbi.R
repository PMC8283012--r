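#' Direct-pathway activation of a verb
#'
#' The synthetic imaging signal of the direct pathway: the summed absolute
#' activation flowing through the input-output connections,
#' \eqn{\sum_o \sum_i |w_{oi} a_i|}, the model analogue of the local field
#' potential (summed post-synaptic input) into the output region.
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem (the input activations \eqn{a_i}).
#' @return Nonnegative scalar.
#' @export
direct_activation <- function(state, x) {
  sum(abs(sweep(state$W_direct, 2, x, "*")))
}

#' Indirect-pathway activation of a verb
#'
#' The summed absolute activation flowing through the hidden-output
#' connections, \eqn{\sum_o |w_{oh} a_h|}, for the single winning hidden
#' unit \eqn{h} (zero when the hidden layer is empty).
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem.
#' @return Nonnegative scalar.
#' @export
indirect_activation <- function(state, x) {
  w <- winner(state, x)
  if (is.na(w$index)) return(0)
  sum(abs(state$W_hidden[, w$index] * w$activation))
}

#' Synthetic brain imaging profile of a corpus
#'
#' Measures, for every verb type, the activation flowing through each
#' pathway, the total, the activation ratio, and the complexity-normalised
#' direct activation.
#'
#' @param state An \code{ncm_state} (typically trained).
#' @param corpus A \code{verb_corpus}.
#' @return A data frame with one row per verb: \code{id}, \code{class},
#'   \code{subtype}, \code{direct}, \code{indirect}, \code{total},
#'   \code{ratio}, \code{normalized_direct}, joined with the per-verb
#'   corpus statistics (\code{past_freq}, \code{friends}, \code{enemies},
#'   \code{complexity}, \code{final_alveolar}).
#' @export
profile_corpus <- function(state, corpus) {
  enc <- encode_corpus(corpus)
  n <- ncol(enc$X)
  colabs <- colSums(abs(state$W_direct))
  direct <- as.numeric(abs(t(enc$X)) %*% colabs)
  indirect <- vapply(seq_len(n), function(i)
    indirect_activation(state, enc$X[, i]), 0)
  active <- colSums(enc$X != 0)
  e <- corpus$entries
  prof <- data.frame(id = e$id, class = e$class, subtype = e$subtype,
                     direct = direct, indirect = indirect,
                     total = direct + indirect,
                     normalized_direct = direct / active,
                     past_freq = e$past_freq, friends = e$friends,
                     enemies = e$enemies, complexity = e$complexity,
                     final_alveolar = e$final_alveolar,
                     stringsAsFactors = FALSE)
  activation_ratio(prof)
}

#' Activation ratio
#'
#' Scales each pathway's activations to a maximum of 1 over the profiled
#' verb set, then computes per verb
#' \eqn{\tilde d / (\tilde d + \tilde i)}. A ratio above 0.5 means the verb
#' activates the direct pathway relatively more than the indirect pathway.
#'
#' @param profiles Data frame with \code{direct} and \code{indirect}
#'   columns.
#' @param scale_direct,scale_indirect Optional externally supplied maxima,
#'   e.g. full-corpus scale factors when profiling a subset so that ratios
#'   stay comparable.
#' @return The data frame with a \code{ratio} column added (\code{NA} for a
#'   verb with zero activation in both pathways).
#' @export
activation_ratio <- function(profiles, scale_direct = NULL,
                             scale_indirect = NULL) {
  md <- if (is.null(scale_direct)) max(profiles$direct) else scale_direct
  mi <- if (is.null(scale_indirect)) max(profiles$indirect) else scale_indirect
  if (md <= 0 && mi <= 0)
    stop("all activations are zero; ratio undefined for every verb")
  d <- if (md > 0) profiles$direct / md else profiles$direct
  i <- if (mi > 0) profiles$indirect / mi else profiles$indirect
  tot <- d + i
  profiles$ratio <- ifelse(tot > 0, d / tot, NA_real_)
  profiles
}

#' Complexity-normalised direct activation
#'
#' Direct-pathway activation divided by the number of active input units.
#' Under the distributed phonological encoding more phonemes mean more
#' active input units, so this removes the phonological-complexity
#' contribution from the direct signal.
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem.
#' @return Scalar.
#' @export
normalized_direct <- function(state, x) {
  n_act <- active_input_count(x)
  if (n_act == 0) stop("zero active input units; normalisation undefined")
  direct_activation(state, x) / n_act
}

#' Developmental activation profile
#'
#' Extracts the time series of class-mean pathway activations (and accuracy
#' and unit counts) from a training record, one row per checkpoint.
#'
#' @param fit An \code{ncm_fit} (or its \code{record} data frame).
#' @return A data frame with columns \code{token}, \code{pathway},
#'   \code{class}, \code{mean_activation} in long format, suitable for
#'   plotting developmental trajectories.
#' @export
developmental_profile <- function(fit) {
  rec <- if (inherits(fit, "ncm_fit")) fit$record else fit
  if (!nrow(rec)) return(data.frame(token = numeric(0), pathway = character(0),
                                    class = character(0),
                                    mean_activation = numeric(0)))
  long <- rbind(
    data.frame(token = rec$token, pathway = "direct", class = "regular",
               mean_activation = rec$direct_regular),
    data.frame(token = rec$token, pathway = "direct", class = "irregular",
               mean_activation = rec$direct_irregular),
    data.frame(token = rec$token, pathway = "indirect", class = "regular",
               mean_activation = rec$indirect_regular),
    data.frame(token = rec$token, pathway = "indirect", class = "irregular",
               mean_activation = rec$indirect_irregular)
  )
  long[order(long$token), ]
}
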