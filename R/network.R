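#' Training configuration for the constructivist network
#'
#' Hyperparameters of the two-pathway network: a direct input-to-output
#' weight layer trained with the perceptron rule, and a growing/pruning
#' hidden layer of Gaussian receptive-field units with winner-take-all
#' lateral inhibition.
#'
#' @param lambda Perceptron learning rate.
#' @param eta_center Receptive-field centre adaptation rate (the winner's
#'   centre moves a small step toward each input it wins).
#' @param eta_width Receptive-field width adaptation rate (widths grow when
#'   a unit wins inputs far from its centre and shrink otherwise).
#' @param sigma_init Initial receptive-field width for inserted units.
#' @param sigma_min,sigma_max Clipping bounds for widths.
#' @param init_w Half-range of the uniform initialisation of output weights.
#' @param theta Dead-zone half-width of the ternary output decision rule:
#'   net input below \code{-theta} maps to -1, above \code{+theta} to +1,
#'   otherwise 0.
#' @param window_short Growth-trigger window: insertion occurs when the mean
#'   pattern error over the last \code{window_short} tokens is no lower than
#'   over the preceding \code{window_long} tokens.
#' @param window_long See \code{window_short}.
#' @param insert_k Number of units inserted per growth event.
#' @param prune_T Units not activated for \code{prune_T} presentations are
#'   pruned.
#' @param prune_every Pruning is checked every this many tokens.
#' @param checkpoint_interval Tokens between developmental checkpoints
#'   (accuracy and class-mean pathway activations).
#' @param seed Integer seed governing weight initialisation, the token
#'   stream, and growth randomness.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(lambda = 0.01, eta_center = 0.01, eta_width = 0.005,
                         sigma_init = 2.0, sigma_min = 0.5, sigma_max = 10,
                         init_w = 0.1, theta = 0.5,
                         window_short = 10000L, window_long = 30000L,
                         insert_k = 3L, prune_T = 30000L, prune_every = 1000L,
                         checkpoint_interval = 100000L, seed = 1L) {
  stopifnot(window_short > 0, window_long > 0, insert_k >= 1,
            window_long %% window_short == 0)
  structure(list(lambda = lambda, eta_center = eta_center,
                 eta_width = eta_width, sigma_init = sigma_init,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 init_w = init_w, theta = theta,
                 window_short = as.integer(window_short),
                 window_long = as.integer(window_long),
                 insert_k = as.integer(insert_k),
                 prune_T = as.integer(prune_T),
                 prune_every = as.integer(prune_every),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Create a fresh network state
#'
#' The network starts with a minimal architecture: input and output layers
#' fully connected (the direct pathway) and an empty hidden layer. Consumes
#' random numbers for the direct-weight initialisation.
#'
#' @param cfg A \code{train_config}.
#' @param n_in,n_out Input and output dimensionality (84 and 97 for the
#'   past-tense task).
#' @return A list of class \code{ncm_state} with elements \code{W_direct}
#'   (\code{n_out x n_in}), \code{W_hidden} (\code{n_out x m}),
#'   \code{centers} (\code{n_in x m}), \code{widths}, \code{local_error},
#'   \code{last_active}, \code{token}, and growth-window accumulators.
#' @export
new_net <- function(cfg = train_config(), n_in = STEM_LEN, n_out = PAST_LEN) {
  structure(list(
    W_direct = matrix(stats::runif(n_out * n_in, -cfg$init_w, cfg$init_w),
                      n_out, n_in),
    W_hidden = matrix(numeric(0), n_out, 0),
    centers = matrix(numeric(0), n_in, 0),
    widths = numeric(0),
    local_error = numeric(0),
    last_active = integer(0),
    token = 0L,
    win_means = numeric(0),  # completed short-window mean errors since last insertion
    cur_sum = 0, cur_n = 0L
  ), class = "ncm_state")
}

n_units <- function(state) length(state$widths)

#' Gaussian receptive-field response
#'
#' \code{exp(-||x - center||^2 / (2 sigma^2))}: maximal (1) when the input
#' sits at the centre, decaying monotonically with Euclidean distance.
#'
#' @param x Input vector.
#' @param center Receptive-field centre.
#' @param sigma Receptive-field width (> 0).
#' @return Response in (0, 1].
#' @export
hidden_response <- function(x, center, sigma) {
  if (sigma <= 0) stop("state error: receptive-field width must be positive")
  exp(-sum((x - center)^2) / (2 * sigma^2))
}

hidden_responses <- function(state, x) {
  m <- n_units(state)
  if (!m) return(numeric(0))
  d2 <- colSums((state$centers - x)^2)
  exp(-d2 / (2 * state$widths^2))
}

#' Winner-take-all hidden unit
#'
#' Lateral inhibition suppresses all but the most active hidden unit; ties
#' are broken by the lowest index.
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem.
#' @return List with \code{index} (or \code{NA} when the layer is empty) and
#'   \code{activation}.
#' @export
winner <- function(state, x) {
  a <- hidden_responses(state, x)
  if (!length(a)) return(list(index = NA_integer_, activation = 0))
  i <- which.max(a)  # which.max returns the first maximum: lowest index on ties
  list(index = i, activation = a[[i]])
}

decide_output <- function(net, theta) {
  out <- numeric(length(net))
  out[net > theta] <- 1
  out[net < -theta] <- -1
  out
}

#' Forward pass
#'
#' Net input to each output unit is the direct-pathway contribution plus the
#' winning hidden unit's contribution; the output decision quantises the net
#' input to \{-1, 0, +1\} with dead zone \code{theta}.
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem (length 84).
#' @param cfg A \code{train_config} (supplies \code{theta}).
#' @return List with \code{net}, \code{output} (ternary decision),
#'   \code{winner}, \code{activation} (the winner's response),
#'   \code{direct} and \code{indirect} net-input contribution vectors.
#' @export
net_forward <- function(state, x, cfg = train_config()) {
  direct <- drop(state$W_direct %*% x)
  w <- winner(state, x)
  indirect <- if (is.na(w$index)) numeric(length(direct))
              else state$W_hidden[, w$index] * w$activation
  net <- direct + indirect
  list(net = net, output = decide_output(net, cfg$theta),
       winner = w$index, activation = w$activation,
       direct = direct, indirect = indirect)
}

#' One online training step
#'
#' Presents one verb: forward pass, perceptron update of both pathways from
#' the ternary error \code{t - output}, winner receptive-field adaptation
#' (centre moves toward the input; width tracks the winning distance), and
#' bookkeeping of the winner's local error counter, activity stamp, and the
#' growth-trigger error windows.
#'
#' @param state An \code{ncm_state}.
#' @param x Encoded stem (length 84).
#' @param y Encoded past-tense target (length 97).
#' @param cfg A \code{train_config}.
#' @return The updated state.
#' @export
train_step <- function(state, x, y, cfg) {
  state$token <- state$token + 1L
  fw <- net_forward(state, x, cfg)
  e <- y - fw$output
  err <- sum(abs(e))
  nz <- e != 0
  if (any(nz)) {
    state$W_direct[nz, ] <- state$W_direct[nz, , drop = FALSE] +
      cfg$lambda * e[nz] %o% x
  }
  h <- fw$winner
  if (!is.na(h)) {
    if (any(nz))
      state$W_hidden[nz, h] <- state$W_hidden[nz, h] +
        cfg$lambda * e[nz] * fw$activation
    d <- sqrt(sum((x - state$centers[, h])^2))  # pre-update distance
    state$centers[, h] <- state$centers[, h] +
      cfg$eta_center * (x - state$centers[, h])
    state$widths[h] <- min(cfg$sigma_max, max(cfg$sigma_min,
      state$widths[h] + cfg$eta_width * (d - state$widths[h])))
    state$local_error[h] <- state$local_error[h] + err
    state$last_active[h] <- state$token
  }
  state$cur_sum <- state$cur_sum + err
  state$cur_n <- state$cur_n + 1L
  if (state$cur_n == cfg$window_short) {
    state$win_means <- c(state$win_means, state$cur_sum / state$cur_n)
    n_keep <- cfg$window_long %/% cfg$window_short + 1L
    if (length(state$win_means) > n_keep)
      state$win_means <- state$win_means[-1]
    state$cur_sum <- 0; state$cur_n <- 0L
  }
  state
}

growth_due <- function(state, cfg) {
  n_long <- cfg$window_long %/% cfg$window_short
  wm <- state$win_means
  length(wm) == n_long + 1L && wm[length(wm)] > 0 &&
    wm[length(wm)] >= mean(wm[seq_len(n_long)])
}

#' Structural growth check
#'
#' When the mean pattern error over the most recent short window is no lower
#' than over the preceding long window (performance has stopped improving),
#' \code{insert_k} new Gaussian units are inserted at (jittered copies of)
#' the centre of the unit with the highest local error counter -- the unit
#' responsible for the most conflicting input-output mappings. With an empty
#' hidden layer the bootstrap insertion is placed at the current input.
#' Error windows and the donor's local error counter are reset.
#'
#' @param state An \code{ncm_state}.
#' @param cfg A \code{train_config}.
#' @param x The current input (bootstrap insertion site for an empty layer).
#' @return The updated state. Consumes random numbers when insertion fires.
#' @export
maybe_grow <- function(state, cfg, x) {
  if (!growth_due(state, cfg)) return(state)
  insert_units(state, cfg, x)
}

insert_units <- function(state, cfg, x) {
  m <- n_units(state)
  if (m) {
    donor <- which.max(state$local_error)
    site <- state$centers[, donor]
    new_sigma <- state$widths[donor]  # inherit the donor's width: newcomers
    state$local_error[donor] <- 0     # must compete with it on equal terms
  } else {
    site <- x
    new_sigma <- cfg$sigma_init
  }
  n_out <- nrow(state$W_direct)
  for (j in seq_len(cfg$insert_k)) {
    center <- site + stats::rnorm(length(site), 0, 0.01)
    wcol <- stats::runif(n_out, -cfg$init_w, cfg$init_w)
    state$centers <- cbind(state$centers, center)
    state$W_hidden <- cbind(state$W_hidden, wcol)
    state$widths <- c(state$widths, new_sigma)
    state$local_error <- c(state$local_error, 0)
    state$last_active <- c(state$last_active, state$token)
  }
  state$win_means <- numeric(0)
  state$cur_sum <- 0; state$cur_n <- 0L
  state
}

#' Prune inactive hidden units
#'
#' Removes every unit that has not won a competition for \code{prune_T}
#' verb presentations, together with its output-weight column.
#'
#' @param state An \code{ncm_state}.
#' @param cfg A \code{train_config}.
#' @return The updated state.
#' @export
prune_units <- function(state, cfg) {
  if (!n_units(state)) return(state)
  keep <- (state$token - state$last_active) < cfg$prune_T
  if (all(keep)) return(state)
  state$W_hidden <- state$W_hidden[, keep, drop = FALSE]
  state$centers <- state$centers[, keep, drop = FALSE]
  state$widths <- state$widths[keep]
  state$local_error <- state$local_error[keep]
  state$last_active <- state$last_active[keep]
  state
}

#' Type accuracy of a network on a corpus
#'
#' Fraction of verb types whose ternary output decision matches the encoded
#' past-tense target at every one of the 97 positions.
#'
#' @param state An \code{ncm_state}.
#' @param corpus A \code{verb_corpus}, or a list with encoded matrices
#'   \code{X} and \code{Y} as returned by \code{\link{encode_corpus}}.
#' @param cfg A \code{train_config}.
#' @return Fraction between 0 and 1.
#' @export
accuracy <- function(state, corpus, cfg = train_config()) {
  enc <- if (inherits(corpus, "verb_corpus")) encode_corpus(corpus) else corpus
  n <- ncol(enc$X)
  ok <- vapply(seq_len(n), function(i) {
    fw <- net_forward(state, enc$X[, i], cfg)
    all(fw$output == enc$Y[, i])
  }, TRUE)
  mean(ok)
}

#' Lesion a network pathway
#'
#' Simulates focal damage: a direct-pathway lesion zeroes a random fraction
#' of the input-output weights; an indirect-pathway lesion removes a random
#' fraction of whole hidden units. The original state is not modified.
#'
#' @param state An \code{ncm_state}.
#' @param pathway \code{"direct"} or \code{"indirect"}.
#' @param fraction Fraction of weights (direct) or units (indirect) to
#'   destroy, between 0 and 1.
#' @param seed Integer seed.
#' @return A new \code{ncm_state}.
#' @export
lesion <- function(state, pathway = c("direct", "indirect"), fraction,
                   seed = 1L) {
  pathway <- match.arg(pathway)
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  if (pathway == "direct") {
    n <- length(state$W_direct)
    kill <- sample.int(n, round(fraction * n))
    state$W_direct[kill] <- 0
  } else {
    m <- n_units(state)
    kill <- sample.int(m, round(fraction * m))
    if (length(kill)) {
      keep <- setdiff(seq_len(m), kill)
      state$W_hidden <- state$W_hidden[, keep, drop = FALSE]
      state$centers <- state$centers[, keep, drop = FALSE]
      state$widths <- state$widths[keep]
      state$local_error <- state$local_error[keep]
      state$last_active <- state$last_active[keep]
    }
  }
  state
}

#' @export
print.ncm_state <- function(x, ...) {
  cat("ncm_state:", nrow(x$W_direct), "outputs x", ncol(x$W_direct),
      "inputs;", n_units(x), "hidden units;", x$token, "tokens seen\n")
  invisible(x)
}
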