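#' Train a network on a synthetic verb corpus
#'
#' Runs online learning on a frequency-weighted token stream: per token a
#' perceptron update of both pathways, receptive-field adaptation of the
#' winning hidden unit, the structural growth check, and periodic pruning.
#' Developmental checkpoints (type accuracy, unit count, and class-mean
#' pathway activations) are recorded every \code{cfg$checkpoint_interval}
#' tokens. Fully deterministic given \code{cfg$seed}.
#'
#' The default engine is compiled; \code{engine = "R"} runs the pure-R
#' reference implementation (identical trajectory, much slower), useful for
#' stepwise inspection and as a cross-check.
#'
#' @param corpus A \code{verb_corpus}.
#' @param n_tokens Number of training tokens.
#' @param cfg A \code{train_config}.
#' @param engine \code{"cpp"} or \code{"R"}.
#' @param record Whether to record developmental checkpoints.
#' @return A list of class \code{ncm_fit} with elements \code{state}
#'   (\code{ncm_state}), \code{record} (checkpoint data frame),
#'   \code{events} (structural event log), \code{config}, and \code{corpus}
#'   summary metadata.
#' @export
train_network <- function(corpus, n_tokens, cfg = train_config(),
                          engine = c("cpp", "R"), record = TRUE) {
  engine <- match.arg(engine)
  if (!nrow(corpus$entries)) stop("corpus is empty")
  set.seed(cfg$seed)
  state <- new_net(cfg)
  enc <- encode_corpus(corpus)
  is_irr <- corpus$entries$class == "irregular"
  if (n_tokens > 0) {
    w <- corpus$entries$past_freq
    stream <- sample.int(nrow(corpus$entries), n_tokens, replace = TRUE,
                         prob = w / sum(w))
    if (engine == "cpp") {
      res <- ncm_train_cpp(enc$X, enc$Y, stream, is_irr,
                           unclass(state), unclass(cfg), record)
      state <- structure(res$state, class = "ncm_state")
      rec <- as.data.frame(res$record)
      events <- as.data.frame(res$events)
    } else {
      res <- train_engine_r(state, enc, stream, is_irr, cfg, record)
      state <- res$state
      rec <- res$record
      events <- res$events
    }
  } else {
    rec <- empty_record()
    events <- data.frame(token = numeric(0), units_added = numeric(0),
                         units_pruned = numeric(0))
  }
  structure(list(state = state, record = rec, events = events,
                 config = cfg, n_tokens = n_tokens),
            class = "ncm_fit")
}

empty_record <- function() {
  data.frame(token = numeric(0), accuracy = numeric(0), n_units = numeric(0),
             direct_regular = numeric(0), direct_irregular = numeric(0),
             indirect_regular = numeric(0), indirect_irregular = numeric(0))
}

# Pure-R engine: token loop over train_step / maybe_grow / prune, mirroring
# the compiled engine's update and RNG order.
train_engine_r <- function(state, enc, stream, is_irr, cfg, record) {
  rec <- list()
  events <- list()
  for (t in seq_along(stream)) {
    v <- stream[t]
    m_before <- n_units(state)
    state <- train_step(state, enc$X[, v], enc$Y[, v], cfg)
    state <- maybe_grow(state, cfg, enc$X[, v])
    if (n_units(state) > m_before)
      events[[length(events) + 1]] <-
        c(state$token, n_units(state) - m_before, 0)
    if (cfg$prune_every > 0 && state$token %% cfg$prune_every == 0) {
      m0 <- n_units(state)
      state <- prune_units(state, cfg)
      if (n_units(state) < m0)
        events[[length(events) + 1]] <- c(state$token, 0, m0 - n_units(state))
    }
    if (record && cfg$checkpoint_interval > 0 &&
        state$token %% cfg$checkpoint_interval == 0) {
      rec[[length(rec) + 1]] <- checkpoint_row(state, enc, is_irr, cfg)
    }
  }
  record_df <- if (length(rec)) do.call(rbind, rec) else empty_record()
  events_df <- if (length(events)) {
    ev <- do.call(rbind, events)
    data.frame(token = ev[, 1], units_added = ev[, 2], units_pruned = ev[, 3])
  } else {
    data.frame(token = numeric(0), units_added = numeric(0),
               units_pruned = numeric(0))
  }
  list(state = state, record = record_df, events = events_df)
}

checkpoint_row <- function(state, enc, is_irr, cfg) {
  n <- ncol(enc$X)
  direct <- numeric(n); indirect <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    x <- enc$X[, i]
    fw <- net_forward(state, x, cfg)
    direct[i] <- direct_activation(state, x)
    indirect[i] <- indirect_activation(state, x)
    ok[i] <- all(fw$output == enc$Y[, i])
  }
  data.frame(token = as.numeric(state$token), accuracy = mean(ok),
             n_units = n_units(state),
             direct_regular = mean(direct[!is_irr]),
             direct_irregular = mean(direct[is_irr]),
             indirect_regular = mean(indirect[!is_irr]),
             indirect_irregular = mean(indirect[is_irr]))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("ncm_fit:", x$n_tokens, "tokens;", n_units(x$state), "hidden units")
  if (nrow(x$record))
    cat("; final checkpoint accuracy",
        sprintf("%.3f", x$record$accuracy[nrow(x$record)]))
  cat("\n")
  invisible(x)
}
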