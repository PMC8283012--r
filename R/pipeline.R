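#' Configuration for a full experiment
#'
#' Bundles the corpus and training configurations with the number of
#' replicate networks. Per-network and corpus seeds are derived
#' deterministically from the master seed.
#'
#' @param corpus A \code{corpus_config}.
#' @param train A \code{train_config}.
#' @param n_networks Number of replicate networks (the original study
#'   trained five; the scaled default uses three).
#' @param n_tokens Training tokens per network.
#' @param seed Master seed.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(corpus = corpus_config(),
                              train = train_config(),
                              n_networks = 3L, n_tokens = 2e6,
                              seed = 1L) {
  set.seed(seed)
  derived <- sample.int(.Machine$integer.max - 1L, n_networks + 1L)
  structure(list(corpus = corpus, train = train,
                 n_networks = as.integer(n_networks),
                 n_tokens = n_tokens, seed = as.integer(seed),
                 corpus_seed = derived[1], net_seeds = derived[-1]),
            class = "experiment_config")
}

#' Scaled-down experiment configuration
#'
#' The package's standard desk-scale study conditions: 330 verb types with
#' 10\% irregular types carrying ~45\% of tokens, 2 million training tokens
#' per network, three replicate networks. This preserves the statistical
#' structure of the full-scale setting (1,271 types, 20 million tokens,
#' five networks) at a fraction of the compute.
#'
#' @param seed Master seed.
#' @param n_tokens Training tokens per network.
#' @param n_networks Number of replicate networks.
#' @param n_types Number of verb types.
#' @return An \code{experiment_config}.
#' @export
scaled_config <- function(seed = 1L, n_tokens = 2e6, n_networks = 3L,
                          n_types = 330L) {
  experiment_config(
    corpus = corpus_config(n_types = n_types, irregular_type_frac = 0.10,
                           irregular_token_frac = 0.45),
    train = train_config(),
    n_networks = n_networks, n_tokens = n_tokens, seed = seed)
}

#' Run a full experiment
#'
#' End-to-end pipeline: generate the synthetic corpus, train
#' \code{n_networks} replicate networks on frequency-weighted token
#' streams, profile every network with synthetic brain imaging, and run the
#' statistical battery on the pooled profiles (group comparisons of both
#' pathways, correlations of verb statistics with the activation ratio,
#' multi-level regressions with and without regularity, typicality
#' rankings, the complexity-matched subset analysis, and the lesion
#' analysis). Optionally writes all artifacts (corpus CSV, per-network
#' train records and SBI tables, stats report JSON, run manifest) to a
#' directory.
#'
#' @param cfg An \code{experiment_config}.
#' @param outdir Output directory, or \code{NULL} to skip writing.
#' @param quiet Suppress progress messages.
#' @return A list of class \code{ncm_experiment}: \code{corpus},
#'   \code{fits} (list of \code{ncm_fit}), \code{profiles} (list of
#'   per-network profile tables), \code{pooled} (stacked profiles with a
#'   \code{network} column), and \code{stats} (the full report).
#' @export
run_experiment <- function(cfg = scaled_config(), outdir = NULL,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  corpus_cfg <- cfg$corpus
  corpus_cfg$seed <- cfg$corpus_seed
  say("generating corpus (", corpus_cfg$n_types, " types)")
  corpus <- generate_corpus(corpus_cfg)

  fits <- vector("list", cfg$n_networks)
  profiles <- vector("list", cfg$n_networks)
  for (k in seq_len(cfg$n_networks)) {
    tcfg <- cfg$train
    tcfg$seed <- cfg$net_seeds[k]
    say("training network ", k, "/", cfg$n_networks, " (",
        format(cfg$n_tokens, big.mark = ","), " tokens)")
    fits[[k]] <- train_network(corpus, cfg$n_tokens, tcfg)
    profiles[[k]] <- profile_corpus(fits[[k]]$state, corpus)
  }
  pooled <- do.call(rbind, lapply(seq_along(profiles), function(k)
    cbind(profiles[[k]], network = k)))

  say("running statistical battery")
  stats_rep <- experiment_stats(corpus, fits, profiles, pooled, cfg)

  exp <- structure(list(corpus = corpus, fits = fits, profiles = profiles,
                        pooled = pooled, stats = stats_rep, config = cfg),
                   class = "ncm_experiment")
  if (!is.null(outdir)) write_experiment(exp, outdir)
  exp
}

# the statistical battery over one experiment
experiment_stats <- function(corpus, fits, profiles, pooled, cfg) {
  prof1 <- profiles[[1]]
  reg <- prof1$class == "regular"
  per_network_tests <- lapply(profiles, function(p) {
    r <- p$class == "regular"
    list(direct = mann_whitney(p$direct[r], p$direct[!r]),
         indirect = mann_whitney(p$indirect[r], p$indirect[!r]),
         normalized_direct = mann_whitney(p$normalized_direct[r],
                                          p$normalized_direct[!r]))
  })
  reg_base <- fit_pathway_model(pooled, "indirect")
  reg_dual <- fit_pathway_model(pooled, "indirect", include_regularity = TRUE)
  dir_base <- fit_pathway_model(pooled, "direct")
  dir_dual <- fit_pathway_model(pooled, "direct", include_regularity = TRUE)
  final_acc <- vapply(seq_along(fits), function(k)
    accuracy(fits[[k]]$state, corpus, fits[[k]]$config), 0)
  lesions <- lapply(seq_along(fits), function(k)
    lesion_effects(fits[[k]]$state, corpus, fits[[k]]$config,
                   seed = cfg$net_seeds[k]))
  list(
    corpus_summary = corpus_summary(corpus),
    accuracy = final_acc,
    n_units = vapply(fits, function(f) n_units(f$state), 0L),
    group_tests = per_network_tests,
    correlations = corr_table(prof1, "ratio"),
    correlations_regularity = corr_table(
      prof1, as.numeric(prof1$class == "regular")),
    regression_indirect = strip_model(reg_base),
    regression_indirect_dual = strip_model(reg_dual),
    regression_direct = strip_model(dir_base),
    regression_direct_dual = strip_model(dir_dual),
    typicality_regular = typicality(prof1, "regular",
                                    k = min(10L, sum(reg))),
    typicality_irregular = typicality(prof1, "irregular",
                                      k = min(10L, sum(!reg))),
    matched = matched_subset(prof1),
    lesions = lesions,
    development = lapply(fits, developmental_profile)
  )
}

strip_model <- function(pm) { pm$model <- NULL; pm }

#' Lesion analysis of a trained network
#'
#' Compares per-class type accuracy of the intact network, the network with
#' the indirect pathway fully removed, and the network with half of the
#' direct-pathway weights destroyed.
#'
#' @param state A trained \code{ncm_state}.
#' @param corpus The training corpus.
#' @param cfg The \code{train_config} used in training.
#' @param direct_fraction Fraction of direct weights destroyed in the
#'   direct lesion condition.
#' @param seed Seed for the random direct lesion.
#' @return A data frame with one row per condition and per-class
#'   accuracies.
#' @export
lesion_effects <- function(state, corpus, cfg = train_config(),
                           direct_fraction = 0.5, seed = 1L) {
  enc <- encode_corpus(corpus)
  irr <- corpus$entries$class == "irregular"
  acc_by_class <- function(st) {
    ok <- vapply(seq_len(ncol(enc$X)), function(i)
      all(net_forward(st, enc$X[, i], cfg)$output == enc$Y[, i]), TRUE)
    c(regular = mean(ok[!irr]), irregular = mean(ok[irr]))
  }
  intact <- acc_by_class(state)
  no_indirect <- acc_by_class(lesion(state, "indirect", 1, seed = seed))
  half_direct <- acc_by_class(lesion(state, "direct", direct_fraction,
                                     seed = seed))
  data.frame(condition = c("intact", "indirect_lesion", "direct_lesion"),
             lesion_fraction = c(0, 1, direct_fraction),
             accuracy_regular = c(intact["regular"], no_indirect["regular"],
                                  half_direct["regular"]),
             accuracy_irregular = c(intact["irregular"],
                                    no_indirect["irregular"],
                                    half_direct["irregular"]),
             row.names = NULL)
}

write_experiment <- function(exp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(exp$corpus, file.path(outdir, "corpus.csv"))
  for (k in seq_along(exp$fits)) {
    utils::write.csv(exp$fits[[k]]$record,
                     file.path(outdir, sprintf("train_record_%d.csv", k)),
                     row.names = FALSE)
    utils::write.csv(exp$profiles[[k]],
                     file.path(outdir, sprintf("sbi_table_%d.csv", k)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    exp$stats, file.path(outdir, "stats_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  manifest <- list(
    seed = exp$config$seed,
    corpus_seed = exp$config$corpus_seed,
    net_seeds = exp$config$net_seeds,
    n_networks = exp$config$n_networks,
    n_tokens = exp$config$n_tokens,
    corpus_config = unclass(exp$config$corpus),
    train_config = unclass(exp$config$train),
    package_version = as.character(utils::packageVersion("pastnet")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.ncm_experiment <- function(x, ...) {
  cat("ncm_experiment:", x$config$n_networks, "networks x",
      format(x$config$n_tokens, big.mark = ","), "tokens\n")
  cat("  corpus: "); print(x$corpus)
  cat("  final type accuracy:",
      paste(sprintf("%.3f", x$stats$accuracy), collapse = ", "), "\n")
  cat("  hidden units:", paste(x$stats$n_units, collapse = ", "), "\n")
  invisible(x)
}
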