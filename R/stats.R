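#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum comparison of two independent samples, reporting the U
#' statistic of the first sample, the tie-corrected normal-approximation z,
#' the two-sided p value, and the mean rank of each group (the form in
#' which group comparisons of pathway activations are reported).
#'
#' @param a,b Numeric samples.
#' @return A list of class \code{mw_test}: \code{U}, \code{z}, \code{p},
#'   \code{mean_rank_a}, \code{mean_rank_b}, \code{mean_a}, \code{sd_a},
#'   \code{mean_b}, \code{sd_b}, \code{n_a}, \code{n_b}.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2          # U of sample a
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(U = U, z = z, p = p,
                 mean_rank_a = mean(r[seq_len(n1)]),
                 mean_rank_b = mean(r[n1 + seq_len(n2)]),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 n_a = n1, n_b = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, z = %.3f, p = %.4g\n", x$U, x$z, x$p))
  cat(sprintf("  group a: n = %d, M = %.2f, SD = %.2f, mean rank = %.2f\n",
              x$n_a, x$mean_a, x$sd_a, x$mean_rank_a))
  cat(sprintf("  group b: n = %d, M = %.2f, SD = %.2f, mean rank = %.2f\n",
              x$n_b, x$mean_b, x$sd_b, x$mean_rank_b))
  invisible(x)
}

#' Correlations between verb statistics and an activation measure
#'
#' Pearson correlations of each per-verb predictor with a response column
#' (typically the activation ratio, or a numeric regularity coding).
#'
#' @param data Data frame of per-verb measures.
#' @param y Name of the response column, or a numeric vector.
#' @param predictors Character vector of predictor column names.
#' @return Named numeric vector of correlations (\code{NA} where a column
#'   has zero variance).
#' @export
corr_table <- function(data, y = "ratio",
                       predictors = c("past_freq", "friends", "enemies",
                                      "complexity")) {
  yv <- if (is.character(y)) data[[y]] else y
  if (length(yv) < 3) stop("need at least 3 verbs")
  vapply(predictors, function(p) {
    xv <- as.numeric(data[[p]])
    if (stats::sd(xv, na.rm = TRUE) == 0 || stats::sd(yv, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(xv, yv, use = "complete.obs")
  }, 0)
}

#' Multi-level regression of pathway activation on verb statistics
#'
#' Fits a random-intercept linear mixed model (maximum likelihood) of a
#' pathway's activation on standardised verb predictors, with verb and
#' network as random effects, pooling profiles from several trained
#' networks. Optionally adds regularity (coded 1 = regular, 0 = irregular,
#' then standardised like every predictor) and compares the augmented model
#' to the base model with a likelihood-ratio test -- the analysis used to
#' view the network's activation patterns from a dual-mechanism
#' perspective. With profiles from a single network the verb random
#' intercept is unidentifiable (one observation per verb), and the fit
#' falls back to ordinary least squares on the standardised predictors.
#'
#' @param data Pooled profile table: one row per verb x network with
#'   columns \code{id}, \code{network}, the pathway activation columns, the
#'   predictors, and \code{class}.
#' @param pathway \code{"indirect"} or \code{"direct"} (the response
#'   column).
#' @param predictors Character vector of predictor columns.
#' @param include_regularity Add regularity as a predictor and run the
#'   nested-model comparison.
#' @return A list of class \code{pathway_model}: \code{beta} (standardised
#'   fixed-effect coefficients), \code{se}, \code{p} (Wald), \code{r2}
#'   (marginal, fixed effects over total variance), and when
#'   \code{include_regularity} is \code{TRUE} also \code{lrt_chisq},
#'   \code{lrt_p}, \code{delta_r2} against the base model.
#' @export
fit_pathway_model <- function(data, pathway = c("indirect", "direct"),
                              predictors = c("past_freq", "friends",
                                             "enemies", "complexity"),
                              include_regularity = FALSE) {
  pathway <- match.arg(pathway)
  y <- data[[pathway]]
  Xd <- data.frame(lapply(data[predictors], function(v) zscore(as.numeric(v))))
  if (include_regularity) {
    Xd$regularity <- zscore(as.numeric(data$class == "regular"))
    predictors <- c(predictors, "regularity")
  }
  mm <- as.matrix(Xd)
  qr_rank <- qr(cbind(1, mm))$rank
  if (qr_rank < ncol(mm) + 1) {
    drop_candidates <- predictors[duplicated(t(round(mm, 10)))]
    stop("singular design; collinear predictors: ",
         paste(if (length(drop_candidates)) drop_candidates else predictors,
               collapse = ", "))
  }
  df <- cbind(Xd, y = y, id = data$id, network = data$network)
  # with a single network every verb contributes one observation, so the
  # verb random intercept is unidentifiable: fall back to plain OLS
  mixed <- length(unique(df$network)) > 1
  fit_one <- function(preds) {
    if (mixed) {
      fml <- paste("y ~", paste(preds, collapse = " + "),
                   "+ (1 | id) + (1 | network)")
      lme4::lmer(stats::as.formula(fml), data = df, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             check.conv.singular = "ignore"))
    } else {
      stats::lm(stats::as.formula(
        paste("y ~", paste(preds, collapse = " + "))), data = df)
    }
  }
  r2_of <- function(m) if (mixed) marginal_r2(m) else summary(m)$r.squared
  m <- fit_one(predictors)
  cf <- summary(m)$coefficients
  beta <- cf[-1, "Estimate"]
  se <- cf[-1, "Std. Error"]
  pvals <- 2 * stats::pnorm(-abs(cf[-1, "t value"]))
  res <- list(beta = beta, se = se, p = pvals,
              r2 = r2_of(m), mixed = mixed, pathway = pathway, model = m)
  if (include_regularity) {
    m0 <- fit_one(setdiff(predictors, "regularity"))
    if (mixed) {
      lrt <- stats::anova(m0, m)
      res$lrt_chisq <- lrt$Chisq[2]
      res$lrt_p <- lrt$`Pr(>Chisq)`[2]
    } else {
      lrt <- stats::anova(m0, m)
      res$lrt_chisq <- lrt$F[2]
      res$lrt_p <- lrt$`Pr(>F)`[2]
    }
    res$delta_r2 <- res$r2 - r2_of(m0)
  }
  class(res) <- "pathway_model"
  res
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

# Marginal R^2: variance of the fixed-effect predictions over total variance
# (fixed + random intercepts + residual).
marginal_r2 <- function(m) {
  var_f <- stats::var(as.numeric(lme4::getME(m, "X") %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  var_r <- sum(vapply(vc, function(v) v[1, 1], 0))
  var_e <- attr(vc, "sc")^2
  var_f / (var_f + var_r + var_e)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Mixed model of", x$pathway, "pathway activation (ML, random",
      "intercepts)\n")
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    p = signif(x$p, 3))
  print(tab)
  cat(sprintf("marginal R^2 = %.3f\n", x$r2))
  if (!is.null(x$lrt_p))
    cat(sprintf("LRT vs model without regularity: chisq = %.2f, p = %.3g, delta R^2 = %.3f\n",
                x$lrt_chisq, x$lrt_p, x$delta_r2))
  invisible(x)
}

#' Typicality ranking by activation ratio
#'
#' Typical regulars are regulars with a high activation ratio (strongly
#' direct-pathway dominated); typical irregulars are irregulars with a low
#' ratio. Returns the k most and least typical verbs of a class.
#'
#' @param profiles A profile table with \code{id}, \code{class},
#'   \code{ratio}.
#' @param class \code{"regular"} or \code{"irregular"}.
#' @param k Number of verbs per list.
#' @return List with \code{most_typical} and \code{least_typical} data
#'   frames (id, subtype, ratio), sorted; ties broken by id. For regulars
#'   "most typical" means highest ratio, for irregulars lowest.
#' @export
typicality <- function(profiles, class = c("regular", "irregular"), k = 10) {
  class <- match.arg(class)
  sub <- profiles[profiles$class == class & !is.na(profiles$ratio), ]
  if (k > nrow(sub)) {
    warning("k larger than class size; truncating to ", nrow(sub))
    k <- nrow(sub)
  }
  decreasing <- class == "regular"   # high ratio is typical for regulars
  ord <- order(sub$ratio, sub$id, decreasing = decreasing)
  sub <- sub[ord, c("id", "subtype", "ratio")]
  list(most_typical = utils::head(sub, k),
       least_typical = utils::tail(sub, k)[seq(k, 1), ])
}

#' Complexity-matched regular/irregular subset
#'
#' Greedily pairs each verb of the smaller class with the unused verb of
#' the other class nearest in the pairing key (phonological complexity by
#' default), then reruns the group comparison of both pathway activations
#' on the matched subset. Matching for complexity tests whether the
#' direct-pathway advantage for regulars is a phonological-complexity
#' effect rather than a regularity effect.
#'
#' @param profiles A profile table.
#' @param pairing_key Column to match on.
#' @return List with \code{pairs} (data frame of matched ids and key
#'   values), \code{subset} (profile rows of the matched verbs),
#'   \code{direct_test}, \code{indirect_test} (each a \code{mw_test},
#'   regulars as sample a).
#' @export
matched_subset <- function(profiles, pairing_key = "complexity") {
  reg <- profiles[profiles$class == "regular", ]
  irr <- profiles[profiles$class == "irregular", ]
  if (!nrow(reg) || !nrow(irr)) stop("both classes must be nonempty")
  swap <- nrow(reg) < nrow(irr)
  small <- if (swap) reg else irr
  large <- if (swap) irr else reg
  small <- small[order(small[[pairing_key]], small$id), ]
  used <- rep(FALSE, nrow(large))
  pick <- integer(nrow(small))
  for (i in seq_len(nrow(small))) {
    d <- abs(large[[pairing_key]] - small[[pairing_key]][i])
    d[used] <- Inf
    j <- which.min(d)                 # which.min: lowest index on ties
    used[j] <- TRUE
    pick[i] <- j
  }
  pairs <- data.frame(
    regular = if (swap) small$id else large$id[pick],
    irregular = if (swap) large$id[pick] else small$id,
    key_regular = if (swap) small[[pairing_key]]
                  else large[[pairing_key]][pick],
    key_irregular = if (swap) large[[pairing_key]][pick]
                    else small[[pairing_key]]
  )
  sub <- rbind(small, large[pick, ])
  list(pairs = pairs, subset = sub,
       direct_test = mann_whitney(sub$direct[sub$class == "regular"],
                                  sub$direct[sub$class == "irregular"]),
       indirect_test = mann_whitney(sub$indirect[sub$class == "regular"],
                                    sub$indirect[sub$class == "irregular"]))
}
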