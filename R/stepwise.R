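#' Stepwise likelihood-ratio predictor selection
#'
#' Candidates are tried one at a time in the stated order. A predictor is
#' kept when adding it reduces -2 x log-likelihood by more than the
#' chi-squared critical value at `alpha`, with degrees of freedom equal to
#' the number of coefficients it adds (number of new design columns times
#' the number of non-reference levels). A candidate that is linearly
#' dependent on the columns already in the design cannot change the
#' likelihood and is rejected outright.
#'
#' @inheritParams fit_multinomial
#' @param candidates character vector of candidate predictors, in order.
#' @param alpha significance level of the likelihood-ratio test (default
#'   0.05).
#' @return a list with `selected` (kept predictor names), `fit` (the
#'   final `breath_mnl`) and `trace` (data.frame with the LR statistic,
#'   df and decision per candidate).
#' @export
stepwise_select <- function(data, outcome, candidates, reference = NULL,
                            alpha = 0.05) {
  selected <- character()
  fit <- fit_multinomial(data, outcome, selected, reference = reference)
  k1 <- length(fit$levels) - 1L
  tr <- data.frame(predictor = character(), lr = numeric(), df = integer(),
                   kept = logical(), stringsAsFactors = FALSE)
  for (cand in candidates) {
    X_cur <- build_design(data, selected)
    X_new <- tryCatch(build_design(data, c(selected, cand)),
                      error = function(e) NULL)
    if (is.null(X_new) ||
        qr(X_new)$rank <= qr(X_cur)$rank) {
      tr <- rbind(tr, data.frame(predictor = cand, lr = 0,
                                 df = 0L, kept = FALSE))
      next
    }
    fit_new <- fit_multinomial(data, outcome, c(selected, cand),
                               reference = reference)
    df <- (ncol(X_new) - ncol(X_cur)) * k1
    lr <- 2 * (fit_new$loglik - fit$loglik)
    keep <- lr > stats::qchisq(1 - alpha, df)
    tr <- rbind(tr, data.frame(predictor = cand, lr = lr, df = df,
                               kept = keep))
    if (keep) {
      selected <- c(selected, cand)
      fit <- fit_new
    }
  }
  list(selected = selected, fit = fit, trace = tr)
}

#' Declarative collinearity screen
#'
#' Duration, amplitude and slope of a breathing segment are near-collinear
#' (slope is amplitude over duration), as are its onset and offset levels.
#' Rather than automatic pruning, each correlated block is represented by
#' a designated predictor: slope for the kinematic block and the offset
#' level for the level block. Candidates not belonging to any block pass
#' through unchanged, preserving order.
#'
#' @param candidates character vector of candidate predictor names.
#' @param blocks named list: each element is a character vector of
#'   mutually collinear predictors whose name is the retained
#'   representative. Defaults cover the exhalatory and inhalatory feature
#'   names of [feature_table()].
#' @return the retained predictors, in candidate order.
#' @export
collinearity_screen <- function(candidates, blocks = default_blocks()) {
  retained <- character()
  for (cand in candidates) {
    rep_of <- cand
    for (r in names(blocks)) {
      if (cand %in% blocks[[r]]) { rep_of <- r; break }
    }
    if (!rep_of %in% retained) retained <- c(retained, rep_of)
  }
  retained
}

default_blocks <- function() {
  list(
    exh_slope = c("exh_duration_log2s", "exh_amplitude", "exh_slope"),
    exh_offset_level = c("exh_onset_level", "exh_offset_level"),
    inh_slope = c("inh_duration_log2s", "inh_amplitude", "inh_slope"),
    inh_offset_level = c("inh_offset_level")
  )
}

#' Pre-registered model families
#'
#' The four multinomial model configurations of the analysis: the
#' exhalatory model over all six interval categories (slope, offset
#' level, hold presence; reference WSS-INH), the inhalatory model over
#' all intervals with an inhalation (slope, offset level; reference
#' WSS+INH), the inhalatory turn-taking model over WSS+INH, TT(O), TT(S)
#' (adding speech lag), and the silent-cycle model over Silent / Hold /
#' TT(S) groups (inhalation amplitude and duration; reference Hold).
#'
#' @param family one of `"exhalatory"`, `"inhalatory_all"`,
#'   `"inhalatory_tt"`, `"silent_cycle"`.
#' @return a list with `outcome`, `levels` (categories entering the
#'   model), `predictors` (in stepwise order), `reference`.
#' @export
mnl_config <- function(family = c("exhalatory", "inhalatory_all",
                                  "inhalatory_tt", "silent_cycle")) {
  family <- match.arg(family)
  switch(family,
    exhalatory = list(
      outcome = "category",
      levels = c("WSS-INH", "WSS+INH", "BSS-INH", "BSS+INH",
                 "BSO-INH", "BSO+INH"),
      predictors = c("exh_slope", "exh_offset_level", "hold_present"),
      reference = "WSS-INH"),
    inhalatory_all = list(
      outcome = "category",
      levels = c("WSS+INH", "BSS+INH", "BSO+INH", "TT(S)", "TT(O)"),
      predictors = c("inh_slope", "inh_offset_level"),
      reference = "WSS+INH"),
    inhalatory_tt = list(
      outcome = "category",
      levels = c("WSS+INH", "TT(S)", "TT(O)"),
      predictors = c("inh_slope", "inh_offset_level", "speech_lag_log2s"),
      reference = "WSS+INH"),
    silent_cycle = list(
      outcome = "group",
      levels = c("Hold", "Silent", "TT(S)"),
      predictors = c("inh_amplitude", "inh_duration_log2s"),
      reference = "Hold"))
}

#' Fit one pre-registered model family on a feature table
#'
#' Subsets the table to the family's categories and complete non-excluded
#' rows, then fits the family's predictors (optionally via
#' [stepwise_select()]).
#'
#' @param features feature table from [feature_table()] (or the
#'   silent-cycle group table for `family = "silent_cycle"`).
#' @param family model family, see [mnl_config()].
#' @param stepwise use stepwise likelihood-ratio selection (default TRUE).
#' @param alpha stepwise significance level.
#' @param min_level_n outcome levels with fewer rows than this are
#'   dropped before fitting (default 5); with only one or two
#'   observations a level's coefficients are unidentifiable and the
#'   Newton iterations walk towards quasi-separation.
#' @return a list with the `breath_mnl` `fit`, the `config`, the number
#'   of rows used and (if stepwise) the selection `trace`.
#' @export
fit_family <- function(features, family, stepwise = TRUE, alpha = 0.05,
                       min_level_n = 5L) {
  cfg <- mnl_config(family)
  d <- features
  if ("excluded" %in% names(d)) d <- d[is.na(d$excluded), , drop = FALSE]
  d <- d[d[[cfg$outcome]] %in% cfg$levels, , drop = FALSE]
  keep_cols <- c(cfg$outcome, cfg$predictors)
  d <- d[stats::complete.cases(d[, keep_cols, drop = FALSE]), , drop = FALSE]
  tab <- table(d[[cfg$outcome]])
  d <- d[d[[cfg$outcome]] %in% names(tab)[tab >= min_level_n], , drop = FALSE]
  if (nrow(d) < 10L || length(unique(d[[cfg$outcome]])) < 2L) {
    stop(sprintf("not enough data to fit the %s model", family), call. = FALSE)
  }
  d[[cfg$outcome]] <- factor(d[[cfg$outcome]],
                             levels = intersect(cfg$levels,
                                                unique(d[[cfg$outcome]])))
  if (stepwise) {
    sel <- stepwise_select(d, cfg$outcome, cfg$predictors,
                           reference = cfg$reference, alpha = alpha)
    list(fit = sel$fit, config = cfg, n = nrow(d), trace = sel$trace,
         selected = sel$selected)
  } else {
    list(fit = fit_multinomial(d, cfg$outcome, cfg$predictors,
                               reference = cfg$reference),
         config = cfg, n = nrow(d), selected = cfg$predictors)
  }
}
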