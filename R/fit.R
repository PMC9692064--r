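# Real-vs-baseline interaction models.
#
# The estimand is the sentence-length x tree-type interaction: with S the
# sentence length, R an indicator (1 = real tree, 0 = baseline tree) and the
# response the per-sentence mean intervener complexity (IC) or mean dependency
# length (DL),
#
#   y_ij = b0 + u0_j + (b1 + u1_j) S_ij + (b2 + u2_j) R_ij
#          + (b3 + u3_j) S_ij R_ij + e_ij
#
# with by-language (j) random adjustments u. A negative b3 means the response
# grows more slowly with sentence length in real trees than in the matched
# baseline -- the minimization signature the hypotheses predict.

#' Build the observation table for a real-vs-baseline comparison
#'
#' Produces two rows per surviving sentence: one from the real tree (`R = 1`)
#' and one from its paired baseline (`R = 0`), each carrying both candidate
#' responses (mean IC and mean DL). Pairing is positional and checked by
#' sentence id; pairs dropped by baseline-generation failure must already be
#' excluded (as [generate_baseline_corpus()] does).
#'
#' @param real a [dep_corpus()] of real trees (the `paired_real` element of
#'   [generate_baseline_corpus()] output).
#' @param baseline the paired baseline [dep_corpus()].
#' @return data.frame with columns `language`, `sentence_id`, `S`, `R`,
#'   `response_ic`, `response_dl`.
#' @export
build_observation_table <- function(real, baseline) {
  if (length(real) != length(baseline))
    stop("real and baseline corpora differ in length", call. = FALSE)
  rid <- vapply(real, function(t) t$sentence_id, character(1))
  bid <- vapply(baseline, function(t) t$sentence_id, character(1))
  bad <- which(!is.na(rid) & !is.na(bid) & rid != bid)
  if (length(bad))
    stop("unpaired sentence ids at positions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  one <- function(corpus, r) {
    m <- corpus_metrics(corpus)
    data.frame(language = m$language, sentence_id = m$sentence_id,
               S = m$n_words, R = r,
               response_ic = m$mean_ic, response_dl = m$mean_dl,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(one(real, 1L), one(baseline, 0L))
  rownames(rows) <- NULL
  rows
}

.re_ladder <- list(
  diag_full   = "(1 + S + R + S:R || language)",
  corr_full   = "(1 + S + R + S:R | language)",
  diag_no_int = "(1 + S + R || language)",
  diag_no_R   = "(1 + S || language)",
  intercept   = "(1 | language)")

.fit_one_lmer <- function(rows, response, re_term) {
  fml <- stats::as.formula(paste(response, "~ S * R +", re_term))
  warn <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(fml, data = rows, REML = TRUE)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # a boundary (singular) fit is converged: variance components may be
  # legitimately estimated at 0; only optimizer failures walk the ladder
  msgs <- c(unlist(fit@optinfo$conv$lme4$messages), warn)
  bad <- grepl("failed to converge|unable to evaluate|degenerate", msgs)
  list(fit = fit, ok = !any(bad),
       singular = any(grepl("singular", msgs)) || lme4::isSingular(fit))
}

# extract a ModelFit from a fitted lmer or lm object
.model_fit <- function(fit, response, re_structure, converged, n_groups,
                       singular = FALSE) {
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(beta) <- names(se) <- c("(Intercept)", "S", "R", "S:R")[seq_along(beta)]
  vc <- if (inherits(fit, "merMod")) as.data.frame(lme4::VarCorr(fit)) else NULL
  ranef <- if (inherits(fit, "merMod")) lme4::ranef(fit)$language else NULL
  structure(list(beta = beta, se = se, t = beta / se,
                 random_effects = ranef, varcorr = vc,
                 residual_sd = stats::sigma(fit),
                 converged = converged, singular = singular,
                 re_structure = re_structure,
                 response = response,
                 n_obs = stats::nobs(fit), n_groups = n_groups,
                 model = fit),
            class = "icdl_fit")
}

#' Fit the mixed-effects interaction model
#'
#' Fits `response ~ S * R` with by-language random intercepts and random
#' slopes for `S`, `R` and `S:R` (REML; random effects uncorrelated by
#' default). If the full random-effects structure fails to converge or is
#' singular, a documented reduction ladder is walked -- drop the `S:R` slope,
#' then the `R` slope, then all slopes -- and the structure that converged is
#' recorded in the returned object.
#'
#' @param rows observation table from [build_observation_table()] (or any
#'   data.frame with `language`, `S`, `R` and the response column).
#' @param response `"ic"` or `"dl"` (columns `response_ic` / `response_dl`).
#' @param correlated if `TRUE`, start the ladder from the fully correlated
#'   random-effects structure instead of the diagonal one.
#' @param center_S if `TRUE`, center sentence length before fitting (off by
#'   default: slopes are reported on the raw length scale).
#' @return an object of class `icdl_fit`: fixed effects `beta`
#'   (`(Intercept)`, `S`, `R`, `S:R`), their `se` and `t = beta/se`,
#'   per-language `random_effects`, variance components, `residual_sd`, the
#'   converged flag and random-effects structure used, `n_obs`, `n_groups`.
#' @seealso [evaluate_hypothesis()], [summarize_fit()], [fit_per_language()]
#' @export
fit_interaction <- function(rows, response = c("ic", "dl"), correlated = FALSE,
                            center_S = FALSE) {
  response <- match.arg(response)
  col <- paste0("response_", response)
  stopifnot(col %in% names(rows))
  rows <- data.frame(language = rows$language, S = as.numeric(rows$S),
                     R = as.numeric(rows$R), y = rows[[col]])
  if (length(unique(rows$language)) < 2L)
    stop("inestimable: need at least 2 languages (use fit_per_language)", call. = FALSE)
  if (length(unique(rows$R)) < 2L)
    stop("inestimable: need both real (R=1) and baseline (R=0) rows", call. = FALSE)
  if (length(unique(rows$S)) < 2L)
    stop("inestimable: need at least 2 distinct sentence lengths", call. = FALSE)
  if (center_S) rows$S <- rows$S - mean(rows$S)

  ladder <- if (correlated) c("corr_full", names(.re_ladder)[-2L]) else
    names(.re_ladder)[-2L]
  fit <- NULL; used <- NULL; ok <- FALSE; singular <- FALSE
  for (lev in ladder) {
    res <- tryCatch(.fit_one_lmer(rows, "y", .re_ladder[[lev]]),
                    error = function(e) NULL)
    if (is.null(res)) next
    fit <- res$fit; used <- lev; singular <- res$singular
    if (res$ok) { ok <- TRUE; break }
  }
  if (is.null(fit)) stop("model could not be fit at any random-effects structure",
                         call. = FALSE)
  .model_fit(fit, response, used, ok, singular = singular,
             n_groups = length(unique(rows$language)))
}

#' Per-language fixed-effects fits
#'
#' Ordinary least-squares `response ~ S * R` fitted separately within each
#' language (the random adjustments of [fit_interaction()] are dropped).
#' Languages with only one `R` level are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @inheritParams fit_interaction
#' @return named list of `icdl_fit` objects, one per language.
#' @export
fit_per_language <- function(rows, response = c("ic", "dl")) {
  response <- match.arg(response)
  col <- paste0("response_", response)
  out <- list(); skipped <- character(0)
  for (lang in unique(rows$language)) {
    d <- rows[rows$language == lang, ]
    if (length(unique(d$R)) < 2L || length(unique(d$S)) < 2L) {
      skipped <- c(skipped, lang)
      next
    }
    d <- data.frame(S = as.numeric(d$S), R = as.numeric(d$R), y = d[[col]])
    fit <- stats::lm(y ~ S * R, data = d)
    out[[lang]] <- .model_fit(fit, response, "none (fixed effects)", TRUE, 1L)
  }
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}

#' Judge a fitted comparison against the minimization prediction
#'
#' The prediction is carried by the interaction term: `beta["S:R"] < 0` with
#' `|t| >` threshold means the response grows more slowly with sentence length
#' in real trees than in the baseline (`"supported"`); a significant positive
#' interaction is `"contradicted"`; anything else (including a non-converged
#' fit) is `"inconclusive"`. The main effect of tree type (`beta["R"]`) is
#' reported alongside, since main effect and interaction can disagree.
#'
#' @param fit an `icdl_fit`.
#' @param threshold |t| cut-off for significance (default 2).
#' @return list: `verdict`, `beta3`, `t3`, `beta2`, `t2`, `reason`.
#' @export
evaluate_hypothesis <- function(fit, threshold = 2) {
  stopifnot(inherits(fit, "icdl_fit"))
  b3 <- unname(fit$beta["S:R"]); t3 <- unname(fit$t["S:R"])
  b2 <- unname(fit$beta["R"]);  t2 <- unname(fit$t["R"])
  if (!isTRUE(fit$converged)) {
    verdict <- "inconclusive"; reason <- "model did not converge"
  } else if (is.na(b3)) {
    verdict <- "inconclusive"; reason <- "interaction not estimated"
  } else if (abs(t3) <= threshold) {
    verdict <- "inconclusive"; reason <- sprintf("|t| = %.2f below %.1f", abs(t3), threshold)
  } else if (b3 < 0) {
    verdict <- "supported"; reason <- sprintf("interaction %.3f, t = %.2f", b3, t3)
  } else {
    verdict <- "contradicted"; reason <- sprintf("interaction %.3f, t = %.2f", b3, t3)
  }
  list(verdict = verdict, beta3 = b3, t3 = t3, beta2 = b2, t2 = t2, reason = reason)
}

#' Four-row estimates table for a fit
#'
#' @param fit an `icdl_fit`.
#' @return data.frame with rows Intercept, S.length, Real, S.length:Real and
#'   columns `term`, `estimate`, `se`, `t`, `signif` (`"*"` iff |t| > 2).
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "icdl_fit"))
  terms <- c("Intercept", "S.length", "Real", "S.length:Real")
  data.frame(term = terms[seq_along(fit$beta)],
             estimate = unname(fit$beta), se = unname(fit$se),
             t = unname(fit$t),
             signif = ifelse(abs(fit$t) > 2, "*", ""),
             stringsAsFactors = FALSE)
}

#' Simulate observation tables from the interaction model
#'
#' Generates data from the generative model behind [fit_interaction()]:
#' by-language random adjustments for intercept and all three slopes
#' (independent normals), Gaussian residuals, sentence lengths uniform on
#' `S_range`, and one real/baseline row pair per sentence. Used for parameter
#' recovery and null calibration.
#'
#' @param beta fixed effects `c(b0, b1, b2, b3)`.
#' @param sd_u standard deviations of the four random adjustments (recycled).
#' @param sigma residual standard deviation.
#' @param n_languages,n_sentences groups and sentences per group.
#' @param S_range inclusive integer range of sentence lengths.
#' @return observation table as from [build_observation_table()], with both
#'   `response_ic` and `response_dl` set to the simulated response.
#' @export
simulate_interaction <- function(beta = c(1.5, 0.30, -0.30, -0.15),
                                 sd_u = 0.1, sigma = 0.2,
                                 n_languages = 40L, n_sentences = 200L,
                                 S_range = c(3L, 11L)) {
  sd_u <- rep_len(sd_u, 4L)
  rows <- vector("list", n_languages)
  for (j in seq_len(n_languages)) {
    u <- stats::rnorm(4L, 0, sd_u)
    S <- sample(seq(S_range[1], S_range[2]), n_sentences, replace = TRUE)
    S2 <- rep(S, 2L)
    R <- rep(c(1L, 0L), each = n_sentences)
    mu <- (beta[1] + u[1]) + (beta[2] + u[2]) * S2 +
      (beta[3] + u[3]) * R + (beta[4] + u[4]) * S2 * R
    y <- mu + stats::rnorm(length(mu), 0, sigma)
    rows[[j]] <- data.frame(
      language = sprintf("L%02d", j),
      sentence_id = paste0(sprintf("L%02d", j), "_s", rep(seq_len(n_sentences), 2L)),
      S = S2, R = R, response_ic = y, response_dl = y,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.icdl_fit <- function(x, ...) {
  cat(sprintf("<icdl_fit> response = mean %s, %d obs, %d language(s)\n",
              toupper(x$response), x$n_obs, x$n_groups))
  cat(sprintf(" random effects: %s%s\n", x$re_structure,
              if (x$converged) "" else "  [did not converge]"))
  tab <- summarize_fit(x)
  tab$estimate <- sprintf("% .4f", tab$estimate)
  tab$se <- sprintf("%.4f", tab$se)
  tab$t <- sprintf("% .2f", tab$t)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.icdl_fit <- function(object, ...) object$beta

#' @export
summary.icdl_fit <- function(object, ...) {
  out <- list(table = summarize_fit(object),
              verdict = evaluate_hypothesis(object),
              residual_sd = object$residual_sd,
              varcorr = object$varcorr,
              re_structure = object$re_structure,
              n_obs = object$n_obs, n_groups = object$n_groups,
              response = object$response)
  class(out) <- "summary.icdl_fit"
  out
}

#' @export
print.summary.icdl_fit <- function(x, ...) {
  cat(sprintf("Interaction model, response = mean %s (%d obs, %d languages)\n",
              toupper(x$response), x$n_obs, x$n_groups))
  print(x$table, row.names = FALSE)
  cat(sprintf("residual SD %.4f; random effects: %s\n", x$residual_sd, x$re_structure))
  cat(sprintf("verdict: %s (%s)\n", x$verdict$verdict, x$verdict$reason))
  invisible(x)
}
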