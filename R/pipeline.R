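# Orchestration: filter -> metrics -> baseline generation -> interaction fits
# -> verdicts + distribution summaries, as one seeded, reproducible run.

# which hypothesis a (baseline kind, response) pair tests
.hypothesis_for <- function(kind, response) {
  if (response == "ic" && kind %in% c("random_structures", "rla"))
    "ICM" else
  if (response == "ic" && startsWith(kind, "dl_matched"))
    "ICM_independent" else
  if (response == "dl" && startsWith(kind, "ic_matched"))
    "DLM_independent" else "exploratory"
}

#' Experiment configuration
#'
#' @param corpus a [dep_corpus()] (already carrying language labels), or a
#'   named character vector of CoNLL-U file paths (names = language labels).
#' @param filter a [corpus_filter()].
#' @param baselines character vector of baseline kinds, or list of
#'   [baseline_spec()] objects.
#' @param responses subset of `c("ic", "dl")` to fit against every baseline.
#' @param seed global seed; baseline specs given as kind strings inherit it.
#' @param max_attempts budget for baseline specs given as kind strings.
#' @param per_language if `TRUE`, also run [fit_per_language()].
#' @param out_dir optional directory; when set, estimate tables, verdicts,
#'   summaries, baseline CoNLL-U files and a JSON manifest are written there.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(corpus, filter = corpus_filter(),
                              baselines = c("random_structures", "rla"),
                              responses = c("ic", "dl"),
                              seed = 1L, max_attempts = 100000L,
                              per_language = FALSE, out_dir = NULL) {
  if (is.character(corpus)) {
    langs <- names(corpus)
    if (is.null(langs)) stop("corpus paths must be named by language", call. = FALSE)
    corpus <- dep_corpus(unlist(lapply(seq_along(corpus), function(i)
      unclass(parse_conllu(corpus[[i]], language = langs[i], is_path = TRUE))),
      recursive = FALSE))
  }
  if (is.character(baselines))
    baselines <- lapply(baselines, baseline_spec, max_attempts = max_attempts,
                        seed = seed)
  stopifnot(all(vapply(baselines, inherits, logical(1), "baseline_spec")),
            all(responses %in% c("ic", "dl")))
  structure(list(corpus = corpus, filter = filter, baselines = baselines,
                 responses = responses, seed = as.integer(seed),
                 per_language = isTRUE(per_language), out_dir = out_dir),
            class = "experiment_config")
}

#' Run a full real-vs-baseline experiment
#'
#' For each configured baseline: generates the paired baseline corpus, fits
#' the interaction model for each requested response, records the hypothesis
#' verdict, and computes the distribution summaries of
#' [summarize_distributions()]. All randomness derives from the config seed;
#' re-running an identical config reproduces every table.
#'
#' @param config an [experiment_config()].
#' @return list of class `icdl_experiment`: `estimates` (named list of
#'   four-row tables, one per baseline x response), `fits` (the `icdl_fit`
#'   objects), `verdicts` (data.frame: hypothesis, baseline, response, verdict,
#'   beta3, t3, beta2, t2), `per_language` (when requested), `reports`
#'   (baseline-generation reports), `summaries` (per baseline, the four
#'   distribution tables), and `manifest` (seeds, counts, filter settings).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  real <- filter_corpus(config$corpus, config$filter)
  if (!length(real)) stop("stage filter: no sentences survive the corpus filter",
                          call. = FALSE)
  estimates <- list(); fits <- list(); reports <- list()
  summaries <- list(); perlang <- list()
  verdicts <- NULL
  for (spec in config$baselines) {
    gen <- tryCatch(generate_baseline_corpus(real, spec), error = function(e)
      stop("stage baseline[", spec$kind, "]: ", conditionMessage(e), call. = FALSE))
    reports[[spec$kind]] <- gen$report
    if (!length(gen$baseline))
      stop("stage baseline[", spec$kind, "]: no baseline tree could be generated",
           call. = FALSE)
    rows <- build_observation_table(gen$paired_real, gen$baseline)
    summaries[[spec$kind]] <- summarize_distributions(gen$paired_real, gen$baseline)
    for (resp in config$responses) {
      key <- paste(spec$kind, resp, sep = "_")
      fit <- tryCatch(fit_interaction(rows, resp), error = function(e)
        stop("stage fit[", key, "]: ", conditionMessage(e), call. = FALSE))
      fits[[key]] <- fit
      estimates[[key]] <- summarize_fit(fit)
      v <- evaluate_hypothesis(fit)
      verdicts <- rbind(verdicts, data.frame(
        hypothesis = .hypothesis_for(spec$kind, resp),
        baseline = spec$kind, response = resp, verdict = v$verdict,
        beta3 = v$beta3, t3 = v$t3, beta2 = v$beta2, t2 = v$t2,
        converged = fit$converged, re_structure = fit$re_structure,
        stringsAsFactors = FALSE))
      if (config$per_language)
        perlang[[key]] <- lapply(fit_per_language(rows, resp), summarize_fit)
    }
  }
  manifest <- list(
    seed = config$seed,
    filter = unclass(config$filter),
    n_sentences_input = length(config$corpus),
    n_sentences_filtered = length(real),
    baselines = lapply(config$baselines, function(s)
      list(kind = s$kind, max_attempts = s$max_attempts, seed = s$seed,
           successes = sum(reports[[s$kind]]$per_tree$success),
           failures = sum(!reports[[s$kind]]$per_tree$success))),
    responses = config$responses)
  out <- structure(list(estimates = estimates, fits = fits, verdicts = verdicts,
                        per_language = if (config$per_language) perlang,
                        reports = reports, summaries = summaries,
                        manifest = manifest),
                   class = "icdl_experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config, real)
  out
}

#' @export
print.icdl_experiment <- function(x, ...) {
  cat("<icdl_experiment>\n")
  print(x$verdicts[, c("hypothesis", "baseline", "response", "verdict", "beta3", "t3")],
        row.names = FALSE)
  invisible(x)
}

# write all TSVs, baseline corpora and the manifest to config$out_dir
write_experiment <- function(result, config, real) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(config$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(result$estimates))
    tsv(result$estimates[[key]], paste0("estimates_", key, ".tsv"))
  tsv(result$verdicts, "verdicts.tsv")
  for (kind in names(result$summaries)) {
    s <- result$summaries[[kind]]
    tsv(s$arity, paste0("summary_arity_", kind, ".tsv"))
    tsv(s$low_ic, paste0("summary_lowic_", kind, ".tsv"))
    tsv(s$short_dl, paste0("summary_shortdl_", kind, ".tsv"))
    tsv(s$mean_dl, paste0("summary_meandl_", kind, ".tsv"))
    tsv(result$reports[[kind]]$per_tree, paste0("report_", kind, ".tsv"))
  }
  if (!is.null(result$per_language)) {
    for (key in names(result$per_language)) {
      tab <- do.call(rbind, Map(function(lang, d) cbind(language = lang, d),
                                names(result$per_language[[key]]),
                                result$per_language[[key]]))
      tsv(tab, paste0("perlang_", key, ".tsv"))
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Distribution summaries contrasting real and baseline trees
#'
#' Four pooled per-edge summary tables: (a) arity statistics by sentence
#' length; (b) count of low-IC (`ic <= low_ic`) dependencies at each
#' dependency length; (c) count of short (`dl <= short_dl`) dependencies at
#' each intervener complexity up to `max_ic` (higher IC cannot be reached by
#' short dependencies, since IC <= DL); (d) mean dependency length at each
#' intervener complexity.
#'
#' @param real,baseline paired [dep_corpus()] objects.
#' @param low_ic IC cutoff for table (b), default 2.
#' @param short_dl DL cutoff for table (c), default 3.
#' @param max_ic largest IC tabulated in table (c), default 4.
#' @return list of data.frames `arity`, `low_ic`, `short_dl`, `mean_dl`, each
#'   with a `source` column (`"real"` / `"baseline"`).
#' @export
summarize_distributions <- function(real, baseline, low_ic = 2L, short_dl = 3L,
                                    max_ic = 4L) {
  pool_edges <- function(corpus, source) {
    do.call(rbind, lapply(corpus, function(t)
      cbind(edge_metrics(t), n_words = t$n_words, source = source)))
  }
  e <- rbind(pool_edges(real, "real"), pool_edges(baseline, "baseline"))
  m <- rbind(cbind(corpus_metrics(real), source = "real"),
             cbind(corpus_metrics(baseline), source = "baseline"))

  arity <- do.call(rbind, lapply(split(m, list(m$source, m$n_words), drop = TRUE),
    function(d) data.frame(source = d$source[1], n_words = d$n_words[1],
                           mean_max_arity = mean(d$max_arity),
                           mean_mean_arity = mean(d$mean_arity),
                           n_sentences = nrow(d))))
  low <- e[e$ic <= low_ic, ]
  low_tab <- as.data.frame(table(source = low$source, dl = low$dl),
                           responseName = "count")
  low_tab$dl <- as.integer(as.character(low_tab$dl))

  short <- e[e$dl <= short_dl & e$ic <= max_ic, ]
  short_tab <- as.data.frame(table(source = short$source, ic = short$ic),
                             responseName = "count")
  short_tab$ic <- as.integer(as.character(short_tab$ic))

  mean_dl <- do.call(rbind, lapply(split(e, list(e$source, e$ic), drop = TRUE),
    function(d) data.frame(source = d$source[1], ic = d$ic[1],
                           mean_dl = mean(d$dl), n_edges = nrow(d))))
  rownames(arity) <- rownames(mean_dl) <- NULL
  list(arity = arity, low_ic = low_tab, short_dl = short_tab, mean_dl = mean_dl)
}
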