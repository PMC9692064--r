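#' Parse a CoNLL-U document into a corpus of dependency trees
#'
#' Reads the 10-column tab-separated CoNLL-U format. Multiword-token range
#' lines (ID `a-b`) and empty-node lines (ID `a.b`) are skipped; `# sent_id =`
#' comments are retained as sentence ids and other comments of the form
#' `# key = value` are kept as metadata. Only ID, FORM, UPOS and HEAD are
#' interpreted; LEMMA, XPOS, FEATS, DEPREL, DEPS and MISC are carried opaquely
#' for round-tripping.
#'
#' @param x a character scalar containing a CoNLL-U document, a character
#'   vector of lines, or a file path (when `is_path = TRUE` or `x` names an
#'   existing file and has length 1).
#' @param language language label attached to every sentence.
#' @param on_error `"skip"` drops malformed or invalid sentences with a
#'   warning; `"abort"` stops at the first bad sentence.
#' @param is_path force interpretation of `x` as a file path.
#' @return a [dep_corpus()]. Skipped sentences are recorded in the
#'   `"skipped"` attribute as a named character vector (id -> reason).
#' @export
parse_conllu <- function(x, language = NA_character_, on_error = c("skip", "abort"),
                         is_path = FALSE) {
  on_error <- match.arg(on_error)
  if (is_path || (length(x) == 1L && !grepl("\n", x) && file.exists(x)))
    x <- readLines(x, warn = FALSE)
  if (length(x) == 1L && grepl("\n", x)) x <- strsplit(x, "\n", fixed = TRUE)[[1]]

  # split into sentence blocks on blank lines
  blank <- !nzchar(trimws(x))
  grp <- cumsum(blank)
  blocks <- split(x[!blank], grp[!blank])

  trees <- list()
  skipped <- character(0)
  for (b in blocks) {
    res <- parse_conllu_sentence(b, language)
    if (is.character(res)) {  # error message
      id <- attr(res, "sent_id")
      if (is.null(id)) id <- sprintf("(sentence %d)", length(trees) + length(skipped) + 1L)
      if (on_error == "abort")
        stop("CoNLL-U parse error in sentence ", id, ": ", res, call. = FALSE)
      skipped[id] <- as.character(res)
    } else {
      trees[[length(trees) + 1L]] <- res
    }
  }
  out <- dep_corpus(trees)
  if (length(skipped)) {
    warning(length(skipped), " sentence(s) skipped during CoNLL-U parsing", call. = FALSE)
    attr(out, "skipped") <- skipped
  }
  out
}

# Parse one sentence block (comment + word lines). Returns a dep_tree or a
# character error message with attr "sent_id".
parse_conllu_sentence <- function(lines, language) {
  comments <- lines[startsWith(lines, "#")]
  word_lines <- lines[!startsWith(lines, "#")]
  meta <- character(0)
  for (cm in comments) {
    m <- regmatches(cm, regexec("^#[ \t]*([^= \t]+)[ \t]*=[ \t]*(.*)$", cm))[[1]]
    if (length(m) == 3L) meta[m[2]] <- trimws(m[3])
  }
  sent_id <- if ("sent_id" %in% names(meta)) meta[["sent_id"]] else NA_character_
  fail <- function(msg) structure(msg, sent_id = sent_id)

  fields <- strsplit(word_lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 10L)
  if (length(bad)) return(fail(sprintf("expected 10 columns, got %d", lengths(fields)[bad[1]])))
  ids <- vapply(fields, `[[`, character(1), 1L)
  keep <- grepl("^[0-9]+$", ids)  # drop range lines "a-b" and empty nodes "a.b"
  if (!any(keep)) return(fail("no word lines"))
  fields <- fields[keep]
  mat <- do.call(rbind, fields)
  pos <- as.integer(mat[, 1])
  n <- length(pos)
  if (!identical(pos, seq_len(n))) return(fail("word IDs not consecutive from 1"))
  head_raw <- mat[, 7]
  if (any(!grepl("^[0-9]+$", head_raw))) return(fail("non-integer HEAD"))
  heads <- as.integer(head_raw)

  tr <- dep_tree(heads, forms = mat[, 2], upos = mat[, 4],
                 sentence_id = sent_id, language = language,
                 extra = data.frame(lemma = mat[, 3], xpos = mat[, 5],
                                    feats = mat[, 6], deprel = mat[, 8],
                                    deps = mat[, 9], misc = mat[, 10],
                                    stringsAsFactors = FALSE),
                 meta = meta[setdiff(names(meta), "sent_id")])
  rep <- validate_tree(tr)
  if (length(rep)) return(fail(paste(rep, collapse = "; ")))
  tr
}

#' Write a corpus to a CoNLL-U document
#'
#' Inverse of [parse_conllu()] on the retained fields: positions, forms, UPOS
#' and heads round-trip exactly; carried columns are written back when present
#' and `_` otherwise. Per-tree metadata (and any `annotations`) are emitted as
#' `# key = value` comments.
#'
#' @param corpus a [dep_corpus()] or list of [dep_tree()].
#' @param path optional output file; when `NULL` the document is returned as a
#'   single character scalar.
#' @param annotations optional named list (or single-row worth of values)
#'   applied to every tree, or a list of per-tree named lists with
#'   `length(annotations) == length(corpus)`; written as comments (e.g.
#'   baseline kind, RNG seed, attempts used).
#' @return the document as a character scalar (invisibly when `path` given).
#' @export
write_conllu <- function(corpus, path = NULL, annotations = NULL) {
  per_tree <- !is.null(annotations) && is.null(names(annotations)) &&
    length(annotations) == length(corpus)
  out <- character(0)
  for (k in seq_along(corpus)) {
    tr <- corpus[[k]]
    ann <- if (is.null(annotations)) NULL else if (per_tree) annotations[[k]] else annotations
    lines <- character(0)
    if (!is.na(tr$sentence_id))
      lines <- c(lines, paste0("# sent_id = ", tr$sentence_id))
    meta <- c(as.list(tr$meta), as.list(ann))
    for (nm in names(meta))
      lines <- c(lines, sprintf("# %s = %s", nm, meta[[nm]]))
    n <- tr$n_words
    ex <- tr$extra
    col <- function(name) if (!is.null(ex) && name %in% names(ex)) ex[[name]] else rep("_", n)
    lines <- c(lines, sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%d\t%s\t%s\t%s",
                              seq_len(n), tr$forms, col("lemma"), tr$upos, col("xpos"),
                              col("feats"), tr$heads, col("deprel"), col("deps"),
                              col("misc")))
    out <- c(out, lines, "")
  }
  doc <- paste0(paste(out, collapse = "\n"), if (length(out)) "" else "")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(doc))
  }
  doc
}

#' Corpus length/punctuation filter
#'
#' @param min_len minimum sentence length retained (words), default 3: a tree
#'   with fewer than 3 words admits no intervener, so such rows carry no
#'   information about intervening material.
#' @param max_len maximum sentence length retained, default 11.
#' @param exclude_punct if `TRUE`, words tagged `PUNCT` are removed before the
#'   length test and positions re-indexed; a tree in which a punctuation word
#'   heads a non-punctuation word is dropped (and logged).
#' @return object of class `corpus_filter`.
#' @export
corpus_filter <- function(min_len = 3L, max_len = 11L, exclude_punct = FALSE) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(min_len >= 2L, max_len >= min_len)
  structure(list(min_len = min_len, max_len = max_len,
                 exclude_punct = isTRUE(exclude_punct)),
            class = "corpus_filter")
}

#' Filter a corpus by sentence length (optionally dropping punctuation)
#'
#' Punctuation removal (when requested) happens before the length test. A word
#' whose head was removed as punctuation cannot be reattached faithfully, so
#' such trees are dropped and recorded in the `"dropped"` attribute.
#'
#' @param corpus a [dep_corpus()].
#' @param filter a [corpus_filter()].
#' @return filtered [dep_corpus()]; attribute `"dropped"` names trees dropped
#'   because punctuation headed non-punctuation material.
#' @export
filter_corpus <- function(corpus, filter = corpus_filter()) {
  stopifnot(inherits(filter, "corpus_filter"))
  dropped <- character(0)
  keep <- list()
  for (tr in corpus) {
    if (filter$exclude_punct) {
      tr2 <- strip_punct(tr)
      if (is.null(tr2)) {
        id <- if (is.na(tr$sentence_id)) "(unnamed)" else tr$sentence_id
        dropped <- c(dropped, id)
        next
      }
      tr <- tr2
    }
    if (tr$n_words >= filter$min_len && tr$n_words <= filter$max_len)
      keep[[length(keep) + 1L]] <- tr
  }
  out <- dep_corpus(keep)
  if (length(dropped)) attr(out, "dropped") <- dropped
  out
}

# Remove PUNCT words and re-index; NULL if a PUNCT word heads a non-PUNCT word.
strip_punct <- function(tree) {
  punct <- tree$upos == "PUNCT"
  if (!any(punct)) return(tree)
  nonp <- which(!punct)
  if (!length(nonp)) return(NULL)
  if (any(tree$heads[nonp] %in% which(punct))) return(NULL)
  newpos <- integer(tree$n_words)
  newpos[nonp] <- seq_along(nonp)
  heads <- tree$heads[nonp]
  heads[heads > 0L] <- newpos[heads[heads > 0L]]
  dep_tree(heads, forms = tree$forms[nonp], upos = tree$upos[nonp],
           sentence_id = tree$sentence_id, language = tree$language,
           extra = if (!is.null(tree$extra)) tree$extra[nonp, , drop = FALSE],
           meta = tree$meta)
}
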