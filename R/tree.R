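#' Construct a dependency tree
#'
#' A `dep_tree` represents one sentence as a rooted dependency tree over
#' linearly ordered words. Word `i` occupies linear position `i` (1-based);
#' `heads[i]` gives the position of its syntactic head, with `0` marking the
#' single word attached to the artificial root. The artificial root itself is
#' not a word and has no linear position; all complexity metrics in this
#' package are computed over word-word dependencies only.
#'
#' @param heads integer vector of head positions; exactly one entry must be 0.
#' @param forms character vector of word forms (defaults to `w1`, `w2`, ...).
#' @param upos character vector of universal POS tags (defaults to `"X"`).
#' @param sentence_id opaque sentence identifier.
#' @param language opaque language label.
#' @param extra optional data.frame of carried CoNLL-U columns
#'   (`lemma`, `xpos`, `feats`, `deprel`, `deps`, `misc`) for round-tripping.
#' @param meta named character vector of comment metadata (minus `sent_id`).
#'
#' @return an object of class `dep_tree`.
#' @seealso [validate_tree()], [parse_conllu()]
#' @examples
#' t <- dep_tree(c(2L, 0L, 2L))  # 3-word tree rooted at position 2
#' validate_tree(t)              # character(0): valid
#' @export
dep_tree <- function(heads, forms = NULL, upos = NULL,
                     sentence_id = NA_character_, language = NA_character_,
                     extra = NULL, meta = NULL) {
  heads <- as.integer(heads)
  n <- length(heads)
  if (is.null(forms)) forms <- paste0("w", seq_len(n))
  if (is.null(upos)) upos <- rep("X", n)
  stopifnot(length(forms) == n, length(upos) == n)
  structure(
    list(heads = heads, forms = as.character(forms), upos = as.character(upos),
         n_words = n, sentence_id = as.character(sentence_id),
         language = as.character(language), extra = extra, meta = meta),
    class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat(sprintf("<dep_tree> %s%s: %d words\n",
              if (is.na(x$sentence_id)) "(unnamed)" else x$sentence_id,
              if (is.na(x$language)) "" else paste0(" [", x$language, "]"),
              x$n_words))
  cat(" heads:", paste(x$heads, collapse = " "), "\n")
  invisible(x)
}

#' Validate a dependency tree
#'
#' Checks the `dep_tree` invariants: exactly one root (head 0), all head
#' positions in range, no self-heading, and a fully connected acyclic head
#' relation. This is a reporting operation: it never throws.
#'
#' @param tree a [dep_tree()].
#' @return character vector of violation descriptions; `character(0)` iff the
#'   tree is valid.
#' @examples
#' validate_tree(dep_tree(c(0L, 1L)))       # valid
#' validate_tree(dep_tree(c(2L, 1L)))       # cycle, no root
#' @export
validate_tree <- function(tree) {
  heads <- tree$heads
  n <- length(heads)
  report <- character(0)
  if (n < 1) return("empty tree")
  n_roots <- sum(heads == 0L)
  if (n_roots == 0L) report <- c(report, "no root")
  if (n_roots > 1L) report <- c(report, "multiple roots")
  oor <- which(heads < 0L | heads > n)
  if (length(oor)) report <- c(report, sprintf("head out of range at position %d", oor))
  selfh <- which(heads == seq_len(n))
  if (length(selfh)) report <- c(report, sprintf("self-headed word at position %d", selfh))
  if (!length(report)) {
    # walk to root from every node; a cycle never reaches 0 within n steps
    for (i in seq_len(n)) {
      w <- i
      for (step in seq_len(n)) {
        w <- heads[w]
        if (w == 0L) break
      }
      if (w != 0L) {
        report <- c(report, "cyclic")
        break
      }
    }
  }
  report
}

#' Assert that a tree is valid, stopping otherwise
#' @param tree a [dep_tree()].
#' @return `tree`, invisibly.
#' @keywords internal
stopifnot_valid <- function(tree) {
  rep <- validate_tree(tree)
  if (length(rep))
    stop("invalid dep_tree", if (!is.na(tree$sentence_id)) paste0(" '", tree$sentence_id, "'"),
         ": ", paste(rep, collapse = "; "), call. = FALSE)
  invisible(tree)
}

#' Construct a corpus (list of dependency trees)
#' @param trees list of [dep_tree()] objects.
#' @return object of class `dep_corpus` (a list).
#' @export
dep_corpus <- function(trees) {
  stopifnot(all(vapply(trees, inherits, logical(1), "dep_tree")))
  structure(trees, class = c("dep_corpus", "list"))
}

#' @export
print.dep_corpus <- function(x, ...) {
  n <- length(x)
  lens <- vapply(x, function(t) t$n_words, integer(1))
  langs <- unique(vapply(x, function(t) t$language, character(1)))
  cat(sprintf("<dep_corpus> %d sentences, %d language(s), lengths %s..%s\n",
              n, length(langs), if (n) min(lens) else "-", if (n) max(lens) else "-"))
  invisible(x)
}

#' @export
`[.dep_corpus` <- function(x, i) {
  dep_corpus(unclass(x)[i])
}
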