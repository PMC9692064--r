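# Per-dependency complexity metrics.
#
# Conventions (fixed package-wide):
#  * dependency length (DL) of an edge = number of words strictly between head
#    and dependent (adjacent words have DL 0), not |i - j|;
#  * intervener complexity (IC) of an edge = number of those intervening words
#    that are syntactic heads, i.e. have >= 1 dependent ANYWHERE in the
#    sentence; intervening terminal dependents (leaves) do not count;
#  * the artificial-root attachment has no linear position and is excluded
#    from all per-edge aggregates.

# ---- lean internals over a plain integer head vector -----------------------

# logical n x n matrix: dom[w, a] TRUE iff a dominates w (reflexive-transitive)
.dominates <- function(heads) {
  n <- length(heads)
  dom <- diag(TRUE, n)
  for (i in seq_len(n)) {
    w <- heads[i]
    while (w != 0L) {
      dom[i, w] <- TRUE
      w <- heads[w]
    }
  }
  dom
}

.is_head <- function(heads) tabulate(heads[heads > 0L], nbins = length(heads)) > 0L

.dl_vec <- function(heads) {
  d <- which(heads > 0L)
  abs(heads[d] - d) - 1L
}

.ic_vec <- function(heads) {
  ih <- .is_head(heads)
  d <- which(heads > 0L)
  vapply(d, function(i) {
    h <- heads[i]
    lo <- min(h, i); hi <- max(h, i)
    if (hi - lo < 2L) 0L else sum(ih[(lo + 1L):(hi - 1L)])
  }, integer(1))
}

# number of edges h->d with an intervener not dominated by h
.np_count <- function(heads) {
  dom <- .dominates(heads)
  cnt <- 0L
  for (i in which(heads > 0L)) {
    h <- heads[i]
    lo <- min(h, i); hi <- max(h, i)
    if (hi - lo >= 2L && any(!dom[(lo + 1L):(hi - 1L), h])) cnt <- cnt + 1L
  }
  cnt
}

# number of unordered edge pairs whose spans strictly interleave; the root
# attachment is included as a virtual edge from position 0, so an edge
# covering the root word crosses it (keeping the zero set identical to the
# edge-level non-projectivity count)
.crossing_pairs_count <- function(heads) {
  d <- which(heads > 0L)
  lo <- c(pmin(heads[d], d), 0L)
  hi <- c(pmax(heads[d], d), which(heads == 0L))
  d <- c(d, 0L)
  m <- length(d)
  cnt <- 0L
  if (m >= 2L) {
    for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
      if ((lo[a] < lo[b] && lo[b] < hi[a] && hi[a] < hi[b]) ||
          (lo[b] < lo[a] && lo[a] < hi[b] && hi[b] < hi[a])) cnt <- cnt + 1L
    }
  }
  cnt
}

.check_edge <- function(tree, head_pos, dep_pos) {
  if (dep_pos < 1L || dep_pos > tree$n_words || tree$heads[dep_pos] != head_pos)
    stop(sprintf("edge %d -> %d not in tree", head_pos, dep_pos), call. = FALSE)
}

# ---- exported per-edge operations ------------------------------------------

#' Dependency length of one edge
#'
#' Number of words strictly intervening between head and dependent; adjacent
#' words have length 0.
#'
#' @param tree a [dep_tree()].
#' @param head_pos,dep_pos positions of the edge's head and dependent; the
#'   edge must exist in the tree.
#' @return non-negative integer.
#' @export
edge_dl <- function(tree, head_pos, dep_pos) {
  .check_edge(tree, head_pos, dep_pos)
  abs(head_pos - dep_pos) - 1L
}

#' Intervener complexity of one edge
#'
#' Number of intervening words that are syntactic heads (have at least one
#' dependent anywhere in the sentence). Intervening leaves do not count, so
#' `edge_ic <= edge_dl` always.
#'
#' @inheritParams edge_dl
#' @return non-negative integer, at most [edge_dl()].
#' @export
edge_ic <- function(tree, head_pos, dep_pos) {
  .check_edge(tree, head_pos, dep_pos)
  lo <- min(head_pos, dep_pos); hi <- max(head_pos, dep_pos)
  if (hi - lo < 2L) return(0L)
  sum(.is_head(tree$heads)[(lo + 1L):(hi - 1L)])
}

#' Arity of a node (its number of dependents)
#' @param tree a [dep_tree()].
#' @param pos word position.
#' @return non-negative integer.
#' @export
node_arity <- function(tree, pos) {
  stopifnot(pos >= 1L, pos <= tree$n_words)
  sum(tree$heads == pos)
}

#' Is an edge non-projective?
#'
#' An edge head -> dependent is non-projective (a crossing dependency) iff
#' some word strictly between them is not dominated, directly or indirectly,
#' by the head.
#'
#' @inheritParams edge_dl
#' @return logical scalar.
#' @export
nonprojective_edge <- function(tree, head_pos, dep_pos) {
  .check_edge(tree, head_pos, dep_pos)
  lo <- min(head_pos, dep_pos); hi <- max(head_pos, dep_pos)
  if (hi - lo < 2L) return(FALSE)
  dom <- .dominates(tree$heads)
  any(!dom[(lo + 1L):(hi - 1L), head_pos])
}

#' Count crossing dependencies in a tree
#'
#' Two counting conventions are supported. `"nonprojective_edges"` (default,
#' used for baseline matching) counts edges for which [nonprojective_edge()]
#' is true; `"crossing_pairs"` counts unordered pairs of edges whose linear
#' spans strictly interleave, with the root attachment included as a virtual
#' edge from position 0 (an edge covering the root word crosses it). Both
#' methods are zero exactly when the tree is projective, though the counts
#' can differ on non-projective trees (one edge may cross several others).
#'
#' @param tree a [dep_tree()].
#' @param method `"nonprojective_edges"` or `"crossing_pairs"`.
#' @return non-negative integer.
#' @export
crossing_count <- function(tree, method = c("nonprojective_edges", "crossing_pairs")) {
  method <- match.arg(method)
  if (method == "nonprojective_edges") .np_count(tree$heads)
  else .crossing_pairs_count(tree$heads)
}

#' Depth of a tree
#'
#' Length of the longest root-to-leaf path counted in words: the root word has
#' depth 1, so a chain of n words has depth n and any star has depth 2.
#'
#' @param tree a [dep_tree()].
#' @return positive integer.
#' @export
tree_depth <- function(tree) {
  heads <- tree$heads
  depth <- integer(length(heads))
  dfun <- function(i) {
    if (depth[i] > 0L) return(depth[i])
    d <- if (heads[i] == 0L) 1L else dfun(heads[i]) + 1L
    depth[i] <<- d
    d
  }
  max(vapply(seq_along(heads), dfun, integer(1)))
}

#' Per-edge metrics table
#'
#' @param tree a [dep_tree()].
#' @return data.frame with one row per word-word dependency: `head_pos`,
#'   `dep_pos`, `dl`, `ic`, `nonprojective`.
#' @export
edge_metrics <- function(tree) {
  heads <- tree$heads
  d <- which(heads > 0L)
  dom <- .dominates(heads)
  ih <- .is_head(heads)
  np <- vapply(d, function(i) {
    h <- heads[i]; lo <- min(h, i); hi <- max(h, i)
    hi - lo >= 2L && any(!dom[(lo + 1L):(hi - 1L), h])
  }, logical(1))
  data.frame(head_pos = heads[d], dep_pos = d,
             dl = abs(heads[d] - d) - 1L,
             ic = .ic_vec(heads),
             nonprojective = np)
}

#' Per-sentence metric summary
#'
#' Aggregates the per-edge metrics of one sentence: mean dependency length and
#' mean intervener complexity over the `n_words - 1` word-word dependencies
#' (the root attachment is excluded), the crossing count, arity statistics and
#' tree depth.
#'
#' @param tree a valid [dep_tree()] with at least 2 words.
#' @param crossing_method passed to [crossing_count()].
#' @return one-row data.frame with columns `sentence_id`, `language`,
#'   `n_words`, `mean_dl`, `mean_ic`, `crossing_count`, `max_arity`,
#'   `mean_arity`, `depth`.
#' @export
sentence_summary <- function(tree, crossing_method = "nonprojective_edges") {
  stopifnot_valid(tree)
  if (tree$n_words < 2L) stop("no dependencies: tree has fewer than 2 words", call. = FALSE)
  heads <- tree$heads
  ar <- tabulate(heads[heads > 0L], nbins = tree$n_words)
  data.frame(sentence_id = tree$sentence_id, language = tree$language,
             n_words = tree$n_words,
             mean_dl = mean(.dl_vec(heads)),
             mean_ic = mean(.ic_vec(heads)),
             crossing_count = crossing_count(tree, crossing_method),
             max_arity = max(ar), mean_arity = mean(ar),
             depth = tree_depth(tree),
             stringsAsFactors = FALSE)
}

#' Per-sentence metrics for a whole corpus
#' @param corpus a [dep_corpus()].
#' @param crossing_method passed to [crossing_count()].
#' @return data.frame, one row per sentence (see [sentence_summary()]).
#' @export
corpus_metrics <- function(corpus, crossing_method = "nonprojective_edges") {
  do.call(rbind, lapply(corpus, sentence_summary, crossing_method = crossing_method))
}
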