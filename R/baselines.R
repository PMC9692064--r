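# Six constrained random baselines. Each baseline tree matches its reference
# real tree in sentence length and in the number of crossing dependencies
# (edge-level count); the dl_matched_* / ic_matched_* families additionally
# match the multiset of per-edge DL / IC values, and the *_rla families
# preserve the reference's full tree topology by permuting word order only.
# Candidates are drawn uniformly (Pruefer codes for structures, uniform
# permutations for linear arrangements) and filtered by rejection sampling, so
# accepted samples are uniform over the constraint-satisfying set.

BASELINE_KINDS <- c("random_structures", "rla",
                    "dl_matched_random_structures", "dl_matched_rla",
                    "ic_matched_random_structures", "ic_matched_rla")

#' Baseline specification
#'
#' @param kind one of `"random_structures"`, `"rla"`,
#'   `"dl_matched_random_structures"`, `"dl_matched_rla"`,
#'   `"ic_matched_random_structures"`, `"ic_matched_rla"`.
#' @param max_attempts rejection-sampling budget per real tree (default 1e5).
#' @param seed integer RNG seed; per-tree streams are derived from it so a
#'   corpus regenerates identically.
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind, max_attempts = 100000L, seed = 1L) {
  kind <- match.arg(kind, BASELINE_KINDS)
  max_attempts <- as.integer(max_attempts)
  if (max_attempts <= 0L) stop("max_attempts must be positive", call. = FALSE)
  structure(list(kind = kind, max_attempts = max_attempts, seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Decode a Pruefer sequence into a labeled tree
#'
#' Standard decode: repeatedly join the smallest current leaf (a label absent
#' from the remaining sequence) to the sequence head; finally join the two
#' remaining leaves. Every sequence in `{1..n}^(n-2)` yields a distinct
#' labeled tree on `n` nodes (Cayley bijection).
#'
#' @param seq integer vector of length `n - 2` with entries in `1..n`
#'   (empty for `n = 2`).
#' @param n number of nodes (>= 2).
#' @return `(n-1) x 2` integer matrix of undirected edges.
#' @export
prufer_decode <- function(seq, n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  seq <- as.integer(seq)
  if (length(seq) != n - 2L)
    stop("sequence length must be n - 2", call. = FALSE)
  if (length(seq) && any(seq < 1L | seq > n))
    stop("sequence entries out of range 1..n", call. = FALSE)
  deg <- tabulate(seq, nbins = n) + 1L
  edges <- matrix(NA_integer_, nrow = n - 1L, ncol = 2L)
  for (k in seq_along(seq)) {
    u <- which(deg == 1L)[1L]       # smallest leaf not in remaining sequence
    v <- seq[k]
    edges[k, ] <- c(u, v)
    deg[u] <- 0L
    deg[v] <- deg[v] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# orient undirected edges away from root -> head vector
.orient <- function(edges, n, root) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  heads <- integer(n)
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE
      heads[w] <- v
      queue <- c(queue, w)
    }
  }
  heads
}

# one uniform rooted labeled tree on 1..n as a head vector
.sample_structure_heads <- function(n) {
  edges <- if (n == 2L) matrix(c(1L, 2L), 1L) else
    prufer_decode(sample.int(n, n - 2L, replace = TRUE), n)
  .orient(edges, n, sample.int(n, 1L))
}

# uniform random linear arrangement of a head vector
.rla_heads <- function(heads) {
  n <- length(heads)
  p <- sample.int(n)                 # p[i] = new position of word i
  nh <- integer(n)
  idx <- heads > 0L
  nh[p[idx]] <- p[heads[idx]]
  nh
}

#' Sample a uniform random rooted tree structure
#'
#' Draws a uniform Pruefer sequence, decodes it, and roots the tree at a
#' uniformly chosen node, giving the uniform distribution over the
#' `n^(n-1)` rooted labeled trees; labels are the linear positions.
#'
#' @param n number of words (>= 2).
#' @param language,sentence_id labels attached to the sampled tree.
#' @return a [dep_tree()].
#' @export
sample_random_structure <- function(n, language = NA_character_,
                                    sentence_id = NA_character_) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  dep_tree(.sample_structure_heads(n), language = language, sentence_id = sentence_id)
}

#' Sample a random linear arrangement of a tree
#'
#' Permutes word order by a uniform random permutation while preserving the
#' dependency relation among word identities, then re-indexes to positions
#' `1..n`. Arity multiset, depth and rooted shape are preserved by
#' construction.
#'
#' @param tree a valid [dep_tree()].
#' @return a [dep_tree()] with the permuted order.
#' @export
sample_rla <- function(tree) {
  dep_tree(.rla_heads(tree$heads), sentence_id = tree$sentence_id,
           language = tree$language)
}

# reference statistics consumed by the rejection test
.ref_stats <- function(heads, kind) {
  list(n = length(heads),
       crossings = .np_count(heads),
       dl = if (startsWith(kind, "dl_matched")) sort(.dl_vec(heads)),
       ic = if (startsWith(kind, "ic_matched")) sort(.ic_vec(heads)))
}

# rejection test on a candidate head vector (cheap checks first)
.matches <- function(cand, ref, kind) {
  if (startsWith(kind, "dl_matched") && !identical(sort(.dl_vec(cand)), ref$dl))
    return(FALSE)
  if (startsWith(kind, "ic_matched") && !identical(sort(.ic_vec(cand)), ref$ic))
    return(FALSE)
  .np_count(cand) == ref$crossings
}

#' Does a candidate tree satisfy a baseline's matching constraints?
#'
#' All kinds require equal crossing counts (edge-level non-projectivity
#' count); `dl_matched_*` kinds additionally require equal multisets of
#' per-edge dependency lengths, `ic_matched_*` equal multisets of per-edge
#' intervener complexities. (Multisets rather than ordered sequences: random
#' structure candidates have no positional edge correspondence with the
#' reference.)
#'
#' @param candidate,reference [dep_tree()] objects with equal `n_words`.
#' @param kind a baseline kind (see [baseline_spec()]).
#' @return logical scalar.
#' @export
matches_constraints <- function(candidate, reference, kind) {
  kind <- match.arg(kind, BASELINE_KINDS)
  if (candidate$n_words != reference$n_words)
    stop("candidate and reference differ in n_words", call. = FALSE)
  .matches(candidate$heads, .ref_stats(reference$heads, kind), kind)
}

#' Generate one baseline tree for a real tree by rejection sampling
#'
#' Draws candidates uniformly -- random rooted structures for the
#' `*_random_structures` kinds, random linear arrangements of the reference
#' for the `*_rla` kinds -- until [matches_constraints()] holds or the attempt
#' budget is exhausted. Exhaustion is a typed failure, not an error.
#'
#' @param tree the real (reference) [dep_tree()].
#' @param spec a [baseline_spec()].
#' @param use_seed if `TRUE` (default) seed the RNG from `spec$seed`; set
#'   `FALSE` when the caller manages the stream (as
#'   [generate_baseline_corpus()] does).
#' @return list of class `baseline_result`: `success` flag, `attempts` used,
#'   and on success `tree` (a [dep_tree()] whose `meta` records the kind, the
#'   seed and the attempts used).
#' @export
generate_baseline <- function(tree, spec, use_seed = TRUE) {
  stopifnot(inherits(spec, "baseline_spec"))
  stopifnot_valid(tree)
  if (use_seed) set.seed(spec$seed)
  res <- .cpp_generate_baseline(tree$heads, spec$kind, spec$max_attempts)
  if (res$success) {
    out <- dep_tree(res$heads, sentence_id = tree$sentence_id,
                    language = tree$language,
                    meta = c(baseline_kind = spec$kind,
                             seed = as.character(spec$seed),
                             attempts = as.character(res$attempts)))
    structure(list(success = TRUE, attempts = res$attempts, tree = out),
              class = "baseline_result")
  } else {
    structure(list(success = FALSE, attempts = spec$max_attempts, tree = NULL),
              class = "baseline_result")
  }
}

# deterministic per-tree seed from (global seed, corpus index), < 2^31
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

#' Generate a baseline corpus paired to a real corpus
#'
#' Attempts one baseline tree per real tree. Per-tree RNG streams are derived
#' from `spec$seed` and the tree's corpus index, so regeneration is
#' deterministic and independent of evaluation order. Trees whose budget is
#' exhausted are excluded (the pairing is by sentence index/id; callers should
#' drop the corresponding real trees too, as [build_observation_table()]
#' does).
#'
#' @param corpus a [dep_corpus()] of real trees.
#' @param spec a [baseline_spec()].
#' @return list with elements `baseline` (a [dep_corpus()] of the successful
#'   baseline trees), `paired_real` (the matching subset of `corpus`), and
#'   `report` -- a list with `per_tree` (data.frame: index, sentence id,
#'   n_words, attempts, success) and `acceptance_by_length` (data.frame of
#'   mean acceptance rate `1/attempts` and success rate per sentence length).
#' @export
generate_baseline_corpus <- function(corpus, spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  m <- length(corpus)
  res <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(.derive_seed(spec$seed, i))
    res[[i]] <- generate_baseline(corpus[[i]], spec, use_seed = FALSE)
  }
  ok <- vapply(res, `[[`, logical(1), "success")
  per_tree <- data.frame(
    index = seq_len(m),
    sentence_id = vapply(corpus, function(t) t$sentence_id, character(1)),
    n_words = vapply(corpus, function(t) t$n_words, integer(1)),
    attempts = vapply(res, `[[`, integer(1), "attempts"),
    success = ok,
    stringsAsFactors = FALSE)
  by_len <- if (m) {
    agg <- split(per_tree, per_tree$n_words)
    do.call(rbind, lapply(agg, function(d) data.frame(
      n_words = d$n_words[1],
      n_trees = nrow(d),
      success_rate = mean(d$success),
      mean_attempts = mean(d$attempts))))
  } else data.frame(n_words = integer(0), n_trees = integer(0),
                    success_rate = numeric(0), mean_attempts = numeric(0))
  list(baseline = dep_corpus(lapply(res[ok], `[[`, "tree")),
       paired_real = corpus[ok],
       report = list(per_tree = per_tree, acceptance_by_length = by_len))
}
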