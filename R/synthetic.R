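# Synthetic treebank generator. Not a model of any natural language: it
# exists so that every pipeline stage can be exercised without external
# downloads and so that word-order preferences of KNOWN direction (dependency
# lengths minimized, or intervening heads avoided, or neither) can be planted
# and recovered end-to-end.

#' Truncated-geometric arity sampler
#'
#' Returns a sampler of dependent counts per head: geometric on `0,1,2,...`
#' truncated at `max_arity`, with the given (pre-truncation) mean. The default
#' mean of 0.9 mirrors the fact that a tree on n words has n-1 dependencies,
#' so the average node has just under one dependent.
#'
#' @param mean mean of the untruncated geometric (`p = 1/(1+mean)`).
#' @param max_arity truncation bound.
#' @return function(m) returning m integer draws.
#' @export
arity_geometric <- function(mean = 0.9, max_arity = 8L) {
  stopifnot(mean > 0)
  p <- 1 / (1 + mean)
  function(m) pmin(stats::rgeom(m, p), as.integer(max_arity))
}

#' Grow an unordered rooted tree shape
#'
#' Starts from a root and repeatedly attaches dependents, drawing each node's
#' dependent count from `arity_sampler`, until exactly `n` nodes exist (the
#' last allocation is truncated). If every pending node draws zero dependents
#' before `n` is reached, one extra dependent is attached to a uniformly
#' chosen existing node and growth continues.
#'
#' @param n number of nodes (>= 2).
#' @param arity_sampler function(m) -> m non-negative integer draws, e.g.
#'   [arity_geometric()].
#' @return integer head vector over node ids in creation order (id 1 = root,
#'   head 0). Creation order carries no linear-order meaning; see the
#'   linearizers.
#' @export
gen_tree_shape <- function(n, arity_sampler = arity_geometric()) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  heads <- integer(n)
  total <- 1L
  queue <- 1L
  qi <- 1L
  while (total < n) {
    if (qi > length(queue)) {
      parent <- sample.int(total, 1L)
      total <- total + 1L
      heads[total] <- parent
      queue <- c(queue, total)
      next
    }
    node <- queue[qi]
    qi <- qi + 1L
    k <- min(arity_sampler(1L), n - total)
    if (k > 0L) for (j in seq_len(k)) {
      total <- total + 1L
      heads[total] <- node
      queue <- c(queue, total)
    }
  }
  heads
}

# shared recursive placement machinery: returns node ids in linear order.
# `child_order(idx, sizes, is_leaf)` returns the placement order (first =
# closest to the head); sides alternate, starting on the side AWAY from the
# parent so each subtree's root hugs the end facing its head (a chain then
# linearizes with every edge adjacent). The root's starting side is random.
.place_alternating <- function(shape_heads, child_order) {
  n <- length(shape_heads)
  kids_list <- vector("list", n)
  for (w in which(shape_heads > 0L))
    kids_list[[shape_heads[w]]] <- c(kids_list[[shape_heads[w]]], w)
  # subtree sizes, processing deeper nodes first
  depth <- integer(n)
  for (v in seq_len(n)) {
    w <- v
    while (shape_heads[w] > 0L) { depth[v] <- depth[v] + 1L; w <- shape_heads[w] }
  }
  sz <- rep(1L, n)
  for (v in order(depth, decreasing = TRUE))
    if (shape_heads[v] > 0L) sz[shape_heads[v]] <- sz[shape_heads[v]] + sz[v]

  rec <- function(v, outward) {
    kids <- kids_list[[v]]
    if (!length(kids)) return(v)
    ord <- child_order(seq_along(kids), sz[kids], sz[kids] == 1L)
    side_left <- if (is.na(outward)) stats::runif(1) < 0.5 else outward == "left"
    left <- list(); right <- list()
    for (k in kids[ord]) {
      b <- rec(k, if (side_left) "left" else "right")
      if (side_left) left <- c(left, list(b)) else right <- c(right, list(b))
      side_left <- !side_left
    }
    c(unlist(rev(left)), v, unlist(right))
  }
  rec(which(shape_heads == 0L), NA)
}

# convert (shape heads over node ids, linear order of node ids) -> dep_tree
.shape_to_tree <- function(shape_heads, order, sentence_id, language) {
  pos <- integer(length(order))
  pos[order] <- seq_along(order)
  heads <- integer(length(order))
  idx <- shape_heads > 0L
  heads[pos[idx]] <- pos[shape_heads[idx]]
  dep_tree(heads, sentence_id = sentence_id, language = language)
}

#' Dependency-length-minimizing projective linearization
#'
#' Classic greedy heuristic: each head's dependents are placed on alternating
#' sides in increasing order of subtree size, smallest closest to the head
#' (ties and the starting side broken by the RNG). Output is always
#' projective, and its mean dependency length is stochastically no larger
#' than that of a uniform random projective linearization of the same shape.
#'
#' @param shape_heads head vector from [gen_tree_shape()].
#' @param sentence_id,language labels for the resulting tree.
#' @return a projective [dep_tree()].
#' @export
dlm_greedy_linearize <- function(shape_heads, sentence_id = NA_character_,
                                 language = NA_character_) {
  ord <- .place_alternating(shape_heads, function(kids, sizes, is_leaf)
    order(sizes, stats::runif(length(kids))))
  .shape_to_tree(shape_heads, ord, sentence_id, language)
}

#' Intervener-complexity-biased projective linearization
#'
#' Places each head's LEAF dependents adjacent to it before any head-bearing
#' subtree (within each group, smaller blocks first; ties by RNG), sides
#' alternating. Words intervening near a head are therefore predominantly
#' terminal, lowering intervener complexity relative to a uniform random
#' projective linearization of the same shape.
#'
#' @inheritParams dlm_greedy_linearize
#' @return a projective [dep_tree()].
#' @export
icm_biased_linearize <- function(shape_heads, sentence_id = NA_character_,
                                 language = NA_character_) {
  ord <- .place_alternating(shape_heads, function(kids, sizes, is_leaf)
    order(!is_leaf, sizes, stats::runif(length(kids))))
  .shape_to_tree(shape_heads, ord, sentence_id, language)
}

#' Uniform random projective linearization
#'
#' At every node, the node and its child subtree blocks are shuffled
#' uniformly; the induced distribution is uniform over all projective
#' linearizations of the shape.
#'
#' @inheritParams dlm_greedy_linearize
#' @return a projective [dep_tree()].
#' @export
random_projective_linearize <- function(shape_heads, sentence_id = NA_character_,
                                        language = NA_character_) {
  n <- length(shape_heads)
  children <- split(seq_len(n)[shape_heads > 0L], shape_heads[shape_heads > 0L])
  rec <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(v)
    blocks <- c(list(v), lapply(kids, rec))
    unlist(blocks[sample.int(length(blocks))])
  }
  .shape_to_tree(shape_heads, rec(which(shape_heads == 0L)), sentence_id, language)
}

#' Synthetic corpus specification
#'
#' Defaults emulate the short-sentence profile this package targets: lengths
#' uniform on 3..11, arity geometric with mean 0.9 dependents per node, and a
#' 5% rate of trees carrying a crossing dependency (crossings are rare in
#' natural language).
#'
#' @param n_languages number of language groups.
#' @param sentences_per_language sentences per language.
#' @param length_probs named numeric vector of sentence-length probabilities
#'   (names = lengths); must sum to 1.
#' @param arity_sampler dependent-count sampler, e.g. [arity_geometric()].
#' @param ordering_policy `"uniform_random"` (uniform projective order),
#'   `"dlm_greedy"` (dependency lengths minimized) or `"icm_biased"`
#'   (intervening heads avoided).
#' @param crossing_rate fraction of trees given one crossing-creating adjacent
#'   transposition (when the shape admits one).
#' @param seed integer RNG seed.
#' @return object of class `synth_corpus_spec`.
#' @export
synth_corpus_spec <- function(n_languages = 5L, sentences_per_language = 100L,
                              length_probs = NULL,
                              arity_sampler = arity_geometric(),
                              ordering_policy = c("uniform_random", "dlm_greedy",
                                                  "icm_biased"),
                              crossing_rate = 0.05, seed = 1L) {
  ordering_policy <- match.arg(ordering_policy)
  if (is.null(length_probs)) {
    length_probs <- rep(1 / 9, 9)
    names(length_probs) <- 3:11
  }
  stopifnot(abs(sum(length_probs) - 1) < 1e-8,
            crossing_rate >= 0, crossing_rate <= 1,
            !is.null(names(length_probs)))
  structure(list(n_languages = as.integer(n_languages),
                 sentences_per_language = as.integer(sentences_per_language),
                 length_probs = length_probs, arity_sampler = arity_sampler,
                 ordering_policy = ordering_policy,
                 crossing_rate = crossing_rate, seed = as.integer(seed)),
            class = "synth_corpus_spec")
}

# apply one adjacent transposition of positions (j, j+1) to a head vector
.adjacent_swap <- function(heads, j) {
  n <- length(heads)
  t <- seq_len(n)
  t[c(j, j + 1L)] <- c(j + 1L, j)
  nh <- integer(n)
  idx <- heads > 0L
  nh[t] <- ifelse(idx, t[pmax(heads, 1L)], 0L)
  nh
}

# try adjacent transpositions in random order until one creates a crossing;
# returns the original heads if the shape is projective under every order
.inject_crossing <- function(heads) {
  n <- length(heads)
  for (j in sample.int(n - 1L)) {
    cand <- .adjacent_swap(heads, j)
    if (.np_count(cand) > 0L) return(cand)
  }
  heads
}

#' Generate a synthetic multi-language corpus
#'
#' Deterministic given `spec$seed`. Each sentence draws a length, grows a
#' shape, linearizes it under the ordering policy, and with probability
#' `crossing_rate` receives one adjacent transposition that creates at least
#' one crossing dependency (shapes projective under every order are left
#' untouched).
#'
#' @param spec a [synth_corpus_spec()].
#' @return a [dep_corpus()] with languages `L01`, `L02`, ... and sentence ids
#'   `<language>_s<k>`.
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_corpus_spec"))
  set.seed(spec$seed)
  lens <- as.integer(names(spec$length_probs))
  linearize <- switch(spec$ordering_policy,
    uniform_random = random_projective_linearize,
    dlm_greedy = dlm_greedy_linearize,
    icm_biased = icm_biased_linearize)
  trees <- vector("list", spec$n_languages * spec$sentences_per_language)
  k <- 0L
  for (lg in seq_len(spec$n_languages)) {
    lang <- sprintf("L%02d", lg)
    for (s in seq_len(spec$sentences_per_language)) {
      n <- sample(lens, 1L, prob = spec$length_probs)
      shape <- gen_tree_shape(n, spec$arity_sampler)
      tr <- linearize(shape, sentence_id = sprintf("%s_s%03d", lang, s),
                      language = lang)
      if (spec$crossing_rate > 0 && stats::runif(1) < spec$crossing_rate) {
        tr <- dep_tree(.inject_crossing(tr$heads), sentence_id = tr$sentence_id,
                       language = tr$language)
      }
      k <- k + 1L
      trees[[k]] <- tr
    }
  }
  dep_corpus(trees)
}
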