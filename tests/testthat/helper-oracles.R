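# Fixture trees and independent brute-force oracles. Oracles deliberately use
# different algorithms from the package internals (descendant-set expansion
# instead of ancestor walks, explicit pair loops, exhaustive enumeration).

# -- fixture trees -----------------------------------------------------------

# six-word schematic: head at 1, dependent at 6, interveners 2..5 all
# terminal dependents of the head (low-intervener-complexity variant)
f6_flat <- function() dep_tree(c(0L, 1L, 1L, 1L, 1L, 1L))

# same span, interveners forming a chain of heads 2<-3<-4<-5, 5 attached to 6
# (high-intervener-complexity variant)
f6_chain <- function() dep_tree(c(0L, 3L, 4L, 5L, 6L, 1L))

chain_tree <- function(n) dep_tree(c(0L, seq_len(n - 1L)))          # 1<-2<-...<-n
star_tree <- function(n, center = 1L) {
  heads <- rep(center, n); heads[center] <- 0L
  dep_tree(as.integer(heads))
}

# 4-word tree with one non-projective edge: heads h(2)=4, h(3)=1, h(4)=1
np4_tree <- function() dep_tree(c(0L, 4L, 1L, 1L))

# -- oracles -----------------------------------------------------------------

# descendant matrix by iterated expansion: desc[a, w] TRUE iff a dominates w
# (reflexive-transitive), independent of the package's ancestor walks
oracle_dominates <- function(heads) {
  n <- length(heads)
  adj <- matrix(FALSE, n, n)
  for (w in seq_len(n)) if (heads[w] > 0L) adj[heads[w], w] <- TRUE
  desc <- diag(TRUE, n)
  repeat {
    nxt <- desc | (desc %*% adj > 0)
    if (identical(nxt, desc)) break
    desc <- nxt
  }
  desc
}

oracle_np_edges <- function(heads) {
  desc <- oracle_dominates(heads)
  cnt <- 0L
  for (d in which(heads > 0L)) {
    h <- heads[d]
    between <- setdiff(seq(min(h, d), max(h, d)), c(h, d))
    if (length(between) && any(!desc[h, between])) cnt <- cnt + 1L
  }
  cnt
}

# pairwise crossing count: edges cross iff exactly one endpoint of one edge
# lies strictly inside the other's span (shared endpoints cannot cross);
# the root attachment participates as an edge from virtual position 0
oracle_crossing_pairs <- function(heads) {
  edges <- lapply(which(heads > 0L), function(d) c(heads[d], d))
  edges <- c(edges, list(c(0L, which(heads == 0L))))
  cnt <- 0L
  m <- length(edges)
  if (m < 2L) return(0L)
  for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
    e1 <- edges[[a]]; e2 <- edges[[b]]
    if (length(intersect(e1, e2))) next
    inside <- e2 > min(e1) & e2 < max(e1)
    if (sum(inside) == 1L) cnt <- cnt + 1L
  }
  cnt
}

oracle_ic <- function(heads, h, d) {
  kids <- function(v) sum(heads == v)
  between <- setdiff(seq(min(h, d), max(h, d)), c(h, d))
  sum(vapply(between, function(w) kids(w) > 0L, logical(1)))
}

oracle_mean_dl <- function(heads) {
  d <- which(heads > 0L)
  mean(abs(heads[d] - d) - 1L)
}

# all valid head vectors on n words (exhaustive enumeration over {0..n}^n)
enumerate_rooted_trees <- function(n) {
  grid <- do.call(expand.grid, rep(list(0:n), n))
  keep <- list()
  for (r in seq_len(nrow(grid))) {
    heads <- as.integer(grid[r, ])
    if (sum(heads == 0L) != 1L) next
    if (!length(validate_tree(dep_tree(heads)))) keep[[length(keep) + 1L]] <- heads
  }
  keep
}

perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, p + (p >= k))))
}

# relinearize a head vector under permutation p (p[i] = new position of word i)
apply_perm <- function(heads, p) {
  nh <- integer(length(heads))
  idx <- heads > 0L
  nh[p] <- 0L
  nh[p[idx]] <- p[heads[idx]]
  as.integer(nh)
}

# chi-square GOF p-value against the uniform distribution; `counts` must
# cover every category (zeros included)
chisq_uniform_p <- function(counts) {
  suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / length(counts), length(counts)))$p.value)
}
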