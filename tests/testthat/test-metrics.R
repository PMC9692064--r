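test_that("edge_dl counts strictly intervening words", {
  tr <- chain_tree(7)
  expect_equal(edge_dl(tr, 2, 3), 0L)          # adjacent pair
  tr2 <- dep_tree(c(0L, 1L, 1L, 1L, 1L, 2L))   # edge 2 -> 6 spans 3,4,5
  expect_equal(edge_dl(tr2, 2, 6), 3L)
  expect_error(edge_dl(tr, 5, 2), "not in tree")
})

test_that("the two six-word schematic structures have equal DL but different IC", {
  a <- f6_flat(); b <- f6_chain()
  expect_equal(edge_dl(a, 1, 6), 4L)
  expect_equal(edge_dl(b, 1, 6), 4L)
  expect_equal(edge_dl(a, 1, 6), edge_dl(b, 1, 6))
  expect_equal(edge_ic(a, 1, 6), 0L)           # all interveners terminal
  expect_equal(edge_ic(b, 1, 6), oracle_ic(b$heads, 1, 6))
  expect_equal(edge_ic(b, 1, 6), 3L)           # chain interveners: 3 heads
  expect_gt(edge_ic(b, 1, 6), edge_ic(a, 1, 6))
})

test_that("edge_ic counts only intervening words with dependents, globally", {
  # intervener 2 has its only dependent OUTSIDE the span 1..3 (word 5):
  # head status is global, so it still counts
  tr <- dep_tree(c(3L, 3L, 0L, 3L, 2L))        # 5 is a dependent of 2
  expect_equal(edge_ic(tr, 3, 1), 1L)
  expect_equal(edge_ic(tr, 3, 1), oracle_ic(tr$heads, 3, 1))
  expect_equal(edge_ic(tr, 2, 5), oracle_ic(tr$heads, 2, 5))
  # any adjacent edge has ic 0
  expect_equal(edge_ic(chain_tree(4), 1, 2), 0L)
})

test_that("node arity sums to n - 1 and matches star/leaf cases", {
  st <- star_tree(6)
  expect_equal(node_arity(st, 1), 5L)
  expect_equal(node_arity(st, 3), 0L)
  set.seed(11)
  for (k in 1:20) {
    tr <- sample_random_structure(sample(3:10, 1))
    expect_equal(sum(vapply(seq_len(tr$n_words), node_arity, integer(1), tree = tr)),
                 tr$n_words - 1L)
  }
})

test_that("nonprojective_edge follows the domination definition", {
  tr <- np4_tree()                              # h(2)=4, h(3)=1, h(4)=1
  expect_true(nonprojective_edge(tr, 4, 2))     # intervener 3 headed by 1
  expect_false(nonprojective_edge(tr, 1, 4))    # interveners 2,3 dominated by 1
  ch <- chain_tree(4)
  for (d in which(ch$heads > 0))
    expect_false(nonprojective_edge(ch, ch$heads[d], d))
})

test_that("crossing counts agree with brute-force oracles on random trees", {
  set.seed(23)
  for (k in 1:1000) {
    tr <- sample_random_structure(7)
    expect_identical(crossing_count(tr, "nonprojective_edges"),
                     oracle_np_edges(tr$heads))
    expect_identical(crossing_count(tr, "crossing_pairs"),
                     oracle_crossing_pairs(tr$heads))
  }
  expect_error(crossing_count(chain_tree(3), "bogus"))
})

test_that("both crossing methods vanish exactly on projective trees", {
  expect_equal(crossing_count(chain_tree(6)), 0L)
  expect_equal(crossing_count(chain_tree(6), "crossing_pairs"), 0L)
  expect_equal(crossing_count(np4_tree()), 1L)
  expect_equal(crossing_count(np4_tree(), "crossing_pairs"), 1L)
  set.seed(31)
  for (k in 1:300) {
    tr <- sample_random_structure(sample(4:9, 1))
    expect_equal(crossing_count(tr, "nonprojective_edges") == 0L,
                 crossing_count(tr, "crossing_pairs") == 0L)
  }
})

test_that("tree depth: star 2, chain n, single word 1", {
  expect_equal(tree_depth(star_tree(8)), 2L)
  expect_equal(tree_depth(star_tree(8, center = 4L)), 2L)
  expect_equal(tree_depth(chain_tree(9)), 9L)
  expect_equal(tree_depth(dep_tree(0L)), 1L)
})

test_that("sentence_summary averages over word-word edges only", {
  ch3 <- dep_tree(c(2L, 0L, 2L))                # 3-word chain rooted mid
  s <- sentence_summary(ch3)
  expect_equal(s$mean_dl, 0)
  expect_equal(s$mean_ic, 0)
  s2 <- sentence_summary(dep_tree(c(3L, 3L, 0L)))
  expect_equal(s2$mean_dl, 0.5)                 # edges (3,1) dl 1 and (3,2) dl 0
  b <- f6_chain()
  em <- edge_metrics(b)
  expect_equal(sentence_summary(b)$mean_ic, sum(em$ic) / 5)
  expect_equal(sentence_summary(b)$mean_ic,
               mean(vapply(which(b$heads > 0), function(d)
                 oracle_ic(b$heads, b$heads[d], d), integer(1))))
  expect_error(sentence_summary(dep_tree(0L)), "no dependencies")
})

test_that("IC is bounded by DL on every edge of every tree", {
  set.seed(37)
  for (k in 1:300) {
    tr <- sample_random_structure(sample(3:11, 1))
    em <- edge_metrics(tr)
    expect_true(all(em$ic >= 0 & em$ic <= em$dl))
    expect_true(all(em$ic[em$dl == 0] == 0))
  }
})

test_that("metrics depend only on positions and head map, not forms", {
  set.seed(41)
  tr <- sample_random_structure(9)
  relab <- dep_tree(tr$heads, forms = sample(letters, 9), upos = sample(LETTERS, 9))
  expect_equal(sentence_summary(tr)[, -(1:2)], sentence_summary(relab)[, -(1:2)])
})

test_that("exhaustive DL-minimal projective order lower-bounds heuristics and identity", {
  set.seed(43)
  for (k in 1:25) {
    n <- sample(4:7, 1)
    shape <- gen_tree_shape(n)
    pm <- perms(n)
    proj_dl <- apply(pm, 1, function(p) {
      h <- apply_perm(shape, p)
      if (oracle_np_edges(h) == 0L) oracle_mean_dl(h) else NA_real_
    })
    minimal <- min(proj_dl, na.rm = TRUE)
    expect_lte(minimal, oracle_mean_dl(dlm_greedy_linearize(shape)$heads))
    expect_lte(minimal, oracle_mean_dl(random_projective_linearize(shape)$heads))
    if (oracle_np_edges(shape) == 0L)           # identity order, when projective
      expect_lte(minimal, oracle_mean_dl(shape))
  }
})
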