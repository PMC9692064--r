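test_that("prufer_decode reproduces hand-checked trees and is a bijection", {
  expect_equal(prufer_decode(integer(0), 2), matrix(c(1L, 2L), 1L))
  # (2,2) on 4 nodes decodes to the star centered at 2
  st <- prufer_decode(c(2L, 2L), 4)
  expect_setequal(apply(st, 1, function(e) paste(sort(e), collapse = "-")),
                  c("1-2", "2-3", "2-4"))
  # all 16 sequences for n = 4 decode to 16 distinct trees
  seqs <- expand.grid(1:4, 1:4)
  keys <- apply(seqs, 1, function(s) {
    e <- prufer_decode(as.integer(s), 4)
    paste(sort(apply(e, 1, function(x) paste(sort(x), collapse = "-"))), collapse = " ")
  })
  expect_length(unique(keys), 16L)
  expect_error(prufer_decode(c(0L, 2L), 4), "out of range")
  expect_error(prufer_decode(c(2L), 4), "length")
})

test_that("sample_random_structure is uniform over the two rooted trees at n=2", {
  set.seed(52)
  roots <- replicate(4000, which(sample_random_structure(2)$heads == 0L))
  expect_gt(chisq_uniform_p(table(factor(roots, levels = 1:2))), 0.001)
})

test_that("sample_rla preserves topology and is uniform at n=2", {
  set.seed(53)
  tr <- dep_tree(c(3L, 3L, 0L, 3L, 4L, 1L, 1L))
  for (k in 1:50) {
    out <- sample_rla(tr)
    expect_identical(validate_tree(out), character(0))
    expect_equal(sort(tabulate(out$heads[out$heads > 0], out$n_words)),
                 sort(tabulate(tr$heads[tr$heads > 0], tr$n_words)))
    expect_equal(tree_depth(out), tree_depth(tr))
  }
  two <- replicate(4000, sample_rla(dep_tree(c(0L, 1L)))$heads[1])
  expect_gt(chisq_uniform_p(table(factor(two, levels = c(0, 2)))), 0.001)
})

test_that("matches_constraints agrees with brute-force statistics for n <= 6", {
  set.seed(54)
  for (k in 1:200) {
    n <- sample(3:6, 1)
    ref <- sample_random_structure(n)
    cand <- sample_random_structure(n)
    for (kind in c("random_structures", "dl_matched_random_structures",
                   "ic_matched_random_structures")) {
      got <- matches_constraints(cand, ref, kind)
      exp_cross <- oracle_np_edges(cand$heads) == oracle_np_edges(ref$heads)
      dl_of <- function(h) sort(abs(h[h > 0] - which(h > 0)) - 1L)
      ic_of <- function(h) sort(vapply(which(h > 0), function(d)
        oracle_ic(h, h[d], d), integer(1)))
      want <- exp_cross &&
        (!startsWith(kind, "dl_matched") || identical(dl_of(cand$heads), dl_of(ref$heads))) &&
        (!startsWith(kind, "ic_matched") || identical(ic_of(cand$heads), ic_of(ref$heads)))
      expect_identical(got, want)
    }
  }
  # identity candidate satisfies every kind
  ref <- sample_random_structure(6)
  for (kind in c("random_structures", "rla", "dl_matched_random_structures",
                 "dl_matched_rla", "ic_matched_random_structures", "ic_matched_rla"))
    expect_true(matches_constraints(ref, ref, kind))
  # projective candidate cannot match a reference with a crossing
  expect_false(matches_constraints(chain_tree(4), np4_tree(), "random_structures"))
  expect_error(matches_constraints(chain_tree(4), chain_tree(5), "rla"), "n_words")
})

test_that("generate_baseline postconditions hold for every kind", {
  set.seed(55)
  star3 <- dep_tree(c(2L, 0L, 2L))
  res <- generate_baseline(star3, baseline_spec("rla", 1000, seed = 55))
  expect_true(res$success)
  expect_equal(crossing_count(res$tree), 0L)

  ref <- sample_random_structure(8)
  for (kind in c("dl_matched_rla", "ic_matched_rla")) {
    res <- generate_baseline(ref, baseline_spec(kind, 50000, seed = 56))
    if (!res$success) next  # budget exhaustion is a legal typed outcome
    expect_identical(validate_tree(res$tree), character(0))
    expect_equal(crossing_count(res$tree), crossing_count(ref))
    em_ref <- edge_metrics(ref); em_out <- edge_metrics(res$tree)
    if (kind == "dl_matched_rla") expect_equal(sort(em_out$dl), sort(em_ref$dl))
    if (kind == "ic_matched_rla") expect_equal(sort(em_out$ic), sort(em_ref$ic))
    expect_equal(res$tree$meta[["baseline_kind"]], kind)
    expect_true(as.integer(res$tree$meta[["attempts"]]) >= 1L)
  }
  expect_error(baseline_spec("rla", max_attempts = 0), "positive")
})

test_that("baseline corpus generation is deterministic and fully reported", {
  set.seed(57)
  corp <- gen_corpus(synth_corpus_spec(n_languages = 2, sentences_per_language = 15,
                                       seed = 57))
  spec <- baseline_spec("rla", max_attempts = 2000, seed = 99)
  g1 <- generate_baseline_corpus(corp, spec)
  g2 <- generate_baseline_corpus(corp, spec)
  expect_identical(write_conllu(g1$baseline), write_conllu(g2$baseline))
  rep <- g1$report$per_tree
  expect_equal(nrow(rep), length(corp))
  expect_equal(sum(rep$success) + sum(!rep$success), length(corp))
  expect_equal(length(g1$baseline), sum(rep$success))
  expect_equal(length(g1$paired_real), length(g1$baseline))
  # every success matches its reference in n_words and crossing count
  for (i in seq_along(g1$baseline)) {
    expect_equal(g1$baseline[[i]]$n_words, g1$paired_real[[i]]$n_words)
    expect_equal(crossing_count(g1$baseline[[i]]),
                 crossing_count(g1$paired_real[[i]]))
    expect_equal(g1$baseline[[i]]$sentence_id, g1$paired_real[[i]]$sentence_id)
  }
  # budget of 1 on a hard constraint: failures recorded, report adds up
  hard <- dep_corpus(list(chain_tree(10), chain_tree(11)))
  gh <- generate_baseline_corpus(hard, baseline_spec("dl_matched_rla", 1, seed = 5))
  expect_equal(sum(gh$report$per_tree$success) + sum(!gh$report$per_tree$success), 2L)
})

test_that("added constraints never make acceptance easier (rla vs ic_matched_rla)", {
  set.seed(58)
  corp <- gen_corpus(synth_corpus_spec(n_languages = 1, sentences_per_language = 25,
                                       length_probs = stats::setNames(rep(1/4, 4), 5:8),
                                       seed = 58))
  att <- function(kind) {
    g <- generate_baseline_corpus(corp, baseline_spec(kind, 30000, seed = 7))
    # count exhausted budgets at full cost
    mean(g$report$per_tree$attempts)
  }
  expect_gte(att("ic_matched_rla"), att("rla"))
})
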