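test_that("build_observation_table yields two rows per surviving pair", {
  set.seed(61)
  corp <- gen_corpus(synth_corpus_spec(n_languages = 2, sentences_per_language = 5,
                                       seed = 61))
  g <- generate_baseline_corpus(corp, baseline_spec("rla", 50000, seed = 8))
  rows <- build_observation_table(g$paired_real, g$baseline)
  expect_equal(nrow(rows), 2L * length(g$baseline))
  expect_setequal(unique(rows$R), c(0L, 1L))
  expect_true(all(table(rows$sentence_id) == 2L))
  # identical real and baseline corpora differ only in R
  rows2 <- build_observation_table(corp, corp)
  r1 <- rows2[rows2$R == 1, setdiff(names(rows2), "R")]
  r0 <- rows2[rows2$R == 0, setdiff(names(rows2), "R")]
  expect_equal(r1, r0, ignore_attr = TRUE)
  # unpaired ids error
  swapped <- corp[c(2, 1, 3:length(corp))]
  expect_error(build_observation_table(corp, swapped), "unpaired")
})

test_that("fit_interaction recovers planted coefficients on simulated data", {
  set.seed(62)
  rows <- simulate_interaction(beta = c(1.5, 0.30, -0.30, -0.15), sd_u = 0.1,
                               sigma = 0.2, n_languages = 15, n_sentences = 60)
  f <- fit_interaction(rows, "ic")
  expect_true(f$converged)
  expect_equal(unname(f$t), unname(f$beta / f$se))
  expect_lt(abs(coef(f)["S:R"] - (-0.15)), 2 * f$se["S:R"])
  expect_lt(abs(coef(f)["S"] - 0.30), 3 * f$se["S"])
})

test_that("a response identical across R levels gives null tree-type effects", {
  set.seed(63)
  rows <- simulate_interaction(beta = c(1, 0.3, 0, 0), sd_u = c(0.1, 0.1, 0, 0),
                               sigma = 0.2, n_languages = 10, n_sentences = 40)
  # force exact equality between R rows: copy the R=1 response onto R=0 rows
  key <- paste(rows$language, rows$sentence_id)
  rows$response_ic <- rows$response_ic[match(key, key[rows$R == 1])]
  f <- fit_interaction(rows, "ic")
  expect_lt(abs(coef(f)["R"]), 1e-6)
  expect_lt(abs(coef(f)["S:R"]), 1e-6)
})

test_that("inestimable designs error out", {
  set.seed(64)
  rows <- simulate_interaction(n_languages = 4, n_sentences = 10)
  expect_error(fit_interaction(rows[rows$language == "L01", ], "ic"), "inestimable")
  expect_error(fit_interaction(rows[rows$R == 1, ], "ic"), "inestimable")
})

test_that("per-language OLS fits obey exact reparameterization identities", {
  set.seed(65)
  rows <- simulate_interaction(n_languages = 3, n_sentences = 50)
  fits <- fit_per_language(rows, "ic")
  expect_length(fits, 3L)
  # swapping the R coding negates the R and S:R coefficients exactly
  flipped <- rows; flipped$R <- 1L - flipped$R
  fits2 <- fit_per_language(flipped, "ic")
  for (lang in names(fits)) {
    expect_equal(coef(fits[[lang]])[["R"]], -coef(fits2[[lang]])[["R"]])
    expect_equal(coef(fits[[lang]])[["S:R"]], -coef(fits2[[lang]])[["S:R"]])
  }
  # adding a constant shifts only the intercept
  shifted <- rows; shifted$response_ic <- shifted$response_ic + 5
  fits3 <- fit_per_language(shifted, "ic")
  for (lang in names(fits)) {
    expect_equal(coef(fits3[[lang]])[["(Intercept)"]],
                 coef(fits[[lang]])[["(Intercept)"]] + 5)
    expect_equal(coef(fits3[[lang]])[-1], coef(fits[[lang]])[-1])
  }
  # two languages built from identical data give identical estimates
  dup <- rows[rows$language == "L01", ]
  dup2 <- dup; dup2$language <- "L99"
  fd <- fit_per_language(rbind(dup, dup2), "ic")
  expect_equal(coef(fd[["L01"]]), coef(fd[["L99"]]))
})

test_that("per-language recovery on a single simulated language", {
  set.seed(66)
  rows <- simulate_interaction(beta = c(1.5, 0.30, -0.30, -0.15), sd_u = 0,
                               sigma = 0.2, n_languages = 1, n_sentences = 2500)
  f <- fit_per_language(rows, "ic")[[1]]
  expect_lt(abs(coef(f)[["S:R"]] - (-0.15)), 2 * f$se[["S:R"]])
  # a language with a single R level is skipped with a log entry
  rows2 <- rbind(rows, within(rows[rows$R == 1, ][1:6, ], language <- "L88"))
  fits <- fit_per_language(rows2, "ic")
  expect_false("L88" %in% names(fits))
  expect_equal(attr(fits, "skipped"), "L88")
})

test_that("hypothesis verdicts follow sign and t-threshold of the interaction", {
  fake <- function(b3, t3, conv = TRUE) {
    nm <- c("(Intercept)", "S", "R", "S:R")
    structure(list(beta = stats::setNames(c(1, 0.3, -0.1, b3), nm),
                   se = stats::setNames(c(0.1, 0.01, 0.01, abs(b3 / t3)), nm),
                   t = stats::setNames(c(10, 30, -10, t3), nm), converged = conv),
              class = "icdl_fit")
  }
  expect_equal(evaluate_hypothesis(fake(-0.17, -24.46))$verdict, "supported")
  expect_equal(evaluate_hypothesis(fake(0.01, 3.51))$verdict, "contradicted")
  expect_equal(evaluate_hypothesis(fake(-0.01, -0.5))$verdict, "inconclusive")
  expect_equal(evaluate_hypothesis(fake(-0.17, -24.46, conv = FALSE))$verdict,
               "inconclusive")
  v <- evaluate_hypothesis(fake(-0.17, -24.46))
  expect_equal(v$beta2, -0.1)  # main effect reported alongside
})

test_that("summarize_fit emits four rows, stars, and TSV round-trips", {
  set.seed(67)
  rows <- simulate_interaction(n_languages = 5, n_sentences = 30)
  f <- fit_interaction(rows, "dl")
  tab <- summarize_fit(f)
  expect_equal(tab$term, c("Intercept", "S.length", "Real", "S.length:Real"))
  expect_equal(tab$signif, ifelse(abs(tab$t) > 2, "*", ""))
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(tf, colClasses = c("character", rep("numeric", 3),
                                               "character"), na.strings = NULL)
  expect_equal(back$estimate, tab$estimate)
  expect_equal(back$t, tab$t)
})
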