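# Lexicon loading, category scoring, normalization and group comparison.

test_that("lexicon JSON loads, deduplicates and validates", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"negate": ["no", "not", "never"]}', path)
  lex <- load_lexicon(path)
  expect_equal(length(lex$categories), 1)
  expect_equal(length(lex$categories$negate), 3)

  writeLines('{"negate": ["no", "no", "not"]}', path)
  expect_equal(length(load_lexicon(path)$categories$negate), 2)

  writeLines("{}", path)
  expect_error(load_lexicon(path), "category")

  writeLines('{"empty": []}', path)
  expect_error(load_lexicon(path), "empty")

  writeLines("{not json", path)
  expect_error(load_lexicon(path), "malformed")
})

test_that("the bundled example lexicon file round-trips", {
  path <- system.file("extdata", "example_lexicon.json", package = "somnia")
  lex <- load_lexicon(path)
  expect_s3_class(lex, "somnia_lexicon")
  out <- withr::local_tempfile(fileext = ".json")
  write_lexicon(lex, out)
  expect_equal(load_lexicon(out)$categories, lex$categories)
})

test_that("scoring matches the closed form and the brute-force recount", {
  lex <- lexicon("t", list(negate = c("no", "not", "never")))
  expect_equal(unname(score_user(c("no", "not", "happy", "never"), lex)),
               75)
  expect_equal(unname(score_user(c("happy", "day"), lex)), 0)
  expect_error(score_user(character(), lex), "empty")

  # random 1000-token document against an independent double-loop recount
  full <- default_lexicon()
  vocab <- c(unlist(full$categories, use.names = FALSE),
             sprintf("x%03d", 1:200))
  set.seed(31)
  for (rep in 1:3) {
    tokens <- sample(vocab, 1000, replace = TRUE)
    got <- score_user(tokens, full)
    for (cat in names(full$categories)) {
      expect_equal(unname(got[cat]),
                   oracle_category_score(tokens, full$categories[[cat]]))
    }
  }
})

test_that("trailing-asterisk entries match by prefix", {
  lex <- lexicon("t", list(anx = c("worr*", "panic")))
  got <- score_user(c("worried", "worrying", "panic", "calm"), lex)
  expect_equal(unname(got), 75)
})

test_that("scores are permutation- and duplication-invariant", {
  lex <- default_lexicon()
  set.seed(5)
  tokens <- sample(c("no", "sad", "w1", "w2", "party"), 60, replace = TRUE)
  s1 <- score_user(tokens, lex)
  expect_equal(score_user(sample(tokens), lex), s1)
  expect_equal(score_user(rep(tokens, 2), lex), s1)
})

test_that("max-min normalization behaves as specified", {
  expect_equal(maxmin_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(maxmin_normalize(c(5, 5)), "constant")
  set.seed(6)
  x <- rnorm(50)
  n1 <- maxmin_normalize(x)
  expect_equal(maxmin_normalize(n1), n1)      # idempotent
  expect_equal(order(n1), order(x))           # order preserved
  expect_equal(n1, oracle_maxmin(x))
})

test_that("group comparison matches manual arithmetic", {
  df <- data.frame(label = c("Yes", "Yes", "No", "No"),
                   anx = c(4, 6, 2, 4))
  g <- compare_groups(df, "anx")
  expect_equal(g$mean_yes, 5)
  expect_equal(g$mean_no, 3)
  expect_equal(g$delta, 2)
  expect_equal(g$relative, 2 / 3)
  expect_error(compare_groups(df[df$label == "Yes", ], "anx"), "classes")
})

test_that("identical class distributions give a near-zero delta", {
  set.seed(7)
  x <- rnorm(400)
  g <- compare_groups(x, labels = rep(c("Yes", "No"), 200))
  expect_lt(abs(g$delta), 3 * sd(x) * sqrt(2 / 200))
})

test_that("the planted anxiety excess of about 10 percent is recovered", {
  feats <- shared_features()
  g <- compare_groups(feats, "anx")
  # multiplier 1.10 => relative difference 0.10, within sampling error
  expect_lt(abs(g$relative - 0.10), 0.08)
  expect_gt(g$relative, 0)
})

test_that("planted categories carry the largest group deltas", {
  feats <- shared_features()
  cfg <- shared_cohort()$config
  cats <- cfg$category_effects$category
  deltas <- vapply(cats, function(cat) {
    abs(compare_groups(feats, cat)$delta)
  }, 0)
  planted <- planted_informative(cfg)
  # every planted category out-ranks every neutral (multiplier 1) category
  neutral <- cfg$category_effects$category[
    cfg$category_effects$yes_multiplier == 1]
  expect_gt(min(deltas[planted]), max(deltas[neutral]))
})
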