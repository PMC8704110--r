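# Synthetic cohort generator: determinism, truncation, calibration, planted
# structure.

test_that("an all-zero configuration yields an empty cohort", {
  cfg <- generator_config(n_yes = 0, n_no = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$users), 0)
  expect_equal(nrow(co$docs), 0)
  expect_error(cohort_summary(co), "empty")
})

test_that("invalid distribution parameters fail naming the field", {
  expect_error(generator_config(tokens_per_tweet = list(mean = 5, sd = 2,
                                                        min = 10, max = 4)),
               "tokens_per_tweet")
  expect_error(generator_config(n_yes = -1), "n_yes")
  expect_error(generator_config(pregnancy_fraction = 1.5),
               "pregnancy_fraction")
  bad <- default_category_effects()
  bad$base_rate[1] <- -0.1
  expect_error(generator_config(category_effects = bad), "category_effects")
})

test_that("identical configurations generate identical cohorts", {
  cfg <- generator_config(n_yes = 40, n_no = 40, max_docs_per_user = 8,
                          seed = 77)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$users, co2$users)
  expect_identical(co1$docs, co2$docs)
})

test_that("sampled counts respect their truncation bounds", {
  co <- shared_cohort()
  cfg <- co$config
  yes <- co$users$label == "Yes"
  expect_true(all(co$users$n_tweets[yes] >= cfg$tweets_per_user_yes$min))
  expect_true(all(co$users$n_tweets[yes] <= cfg$tweets_per_user_yes$max))
  expect_true(all(co$users$n_tweets[!yes] >= cfg$tweets_per_user_no$min))
  expect_true(all(co$users$n_tweets[!yes] <= cfg$tweets_per_user_no$max))
  expect_true(all(co$users$disclosure_count[yes] >=
                    cfg$disclosure_count$min))
  expect_true(all(co$users$disclosure_count[yes] <=
                    cfg$disclosure_count$max))
  expect_true(all(co$users$disclosure_count[!yes] == 0))
  traits <- as.matrix(co$users[, c("openness", "conscientiousness",
                                   "extraversion", "agreeableness",
                                   "neuroticism")])
  expect_true(all(traits >= 0 & traits <= 1))
})

test_that("configured moments are recovered within sampling error", {
  co <- shared_cohort()
  users <- co$users
  yes <- users$label == "Yes"
  n1 <- sum(yes)
  d <- users$disclosure_count[yes]
  expect_lt(abs(mean(d) - 28.60), 3 * sd(d) / sqrt(n1))
  tw <- users$n_tweets[yes]
  expect_lt(abs(mean(tw) - 2437.42), 3 * sd(tw) / sqrt(n1))
  nr <- users$neuroticism[yes]
  expect_lt(abs(mean(nr) - 0.83), 3 * sd(nr) / sqrt(n1))
  cs <- abs(mean(users$conscientiousness[yes]) - 0.29)
  expect_lt(cs, 3 * sd(users$conscientiousness[yes]) / sqrt(n1))
})

test_that("disclosure documents exist only for insomniac users and carry a seed phrase", {
  co <- shared_cohort()
  disc <- co$docs[co$docs$is_disclosure, ]
  lab <- co$users$label[match(disc$user_id, co$users$user_id)]
  expect_true(all(lab == "Yes"))
  expect_true(all(grepl("insomnia|sleepless", disc$raw_text)))
  # every insomniac user gets at least one materialised disclosure doc
  yes_ids <- co$users$user_id[co$users$label == "Yes"]
  expect_true(all(yes_ids %in% disc$user_id))
  # pregnancy flags only on insomniac women
  pf <- co$users[co$users$pregnancy_flag, ]
  expect_true(all(pf$label == "Yes" & pf$gender == "female"))
})

test_that("gender table cells match configured probabilities within binomial error", {
  cfg <- generator_config(n_yes = 5000, n_no = 5000, seed = 8)
  co <- generate_cohort(cfg, docs = FALSE)
  tab <- sample_gender_table(co$users)
  expect_equal(sum(tab), 10000)
  p <- c(309 / 820, 363 / 754)  # male probability per class
  for (j in 1:2) {
    n <- sum(tab[, j])
    se <- sqrt(p[j] * (1 - p[j]) / n)
    expect_lt(abs(tab["male", j] / n - p[j]), 3 * se)
  }
  # expected male-and-Yes fraction under the reference composition
  expect_equal(309 / 1574, 0.196, tolerance = 0.005)
})

test_that("a degenerate all-male configuration empties the female row", {
  cfg <- generator_config(n_yes = 50, n_no = 50,
                          gender_probs = c(yes = 1, no = 1), seed = 2)
  tab <- sample_gender_table(generate_cohort(cfg, docs = FALSE)$users)
  expect_equal(unname(tab["female", ]), c(0L, 0L))
})

test_that("every category with multiplier above one is over-expressed in the insomniac class", {
  feats <- shared_features()
  cfg <- shared_cohort()$config
  eff <- cfg$category_effects
  up <- eff$category[eff$yes_multiplier > 1]
  yes <- feats$label == "Yes"
  for (cat in up) {
    expect_gt(mean(feats[[cat]][yes]), mean(feats[[cat]][!yes]))
  }
  down <- eff$category[eff$yes_multiplier < 1]
  for (cat in down) {
    expect_lt(mean(feats[[cat]][yes]), mean(feats[[cat]][!yes]))
  }
})

test_that("cohort_summary reduces correctly for a single user", {
  users <- data.frame(user_id = "u1", label = "Yes", gender = "female",
                      country = "UK", openness = 0.5,
                      conscientiousness = 0.5, extraversion = 0.5,
                      agreeableness = 0.5, neuroticism = 0.5,
                      n_tweets = 26L, disclosure_count = 9L,
                      pregnancy_flag = FALSE, stringsAsFactors = FALSE)
  s <- cohort_summary(users)
  expect_equal(unname(s$tweets$Yes[c("mean", "sd", "min", "max")]),
               c(26, 0, 26, 26))
  expect_equal(unname(s$n), c(1, 0))
})

test_that("expected category J identifies the designed informative set", {
  cfg <- shared_cohort()$config
  j <- expected_category_j(cfg)
  planted <- planted_informative(cfg)
  expect_setequal(planted, c("negate", "swear", "health", "sad", "death"))
  expect_true(all(j[planted] > 1.5))
  expect_true(all(j[setdiff(names(j), planted)] < 1))
})
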