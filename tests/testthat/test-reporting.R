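# ROC/AUC, chi-square association, trait bins, and LDA topics.

test_that("AUC hits its exact endpoints and handles ties at chance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney pair probability on random instances", {
  set.seed(81)
  for (rep in 1:200) {
    n <- sample(8:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(s, y)$auc, oracle_auc_pairs(s, y))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(82)
  s <- rnorm(60)
  y <- rbinom(60, 1, 0.5)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a)
  expect_equal(roc_auc(5 * s - 3, y)$auc, a)
})

test_that("the ROC curve is a valid staircase consistent with pROC", {
  set.seed(83)
  s <- runif(40)
  y <- rbinom(40, 1, 0.5)
  out <- roc_auc(s, y)
  expect_equal(out$roc$fpr[1], 0)
  expect_equal(out$roc$tpr[nrow(out$roc)], 1)
  expect_true(all(diff(out$roc$fpr) >= 0) && all(diff(out$roc$tpr) >= 0))
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(out$auc, as.numeric(pROC::auc(ref)))
})

test_that("the gender table association replicates the printed analysis", {
  tab <- cohort_reference()$gender_table
  out <- chi_square_2x2(tab)
  expect_equal(out$df, 1L)
  expect_lt(out$p_value, 0.001)
  # independent hand computation of sum (O-E)^2/E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic, sum((tab - E)^2 / E))
  # and the stats::chisq.test oracle, with and without correction
  expect_equal(out$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
               unname(chisq.test(tab, correct = TRUE)$statistic))
})

test_that("chi-square is zero for proportional rows and symmetric under swaps", {
  even <- matrix(c(20, 40, 10, 20), 2, byrow = TRUE)
  out <- chi_square_2x2(even)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  tab <- matrix(c(30, 10, 12, 44), 2)
  s <- chi_square_2x2(tab)$statistic
  expect_equal(chi_square_2x2(tab[2:1, ])$statistic, s)
  expect_equal(chi_square_2x2(tab[, 2:1])$statistic, s)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("trait bins use left-closed edges and conserve counts", {
  expect_equal(trait_bin_distribution(rep(0.9, 7))$percent,
               c(0, 0, 0, 0, 100))
  b <- trait_bin_distribution(c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(b$count, c(1, 1, 1, 1, 2))  # 1.0 closes the last bin
  set.seed(84)
  v <- runif(1234)
  expect_equal(sum(trait_bin_distribution(v)$count), 1234)
  expect_error(trait_bin_distribution(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("uniform draws fill each bin at twenty percent", {
  set.seed(85)
  b <- trait_bin_distribution(runif(10000))
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(b$percent / 100 - 0.2) < 3 * se))
})

test_that("LDA topic distributions normalise and the fit is reproducible", {
  set.seed(86)
  docs <- vapply(1:30, function(i) {
    paste(sample(letters[1:12], 15, replace = TRUE), collapse = " ")
  }, "")
  m1 <- lda_topics(docs, k = 3, seed = 10, iterations = 100)
  m2 <- lda_topics(docs, k = 3, seed = 10, iterations = 100)
  expect_equal(rowSums(m1$phi), rep(1, 3))
  expect_equal(rowSums(m1$theta), rep(1, 30))
  expect_identical(m1$phi, m2$phi)
  expect_error(lda_topics(docs, k = 20), "vocabulary")
  expect_error(lda_topics(docs[1:2], k = 5), "documents")
})

test_that("a single dominant word dominates every topic", {
  # vocabulary barely reaches k so the fit is defined; "sleep" carries
  # almost all mass and must top every topic
  docs <- c(rep("sleep sleep sleep sleep sleep sleep sleep sleep", 40),
            "sleep night", "sleep tired", "sleep child", "sleep weird")
  m <- lda_topics(docs, k = 5, seed = 2, iterations = 100)
  tops <- vapply(m$topics, function(t) t$word[1], "")
  expect_true(all(tops == "sleep"))
})

test_that("planted topic vocabularies are recovered with high purity", {
  blocks <- split(sprintf("t%02d", 1:40), rep(1:5, each = 8))
  purities <- vapply(1:10, function(s) {
    set.seed(900 + s)
    docs <- vapply(1:150, function(i) {
      paste(sample(blocks[[sample.int(5, 1)]], 25, replace = TRUE),
            collapse = " ")
    }, "")
    m <- lda_topics(docs, k = 5, seed = 900 + s, iterations = 250)
    # topic-by-block mass, greedily matched one-to-one
    mass <- vapply(blocks, function(b) {
      rowSums(m$phi[, b, drop = FALSE])
    }, numeric(5))
    matched <- numeric(5)
    taken <- rep(FALSE, 5)
    for (t in order(-apply(mass, 1, max))) {
      j <- order(-mass[t, ])
      j <- j[!taken[j]][1]
      matched[t] <- mass[t, j]
      taken[j] <- TRUE
    }
    mean(matched)
  }, 0)
  expect_gte(mean(purities >= 0.8), 0.8)
  expect_gte(stats::median(purities), 0.8)
})
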