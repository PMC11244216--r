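test_that("standardization yields mean 0 / sd 1 and is leak-free", {
  tab <- generate_patient_table(132, seed = 8)
  sc <- standardize_features(tab)
  expect_lt(max(abs(colMeans(sc$x))), 1e-9)
  expect_lt(max(abs(apply(sc$x, 2, sd) - 1)), 1e-9)

  # idempotence: re-scaling an already scaled column changes nothing
  again <- sweep(sweep(sc$x, 2, colMeans(sc$x), "-"), 2,
                 apply(sc$x, 2, sd), "/")
  expect_equal(again, sc$x, tolerance = 1e-9)

  # balanced binary column scales to +/- 1
  tab2 <- tab[1:10, ]
  tab2$Smoking <- rep(c(0, 1), 5)
  sm <- standardize_features(tab2)$x[, "Smoking"]
  # hand z-score: (x - 1/2) / sqrt(n/(n-1) * 1/4) = +/- sqrt((n-1)/n)
  expect_equal(sort(unique(sm)), c(-1, 1) * sqrt(9 / 10), tolerance = 1e-12)

  # training parameters are a pure function of the training rows
  p1 <- standardize_features(tab[1:100, ])$params
  p2 <- standardize_features(tab[1:100, ])$params
  expect_identical(p1, p2)
  held <- standardize_features(tab[101:132, ], params = p1)
  expect_gt(max(abs(colMeans(held$x))), 1e-6)  # not re-centred on the fold

  tab3 <- tab
  tab3$Diabetes <- 0
  expect_error(standardize_features(tab3), "Diabetes")
})

test_that("correlation matrix is symmetric, unit-diagonal, oracle-checked", {
  tab <- table5_df()
  m <- correlation_matrix(tab)
  expect_identical(dim(m), c(10L, 10L))
  expect_true(all(diag(m) == 1))
  expect_identical(m, t(m))
  expect_equal(m["Smoking", "Condition"],
               pearson_oracle(tab$Smoking, tab$Condition))
  # chest pain is constant in the excerpt: undefined correlations
  expect_true(all(is.na(m["Chest Pain", colnames(m) != "Chest Pain"])))
  expect_error(correlation_matrix(tab[1:2, ]), "at least 3")
})

test_that("boxplot summaries use type-7 quartiles and 1.5 IQR fences", {
  tab <- table5_df()
  tab$Age[1] <- 35
  s <- boxplot_summary(tab)
  expect_true(all(c("variable", "condition", "median") %in% names(s)))

  # hand-checkable group: cholesterol values of the condition-0 patients
  chol0 <- sort(tab$Cholesterol[tab$Condition == 0])
  row <- s[s$variable == "Cholesterol" & s$condition == 0, ]
  expect_equal(row$median, median(chol0))
  expect_equal(row$q1, quantile(chol0, 0.25, names = FALSE, type = 7))
  expect_equal(row$q3, quantile(chol0, 0.75, names = FALSE, type = 7))

  # a value far beyond the fence is flagged
  tab2 <- tab
  tab2$Cholesterol[6] <- 10000
  s2 <- boxplot_summary(tab2)
  flagged <- s2[s2$variable == "Cholesterol" & s2$condition == 0, ]
  expect_gte(flagged$n_outliers, 1)
  expect_true(10000 %in% flagged$outliers[[1]])

  one <- tab; one$Condition <- 1
  expect_error(boxplot_summary(one), "both condition groups")
})

test_that("all-equal groups have zero IQR and no outliers", {
  tab <- table5_df()
  tab$Age <- 50
  s <- boxplot_summary(tab)
  a <- s[s$variable == "Age" & s$condition == 1, ]
  expect_equal(a$q3 - a$q1, 0)
  expect_equal(a$n_outliers, 0)
})

test_that("model report covers the requested families with seeded results", {
  tab <- generate_patient_table(150, seed = 5, link = "threshold")
  r1 <- evaluate_models(tab, models = c("logistic", "decision_tree", "cnn"),
                        repeats = 3, seed = 7)
  r2 <- evaluate_models(tab, models = c("logistic", "decision_tree", "cnn"),
                        repeats = 3, seed = 7)
  expect_identical(r1$results, r2$results)
  expect_identical(sort(unique(r1$results$model)),
                   sort(c("logistic", "decision_tree", "cnn")))
  expect_equal(nrow(r1$results), 9)
  expect_true(all(r1$results$accuracy >= 0 & r1$results$accuracy <= 1))
  expect_true(all(r1$results$f1 >= 0 & r1$results$f1 <= 1))
  expect_error(evaluate_models(tab, models = "perceptron"), "arg")
})

test_that("F1 convention and single-class split handling are explicit", {
  expect_warning(v <- ecgflow:::binary_f1(c(0, 0), c(0, 0)), "undefined")
  expect_equal(v, 0)
  expect_equal(ecgflow:::binary_f1(c(1, 0, 1), c(1, 1, 1)), 0.8)
})
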