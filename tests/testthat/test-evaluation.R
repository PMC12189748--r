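# Metric suite against independent brute-force oracles.

test_that("precision/recall: identity, 1-D hand case, and the sphere oracle", {
  set.seed(61)
  A <- matrix(rnorm(60), 15, 4)
  pr <- precision_recall(A, A, t = 3)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  # 1-D: X_real = {0, 10}, X_syn = {1, 2}, t = 1
  pr1 <- precision_recall(matrix(c(0, 10)), matrix(c(1, 2)), t = 1)
  expect_equal(pr1$precision, 1)   # both 1 and 2 within 10 of 0
  expect_equal(pr1$recall, 0.5)    # 0 within 1 of 1; 10 is 8 away

  # exhaustive double-loop oracle on instances with <= 50 points
  for (s in 1:4) {
    set.seed(70 + s)
    nA <- sample(12:50, 1); nB <- sample(12:50, 1)
    A <- matrix(rnorm(nA * 3), nA, 3)
    B <- matrix(rnorm(nB * 3, mean = 0.5), nB, 3)
    got <- precision_recall(A, B, t = 10)
    want <- oracle_precision_recall(A, B, t = 10)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
  expect_error(precision_recall(matrix(rnorm(10)), matrix(rnorm(10)), t = 10),
               class = "synexpr_validation_error")
})

test_that("a constant generator shows the mode-collapse signature", {
  set.seed(90)
  # two well-separated modes in the real data
  real <- rbind(matrix(rnorm(250 * 5, mean = 0, sd = 0.3), 250, 5),
                matrix(rnorm(250 * 5, mean = 5, sd = 0.3), 250, 5))
  v <- real[7, ] # a constant inside the real manifold
  syn <- matrix(rep(v, each = 100), 100, 5) +
    matrix(rnorm(500, sd = 1e-4), 100, 5)
  pr <- precision_recall(real, syn, t = 10)
  expect_equal(pr$precision, 1)
  expect_lte(pr$recall, 0.05)
})

test_that("correlation coefficient preserves and inverts pairwise structure", {
  set.seed(41)
  X <- matrix(rnorm(300), 50, 6)
  X[, 2] <- 0.9 * X[, 1] + 0.3 * rnorm(50)
  # row-permuted data has the identical correlation matrix
  expect_equal(correlation_coefficient(X, X[sample(50), ]), 1)
  expect_equal(correlation_coefficient(X, X), 1)

  # 2-gene system: flipping one gene's sign flips the single pair corr
  Y <- X[, 1:2]
  Yneg <- cbind(Y[, 1], -Y[, 2])
  # single pair: population-sd standardization degenerates; use 3 genes
  Z3 <- cbind(X[, 1], X[, 2], rnorm(50))
  Z3neg <- cbind(Z3[, 1], -Z3[, 2], Z3[, 3])
  expect_lt(correlation_coefficient(Z3, Z3neg), 0)

  # 4-gene fixture against the explicit upper-triangle loop
  A <- matrix(rnorm(200), 50, 4)
  B <- matrix(rnorm(200), 50, 4)
  B[, 2] <- B[, 1] + 0.5 * rnorm(50)
  expect_equal(correlation_coefficient(A, B),
               oracle_correlation_coefficient(A, B))
  # symmetry in the arguments
  expect_equal(correlation_coefficient(A, B), correlation_coefficient(B, A))
  # constant genes are dropped pairwise with a warning
  Ac <- cbind(A, const = 1)
  Bc <- cbind(B, const = rnorm(50))
  expect_warning(cc <- correlation_coefficient(Ac, Bc), "constant")
  expect_equal(cc, correlation_coefficient(A, B))
})

test_that("detectability separates what is separable and ignores row order", {
  set.seed(55)
  A <- matrix(rnorm(120 * 6), 120, 6)
  B <- matrix(rnorm(120 * 6, mean = 100), 120, 6) # 100 sd away
  det <- detectability(A, B, classifiers = c("lr", "knn"), n_runs = 2)
  expect_true(all(det$f1 >= 0.99))
  # row order invariance (same seeds)
  det2 <- detectability(A[sample(120), ], B[sample(120), ],
                        classifiers = c("lr", "knn"), n_runs = 2)
  expect_equal(dplyr::arrange(det, classifier, run)$f1,
               dplyr::arrange(det2, classifier, run)$f1)
  # PC space runs and stays in range
  detpc <- detectability(A, B, classifiers = "lr", space = "pc",
                         n_pc = 3, n_runs = 1)
  expect_true(all(detpc$f1 >= 0 & detpc$f1 <= 1))
})

test_that("TSTR reproduces identity substitution, chance floor and separability", {
  set.seed(66)
  n_per <- 120
  centers <- rbind(c(0, 0, 0, 0), c(4, 0, 4, 0), c(0, 4, 0, 4))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 4, sd = 0.5), n_per, 4), 2, centers[k, ], "+")))
  y <- rep(c("a", "b", "c"), each = n_per)
  te <- sample(nrow(X), 100)
  # class-separated "synthetic" data: held-in real data with true labels
  res <- tstr(X[-te, ], y[-te], X[te, ], y[te],
              classifiers = c("lr", "knn"), seed = 2)
  expect_true(all(res$balanced_accuracy >= 0.95))
  # identity substitution: same inputs, same seed, same result
  res2 <- tstr(X[-te, ], y[-te], X[te, ], y[te],
               classifiers = c("lr", "knn"), seed = 2)
  expect_identical(res, res2)
  # shuffled synthetic labels fall to the 1/K chance floor; measured on
  # unclustered features (clustered features make a label-free classifier
  # assign whole clusters, quantizing balanced accuracy at k/K)
  set.seed(3)
  Xn2 <- matrix(rnorm(1000 * 4), 1000, 4)
  yn2 <- rep(c("a", "b", "c"), length.out = 1000)
  ysh <- sample(yn2[1:600])
  cha <- tstr(Xn2[1:600, ], ysh, Xn2[601:1000, ], yn2[601:1000],
              classifiers = "lr", seed = 2)
  expect_lt(abs(cha$balanced_accuracy - 1 / 3), 0.12)
  # single-class synthetic labels are degenerate
  expect_error(tstr(X[-te, ], rep("a", nrow(X) - 100), X[te, ], y[te]),
               class = "synexpr_degenerate_error")
  # missing classes are reported
  keep <- y[-te] != "c"
  r3 <- tstr(X[-te, ][keep, ], y[-te][keep], X[te, ], y[te],
             classifiers = "knn", seed = 1)
  expect_identical(attr(r3, "missing_classes"), "c")
})

test_that("per-gene KS statistics match the ECDF-gap oracle", {
  set.seed(74)
  A <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  expect_true(all(ks_per_gene(A, A)$statistic == 0))
  # disjoint supports give statistic 1
  B <- A; B[, 1] <- abs(B[, 1]) + 10
  expect_equal(ks_per_gene(A, B)$statistic[1], 1)
  # 30-sample fixture per set: equality with the brute-force max ECDF gap
  C2 <- matrix(rnorm(90, mean = 0.4), 30, 3,
               dimnames = list(NULL, colnames(A)))
  ks <- ks_per_gene(A, C2)
  for (j in 1:3)
    expect_equal(ks$statistic[j], oracle_ks_statistic(A[, j], C2[, j]))
  expect_true(all(ks$p_adjusted >= ks$p - 1e-12))
  expect_equal(ks$p_adjusted, p.adjust(ks$p, "BH"))
  # monotone under increasing location shift
  shifts <- c(0.5, 1, 2, 4)
  stats <- sapply(shifts, function(s)
    ks_per_gene(A[, 1, drop = FALSE], A[, 1, drop = FALSE] + s)$statistic)
  expect_true(all(diff(stats) >= 0))
})

test_that("per-gene Wasserstein matches quantile oracles and metric axioms", {
  # identical matrices
  set.seed(81)
  A <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(mean_gene_wasserstein(A, A), 0)
  # point masses at 0 and 3: translation distance 3
  expect_equal(mean_gene_wasserstein(matrix(rep(0, 5)), matrix(rep(3, 5))), 3)
  # two 5-point distributions: equal-n sorted-quantile brute force
  x <- c(0.1, 2, 3.5, 4, 9); y <- c(1, 1.2, 2, 8, 8.5)
  expect_equal(mean_gene_wasserstein(matrix(x), matrix(y), order = 2),
               sqrt(mean((sort(x) - sort(y))^2)))
  # unequal sample sizes against the fine-grid quantile oracle
  set.seed(82)
  u <- rnorm(23); v <- rnorm(37, mean = 1)
  expect_equal(mean_gene_wasserstein(matrix(u), matrix(v), order = 2),
               oracle_wasserstein_1d(u, v, 2), tolerance = 1e-3)
  expect_equal(mean_gene_wasserstein(matrix(u), matrix(v), order = 1),
               oracle_wasserstein_1d(u, v, 1), tolerance = 1e-3)
  # zero iff identical sorted samples
  expect_equal(mean_gene_wasserstein(matrix(sample(x)), matrix(sort(x))), 0)
  expect_gt(mean_gene_wasserstein(matrix(x), matrix(y)), 0)
  # triangle inequality on random triples
  for (s in 1:5) {
    set.seed(s + 200)
    a <- matrix(rnorm(15)); b <- matrix(rnorm(15)); c2 <- matrix(rnorm(15))
    dab <- mean_gene_wasserstein(a, b)
    dbc <- mean_gene_wasserstein(b, c2)
    dac <- mean_gene_wasserstein(a, c2)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("evaluate_all populates a reproducible report and skips TSTR cleanly", {
  fx <- get_fixture("tiny")
  half <- seq_len(32)
  Xr <- fx$Xn$values[half, ]
  Xs <- fx$Xn$values[-half, ]
  Cr <- fx$C[half, ]; Cs <- fx$C[-half, ]
  rep1 <- evaluate_all(Xr, Xs, Cr, Cs, t = 5, n_runs = 2,
                       classifiers = c("lr", "knn"), seed = 9)
  expect_s3_class(rep1, "evaluation_report")
  expect_true(rep1$precision >= 0 && rep1$precision <= 1)
  expect_true(rep1$recall >= 0 && rep1$recall <= 1)
  expect_true(abs(rep1$correlation_coefficient) <= 1)
  expect_true(all(rep1$detectability$f1 >= 0 & rep1$detectability$f1 <= 1))
  expect_false(rep1$tstr_skipped)
  expect_equal(nrow(rep1$ks), 20)
  rep2 <- evaluate_all(Xr, Xs, Cr, Cs, t = 5, n_runs = 2,
                       classifiers = c("lr", "knn"), seed = 9)
  expect_equal(tidy(rep1), tidy(rep2))
  # no synthetic covariates: TSTR skipped with an explicit marker
  rep3 <- evaluate_all(Xr, Xs, Cr, NULL, t = 5, n_runs = 1,
                       classifiers = "lr", seed = 9)
  expect_true(rep3$tstr_skipped)
  expect_null(rep3$tstr)
  # tidiers and report serialization
  td <- tidy(rep1)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_s3_class(glance(rep1), "tbl_df")
  out <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep1, out)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".genes.tsv")))
  js <- jsonlite::read_json(out)
  expect_equal(js$precision, rep1$precision)
})
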