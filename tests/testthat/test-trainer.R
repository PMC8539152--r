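test_that("design systems are occurrence matrices over the used vocabulary", {
  recs <- list(list(counts = c(g1 = 2L), hc = -10, name = "a"),
               list(counts = c(g1 = 1L, g2 = 1L), hc = -7, name = "b"))
  sys <- buildDesignSystem(recs)
  expect_equal(unname(sys$X), matrix(c(2, 1, 0, 1), nrow = 2))
  expect_equal(colnames(sys$X), c("g1", "g2"))
  expect_equal(sys$y, c(-10, -7))

  dk <- decompose(normalizeConventions(parseSmiles("C1(=C)OC(=O)C1", "diketene")), ctab)
  sys1 <- buildDesignSystem(list(list(counts = groupCounts(dk), hc = -1913.4)))
  expect_equal(dim(sys1$X), c(1, 6))
  expect_equal(sort(unname(sys1$X[1, ])), c(1, 1, 1, 1, 1, 4))

  expect_error(buildDesignSystem(recs, vocab = c("zz")), "no overlap")
  expect_warning(buildDesignSystem(recs, vocab = c("g1", "g2", "g3")),
                 "unused vocabulary")
  ## records with uncovered atoms are excluded with a message
  recs2 <- c(recs, list(list(counts = c(g1 = 1L), hc = -5, uncovered = 3L)))
  expect_message(sys2 <- buildDesignSystem(recs2), "excluded")
  expect_equal(nrow(sys2$X), 2)
})

test_that("Gauss-Seidel solves diagonal systems in closed form", {
  X <- diag(c(2, 3, 5))
  colnames(X) <- paste0("g", 1:3)
  y <- c(-20, -9, -35)
  fit <- gaussSeidelSolve(X, y)
  expect_equal(unname(fit$x), y / c(2, 3, 5), tolerance = 1e-9)
})

test_that("Gauss-Seidel matches the direct least-squares oracle on random systems", {
  set.seed(7)
  for (rep in 1:25) {
    M <- sample(10:60, 1); N <- sample(3:15, 1)
    X <- matrix(rpois(M * N, 1.2), M, N)
    X[cbind(seq_len(N), seq_len(N))] <- X[cbind(seq_len(N), seq_len(N))] + 1
    colnames(X) <- paste0("g", seq_len(N))
    y <- rnorm(M, -500, 200)
    direct <- qr.solve(crossprod(X), crossprod(X, y))
    gs <- gaussSeidelSolve(X, y, tol = 1e-9)
    expect_lt(max(abs(gs$x - drop(direct))), 1e-6)
  }
})

test_that("degenerate solver inputs fail loudly, never silently", {
  X <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))  # perfectly collinear
  expect_error(gaussSeidelSolve(X, c(1, 2, 3)), class = "hcgroups_nonidentifiable")
  X2 <- cbind(g1 = c(1, 1), g2 = c(0, 0))
  expect_warning(fit <- gaussSeidelSolve(X2, c(1, 2)), "zero-occurrence")
  expect_equal(fit$dropped, "g2")
  ## an impossible sweep budget raises a convergence error carrying the iterate
  X3 <- matrix(rpois(80, 1.5) + 1, 20, 4, dimnames = list(NULL, paste0("g", 1:4)))
  err <- tryCatch(gaussSeidelSolve(X3, rnorm(20), tol = 1e-12, max_iter = 1L),
                  condition = identity)
  expect_s3_class(err, "hcgroups_convergence_error")
  expect_length(err$x, 4)
})

test_that("noise-free synthetic fits are exact with no outliers rejected", {
  g <- genDesign(syntheticDesignSpec(n_molecules = 40, n_groups = 6,
                                     noise_sd = 0, seed = 11))
  res <- fitContributions(g$records, folds = 10, seed = 3, tol = 1e-9)
  expect_length(res$outliers, 0)
  expect_equal(res$fit$r2, 1, tolerance = 1e-9)
  expect_lt(res$fit$sigma_n, 1e-5)
  expect_lt(max(abs(res$fit$contributions[names(g$truth)] - g$truth)), 1e-6)
})

test_that("cross-validation tests every record exactly once, including leave-one-out", {
  g <- genDesign(syntheticDesignSpec(n_molecules = 12, n_groups = 3,
                                     noise_sd = 2, seed = 5))
  cv <- crossValidate(g$X, g$y, folds = 12, seed = 9)
  expect_equal(sort(unique(cv$fold)), 1:12)
  expect_true(all(table(cv$fold) == 1))
  cv10 <- crossValidate(g$X, g$y, folds = 4, seed = 9)
  expect_equal(length(cv10$pred), 12)
  expect_true(all(table(cv10$fold) == 3))
  ## deterministic under the seed
  cv10b <- crossValidate(g$X, g$y, folds = 4, seed = 9)
  expect_identical(cv10, cv10b)
  expect_error(crossValidate(g$X, g$y, folds = 13), "folds")
})

test_that("the 3xS rejection loop removes planted gross outliers and is monotone", {
  hits <- numeric(5)
  for (rep in 1:5) {
    g <- genDesign(syntheticDesignSpec(n_molecules = 60, n_groups = 8,
                                       noise_sd = 5, outlier_fraction = 0.05,
                                       outlier_magnitude = 10, seed = 100 + rep))
    res <- fitContributions(g$records, folds = 10, seed = rep)
    planted <- paste0("syn", g$outliers)
    hits[rep] <- mean(planted %in% res$outliers)
    ## survivors never grow: kept + outliers partition the input
    expect_equal(length(res$kept) + length(res$outliers), 60)
    expect_length(intersect(res$kept, res$outliers), 0)
  }
  expect_gte(median(hits), 0.9)
})

test_that("validity interplay: accuracy statistics cover fewer compounds than the fit", {
  g <- genDesign(syntheticDesignSpec(n_molecules = 50, n_groups = 10,
                                     count_lambda = 0.8, zipf_s = 1.6,
                                     noise_sd = 3, seed = 21))
  res <- fitContributions(g$records, min_molecules = 3, folds = 10, seed = 2)
  expect_lte(res$fit$n_compounds_evaluated, res$fit$n_compounds_fit)
  ## rare groups exist in this sparse design, so the gap is real
  expect_lt(res$fit$n_compounds_evaluated, res$fit$n_compounds_fit)
  ## the returned table is usable for prediction with the validity rule
  expect_s4_class(res$table, "ContributionTable")
  expect_equal(validGroupCount(res$table),
               sum(res$fit$molecules >= 3))
})

test_that("cross-validated fit does not look better than the resubstitution fit", {
  q2r2 <- t(vapply(1:5, function(rep) {
    g <- genDesign(syntheticDesignSpec(n_molecules = 60, n_groups = 6,
                                       noise_sd = 20, seed = 300 + rep))
    res <- fitContributions(g$records, folds = 10, seed = rep)
    c(q2 = res$cv$q2, r2 = res$fit$r2)
  }, numeric(2)))
  expect_lte(median(q2r2[, "q2"]), median(q2r2[, "r2"]) + 1e-6)
})

test_that("summary statistics match hand arithmetic and the published suite", {
  s <- computeStats(c(-10, -20, -30), c(-10, -20, -30))
  expect_equal(s$r2, 1)
  expect_equal(s$sigma_n, 0)
  expect_equal(s$avg_dev, 0)
  expect_equal(s$mad_percent, 0)
  ## two-point hand example: residuals 1 and -1
  s2 <- computeStats(c(-100, -200), c(-101, -199))
  expect_equal(s2$sigma_n, 1)
  expect_equal(s2$avg_dev, 1)
  expect_equal(s2$mad_percent, mean(c(1 / 100, 1 / 200)) * 100)
  ## the printed reference columns of the ionic-liquid comparison
  il <- ionicLiquidSuite()
  s3 <- computeStats(il$hc_exp, il$hc_calc_ref)
  expect_equal(round(s3$mad_percent, 2), 0.23)
  expect_error(computeStats(c(-5, -5), c(-4, -6)), "zero variance")
})

test_that("kcal training inputs are converted on ingestion", {
  m <- parseSmiles("CC(=O)C", "acetone")
  r <- recordsFromMolecules(list(m), -427.95, ctab, units = "kcal")
  expect_equal(r[[1]]$hc, -427.95 * 4.1858)
  expect_equal(sum(r[[1]]$counts), 3)
})
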