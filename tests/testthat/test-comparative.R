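test_that("residualization removes exactly the fitted covariates", {
  x <- 1:20
  expect_equal(residualize(2 * x, x), rep(0, 20))

  y <- rnorm(20)
  expect_equal(residualize(y, rep(1, 20) * 0 + 5), y - mean(y))

  # two covariates: match the normal-equations solution computed directly
  set.seed(41)
  X <- cbind(rnorm(30), runif(30))
  y <- 3 + 2 * X[, 1] - X[, 2] + rnorm(30)
  M <- cbind(1, X)
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(residualize(y, X), as.numeric(y - M %*% beta))
  r <- residualize(y, X)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(max(abs(crossprod(X, r))), 1e-9)

  expect_error(residualize(y, cbind(X[, 1], 2 * X[, 1])), "collinear")
  expect_error(residualize(c(y, NA), rbind(X, 0)), "missing")
})

test_that("contrasts reproduce hand-executed pruning", {
  # two leaves, unit branches, traits 4 and 2: single contrast 2/sqrt(2)
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(independent_contrasts(t2, c(A = 4, B = 2))),
               2 / sqrt(2), tolerance = 1e-9)

  # ((A:1,B:1):1,C:2): contrast AB = sqrt(2), ancestral value 2 with its
  # branch extended to 1.5, so the root contrast is (2-2)/sqrt(3.5) = 0
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cs <- independent_contrasts(t3, c(A = 3, B = 1, C = 2))
  expect_equal(sort(abs(unname(cs))), c(0, sqrt(2)), tolerance = 1e-9)

  # flat traits give all-zero contrasts
  expect_equal(unname(independent_contrasts(t3, c(A = 1, B = 1, C = 1))),
               c(0, 0))
})

test_that("contrasts agree with an established implementation", {
  set.seed(42)
  for (r in 1:10) {
    tr <- ape::rphylo(sample(5:40, 1), 1, 0)
    x <- stats::setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    mine <- independent_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    # contrast signs depend on arbitrary child ordering; magnitudes do not
    expect_equal(abs(mine[names(ref)]), abs(ref), tolerance = 1e-10)
  }
})

test_that("contrast preconditions are enforced", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(independent_contrasts(t3, c(A = 1, B = 2)), "C")
  expect_error(independent_contrasts(t3, c(A = 1, B = 2, C = NA)), "NA|value")
  tz <- ape::read.tree(text = "((A:1,B:1):0,C:2);")
  expect_message(cs <- independent_contrasts(tz, c(A = 3, B = 1, C = 2)),
                 "zero-length")
  expect_equal(length(cs), 2L)
})

test_that("through-origin contrast correlation behaves at its anchors", {
  set.seed(43)
  cx <- rnorm(50)
  expect_equal(contrast_correlation(cx, 2 * cx)$rho, 1)
  cy <- rnorm(50)
  cy <- cy - cx * sum(cx * cy) / sum(cx^2)   # project out cx
  expect_lt(abs(contrast_correlation(cx, cy)$rho), 1e-10)
  expect_equal(contrast_correlation(cx, cy)$df, 49L)
  expect_error(contrast_correlation(cx[1:2], cy[1:2]), "at least 3")
})

test_that("correlation strength is recovered from simulated contrasts", {
  # BM trait pairs with true correlation 0.8 on one Yule tree
  set.seed(44)
  tree <- ape::rphylo(64, 1, 0)
  rhos <- replicate(120, {
    xy <- bm_pair_oracle(tree, rho = 0.8)
    cx <- independent_contrasts(tree, xy[, 1])
    cy <- independent_contrasts(tree, xy[, 2])
    contrast_correlation(cx, cy)$rho
  })
  expect_lt(abs(mean(rhos) - 0.8), 0.05)
})

test_that("star-like trees reduce contrasts to ordinary correlation", {
  set.seed(45)
  n <- 100
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star <- ape::multi2di(star)
  x <- stats::setNames(rnorm(n), star$tip.label)
  y <- stats::setNames(0.6 * x + rnorm(n, sd = 0.8), star$tip.label)
  cx <- suppressMessages(independent_contrasts(star, x))
  cy <- suppressMessages(independent_contrasts(star, y))
  expect_lt(abs(contrast_correlation(cx, cy)$rho - cor(x, y)), 0.05)
})

test_that("subpopulation splits and tests follow the spec'd conventions", {
  rec <- data.frame(lifespan = 1:10, dr_count = c(1:5, 1:5))
  out <- subpopulation_tests(rec, percentile = 50, value = "dr_count")
  expect_equal(out$n_short, 5L)
  expect_equal(out$n_long, 5L)
  # identical distributions: KS statistic 0, p = 1
  expect_equal(out$ks$statistic, 0)
  expect_equal(out$ks$p, 1)
  expect_error(subpopulation_tests(rec, 50, value = "nope"), "nope")
})

test_that("the one-sided t-test has power at a 1-sd shift", {
  set.seed(46)
  hits <- 0L
  for (r in 1:200) {
    short <- rnorm(100)
    long <- rnorm(100, mean = 1)
    rec <- data.frame(lifespan = c(rep(1, 100), rep(10, 100)),
                      dr_count = c(short, long))
    out <- subpopulation_tests(rec, percentile = 50, value = "dr_count",
                               alternative = "less")
    if (out$t$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("ensemble z-test matches the normal CDF", {
  flat <- list(mean = 10, sd = 2)
  expect_equal(ensemble_z_test(10, flat)$z, 0)
  expect_equal(ensemble_z_test(10, flat)$p, 1)
  zt <- ensemble_z_test(16, flat)
  expect_equal(zt$z, 3)
  expect_equal(zt$p, 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(ensemble_z_test(16, flat, "greater")$p, pnorm(-3),
               tolerance = 1e-12)
  expect_error(ensemble_z_test(5, list(mean = 10, sd = 0)), "positive")
})

test_that("constraint line fits its support set only", {
  pts <- data.frame(id = letters[1:8], x = 1:8,
                    y = c(2, 4.2, 6, 8, 10, 3, 1, 12.5))
  # support a,c,d,e are exactly collinear: y = 2x
  fit <- constraint_line(pts, support = c("a", "c", "d", "e"))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_setequal(fit$above, "b")
  # support = all points equals the ordinary regression line
  all_fit <- constraint_line(pts, support = pts$id)
  lm_fit <- lm(y ~ x, data = pts)
  expect_equal(all_fit$slope, unname(coef(lm_fit)[2]))
  expect_equal(all_fit$intercept, unname(coef(lm_fit)[1]))
  # closed-form slope on 5 support points
  sub <- pts[1:5, ]
  cf <- sum((sub$x - mean(sub$x)) * (sub$y - mean(sub$y))) /
    sum((sub$x - mean(sub$x))^2)
  expect_equal(constraint_line(pts, support = pts$id[1:5])$slope, cf)
  # exclusions shrink the support (bowhead-whale style exclusion)
  expect_error(constraint_line(pts, support = c("a", "b"), exclude = "b"),
               "at least 2")
})

test_that("pairwise group tests are symmetric and detect real shifts", {
  set.seed(47)
  g1 <- rnorm(50)
  g2 <- rnorm(50)
  g3 <- rnorm(50, mean = 2)
  vals <- c(g1, g2, g3)
  grp <- rep(c("A", "B", "C"), each = 50)
  P <- group_pairwise_tests(vals, grp)
  expect_equal(P["A", "B"], P["B", "A"])
  expect_gt(P["A", "B"], 0.05)
  expect_lt(P["A", "C"], 0.01)
  expect_lt(P["B", "C"], 0.01)
  expect_true(all(is.na(diag(P))))
  # degenerate groups are skipped, not fatal
  P2 <- group_pairwise_tests(c(1, 1, 2, 3), c("A", "A", "B", "B")[c(1, 2, 3, 4)])
  expect_true(is.matrix(P2))
})
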