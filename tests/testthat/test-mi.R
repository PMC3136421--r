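test_that("copula transform maps to scaled ranks and is monotone-invariant", {
  expect_equal(as.numeric(copula_transform(rbind(c(3, 1, 2)))),
               c(0.75, 0.25, 0.50))
  # average ranks for ties: constant gene maps to 0.5 everywhere
  expect_equal(as.numeric(copula_transform(rbind(c(5, 5, 5, 5)))),
               rep(0.5, 4))
  set.seed(1)
  x <- matrix(runif(40), 4, 10)
  expect_equal(copula_transform(x), copula_transform(exp(x)))
  expect_error(copula_transform(matrix(1, 2, 1)), "2 samples")
})

test_that("Gaussian MI estimator matches its closed form and basic symmetries", {
  expect_error(mi_gaussian(1:3, 1:4), "equal length")

  # symmetry and rank symmetry under sign flip / monotone shift
  set.seed(2)
  x <- runif(50); y <- runif(50)
  expect_equal(mi_gaussian(x, y), mi_gaussian(y, x))
  expect_equal(mi_gaussian(x, -x), mi_gaussian(x, exp(x) + 1))
  expect_gte(mi_gaussian(x, y), 0)

  # closed-form oracle: pair with correlation 0.5 on the copula scale
  # -> MI converges to -0.5 * log(0.75) = 0.1438 nats. The latent Gaussian
  # correlation is chosen so the rank-scale Pearson correlation is 0.5.
  target <- -0.5 * log(1 - 0.5^2)
  rho_z <- 2 * sin(pi * 0.5 / 6)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    m <- 4000
    z1 <- rnorm(m); z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(m)
    abs(mi_gaussian(pnorm(z1), pnorm(z2)) - target)
  }, numeric(1))
  expect_gte(mean(errs < 0.02), 0.95)

  # independence: MI near zero at large m
  small <- vapply(1:20, function(s) {
    set.seed(s + 100)
    mi_gaussian(runif(10000), runif(10000))
  }, numeric(1))
  expect_gte(mean(small < 0.01), 0.95)
})

test_that("MI matrix equals brute-force pairwise estimation on a shared copula", {
  set.seed(3)
  data <- matrix(runif(5 * 30), 5, 30,
                 dimnames = list(paste0("g", 1:5), NULL))
  mim <- mi_matrix(data)
  expect_equal(mim, t(mim))
  expect_equal(unname(diag(mim)), rep(0, 5))
  u <- copula_transform(data)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(mim[i, j], mi_gaussian(u[i, ], u[j, ], transformed = TRUE))
  }

  # duplicated gene rows hit the correlation clip: large finite MI
  dup <- rbind(a = data[1, ], b = data[1, ])
  md <- mi_matrix(dup)
  expect_true(is.finite(md[1, 2]))
  expect_equal(md[1, 2], -0.5 * log(1 - (1 - 1e-12)^2))

  # rank invariance of the whole matrix to 12 digits
  distorted <- data
  distorted[2, ] <- exp(distorted[2, ])
  distorted[4, ] <- distorted[4, ]^3
  expect_equal(mi_matrix(distorted), mim, tolerance = 1e-12)
})

test_that("permutation null has the right size and matches the observed
           distribution under independence", {
  set.seed(4)
  data <- matrix(runif(3 * 20), 3, 20)
  null1 <- build_null(data, itnum = 1, seed = 1)
  expect_length(null1$null_values, 3L)      # n(n-1)/2 per iteration
  null5 <- build_null(data, itnum = 5, seed = 1)
  expect_length(null5$null_values, 15L)
  expect_identical(build_null(data, itnum = 3, seed = 2),
                   build_null(data, itnum = 3, seed = 2))

  # on independent data the null is distributed like the observed MI values
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    d <- matrix(runif(8 * 50), 8, 50)
    obs <- mi_matrix(d)
    nl <- build_null(d, itnum = 3, seed = s + 50)
    suppressWarnings(stats::ks.test(obs[upper.tri(obs)],
                                    nl$null_values)$p.value)
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("empirical p-values follow the add-one permutation rule", {
  mim <- matrix(c(0, 0.25, 0.25, 0), 2, 2)
  null <- structure(list(null_values = c(0.1, 0.2, 0.3, 0.4), itnum = 1L,
                         seed = 1L), class = "minull")
  p <- mi_pvalues(mim, null)
  expect_equal(p[1, 2], (1 + 2) / 5)   # two null values >= 0.25

  null99 <- structure(list(null_values = sort(runif(99, 0, 0.5)), itnum = 1L,
                           seed = 1L), class = "minull")
  phigh <- mi_pvalues(matrix(c(0, 0.9, 0.9, 0), 2, 2), null99)
  expect_equal(phigh[1, 2], 1 / 100)
  plow <- mi_pvalues(matrix(0, 2, 2) , null99)
  expect_equal(plow[1, 2], 1)
  expect_error(mi_pvalues(mim, structure(list(null_values = numeric(0)),
                                         class = "minull")),
               "empty null")
})

test_that("p-value adjustment wraps the standard procedures and dominates raw p", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  # BH step-up computed by hand
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_error(adjust_pvalues(0.5, "bogus"), "BH")
  expect_error(adjust_pvalues(1.2, "BH"), "\\[0, 1\\]")

  # dominance: adjusted >= raw; bonferroni >= holm >= BH elementwise
  set.seed(5)
  for (rep_ in 1:20) {
    p <- runif(25)
    for (m in c("BH", "bonferroni", "BY", "hochberg", "holm", "hommel")) {
      expect_true(all(adjust_pvalues(p, m) >= p))
    }
    bon <- adjust_pvalues(p, "bonferroni")
    hol <- adjust_pvalues(p, "holm")
    bh <- adjust_pvalues(p, "BH")
    expect_true(all(bon >= hol - 1e-15))
    expect_true(all(hol >= bh - 1e-15))
  }
})

test_that("significance masks implement the three elimination modes", {
  set.seed(6)
  data <- matrix(runif(6 * 40), 6, 40)
  mim <- mi_matrix(data)

  high <- significance_mask(mim, "cutoff", cutoffMI = max(mim) + 1)
  expect_false(any(high$mask))
  zero <- significance_mask(mim, "cutoff", cutoffMI = 0)
  expect_true(all(zero$mask[upper.tri(zero$mask)]))
  expect_false(any(diag(zero$mask)))

  expect_error(significance_mask(mim, "justp"), "data")
  jp <- significance_mask(mim, "justp", data = data, alpha = 0.4,
                          itnum = 2, seed = 3)
  expect_equal(jp$mask, t(jp$mask))

  mtc <- significance_mask(mim, "MTC", data = data, alpha = 0.4,
                           MTCmethod = "BH", itnum = 2, seed = 3)
  # MTC keeps a subset of what justp keeps at the same alpha and null seed
  expect_true(all(which(mtc$mask) %in% which(jp$mask)))
})
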