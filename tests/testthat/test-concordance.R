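test_that("kappa point estimates match hand-computed values", {
  expect_equal(cohen_kappa(19, 0, 0, 11)$kappa, 1)
  # po = 28/30, pe = 482/900
  k <- cohen_kappa(18, 1, 1, 10)
  expect_equal(k$kappa, (28 / 30 - 482 / 900) / (1 - 482 / 900))
  expect_equal(k$kappa, 0.856459, tolerance = 1e-6)
  expect_equal(cohen_kappa(9, 9, 1, 1)$kappa, 0)  # marginal independence
})

test_that("kappa standard errors, CI and p-value match the asymptotic formulas", {
  # frozen reference values computed independently from the Fleiss-Cohen
  # variance formulas (cross-checked against statsmodels' cohens_kappa)
  k <- cohen_kappa(18, 1, 1, 10)
  expect_equal(k$se, 0.097980, tolerance = 1e-5)
  expect_equal(k$se0, 0.182574, tolerance = 1e-5)
  expect_equal(k$p, 2.71845e-06, tolerance = 1e-4)
  expect_equal(k$ci,
               pmin(pmax(k$kappa + c(-1, 1) * qnorm(0.975) * k$se, -1), 1))

  k2 <- cohen_kappa(28, 1, 0, 1)
  expect_equal(k2$kappa, 0.651163, tolerance = 1e-6)
  expect_equal(k2$se, 0.321429, tolerance = 1e-5)
  expect_equal(k2$p, 0.000141448, tolerance = 1e-4)
  expect_lte(k2$ci[2], 1)  # clipped

  k3 <- cohen_kappa(matrix(c(20, 2, 3, 5), 2, 2, byrow = TRUE))
  expect_equal(k3$kappa, 0.556213, tolerance = 1e-6)
  expect_true(k3$ci[1] <= k3$kappa && k3$kappa <= k3$ci[2])
})

test_that("kappa is symmetric in raters and invariant to class relabeling", {
  set.seed(31)
  for (rep in 1:25) {
    t <- as.list(sample(0:8, 4, replace = TRUE))
    names(t) <- c("a", "b", "c", "d")
    if (sum(unlist(t)) == 0) next
    k1 <- cohen_kappa(t$a, t$b, t$c, t$d)
    k2 <- cohen_kappa(t$a, t$c, t$b, t$d)  # raters swapped
    k3 <- cohen_kappa(t$d, t$c, t$b, t$a)  # classes relabeled
    if (k1$estimable) {
      expect_equal(k1$kappa, k2$kappa)
      expect_equal(k1$kappa, k3$kappa)
    }
    # kappa = 1 iff no discordant pairs (with both classes present)
    if (k1$estimable && t$a > 0 && t$d > 0) {
      expect_identical(k1$kappa == 1, t$b == 0 && t$c == 0)
    }
  }
})

test_that("constant identical raters give a non-estimable kappa, never 0", {
  k <- cohen_kappa(30, 0, 0, 0)
  expect_false(k$estimable)
  expect_true(is.na(k$kappa))
  expect_true(is.na(k$p))
})

test_that("agreement bands reproduce the published categories", {
  expect_identical(categorize_kappa(0.930), "very good")
  expect_identical(categorize_kappa(1.0), "very good")
  expect_identical(categorize_kappa(0.902), "very good")
  expect_identical(categorize_kappa(0.870), "very good")
  expect_identical(categorize_kappa(0.789), "good")
  expect_identical(categorize_kappa(0.783), "good")
  expect_identical(categorize_kappa(0.760), "good")
  expect_identical(categorize_kappa(c(0.667, 0.651, 0.615, 0.609)),
                   rep("good", 4L))
  expect_identical(categorize_kappa(c(0.516, 0.444, 0.429)),
                   rep("moderate", 3L))
  expect_identical(categorize_kappa(0.348), "weak")
  expect_identical(categorize_kappa(-0.047), "poor")
  expect_error(categorize_kappa(1.2), "\\[-1, 1\\]")
})

test_that("exact McNemar p-values match the binomial enumeration", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(1, 1), 1)          # 2 * P(X <= 1 | n = 2) capped
  expect_equal(mcnemar_exact(5, 0), 0.0625)     # 2 * (1/2)^5
  for (b in 0:12) for (c in 0:(12 - b)) {
    expect_equal(mcnemar_exact(b, c), oracle_mcnemar(b, c),
                 tolerance = 1e-12, info = paste(b, c))
  }
})

test_that("t-based CIs reproduce published descriptive intervals", {
  expect_equal(round(mean_ci_t(30, 46.1, 13.9), 1), c(low = 40.9, high = 51.3))
  expect_equal(round(mean_ci_t(30, 161.5, 5.9), 1), c(low = 159.3, high = 163.7))
  expect_equal(round(mean_ci_t(30, 1.5, 1.1), 1), c(low = 1.1, high = 1.9))
  expect_equal(unname(mean_ci_t(10, 5, 0)), c(5, 5))
  expect_error(mean_ci_t(1, 5, 1), "n >= 2")
})

test_that("the concordance table composes kappa and McNemar per endpoint", {
  set.seed(77)
  n <- 30L
  truth <- data.frame(patient_id = sprintf("P%03d", 1:n))
  for (org in organ_ids()) {
    truth[[org]] <- rbinom(n, 1L, 0.8)
    truth[[org]][1:2] <- c(0L, 1L)  # keep both classes present
  }
  truth$vagina <- 1L  # constant endpoint on both sides
  truth$plane_correct <- as.integer(rowSums(truth[organ_ids()]) == 8L)

  rater <- truth
  flip <- c(3L, 11L, 20L)
  rater$rectum[flip] <- 1L - rater$rectum[flip]
  rater$plane_correct <- as.integer(rowSums(rater[organ_ids()]) == 8L)

  tab <- concordance_table(truth, rater)
  expect_identical(tab$endpoint, c("midsagittal_plane", organ_ids()))
  expect_identical(tab$n, rep(n, 9L))

  # perfect self-agreement endpoints
  for (ep in setdiff(organ_ids(), c("rectum", "vagina"))) {
    expect_equal(tab$kappa[tab$endpoint == ep], 1)
  }
  # constant endpoint: kappa and McNemar not estimable
  expect_true(is.na(tab$kappa[tab$endpoint == "vagina"]))
  expect_true(is.na(tab$mcnemar_p[tab$endpoint == "vagina"]))

  # composition: table row equals direct computation on the same vectors
  a <- sum(truth$rectum == 1 & rater$rectum == 1)
  b <- sum(truth$rectum == 1 & rater$rectum == 0)
  c_ <- sum(truth$rectum == 0 & rater$rectum == 1)
  d <- sum(truth$rectum == 0 & rater$rectum == 0)
  direct <- cohen_kappa(a, b, c_, d)
  row <- tab[tab$endpoint == "rectum", ]
  expect_equal(row$kappa, direct$kappa)
  expect_equal(row$mcnemar_p, mcnemar_exact(b, c_))
  expect_identical(row$rater_correct, a + c_)
  expect_identical(row$category, direct$category)

  # rows are matched by patient id, not position
  shuffled <- rater[sample(n), ]
  tab2 <- concordance_table(truth, shuffled)
  expect_equal(tab2$kappa, tab$kappa)

  expect_error(concordance_table(truth, rater[-1L, ]), "same patients")
})
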