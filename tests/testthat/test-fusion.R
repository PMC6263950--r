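test_that("probability outputs discount into valid mass functions", {
  m <- proba_to_bpa(c(0.7, 0.1, 0.1, 0.1), reliability = 0.9)
  expect_equal(unname(mvec(m)), c(0.63, 0.09, 0.09, 0.09, 0.10),
               tolerance = 1e-12)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  full <- proba_to_bpa(c(1, 0, 0, 0), reliability = 1)
  expect_equal(mvec(full)[["normal"]], 1)
  vac <- proba_to_bpa(c(0.7, 0.1, 0.1, 0.1), reliability = 0)
  expect_equal(mvec(vac)[["U"]], 1)
  expect_error(proba_to_bpa(c(0.5, 0.2, 0.1, 0.1)), "invalid probability")
  expect_error(proba_to_bpa(c(0.7, 0.1, 0.1, 0.1), reliability = 1.2),
               "reliability")
})

test_that("Dempster combination matches hand-worked two-singleton example", {
  fr <- c("normal", "moldy", "U")
  m1 <- mass_function(c(normal = 0.6, moldy = 0.3, U = 0.1), frame = fr)
  m2 <- mass_function(c(normal = 0.5, moldy = 0.4, U = 0.1), frame = fr)
  res <- dempster_combine(m1, m2)
  expect_equal(res$K, 0.6 * 0.4 + 0.3 * 0.5, tolerance = 1e-12)
  expect_equal(mvec(res$mass)[["normal"]],
               (0.30 + 0.06 + 0.05) / 0.61, tolerance = 1e-12)
})

test_that("the vacuous mass is the neutral element and conflict is bounded", {
  set.seed(14)
  vac <- mass_function(c(U = 1))
  for (i in 1:20) {
    m <- random_mass()
    res <- dempster_combine(m, vac)
    expect_equal(mvec(res$mass), mvec(m), tolerance = 1e-12)
    expect_equal(res$K, 0)
    m2 <- random_mass()
    K <- dempster_combine(m, m2)$K
    expect_true(K >= 0 && K < 1)
  }
})

test_that("total conflict between certain contradictory sources errors", {
  m1 <- mass_function(c(normal = 1))
  m2 <- mass_function(c(moldy = 1))
  expect_error(dempster_combine(m1, m2), "total conflict")
})

test_that("combination is commutative and associative", {
  set.seed(15)
  for (i in 1:15) {
    a <- random_mass(); b <- random_mass(); cc <- random_mass()
    ab <- dempster_combine(a, b)
    ba <- dempster_combine(b, a)
    expect_equal(mvec(ab$mass), mvec(ba$mass), tolerance = 1e-12)
    expect_equal(ab$K, ba$K, tolerance = 1e-12)
    abc1 <- dempster_combine(ab$mass, cc)$mass
    abc2 <- dempster_combine(a, dempster_combine(b, cc)$mass)$mass
    expect_equal(mvec(abc1), mvec(abc2), tolerance = 1e-10)
  }
})

test_that("repeated concordant evidence reinforces the leading hypothesis", {
  set.seed(16)
  for (i in 1:10) {
    m <- random_mass()
    s <- mvec(m)[wheat_classes()]
    if (max(s) == sort(s, decreasing = TRUE)[2]) next  # need a strict max
    top <- names(s)[which.max(s)]
    comb <- dempster_combine(m, m)$mass
    expect_gt(mvec(comb)[[top]], mvec(m)[[top]])
  }
})

test_that("combination equals the exhaustive focal-pair enumeration oracle", {
  set.seed(17)
  for (i in 1:25) {
    m1 <- random_mass(); m2 <- random_mass()
    got <- dempster_combine(m1, m2)
    want <- ds_combine_oracle(m1, m2)
    expect_equal(mvec(got$mass), want$mass, tolerance = 1e-12)
    expect_equal(got$K, want$K, tolerance = 1e-12)
  }
})

test_that("the epsilon-threshold decision rule follows its three conditions", {
  dominant <- mass_function(c(normal = 0.9, germinated = 0.02, moldy = 0.02,
                              `worm-eaten` = 0.02, U = 0.04))
  expect_equal(as.character(ds_decide(dominant, 0.1, 0.3)), "normal")
  close_race <- mass_function(c(normal = 0.40, germinated = 0.35,
                                moldy = 0.1, `worm-eaten` = 0.05, U = 0.10))
  expect_equal(as.character(ds_decide(close_race, 0.1, 0.3)), "uncertain")
  # heavy mass on U defers regardless of the singleton race
  hazy <- mass_function(c(normal = 0.4, germinated = 0.05, moldy = 0.03,
                          `worm-eaten` = 0.02, U = 0.5))
  expect_equal(as.character(ds_decide(hazy, 0.1, 0.3)), "uncertain")
  tied <- mass_function(c(normal = 0.45, germinated = 0.45, U = 0.10))
  d <- ds_decide(tied, 0.1, 0.3)
  expect_equal(as.character(d), "uncertain")
  expect_true(attr(d, "tie"))
  expect_equal(attr(d, "A1"), "normal")   # fixed class order breaks the tie
})

test_that("the decision pipeline resolves agreement and defers conflict", {
  fx <- blob_features(n_per_class = 40, seed = 19)
  clf_a <- train_svm(fx$x, fx$y, kernel = "radial", gamma = 0.5, cost = 10,
                     seed = 1)
  clf_b <- train_svm(fx$x, fx$y, kernel = "radial", gamma = 0.5, cost = 10,
                     seed = 2)
  # same confident features to both sources -> agreement, tiny conflict
  probe <- matrix(c(0, 0), 1)              # deep inside "normal"
  agree <- ds_pipeline(clf_a, clf_b, probe, probe,
                       bel_abs = 0.95, bel_ref = 0.95)
  expect_equal(agree$decision, "normal")
  expect_lt(agree$K, 0.35)
  # contradictory confident features -> high conflict, deferred
  probe_b <- matrix(c(8, 8), 1)            # deep inside "worm-eaten"
  clash <- ds_pipeline(clf_a, clf_b, probe, probe_b,
                       bel_abs = 0.95, bel_ref = 0.95)
  expect_equal(clash$decision, "uncertain")
  expect_gt(clash$K, 0.5)
  expect_error(ds_pipeline(clf_a, clf_b, probe, rbind(probe, probe)),
               "different numbers")
})
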