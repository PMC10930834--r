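tab <- broiler_batches()

test_that("reference dataset: CRS frontier is {4, 23}, score regression", {
  res <- dea(tab, dea_model("crs", "input"))
  expect_equal(efficient_dmus(res), c(4, 23))
  # frozen from this dataset; independently confirmed by vertex/dual checks
  expect_equal(unname(res$scores["31"]), 0.8841634618, tolerance = 1e-8)
  expect_equal(unname(res$scores["4"]), 1)
})

test_that("CRS input and output orientations report the same score", {
  rin <- dea(tab, dea_model("crs", "input"))
  rout <- dea(tab, dea_model("crs", "output"))
  expect_equal(rin$scores, rout$scores, tolerance = 1e-9)
  for (seed in 1:5) {
    rt <- random_table(6, 2, seed = 100 + seed)
    expect_equal(dea(rt)$scores,
                 dea(rt, dea_model("crs", "output"))$scores,
                 tolerance = 1e-9)
  }
})

test_that("VRS scores dominate CRS scores in both orientations", {
  for (orient in c("input", "output")) {
    crs <- dea(tab, dea_model("crs", orient))$scores
    vrs <- dea(tab, dea_model("vrs", orient))$scores
    expect_true(all(vrs >= crs - 1e-9))
    expect_true(any(vrs >= 1 - 1e-6))     # frontier never empty
  }
})

test_that("VRS frontier of the reference dataset", {
  vrs <- dea(tab, dea_model("vrs", "input"))$scores
  expect_equal(efficient_dmus(dea(tab, dea_model("vrs", "input"))),
               c(4, 7, 22, 23, 25, 28, 30, 31))
  # DMU 14 sits just inside the frontier as printed data have it
  expect_equal(unname(vrs["14"]), 0.9996650416, tolerance = 1e-8)
  expect_equal(sum(round(vrs, 2) == 1), 9)  # nine display as 1.00
})

test_that("scores are invariant under positive column rescaling", {
  res <- dea(tab)$scores
  scaled <- as.data.frame(tab)
  scaled$housing <- scaled$housing * 1e-5
  scaled$cost <- scaled$cost * 3172.4
  res2 <- dea(dmu_table(scaled))$scores
  expect_lt(max(abs(res - res2)), 1e-9)
})

test_that("solver agrees with exhaustive dual-vertex enumeration", {
  for (seed in 1:20) {
    rt <- random_table(3, 2, seed = 200 + seed)
    X <- as.matrix(as.data.frame(rt)[, c("x1", "x2")])
    Y <- as.matrix(as.data.frame(rt)[, "y", drop = FALSE])
    got <- dea(rt)$scores
    want <- vapply(1:3, function(o) crs_input_oracle(X, Y, o), numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("adding a dominated DMU leaves every other score unchanged", {
  for (seed in 1:5) {
    rt <- random_table(6, 2, seed = 300 + seed)
    base <- dea(rt)$scores
    aug <- as.data.frame(rt)
    dom <- aug[which.max(aug$x1), ]
    dom$dmu <- 99; dom$x1 <- dom$x1 * 1.5; dom$y <- dom$y * 0.7
    aug <- dmu_table(rbind(aug, dom), input_names = c("x1", "x2"),
                     output_names = "y")
    expect_equal(dea(aug)$scores[as.character(rt$dmu)], base,
                 tolerance = 1e-9)
  }
})

test_that("two-unit table: the dominating unit defines the frontier", {
  d <- dmu_table(data.frame(dmu = 1:2, x = c(1, 2), y = c(1, 1)),
                 input_names = "x", output_names = "y")
  sc <- dea(d)$scores
  expect_equal(unname(sc), c(1, 0.5))
})

test_that("slacks, targets and benchmarks satisfy the envelopment identity", {
  res <- dea(tab)
  tg <- projection_targets(res, tab)          # errors if identity violated
  # input orientation: targets never exceed observed inputs
  obs_in <- as.matrix(as.data.frame(tab)[, attr(tab, "inputs")])
  expect_true(all(tg[, 1:5] <= obs_in + 1e-9))
  # efficient DMUs project onto themselves
  for (id in c("4", "23")) {
    i <- which(tab$dmu == as.integer(id))
    expect_equal(unname(tg[id, ]),
                 unname(unlist(as.data.frame(tab)[i, c(attr(tab, "inputs"),
                                                       attr(tab, "outputs"))])),
                 tolerance = 1e-8)
  }
  # peers of every unit are themselves efficient
  sc <- res$scores
  for (b in unique(unlist(res$benchmarks)))
    expect_gte(sc[as.character(b)], 1 - 1e-6)
  # output orientation targets expand outputs only
  ro <- dea(tab, dea_model("crs", "output"))
  tgo <- projection_targets(ro, tab)
  expect_true(all(tgo[, 6] >= tab$total_weight - 1e-9))
})

test_that("multiplier weights are feasible and reproduce the score", {
  res <- dea(tab)
  X <- as.matrix(as.data.frame(tab)[, attr(tab, "inputs")])
  X <- sweep(X, 2, colMeans(X), "/")
  Y <- as.matrix(as.data.frame(tab)[, attr(tab, "outputs"), drop = FALSE])
  Y <- sweep(Y, 2, colMeans(Y), "/")
  mu <- res$weights$mu; v <- res$weights$v
  expect_true(all(mu >= -1e-9) && all(v >= -1e-9))
  for (i in seq_len(nrow(tab))) {
    expect_equal(sum(v[i, ] * X[i, ]), 1, tolerance = 1e-8)    # virtual input
    expect_equal(sum(mu[i, ] * Y[i, ]), unname(res$scores[i]),
                 tolerance = 1e-7)                             # strong duality
    expect_true(all(Y %*% mu[i, ] - X %*% v[i, ] <= 1e-8))     # ratio rows
  }
})

test_that("explicit-epsilon mode perturbs scores at the epsilon scale only", {
  two_phase <- dea(tab)$scores
  eps <- dea(tab, dea_model("crs", "input", epsilon = "explicit",
                            eps_value = 1e-6))$scores
  expect_lt(max(abs(two_phase - eps)), 5e-5)
  expect_true(all(eps <= two_phase + 1e-12))  # bounding weights cannot help
  expect_error(dea_model(epsilon = "explicit", eps_value = 1e-3), "epsilon")
})

test_that("unknown ids and model arguments are rejected", {
  expect_error(dea(tab, ids = c(4, 99)), "99")
  expect_error(dea_model("fdh"), "arg")
})
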