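test_that("fixture loads with the documented dimensions and values", {
  tab <- broiler_batches()
  expect_s3_class(tab, "dmu_table")
  expect_equal(nrow(tab), 31)
  expect_equal(attr(tab, "inputs"),
               c("housing", "age", "feed", "mortality", "cost"))
  expect_equal(attr(tab, "outputs"), "total_weight")
  r31 <- tab[tab$dmu == 31, ]
  expect_equal(r31$housing, 74668)
  expect_equal(r31$feed, 325)
  expect_equal(r31$total_weight, 195)
  expect_equal(r31$mortality, 0.0665)   # "6.65%" parsed to a fraction
  r4 <- tab[tab$dmu == 4, ]
  expect_equal(unlist(r4[c("housing", "age", "feed", "mortality", "cost",
                           "total_weight")], use.names = FALSE),
               c(1249391, 43.04, 5940, 0.0349, 4.15, 3956))
  expect_equal(min(tab$housing), 74668)
})

test_that("write/read round-trips every cell", {
  tab <- broiler_batches()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dmu_table(tab, path)
  back <- read_dmu_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "inputs"), attr(tab, "inputs"))
})

test_that("validation rejects malformed tables with named offenders", {
  base <- data.frame(dmu = 1:3, housing = c(100, 200, 300), age = 40,
                     feed = c(1, 2, 3), mortality = 0.05, cost = 4,
                     total_weight = c(0.8, 1.6, 2.4))
  expect_error(dmu_table(base[-1, -2]), "housing")
  expect_error(dmu_table(base[1, , drop = FALSE]), "at least 2")
  expect_error(dmu_table(transform(base, dmu = c(1, 1, 2))), "duplicated")
  bad <- base; bad$feed[2] <- -5
  expect_error(dmu_table(bad), "feed.*DMU 2")
  warn <- base; warn$feed <- warn$total_weight * 10   # FCR 10, implausible
  expect_warning(dmu_table(warn), "feed conversion")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dmu,housing,age,feed,mortality,cost,total_weight",
               "1,100,40,1,-1%,4,0.8", "2,200,40,2,5%,4,1.6"), f)
  expect_error(read_dmu_table(f), "mortality")
})

test_that("reader strips thousands separators and percent suffixes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dmu\thousing\tage\tfeed\tmortality\tcost\ttotal_weight",
               "1\t1,249,391\t43.04\t5,940\t3.49%\t4.15\t3956",
               "2\t74,668\t43.53\t325\t6.65%\t4.57\t195"), f)
  tab <- read_dmu_table(f)
  expect_equal(tab$housing, c(1249391, 74668))
  expect_equal(tab$mortality, c(0.0349, 0.0665))
  # alternate headers through the column map
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lodging,age,feed,mortality,cost,weight",
               "1,100,40,1,5%,4,0.8", "2,200,41,2,4%,4,1.6"), f2)
  tab2 <- read_dmu_table(f2, column_map = c(id = "dmu", lodging = "housing",
                                            weight = "total_weight"))
  expect_equal(tab2$housing, c(100, 200))
})

test_that("descriptive statistics match brute-force column summaries", {
  tab <- broiler_batches()
  st <- descriptive_stats(tab)
  raw <- as.data.frame(tab)
  raw$mortality <- raw$mortality * 100
  for (v in setdiff(names(raw), "dmu")) {
    expect_equal(st["max", v], max(raw[[v]]))
    expect_equal(st["min", v], min(raw[[v]]))
    expect_equal(st["median", v], median(raw[[v]]))
    expect_equal(st["mean", v], mean(raw[[v]]))
  }
  n <- nrow(raw)
  expect_equal(st["sd", "housing"], sd(raw$housing) * sqrt((n - 1) / n))
  expect_equal(descriptive_stats(tab, "sample")["sd", "housing"],
               sd(raw$housing))
  expect_equal(st["cv", "feed"], 100 * st["sd", "feed"] / st["mean", "feed"])
  # even-length column: median is the midpoint of the central pair
  even <- dmu_table(data.frame(dmu = 1:4, housing = c(10, 20, 30, 40),
                               age = 40, feed = 1:4, mortality = 0.05,
                               cost = 4, total_weight = c(1, 2, 3, 4)))
  expect_equal(descriptive_stats(even)["median", "housing"], 25)
})

test_that("correlation matrix is symmetric, unit-diagonal, and bounded", {
  cm <- correlation_matrix(broiler_batches())
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_true(all(cm >= -1 & cm <= 1))
  for (seed in 1:5) {
    cm2 <- correlation_matrix(random_table(8, 2, seed = seed))
    expect_equal(cm2, t(cm2))
    expect_equal(unname(diag(cm2)), rep(1, 3))
  }
  const <- dmu_table(data.frame(dmu = 1:3, housing = c(1, 2, 3), age = 40,
                                feed = 1:3, mortality = 0.05, cost = 4,
                                total_weight = 1:3))
  expect_error(correlation_matrix(const), "age")
})
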