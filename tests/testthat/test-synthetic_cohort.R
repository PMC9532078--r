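test_that("default schema carries the published summaries", {
  sch <- default_schema()
  expect_length(sch$features, 26)
  kinds <- vapply(sch$features, `[[`, "", "kind")
  expect_equal(sum(kinds == "continuous"), 21)
  expect_equal(sum(kinds == "categorical"), 5)
  tl <- sch$features$tumor_length
  expect_equal(tl$mean, 4.112)
  expect_equal(c(tl$min, tl$max), c(1, 11))
  g <- sch$features$gender
  expect_equal(g$probs[g$labels == "Male"], 247 / 398)
  ss <- sch$outcomes$survival_status
  expect_equal(ss$probs, c(101, 297) / 398)
  expect_equal(sch$outcomes$survival_time$max, 11L)
})

test_that("exact-counts cohort reproduces every published count", {
  co <- generate_cohort(n = 398, seed = 1, exact_counts = TRUE)
  expect_equal(as.integer(table(co$survival_status)), c(101, 297))
  expect_equal(as.integer(table(co$gender)), c(247, 151))
  expect_equal(as.integer(table(co$transfer)), c(200, 198))
  expect_equal(as.integer(table(co$differentiation)), c(158, 217, 23))
  expect_equal(as.integer(table(co$tumor_site)), c(78, 267, 53))
  expect_equal(as.integer(table(co$tnm_stage)), c(39, 172, 166, 21))
})

test_that("continuous features stay in range and match moments at n=398", {
  co <- generate_cohort(n = 398, seed = 3)
  sch <- default_schema()
  for (fs in sch$features) {
    if (fs$kind != "continuous") next
    x <- co[[fs$name]]
    expect_gte(min(x), fs$min)
    expect_lte(max(x), fs$max)
  }
  expect_equal(mean(co$tumor_length), 4.112, tolerance = 0.30 / 4.112)
  expect_true(all(co$survival_time >= 0 & co$survival_time <= 11))
  # dead implies shorter survival than live by construction
  expect_lt(max(co$survival_time[co$survival_status == "dead"]),
            min(co$survival_time[co$survival_status == "live"]))
})

test_that("generation is deterministic and validates signal names", {
  c1 <- generate_cohort(n = 100, seed = 5)
  c2 <- generate_cohort(n = 100, seed = 5)
  expect_identical(c1, c2)
  expect_error(generate_cohort(n = 50, seed = 1,
                               signal = c(not_a_feature = 1)),
               "unknown signal")
  expect_error(generate_cohort(n = 100, seed = 1, exact_counts = TRUE),
               "exact_counts")
})

test_that("zero signal gives the marginal 25/75 split", {
  co <- generate_cohort(n = 5000, seed = 7, signal = c())
  frac_dead <- mean(co$survival_status == "dead")
  expect_equal(frac_dead, 0.746, tolerance = 0.02 / 0.746)
})

test_that("increasing a positive coefficient increases the feature-death association", {
  pb_cor <- function(co) {
    cor(as.numeric(co$tumor_length), as.numeric(co$survival_status == "dead"))
  }
  weak <- generate_cohort(n = 5000, seed = 9,
                          signal = c(tumor_length = 0.3))
  strong <- generate_cohort(n = 5000, seed = 9,
                            signal = c(tumor_length = 1.5))
  expect_gt(pb_cor(strong), pb_cor(weak))
  expect_gt(pb_cor(weak), 0)
})

test_that("summaries, feature encoding and CSV round trip agree", {
  co <- generate_cohort(n = 398, seed = 2, exact_counts = TRUE)
  sm <- summarize_cohort(co)
  expect_equal(sm$categorical$count[sm$categorical$feature == "gender"],
               c(247, 151))
  tl <- sm$continuous[sm$continuous$feature == "tumor_length", ]
  expect_equal(tl$mean, mean(co$tumor_length))
  X <- cohort_features(co)
  expect_equal(dim(X), c(398, 26))
  expect_true(is.numeric(X))
  expect_equal(cohort_labels(co), as.numeric(co$survival_status == "dead"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.integer(table(back$tnm_stage)), c(39, 172, 166, 21))
  expect_equal(back$tumor_length, co$tumor_length, tolerance = 1e-10)
  expect_equal(levels(back$survival_status), c("live", "dead"))
})

test_that("single-record summary collapses mean to the value", {
  co <- generate_cohort(n = 10, seed = 4)
  one <- co[1, ]
  sm <- summarize_cohort(one)
  tl <- sm$continuous[sm$continuous$feature == "tumor_length", ]
  expect_equal(tl$mean, tl$median)
  expect_equal(tl$mean, one$tumor_length)
})
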