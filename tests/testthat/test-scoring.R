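# The scoring table, composite total, and risk stratification.

test_that("point lookup reproduces the published scoring table", {
  expected <- list(
    consciousness = c(clear = 0L, `JCS-I` = 3L, `JCS-II` = 10L, `JCS-III` = 15L),
    spo2 = c(`>=95%` = 0L, `92-94%` = 5L, `<=91%-or-oxygen` = 10L),
    suction = c(none = 0L, `1-7/day` = 10L, `>=8/day` = 20L),
    sitting_balance = c(`no-hand-support` = 0L, `hand-support` = 5L, unable = 15L),
    nutrition = c(`normal/overnutrition` = 0L, `at-risk` = 5L, malnourished = 10L),
    saliva = c(healthy = 0L, `changes-present` = 3L, pathological = 5L)
  )
  for (p in names(expected)) {
    labels <- names(expected[[p]])
    expect_identical(points_for(p, labels), unname(expected[[p]]),
                     info = p)
    # integer band codes agree with labels
    expect_identical(points_for(p, seq_along(labels) - 1L),
                     unname(expected[[p]]))
  }
  # FILS levels partition into 8-10 / 7 / 4-6 / 1-3
  expect_identical(points_for("fils", 1:10),
                   c(15L, 15L, 15L, 10L, 10L, 10L, 5L, 0L, 0L, 0L))
  # respiratory diagnosis counts band as 0 / 1 / 2 / >=3
  expect_identical(points_for("resp_disease", c(0, 1, 2, 3, 4, 10)),
                   c(0L, 5L, 8L, 10L, 10L, 10L))
})

test_that("oxygen therapy forces the worst SpO2 band", {
  expect_identical(points_for("spo2", 0L, on_oxygen = TRUE), 10L)
  expect_identical(points_for("spo2", c(0L, 1L), on_oxygen = c(FALSE, TRUE)),
                   c(0L, 10L))
})

test_that("invalid inputs are rejected with the field named", {
  expect_error(points_for("pulse", 1), "unknown CoRAS parameter")
  expect_error(points_for("fils", 0), "fils")
  expect_error(points_for("fils", 11), "fils")
  expect_error(points_for("resp_disease", -1), "resp_dx_count")
  expect_error(points_for("spo2", 3L), "spo2")
  expect_error(points_for("saliva", "wet"), "saliva")
  expect_error(points_for("consciousness", NA_integer_), "missing")
  expect_error(total_score(assessment(fils = NULL)), "missing assessment field")
})

test_that("composite totals match hand-summed table entries", {
  healthy <- total_score(assessment())
  expect_identical(healthy$total, 0L)
  expect_equal(as.character(healthy$category), "low")

  worst <- total_score(assessment(consciousness = 3L, spo2 = 2L, suction = 2L,
                                  sitting_balance = 2L, fils = 1L,
                                  resp_disease = 3L, nutrition = 2L,
                                  saliva = 2L))
  expect_identical(worst$total, 100L)
  expect_equal(as.character(worst$category), "high")

  # 3 + 5 + 10 + 5 + 10 + 5 + 5 + 3 = 46
  mid <- total_score(assessment(consciousness = 1L, spo2 = 1L, suction = 1L,
                                sitting_balance = 1L, fils = 5L,
                                resp_disease = 1L, nutrition = 1L,
                                saliva = 1L))
  expect_identical(mid$total, 46L)
  expect_identical(unname(mid$points[1, ]), c(3L, 5L, 10L, 5L, 10L, 5L, 5L, 3L))
  expect_identical(sum(mid$points), mid$total)
})

test_that("risk thresholds are inclusive as stated", {
  expect_equal(as.character(categorize(c(0L, 14L, 15L, 39L, 40L, 100L))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(categorize(101L), "0..100")
  expect_error(categorize(-1L), "0..100")
})

test_that("categories partition 0..100 with no gaps or overlaps", {
  cat <- categorize(0:100)
  expect_false(anyNA(cat))
  expect_true(all(diff(as.integer(cat)) >= 0))  # monotone in the total
  expect_identical(as.vector(table(cat)), c(15L, 25L, 61L))
})

test_that("exhaustive enumeration of all band combinations spans exactly 0..100", {
  e <- enumerate_scores()
  expect_identical(nrow(e), 15552L)
  expect_true(all(e$total >= 0L & e$total <= 100L))
  expect_identical(min(e$total), 0L)
  expect_identical(max(e$total), 100L)
})

test_that("worsening any single parameter never decreases the total", {
  base <- assessment(consciousness = 1L, spo2 = 1L, suction = 1L,
                     sitting_balance = 1L, fils = 6L, resp_disease = 1L,
                     nutrition = 1L, saliva = 1L)
  worse_values <- list(
    consciousness = 0:3, spo2 = 0:2, suction = 0:2, sitting_balance = 0:2,
    fils = 10:1, resp_disease = 0:4, nutrition = 0:2, saliva = 0:2
  )
  for (p in names(worse_values)) {
    vals <- worse_values[[p]]
    totals <- vapply(vals, function(v) {
      a <- base; a[[p]] <- as.integer(v)
      total_score(a)$total
    }, integer(1))
    expect_true(all(diff(totals) >= 0L), info = p)
  }
})
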