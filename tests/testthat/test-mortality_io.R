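test_that("canonical long CSV reads back a single record faithfully", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,sex,age_lower,age_width,cause,deaths",
               "IRN,2015,male,0,1,A00,3"), f)
  t <- read_long(f)
  expect_s3_class(t, "mortality_table")
  expect_equal(nrow(t), 1)
  expect_equal(t$deaths, 3)
  expect_equal(t$age_lower, 0L)
})

test_that("long reader enforces the schema and value contracts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,sex,age_lower,age_width,cause,deaths",
               "IRN,2015,male,0,1,A00,-1"), f)
  expect_error(read_long(f), "negative deaths", class = "avoidgap_validation_error")

  writeLines(c("country,year,sex,age_lower,cause,deaths",
               "IRN,2015,male,0,A00,3"), f)
  expect_error(read_long(f), "missing column", class = "avoidgap_format_error")

  writeLines(c("country,year,sex,age_lower,age_width,cause,deaths",
               "IRN,2015,male,0,2,A00,3"), f)
  expect_error(read_long(f), "canonical ladder")

  writeLines(c("country,year,sex,age_lower,age_width,cause,deaths",
               "IRN,2015,male,0,1,A00,3",
               "IRN,2015,male,0,1,A00,4"), f)
  expect_error(read_long(f), "duplicate key")
})

test_that("write_long(read_long(f)) is byte-identical to a canonicalized file", {
  t <- random_long_table()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_long(t, f1)               # canonical form
  write_long(read_long(f1), f2)   # round trip
  expect_identical(readLines(f2), readLines(f1))
})

test_that("WHO wide dialect maps, sums sub-ladder buckets, and zeroes blanks", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Country,Year,Sex,Cause,Deaths1,Deaths2,Deaths3,Deaths4,Deaths5,Deaths6,Deaths7,Deaths8",
    "IRN,2015,1,A00,99,5,1,1,1,1,7,2",
    "IRN,2015,1,B20,99,2,0,0,0,0,,1"), f)
  fmt <- list(Deaths1 = "ignore",
              Deaths2 = list(lower = 0, width = 1),
              Deaths3 = list(lower = 1, width = 1),
              Deaths4 = list(lower = 2, width = 1),
              Deaths5 = list(lower = 3, width = 1),
              Deaths6 = list(lower = 4, width = 1),
              Deaths7 = list(lower = 5, width = 5),
              Deaths8 = "unknown")
  expect_warning(t <- read_who_wide(f, fmt), "empty deaths cell")
  a00 <- t[t$cause == "A00", ]
  # single-year buckets 1..4 collapse into [1,5)
  expect_equal(a00$deaths[a00$age_lower == 1], 4)
  expect_equal(a00$deaths[a00$age_lower == 0], 5)
  expect_equal(a00$deaths[a00$age_lower == 5], 7)
  # blank cell became zero; unknown-age bucket dropped entirely
  expect_equal(t$deaths[t$cause == "B20" & t$age_lower == 5], 0)
  expect_equal(sum(t$deaths), 5 + 4 + 7 + 2)
})

test_that("WHO wide dialect rejects unmapped and non-numeric columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Country,Year,Sex,Cause,Deaths1,Deaths2",
               "IRN,2015,1,A00,1,2"), f)
  expect_error(read_who_wide(f, list(Deaths1 = list(lower = 0, width = 1))),
               "unmapped", class = "avoidgap_format_error")
  writeLines(c("Country,Year,Sex,Cause,Deaths1",
               "IRN,2015,1,A00,oops"), f)
  expect_error(read_who_wide(f, list(Deaths1 = list(lower = 0, width = 1))),
               "non-numeric", class = "avoidgap_validation_error")
  # bucket spanning two canonical groups must be rejected, not split
  writeLines(c("Country,Year,Sex,Cause,Deaths1",
               "IRN,2015,1,A00,4"), f)
  expect_error(read_who_wide(f, list(Deaths1 = list(lower = 0, width = 10))),
               "spans")
})

test_that("pooling years sums counts, labels the period, and conserves totals", {
  t <- random_long_table()
  one <- t[t$country == "AAA" & t$cause == "C11" & t$age_lower == 0, ]
  pooled <- pool_years(t, 2015:2016)
  expect_equal(unique(pooled$year), "2015-2016")
  got <- pooled$deaths[pooled$country == "AAA" & pooled$cause == "C11" &
                         pooled$age_lower == 0]
  expect_equal(got, sum(one$deaths))
  expect_equal(sum(pooled$deaths), sum(t$deaths))  # conservation
  single <- pool_years(t, 2015)
  expect_equal(sum(single$deaths), sum(t$deaths[t$year == "2015"]))
  expect_error(pool_years(t, 2014), "not present")
})

test_that("rate conversion divides pooled deaths by person-years", {
  # the one-cell arithmetic: 30,369 deaths over 1,019,094 person-years
  df <- data.frame(country = "X", year = "2015-2016", sex = "male",
                   age_lower = 70, age_width = 5, cause = "ALL",
                   deaths = 30369)
  pop <- data.frame(country = "X", year = "2015-2016", sex = "male",
                    age_lower = 70, age_width = 5, population = 1019094)
  rm <- to_rate_matrix(mortality_table(df), population_table(pop))
  expect_equal(signif(rm$rates["70-74", "ALL"], 3), 0.0298)
})

test_that("rate conversion is additive over causes and linear in the inputs", {
  t <- pool_years(random_long_table(), 2015:2016)
  t1 <- t[t$country == "AAA", ]; class(t1) <- class(t)
  pop <- population_table(data.frame(
    country = "AAA", year = "2015-2016", sex = "male",
    age_lower = lad$lower, age_width = lad$width,
    population = seq(5e4, by = 1e3, length.out = nrow(lad))))
  rm <- to_rate_matrix(t1, pop)
  # row sums match an all-cause-only table
  allc <- stats::aggregate(deaths ~ country + year + sex + age_lower + age_width,
                           data = as.data.frame(t1), FUN = sum)
  allc$cause <- "ALL"
  rm_all <- to_rate_matrix(mortality_table(allc, allow_fractional = TRUE), pop)
  expect_equal(unname(all_cause_rates(rm)), unname(rm_all$rates[, "ALL"]))
  # doubling deaths doubles rates; doubling population halves them
  t2 <- t1; t2$deaths <- t2$deaths * 2; class(t2) <- class(t1)
  p2 <- pop; p2$population <- p2$population * 2; class(p2) <- class(pop)
  expect_equal(to_rate_matrix(t2, pop)$rates, rm$rates * 2)
  expect_equal(to_rate_matrix(t1, p2)$rates, rm$rates / 2)
})

test_that("rate conversion names the stratum when exposure is missing", {
  df <- mortality_table(data.frame(
    country = "X", year = "2015", sex = "male", age_lower = 0, age_width = 1,
    cause = "A00", deaths = 5))
  pop <- population_table(data.frame(
    country = "X", year = "2015", sex = "male", age_lower = 5, age_width = 5,
    population = 100))
  expect_error(to_rate_matrix(df, pop), "zero or missing population")
  # all-zero deaths give an all-zero matrix even without matching exposure
  df0 <- df; df0$deaths <- 0; class(df0) <- class(df)
  expect_true(all(to_rate_matrix(df0, pop)$rates == 0))
})
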