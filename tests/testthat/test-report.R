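make_config <- function(fix, out, seed = 7, external = NULL) {
  run_config(reference = "REF", comparators = "CMP", years = 2015:2016,
             sexes = "male", mortality = fix$mortality,
             population = fix$population, external = external,
             measures = c("LE", "LI"), n_steps = 12, output_dir = out,
             seed = seed)
}

test_that("the end-to-end run reproduces the stratum gaps it reports", {
  dir <- withr::local_tempdir()
  fix <- write_scenario_fixture(file.path(dir, "fix"))
  out <- file.path(dir, "out")
  res <- run_analysis(make_config(fix, out))
  summ <- res$summary
  expect_setequal(summ$measure, c("LE", "LI"))
  expect_true(all(summ$gap == summ$reference_value - summ$comparator_value))
  # summary gaps equal the independently recomputed life-table values
  pooled <- collapse_causes(pool_years(read_long(fix$mortality), 2015:2016),
                            default_scheme())
  pop <- pool_years(read_population(fix$population), 2015:2016)
  vals <- lapply(c(REF = "REF", CMP = "CMP"), function(co) {
    t_ <- pooled[pooled$country == co, ]; class(t_) <- class(pooled)
    p_ <- pop[pop$country == co, ]; class(p_) <- class(pop)
    lt <- build_lifetable(all_cause_rates(to_rate_matrix(t_, p_)), sex = "male")
    c(LE = life_expectancy(lt), LI = lifespan_sd(lt))
  })
  for (me in c("LE", "LI")) {
    row <- summ[summ$measure == me, ]
    expect_equal(row$reference_value, unname(vals$REF[me]), tolerance = 1e-12)
    expect_equal(row$gap, unname(vals$REF[me] - vals$CMP[me]), tolerance = 1e-12)
  }
  # the injected advantage for CMP (lower preventable mortality 15-49)
  # appears in the contribution files
  cm <- read_contributions(file.path(out, "contributions_LE_CMP_male.csv"))
  expect_equal(cm$total_gap, summ$gap[summ$measure == "LE"], tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "run_log.txt")))
})

test_that("identical config and seed give a byte-identical output bundle", {
  dir <- withr::local_tempdir()
  fix1 <- write_scenario_fixture(file.path(dir, "fix1"), seed = 7)
  fix2 <- write_scenario_fixture(file.path(dir, "fix2"), seed = 7)
  expect_identical(readLines(fix1$mortality), readLines(fix2$mortality))
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  run_analysis(make_config(fix1, out1))
  run_analysis(make_config(fix2, out2))
  files <- list.files(out1, recursive = TRUE)
  expect_identical(files, list.files(out2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("identical countries yield all-zero gaps and contributions", {
  dir <- withr::local_tempdir()
  sc <- scenario_spec(
    hazard_spec(cause_mix = list(V40 = 0.3, J80 = 0.7)),
    countries = c("REF", "CMP"), perturbations = list(),
    population = 1e6, years = 2015, sex = "male", seed = 4)
  pair <- make_country_pair(sc)
  # identical exact rates: decompose directly
  cm <- decompose_gap("LE", pair$exact_rates$REF, pair$exact_rates$CMP)
  expect_true(all(cm$contributions == 0))
  expect_equal(cm$total_gap, 0)
})

test_that("a sensitivity bundle is produced when an external table is given", {
  dir <- withr::local_tempdir()
  fix <- write_scenario_fixture(file.path(dir, "fix"))
  extf <- file.path(dir, "ext.csv")
  write_external_lifetable(toy_external(), extf)
  out <- file.path(dir, "out")
  res <- run_analysis(make_config(fix, out, external = extf))
  expect_true(file.exists(file.path(out, "sensitivity",
                                    "contributions_LE_CMP_male.csv")))
  summ <- res$summary
  expect_setequal(summ$bundle, c("main", "sensitivity"))
  # recalibrated values differ from the raw ones (the external table is scaled)
  le_main <- summ$reference_value[summ$bundle == "main" & summ$measure == "LE"]
  le_sens <- summ$reference_value[summ$bundle == "sensitivity" &
                                    summ$measure == "LE"]
  expect_false(isTRUE(all.equal(le_main, le_sens)))
})

test_that("failures abort with the stage named and leave no partial outputs", {
  dir <- withr::local_tempdir()
  fix <- write_scenario_fixture(file.path(dir, "fix"))
  out <- file.path(dir, "out")
  cfg <- run_config(reference = "REF", comparators = "NOPE",
                    years = 2015:2016, sexes = "male",
                    mortality = fix$mortality, population = fix$population,
                    output_dir = out)
  expect_error(run_analysis(cfg), "absent from mortality data")
  expect_equal(length(list.files(out, recursive = TRUE)), 0)
  expect_error(run_config(reference = "REF", comparators = c("REF", "CMP"),
                          years = 2015, mortality = fix$mortality,
                          population = fix$population),
               "must not appear")
})

test_that("aggregation preserves totals under any partition", {
  pair <- gompertz_pair(causes = paste0("c", 1:5), shares = rep(0.2, 5),
                        scale_cause = "c2",
                        scale_rows = lad$lower <= 49, scale_factor = 1.5)
  cm <- decompose_gap("LE", pair$ref, pair$cmp, n_steps = 8)
  # identity binning reproduces the matrix
  ident <- aggregate_contributions(cm)
  expect_equal(sum(ident$contribution_years), sum(cm$contributions),
               tolerance = 1e-12)
  expect_equal(nrow(ident), 19 * 5)
  # one big bin and one cause group: single cell = total - residual
  one <- aggregate_contributions(cm, age_bins = list(c(0, Inf)),
                                 cause_groups = list(all = paste0("c", 1:5)))
  expect_equal(nrow(one), 1)
  expect_equal(one$contribution_years, cm$total_gap - cm$residual,
               tolerance = 1e-12)
  # a figure-style binning conserves the grand total
  bins <- list(c(0, 0), c(1, 14), c(15, 49), c(50, 74), c(75, Inf))
  groups <- list(g1 = c("c1", "c2"), g2 = c("c3", "c4", "c5"))
  agg <- aggregate_contributions(cm, bins, groups)
  expect_equal(sum(agg$contribution_years), sum(cm$contributions),
               tolerance = 1e-12)
  # non-partitions are refused
  expect_error(aggregate_contributions(cm, age_bins = list(c(0, 49))),
               "do not cover")
  expect_error(aggregate_contributions(cm, cause_groups = list(g = "c1")),
               "do not cover")
  expect_error(aggregate_contributions(
    cm, age_bins = list(c(0, 49), c(40, Inf))), "overlap")
})
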