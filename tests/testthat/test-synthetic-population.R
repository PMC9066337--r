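test_that("generated bundle satisfies every structural invariant and is reproducible", {
  b <- test_bundle()
  expect_s3_class(b, "pmslt_bundle")
  expect_length(validate_bundle(b), 0)

  b2 <- generate_bundle(42)
  expect_identical(b, b2)
  b3 <- generate_bundle(43)
  expect_false(identical(b$demography$mortality, b3$demography$mortality))

  # ethnic gradients built into the defaults
  d <- b$demography
  m <- merge(d[d$ethnicity == "maori", c("sex", "age", "mortality", "pyld")],
             d[d$ethnicity == "non_maori", c("sex", "age", "mortality", "pyld")],
             by = c("sex", "age"), suffixes = c("_m", "_nm"))
  expect_true(all(m$mortality_m >= m$mortality_nm))
  bm <- merge(b$bmi[b$bmi$ethnicity == "maori", c("sex", "age", "mean_bmi")],
              b$bmi[b$bmi$ethnicity == "non_maori", c("sex", "age", "mean_bmi")],
              by = c("sex", "age"), suffixes = c("_m", "_nm"))
  expect_true(all(bm$mean_bmi_m >= bm$mean_bmi_nm))

  # remission only for the ten cancers
  r <- b$disease_rates
  expect_true(all(r$remission[!(r$disease %in% CANCERS)] == 0))
  expect_true(all(tapply(r$remission[r$disease %in% CANCERS],
                         r$disease[r$disease %in% CANCERS], max) > 0))
})

test_that("a mortality gap factor of 1 removes the ethnic mortality gap", {
  b <- generate_bundle(1, bundle_config(maori_mortality_gap = 1))
  d <- b$demography
  m <- d[d$ethnicity == "maori", ]
  nm <- d[d$ethnicity == "non_maori", ]
  key <- function(x) x[order(x$sex, x$age), "mortality"]
  expect_equal(key(m), key(nm))
})

test_that("validate_bundle pinpoints injected defects and config errors name fields", {
  b <- test_bundle()
  bad <- b
  i <- which(bad$demography$sex == "female" & bad$demography$age == 40 &
               bad$demography$ethnicity == "maori")
  bad$demography$pyld[i] <- 1.2
  v <- validate_bundle(bad)
  expect_length(v, 1)
  expect_match(v, "female/maori/40")
  expect_match(v, "pyld")

  bad2 <- b
  sel <- bad2$disease_rates$disease == "coronary_heart_disease" &
    bad2$disease_rates$age == 50
  bad2$disease_rates$remission[sel] <- 0.1
  v2 <- validate_bundle(bad2)
  expect_length(v2, 1)
  expect_match(v2, "coronary_heart_disease")
  expect_match(v2, "remission")

  expect_error(bundle_config(maori_mortality_gap = -1), "maori_mortality_gap")
  expect_error(bundle_config(p_overweight = 1.4), "p_overweight")
})

test_that("bundle round-trips through a CSV directory with a manifest", {
  b <- test_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  b2 <- read_bundle(dir)
  for (tb in c("demography", "bmi", "disease_rates", "diseases", "rr",
               "unrelated_cost")) {
    expect_equal(b2[[tb]], b[[tb]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(b2$meta$closure_age, b$meta$closure_age)

  # a corrupted bundle on disk is rejected at read time
  demo <- read.csv(file.path(dir, "demography.csv"))
  demo$pyld[5] <- 2
  write.csv(demo, file.path(dir, "demography.csv"), row.names = FALSE)
  expect_error(read_bundle(dir), "validation")
})

test_that("baseline life expectancy at 18 is plausible and ordered by ethnicity", {
  b <- test_bundle()
  le <- function(sx, eth) {
    d <- b$demography
    d <- d[d$sex == sx & d$ethnicity == eth, ]
    d <- d[order(d$age), ]
    18 + sum(run_main_lifetable(d$mortality, 0)$life_years)
  }
  for (sx in SEXES) {
    expect_gt(le(sx, "non_maori"), 60)
    expect_lt(le(sx, "non_maori"), 100)
    expect_gt(le(sx, "maori"), 60)
    expect_lt(le(sx, "maori"), le(sx, "non_maori"))
  }
})

test_that("scaling all cost inputs by k scales cost offsets by exactly k", {
  b1 <- generate_bundle(7, bundle_config(cost_scale = 1))
  b2 <- generate_bundle(7, bundle_config(cost_scale = 2.5))
  r1 <- run_pmslt(b1, intervention_cost = 0)
  r2 <- run_pmslt(b2, intervention_cost = 0)
  expect_equal(lifetime_net_cost(r2), 2.5 * lifetime_net_cost(r1),
               tolerance = 1e-12)
  expect_equal(lifetime_qalys(r2), lifetime_qalys(r1), tolerance = 1e-12)
})
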