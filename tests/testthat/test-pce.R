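test_that("packaged coefficient file validates: 4 groups, known terms, s10 in (0,1)", {
  coefs <- pce_coefficients()
  expect_s3_class(coefs, "oxb_pce")
  expect_setequal(unique(coefs$group),
                  c("white_female", "black_female", "white_male",
                    "black_male"))
  s10 <- coefs$value[coefs$term == "s10"]
  expect_length(s10, 4)
  expect_true(all(s10 > 0 & s10 < 1))
  expect_true(is.numeric(attr(coefs, "checksum")))
})

test_that("schema errors name the offending entry", {
  coefs <- readr::read_csv(
    system.file("extdata", "pce_coefficients.csv", package = "oxbalance"),
    show_col_types = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- coefs
  bad$value[bad$group == "white_male" & bad$term == "s10"] <- 1.2
  readr::write_csv(bad, path)
  expect_error(pce_coefficients(path), "s10 must lie strictly in \\(0, 1\\)")
  bad <- coefs
  bad$term[5] <- "ln_bmi"
  readr::write_csv(bad, path)
  expect_error(pce_coefficients(path), "ln_bmi")
  bad <- coefs[coefs$group != "black_female", ]
  readr::write_csv(bad, path)
  expect_error(pce_coefficients(path), "black_female")
})

ref_profile <- function(sex, ethnicity) {
  tibble::tibble(age = 55, sex = sex, ethnicity = ethnicity,
                 total_chol = 213, hdl = 50, sbp = 120,
                 bp_treated = FALSE, diabetes = FALSE, smoker = FALSE)
}

test_that("pce_risk matches the hand-arithmetic oracle on varied profiles", {
  set.seed(31)
  for (i in 1:25) {
    d <- tibble::tibble(
      age = runif(1, 40, 79), sex = sample(c("male", "female"), 1),
      ethnicity = sample(c("white", "black", "other"), 1),
      total_chol = runif(1, 130, 320), hdl = runif(1, 20, 100),
      sbp = runif(1, 90, 200), bp_treated = runif(1) < 0.5,
      diabetes = runif(1) < 0.3, smoker = runif(1) < 0.3
    )
    expected <- oracle_pce_risk(d$age, d$sex, d$ethnicity == "black",
                                d$total_chol, d$hdl, d$sbp, d$bp_treated,
                                d$diabetes, d$smoker)
    expect_equal(as.numeric(pce_risk(d)), expected, tolerance = 1e-12)
  }
})

test_that("reference profiles reproduce the published example risks", {
  # 55-year-old, TC 213, HDL 50, untreated SBP 120, nonsmoker, nondiabetic:
  # the source guideline prints 5.3% / 6.1% / 2.1% / 3.0% (1 dp, rounded
  # from higher-precision internals)
  cases <- list(
    list(p = ref_profile("male", "white"), printed = 0.053),
    list(p = ref_profile("male", "black"), printed = 0.061),
    list(p = ref_profile("female", "white"), printed = 0.021),
    list(p = ref_profile("female", "black"), printed = 0.030)
  )
  for (cs in cases) {
    expect_lt(abs(as.numeric(pce_risk(cs$p)) - cs$printed), 0.002)
  }
  # "other" ethnicity uses the white equations
  other <- ref_profile("male", "other")
  expect_equal(as.numeric(pce_risk(other)),
               as.numeric(pce_risk(ref_profile("male", "white"))))
})

test_that("risk is monotone in age, SBP, TC, smoking, diabetes and falls with HDL", {
  grid_risk <- function(col, values) {
    d <- ref_profile("male", "white")[rep(1, length(values)), ]
    d[[col]] <- values
    as.numeric(pce_risk(d))
  }
  expect_true(all(diff(grid_risk("age", seq(40, 75, by = 5))) > 0))
  expect_true(all(diff(grid_risk("sbp", seq(95, 190, by = 5))) > 0))
  expect_true(all(diff(grid_risk("total_chol", seq(140, 300, by = 10))) > 0))
  expect_true(all(diff(grid_risk("hdl", seq(25, 95, by = 5))) < 0))
  expect_lt(grid_risk("smoker", c(FALSE, TRUE))[1],
            grid_risk("smoker", c(FALSE, TRUE))[2])
  expect_lt(grid_risk("diabetes", c(FALSE, TRUE))[1],
            grid_risk("diabetes", c(FALSE, TRUE))[2])
  # determinism: identical profile + file -> bit-identical risk
  expect_identical(as.numeric(pce_risk(ref_profile("male", "white"))),
                   as.numeric(pce_risk(ref_profile("male", "white"))))
})

test_that("risks stay inside (0,1) across a broad profile grid", {
  set.seed(33)
  d <- tibble::tibble(
    age = runif(500, 20, 79), sex = sample(c("male", "female"), 500, TRUE),
    ethnicity = sample(c("white", "black", "other"), 500, TRUE),
    total_chol = runif(500, 100, 350), hdl = runif(500, 15, 110),
    sbp = runif(500, 85, 210), bp_treated = runif(500) < 0.4,
    diabetes = runif(500) < 0.3, smoker = runif(500) < 0.3
  )
  r <- as.numeric(pce_risk(d))
  expect_true(all(r > 0 & r < 1))
})

test_that("high-risk classification is right-closed at the 7.5% threshold", {
  expect_equal(as.character(classify_high_risk(c(0.075, 0.0749, 0))),
               c("high", "low", "low"))
  expect_error(classify_high_risk(1.3), "\\[0, 1\\]")
  expect_error(classify_high_risk(0.5, threshold = -1), "probability")
})

test_that("out-of-range ages are flagged and warned about, not clamped", {
  d <- ref_profile("male", "white")[rep(1, 3), ]
  d$age <- c(55, 19, 85)
  expect_warning(out <- add_ascvd_risk(d), "PCE-valid age range")
  expect_equal(out$pce_valid_age, c(TRUE, FALSE, FALSE))
  expect_true(all(c("ascvd_risk", "ascvd_high") %in% names(out)))
})
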