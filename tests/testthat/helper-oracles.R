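# Independent oracles used across the suite. Deliberately naive
# implementations on a different code path from the package.

# sort-and-split tertile assignment: cutpoints are the ceil(n/3)-th and
# ceil(2n/3)-th order statistics, right-closed intervals
oracle_tertile <- function(values, new_value = values) {
  s <- sort(values)
  n <- length(s)
  t1 <- s[ceiling(n / 3)]
  t2 <- s[ceiling(2 * n / 3)]
  1L + (new_value > t1) + (new_value > t2)
}

# spreadsheet-style OBS recomputation for a single row, from raw component
# values and the full sample the cutpoints were fitted on
oracle_obs_row <- function(row, sample_data) {
  comps <- obs_components()
  total <- 0L
  dietary <- 0L
  lifestyle <- 0L
  for (i in seq_len(nrow(comps))) {
    comp <- comps$component[i]
    if (comps$rule[i] == "alcohol") {
      thr <- if (row$sex == "male") 30 else 15
      sc <- if (row[[comp]] == 0) 2L else if (row[[comp]] < thr) 1L else 0L
    } else {
      stratum <- sample_data[[comp]][sample_data$sex == row$sex]
      g <- oracle_tertile(stratum, row[[comp]])
      sc <- if (comps$polarity[i] == "antioxidant") g - 1L else 3L - g
    }
    total <- total + sc
    if (comps$class[i] == "dietary") dietary <- dietary + sc
    else lifestyle <- lifestyle + sc
  }
  list(total = total, dietary = dietary, lifestyle = lifestyle)
}

# hand-transcribed PCE arithmetic, written out formula-by-formula rather
# than driven by the coefficient table machinery
oracle_pce_risk <- function(age, sex, black, tc, hdl, sbp, treated,
                            diabetes, smoker) {
  la <- log(age); ltc <- log(tc); lhdl <- log(hdl); lsbp <- log(sbp)
  if (!black && sex == "male") {
    lp <- 12.344 * la + 11.853 * ltc - 2.664 * la * ltc - 7.990 * lhdl +
      1.769 * la * lhdl +
      (if (treated) 1.797 * lsbp else 1.764 * lsbp) +
      smoker * (7.837 - 1.795 * la) + 0.658 * diabetes
    s10 <- 0.9144; mean_lp <- 61.18
  } else if (black && sex == "male") {
    lp <- 2.469 * la + 0.302 * ltc - 0.307 * lhdl +
      (if (treated) 1.916 * lsbp else 1.809 * lsbp) +
      0.549 * smoker + 0.645 * diabetes
    s10 <- 0.8954; mean_lp <- 19.54
  } else if (!black) {
    lp <- -29.799 * la + 4.884 * la^2 + 13.540 * ltc - 3.114 * la * ltc -
      13.578 * lhdl + 3.149 * la * lhdl +
      (if (treated) 2.019 * lsbp else 1.957 * lsbp) +
      smoker * (7.574 - 1.665 * la) + 0.661 * diabetes
    s10 <- 0.9665; mean_lp <- -29.18
  } else {
    lp <- 17.114 * la + 0.940 * ltc - 18.920 * lhdl + 4.475 * la * lhdl +
      (if (treated) (29.291 * lsbp - 6.432 * la * lsbp)
       else (27.820 * lsbp - 6.087 * la * lsbp)) +
      0.691 * smoker + 0.874 * diabetes
    s10 <- 0.9533; mean_lp <- 86.61
  }
  1 - s10^exp(lp - mean_lp)
}

# naive unweighted product-limit estimator evaluated at time t
oracle_km_at <- function(time, event, t_eval) {
  te <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in te[te <= t_eval]) {
    s <- s * (1 - sum(time == tt & event == 1) / sum(time >= tt))
  }
  s
}

# quick iid logistic data with an rcs-shaped truth on the logit scale
sim_logit_data <- function(n, lp_fun) {
  x <- runif(n, 0, 10)
  tibble::tibble(
    x = x,
    y = runif(n) < plogis(lp_fun(x)),
    stratum = 1L, psu = seq_len(n), weight = 1
  )
}

# drop dimnames and auxiliary attributes for matrix comparisons
strip_mat <- function(m) {
  m <- as.matrix(m)
  attributes(m) <- list(dim = dim(m))
  m
}
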