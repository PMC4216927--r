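make_surv <- function(time, event, ids = sprintf("s%03d", seq_along(time)),
                      cause = NULL) {
  s <- data.frame(sample_id = ids, time = time, event = event,
                  stringsAsFactors = FALSE)
  if (!is.null(cause)) s$cause <- cause
  s
}

test_that("other-cause deaths are removed, censored rows kept", {
  s <- make_surv(1:4, c(1, 1, 0, 0),
                 cause = c("disease", "other", NA, "other"))
  out <- filter_other_cause(s)
  expect_identical(out$sample_id, c("s001", "s003", "s004"))
})

test_that("univariate screen separates prognostic from null covariates", {
  set.seed(51)
  n <- 200
  x <- matrix(rnorm(11 * n), 11,
              dimnames = list(c("hit", paste0("null", 1:10)),
                              sprintf("s%03d", 1:n)))
  t_event <- rexp(n, rate = 0.1 * exp(x["hit", ]))   # log-HR 1 for 'hit'
  t_cens <- rexp(n, rate = 0.03)
  s <- make_surv(pmin(t_event, t_cens), as.integer(t_event <= t_cens))
  sc <- univariate_screen(x, s, p_threshold = 0.001)
  expect_true("hit" %in% sc$protein)
  expect_false(any(grepl("null", sc$protein)))
  expect_equal(sc$coefficient[sc$protein == "hit"], 1, tolerance = 0.3)
  all_tab <- univariate_screen(x, s, p_threshold = 1.0)
  expect_identical(nrow(all_tab), 11L)
  expect_error(univariate_screen(x, make_surv(1:20, rep(0, 20))), "events")
})

test_that("stepwise consensus selects the prognostic covariate", {
  set.seed(52)
  n <- 150
  x <- matrix(rnorm(8 * n), 8,
              dimnames = list(c("hit", paste0("null", 1:7)), sprintf("s%03d", 1:n)))
  t_event <- rexp(n, rate = 0.1 * exp(1.5 * x["hit", ]))
  s <- make_surv(pmin(t_event, 30), as.integer(t_event <= 30))
  rm_ <- stepwise_multivariate(x, s, n_repeats = 30, seed = 2)
  expect_gte(rm_$selection_frequency["hit"], 0.8)
  expect_true("hit" %in% rm_$covariates)
  rm2 <- stepwise_multivariate(x, s, n_repeats = 30, seed = 2)
  expect_identical(rm_$coefficients, rm2$coefficients)
  expect_identical(rm_$selection_frequency, rm2$selection_frequency)
})

test_that("duplicated covariates share selections but keep joint frequency", {
  set.seed(53)
  n <- 150
  hit <- rnorm(n)
  x <- rbind(dupA = hit, dupB = hit + rnorm(n, sd = 1e-3),
             noise = rnorm(n))
  colnames(x) <- sprintf("s%03d", 1:n)
  t_event <- rexp(n, rate = 0.1 * exp(1.5 * hit))
  s <- make_surv(pmin(t_event, 30), as.integer(t_event <= 30))
  rm_ <- stepwise_multivariate(x, s, n_repeats = 30, seed = 3)
  freq <- rm_$selection_frequency
  expect_gte(freq["dupA"] + freq["dupB"], 0.8)
  expect_error(stepwise_multivariate(x, s, covariates = character(0)),
               "no candidate")
})

test_that("risk stratification splits 40/40 with floors and stable ties", {
  a10 <- matrix(seq(10, 1), 1, dimnames = list("PR1", sprintf("s%02d", 1:10)))
  grp <- stratify_risk(setNames(1, "PR1"), a10)
  expect_identical(as.integer(table(grp)[c("high", "low", "excluded")]),
                   c(4L, 4L, 2L))
  expect_identical(unname(grp[c("s01", "s10", "s05")]),
                   c("high", "low", "excluded"))
  a5 <- a10[, 1:5, drop = FALSE]
  expect_identical(as.integer(table(stratify_risk(setNames(1, "PR1"), a5))[
    c("high", "low", "excluded")]), c(2L, 2L, 1L))
  tied <- matrix(1, 1, 10, dimnames = dimnames(a10))
  expect_message(gt <- stratify_risk(setNames(1, "PR1"), tied), "ties")
  expect_identical(unname(gt[1:4]), rep("high", 4))  # stable order
  expect_error(stratify_risk(setNames(1, "PRx"), a10), "lack covariate")
})

test_that("log-rank test behaves at the null, under signal, and under relabeling", {
  # identical survival experience duplicated across groups
  s <- make_surv(rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  grp <- setNames(rep(c("high", "low"), each = 4), s$sample_id)
  lr <- logrank_test(grp, s)
  expect_lt(lr$chisq, 1e-10)
  expect_gt(lr$p, 0.999)

  set.seed(54)
  n <- 300
  g <- rep(c("high", "low"), each = n / 2)
  t_event <- rexp(n, rate = 0.1 * ifelse(g == "high", 3, 1))
  s2 <- make_surv(pmin(t_event, 20), as.integer(t_event <= 20))
  grp2 <- setNames(g, s2$sample_id)
  lr2 <- logrank_test(grp2, s2)
  expect_lt(lr2$p, 0.01)
  swapped <- setNames(ifelse(g == "high", "low", "high"), s2$sample_id)
  expect_equal(logrank_test(swapped, s2)$chisq, lr2$chisq, tolerance = 1e-12)
  expect_warning(
    logrank_test(grp, make_surv(rep(1:4, 2), c(rep(0, 4), 1, 1, 0, 1))),
    "zero events")
})

test_that("Cox coefficients agree with a brute-force partial-likelihood oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 18
    x <- matrix(rnorm(2 * n), n)
    t_event <- rexp(n, rate = 0.2 * exp(x %*% c(0.8, -0.5)))
    t_cens <- rexp(n, rate = 0.05)
    df <- data.frame(time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     x1 = x[, 1], x2 = x[, 2])
    fit <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = df)
    oracle <- cox_brute_force(df$time, df$event, x)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-4)
  }
})

test_that("Kaplan-Meier curves start at one and never increase", {
  set.seed(55)
  s <- make_surv(rexp(40), rbinom(40, 1, 0.7))
  grp <- setNames(rep(c("high", "low"), 20), s$sample_id)
  km <- km_curve(grp, s)
  for (g in unique(km$group)) {
    sv <- km$surv[km$group == g]
    expect_lte(sv[1], 1)
    expect_true(all(diff(sv) <= 1e-12))
  }
})
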