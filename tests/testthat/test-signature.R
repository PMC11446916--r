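# --- nCounter-style normalization -------------------------------------------

test_that("normalization matches the hand-worked 3-sample table", {
  m <- ncounter_toy()
  out <- ncounter_normalize(m, neg_probes = c("NEG1", "NEG2"),
                            pos_probes = "POS1", hk_genes = "HK1")
  # hand computation: background = mean + 2 sd of negatives, per sample
  b <- c(3 + 2 * sd(c(2, 4)), 6 + 2 * sd(c(4, 8)), 2 + 2 * sd(c(1, 3)))
  expect_equal(unname(attr(out, "background")), b, tolerance = 1e-12)
  # positive-control factors: cohort mean of (100, 200, 50) over each
  f_pos <- mean(c(100, 200, 50)) / c(100, 200, 50)
  expect_equal(unname(attr(out, "pos_factors")), f_pos, tolerance = 1e-12)
  # HK1 is proportional to POS1, so housekeeping factors are all 1
  expect_equal(unname(attr(out, "hk_factors")), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(out["G1", ]), c(10, 20, 5) * f_pos, tolerance = 1e-12)
  # G2 is floored to background in S1 and S3 before scaling
  expect_equal(unname(out["G2", ]), c(b[1], 50, b[3]) * f_pos, tolerance = 1e-12)
})

test_that("identical samples are left unchanged above background", {
  m <- ncounter_toy()[, c(1, 1, 1)]
  colnames(m) <- c("A", "B", "C")
  out <- ncounter_normalize(m, c("NEG1", "NEG2"), "POS1", "HK1")
  expect_equal(unname(attr(out, "pos_factors")), c(1, 1, 1))
  expect_equal(unname(attr(out, "hk_factors")), c(1, 1, 1))
  expect_equal(out["G1", ], m["G1", ])
})

test_that("a sample at half the positive-control mean gets factor 2", {
  m <- ncounter_toy()
  m["POS1", ] <- c(50, 100, 150)  # cohort mean 100
  out <- ncounter_normalize(m, c("NEG1", "NEG2"), "POS1", "HK1")
  expect_equal(unname(attr(out, "pos_factors")), c(2, 1, 2 / 3))
})

test_that("missing control rows raise a configuration error", {
  expect_error(ncounter_normalize(ncounter_toy(), "NEG9", "POS1", "HK1"),
               class = "emdmn_config_error")
})

# --- differential expression -------------------------------------------------

test_that("identical groups give null fold change and p near 1", {
  m <- matrix(rep(c(5, 6, 7, 5, 6, 7), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  de <- differential_expression(m, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(de$log2fc, c(0, 0))
  expect_true(all(de$p > 0.99))
})

test_that("the exact two-sided Mann-Whitney p for {1,2,3} vs {4,5,6} is 0.1", {
  m <- matrix(c(4, 5, 6, 1, 2, 3), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  de <- differential_expression(m, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(de$p, 0.1)  # U = 0; 2/20 of the exact enumeration
})

test_that("median fold change uses the half-count offset", {
  m <- matrix(c(8, 8, 8, 1, 1, 1), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(differential_expression(m, grp)$log2fc, log2(8.5 / 1.5))
  expect_equal(differential_expression(m, grp, eps = 1e-9)$log2fc, 3,
               tolerance = 1e-8)
  expect_error(differential_expression(m, c(TRUE, rep(FALSE, 5))),
               class = "emdmn_input_error")
})

test_that("DEG p-values are uniform under the null", {
  set.seed(77)
  n <- 30
  m <- matrix(rlnorm(2000 * 2 * n, meanlog = 5), nrow = 2000,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:(2 * n))))
  de <- differential_expression(m, rep(c(TRUE, FALSE), each = n))
  # exact Mann-Whitney p-values are discrete; the KS tie warning is expected
  expect_gt(suppressWarnings(ks.test(de$p, "punif"))$p.value, 0.01)
})

# --- pauperization score -----------------------------------------------------

test_that("the 9-gene score matches hand computation", {
  m <- score_matrix(list(rep(1, 9), rep(0, 9)))
  st <- pauperization_score(m)
  expect_equal(st$score, c(1, 0))
  m2 <- score_matrix(list(2^(1:9) - 1, rep(1, 9)))
  st2 <- pauperization_score(m2)
  expect_equal(st2$score, c(mean(1:9), 1), tolerance = 1e-12)
})

test_that("the score ignores gene order and extra genes", {
  set.seed(5)
  m <- score_matrix(replicate(12, rexp(9, 0.01), simplify = FALSE))
  base <- pauperization_score(m)$score
  expect_equal(pauperization_score(m[sample(nrow(m)), ])$score, base)
  extra <- rbind(m, NOISE = runif(12, 0, 1e4))
  expect_equal(pauperization_score(extra)$score, base)
})

test_that("a missing signature gene is reported by name", {
  m <- score_matrix(list(rep(1, 9)))
  expect_error(pauperization_score(m[rownames(m) != "GSN", , drop = FALSE]),
               regexp = "GSN", class = "emdmn_input_error")
})

test_that("upper-quartile flags count floor(n/4) at exact-quartile sizes", {
  for (n in c(8, 9, 12, 16, 17)) {
    set.seed(n)
    m <- score_matrix(replicate(n, rexp(9, 0.01), simplify = FALSE))
    st <- pauperization_score(m)
    expect_identical(sum(st$high_flag), as.integer(floor(n / 4)))
  }
})

# --- survival association ----------------------------------------------------

test_that("the log-rank statistic matches the 6-subject hand table", {
  surv <- data.frame(time = 1:6, event = 1)
  grp <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)  # A = {1,3,5}, B = {2,4,6}
  r <- survival_association(surv, grp)
  e1 <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2 + 0
  v <- 1 / 4 + (2 / 5) * (3 / 5) + 1 / 4 + (1 / 3) * (2 / 3) + 1 / 4 + 0
  expect_equal(r$logrank_chisq, (3 - e1)^2 / v, tolerance = 1e-12)
  expect_equal(r$logrank_p, pchisq((3 - e1)^2 / v, 1, lower.tail = FALSE))
})

test_that("the log-rank statistic agrees with survival::survdiff", {
  set.seed(13)
  for (i in 1:5) {
    n <- 60
    surv <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.7))
    grp <- rep(c(TRUE, FALSE), n / 2)
    r <- survival_association(surv, grp)
    sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
    expect_equal(r$logrank_chisq, sd$chisq, tolerance = 1e-8)
  }
})

test_that("identical groups give HR 1 and a flat log-rank", {
  surv <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = 1)
  r <- survival_association(surv, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$hr, 1, tolerance = 1e-6)
  expect_gt(r$logrank_p, 0.99)
})

test_that("a group without events yields a missing HR with a warning", {
  surv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  expect_warning(r <- survival_association(surv, c(FALSE, FALSE, TRUE, TRUE)),
                 "zero events")
  expect_true(is.na(r$hr))
  expect_error(survival_association(data.frame(time = c(-1, 2), event = c(1, 1)),
                                    c(TRUE, FALSE)),
               class = "emdmn_input_error")
})

test_that("log hazard-ratio estimation is nearly unbiased at large n", {
  est <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(n_samples = 2000, n_noise_genes = 0,
                                        seed = 900 + s))
    log(survival_association(co$survival, co$labels)$hr)
  }, numeric(1))
  expect_lt(abs(mean(est) - log(1.75)), 0.05)
})
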