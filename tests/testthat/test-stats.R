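test_that("signed-rank test reproduces the textbook reference cases", {
  # n = 10, every subject increases by a distinct amount, no ties:
  # W = 0, z = -27.5 / sqrt(96.25) = -2.803, exact p = 2/1024
  t1 <- c(10, 12, 14, 11, 13, 15, 16, 12.5, 13.5, 11.5)
  t2 <- t1 + seq(0.1, 1, by = 0.1)
  w <- wilcoxon_signed_rank(t1, t2)
  expect_equal(w$statistic, 0)
  expect_equal(w$z, -2.8030595, tolerance = 1e-6)
  expect_equal(w$p_value, 2 / 1024)
  expect_equal(w$method, "exact")
  # direction: a T2 increase is a negative z; swapping flips the sign
  expect_equal(wilcoxon_signed_rank(t2, t1)$z, -w$z)
})

test_that("zero differences are dropped before ranking", {
  withr::local_seed(101)
  t1 <- c(rnorm(7), 5)
  t2 <- c(t1[1:7] + rnorm(7), 5)  # one exactly-zero difference
  w <- wilcoxon_signed_rank(t1, t2)
  expect_equal(w$n, 7)
  expect_equal(w$p_value, brute_wsr_p(t1 - t2))
  # fully degenerate input
  expect_warning(wd <- wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "degenerate")
  expect_equal(wd$p_value, 1)
})

test_that("exact p equals exhaustive enumeration and tracks wilcox.test", {
  withr::local_seed(103)
  for (n in c(5, 8, 12)) {
    t1 <- rnorm(n); t2 <- rnorm(n)
    w <- wilcoxon_signed_rank(t1, t2, method = "exact")
    expect_equal(w$p_value, brute_wsr_p(t1 - t2), tolerance = 1e-12)
    ref <- stats::wilcox.test(t1, t2, paired = TRUE, exact = TRUE)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
    # the continuity-corrected approximation tracks the exact p; its
    # worst-case gap over all statistics is 0.035 at n = 5, shrinking with n
    wa <- wilcoxon_signed_rank(t1, t2, method = "approx")
    expect_lt(abs(wa$p_value - w$p_value), 0.04)
  }
})

test_that("per-band FDR reproduces the step-up procedure and its scoping", {
  # one test in a band: BH with m = 1 keeps the raw p
  one <- tibble::tibble(band = "delta", p_value = 0.003)
  expect_true(fdr_per_band(one)$fdr_significant)
  # the band-family scoping: a 0.027 network p survives in no 4-test family
  # alongside large p-values, while 0.003 does — the theta/lower-alpha vs
  # upper-alpha pattern of a two-band analysis
  res <- tibble::tibble(
    band = rep(c("theta", "upper_alpha"), each = 4),
    network = rep(c("DMN", "FPN_left", "FPN_right", "ECN"), 2),
    p_value = c(0.027, 0.5, 0.6, 0.9, 0.003, 0.5, 0.6, 0.9)
  )
  out <- fdr_per_band(res)
  expect_false(any(out$fdr_significant[out$band == "theta"]))
  expect_identical(out$fdr_significant[out$band == "upper_alpha"],
                   c(TRUE, FALSE, FALSE, FALSE))
  # flags identical to a brute-force step-up on random p-vectors
  withr::local_seed(107)
  for (i in 1:1000) {
    m <- sample(1:8, 1)
    p <- runif(m)^sample(1:3, 1)
    tbl <- tibble::tibble(band = "b", p_value = p)
    expect_identical(fdr_per_band(tbl)$fdr_significant, brute_bh(p))
  }
})

test_that("uniform null p-values keep the empirical FDR at or below q", {
  withr::local_seed(109)
  fdp <- replicate(200, {
    p <- runif(8)
    mean(brute_bh(p))  # all nulls: any rejection is a false discovery
  })
  any_fd <- mean(fdp > 0)
  expect_lt(any_fd, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("Kendall tau-b matches enumeration, references and cor.test", {
  # perfectly concordant
  expect_equal(kendall_tau(1:8, (1:8)^2)$tau, 1)
  # one discordant pair among 28: tau = 26/28, exact p = 16/40320
  x <- 1:8; y <- c(1, 2, 3, 4, 5, 6, 8, 7)
  k <- kendall_tau(x, y)
  expect_equal(k$tau, 26 / 28, tolerance = 1e-12)
  expect_equal(k$p_value, 16 / 40320, tolerance = 1e-12)
  withr::local_seed(113)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    k <- kendall_tau(x, y)
    expect_equal(k$tau, brute_tau(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                            exact = TRUE))
    expect_equal(k$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(k$p_value, ref$p.value, tolerance = 1e-12)
    # antisymmetry on tie-free data
    expect_equal(kendall_tau(x, -y)$tau, -k$tau, tolerance = 1e-12)
  }
  # ties: tau-b tie correction against cor.test's estimate
  xt <- c(1, 1, 2, 3, 4, 4, 5, 6); yt <- c(2, 1, 1, 3, 3, 5, 6, 6)
  kt <- kendall_tau(xt, yt)
  rt <- suppressWarnings(stats::cor.test(xt, yt, method = "kendall"))
  expect_equal(kt$tau, unname(rt$estimate), tolerance = 1e-12)
  expect_equal(kt$method, "approx")
  expect_warning(kc <- kendall_tau(rep(1, 6), 1:6), "constant")
  expect_true(is.na(kc$tau))
})

make_summaries <- function(n = 10, bands = c("theta", "lower_alpha"),
                           networks = c("DMN", "FPN_left"),
                           effect_cell = NULL, effect = 0.1, seed = 1,
                           include_global = TRUE) {
  set.seed(seed)
  nets <- if (include_global) c(networks, "global") else networks
  g <- tidyr::expand_grid(subject = seq_len(n), timepoint = c("T1", "T2"),
                          band = bands, network = nets)
  g$mean_pli <- 0.2 + runif(nrow(g), -0.02, 0.02)
  if (!is.null(effect_cell)) {
    sel <- g$timepoint == "T2" & g$band == effect_cell[1] &
      g$network == effect_cell[2]
    g$mean_pli[sel] <- g$mean_pli[sel] + effect
  }
  g
}

test_that("full inference gates post-hoc correlations on FDR survival", {
  s <- make_summaries(effect_cell = c("lower_alpha", "DMN"), seed = 3)
  cog <- tidyr::expand_grid(subject = 1:10, domain = cognitive_domains())
  set.seed(4)
  cog$delta <- rnorm(nrow(cog))
  rep <- run_full_inference(s, cog)
  expect_s3_class(rep, "stat_report")
  surv <- rep$network_tests[rep$network_tests$fdr_significant, ]
  expect_true(nrow(surv) >= 1)
  expect_true(all(rep$correlations$band %in% surv$band &
                    rep$correlations$network %in% surv$network))
  # stage 3 covers exactly the six domains per surviving cell
  expect_equal(nrow(rep$correlations), nrow(surv) * 6)
  # the injected DMN/lower-alpha cell must be among the survivors
  expect_true(any(surv$band == "lower_alpha" & surv$network == "DMN"))
  # global tests present, one per band
  expect_equal(nrow(rep$global_tests), 2)
  expect_equal(rep$n_subjects, 10)
  g <- glance(rep)
  expect_equal(g$n_network_tests, 4)
  expect_identical(tidy(rep, "correlations"), tibble::as_tibble(rep$correlations))
})

test_that("null summaries yield empty stage 3 and subjects are counted", {
  s <- make_summaries(seed = 15)
  cog <- tidyr::expand_grid(subject = 1:10, domain = cognitive_domains())
  set.seed(6)
  cog$delta <- rnorm(nrow(cog))
  cog$delta[cog$subject %in% c(5, 7)] <- NA  # two incomplete subjects
  rep <- run_full_inference(s, cog)
  expect_equal(nrow(rep$correlations), 0)
  # force a surviving cell: stage 3 then runs on the 8 complete subjects
  s2 <- make_summaries(effect_cell = c("theta", "FPN_left"), effect = 0.2,
                       seed = 7)
  rep2 <- run_full_inference(s2, cog)
  expect_true(nrow(rep2$correlations) > 0)
  expect_equal(unique(rep2$correlations$n), 8)
  expect_equal(rep2$n_subjects, 10)
  expect_equal(rep2$n_cognition, 8)
})

test_that("inference rejects incomplete summaries", {
  s <- make_summaries()
  expect_error(run_full_inference(s[s$timepoint == "T1", ]), "both timepoints")
  s3 <- make_summaries(n = 4)
  expect_error(run_full_inference(s3), "at least 5")
})
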