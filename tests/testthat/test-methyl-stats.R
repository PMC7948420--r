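test_that("identical strains fit a null effect with OR 1", {
  counts <- data.frame(strain = rep(c("WT", "mut"), each = 2),
                       replicate = c(1, 2, 1, 2),
                       me0 = 40, me1 = 15, me2 = 15, me3 = 30)
  fit <- fit_proportional_odds(counts, reference = "WT", counts_mode = TRUE)
  expect_equal(unname(fit$beta["mut"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$odds_ratio["mut"]), 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a single-strain fit returns the empirical cumulative logits", {
  counts <- data.frame(strain = "WT", replicate = 1,
                       me0 = 400, me1 = 150, me2 = 150, me3 = 300)
  fit <- fit_proportional_odds(counts, counts_mode = TRUE)
  p <- c(400, 150, 150, 300) / 1000
  expect_equal(fit$cutpoints, stats::qlogis(cumsum(p)[1:3]), tolerance = 1e-5)
})

test_that("the fit matches an independent ML implementation", {
  skip_if_not_installed("MASS")
  g <- gen_methyl_counts(c(WT = 0, mut = 1.2, strong = -0.8),
                         n_replicates = 3, effective_n = 500, seed = 23)
  fit <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  long <- do.call(rbind, lapply(seq_len(nrow(g$counts)), function(i)
    data.frame(strain = g$counts$strain[i],
               y = rep(factor(c("me0", "me1", "me2", "me3"), ordered = TRUE),
                       times = as.numeric(g$counts[i, 3:6])))))
  long$strain <- factor(long$strain, levels = c("WT", "mut", "strong"))
  ref <- MASS::polr(y ~ strain, data = long, Hess = TRUE)
  expect_equal(unname(fit$beta[c("mut", "strong")]),
               unname(coef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$cutpoints), unname(ref$zeta), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("the fit matches a generically optimized likelihood to 1e-4", {
  g <- gen_methyl_counts(c(WT = 0, mut = 1.2), n_replicates = 2,
                         effective_n = 400, seed = 67)
  fit <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  # independently written cumulative-logit likelihood, generic optimizer
  w <- t(sapply(c("WT", "mut"), function(s)
    colSums(g$counts[g$counts$strain == s, c("me0", "me1", "me2", "me3")])))
  nll <- function(par) {
    th <- par[1:3]
    if (th[1] >= th[2] || th[2] >= th[3]) return(1e10)
    ll <- 0
    for (s in 1:2) {
      b <- if (s == 1) 0 else par[4]
      cum <- c(plogis(th - b), 1)
      pj <- c(cum[1], diff(cum))
      ll <- ll + sum(w[s, ] * log(pmax(pj, 1e-300)))
    }
    -ll
  }
  ref <- stats::optim(c(-1, 0, 1, 0.5), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  ref <- stats::optim(ref$par, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(fit$cutpoints, fit$beta["mut"])), unname(ref$par),
               tolerance = 1e-4)
  expect_equal(fit$logLik, -ref$value, tolerance = 1e-8)
})

test_that("planted effects are recovered and reversing states negates beta", {
  g <- gen_methyl_counts(c(WT = 0, mut = 1.5), n_replicates = 3,
                         effective_n = 2000, seed = 77)
  fit <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  expect_equal(unname(fit$beta["mut"]), 1.5, tolerance = 0.15)
  rev_counts <- g$counts
  rev_counts[, c("me0", "me1", "me2", "me3")] <-
    rev_counts[, c("me3", "me2", "me1", "me0")]
  rev_fit <- fit_proportional_odds(rev_counts, reference = "WT",
                                   counts_mode = TRUE)
  expect_equal(unname(rev_fit$beta["mut"]), -unname(fit$beta["mut"]),
               tolerance = 1e-4)
})

test_that("relabeling strains permutes coefficients consistently", {
  g <- gen_methyl_counts(c(WT = 0, a = 0.8, b = -0.5), n_replicates = 2,
                         effective_n = 800, seed = 41)
  fit <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  swapped <- g$counts
  swapped$strain <- c(a = "b", b = "a", WT = "WT")[swapped$strain]
  fit2 <- fit_proportional_odds(swapped, reference = "WT", counts_mode = TRUE)
  expect_equal(unname(fit2$beta["b"]), unname(fit$beta["a"]), tolerance = 1e-6)
  expect_equal(unname(fit2$beta["a"]), unname(fit$beta["b"]), tolerance = 1e-6)
})

test_that("the adjacent-category model nests the proportional-odds fit", {
  g <- gen_methyl_counts(c(WT = 0, mut = 1.0), n_replicates = 3,
                         effective_n = 1000, seed = 19)
  po <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  ac <- fit_adjacent_category(g$counts, reference = "WT", counts_mode = TRUE)
  expect_gte(ac$logLik, po$logLik)
  # under proportional-odds data the per-boundary slopes are about equal
  expect_lt(diff(range(ac$gamma["mut", ])), 0.5)
  # identical strains give zero slopes
  null_counts <- data.frame(strain = rep(c("WT", "mut"), each = 1),
                            replicate = 1, me0 = 40, me1 = 15, me2 = 15,
                            me3 = 30)
  ac0 <- fit_adjacent_category(null_counts, reference = "WT",
                               counts_mode = TRUE)
  expect_equal(unname(ac0$gamma["mut", ]), c(0, 0, 0), tolerance = 1e-9)
})

test_that("likelihood-ratio test behaves at its boundaries", {
  g <- gen_methyl_counts(c(WT = 0, mut = 0.6), n_replicates = 2,
                         effective_n = 500, seed = 53)
  po <- fit_proportional_odds(g$counts, reference = "WT", counts_mode = TRUE)
  ac <- fit_adjacent_category(g$counts, reference = "WT", counts_mode = TRUE)
  same <- lr_test(po, po)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lrt <- lr_test(po, ac)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 2)
  expect_error(lr_test(ac, po), "non-nested")
})

test_that("complete separation is flagged, not silently reported", {
  counts <- data.frame(strain = c("WT", "ko"), replicate = 1,
                       me0 = c(400, 1000), me1 = c(150, 0),
                       me2 = c(150, 0), me3 = c(300, 0))
  expect_warning(fit <- fit_proportional_odds(counts, reference = "WT",
                                              counts_mode = TRUE),
                 "separation")
  expect_true(fit$separation)
})
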