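# abundance filter, fold changes, empirical-Bayes moderated t

sim_cm <- function(norm, conditions, replicates = NULL) {
  sheet <- data.frame(sample = colnames(norm), condition = conditions,
                      replicate = replicates %||%
                        stats::ave(seq_along(conditions), conditions,
                                   FUN = seq_along),
                      stringsAsFactors = FALSE)
  structure(list(raw = NULL, norm = norm, samples = sheet),
            class = "count_matrix")
}

test_that("the abundance filter keys on condition means at 300 cpm", {
  norm <- rbind(everywhere299 = c(299, 299, 299, 299),
                one_cond300  = c(300, 300, 10, 10),
                borderline   = c(299, 301, 200, 200))
  colnames(norm) <- c("a1", "a2", "b1", "b2")
  cm <- sim_cm(norm, c("ND", "ND", "AD8", "AD8"))
  fl <- abundance_filter(cm)
  expect_false(fl[["everywhere299"]])
  expect_true(fl[["one_cond300"]])
  expect_true(fl[["borderline"]])  # condition mean (299+301)/2 = 300
})

test_that("log2 fold changes pair replicates and flip sign with the contrast", {
  norm <- rbind(f1 = c(100, 100, 100, 100),
                f2 = c(800, 820, 100, 105))
  colnames(norm) <- c("a1", "a2", "b1", "b2")
  cm <- sim_cm(norm, c("AD8", "AD8", "ND", "ND"), c(1, 2, 1, 2))
  fc <- log2fc_table(cm, c("AD8", "ND"), pseudocount = 0)
  expect_equal(fc$log2fc[fc$feature == "f1"], 0)
  expect_equal(fc$log2fc[fc$feature == "f2"],
               mean(log2(c(800 / 100, 820 / 105))))
  rev <- log2fc_table(cm, c("ND", "AD8"), pseudocount = 0)
  expect_equal(rev$log2fc, -fc$log2fc)
  expect_error(log2fc_table(cm, c("AD8", "AD3")), "absent")
})

test_that("moderated statistics match an independent closed-form evaluation", {
  set.seed(41)
  n <- 200
  norm <- 2^matrix(rnorm(n * 4, mean = 10, sd = 1), n,
                   dimnames = list(sprintf("f%03d", 1:n),
                                   c("a1", "a2", "b1", "b2")))
  cm <- sim_cm(norm, c("AD8", "AD8", "ND", "ND"), c(1, 2, 1, 2))
  diff <- fit_moderated_t(cm, c("AD8", "ND"))
  # independent route: limma estimates the same prior from (s2, df)
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(diff$s2, df = attr(diff, "df_residual"))
  expect_equal(attr(diff, "df_prior"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(diff, "var_prior"), sq$var.prior, tolerance = 1e-6)
  # direct evaluation of the closed forms from the reported prior
  d0 <- attr(diff, "df_prior"); s02 <- attr(diff, "var_prior")
  d <- attr(diff, "df_residual")
  x <- log2(norm + 0.5)
  delta <- rowMeans(x[, 1:2]) - rowMeans(x[, 3:4])
  s2 <- (apply(x[, 1:2], 1, var) + apply(x[, 3:4], 1, var)) / 2
  s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  tstat <- delta / sqrt(s2_post * (1 / 2 + 1 / 2))
  pval <- 2 * pt(-abs(tstat), df = d0 + d)
  expect_equal(diff$s2, unname(s2), tolerance = 1e-10)
  expect_equal(diff$s2_post, unname(s2_post), tolerance = 1e-10)
  expect_equal(diff$t, unname(tstat), tolerance = 1e-10)
  expect_equal(diff$p_value, unname(pval), tolerance = 1e-10)
})

test_that("shrinkage interpolates between s2 and the prior", {
  set.seed(42)
  s2 <- rchisq(100, df = 3) / 3
  pr <- fit_variance_prior(s2, df = 3)
  d0 <- pr$df_prior; s02 <- pr$var_prior
  post <- (d0 * s02 + 3 * s2) / (d0 + 3)
  expect_true(all(post >= pmin(s2, s02) - 1e-12))
  expect_true(all(post <= pmax(s2, s02) + 1e-12))
  # d0 -> 0: the moderated t degenerates to the ordinary t
  expect_equal((0 * s02 + 3 * s2) / (0 + 3), s2)
  # d0 -> Inf: everything shrinks onto the prior
  expect_equal((1e12 * s02 + 3 * s2) / (1e12 + 3), rep(s02, 100),
               tolerance = 1e-9)
  # homogeneous variances: no excess spread, prior df infinite
  s2_h <- rchisq(2000, df = 50) / 50
  pr_h <- fit_variance_prior(s2_h, df = 50)
  expect_true(is.infinite(pr_h$df_prior) || pr_h$df_prior > 50)
  expect_error(fit_variance_prior(rep(0, 5), 2), "zero")
})

test_that("trigamma inversion solves trigamma(x) = y", {
  y <- c(1e-5, 0.01, 0.5, 2, 10, 1e5)
  x <- mirsolid:::trigamma_inverse(y)
  expect_equal(trigamma(x), y, tolerance = 1e-8)
})

test_that("equal group means give t near zero and top_table partitions", {
  norm <- rbind(f1 = c(1000, 1000, 1000, 1000),
                f2 = c(4000, 4100, 980, 1020),
                f3 = c(250, 260, 1010, 990))
  colnames(norm) <- c("a1", "a2", "b1", "b2")
  cm <- sim_cm(norm, c("AD8", "AD8", "ND", "ND"), c(1, 2, 1, 2))
  diff <- fit_moderated_t(cm, c("AD8", "ND"), min_cpm = 100)
  expect_equal(diff$t[diff$feature == "f1"], 0)
  expect_equal(diff$p_value[diff$feature == "f1"], 1)
  top <- top_table(diff, alpha = 0.05)
  expect_identical(top$n_up + top$n_down, nrow(top$table))
  expect_true(all(diff(top$table$p_value) >= 0))
  # BH never lowers a raw P
  expect_true(all(diff$adj_p_value >= diff$p_value - 1e-15))
  # nothing can be selected at alpha = 0
  expect_identical(nrow(top_table(diff, alpha = 0)$table), 0L)
})

test_that("null features reject at close to the nominal rate", {
  set.seed(43)
  n <- 2000
  norm <- 2^matrix(rnorm(n * 4, mean = 10, sd = 0.8), n,
                   dimnames = list(sprintf("f%04d", 1:n),
                                   c("a1", "a2", "b1", "b2")))
  cm <- sim_cm(norm, c("AD8", "AD8", "ND", "ND"), c(1, 2, 1, 2))
  diff <- fit_moderated_t(cm, c("AD8", "ND"), min_cpm = 0)
  fp <- mean(diff$p_value < 0.05)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(fp, ci[1])
  expect_lte(fp, ci[2])
})
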