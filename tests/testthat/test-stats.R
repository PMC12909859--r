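# Oracles live in helper-oracles.R.

make_table <- function(values, age = NULL, sex = NULL,
                       bands = c("theta", "alpha")) {
  # values: named list band_cond -> numeric vector over dyads
  n <- length(values[[1]])
  df <- data.frame(dyad_id = sprintf("d%02d", seq_len(n)))
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  df$infant_age <- if (is.null(age)) runif(n, 5, 12) else age
  df$infant_sex <- if (is.null(sex)) rep(c("F", "M"), length.out = n) else sex
  as_cohort_table(df, bands = bands)
}

rand_table <- function(n = 12, seed = 1) {
  set.seed(seed)
  vals <- list()
  for (b in c("theta", "alpha")) for (cc in c("FP1", "SF1", "FP2", "SF2", "RU"))
    vals[[paste(b, cc, sep = "_")]] <- runif(n, 0.3, 0.5)
  make_table(vals)
}

test_that("cohort table construction accepts long and deposited layouts", {
  long <- expand.grid(dyad_id = c("a", "b", "c"),
                      band = c("theta", "alpha"),
                      condition = c("FP1", "SF1", "FP2", "SF2", "RU"),
                      stringsAsFactors = FALSE)
  long$global_wpli <- seq_len(nrow(long)) / 100
  long$infant_age <- 8; long$infant_sex <- "F"
  tab <- as_cohort_table(long)
  expect_s3_class(tab, "cohort_table")
  expect_equal(tab$theta_FP1,
               long$global_wpli[long$band == "theta" & long$condition == "FP1"])
  # deposited wide layout with assorted capitalisation and id column
  dep <- data.frame(Participant = 1:6,
                    Age = 7:12, Sex = rep(c("F", "M"), 3))
  for (b in c("Theta", "Alpha")) for (cc in c("FP1", "SF1", "FP2", "SF2", "RU"))
    dep[[paste(b, cc, sep = ".")]] <- runif(6)
  tab2 <- as_cohort_table(dep)
  expect_equal(tab2$alpha_RU, dep$Alpha.RU)
  expect_equal(tab2$infant_age, dep$Age)
})

test_that("outlier rule flags only gross deviations", {
  set.seed(64)
  vals <- list()
  for (b in c("theta", "alpha")) for (cc in c("FP1", "SF1", "FP2", "SF2", "RU"))
    vals[[paste(b, cc, sep = "_")]] <- runif(33, 0.39, 0.41)
  tab <- make_table(vals)
  # plant one far-out value (cohort-scale n keeps the rule sensitive even
  # though the planted point inflates the column SD)
  base <- tab$theta_SF1
  tab$theta_SF1[3] <- mean(base) + 8 * sd(base)
  flags <- detect_outliers(tab, "theta")
  expect_equal(flags$dyad_id, "d03")
  expect_equal(flags$condition, "SF1")
  # tight columns produce no flags
  expect_equal(nrow(detect_outliers(tab, "alpha")), 0)
  expect_equal(nrow(detect_outliers(tab, rule = "none")), 0)
  # removal blanks exactly that cell
  tab2 <- remove_outliers(tab, flags)
  expect_true(is.na(tab2$theta_SF1[3]))
  expect_equal(sum(is.na(tab2$theta_SF1)), 1)
})

test_that("Friedman matches a rank-sum oracle and handles ties", {
  set.seed(41)
  m <- matrix(runif(4 * 3), 4, 3)     # 4 dyads x 3 conditions
  vals <- list()
  for (cc in c("FP1", "SF1", "FP2"))
    vals[[paste("theta", cc, sep = "_")]] <- m[, match(cc, c("FP1", "SF1", "FP2"))]
  df <- data.frame(dyad_id = sprintf("d%d", 1:4), infant_age = 8,
                   infant_sex = rep(c("F", "M"), 2))
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  tab <- as_cohort_table(df, conditions = c("FP1", "SF1", "FP2"),
                         bands = "theta")
  res <- friedman_conditions(tab, "theta")
  expect_equal(res$statistic, friedman_oracle(m), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_raw, pchisq(friedman_oracle(m), 2, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical condition values: chi^2 = 0, p = 1
  tab0 <- rand_table(8, seed = 2)
  for (cc in c("SF1", "FP2", "SF2", "RU"))
    tab0[[paste0("theta_", cc)]] <- tab0$theta_FP1
  res0 <- friedman_conditions(tab0, "theta")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_raw, 1)
})

test_that("Friedman is invariant to strictly monotone transforms", {
  tab <- rand_table(10, seed = 3)
  a <- friedman_conditions(tab, "theta")
  tab2 <- tab
  for (cc in c("FP1", "SF1", "FP2", "SF2", "RU")) {
    col <- paste0("theta_", cc)
    tab2[[col]] <- exp(5 * tab2[[col]])
  }
  b <- friedman_conditions(tab2, "theta")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank matches exact enumeration at n = 5", {
  x <- c(1, 2, 3, 4, 5)
  y <- x - c(1, -2, 3, -4, 5)         # d = (1,-2,3,-4,5), distinct |d|
  st <- dyadsync:::signed_rank_test(x, y)
  # brute force over all 2^5 sign patterns of the rank vector
  ranks <- rank(abs(c(1, -2, 3, -4, 5)))
  sums <- sapply(0:31, function(mask) {
    sel <- as.logical(bitwAnd(mask, 2^(0:4)))
    sum(ranks[sel])
  })
  W_obs <- min(sum(ranks[c(1, -2, 3, -4, 5) > 0]),
               sum(ranks[c(1, -2, 3, -4, 5) < 0]))
  p_exact <- min(1, 2 * mean(sums <= W_obs))
  expect_equal(st$W, W_obs)
  expect_equal(st$p, p_exact, tolerance = 1e-12)
  expect_equal(st$method, "exact")
  # degenerate all-zero differences
  st0 <- dyadsync:::signed_rank_test(x, x)
  expect_equal(st0$W, 0)
  expect_equal(st0$p, 1)
})

test_that("pairwise post hocs cover all 10 pairs with BH correction", {
  tab <- rand_table(14, seed = 6)
  res <- pairwise_wilcoxon_fdr(tab, "theta")
  expect_equal(nrow(res), 10)
  expect_equal(res$p_fdr, bh_oracle(res$p_raw), tolerance = 1e-12)
  expect_true(all(res$p_fdr >= res$p_raw))
  # identical condition columns: all adjusted p = 1
  tab1 <- tab
  for (cc in c("SF1", "FP2", "SF2", "RU"))
    tab1[[paste0("theta_", cc)]] <- tab1$theta_FP1
  res1 <- pairwise_wilcoxon_fdr(tab1, "theta")
  expect_true(all(res1$p_fdr == 1))
})

test_that("BH step-up equals the brute-force oracle on random p-vectors", {
  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # hand case: (0.01, 0.02, 0.03, 0.04, 0.05) with m = 5 -> all 0.05
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), "BH"),
               rep(0.05, 5))
})

test_that("covariate screening uses Welch df and exact Pearson r", {
  set.seed(91)
  tab <- rand_table(16, seed = 91)
  # age perfectly linear in synchrony for one cell
  tab$infant_age <- tab$theta_FP1 * 10 + 2
  res <- covariate_checks(tab)
  r_fp1 <- res[res$test == "pearson_age" & res$band == "theta" &
                 res$comparison == "FP1", ]
  expect_equal(r_fp1$statistic, 1, tolerance = 1e-10)
  # Welch df against the Welch-Satterthwaite closed form
  t_fp1 <- res[res$test == "welch_t_sex" & res$band == "theta" &
                 res$comparison == "FP1", ]
  g <- split(tab$theta_FP1, tab$infant_sex)
  expect_equal(t_fp1$df, welch_df_oracle(g[[1]], g[[2]]), tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  tab2 <- rand_table(8, seed = 92)
  tab2$theta_FP1 <- rep(c(0.4, 0.5, 0.6, 0.7), 2)
  tab2$infant_sex <- rep(c("F", "M"), each = 4)
  res2 <- covariate_checks(tab2)
  t2 <- res2[res2$test == "welch_t_sex" & res2$band == "theta" &
               res2$comparison == "FP1", ]
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_raw, 1)
})

test_that("parametric sensitivity check returns F = 0 for flat conditions", {
  tab <- rand_table(10, seed = 13)
  for (cc in c("SF1", "FP2", "SF2", "RU"))
    tab[[paste0("theta_", cc)]] <- tab$theta_FP1
  res <- rm_anova_sensitivity(tab, "theta")
  cond <- res[res$comparison == "condition", ]
  expect_equal(cond$statistic, 0, tolerance = 1e-8)
  # missing cell -> listwise drop reflected in n
  tab$theta_SF1[2] <- NA
  res2 <- rm_anova_sensitivity(tab, "theta")
  expect_equal(unique(res2$n), 9)
})

test_that("type-I error of the cohort Friedman chain is near nominal", {
  # null cohort tables (exchangeable conditions); desk-scale replication
  set.seed(314)
  rejections <- replicate(500, {
    tab <- suppressWarnings(make_table(local({
      v <- list()
      for (cc in c("FP1", "SF1", "FP2", "SF2", "RU"))
        v[[paste0("theta_", cc)]] <- rnorm(15, 0.4, 0.03)
      v
    }), bands = "theta"))
    friedman_conditions(tab, "theta")$p_raw < 0.05
  })
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})
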