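# Cohort-level inference on global synchrony: outlier screening, covariate
# checks, Friedman omnibus per band, pairwise Wilcoxon post hocs with
# Benjamini-Hochberg FDR, and a parametric repeated-measures sensitivity
# check.

sfp_conditions <- function() c("FP1", "SF1", "FP2", "SF2", "RU")

#' Build the cohort table of global synchrony values
#'
#' One row per dyad; columns `<band>_<condition>` holding global wPLI for the
#' five Still-Face Paradigm conditions in each band, plus `infant_age`
#' (months) and `infant_sex`. Accepts either a list of per-dyad
#' `synchrony_table`s (from [dyad_synchrony()]/[process_dyad()]), a stacked
#' long data.frame with columns `dyad_id`, `band`, `condition`,
#' `global_wpli`, or an externally deposited wide table whose columns already
#' match the `<band>_<condition>` pattern (case-insensitive, separator `_`,
#' `.` or `-`), e.g. the one-row-per-dyad, ten-synchrony-column layout used
#' for public data deposits.
#'
#' @param x list of synchrony tables, long data.frame, or wide data.frame.
#' @param conditions condition labels (default the five SFP phases).
#' @param bands band names (default theta, alpha).
#' @return data.frame of class `cohort_table`.
#' @export
as_cohort_table <- function(x, conditions = sfp_conditions(),
                            bands = c("theta", "alpha")) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, function(s)
    s[, setdiff(names(s), "pair_matrix"), drop = FALSE]))
  stopifnot(is.data.frame(x))
  target <- as.vector(outer(bands, conditions, paste, sep = "_"))
  if (all(c("dyad_id", "band", "condition", "global_wpli") %in% names(x))) {
    ids <- unique(x$dyad_id)
    wide <- data.frame(dyad_id = ids)
    for (b in bands) for (cond in conditions) {
      sel <- x$band == b & x$condition == cond
      v <- x$global_wpli[sel][match(ids, x$dyad_id[sel])]
      wide[[paste(b, cond, sep = "_")]] <- v
    }
    wide$infant_age <- x$infant_age[match(ids, x$dyad_id)]
    wide$infant_sex <- x$infant_sex[match(ids, x$dyad_id)]
    x <- wide
  } else {
    # deposited wide layout: normalize column names
    norm <- tolower(gsub("[.-]", "_", names(x)))
    for (tc in target) {
      hit <- which(norm == tolower(tc) |
                   norm == tolower(paste(rev(strsplit(tc, "_")[[1]]),
                                         collapse = "_")))
      if (length(hit) == 1) names(x)[hit] <- tc
    }
    if (!"dyad_id" %in% names(x)) {
      idcol <- which(norm %in% c("dyad", "id", "subject", "participant"))
      if (length(idcol)) names(x)[idcol[1]] <- "dyad_id"
      else x$dyad_id <- sprintf("dyad%03d", seq_len(nrow(x)))
    }
    for (alias in list(c("age", "infant_age"), c("sex", "infant_sex"))) {
      if (!alias[2] %in% names(x) && alias[1] %in% norm)
        names(x)[which(norm == alias[1])[1]] <- alias[2]
    }
  }
  miss <- setdiff(target, names(x))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (!"infant_age" %in% names(x)) x$infant_age <- NA_real_
  if (!"infant_sex" %in% names(x)) x$infant_sex <- NA_character_
  out <- x[, c("dyad_id", "infant_age", "infant_sex", target)]
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "bands") <- bands
  attr(out, "conditions") <- conditions
  out
}

band_columns <- function(tab, band) {
  paste(band, attr(tab, "conditions"), sep = "_")
}

#' Flag outlying global synchrony values
#'
#' Default rule: within each (band, condition) column, flag values more than
#' `k` standard deviations from the column mean (`k = 3`). The study this
#' mirrors reported removing two alpha-band values without stating its
#' criterion, so the rule is configurable and `rule = "none"` disables
#' screening.
#'
#' @param tab a `cohort_table`.
#' @param band band name, or `NULL` for all bands.
#' @param rule `"sd"` or `"none"`.
#' @param k SD multiplier (default 3).
#' @return data.frame of flags: `dyad_id`, `band`, `condition`, `value`.
#' @export
detect_outliers <- function(tab, band = NULL, rule = c("sd", "none"), k = 3) {
  rule <- match.arg(rule)
  stopifnot(inherits(tab, "cohort_table"), nrow(tab) >= 5)
  flags <- data.frame(dyad_id = character(), band = character(),
                      condition = character(), value = numeric())
  if (rule == "none") return(flags)
  bands <- if (is.null(band)) attr(tab, "bands") else band
  for (b in bands) for (cond in attr(tab, "conditions")) {
    col <- paste(b, cond, sep = "_")
    v <- tab[[col]]
    z <- abs(v - mean(v, na.rm = TRUE))
    bad <- which(!is.na(v) & z > k * sd(v, na.rm = TRUE))
    if (length(bad))
      flags <- rbind(flags, data.frame(dyad_id = tab$dyad_id[bad], band = b,
                                       condition = cond, value = v[bad]))
  }
  flags
}

#' Blank flagged outlier cells
#'
#' Sets flagged cells to `NA`. Downstream, the Friedman omnibus drops such
#' dyads listwise (complete blocks required) while pairwise Wilcoxon tests
#' drop them pairwise.
#'
#' @param tab a `cohort_table`.
#' @param flags output of [detect_outliers()].
#' @return the `cohort_table` with flagged cells set `NA`.
#' @export
remove_outliers <- function(tab, flags) {
  for (i in seq_len(nrow(flags))) {
    col <- paste(flags$band[i], flags$condition[i], sep = "_")
    tab[tab$dyad_id == flags$dyad_id[i], col] <- NA_real_
  }
  tab
}

contrast_row <- function(test, band, comparison, statistic, df, p_raw,
                         p_fdr = NA_real_, n = NA_integer_) {
  data.frame(test = test, band = band, comparison = comparison,
             statistic = statistic, df = df, p_raw = p_raw, p_fdr = p_fdr,
             n = n)
}

#' Friedman omnibus test across the five conditions
#'
#' Rank-based repeated-measures omnibus on the per-dyad global wPLI of one
#' band across the five SFP conditions. Dyads with any missing condition
#' value are dropped listwise (the test needs complete blocks); the retained
#' n is reported. The statistic is chi-squared with `k - 1 = 4` degrees of
#' freedom.
#'
#' @param tab a `cohort_table`.
#' @param band band name.
#' @return one-row `ContrastResult` data.frame (`test`, `band`,
#'   `comparison`, `statistic`, `df`, `p_raw`, `p_fdr`, `n`).
#' @export
friedman_conditions <- function(tab, band) {
  m <- as.matrix(tab[, band_columns(tab, band)])
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 complete dyads for band ", band)
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) { stat <- 0; p <- 1 }  # all-ties degenerate case
  contrast_row("friedman", band,
               paste(attr(tab, "conditions"), collapse = "|"),
               stat, unname(ft$parameter), p, n = nrow(m))
}

# Wilcoxon signed-rank on paired vectors: W = smaller of the two signed-rank
# sums; exact two-sided p for n <= 25 without ties/zeros, otherwise normal
# approximation with continuity correction.
signed_rank_test <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0)
    return(list(W = 0, p = 1, n = 0, method = "degenerate"))
  r <- rank(abs(nz))
  w_pos <- sum(r[nz > 0]); w_neg <- sum(r[nz < 0])
  W <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(nz)))
  zeros <- any(d == 0)
  if (n <= exact_max && !ties && !zeros) {
    p <- min(1, 2 * stats::psignrank(W, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sig2)   # continuity-corrected, lower side
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  list(W = W, p = p, n = n, method = method)
}

#' Pairwise Wilcoxon signed-rank post hocs with FDR correction
#'
#' All 10 unordered condition pairs of one band, two-sided, on pairwise
#' complete dyads. `W` is reported as the smaller of the two signed-rank
#' sums (exact null distribution up to n = 25 without ties; normal
#' approximation with continuity correction otherwise). Benjamini-Hochberg
#' adjustment is applied across the 10 comparisons of the band — one family
#' per band, matching the per-band post-hoc reporting structure.
#'
#' @param tab a `cohort_table`.
#' @param band band name.
#' @return 10-row `ContrastResult` data.frame; `comparison` is
#'   `"<condA> vs <condB>"`.
#' @export
pairwise_wilcoxon_fdr <- function(tab, band) {
  conds <- attr(tab, "conditions")
  prs <- combn(conds, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- tab[[paste(band, prs[1, i], sep = "_")]]
    b <- tab[[paste(band, prs[2, i], sep = "_")]]
    ok <- !is.na(a) & !is.na(b)
    st <- signed_rank_test(a[ok], b[ok])
    contrast_row("wilcoxon", band, paste(prs[1, i], "vs", prs[2, i]),
                 st$W, NA_real_, st$p, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out
}

#' Covariate screening: infant sex and age
#'
#' For every (band, condition) cell: Welch two-sample t-test of global wPLI
#' between mother-daughter and mother-son dyads (unequal variances,
#' Welch-Satterthwaite df) and the Pearson correlation with infant age in
#' months.
#'
#' @param tab a `cohort_table`.
#' @return `ContrastResult` data.frame with `test` in
#'   `c("welch_t_sex", "pearson_age")`.
#' @export
covariate_checks <- function(tab) {
  if (length(stats::na.omit(unique(tab$infant_sex))) != 2)
    stop("infant_sex must have exactly two levels")
  if (min(table(tab$infant_sex)) < 2)
    stop("a sex group has fewer than 2 dyads")
  rows <- list()
  for (b in attr(tab, "bands")) for (cond in attr(tab, "conditions")) {
    v <- tab[[paste(b, cond, sep = "_")]]
    tt <- t.test(v ~ tab$infant_sex, var.equal = FALSE)
    rows <- c(rows, list(contrast_row(
      "welch_t_sex", b, cond, unname(tt$statistic), unname(tt$parameter),
      tt$p.value, n = sum(!is.na(v)))))
    ok <- !is.na(v) & !is.na(tab$infant_age)
    if (sum(ok) >= 3) {
      ct <- cor.test(v[ok], tab$infant_age[ok])
      rows <- c(rows, list(contrast_row(
        "pearson_age", b, cond, unname(ct$estimate), unname(ct$parameter),
        ct$p.value, n = sum(ok))))
    }
  }
  do.call(rbind, rows)
}

#' Parametric repeated-measures sensitivity analysis
#'
#' Convenience cross-check mirroring a repeated-measures ANCOVA: univariate
#' split-plot ANOVA of global wPLI on condition (within dyads) with infant
#' age and sex as between-dyad covariates, including condition x covariate
#' interactions. Dyads with missing cells are dropped listwise. A rank test
#' such as Friedman admits no covariates, so this parametric path is where
#' covariate main and interaction effects are assessed.
#'
#' @param tab a `cohort_table`.
#' @param band band name.
#' @return `ContrastResult` data.frame with one row per model term
#'   (condition, covariates, interactions).
#' @export
rm_anova_sensitivity <- function(tab, band) {
  cols <- band_columns(tab, band)
  sub <- tab[complete.cases(tab[, cols]), , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 complete dyads for band ", band)
  long <- data.frame(
    dyad = factor(rep(sub$dyad_id, times = length(cols))),
    condition = factor(rep(attr(tab, "conditions"), each = nrow(sub)),
                       levels = attr(tab, "conditions")),
    age = rep(sub$infant_age, times = length(cols)),
    sex = factor(rep(sub$infant_sex, times = length(cols))),
    value = unlist(sub[, cols], use.names = FALSE)
  )
  has_cov <- !anyNA(long$age) && nlevels(long$sex) == 2
  form <- if (has_cov)
    value ~ age + sex + condition + condition:age + condition:sex + Error(dyad)
  else value ~ condition + Error(dyad)
  fit <- aov(form, data = long)
  sm <- summary(fit)
  ss_tol <- 1e-10 * sum(long$value^2) + 1e-300  # numerically-zero strata
  rows <- list()
  for (stratum in sm) {
    a <- stratum[[1]]
    terms <- trimws(rownames(a))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      fv <- a[i, "F value"]
      pv <- a[i, "Pr(>F)"]
      if (is.na(fv) || a[i, "Sum Sq"] < ss_tol) { fv <- 0; pv <- 1 }
      rows <- c(rows, list(contrast_row(
        "rm_anova", band, terms[i], fv, a[i, "Df"], pv, n = nrow(sub))))
    }
  }
  do.call(rbind, rows)
}

#' Run the full inferential chain for one band
#'
#' Outlier screening (3 SD rule), Friedman omnibus, pairwise Wilcoxon post
#' hocs with per-band FDR — the nonparametric chain applied to each band's
#' global synchrony values.
#'
#' @param tab a `cohort_table`.
#' @param band band name.
#' @param outlier_rule `"sd"` (default) or `"none"`.
#' @return list with `flags`, `friedman`, `wilcoxon` and the screened table.
#' @export
band_inference <- function(tab, band, outlier_rule = "sd") {
  if (nrow(tab) < 5) outlier_rule <- "none"   # screening needs a cohort
  flags <- if (outlier_rule == "none")
    data.frame(dyad_id = character(), band = character(),
               condition = character(), value = numeric())
  else detect_outliers(tab, band, rule = outlier_rule)
  tab2 <- if (nrow(flags)) remove_outliers(tab, flags) else tab
  list(flags = flags,
       friedman = friedman_conditions(tab2, band),
       wilcoxon = pairwise_wilcoxon_fdr(tab2, band),
       table = tab2)
}
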