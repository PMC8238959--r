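#' Fit the group-level model for one metric in one condition
#'
#' Linear (mixed) model of a condition-level metric on diagnosis, culture,
#' and their interaction, with sex and age as control covariates; IQ is
#' added for the naming-performance responses (naming time and errors) only.
#' When participants contribute repeated rows a random by-participant
#' intercept is included and the model is fitted by REML with
#' Satterthwaite-approximation t tests; with a single row per participant
#' the random intercept is unidentifiable and the model reduces to ordinary
#' least squares, which it is fitted as.
#'
#' Factor coding is treatment coding with ASD and HK as reference levels, so
#' the reported `diagnosis` estimate is control minus ASD and `culture` is
#' US minus HK: negative estimates mean the ASD (or HK) cell is higher.
#'
#' @param table Cohort table: one row per participant (x condition) with the
#'   metric columns plus `participant_id`, `diagnosis` (`"ASD"`/`"control"`),
#'   `culture` (`"HK"`/`"US"`), `sex`, `age`, and `iq`.
#' @param response Name of the response column.
#' @param condition Optional condition to filter to (`"symbolic"` or
#'   `"non_symbolic"`); `NULL` uses the table as given.
#' @param covariates Character vector of control covariates; `NULL` selects
#'   sex + age, plus IQ for `naming_time_s` and `n_errors`.
#' @return Object of class `ran_group_fit`: list with `estimates` (tibble
#'   `term`, `estimate`, `se`, `t`, `df`, `p` for culture, diagnosis,
#'   interaction), the fitted `model`, `response`, `condition`, and
#'   `interaction_lrt` (likelihood-ratio comparison of models with and
#'   without the interaction; inference proceeds with it retained).
#' @export
fit_group_model <- function(table, response, condition = NULL,
                            covariates = NULL) {
  if (!is.null(condition)) {
    table <- dplyr::filter(table, .data$condition == !!condition)
  }
  if (is.null(covariates)) {
    covariates <- c("sex", "age")
    if (response %in% c("naming_time_s", "n_errors")) {
      covariates <- c(covariates, "iq")
    }
  }
  covariates <- intersect(covariates, names(table))
  table <- as.data.frame(table)
  table$diagnosis <- factor(table$diagnosis, levels = c("ASD", "control"))
  table$culture <- factor(table$culture, levels = c("HK", "US"))
  for (f in c("diagnosis", "culture")) {
    if (nlevels(droplevels(table[[f]])) < 2) {
      stop("response requires 2 levels of ", f, " to be present", call. = FALSE)
    }
  }
  keep <- complete.cases(table[c(response, "diagnosis", "culture", covariates)])
  table <- table[keep, ]
  rhs <- paste(c("culture * diagnosis", covariates), collapse = " + ")
  repeated <- anyDuplicated(table$participant_id) > 0
  if (repeated) {
    fml <- as.formula(paste(response, "~", rhs, "+ (1 | participant_id)"))
    model <- lmerTest::lmer(fml, data = table)
    cf <- as.data.frame(coef(summary(model)))  # Satterthwaite df
    est <- tibble::tibble(term_raw = rownames(cf), estimate = cf$Estimate,
                          se = cf$`Std. Error`, t = cf$`t value`,
                          df = cf$df, p = cf$`Pr(>|t|)`)
    fml0 <- as.formula(paste(response, "~",
                             paste(c("culture + diagnosis", covariates),
                                   collapse = " + "),
                             "+ (1 | participant_id)"))
    m1 <- lme4::lmer(fml, data = table, REML = FALSE)
    m0 <- lme4::lmer(fml0, data = table, REML = FALSE)
  } else {
    fml <- as.formula(paste(response, "~", rhs))
    model <- lm(fml, data = table)
    cf <- as.data.frame(coef(summary(model)))
    est <- tibble::tibble(term_raw = rownames(cf), estimate = cf$Estimate,
                          se = cf$`Std. Error`, t = cf$`t value`,
                          df = model$df.residual, p = cf$`Pr(>|t|)`)
    m1 <- model
    m0 <- lm(as.formula(paste(response, "~",
                              paste(c("culture + diagnosis", covariates),
                                    collapse = " + "))), data = table)
  }
  aliased <- setdiff(c("cultureUS", "diagnosiscontrol",
                       "cultureUS:diagnosiscontrol"), est$term_raw)
  if (length(aliased)) {
    stop("rank-deficient design: aliased term(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  term_map <- c(cultureUS = "culture", diagnosiscontrol = "diagnosis",
                `cultureUS:diagnosiscontrol` = "interaction")
  est <- est[est$term_raw %in% names(term_map), ]
  est$term <- unname(term_map[est$term_raw])
  est <- est[match(c("culture", "diagnosis", "interaction"), est$term),
             c("term", "estimate", "se", "t", "df", "p")]
  lrt_stat <- as.numeric(2 * (logLik(m1) - logLik(m0)))
  lrt <- list(chisq = lrt_stat, df = 1L,
              p = pchisq(lrt_stat, df = 1, lower.tail = FALSE))
  structure(list(estimates = est, model = model, response = response,
                 condition = condition, interaction_lrt = lrt),
            class = "ran_group_fit")
}

#' @export
print.ran_group_fit <- function(x, ...) {
  cat(sprintf("<ran_group_fit> %s%s\n", x$response,
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else ""))
  print(as.data.frame(x$estimates), digits = 3)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment; adjusted values are compared to
#' the chosen FDR level (0.10 by convention here).
#'
#' @param p Vector of p values in (0, 1].
#' @param fdr_level FDR level the adjusted values are meant to be compared
#'   against (documentation of intent; does not change the values).
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p, fdr_level = 0.10) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Tukey-adjusted pairwise contrasts of the diagnosis x culture cells
#'
#' Least-square-means (estimated marginal means) of the four diagnosis x
#' culture cells and their pairwise differences with family-wise Tukey
#' adjustment.
#'
#' @param fit A [fit_group_model()] result.
#' @return List with `emmeans` (cell means tibble) and `contrasts` (tibble
#'   `contrast`, `estimate`, `se`, `df`, `t`, `p_adj`).
#' @export
pairwise_contrasts <- function(fit) {
  emm <- emmeans::emmeans(fit$model, ~ diagnosis * culture)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  cells <- tibble::as_tibble(as.data.frame(summary(emm)))
  contrasts <- tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate, se = prs$SE, df = prs$df,
    t = prs$t.ratio, p_adj = prs$p.value
  )
  list(emmeans = cells, contrasts = contrasts)
}

#' Mann-Whitney U test
#'
#' U statistic for `x` versus `y` with an exact p value by enumeration when
#' both samples are small (`n1 + n2 <= 12`) and untied, and a tie-corrected
#' normal approximation otherwise (no continuity correction).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U`, `p`, `n1`, `n2`, and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, n1 = n1, n2 = n2,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Partial Pearson correlation
#'
#' Correlation of `x` and `y` after linear removal of covariates from both,
#' with the p value from the t transform on `n - 2 - k` degrees of freedom.
#' Without covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates.
#' @return List with `r`, `t`, `df`, `p`, `n`; `r` is `NA` (with a warning)
#'   when a residual is degenerate (zero variance).
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    cc <- complete.cases(x, y)
    k <- 0L
    rx <- x[cc]; ry <- y[cc]
  } else {
    covariates <- as.data.frame(covariates)
    cc <- complete.cases(x, y, covariates)
    Z <- as.matrix(covariates[cc, , drop = FALSE])
    k <- ncol(Z)
    rx <- resid(lm(x[cc] ~ Z))
    ry <- resid(lm(y[cc] ~ Z))
  }
  n <- sum(cc)
  if (n < k + 3) stop("need at least covariates + 3 complete cases", call. = FALSE)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("degenerate (zero-variance) residuals; correlation undefined")
    return(list(r = NA_real_, t = NA_real_, df = n - 2L - k, p = NA_real_, n = n))
  }
  r <- as.numeric(stats::cor(rx, ry))
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, t = tval, df = df, p = 2 * pt(-abs(tval), df), n = n)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param contingency Matrix of non-negative counts.
#' @return List with `X2`, `df`, `p`.
#' @export
chisq_counts <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(contingency, correct = FALSE))
  list(X2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
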