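#' Simulate an MSD-style fluid biomarker panel
#'
#' Per participant, analyte concentrations are lognormal with group-specific
#' means; CCL22 and ferritin are drawn from a bivariate lognormal with
#' group-specific correlation rho on the log scale (positive inside the IBD
#' and PD arms, zero in NHC by default, matching the reported disease-specific
#' CCL22-ferritin relationship). PD participants carry a disease duration and
#' a planted negative duration-CCL22 relationship with a configurable target
#' R-squared. Plasma and stool matrices are generated with independent draws;
#' stool rows carry a total-protein value for BCA normalization. Deterministic
#' given the seed.
#'
#' @param config \code{\link{sim_config}} (uses the \code{fluid} block and seed)
#' @param matrix_type "plasma" or "stool"
#' @return list(panel = data.frame(participant, group, matrix,
#'   disease_duration, total_protein, one column per analyte), truth = list
#'   with the planted rho and duration effect)
#' @export
simulate_fluid_panel <- function(config = sim_config(), matrix_type = c("plasma", "stool")) {
  matrix_type <- match.arg(matrix_type)
  fl <- config$fluid
  if (!all(c("CCL22", "ferritin") %in% fl$analytes))
    stop("fluid analyte list must include CCL22 and ferritin")
  if (any(abs(fl$rho) >= 1)) stop("|rho| must be < 1")
  set.seed(config$seed + if (matrix_type == "stool") 1L else 0L)
  groups <- rep(names(fl$n), fl$n)
  ids <- unlist(lapply(names(fl$n), function(g)
    sprintf("%s_s%02d", g, seq_len(fl$n[[g]]))))
  n <- length(ids)
  meanlog <- function(an, g) {
    m <- if (an %in% names(fl$meanlog)) fl$meanlog[[an]] else log(100)
    sh <- fl$group_shift[[g]]
    if (!is.null(sh) && an %in% names(sh)) m <- m + sh[[an]] else m
  }
  panel <- data.frame(participant = ids, group = groups, matrix = matrix_type,
                      disease_duration = NA_real_,
                      total_protein = if (matrix_type == "stool")
                        stats::rlnorm(n, log(2), 0.3) else NA_real_,
                      stringsAsFactors = FALSE)
  for (an in setdiff(fl$analytes, c("CCL22", "ferritin"))) {
    panel[[an]] <- vapply(seq_len(n), function(i)
      stats::rlnorm(1, meanlog(an, groups[i]), fl$sdlog), 0)
  }
  # bivariate lognormal CCL22-ferritin with per-group log-scale correlation
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- unname(fl$rho[groups])
  l_ccl22 <- vapply(seq_len(n), function(i) meanlog("CCL22", groups[i]), 0) +
    fl$sdlog * z1
  l_ferr <- vapply(seq_len(n), function(i) meanlog("ferritin", groups[i]), 0) +
    fl$sdlog * (rho * z1 + sqrt(1 - rho^2) * z2)
  # planted duration effect in PD, additive on log CCL22 with variance chosen
  # to hit the target R-squared
  is_pd <- groups == "PD"
  panel$disease_duration[is_pd] <- stats::runif(sum(is_pd), fl$duration_range[1],
                                                fl$duration_range[2])
  if (fl$duration_r2 > 0 && any(is_pd)) {
    d <- panel$disease_duration[is_pd]
    ds <- (d - mean(d)) / stats::sd(d)
    beta <- sqrt(fl$duration_r2 / (1 - fl$duration_r2)) * fl$sdlog
    l_ccl22[is_pd] <- l_ccl22[is_pd] - beta * ds
  }
  panel$CCL22 <- exp(l_ccl22)
  panel$ferritin <- exp(l_ferr)
  list(panel = panel,
       truth = list(rho = fl$rho, duration_r2 = fl$duration_r2))
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y finite paired numeric vectors, n >= 2; x must vary
#' @return list of class \code{regression_fit}: slope, intercept, r_squared,
#'   p (two-sided slope t-test, NA when n < 3), n
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 finite pairs")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  p <- if (length(x) >= 3) unname(s$coefficients["x", "Pr(>|t|)"]) else NA_real_
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = s$r.squared, p = p, n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("ols fit (n=%d): y = %.4g + %.4g x, R^2 = %.3f, p = %.3g\n",
              x$n, x$intercept, x$slope, x$r_squared, x$p))
  invisible(x)
}

#' Disease-vs-control group comparison of one analyte
#'
#' Two-sided Wilcoxon rank-sum test (chosen for small, skewed immunoassay
#' samples) of the analyte concentration in a disease arm against NHC, with a
#' Welch t-test available behind a flag.
#'
#' @param panel fluid panel data.frame (from \code{\link{simulate_fluid_panel}}
#'   or read from file)
#' @param analyte analyte column name
#' @param comparison disease group compared against NHC
#' @param test "wilcoxon" (default) or "t"
#' @param params \code{\link{stat_params}} (star levels)
#' @return list(p, code, n_disease, n_nhc)
#' @export
group_compare <- function(panel, analyte, comparison = c("IBD", "PD"),
                          test = c("wilcoxon", "t"), params = stat_params()) {
  comparison <- match.arg(comparison)
  test <- match.arg(test)
  if (!analyte %in% names(panel)) stop("missing analyte: ", analyte)
  x <- panel[[analyte]][panel$group == comparison]
  y <- panel[[analyte]][panel$group == "NHC"]
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 participants per arm")
  p <- if (test == "wilcoxon") wilcoxon_rank_sum(x, y) else
    stats::t.test(x, y)$p.value
  lv <- sort(params$star_levels, decreasing = TRUE)
  code <- ""
  for (i in seq_along(lv)) if (p < lv[i]) code <- names(lv)[i]
  list(p = p, code = code, n_disease = length(x), n_nhc = length(y))
}

#' Normalize stool analyte concentrations to total protein
#'
#' Divides each analyte by the participant's BCA total-protein value
#' (analyte per mg protein); plasma rows are left unchanged.
#'
#' @param panel fluid panel with a \code{total_protein} column
#' @param analytes analyte column names to normalize
#' @return panel with normalized stool rows
#' @export
normalize_stool <- function(panel, analytes) {
  st <- panel$matrix == "stool"
  if (!any(st)) return(panel)
  tp <- panel$total_protein[st]
  if (any(is.na(tp)) || any(tp <= 0))
    stop("total_protein missing or non-positive for stool rows")
  for (an in analytes) panel[[an]][st] <- panel[[an]][st] / tp
  panel
}

#' Average assay duplicates, flagging high-CV wells
#'
#' Standard immunoassay QC: duplicate wells are averaged and pairs with a
#' coefficient of variation above the threshold are flagged.
#'
#' @param a,b duplicate measurements
#' @param cv_max CV flag threshold (default 20%)
#' @return data.frame(value = mean, cv, flagged)
#' @export
average_duplicates <- function(a, b, cv_max = 0.20) {
  m <- (a + b) / 2
  cv <- ifelse(m > 0, abs(a - b) / (sqrt(2) * m), 0)
  data.frame(value = m, cv = cv, flagged = cv > cv_max)
}
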