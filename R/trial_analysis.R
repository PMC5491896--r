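#' Summarize arm-level PIP rates and the difference-in-differences
#'
#' Rates are computed by exact integer arithmetic up to the final
#' division: `100 * numerator / denominator` per arm and window from the
#' hub's arm totals.  Per-arm change is treatment minus baseline, and
#' the difference-in-differences (intervention change minus control
#' change) is the trial's effect measure on the percentage-point scale.
#' Display values are rounded per `digits` (trial tables print 1 d.p.)
#' while full precision is kept internally; the displayed change is the
#' difference of the *displayed* rates so the table is self-consistent.
#'
#' @param hub A `hub_collection` (both arms, both windows required).
#' @param digits Display rounding for rates (default 1).
#' @return An object of class `trial_result`.
#' @export
summarize_trial <- function(hub, digits = 1) {
  stopifnot(inherits(hub, "hub_collection"))
  tot <- hub$arm_totals[hub$arm_totals$measure_id == "total", , drop = FALSE]
  need <- expand.grid(arm = c("control", "intervention"),
                      window = c("baseline", "treatment"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$arm, d$window)
  if (!all(key(need) %in% key(tot))) {
    stop("hub is missing arm/window total(s): ",
         paste(setdiff(key(need), key(tot)), collapse = ", "), call. = FALSE)
  }
  tot <- tot[match(key(need), key(tot)), , drop = FALSE]
  tot$rate <- pip_rate(tot$numerator, tot$denominator)
  tot$rate_display <- round(tot$rate, digits)
  g <- function(a, w, col) tot[tot$arm == a & tot$window == w, col]
  per_arm <- data.frame(
    arm = c("control", "intervention"),
    baseline_rate = c(g("control", "baseline", "rate"),
                      g("intervention", "baseline", "rate")),
    treatment_rate = c(g("control", "treatment", "rate"),
                       g("intervention", "treatment", "rate")))
  per_arm$change <- per_arm$treatment_rate - per_arm$baseline_rate
  per_arm$change_display <- round(per_arm$treatment_rate, digits) -
    round(per_arm$baseline_rate, digits)
  did <- per_arm$change[per_arm$arm == "intervention"] -
    per_arm$change[per_arm$arm == "control"]
  did_display <- per_arm$change_display[per_arm$arm == "intervention"] -
    per_arm$change_display[per_arm$arm == "control"]
  structure(list(cells = tot[c("arm", "window", "numerator", "denominator",
                               "rate", "rate_display")],
                 per_arm = per_arm,
                 did = did, did_display = did_display, digits = digits),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("PIP rates (%) by arm and period\n")
  f <- function(v) formatC(round(v, x$digits), format = "f", digits = x$digits)
  for (a in c("intervention", "control")) {
    p <- x$per_arm[x$per_arm$arm == a, ]
    cat(sprintf("  %-12s baseline %s | treatment %s | change %s\n", a,
                f(p$baseline_rate), f(p$treatment_rate), f(p$change_display)))
  }
  cat(sprintf("  difference-in-differences: %s percentage points\n",
              f(x$did_display)))
  invisible(x)
}

#' Clinic-clustered GEE test of the intervention effect
#'
#' Fits a binomial-logit marginal model to per-(patient, rule) PIP
#' outcomes aggregated to clinic-by-window binomial counts, with
#' covariates arm, period and their interaction, an exchangeable working
#' correlation within clinic, and the robust (sandwich) covariance taken
#' over clinics.  The arm-by-period interaction coefficient is the
#' trial's effect estimate on the log-odds scale; its two-sided Wald
#' test is referred to a t distribution with (clinics - 4) degrees of
#' freedom rather than the normal — with a handful of clinics the
#' plain sandwich Wald-z test is badly anticonservative, and the
#' t reference is the standard small-sample repair.
#'
#' Fitting on clinic-by-window aggregates is score-equivalent to fitting
#' the individual Bernoulli rows under this design: all members of a
#' clinic-window cell share one covariate row, so the estimating
#' equations collapse onto the cell proportions.
#'
#' @param counts Data frame with columns `clinic_id`, `arm`
#'   (`control`/`intervention`), `window` (`baseline`/`treatment`),
#'   `fired`, `eligible` (see [hub_pip_counts()]).
#' @param df Degrees of freedom for the Wald reference; default
#'   `n_clinics - 4` (clusters minus regression parameters).
#' @param maxit,tol Fisher-scoring controls.
#' @return An object of class `gee_fit`: `estimate` (interaction
#'   log-odds), `se`, `statistic`, `df`, `p_value`, working correlation
#'   `alpha`, full `coefficients` and robust `vcov`.  A fit with zero
#'   numerators everywhere is flagged `degenerate` and returns `NA`
#'   inference rather than failing.
#' @export
gee_test <- function(counts, df = NULL, maxit = 50, tol = 1e-10) {
  req <- c("clinic_id", "arm", "window", "fired", "eligible")
  if (!all(req %in% names(counts))) {
    stop("counts needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  counts <- counts[counts$eligible > 0, , drop = FALSE]
  ncl <- tapply(counts$clinic_id, counts$arm, function(x) length(unique(x)))
  if (any(is.na(ncl[c("control", "intervention")])) || any(ncl < 2)) {
    stop("gee_test needs >= 2 clinics per arm; got ",
         paste(names(ncl), ncl, sep = "=", collapse = ", "), call. = FALSE)
  }
  stopifnot(all(counts$fired >= 0), all(counts$fired <= counts$eligible))
  cells <- with(counts, table(arm, window))
  if (any(cells == 0)) {
    stop("inestimable: no clinic contributes eligible pairs in some ",
         "arm-by-window cell (", paste(colnames(cells), collapse = "/"),
         "); the interaction cannot be identified", call. = FALSE)
  }
  arm <- as.integer(counts$arm == "intervention")
  per <- as.integer(counts$window == "treatment")
  X <- cbind("(Intercept)" = 1, arm = arm, period = per, "arm:period" = arm * per)
  y <- counts$fired / counts$eligible
  n <- counts$eligible
  cl <- split(seq_len(nrow(counts)), counts$clinic_id)
  K <- length(cl)
  npar <- ncol(X)
  if (is.null(df)) df <- K - npar
  if (df < 1) stop("too few clinics for the t reference (df = ", df, ")", call. = FALSE)
  degenerate <- sum(counts$fired) == 0L
  if (degenerate) {
    warning("all numerators are zero: degenerate fit, no effect is estimable",
            call. = FALSE)
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          statistic = NA_real_, df = df, p_value = NA_real_,
                          alpha = NA_real_, coefficients = rep(NA_real_, npar),
                          vcov = matrix(NA_real_, npar, npar), n_clinics = K,
                          degenerate = TRUE), class = "gee_fit"))
  }
  beta <- stats::coef(stats::glm.fit(X, y, weights = n,
                                     family = stats::binomial()))
  alpha <- 0
  cluster_parts <- function(p) {
    lapply(cl, function(idx) {
      m <- length(idx)
      A <- p[idx] * (1 - p[idx]) / n[idx]
      R <- matrix(alpha, m, m); diag(R) <- 1
      V <- sqrt(A) %o% sqrt(A) * R
      list(idx = idx,
           D = p[idx] * (1 - p[idx]) * X[idx, , drop = FALSE],
           Vi = solve(V),
           e = y[idx] - p[idx])
    })
  }
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% beta))
    r <- (y - p) / sqrt(p * (1 - p) / n)
    num <- 0; den <- 0
    for (idx in cl) {
      m <- length(idx)
      if (m > 1L) {
        rr <- r[idx]
        num <- num + (sum(rr)^2 - sum(rr^2)) / 2
        den <- den + m * (m - 1) / 2
      }
    }
    alpha <- max(min(num / max(den, 1), 0.95), -0.95)
    U <- numeric(npar); Imat <- matrix(0, npar, npar)
    for (part in cluster_parts(p)) {
      U <- U + drop(t(part$D) %*% part$Vi %*% part$e)
      Imat <- Imat + t(part$D) %*% part$Vi %*% part$D
    }
    delta <- solve(Imat, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  p <- stats::plogis(drop(X %*% beta))
  B <- matrix(0, npar, npar); M <- matrix(0, npar, npar)
  for (part in cluster_parts(p)) {
    B <- B + t(part$D) %*% part$Vi %*% part$D
    M <- M + t(part$D) %*% part$Vi %*% (part$e %o% part$e) %*% part$Vi %*% part$D
  }
  Bi <- solve(B)
  V <- Bi %*% M %*% Bi
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  est <- beta[["arm:period"]]
  se <- sqrt(V["arm:period", "arm:period"])
  stat <- est / se
  structure(list(estimate = est, se = se, statistic = stat, df = df,
                 p_value = 2 * stats::pt(-abs(stat), df = df),
                 alpha = alpha, coefficients = beta, vcov = V,
                 n_clinics = K, degenerate = FALSE),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<gee_fit> degenerate (all numerators zero)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<gee_fit> arm:period log-odds %.4f (robust SE %.4f), ",
                     "t = %.3f on %d df, p = %.3g\n"),
              x$estimate, x$se, x$statistic, x$df, x$p_value))
  cat(sprintf("  %d clinics, exchangeable working correlation alpha = %.3f\n",
              x$n_clinics, x$alpha))
  invisible(x)
}

#' Sample size for a two-arm comparison of PIP proportions
#'
#' Textbook two-proportion normal-approximation sample size,
#' \deqn{n = (z_{1-\alpha/2} + z_{power})^2 (p_1 q_1 + p_2 q_2) / (p_1-p_2)^2,}
#' multiplied by the cluster design effect `1 + (m - 1) rho` (supplied
#' directly as `design_effect`).  Clinics per arm is the ceiling of
#' n over the expected encounters per clinic.
#'
#' @param p_control Control-arm proportion (e.g. 0.20).
#' @param relative_reduction Expected relative reduction (e.g. 0.20 for
#'   a drop from 20\% to 16\%).  Must be strictly positive: a zero
#'   effect needs an infinite sample.
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param design_effect Variance inflation for clustering (>= 1).
#' @param encounters_per_clinic Expected eligible encounters per clinic,
#'   to convert n into clinics per arm (optional).
#' @return List with `n_per_arm` (exact, unrounded — linear in
#'   `design_effect`), `n_per_arm_ceil`, `clinics_per_arm` (or `NA`),
#'   `p_control`, `p_intervention`.
#' @examples
#' sample_size(0.20, 0.20)$n_per_arm_ceil  # ~1445 encounters per arm
#' @export
sample_size <- function(p_control, relative_reduction, alpha = 0.05,
                        power = 0.8, design_effect = 1,
                        encounters_per_clinic = NULL) {
  stopifnot(p_control > 0, p_control < 1, alpha > 0, alpha < 1,
            power > 0, power < 1, design_effect >= 1)
  if (relative_reduction <= 0 || relative_reduction >= 1) {
    stop("relative_reduction must be in (0, 1); a zero effect needs infinite n",
         call. = FALSE)
  }
  p1 <- p_control
  p2 <- p_control * (1 - relative_reduction)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- design_effect * (za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
  list(n_per_arm = n,
       n_per_arm_ceil = ceiling(n),
       clinics_per_arm = if (is.null(encounters_per_clinic)) NA_integer_ else
         as.integer(ceiling(n / encounters_per_clinic)),
       p_control = p1, p_intervention = p2)
}

#' Analytic power at a given sample size
#'
#' The prediction side of the sample-size calculation.  For the
#' `"two-sample"` design (what [sample_size()] assumes) this is the
#' closed-form normal-approximation power of the two-proportion z test
#' at `n` per arm.  For the `"did"` design it predicts the power of the
#' cluster-GEE arm-by-period interaction test on the risk-difference
#' scale: four cells of size `n` (both arms at `p1` at baseline, the
#' intervention arm moving to `p2`), variance `3 p1 q1 + p2 q2` over
#' `n`, referred — like [gee_test()] itself — to a t distribution with
#' `n_clinics - 4` df, via the noncentral t.
#'
#' @param p1 Baseline/control proportion.
#' @param p2 Intervention proportion under the alternative.
#' @param n_per_arm Eligible observations per arm (per window for
#'   `"did"`).
#' @param alpha Two-sided type-I error.
#' @param design_effect Cluster variance inflation.
#' @param design `"two-sample"` or `"did"`.
#' @param n_clinics Total clinic count (required for `"did"`).
#' @return Predicted power in (0, 1).
#' @export
power_for_n <- function(p1, p2, n_per_arm, alpha = 0.05, design_effect = 1,
                        design = c("two-sample", "did"), n_clinics = NULL) {
  design <- match.arg(design)
  delta <- abs(p1 - p2)
  stopifnot(delta > 0, n_per_arm > 0)
  if (design == "two-sample") {
    se <- sqrt(design_effect * (p1 * (1 - p1) + p2 * (1 - p2)) / n_per_arm)
    stats::pnorm(delta / se - stats::qnorm(1 - alpha / 2))
  } else {
    stopifnot(!is.null(n_clinics))
    df <- n_clinics - 4L
    stopifnot(df >= 1)
    se <- sqrt(design_effect * (3 * p1 * (1 - p1) + p2 * (1 - p2)) / n_per_arm)
    crit <- stats::qt(1 - alpha / 2, df)
    ncp <- delta / se
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
}
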