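#' Factorial group comparison with AIC model selection
#'
#' Fits the family of (generalized) linear models over the given factors --
#' main effects only, all two-way interactions, and the full factorial --
#' selects the one with the lowest AIC, and reports Holm-adjusted post hoc
#' contrasts between the factor-combination cell means (via emmeans).
#'
#' @param data A data.frame of per-fish (or per-group) measurements.
#' @param response Name of the response column.
#' @param factors Character vector of 2 or 3 factor column names, each with
#'   at least 2 levels and at least 2 observations per cell.
#' @param family A [stats::family()] object. Default `gaussian()`.
#' @return An object of class `stat_result`: list with `response`,
#'   `candidates` (data.frame formula, aic), `chosen` (formula string),
#'   `fit` (the glm), `coefficients`, `anova` (Type-II-style drop tests via
#'   [stats::drop1()]), `contrasts` (emmeans pairs with raw and Holm p).
#' @export
compare_factorial <- function(data, response, factors,
                              family = stats::gaussian()) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)),
            length(factors) >= 2, length(factors) <= 3)
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(data[factors], nlevels, integer(1)) < 2)) {
    stop("each factor needs at least 2 levels")
  }
  cells <- table(data[factors])
  if (any(cells < 2)) {
    stop("need at least 2 observations per factor cell (singular design)")
  }
  if (!all(is.finite(data[[response]]))) stop("response must be finite")
  rhs <- c(paste(factors, collapse = " + "),
           if (length(factors) == 2) paste(factors, collapse = " * ")
           else c(paste0("(", paste(factors, collapse = " + "), ")^2"),
                  paste(factors, collapse = " * ")))
  fits <- lapply(rhs, function(r) {
    stats::glm(stats::reformulate(r, response), data = data, family = family)
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  best <- which.min(aics)
  fit <- fits[[best]]
  em <- emmeans::emmeans(fit, specs = stats::reformulate(
    paste(factors, collapse = " * ")))
  prs_raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  prs <- prs_raw
  prs$p_holm <- holm_adjust(prs_raw$p.value)
  structure(list(response = response,
                 candidates = data.frame(formula = rhs, aic = aics),
                 chosen = rhs[best], fit = fit,
                 coefficients = stats::coef(summary(fit)),
                 anova = stats::drop1(fit, test = if (family$family ==
                   "gaussian") "F" else "Chisq"),
                 contrasts = prs),
            class = "stat_result")
}

#' Logarithmic-curve fit of a response on a positive index
#'
#' Ordinary least squares of `y` on `log(x)`; when any index is zero (or
#' negative within rounding) a small constant `c` is added first so that
#' perfectly balanced turners, whose bias index is 0, stay in the fit.
#'
#' @param x Predictor (e.g. turning-bias index), non-negative.
#' @param y Response (e.g. adjusted nearby-interaction duration).
#' @param c Offset added to `x` when `min(x) <= 0`. Default 0.01.
#' @return List with `adj_r2`, `f`, `p`, `coefficients` (intercept, slope),
#'   and the underlying `fit`.
#' @export
log_curve_fit <- function(x, y, c = 0.01) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (min(x) <= 0) x <- x + c
  fit <- stats::lm(y ~ log(x))
  s <- summary(fit)
  fstat <- s$fstatistic
  list(adj_r2 = s$adj.r.squared,
       f = unname(fstat[1]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)),
       coefficients = stats::coef(fit),
       fit = fit)
}

#' Intraclass correlation for repeatability across sessions
#'
#' Two-way absolute-agreement ICC for single measures, ICC(A,1): from the
#' subject, session and residual mean squares of the subjects x sessions
#' matrix,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Significance is the F-test of between-subject variance, F = MSR/MSE on
#' (n-1, (n-1)(k-1)) df. The consistency variant ICC(C,1), which ignores
#' session mean shifts, is available via `type = "consistency"`.
#'
#' @param m Numeric matrix, subjects in rows, sessions in columns (>= 3
#'   subjects, >= 2 sessions, no missing values).
#' @param type "agreement" (default) or "consistency".
#' @return List with `icc`, `f`, `df1`, `df2`, `p`, `ms` (the three mean
#'   squares). `icc` is `NA` with a warning when between-subject variance is
#'   zero.
#' @export
icc_repeatability <- function(m, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 3, ncol(m) >= 2, all(is.finite(m)))
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rmean <- rowMeans(m); cmean <- colMeans(m)
  ssr <- k * sum((rmean - grand)^2)
  ssc <- n * sum((cmean - grand)^2)
  sse <- sum((m - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || (msr == mse && mse == 0)) {
    warning("zero between-subject variance; ICC undefined")
    return(list(icc = NA_real_, f = NA_real_, df1 = n - 1,
                df2 = (n - 1) * (k - 1), p = NA_real_,
                ms = c(msr = msr, msc = msc, mse = mse)))
  }
  icc <- switch(type,
                agreement = (msr - mse) /
                  (msr + (k - 1) * mse + k * (msc - mse) / n),
                consistency = (msr - mse) / (msr + (k - 1) * mse))
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(icc = icc, f = f, df1 = df1, df2 = df2, p = p,
       ms = c(msr = msr, msc = msc, mse = mse))
}

#' Paired, unpaired and rank-based two-sample tests with Holm adjustment
#'
#' Dispatches Student/Welch t or Wilcoxon signed-rank / rank-sum tests over
#' one or several contrasts and reports raw and Holm-adjusted p-values as
#' one family.
#'
#' @param contrasts A list of contrasts, each a list with elements `x`, `y`
#'   (numeric vectors), optional `name`, optional `paired` (default the
#'   top-level `paired`).
#' @param test "t" (Welch for unpaired, paired t otherwise) or "wilcoxon".
#' @param paired Default pairing for contrasts that do not set their own.
#' @return A `stat_result` whose `contrasts` data.frame has name, statistic,
#'   p_raw, p_holm, n.
#' @export
paired_and_rank_tests <- function(contrasts, test = c("t", "wilcoxon"),
                                  paired = FALSE) {
  test <- match.arg(test)
  if (!is.null(contrasts$x)) contrasts <- list(contrasts)
  rows <- lapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    stopifnot(!is.null(ct$x), !is.null(ct$y))
    if (length(ct$x) < 2 || length(ct$y) < 2) {
      stop("each contrast needs at least 2 observations per sample")
    }
    pr <- if (is.null(ct$paired)) paired else ct$paired
    ht <- if (test == "t") {
      stats::t.test(ct$x, ct$y, paired = pr)
    } else {
      stats::wilcox.test(ct$x, ct$y, paired = pr, exact = FALSE)
    }
    data.frame(name = if (is.null(ct$name)) paste0("contrast_", i)
               else ct$name,
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               n = length(ct$x) + length(ct$y))
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- holm_adjust(tab$p_raw)
  structure(list(response = "two-sample tests", test = test,
                 contrasts = tab),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$response, "\n")
  if (!is.null(x$chosen)) cat("  chosen model:", x$chosen, "\n")
  if (!is.null(x$contrasts)) {
    cat("  contrasts:\n")
    print(utils::head(x$contrasts, 10))
  }
  invisible(x)
}

#' Run the full study pipeline over one or two cohorts
#'
#' Orchestrates the whole analysis: trim the lead-in, fill tracking gaps,
#' compute per-fish kinematics and turning bias, build the random-regrouping
#' null ensemble, calibrate (or accept fixed) distance/duration cutoffs,
#' detect nearby-interaction bouts, apply the passing-by correction,
#' extract bout-anchored speed profiles, and -- when two cohorts are given
#' -- compare adjusted interaction durations between them. All randomness
#' flows from `seed`.
#'
#' @param cohorts Named list of one or two lists of [group_recording()]s
#'   (e.g. `list(surface = ..., cave = ...)`).
#' @param trim_s Lead-in to discard, s. Default 0 (simulated recordings
#'   need none; use 60 for raw 6-min videos).
#' @param calibrate If `TRUE`, derive cutoffs from the first cohort against
#'   its null ensemble; otherwise use `dist_cutoff`/`dur_cutoff` as given.
#' @param dist_cutoff,dur_cutoff Fixed cutoffs (cm, s). Defaults 5 and 4.
#' @param n_null Null-ensemble size. Default 200.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, tidy CSVs and a JSON
#'   report are written there.
#' @return List with `config`, `cutoffs`, `calibration` (when run),
#'   `fish_table` (per-fish metrics + interaction totals), `bouts`,
#'   `profiles`, `null_seed`, and `comparison` (when two cohorts).
#' @export
run_study <- function(cohorts, trim_s = 0, calibrate = FALSE,
                      dist_cutoff = 5, dur_cutoff = 4, n_null = 200,
                      seed = 1, out_dir = NULL) {
  if (inherits(cohorts, "group_recording")) cohorts <- list(list(cohorts))
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  if (length(cohorts) == 0 || length(cohorts[[1]]) == 0) {
    stop("no recordings supplied")
  }
  prep <- lapply(cohorts, function(recs) {
    lapply(recs, function(r) {
      if (trim_s > 0) r <- trim_lead_in(r, trim_s)
      fill_gaps(r)
    })
  })
  calib <- NULL
  if (calibrate) {
    nullens <- build_null_groups(prep[[1]], n = n_null, seed = seed)
    dcal <- distance_calibration(prep[[1]], nullens)
    dist_cutoff <- if (length(dcal$significant)) dcal$selected_cutoff
                   else dist_cutoff
    ucal <- duration_calibration(prep[[1]], nullens,
                                 dist_cutoff = dist_cutoff)
    dur_cutoff <- if (length(ucal$significant)) ucal$selected_cutoff
                  else dur_cutoff
    calib <- list(distance = dcal, duration = ucal)
  }
  all_bouts <- list(); fish_rows <- list(); profiles <- list()
  for (cname in names(prep)) {
    for (rec in prep[[cname]]) {
      V <- group_mean_speed(rec)
      pbm <- passing_by_duration(V, cutoff = dist_cutoff)
      bouts <- detect_group_bouts(rec, dist_cutoff, dur_cutoff)
      summ <- adjust_and_summarize(bouts, pbm, names(rec$trajectories))
      met <- fish_metrics(rec)
      met$cohort <- cname
      met$group_V <- V
      met$pbdur_s <- pbm$pbdur
      met <- merge(met, summ$per_fish, by = "fish_id", sort = FALSE)
      fish_rows[[length(fish_rows) + 1L]] <- met
      all_bouts[[length(all_bouts) + 1L]] <- summ$bouts
      profiles[[paste(cname, rec$group_id, sep = ":")]] <-
        lapply(names(rec$trajectories), function(f) {
          speed_profile(rec, f, summ$bouts)
        })
    }
  }
  fish_table <- do.call(rbind, fish_rows)
  bouts <- do.call(rbind, all_bouts)
  comparison <- NULL
  if (length(prep) == 2) {
    a <- fish_table$total_adjusted_s[fish_table$cohort == names(prep)[1]]
    b <- fish_table$total_adjusted_s[fish_table$cohort == names(prep)[2]]
    comparison <- paired_and_rank_tests(
      list(x = a, y = b, name = paste(names(prep), collapse = "_vs_")),
      test = "wilcoxon")
  }
  out <- list(config = list(trim_s = trim_s, calibrate = calibrate,
                            n_null = n_null, seed = seed),
              cutoffs = list(dist_cm = dist_cutoff, dur_s = dur_cutoff),
              calibration = calib, fish_table = fish_table, bouts = bouts,
              profiles = profiles, comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fish_table, file.path(out_dir, "fish_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(bouts, file.path(out_dir, "bouts.csv"),
                     row.names = FALSE)
    report <- list(config = out$config, cutoffs = out$cutoffs,
                   n_groups = vapply(prep, length, integer(1)),
                   mean_adjusted_s = mean(fish_table$total_adjusted_s),
                   comparison_p = if (!is.null(comparison))
                     comparison$contrasts$p_raw else NULL)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
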