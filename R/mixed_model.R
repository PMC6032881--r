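#' Fit the log-outcome linear mixed-effects model
#'
#' Estimates, by REML, the model
#' \deqn{\log y = \alpha + \beta_{abs}(A-1) + \beta_{spec}(S-1) +
#'   \beta_{sw} W + b_{cell} + \varepsilon}
#' where `A` is the absolute list number, `S` the procedure-specific list
#' number, `W` the switch indicator, and `b_cell` a random intercept shared by
#' all records in the same (procedure, age group, ASA) cell — the conservative
#' assumption that baseline operating times are independent between cells.
#' Centring the order covariates at 1 makes the intercept the log baseline of
#' a first-position, non-switch case.
#'
#' Confidence intervals and p-values for the fixed effects are Wald (normal
#' approximation), two-sided at the 5% level. A covariate with no variation in
#' the data (e.g. no switches present) yields an `NA` estimate rather than a
#' spurious zero.
#'
#' @param coded coded tibble from [code_records()].
#' @param outcome `"duration"` (operating time, the primary outcome) or
#'   `"los"` (length of stay, in minutes). Rows with a missing or
#'   non-positive outcome are dropped.
#' @param cell_vars character vector of columns defining the random-intercept
#'   cell; default the full (procedure, age, ASA) triple. Per-procedure fits
#'   use (age, ASA) within one code.
#' @return an object of class `list_order_fit`: a list with `effects` (tibble
#'   with one row per fixed effect: `name`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pct`, `pct_low`, `pct_high`, `p_value`), `intercept`, `tau_hat`,
#'   `sigma_hat`, `n_obs`, `n_cells`, `outcome`, `converged`, and the
#'   underlying `lme4` fit in `model`.
#' @export
fit_lmm <- function(coded, outcome = c("duration", "los"),
                    cell_vars = c("procedure_code", "age_group", "asa_grade")) {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "duration") "duration_min" else "los_min"
  if (!ycol %in% names(coded)) {
    stop("coded data lack outcome column ", ycol, call. = FALSE)
  }

  dat <- coded[!is.na(coded[[ycol]]) & coded[[ycol]] > 0, , drop = FALSE]
  dat <- tibble(
    y = log(dat[[ycol]]),
    abs0 = dat$absolute_list_no - 1,
    spec0 = dat$procedure_specific_list_no - 1,
    sw = as.numeric(dat$switch),
    cell = do.call(paste, c(lapply(cell_vars, function(v) dat[[v]]),
                            sep = "|"))
  )
  cell_sizes <- table(dat$cell)
  if (sum(cell_sizes >= 2) < 2) {
    stop("need at least two cells with at least two observations",
         call. = FALSE)
  }

  term_map <- c(absolute_order = "abs0", specific_order = "spec0",
                switch = "sw")
  usable <- vapply(term_map, function(v) stats::var(dat[[v]]) > 0, logical(1))
  if (!any(usable)) {
    stop("no fixed-effect covariate varies in these data", call. = FALSE)
  }
  rhs <- paste(c(term_map[usable], "(1 | cell)"), collapse = " + ")
  fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))

  fe <- lme4::fixef(fit)
  se_all <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z975 <- qnorm(0.975)

  pull <- function(col) {
    if (col %in% names(fe)) c(fe[[col]], se_all[[col]]) else c(NA_real_, NA_real_)
  }
  est <- t(vapply(term_map, pull, numeric(2)))
  beta <- est[, 1]
  se <- est[, 2]
  effects <- tibble(
    name = names(term_map),
    beta = unname(beta),
    se = unname(se),
    ci_low = unname(beta - z975 * se),
    ci_high = unname(beta + z975 * se),
    pct = to_percent(unname(beta)),
    pct_low = to_percent(unname(beta - z975 * se)),
    pct_high = to_percent(unname(beta + z975 * se)),
    p_value = unname(2 * pnorm(-abs(beta / se)))
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau_hat <- sqrt(vc$vcov[vc$grp == "cell"])
  sigma_hat <- sqrt(vc$vcov[vc$grp == "Residual"])
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0

  structure(
    list(
      effects = effects,
      intercept = unname(fe[["(Intercept)"]]),
      tau_hat = tau_hat,
      sigma_hat = sigma_hat,
      n_obs = nrow(dat),
      n_cells = length(cell_sizes),
      outcome = outcome,
      converged = conv,
      model = fit
    ),
    class = "list_order_fit"
  )
}

#' @export
print.list_order_fit <- function(x, ...) {
  cat(sprintf("Log-%s mixed model: %d observations, %d cells%s\n",
              if (x$outcome == "duration") "duration" else "length-of-stay",
              x$n_obs, x$n_cells,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  cell SD (tau) %.4f, residual SD (sigma) %.4f\n",
              x$tau_hat, x$sigma_hat))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    if (is.na(eff$beta[i])) {
      cat(sprintf("  %-15s undefined (no variation in covariate)\n",
                  eff$name[i]))
    } else {
      cat(sprintf("  %-15s %+.2f%% (95%% CI %+.2f to %+.2f), P %s\n",
                  eff$name[i], eff$pct[i], eff$pct_low[i], eff$pct_high[i],
                  format.pval(eff$p_value[i], digits = 3, eps = 1e-3)))
    }
  }
  invisible(x)
}

#' Per-procedure mixed-model fits
#'
#' Refits the model of [fit_lmm()] separately within each procedure code,
#' with random intercepts over (age group, ASA) cells, so each case is
#' compared only against cases of the same procedure. Codes with fewer than
#' `min_cases` records, or whose restricted design is degenerate, are skipped
#' and listed.
#'
#' @inheritParams fit_lmm
#' @param min_cases minimum records a code needs to be fitted (default 200).
#' @return list with `fits` (named list of `list_order_fit`) and `skipped`
#'   (tibble of `procedure_code`, `n_obs`, `reason`).
#' @export
per_procedure_fits <- function(coded, outcome = c("duration", "los"),
                               min_cases = 200) {
  outcome <- match.arg(outcome)
  fits <- list()
  skipped <- list()
  for (code in sort(unique(coded$procedure_code))) {
    sub <- coded[coded$procedure_code == code, , drop = FALSE]
    if (nrow(sub) < min_cases) {
      skipped[[code]] <- tibble(procedure_code = code, n_obs = nrow(sub),
                                reason = "below minimum case count")
      next
    }
    res <- tryCatch(
      fit_lmm(sub, outcome, cell_vars = c("age_group", "asa_grade")),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped[[code]] <- tibble(procedure_code = code, n_obs = nrow(sub),
                                reason = conditionMessage(res))
    } else {
      fits[[code]] <- res
    }
  }
  list(
    fits = fits,
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(procedure_code = character(), n_obs = integer(),
             reason = character())
  )
}

#' Collect fixed-effect rows from fits into one table
#'
#' @param fits a `list_order_fit`, or a named list of them (names become the
#'   `label` column).
#' @param effect optionally restrict to one of `"absolute_order"`,
#'   `"specific_order"`, `"switch"`.
#' @return tibble of effect rows with a `label` column and per-fit `n`.
#' @export
effects_table <- function(fits, effect = NULL) {
  if (inherits(fits, "list_order_fit")) fits <- list(Overall = fits)
  rows <- lapply(names(fits), function(lab) {
    eff <- fits[[lab]]$effects
    eff$label <- lab
    eff$n <- fits[[lab]]$n_obs
    eff
  })
  out <- bind_rows(rows)
  if (!is.null(effect)) out <- out[out$name %in% effect, , drop = FALSE]
  out[, c("label", setdiff(names(out), "label"))]
}
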