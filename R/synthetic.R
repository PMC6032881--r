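#' Default procedure catalogue
#'
#' A small catalogue of common elective procedures with plausible baseline
#' median operating times (minutes), baseline lengths of stay (minutes), and
#' method/complexity grades. Baselines are log-normal medians: at position 1,
#' non-switch, a cell with zero random intercept has median duration equal to
#' `baseline_min`.
#'
#' @return tibble with columns `procedure_code`, `baseline_min`,
#'   `baseline_los_min`, `method`, `complexity`.
#' @export
default_catalogue <- function() {
  tibble::tribble(
    ~procedure_code,        ~baseline_min, ~baseline_los_min, ~method,              ~complexity,
    "lap_cholecystectomy",   45,            1440,              "minimally_invasive", "3",
    "open_inguinal_hernia",  40,            720,               "open",               "2",
    "ogd_biopsy",            12,            300,               "minimally_invasive", "1",
    "colonoscopy",           25,            360,               "minimally_invasive", "1",
    "cataract_lens_implant", 20,            240,               "minimally_invasive", "1",
    "knee_arthroscopy",      30,            600,               "minimally_invasive", "2",
    "total_knee_replacement", 90,           4320,              "open",               "4",
    "total_hip_replacement",  95,           4320,              "open",               "4"
  )
}

#' Configuration for the synthetic theatre-record generator
#'
#' Parameterises a synthetic world of surgeons, hospitals and theatre lists
#' whose log-scale structure matches the model the analysis fits: for record
#' `i` with (recomputable) absolute position `A`, procedure-specific position
#' `S` and switch flag `W`,
#' \deqn{\log d_i = \log \mu_{c(i)} + b_{g(i)} + \beta_{abs}(A_i-1) +
#'   \beta_{spec}(S_i-1) + \beta_{sw} W_i + \varepsilon_i,}
#' with one random intercept `b_g ~ N(0, tau^2)` per (procedure, age group,
#' ASA) cell and `eps ~ N(0, sigma^2)`. Log length of stay follows the same
#' form with the `gamma_*` coefficients, its own per-code baseline, an
#' independent cell intercept of the same SD `tau`, and residual SD
#' `sigma_los`.
#'
#' Default effect sizes are the package's reference scenario: a 0.39% saving
#' per absolute position, a 0.98% saving per same-procedure repetition, a
#' 6.48% switching cost on duration; +0.55% and -0.72% per position on length
#' of stay with no switching effect. List composition is first-order Markov:
#' each case repeats the previous procedure with probability `p_same`,
#' otherwise a different catalogue code is drawn uniformly. With the default
#' length law (mean list length about 4.4) `p_same = 0.33` yields a switch
#' fraction close to 52%.
#'
#' @param n_surgeons,n_hospitals,n_lists world size. Each surgeon has a fixed
#'   home hospital; each list is a distinct (surgeon, date) pair within a
#'   26-month window.
#' @param list_length_law probability vector over list lengths `1..length()`.
#' @param p_same probability the next case repeats the previous procedure.
#' @param catalogue tibble as [default_catalogue()].
#' @param beta_abs,beta_spec,beta_switch log-scale fixed effects on duration.
#' @param tau SD of cell random intercepts (log scale).
#' @param sigma residual SD of log duration.
#' @param age_law,asa_law categorical laws over the 8 age bins / 5 ASA grades.
#' @param gamma_abs,gamma_spec,gamma_switch,sigma_los log length-of-stay model.
#' @param p_missing_surgeon,p_missing_start,p_duplicate noise-injection rates.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_surgeons = 200,
    n_hospitals = 10,
    n_lists = 9000,
    list_length_law = c(0.10, 0.15, 0.17, 0.16, 0.13, 0.10, 0.07, 0.05,
                        0.03, 0.02, 0.01, 0.01),
    p_same = 0.33,
    catalogue = default_catalogue(),
    beta_abs = from_percent(-0.39),
    beta_spec = from_percent(-0.98),
    beta_switch = from_percent(6.48),
    tau = 0.20,
    sigma = 0.35,
    age_law = c(0.02, 0.04, 0.10, 0.14, 0.20, 0.22, 0.18, 0.10),
    asa_law = c(0.35, 0.45, 0.17, 0.028, 0.002),
    gamma_abs = from_percent(0.55),
    gamma_spec = from_percent(-0.72),
    gamma_switch = 0,
    sigma_los = 0.50,
    p_missing_surgeon = 8807 / 478519,
    p_missing_start = 1422 / 478519,
    p_duplicate = 32 / 478519,
    seed = 20130401) {
  cfg <- structure(
    list(
      n_surgeons = as.integer(n_surgeons),
      n_hospitals = as.integer(n_hospitals),
      n_lists = as.integer(n_lists),
      list_length_law = as.numeric(list_length_law),
      p_same = p_same,
      catalogue = tibble::as_tibble(catalogue),
      beta_abs = beta_abs, beta_spec = beta_spec, beta_switch = beta_switch,
      tau = tau, sigma = sigma,
      age_law = as.numeric(age_law), asa_law = as.numeric(asa_law),
      gamma_abs = gamma_abs, gamma_spec = gamma_spec,
      gamma_switch = gamma_switch, sigma_los = sigma_los,
      p_missing_surgeon = p_missing_surgeon,
      p_missing_start = p_missing_start,
      p_duplicate = p_duplicate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  check_law <- function(p, what, len = NULL) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
    if (!is.null(len) && length(p) != len) {
      stop(what, " must have length ", len, call. = FALSE)
    }
  }
  check_law(cfg$list_length_law, "list_length_law")
  check_law(cfg$age_law, "age_law", length(AGE_GROUPS))
  check_law(cfg$asa_law, "asa_law", length(ASA_GRADES))
  if (cfg$p_same < 0 || cfg$p_same > 1) {
    stop("p_same must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$tau < 0 || cfg$sigma < 0 || cfg$sigma_los < 0) {
    stop("tau, sigma and sigma_los must be non-negative", call. = FALSE)
  }
  if (any(cfg$catalogue$baseline_min <= 0) ||
      any(cfg$catalogue$baseline_los_min <= 0)) {
    stop("catalogue baselines must be positive", call. = FALSE)
  }
  rates <- c(cfg$p_missing_surgeon, cfg$p_missing_start, cfg$p_duplicate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_surgeons < 1 || cfg$n_hospitals < 1 || cfg$n_lists < 1) {
    stop("world sizes must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# Markov procedure sequence for one list: repeat with prob p_same, otherwise
# uniform over the other codes.
markov_codes <- function(len, codes, p_same) {
  K <- length(codes)
  if (K == 1L) return(rep(codes, len))
  s <- integer(len)
  s[1] <- sample.int(K, 1L)
  if (len > 1L) {
    rep_flag <- runif(len - 1L) < p_same
    jump <- sample.int(K - 1L, len - 1L, replace = TRUE)
    for (i in 2:len) {
      if (rep_flag[i - 1L]) {
        s[i] <- s[i - 1L]
      } else {
        j <- jump[i - 1L]
        s[i] <- if (j >= s[i - 1L]) j + 1L else j
      }
    }
  }
  codes[s]
}

#' Generate a raw synthetic procedure-record dataset
#'
#' Simulates theatre lists under the configured generative model and returns
#' raw, pre-cleaning rows in the schema of [read_procedure_records()]. True
#' list-order covariates are used internally to generate durations but are
#' deliberately not emitted: the downstream coding stage must recompute them.
#' Noise is injected last: surgeon ids and start times are blanked at the
#' configured rates and duplicate rows (byte-identical copies of uniformly
#' chosen rows) are appended.
#'
#' @param cfg a [generator_config()].
#' @return tibble of raw records.
#' @export
generate_dataset <- function(cfg) {
  validate_generator_config(cfg)
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  dates <- seq(as.Date("2013-04-01"), as.Date("2015-05-31"), by = "day")
  nd <- length(dates)
  if (cfg$n_lists > cfg$n_surgeons * nd) {
    stop("n_lists exceeds the number of distinct (surgeon, date) slots",
         call. = FALSE)
  }
  # distinct (surgeon, date) slots so generated lists never merge downstream
  slot <- sample.int(cfg$n_surgeons * nd, cfg$n_lists)
  surgeon <- (slot - 1L) %% cfg$n_surgeons + 1L
  date <- dates[(slot - 1L) %/% cfg$n_surgeons + 1L]
  hospital <- (surgeon - 1L) %% cfg$n_hospitals + 1L

  len <- sample.int(length(cfg$list_length_law), cfg$n_lists, replace = TRUE,
                    prob = cfg$list_length_law)
  N <- sum(len)
  list_id <- rep.int(seq_len(cfg$n_lists), len)

  codes <- cfg$catalogue$procedure_code
  code <- unlist(lapply(len, markov_codes, codes = codes,
                        p_same = cfg$p_same), use.names = FALSE)

  age <- sample(AGE_GROUPS, N, replace = TRUE, prob = cfg$age_law)
  asa <- sample(ASA_GRADES, N, replace = TRUE, prob = cfg$asa_law)

  # true list-order covariates (recomputed downstream from start times)
  absolute <- sequence(len)
  prev_code <- c(NA_character_, code[-N])
  sw <- absolute > 1L & code != prev_code
  specific <- dplyr::tibble(list_id = list_id, code = code) |>
    group_by(.data$list_id, .data$code) |>
    mutate(s = row_number()) |>
    dplyr::pull(.data$s)

  # one random intercept per (procedure, age, ASA) cell, for each outcome
  grid <- expand.grid(code = codes, age = AGE_GROUPS, asa = ASA_GRADES,
                      stringsAsFactors = FALSE)
  cell_key <- paste(grid$code, grid$age, grid$asa, sep = "|")
  b_dur <- setNames(rnorm(nrow(grid), 0, cfg$tau), cell_key)
  b_los <- setNames(rnorm(nrow(grid), 0, cfg$tau), cell_key)
  key <- paste(code, age, asa, sep = "|")

  base_dur <- setNames(cfg$catalogue$baseline_min, codes)
  base_los <- setNames(cfg$catalogue$baseline_los_min, codes)

  log_dur <- log(base_dur[code]) + b_dur[key] +
    cfg$beta_abs * (absolute - 1L) + cfg$beta_spec * (specific - 1L) +
    cfg$beta_switch * sw + rnorm(N, 0, cfg$sigma)
  log_los <- log(base_los[code]) + b_los[key] +
    cfg$gamma_abs * (absolute - 1L) + cfg$gamma_spec * (specific - 1L) +
    cfg$gamma_switch * sw + rnorm(N, 0, cfg$sigma_los)
  duration <- unname(exp(log_dur))
  los <- unname(exp(log_los))

  # start times: 08:30 start, cases back to back with a 15-minute turnover
  start_min <- dplyr::tibble(list_id = list_id, duration = duration) |>
    group_by(.data$list_id) |>
    mutate(t = 510 + cumsum(dplyr::lag(.data$duration + 15, default = 0))) |>
    dplyr::pull(.data$t)
  start_min <- pmin(as.integer(floor(start_min)), 1439L)

  out <- tibble(
    record_id = sprintf("R%07d", seq_len(N)),
    surgeon_id = sprintf("S%04d", surgeon[list_id]),
    hospital_id = sprintf("H%02d", hospital[list_id]),
    list_date = date[list_id],
    start_time = sprintf("%02d:%02d", start_min %/% 60L, start_min %% 60L),
    procedure_code = code,
    age_group = age,
    asa_grade = asa,
    duration_min = duration,
    los_min = los
  )

  # noise injection, mirroring the exclusion-flow categories
  out$surgeon_id[runif(N) < cfg$p_missing_surgeon] <- NA_character_
  out$start_time[runif(N) < cfg$p_missing_start] <- NA_character_
  n_dup <- stats::rbinom(1L, N, cfg$p_duplicate)
  if (n_dup > 0) {
    out <- bind_rows(out, out[sample.int(N, n_dup, replace = TRUE), ])
  }
  out
}

#' Generating parameters of a configuration, as a recovery oracle
#'
#' Machine-readable dump of the fixed effects (log scale and percent), the
#' variance components, the length-of-stay coefficients and the seed — the
#' ground truth a recovery analysis should reproduce.
#'
#' @param cfg a [generator_config()].
#' @return a named list of class `truth_table`.
#' @export
truth_table <- function(cfg) {
  validate_generator_config(cfg)
  structure(
    list(
      beta = c(absolute_order = cfg$beta_abs,
               specific_order = cfg$beta_spec,
               switch = cfg$beta_switch),
      pct = c(absolute_order = to_percent(cfg$beta_abs),
              specific_order = to_percent(cfg$beta_spec),
              switch = to_percent(cfg$beta_switch)),
      tau = cfg$tau,
      sigma = cfg$sigma,
      los = list(
        gamma = c(absolute_order = cfg$gamma_abs,
                  specific_order = cfg$gamma_spec,
                  switch = cfg$gamma_switch),
        pct = c(absolute_order = to_percent(cfg$gamma_abs),
                specific_order = to_percent(cfg$gamma_spec),
                switch = to_percent(cfg$gamma_switch)),
        sigma_los = cfg$sigma_los
      ),
      seed = cfg$seed
    ),
    class = "truth_table"
  )
}

#' Serialize / parse a generator configuration
#'
#' @param cfg a [generator_config()].
#' @param path YAML file path.
#' @export
write_generator_config <- function(cfg, path) {
  validate_generator_config(cfg)
  x <- unclass(cfg)
  x$catalogue <- lapply(seq_len(nrow(cfg$catalogue)), function(i) {
    as.list(cfg$catalogue[i, ])
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$catalogue <- bind_rows(lapply(x$catalogue, tibble::as_tibble))
  do.call(generator_config, x)
}
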