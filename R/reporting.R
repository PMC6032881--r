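#' Mean duration by procedure-specific position
#'
#' Arithmetic mean operating time per procedure-specific list position for
#' one procedure, with normal-approximation 95% confidence intervals.
#' Positions with fewer than `min_n` cases are suppressed.
#'
#' @param coded coded tibble from [code_records()].
#' @param code a procedure code present in the data (an absent code yields an
#'   empty table).
#' @param max_position highest position to report (default 12).
#' @param min_n minimum cases a position needs to be shown (default 5).
#' @return tibble with columns `position`, `n`, `mean_duration`, `ci_low`,
#'   `ci_high`.
#' @export
position_profile <- function(coded, code, max_position = 12, min_n = 5) {
  sub <- coded[coded$procedure_code == code &
                 coded$procedure_specific_list_no <= max_position, ,
               drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble(position = integer(), n = integer(),
                  mean_duration = numeric(), ci_low = numeric(),
                  ci_high = numeric()))
  }
  out <- sub |>
    group_by(position = .data$procedure_specific_list_no) |>
    summarise(
      n = dplyr::n(),
      mean_duration = mean(.data$duration_min),
      se = stats::sd(.data$duration_min) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    mutate(
      ci_low = .data$mean_duration - qnorm(0.975) * .data$se,
      ci_high = .data$mean_duration + qnorm(0.975) * .data$se
    ) |>
    filter(.data$n >= min_n) |>
    select("position", "n", "mean_duration", "ci_low", "ci_high")
  out
}

#' Forest-style table of percent effects
#'
#' Arranges effect estimates as a forest-plot table: one `Overall` row first,
#' then one row per label (procedure code or stratum) in label order.
#' Negative percentages are reductions in duration, positive ones increases.
#'
#' @param overall one-row tibble with columns `pct`, `pct_low`, `pct_high`,
#'   `n` (e.g. from [paired_effect()] or a row of a fit's `effects` table
#'   joined with its `n_obs`).
#' @param per_label tibble of the same columns plus a `label` column, one row
#'   per procedure or stratum; may be empty or `NULL`.
#' @return tibble with columns `label`, `pct`, `pct_low`, `pct_high`, `n`.
#' @export
forest_table <- function(overall, per_label = NULL) {
  cols <- c("pct", "pct_low", "pct_high", "n")
  stopifnot(nrow(overall) == 1, all(cols %in% names(overall)))
  top <- tibble(label = "Overall")
  top[cols] <- overall[cols]
  rows <- top
  if (!is.null(per_label) && nrow(per_label) > 0) {
    stopifnot(all(c("label", cols) %in% names(per_label)))
    rest <- per_label[order(per_label$label), c("label", cols), drop = FALSE]
    rows <- bind_rows(rows, rest)
  }
  bad <- with(rows, pct_low > pct | pct > pct_high)
  if (any(bad, na.rm = TRUE)) {
    stop("forest rows must satisfy pct_low <= pct <= pct_high",
         call. = FALSE)
  }
  rows
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Cleans (or simulates) raw records, reconstructs and codes theatre lists,
#' classifies procedures, fits the pooled duration and length-of-stay mixed
#' models, runs the matched analysis (pooled, per procedure, and stratified
#' by method and complexity when a mapping is available), and writes all
#' tables plus a run manifest to `out_dir`.
#'
#' @param config a list with elements:
#'   * `input`: path to a raw-records CSV, or `generator`: a
#'     [generator_config()] (or path to one in YAML) to simulate instead;
#'   * `mapping`: method/complexity mapping tibble or YAML path (optional;
#'     defaults to the generator catalogue when simulating);
#'   * `seed`: integer seed for the matched analysis (default 1);
#'   * `k`: matched position (default 1);
#'   * `min_cases`: per-procedure fit threshold (default 200);
#'   * `fit_los`, `match`, `per_procedure`: logical stage switches
#'     (default `TRUE`).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the run `manifest`, the file `artifacts`,
#'   and in-memory `results` (coded data, fits, matched results).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$seed <- cfg$seed %||% 1L
  cfg$k <- cfg$k %||% 1L
  cfg$min_cases <- cfg$min_cases %||% 200
  cfg$fit_los <- cfg$fit_los %||% TRUE
  cfg$match <- cfg$match %||% TRUE
  cfg$per_procedure <- cfg$per_procedure %||% TRUE
  skipped_stages <- character()

  raw <- stage("input", {
    if (!is.null(cfg$generator)) {
      gen <- cfg$generator
      if (is.character(gen)) gen <- read_generator_config(gen)
      generate_dataset(gen)
    } else if (!is.null(cfg$input)) {
      read_procedure_records(cfg$input)
    } else {
      stop("config needs either 'input' or 'generator'")
    }
  })

  cleaned <- stage("clean", clean_records(raw))
  coded <- stage("code", code_records(cleaned$records))

  mapping <- cfg$mapping
  if (is.null(mapping) && !is.null(cfg$generator)) {
    gen <- cfg$generator
    if (is.character(gen)) gen <- read_generator_config(gen)
    mapping <- gen$catalogue[, c("procedure_code", "method", "complexity")]
  }
  if (!is.null(mapping)) {
    coded <- stage("classify", classify_records(coded, mapping))
  }

  artifacts <- list()
  write_artifact <- function(obj, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(obj)) {
      readr::write_csv(obj, path)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    artifacts[[file]] <<- path
    path
  }
  write_artifact(coded, "coded_records.csv")
  write_artifact(unclass(cleaned$summary), "exclusion_summary.json")

  results <- list(coded = coded, exclusions = cleaned$summary)

  fit_dur <- stage("fit_duration", fit_lmm(coded, "duration"))
  results$fit_duration <- fit_dur
  tabs <- list(effects_table(fit_dur))
  if (cfg$per_procedure) {
    pp <- stage("fit_per_procedure",
                per_procedure_fits(coded, "duration", cfg$min_cases))
    results$fits_per_procedure <- pp
    if (length(pp$fits)) tabs <- c(tabs, list(effects_table(pp$fits)))
    write_artifact(pp$skipped, "fits_skipped.csv")
  } else {
    skipped_stages <- c(skipped_stages, "fit_per_procedure")
  }
  write_artifact(bind_rows(tabs), "effects_duration.csv")

  if (cfg$fit_los) {
    fit_los <- stage("fit_los", fit_lmm(coded, "los"))
    results$fit_los <- fit_los
    write_artifact(effects_table(fit_los), "effects_los.csv")
  } else {
    skipped_stages <- c(skipped_stages, "fit_los")
  }

  if (cfg$match) {
    mres <- stage("match", match_pairs(coded, k = cfg$k, seed = cfg$seed))
    results$matched <- mres
    pooled <- paired_effect(mres)
    per_code <- per_procedure_matched(coded, k = cfg$k, seed = cfg$seed)
    results$matched_per_procedure <- per_code
    write_artifact(mres$pairs, "matched_pairs.csv")
    write_artifact(pooled, "matched_effect_overall.csv")
    if (nrow(per_code$effects)) {
      write_artifact(per_code$effects, "matched_effects_per_procedure.csv")
      fl <- per_code$effects
      fl$label <- fl$procedure_code
      write_artifact(forest_table(pooled, fl), "forest_matched.csv")
    } else {
      write_artifact(forest_table(pooled), "forest_matched.csv")
    }
    if (!is.null(mapping)) {
      for (strat in c("method", "complexity")) {
        sm <- stage(paste0("match_", strat),
                    stratified_matched(coded, strat, k = cfg$k,
                                       seed = cfg$seed))
        results[[paste0("matched_", strat)]] <- sm
        write_artifact(sm$effects, paste0("matched_by_", strat, ".csv"))
      }
    }
  } else {
    skipped_stages <- c(skipped_stages, "match")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("theatreflow")),
    config_hash = rlang::hash(config),
    seed = cfg$seed,
    k = cfg$k,
    input = if (!is.null(cfg$input)) cfg$input else "simulated",
    exclusion_summary = unclass(cleaned$summary),
    n_coded = nrow(coded),
    n_matched = if (cfg$match) results$matched$n_matched else NA,
    skipped_stages = skipped_stages
  )
  write_artifact(manifest, "manifest.json")

  invisible(list(manifest = manifest, artifacts = artifacts,
                 results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
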