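#' Randomized exact matching of adjacent procedure-specific positions
#'
#' Within each procedure code, cases at procedure-specific position `k` are
#' paired with cases at position `k + 1` that have the same age group and ASA
#' grade. Position-`k` cases are scanned in a randomly determined order; for
#' each, one compatible position-`k+1` candidate is selected uniformly at
#' random and both leave the pool (non-selected candidates return to the pool
#' for later cases). Each record joins at most one pair; matching stops when
#' no further pair can be formed. Because compatibility is exact on the
#' (procedure, age, ASA) cell, this greedy procedure is maximal: every cell
#' yields `min(n_k, n_k+1)` pairs whatever the seed — only the identity of
#' the pairings is random.
#'
#' @param coded coded tibble from [code_records()].
#' @param k procedure-specific position matched against `k + 1` (default 1,
#'   i.e. first vs second same-procedure case).
#' @param seed integer seed governing both the scan order and candidate
#'   selection; recorded in the result for replay.
#' @return an object of class `match_result`: list with `pairs` (tibble:
#'   `pair_id`, `first_record_id`, `second_record_id`, `procedure_code`,
#'   `age_group`, `asa_grade`, `duration_first`, `duration_second`,
#'   `los_first`, `los_second`), `n_candidates_first`, `n_candidates_second`,
#'   `n_matched`, `cell_counts` (per-cell candidate and pair counts), `k` and
#'   `seed`.
#' @export
match_pairs <- function(coded, k = 1, seed = 1L) {
  stopifnot(k >= 1)
  p1 <- coded[coded$procedure_specific_list_no == k, , drop = FALSE]
  p2 <- coded[coded$procedure_specific_list_no == k + 1, , drop = FALSE]
  cell_of <- function(d) paste(d$procedure_code, d$age_group, d$asa_grade,
                               sep = "|")
  cell1 <- cell_of(p1)
  cell2 <- cell_of(p2)

  pick <- rep(NA_integer_, nrow(p1))
  if (nrow(p1) > 0 && nrow(p2) > 0) {
    withr::with_seed(as.integer(seed), {
      scan <- sample.int(nrow(p1))
      pools <- list2env(split(seq_len(nrow(p2)), cell2), hash = TRUE)
      for (i in scan) {
        pool <- get0(cell1[i], envir = pools, inherits = FALSE)
        m <- length(pool)
        if (m == 0L) next
        j <- if (m == 1L) 1L else sample.int(m, 1L)
        pick[i] <- pool[j]
        pools[[cell1[i]]] <- pool[-j]
      }
    })
  }

  matched <- which(!is.na(pick))
  # pairs reported in scan-independent (first-record) order for determinism
  matched <- matched[order(p1$record_id[matched])]
  first <- p1[matched, , drop = FALSE]
  second <- p2[pick[matched], , drop = FALSE]
  pairs <- tibble(
    pair_id = seq_along(matched),
    first_record_id = first$record_id,
    second_record_id = second$record_id,
    procedure_code = first$procedure_code,
    age_group = first$age_group,
    asa_grade = first$asa_grade,
    duration_first = first$duration_min,
    duration_second = second$duration_min,
    los_first = if ("los_min" %in% names(first)) first$los_min else NA_real_,
    los_second = if ("los_min" %in% names(second)) second$los_min else NA_real_
  )

  all_cells <- sort(unique(c(cell1, cell2)))
  cc <- tibble(cell = all_cells)
  cc$n_first <- as.integer(table(factor(cell1, levels = all_cells)))
  cc$n_second <- as.integer(table(factor(cell2, levels = all_cells)))
  pc <- cell_of(pairs[, c("procedure_code", "age_group", "asa_grade")])
  cc$n_matched <- as.integer(table(factor(pc, levels = all_cells)))
  parts <- strsplit(cc$cell, "|", fixed = TRUE)
  cc$procedure_code <- vapply(parts, `[`, character(1), 1)
  cc$age_group <- vapply(parts, `[`, character(1), 2)
  cc$asa_grade <- vapply(parts, `[`, character(1), 3)
  cc <- cc[, c("procedure_code", "age_group", "asa_grade",
               "n_first", "n_second", "n_matched")]

  structure(
    list(
      pairs = pairs,
      n_candidates_first = nrow(p1),
      n_candidates_second = nrow(p2),
      n_matched = nrow(pairs),
      cell_counts = cc,
      k = k,
      seed = as.integer(seed)
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "Matched %d pairs (positions %d vs %d) from %d and %d candidates (seed %d)\n",
    x$n_matched, x$k, x$k + 1, x$n_candidates_first, x$n_candidates_second,
    x$seed))
  invisible(x)
}

# paired effect from a vector of within-pair log differences
paired_log_effect <- function(d, name, n_label = length(d)) {
  n <- length(d)
  if (n < 2) {
    stop("paired effect is undefined with fewer than two pairs",
         call. = FALSE)
  }
  beta <- mean(d)
  se <- sd(d) / sqrt(n)
  tq <- qt(0.975, n - 1)
  ci_low <- beta - tq * se
  ci_high <- beta + tq * se
  p <- if (se > 0) {
    2 * pt(-abs(beta / se), n - 1)
  } else if (beta != 0) 0 else NA_real_
  tibble(
    name = name,
    beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
    pct = to_percent(beta),
    pct_low = to_percent(ci_low), pct_high = to_percent(ci_high),
    p_value = p, n = n_label
  )
}

#' Paired log-duration effect of repeating a procedure
#'
#' The effect estimate is the mean over pairs of
#' `log(duration_second) - log(duration_first)`, with a paired two-sided
#' t-based standard error, 95% CI and p-value on the log differences, and a
#' percent rendering via [to_percent()]. Because members of a pair share
#' their (procedure, age, ASA) cell exactly, any shared cell baseline cancels
#' within each pair.
#'
#' @param result a `match_result` from [match_pairs()].
#' @param outcome `"duration"` or `"los"`.
#' @return a one-row tibble (`name`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pct`, `pct_low`, `pct_high`, `p_value`, `n`).
#' @export
paired_effect <- function(result, outcome = c("duration", "los")) {
  outcome <- match.arg(outcome)
  pr <- result$pairs
  a <- if (outcome == "duration") pr$duration_first else pr$los_first
  b <- if (outcome == "duration") pr$duration_second else pr$los_second
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  paired_log_effect(
    log(b[ok]) - log(a[ok]),
    name = sprintf("position_%d_vs_%d", result$k + 1, result$k)
  )
}

#' Per-procedure matched effects
#'
#' Runs the matched analysis within each procedure code. Matching is
#' independent across codes (candidates never cross a code boundary), so one
#' [match_pairs()] run is partitioned by code. Codes with fewer than two
#' pairs are skipped and listed.
#'
#' @inheritParams match_pairs
#' @return list with `effects` (tibble, one row per code with a
#'   `procedure_code` column) and `skipped` (tibble of `procedure_code`,
#'   `n_pairs`).
#' @export
per_procedure_matched <- function(coded, k = 1, seed = 1L) {
  res <- match_pairs(coded, k = k, seed = seed)
  effects <- list()
  skipped <- list()
  for (code in sort(unique(res$pairs$procedure_code))) {
    pr <- res$pairs[res$pairs$procedure_code == code, , drop = FALSE]
    if (nrow(pr) < 2) {
      skipped[[code]] <- tibble(procedure_code = code, n_pairs = nrow(pr))
      next
    }
    sub <- res
    sub$pairs <- pr
    eff <- paired_effect(sub)
    eff$procedure_code <- code
    effects[[code]] <- eff
  }
  list(
    effects = if (length(effects)) bind_rows(effects) else tibble(),
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(procedure_code = character(), n_pairs = integer())
  )
}

#' Matched analysis stratified by method or complexity
#'
#' Repeats the full matching and paired-effect chain independently within
#' each method or complexity stratum (records must first be classified via
#' [classify_records()]). Unclassified records are excluded from the
#' stratified run and counted; strata yielding fewer than two pairs are
#' skipped and listed.
#'
#' @inheritParams match_pairs
#' @param stratifier `"method"` or `"complexity"`.
#' @return list with `effects` (tibble with a `stratum` column and pair
#'   counts), `skipped` (tibble of `stratum`, `n_pairs`) and
#'   `n_unclassified` (records dropped for lacking a classification).
#' @export
stratified_matched <- function(coded, stratifier = c("method", "complexity"),
                               k = 1, seed = 1L) {
  stratifier <- match.arg(stratifier)
  if (!stratifier %in% names(coded)) {
    stop("records are not classified; run classify_records() first",
         call. = FALSE)
  }
  strat <- coded[[stratifier]]
  n_unclassified <- sum(strat == "unclassified" | is.na(strat))
  keep <- coded[!is.na(strat) & strat != "unclassified", , drop = FALSE]

  effects <- list()
  skipped <- list()
  for (s in sort(unique(keep[[stratifier]]))) {
    sub <- keep[keep[[stratifier]] == s, , drop = FALSE]
    # strata are disjoint datasets, so reusing the seed is harmless and keeps
    # a single-stratum run identical to the pooled one
    res <- match_pairs(sub, k = k, seed = seed)
    if (res$n_matched < 2) {
      skipped[[s]] <- tibble(stratum = s, n_pairs = res$n_matched)
      next
    }
    eff <- paired_effect(res)
    eff$stratum <- s
    effects[[s]] <- eff
  }
  list(
    effects = if (length(effects)) bind_rows(effects) else tibble(),
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(stratum = character(), n_pairs = integer()),
    n_unclassified = n_unclassified
  )
}
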