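#' Read raw procedure records from CSV
#'
#' Expects a header with columns `record_id, surgeon_id, hospital_id,
#' list_date, start_time, procedure_code, age_group, asa_grade, duration_min,
#' los_min`. Dates are ISO 8601 (`YYYY-MM-DD`); start times are 24-h `HH:MM`
#' strings (kept as character; lexicographic order equals temporal order
#' within a day). Method and complexity are not part of the raw schema; they
#' are attached later from a code mapping via [classify_records()].
#'
#' @param path path to a CSV file.
#' @return a tibble of raw records (uncleaned).
#' @export
read_procedure_records <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      record_id = readr::col_character(),
      surgeon_id = readr::col_character(),
      hospital_id = readr::col_character(),
      list_date = readr::col_date(format = "%Y-%m-%d"),
      start_time = readr::col_character(),
      procedure_code = readr::col_character(),
      age_group = readr::col_character(),
      asa_grade = readr::col_character(),
      duration_min = readr::col_double(),
      los_min = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("unparseable input at line ", probs$row[1] + 1L, " of ", path,
         ": ", probs$expected[1], call. = FALSE)
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw
}

#' Clean raw records and summarise exclusions
#'
#' Applies the exclusion flow in a fixed order, counting each record under the
#' first rule that removes it:
#' 1. no surgeon identifier;
#' 2. no start time;
#' 3. duplicate (a row identical on all fields to an earlier surviving row;
#'    the earlier row is kept);
#' 4. missing or non-positive duration;
#' 5. age group or ASA grade outside the recognised categories.
#'
#' The counts partition the input: `n_retained` plus all exclusion tallies
#' equals `n_input`.
#'
#' @param raw tibble of raw records as returned by [read_procedure_records()]
#'   or [generate_dataset()].
#' @return a list with elements `records` (the retained tibble) and `summary`
#'   (an `exclusion_summary` with the tallies above).
#' @export
clean_records <- function(raw) {
  n_input <- nrow(raw)
  reason <- rep(NA_character_, n_input)

  blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

  reason[blank(raw$surgeon_id)] <- "missing_surgeon"
  reason[is.na(reason) & blank(raw$start_time)] <- "missing_start"

  alive <- is.na(reason)
  dup <- rep(FALSE, n_input)
  dup[alive] <- duplicated(as.data.frame(raw)[alive, , drop = FALSE])
  reason[is.na(reason) & dup] <- "duplicate"

  bad_dur <- is.na(raw$duration_min) | raw$duration_min <= 0
  reason[is.na(reason) & bad_dur] <- "nonpositive_duration"

  bad_cat <- !(raw$age_group %in% AGE_GROUPS) | !(raw$asa_grade %in% ASA_GRADES)
  reason[is.na(reason) & bad_cat] <- "invalid_category"

  records <- raw[is.na(reason), , drop = FALSE]
  if (anyDuplicated(records$record_id) > 0) {
    warning("record_id not unique after cleaning; downstream tie-breaks ",
            "may be unstable", call. = FALSE)
  }

  tally <- function(lab) sum(reason == lab, na.rm = TRUE)
  summary <- structure(
    list(
      n_input = n_input,
      n_missing_surgeon = tally("missing_surgeon"),
      n_missing_start = tally("missing_start"),
      n_duplicates = tally("duplicate"),
      n_nonpositive_duration = tally("nonpositive_duration"),
      n_invalid_category = tally("invalid_category"),
      n_retained = nrow(records)
    ),
    class = "exclusion_summary"
  )
  list(records = records, summary = summary)
}

#' @export
print.exclusion_summary <- function(x, ...) {
  cat("Exclusion summary\n")
  cat(sprintf("  input records        %d\n", x$n_input))
  cat(sprintf("  no surgeon id        %d\n", x$n_missing_surgeon))
  cat(sprintf("  no start time        %d\n", x$n_missing_start))
  cat(sprintf("  duplicates           %d\n", x$n_duplicates))
  cat(sprintf("  non-positive duration %d\n", x$n_nonpositive_duration))
  cat(sprintf("  invalid category     %d\n", x$n_invalid_category))
  cat(sprintf("  retained             %d\n", x$n_retained))
  invisible(x)
}

list_key_vars <- function(include_hospital = TRUE) {
  c("surgeon_id", if (include_hospital) "hospital_id", "list_date")
}

#' Group cleaned records into theatre lists
#'
#' A theatre list is the ordered set of procedures one surgeon performs on one
#' date (at one hospital, unless `include_hospital = FALSE`). Records within a
#' list are ordered by start time, with ties broken deterministically by
#' `record_id`.
#'
#' @param records tibble of cleaned records.
#' @param include_hospital logical; include `hospital_id` in the grouping key
#'   (default `TRUE`).
#' @return a named list of tibbles, one per theatre list, in key order; each
#'   element carries its key as the name `surgeon|hospital|date` (or
#'   `surgeon|date`).
#' @export
build_lists <- function(records, include_hospital = TRUE) {
  kv <- list_key_vars(include_hospital)
  ord <- dplyr::arrange(records, across(all_of(kv)), .data$start_time,
                        .data$record_id)
  key <- do.call(paste, c(lapply(kv, function(v) ord[[v]]), sep = "|"))
  out <- split(ord, factor(key, levels = unique(key)))
  lapply(out, tibble::as_tibble)
}

#' Assign list-order codes to one theatre list
#'
#' Adds, in list order: `absolute_list_no` (position among all procedures on
#' the list, 1-based), `procedure_specific_list_no` (how many times this
#' procedure has occurred on the list up to and including this case), and
#' `switch` (`TRUE` when the immediately preceding case is a different
#' procedure). The first case on a list is coded `switch = FALSE`: there is no
#' preceding case, so no switch cost applies.
#'
#' @param lst a tibble of one theatre list in order (an element of
#'   [build_lists()] output).
#' @return the tibble with the three coding columns appended.
#' @export
assign_list_numbers <- function(lst) {
  n <- nrow(lst)
  if (n == 0) {
    lst$absolute_list_no <- integer(0)
    lst$procedure_specific_list_no <- integer(0)
    lst$switch <- logical(0)
    return(lst)
  }
  code <- lst$procedure_code
  lst$absolute_list_no <- seq_len(n)
  lst$procedure_specific_list_no <-
    stats::ave(rep(1L, n), code, FUN = cumsum)
  lst$switch <- c(FALSE, code[-1] != code[-n])
  lst
}

#' Code a whole dataset of cleaned records
#'
#' Vectorised equivalent of [build_lists()] followed by
#' [assign_list_numbers()] on every list, returned as one tibble. The result
#' is canonical: permuting the input rows does not change it.
#'
#' @inheritParams build_lists
#' @return a coded tibble (input columns plus `absolute_list_no`,
#'   `procedure_specific_list_no`, `switch`), ordered by list key and position.
#' @export
code_records <- function(records, include_hospital = TRUE) {
  kv <- list_key_vars(include_hospital)
  records |>
    arrange(across(all_of(kv)), .data$start_time, .data$record_id) |>
    group_by(across(all_of(kv))) |>
    mutate(
      absolute_list_no = row_number(),
      switch = .data$absolute_list_no > 1L &
        .data$procedure_code != lag(.data$procedure_code)
    ) |>
    group_by(across(all_of(kv)), .data$procedure_code) |>
    mutate(procedure_specific_list_no = row_number()) |>
    ungroup() |>
    select(all_of(names(records)),
           "absolute_list_no", "procedure_specific_list_no", "switch")
}

#' Attach method and complexity strata from a code mapping
#'
#' Procedure codes are graded for surgical method (open vs minimally invasive)
#' and complexity by an externally supplied mapping (the AXA-style grading is
#' site-specific configuration, not shipped here). Codes absent from the
#' mapping are labelled `"unclassified"`; such records stay in the pooled
#' analyses and are only dropped from method/complexity-stratified ones.
#'
#' @param records tibble of records (raw, cleaned or coded).
#' @param mapping tibble with columns `procedure_code`, `method`,
#'   `complexity`, or a path readable by [read_procedure_mapping()].
#' @return `records` with `method` and `complexity` character columns.
#' @export
classify_records <- function(records, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- read_procedure_mapping(mapping)
  }
  mapping <- tibble::as_tibble(mapping)[, c("procedure_code", "method",
                                            "complexity")]
  mapping$complexity <- as.character(mapping$complexity)
  if (anyDuplicated(mapping$procedure_code) > 0) {
    stop("mapping has duplicated procedure codes", call. = FALSE)
  }
  out <- records
  out$method <- NULL
  out$complexity <- NULL
  out <- left_join(out, mapping, by = "procedure_code")
  out$method[is.na(out$method)] <- "unclassified"
  out$complexity[is.na(out$complexity)] <- "unclassified"
  out
}

#' Read / write a procedure-code mapping file
#'
#' The mapping is a YAML file keyed by procedure code, each entry holding
#' `method` and `complexity`.
#'
#' @param path file path.
#' @return `read_procedure_mapping()` returns a tibble with columns
#'   `procedure_code`, `method`, `complexity`.
#' @export
read_procedure_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  tibble(
    procedure_code = names(m),
    method = unname(vapply(m, function(e) as.character(e$method),
                           character(1))),
    complexity = unname(vapply(m, function(e) as.character(e$complexity),
                               character(1)))
  )
}

#' @rdname read_procedure_mapping
#' @param mapping tibble with columns `procedure_code`, `method`, `complexity`.
#' @export
write_procedure_mapping <- function(mapping, path) {
  entries <- lapply(seq_len(nrow(mapping)), function(i) {
    list(method = mapping$method[i],
         complexity = as.character(mapping$complexity[i]))
  })
  names(entries) <- mapping$procedure_code
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Fraction of coded records that are switches
#'
#' @param coded coded tibble from [code_records()].
#' @return proportion in `[0, 1]`.
#' @export
switch_fraction <- function(coded) {
  if (nrow(coded) == 0) {
    stop("switch_fraction is undefined for an empty dataset", call. = FALSE)
  }
  mean(coded$switch)
}
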