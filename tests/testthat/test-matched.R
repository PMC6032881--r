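# minimal coded frame for matching tests: one row per record with the fields
# matching reads
mk_coded <- function(code, age, asa, S, dur, A = S, sw = FALSE) {
  tibble::tibble(
    record_id = sprintf("M%03d", seq_along(code)),
    procedure_code = code, age_group = age, asa_grade = asa,
    absolute_list_no = A, procedure_specific_list_no = S,
    switch = sw, duration_min = dur, los_min = dur * 20
  )
}

test_that("uniquely compatible candidates are always matched; disjoint cells never", {
  d <- mk_coded(
    code = rep("P1", 6),
    age = rep(c("25-34", "35-44", "45-54"), 2),
    asa = "II",
    S = rep(c(1L, 2L), each = 3),
    dur = c(40, 42, 44, 38, 40, 41)
  )
  for (s in c(1, 2, 99)) {
    res <- match_pairs(d, k = 1, seed = s)
    expect_equal(res$n_matched, 3)
    expect_equal(sort(res$pairs$first_record_id), c("M001", "M002", "M003"))
  }

  disjoint <- mk_coded(
    code = rep("P1", 4),
    age = c("25-34", "25-34", "45-54", "45-54"),
    asa = "II",
    S = c(1L, 1L, 2L, 2L),
    dur = c(40, 41, 42, 43)
  )
  disjoint$asa_grade <- c("I", "I", "III", "III")
  expect_equal(match_pairs(disjoint, seed = 1)$n_matched, 0)
  expect_error(paired_effect(match_pairs(disjoint, seed = 1)), "fewer than two")
})

test_that("matching is maximal per cell for every seed, with seed-stable counts", {
  cfg <- generator_config(n_lists = 600, seed = 401)
  coded <- code_records(clean_records(generate_dataset(cfg))$records)
  oracle <- min_count_oracle(coded, k = 1)
  counts <- NULL
  for (s in 1:5) {
    res <- match_pairs(coded, k = 1, seed = s)
    got <- stats::setNames(res$cell_counts$n_matched,
                           paste(res$cell_counts$procedure_code,
                                 res$cell_counts$age_group,
                                 res$cell_counts$asa_grade, sep = "|"))
    expect_equal(got[names(oracle)], oracle)
    expect_true(res$n_matched <= min(res$n_candidates_first,
                                     res$n_candidates_second))
    counts <- c(counts, res$n_matched)
  }
  expect_equal(length(unique(counts)), 1)     # counts are seed-invariant
  expect_identical(match_pairs(coded, k = 1, seed = 3),
                   match_pairs(coded, k = 1, seed = 3))
  # the same contract holds one position further down the list
  oracle2 <- min_count_oracle(coded, k = 2)
  res2 <- match_pairs(coded, k = 2, seed = 1)
  expect_equal(res2$n_matched, sum(oracle2))
})

test_that("surplus candidates are selected uniformly at random", {
  d <- mk_coded(
    code = rep("P1", 3), age = "45-54", asa = "II",
    S = c(1L, 1L, 2L), dur = c(40, 42, 41)
  )
  picks <- vapply(1:500, function(s) {
    match_pairs(d, k = 1, seed = s)$pairs$first_record_id
  }, character(1))
  n_first <- sum(picks == "M001")
  expect_equal(n_first + sum(picks == "M002"), 500)
  # 99.9% binomial bounds around 250
  expect_true(n_first > stats::qbinom(5e-4, 500, 0.5) &&
                n_first < stats::qbinom(1 - 5e-4, 500, 0.5))
})

test_that("paired effect reproduces an exact common log ratio", {
  n <- 20
  d1 <- stats::runif(n, 20, 120)
  d <- mk_coded(
    code = rep("P1", 2 * n),
    age = rep(theatreflow::AGE_GROUPS[(seq_len(n) %% 8) + 1], 2),
    asa = rep(theatreflow::ASA_GRADES[(seq_len(n) %% 5) + 1], 2),
    S = rep(c(1L, 2L), each = n),
    dur = c(d1, d1 * exp(-0.0618))
  )
  res <- match_pairs(d, k = 1, seed = 4)
  expect_equal(res$n_matched, n)
  eff <- paired_effect(res)
  expect_equal(eff$beta, -0.0618, tolerance = 1e-12)
  expect_equal(eff$se, 0)
  expect_equal(eff$pct, to_percent(-0.0618), tolerance = 1e-12)
  expect_equal(eff$p_value, 0)

  # equal durations: null effect exactly
  d0 <- dplyr::mutate(d, duration_min = 50)
  eff0 <- paired_effect(match_pairs(d0, k = 1, seed = 4))
  expect_equal(eff0$beta, 0)
  expect_equal(eff0$pct, 0)
})

test_that("the estimate is invariant to pair order and common rescaling", {
  cfg <- generator_config(n_lists = 400, seed = 411, p_same = 1)
  coded <- code_records(clean_records(generate_dataset(cfg))$records)
  res <- match_pairs(coded, k = 1, seed = 2)
  eff <- paired_effect(res)

  shuffled <- res
  shuffled$pairs <- res$pairs[withr::with_seed(8, sample(nrow(res$pairs))), ]
  eff_shuffled <- paired_effect(shuffled)
  expect_equal(eff_shuffled$beta, eff$beta, tolerance = 1e-12)
  expect_equal(eff_shuffled$se, eff$se, tolerance = 1e-12)

  rescaled <- res
  rescaled$pairs <- dplyr::mutate(res$pairs,
                                  duration_first = duration_first * 7,
                                  duration_second = duration_second * 7)
  expect_equal(paired_effect(rescaled)$beta, eff$beta, tolerance = 1e-12)
})

test_that("the matched estimate recovers a generated repeat effect", {
  delta <- from_percent(-6.18)
  cfg <- generator_config(n_lists = 3000, seed = 421, p_same = 1,
                          beta_abs = 0, beta_spec = delta, beta_switch = 0)
  coded <- code_records(clean_records(generate_dataset(cfg))$records)
  eff <- paired_effect(match_pairs(coded, k = 1, seed = 5))
  expect_true(eff$ci_low <= delta && delta <= eff$ci_high)
  expect_true(eff$pct_low <= -6.18 && -6.18 <= eff$pct_high)

  # matched estimate and the mixed model predict the same contrast here; on
  # unimodal lists absolute and specific order coincide, so the single
  # estimable order coefficient carries their sum (= delta)
  fit <- suppressMessages(fit_lmm(coded, "duration"))
  ord <- fit$effects[fit$effects$name %in% c("absolute_order",
                                             "specific_order"), ]
  ord <- ord[!is.na(ord$beta), ]
  expect_equal(nrow(ord), 1)
  expect_lt(abs(ord$beta - eff$beta), 2.5 * sqrt(ord$se^2 + eff$se^2))
})

test_that("per-procedure matched effects recover opposite signs and reduce to
           the pooled estimate on one code", {
  one_code <- generator_config(n_lists = 500, seed = 431, p_same = 1,
                               catalogue = default_catalogue()[1, ])
  coded1 <- code_records(clean_records(generate_dataset(one_code))$records)
  pooled <- paired_effect(match_pairs(coded1, k = 1, seed = 9))
  per <- per_procedure_matched(coded1, k = 1, seed = 9)
  expect_equal(nrow(per$effects), 1)
  expect_equal(per$effects$beta, pooled$beta, tolerance = 1e-12)
  expect_false("absent_code" %in% per$effects$procedure_code)

  correct <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    up <- generator_config(n_lists = 500, seed = 5000 + r, p_same = 1,
                           catalogue = default_catalogue()[1, ],
                           beta_abs = 0, beta_spec = 0.06, beta_switch = 0)
    dn <- generator_config(n_lists = 500, seed = 6000 + r, p_same = 1,
                           catalogue = default_catalogue()[2, ],
                           beta_abs = 0, beta_spec = -0.06, beta_switch = 0)
    cu <- code_records(clean_records(generate_dataset(up))$records)
    cd <- code_records(clean_records(generate_dataset(dn))$records)
    cu$record_id <- paste0("U", cu$record_id)
    cd$record_id <- paste0("D", cd$record_id)
    both <- dplyr::bind_rows(cu, cd)
    eff <- per_procedure_matched(both, k = 1, seed = r)$effects
    up_hat <- eff$beta[eff$procedure_code ==
                         default_catalogue()$procedure_code[1]]
    dn_hat <- eff$beta[eff$procedure_code ==
                         default_catalogue()$procedure_code[2]]
    correct <- correct + as.integer(up_hat > 0 && dn_hat < 0)
  }
  expect_gte(correct / reps, 0.95)
})

test_that("stratified matching runs per stratum and accounts for the rest", {
  cfg <- generator_config(n_lists = 700, seed = 441)
  coded <- code_records(clean_records(generate_dataset(cfg))$records)
  coded <- classify_records(coded, default_catalogue()[
    , c("procedure_code", "method", "complexity")])

  # single stratum: identical to the pooled chain
  mis <- coded[coded$method == "minimally_invasive", ]
  sm1 <- stratified_matched(mis, "method", k = 1, seed = 3)
  pooled <- paired_effect(match_pairs(mis, k = 1, seed = 3))
  expect_equal(nrow(sm1$effects), 1)
  expect_equal(sm1$effects$beta, pooled$beta, tolerance = 1e-12)

  sm <- stratified_matched(coded, "method", k = 1, seed = 3)
  expect_setequal(sm$effects$stratum, c("open", "minimally_invasive"))
  expect_equal(sm$n_unclassified, 0)

  # an unmapped code is excluded from strata and counted
  part <- classify_records(coded, default_catalogue()[
    -1, c("procedure_code", "method", "complexity")])
  smp <- stratified_matched(part, "method", k = 1, seed = 3)
  expect_equal(smp$n_unclassified,
               sum(coded$procedure_code ==
                     default_catalogue()$procedure_code[1]))

  # a stratum with too few pairs is skipped and listed
  few <- coded[coded$method == "open", ][1:2, ]
  few$procedure_specific_list_no <- c(1L, 1L)
  smf <- stratified_matched(few, "method", k = 1, seed = 3)
  expect_equal(nrow(smf$effects), 0)
  expect_equal(smf$skipped$stratum, "open")
})
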