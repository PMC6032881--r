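# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lme4): dense linear algebra only, usable on
# small instances.

# Profiled-REML oracle for y = X beta + Z u + e with one grouping factor.
# For a fixed variance ratio lambda = tau^2 / sigma^2, beta (GLS) and sigma^2
# profile out in closed form; the restricted log-likelihood
#   -2 l_R(lambda) = (n - p) log(sigma^2) + log|V| + log|X' V^-1 X| + const,
#   V = I + lambda Z Z',
# is maximised over lambda >= 0 by a coarse grid plus local refinement.
reml_oracle <- function(y, X, cell) {
  Z <- stats::model.matrix(~ 0 + factor(cell))
  n <- length(y)
  p <- ncol(X)
  eval_lambda <- function(lambda) {
    V <- diag(n) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    beta <- solve(A, XtVi %*% y)
    r <- y - X %*% beta
    s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) +
                    as.numeric(determinant(V)$modulus) +
                    as.numeric(determinant(A)$modulus))
    list(ll = ll, beta = drop(beta), sigma2 = s2, lambda = lambda)
  }
  grid <- c(0, 10^seq(-4, 3, length.out = 80))
  lls <- vapply(grid, function(l) eval_lambda(l)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(l) eval_lambda(l)$ll, c(lo, hi),
                         maximum = TRUE, tol = 1e-12)
  best <- eval_lambda(opt$maximum)
  if (lls[i] > best$ll) best <- eval_lambda(grid[i])
  best
}

# Exhaustive per-cell pair-count oracle: exact matching on the
# (procedure, age, ASA) cell can pair exactly min(n_k, n_{k+1}) cases per cell.
min_count_oracle <- function(coded, k) {
  cell <- function(d) paste(d$procedure_code, d$age_group, d$asa_grade,
                            sep = "|")
  n1 <- table(cell(coded[coded$procedure_specific_list_no == k, ]))
  n2 <- table(cell(coded[coded$procedure_specific_list_no == k + 1, ]))
  cells <- sort(union(names(n1), names(n2)))
  g <- function(tab, nm) ifelse(nm %in% names(tab), as.integer(tab[nm]), 0L)
  stats::setNames(pmin(g(n1, cells), g(n2, cells)), cells)
}

# The published five-row worked example of list coding.
table1_list <- function() {
  tibble::tibble(
    record_id = sprintf("T%d", 1:5),
    surgeon_id = "S1",
    hospital_id = "H1",
    list_date = as.Date("2014-01-06"),
    start_time = c("08:30", "09:45", "10:40", "11:45", "12:50"),
    procedure_code = c("lap_chole", "open_hernia", "lap_chole",
                       "lap_chole", "open_hernia"),
    age_group = c("45-54", "55-64", "35-44", "65-75", "45-54"),
    asa_grade = c("II", "I", "II", "III", "II"),
    duration_min = c(48, 41, 44, 42, 39),
    los_min = c(1440, 720, 1500, 1410, 700)
  )
}

# Hand-built coded records: coding columns are set directly so model and
# matching behaviour can be tested on exactly controlled designs.
fabricate_coded <- function(n, n_codes = 2, seed = 1,
                            beta = c(abs = 0, spec = 0, sw = 0),
                            tau = 0, sigma = 0.1, baseline = 40) {
  withr::with_seed(seed, {
    code <- sample(paste0("P", seq_len(n_codes)), n, replace = TRUE)
    age <- sample(theatreflow::AGE_GROUPS[1:4], n, replace = TRUE)
    asa <- sample(theatreflow::ASA_GRADES[1:3], n, replace = TRUE)
    A <- sample(1:6, n, replace = TRUE)
    S <- vapply(A, function(a) sample.int(a, 1L), integer(1))
    W <- A > 1 & stats::runif(n) < 0.5
    cell <- paste(code, age, asa, sep = "|")
    b <- stats::rnorm(length(unique(cell)), 0, tau)
    names(b) <- unique(cell)
    y <- log(baseline) + b[cell] + beta[["abs"]] * (A - 1) +
      beta[["spec"]] * (S - 1) + beta[["sw"]] * W + stats::rnorm(n, 0, sigma)
    tibble::tibble(
      record_id = sprintf("F%05d", seq_len(n)),
      procedure_code = code, age_group = age, asa_grade = asa,
      absolute_list_no = A, procedure_specific_list_no = S, switch = W,
      duration_min = unname(exp(y)), los_min = unname(exp(y)) * 20
    )
  })
}
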