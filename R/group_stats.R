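#' Significance tier of a p-value
#'
#' The conventional three-tier annotation: 3 for p < 0.001, 2 for
#' p < 0.01, 1 for p < 0.05, 0 otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Integer vector of tiers in 0..3.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, 3L, ifelse(p < 0.01, 2L, ifelse(p < 0.05, 1L, 0L)))
}

# Exact null distribution of U by full enumeration of rank assignments.
# Only used for tie-free samples with n1 + n2 <= 20 (<= 184756 subsets).
mwu_exact_p <- function(u, n1, n2) {
  N <- n1 + n2
  sets <- combn(N, n1)
  u_null <- colSums(matrix(seq_len(N)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  lo <- mean(u_null <= u)
  hi <- mean(u_null >= u)
  min(1, 2 * min(lo, hi))
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The exact two-tailed p-value is
#' computed by full enumeration of all `choose(n1+n2, n1)` rank
#' assignments when `n1 + n2 <= 20` and the pooled sample is tie-free;
#' otherwise a normal approximation with tie correction and (by default)
#' continuity correction is used. The two-tailed p is twice the smaller
#' tail, capped at 1.
#'
#' @param a,b Numeric vectors (the two groups); both non-empty.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact method;
#'   default `NULL` chooses automatically. Exact with ties is refused.
#' @return List of class `mwu_result`: `U` (statistic of group `a`),
#'   `p_two_tailed`, `method` (`"exact"` or `"normal_approximation"`),
#'   `tier`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(a, b, continuity = TRUE, exact = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("groups must not contain NA", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  use_exact <- if (is.null(exact)) (N <= 20 && !ties) else isTRUE(exact)
  if (use_exact && ties) {
    warning("exact method unavailable with ties; using normal approximation")
    use_exact <- FALSE
  }
  if (use_exact && N > 20) {
    warning("exact enumeration limited to n1 + n2 <= 20; using normal ",
            "approximation")
    use_exact <- FALSE
  }

  if (use_exact) {
    p <- mwu_exact_p(U, n1, n2)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (continuity) z <- z - sign(z) * min(0.5, abs(z))
      p <- min(1, 2 * pnorm(-abs(z / sqrt(sigma2))))
    }
    method <- "normal_approximation"
  }
  structure(list(U = U, p_two_tailed = p, method = method,
                 tier = significance_tier(p), n1 = n1, n2 = n2),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), %s p = %.4g, tier %d\n",
              x$U, x$n1, x$n2, x$method, x$p_two_tailed, x$tier))
  invisible(x)
}

#' Summarize a group as mean and SEM
#'
#' @param x Numeric vector (one SLA parameter for one group).
#' @return List with `mean`, `sem` (sample SD over sqrt(n); `NA` for
#'   n = 1) and `n`.
#' @export
summarize_group <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n == 0) stop("empty group", call. = FALSE)
  list(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else NA_real_, n = n)
}

SLA_PARAMETERS <- c("index_of_activity", "run_frequency", "running_speed",
                    "total_speed", "run_bout_time", "centrophobia_index")

#' Mean/SEM summary of a per-fly profile table
#'
#' @param profiles data.frame of per-fly profiles with grouping columns.
#' @param parameters Parameter columns to summarize.
#' @param strain_col,age_col Grouping column names (`age_col` may be
#'   absent from the table).
#' @return Long data.frame: strain, age, parameter, mean, sem, n.
#' @export
summarize_profiles <- function(profiles, parameters = SLA_PARAMETERS,
                               strain_col = "strain", age_col = "age") {
  parameters <- intersect(parameters, names(profiles))
  has_age <- age_col %in% names(profiles) &&
    !all(is.na(profiles[[age_col]]))
  key <- if (has_age) {
    interaction(profiles[[strain_col]], profiles[[age_col]], drop = TRUE)
  } else {
    factor(profiles[[strain_col]])
  }
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- profiles[key == k, , drop = FALSE]
    do.call(rbind, lapply(parameters, function(par) {
      v <- sub[[par]][!is.na(sub[[par]])]
      if (length(v) == 0) return(NULL)
      s <- summarize_group(v)
      data.frame(strain = as.character(sub[[strain_col]][1]),
                 age = if (has_age) sub[[age_col]][1] else NA,
                 parameter = par, mean = s$mean, sem = s$sem, n = s$n)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Between-group comparison table for SLA parameters
#'
#' For every parameter: all between-strain Mann-Whitney tests at matched
#' ages, plus each strain's older ages against its own baseline age.
#' No multiple-testing correction is applied by default (each comparison
#' reported at its nominal p); set `p_adjust` to a [stats::p.adjust()]
#' method to correct across the table.
#'
#' @param profiles Per-fly profile data.frame with strain (and
#'   optionally age) columns.
#' @param parameters Parameter columns to test.
#' @param strain_col,age_col Grouping columns.
#' @param baseline_age Age used as the within-strain baseline (default 5
#'   days; ignored when no age column exists).
#' @param p_adjust Multiplicity correction method (default `"none"`).
#' @param ... Passed to [mann_whitney_u()].
#' @return Long data.frame: parameter, comparison, group_a, group_b,
#'   n_a, n_b, U, p, tier.
#' @export
build_comparison_table <- function(profiles, parameters = SLA_PARAMETERS,
                                   strain_col = "strain", age_col = "age",
                                   baseline_age = 5, p_adjust = "none", ...) {
  parameters <- intersect(parameters, names(profiles))
  if (length(parameters) == 0) {
    stop("no shared parameter columns to compare", call. = FALSE)
  }
  has_age <- age_col %in% names(profiles) &&
    !all(is.na(profiles[[age_col]]))
  strains <- unique(as.character(profiles[[strain_col]]))
  if (length(strains) < 2 && !has_age) {
    stop("need at least two groups to compare", call. = FALSE)
  }
  ages <- if (has_age) sort(unique(profiles[[age_col]])) else NA

  grab <- function(strain, age, par) {
    sel <- profiles[[strain_col]] == strain
    if (has_age && !is.na(age)) sel <- sel & profiles[[age_col]] == age
    v <- profiles[[par]][sel]
    v[!is.na(v)]
  }
  rows <- list()
  add <- function(par, comparison, la, lb, va, vb, ...) {
    if (length(va) == 0 || length(vb) == 0) return()
    res <- mann_whitney_u(va, vb, ...)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = par, comparison = comparison,
      group_a = la, group_b = lb, n_a = res$n1, n_b = res$n2,
      U = res$U, p = res$p_two_tailed, tier = res$tier)
  }
  lab <- function(strain, age) {
    if (has_age && !is.na(age)) sprintf("%s@%s", strain, age) else strain
  }
  for (par in parameters) {
    for (age in ages) {
      if (length(strains) >= 2) {
        pairs <- combn(strains, 2)
        for (j in seq_len(ncol(pairs))) {
          add(par, "between_strain", lab(pairs[1, j], age),
              lab(pairs[2, j], age),
              grab(pairs[1, j], age, par), grab(pairs[2, j], age, par), ...)
        }
      }
    }
    if (has_age && baseline_age %in% ages) {
      for (s in strains) {
        for (age in setdiff(ages, baseline_age)) {
          add(par, "vs_baseline_age", lab(s, age), lab(s, baseline_age),
              grab(s, age, par), grab(s, baseline_age, par), ...)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparable groups found", call. = FALSE)
  if (p_adjust != "none") {
    out$p <- p.adjust(out$p, method = p_adjust)
    out$tier <- significance_tier(out$p)
  }
  rownames(out) <- NULL
  out
}
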