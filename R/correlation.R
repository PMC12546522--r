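#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of midranks (average ranks for ties),
#' computed after pairwise deletion of missing values. The two-sided p-value
#' uses the t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom; |rho| = 1 gives p = 0. For n <= 8 an exact permutation
#' p-value (proportion of the n! rank permutations with |rho| at least as
#' large) is available.
#'
#' @param x,y numeric vectors of equal length
#' @param exact use exact permutation p (n <= 8 only)
#' @return list(rho, p, n, flagged = TRUE when a vector has zero rank variance)
#' @export
spearman <- function(x, y, exact = FALSE) {
  stop_if_not(length(x) == length(y), "length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  rho <- rank_pearson(rx, ry)
  if (exact) {
    stop_if_not(n <= 8, "exact permutation p limited to n <= 8")
    perms <- all_permutations(n)
    ref <- abs(rho)
    cnt <- 0L
    for (r in seq_len(nrow(perms))) {
      if (abs(rank_pearson(rx, ry[perms[r, ]])) >= ref - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else if (abs(rho) >= 1 - 1e-14) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, flagged = FALSE)
}

rank_pearson <- function(rx, ry) {
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Correlation screen between radiomic features and aneurysm parameters
#'
#' All feature x parameter pairs, overall and per subgroup, with strong-pair
#' flags. The published rule is "rho > 0.7 and p < 0.05"; because one reported
#' strong pair is negative (Coarseness vs vortex volume, -0.75), the default
#' mode applies the threshold to |rho|; `mode = "signed"` applies it to rho
#' itself. No multiple-testing correction by default (mirroring common
#' practice); `adjust = "BH"` applies Benjamini-Hochberg within the screen.
#'
#' @param cohort data.frame with one row per case
#' @param features column names of radiomic features
#' @param parameters either a character vector of parameter columns, or a
#'   named list of character vectors (names become categories, e.g.
#'   morphology / wss / vortex)
#' @param rho_threshold strong-pair threshold (default 0.7)
#' @param alpha significance level (default 0.05)
#' @param mode "abs" (default) or "signed"
#' @param subgroup_col optional column with subgroup labels; subgroups with
#'   fewer than 3 cases are skipped with a message
#' @param adjust "none" (default) or "BH"
#' @return data.frame(category, feature, parameter, subgroup, rho, p, n,
#'   strong), deterministically ordered
#' @export
correlation_screen <- function(cohort, features, parameters,
                               rho_threshold = 0.7, alpha = 0.05,
                               mode = c("abs", "signed"),
                               subgroup_col = NULL, adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!is.list(parameters)) parameters <- list(all = parameters)
  needed <- c(features, unlist(parameters), subgroup_col)
  missing_cols <- setdiff(needed, names(cohort))
  stop_if_not(length(missing_cols) == 0, "missing columns: %s",
              paste(missing_cols, collapse = ", "))
  groups <- list(overall = rep(TRUE, nrow(cohort)))
  if (!is.null(subgroup_col)) {
    for (g in sort(unique(cohort[[subgroup_col]]))) {
      sel <- cohort[[subgroup_col]] == g
      if (sum(sel) < 3) {
        message(sprintf("subgroup '%s' skipped (n = %d < 3)", g, sum(sel)))
        next
      }
      groups[[g]] <- sel
    }
  }
  rows <- list()
  for (cat in sort(names(parameters))) {
    for (f in sort(features)) for (prm in sort(parameters[[cat]])) {
      for (g in names(groups)) {
        sel <- groups[[g]]
        sp <- tryCatch(spearman(cohort[[f]][sel], cohort[[prm]][sel]),
                       error = function(e) NULL)
        if (is.null(sp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, feature = f, parameter = prm, subgroup = g,
          rho = sp$rho, p = sp$p, n = sp$n, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (adjust == "BH") res$p <- stats::p.adjust(res$p, method = "BH")
  stat <- if (mode == "abs") abs(res$rho) else res$rho
  res$strong <- !is.na(res$rho) & stat > rho_threshold & res$p < alpha
  res[order(res$category, res$feature, res$parameter, res$subgroup), ]
}

#' Cohort screening summary
#'
#' Inclusion/exclusion arithmetic for a case-screening log: per-reason
#' exclusion percentages of the identified total, and per-type/per-location
#' percentages of the included cases. Percentages are rounded half-up to one
#' decimal, the convention of clinical tables.
#'
#' @param log data.frame with columns `case_id`, `included` (logical),
#'   `exclusion_reason` (NA for included), `type` (e.g. saccular/fusiform,
#'   required for included cases), `location` (optional)
#' @return list: n_identified, n_included, exclusions (data.frame reason, n,
#'   pct), types (data.frame type, n, pct), locations (data.frame or NULL)
#' @export
cohort_screening_summary <- function(log) {
  stop_if_not(is.data.frame(log) && nrow(log) > 0, "empty screening log")
  stop_if_not(all(c("case_id", "included") %in% names(log)),
              "log needs case_id and included columns")
  stop_if_not(!any(duplicated(log$case_id)), "duplicated case ids")
  n_id <- nrow(log)
  inc <- log[log$included, , drop = FALSE]
  exc <- log[!log$included, , drop = FALSE]
  stop_if_not("type" %in% names(log) && !any(is.na(inc$type)),
              "included cases must carry a type label")
  pct <- function(n, d) round_half_up(100 * n / d, 1)
  tab <- function(x, denom) {
    t <- sort(table(x), decreasing = TRUE)
    data.frame(level = names(t), n = as.integer(t),
               pct = pct(as.integer(t), denom), stringsAsFactors = FALSE)
  }
  exclusions <- if (nrow(exc) > 0) tab(exc$exclusion_reason, n_id) else NULL
  types <- tab(inc$type, nrow(inc))
  locations <- if ("location" %in% names(log) && !all(is.na(inc$location)))
    tab(inc$location, nrow(inc)) else NULL
  list(n_identified = n_id, n_included = nrow(inc),
       exclusions = exclusions, types = types, locations = locations)
}
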