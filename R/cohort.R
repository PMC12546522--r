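#' Synthetic cohort with planted rank correlation
#'
#' Generates paired (feature, parameter) columns through a Gaussian copula
#' whose latent Pearson correlation r = 2 sin(pi * rho / 6) yields the target
#' Spearman rank correlation rho*. Because Spearman's rho is rank-based, any
#' strictly monotone margin gives the same population rho, so an optional
#' monotone link may be applied to the feature column. Subgroup labels
#' (saccular / fusiform) carry subgroup-specific rho*.
#'
#' @param n_cases total cases (>= 5)
#' @param planted_rho target Spearman rho*, either a single value or a named
#'   vector `c(saccular = ..., fusiform = ...)`
#' @param n_saccular number of saccular cases (default balanced split)
#' @param link optional strictly monotone function applied to the feature
#'   column (e.g. `exp`); identity by default
#' @param seed RNG seed
#' @return list(cohort = data.frame(case_id, subgroup, feature, parameter),
#'   truth = list(planted rho per subgroup, seed))
#' @export
make_coupled_cohort <- function(n_cases, planted_rho = 0.8,
                                n_saccular = floor(n_cases / 2),
                                link = identity, seed = 1) {
  stop_if_not(n_cases >= 5, "need at least 5 cases")
  stop_if_not(all(planted_rho >= -1 & planted_rho <= 1),
              "planted_rho must be in [-1, 1]")
  stop_if_not(n_saccular >= 0 && n_saccular <= n_cases, "bad n_saccular")
  if (is.null(names(planted_rho)) && length(planted_rho) == 1)
    planted_rho <- c(saccular = unname(planted_rho),
                     fusiform = unname(planted_rho))
  stop_if_not(all(c("saccular", "fusiform") %in% names(planted_rho)),
              "planted_rho must name both subgroups")
  subgroup <- rep(c("saccular", "fusiform"),
                  c(n_saccular, n_cases - n_saccular))
  set.seed(seed)
  x <- y <- numeric(n_cases)
  for (g in c("saccular", "fusiform")) {
    idx <- which(subgroup == g)
    if (!length(idx)) next
    r <- 2 * sin(pi * planted_rho[[g]] / 6)   # copula latent correlation
    z1 <- stats::rnorm(length(idx))
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(length(idx))
    x[idx] <- z1
    y[idx] <- z2
  }
  cohort <- data.frame(case_id = sprintf("case_%03d", seq_len(n_cases)),
                       subgroup = subgroup,
                       feature = link(x), parameter = y,
                       stringsAsFactors = FALSE)
  truth <- list(generator = "make_coupled_cohort",
                planted_rho = planted_rho, n_saccular = n_saccular,
                seed = seed)
  list(cohort = cohort, truth = truth)
}
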