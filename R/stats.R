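# Transduction-rate statistics: per-sample rates, t-based species summaries,
# Wald species comparisons and validation-based FDR arithmetic.

#' Per-sample transduction rate
#'
#' The percentage of all non-reference L1 insertions (solo plus transducing)
#' that carry a 3' transduction: `100 * n_td / n_l1`.
#'
#' @param n_td number of transduction calls in the sample.
#' @param n_l1 total number of non-reference L1 insertions in the sample.
#' @return rate in percent.
#' @export
transduction_rate <- function(n_td, n_l1) {
  if (any(n_l1 <= 0)) stop("n_l1 must be positive")
  if (any(n_td > n_l1))
    warning("n_td > n_l1: the caller can recover L1s missed upstream")
  100 * n_td / n_l1
}

#' Species-level rate summary with a one-sample t interval
#'
#' Rates are computed per sample and averaged (not pooled over counts); the
#' 95% confidence half-width is `t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param counts data.frame with columns `sample`, `species`, `n_l1`, `n_td`
#'   for the samples of one species (or several; summarised per species).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per species: `mean_rate`, `ci_half_width`
#'   (NA when n < 2), `n_samples`, and the per-sample rates as a comma list.
#' @export
species_rate_summary <- function(counts, conf = 0.95) {
  stopifnot(all(c("sample", "species", "n_l1", "n_td") %in% names(counts)))
  res <- lapply(split(counts, counts$species), function(g) {
    r <- transduction_rate(g$n_td, g$n_l1)
    n <- length(r)
    hw <- if (n >= 2) stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(r) / sqrt(n)
    else NA_real_
    data.frame(species = g$species[1], mean_rate = mean(r), ci_half_width = hw,
               n_samples = n, rates = paste(sprintf("%.4f", r), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wald comparison of transduction rates between two species
#'
#' Default: a z statistic on per-sample percentage rates,
#' `z = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`, with a two-sided
#' p-value from the standard normal. With `method = "glm"`, a binomial GLM
#' Wald test on the pooled counts (species coefficient z test) is used
#' instead.
#'
#' @param a,b data.frames of `SampleCounts` (columns `n_l1`, `n_td`), one per
#'   species, each with >= 2 samples.
#' @param method `"rates"` (default) or `"glm"`.
#' @return list with `statistic` and `p_value`.
#' @export
compare_species_rates <- function(a, b, method = c("rates", "glm")) {
  method <- match.arg(method)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 samples per species")
  if (method == "glm") {
    df <- rbind(data.frame(sp = "a", n_td = a$n_td, n_l1 = a$n_l1),
                data.frame(sp = "b", n_td = b$n_td, n_l1 = b$n_l1))
    fit <- stats::glm(cbind(n_td, n_l1 - n_td) ~ sp, data = df,
                      family = stats::binomial())
    z <- summary(fit)$coefficients["spb", "z value"]
    return(list(statistic = unname(z),
                p_value = 2 * stats::pnorm(-abs(unname(z)))))
  }
  ra <- transduction_rate(a$n_td, a$n_l1)
  rb <- transduction_rate(b$n_td, b$n_l1)
  se <- sqrt(stats::var(ra) / length(ra) + stats::var(rb) / length(rb))
  if (se == 0) {
    if (mean(ra) == mean(rb)) return(list(statistic = 0, p_value = 1))
    stop("zero variance in both groups with unequal means: p undefined")
  }
  z <- (mean(ra) - mean(rb)) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' False discovery rate from validation counts
#'
#' @param n_tested number of calls subjected to validation.
#' @param n_confirmed number confirmed.
#' @return FDR in percent: `100 * (n_tested - n_confirmed) / n_tested`.
#' @export
fdr_from_validation <- function(n_tested, n_confirmed) {
  if (n_tested <= 0) stop("n_tested must be positive")
  if (n_confirmed < 0 || n_confirmed > n_tested)
    stop("n_confirmed must be in [0, n_tested]")
  100 * (n_tested - n_confirmed) / n_tested
}

#' Example cohort counts bundled with the package
#'
#' Per-sample non-reference L1 insertion and transduction-call counts for a
#' fifteen-genome, three-species primate cohort, shipped as a plain-text
#' input for the rate statistics (see
#' `system.file("extdata", "primate_cohort_counts.tsv", package = "tiger")`).
#'
#' @return data.frame with columns `sample`, `species`, `n_l1`, `n_td`.
#' @export
primate_cohort_counts <- function() {
  path <- system.file("extdata", "primate_cohort_counts.tsv", package = "tiger")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
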