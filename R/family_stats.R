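#' Disease prevalence in a family
#' @param cases number of affected individuals
#' @param n total number of individuals (> 0)
#' @return prevalence as a percentage, rounded to 1 decimal
#' @examples
#' prevalence(48, 750)  # 6.4
#' @export
prevalence <- function(cases, n) {
  if (n <= 0) stop("n must be positive")
  if (cases > n) stop("cases cannot exceed n")
  round(100 * cases / n, 1)
}

#' Expected case count under independent disease risk
#'
#' Under a binomial model with population prevalence `p`, returns the
#' expected number of cases among `n` individuals and the upper limit of
#' the two-sided 95% interval: the smallest `k` with
#' `P(Binomial(n, p) <= k) >= 0.975`.
#'
#' @param n number of individuals (>= 1)
#' @param p population prevalence, in (0,1)
#' @return list with `expectation` (`n * p`) and `upper95` (integer bound)
#' @examples
#' expected_cases(750, 0.013)$upper95  # 16
#' @export
expected_cases <- function(n, p) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)")
  stopifnot(n >= 1)
  list(expectation = n * p,
       upper95 = stats::qbinom(0.975, n, p))
}

#' Two-sided exact binomial sex-ratio test
#'
#' Tests the male:female case split against 1:1 by the exact binomial
#' distribution, two-sided by doubling the smaller tail (capped at 1).
#' The minimum-likelihood two-sided P is also returned.
#'
#' @param males,females case counts by sex (sum >= 1)
#' @return list with `p` (tail-doubling), `p_minlik` (minimum-likelihood
#'   method, as in [stats::binom.test()]) and counts
#' @examples
#' sex_ratio_test(25, 29)$p  # 0.683
#' @export
sex_ratio_test <- function(males, females) {
  n <- males + females
  stopifnot(n >= 1)
  lower <- stats::pbinom(min(males, females), n, 0.5)
  list(p = min(1, 2 * lower),
       p_minlik = stats::binom.test(males, n, 0.5)$p.value,
       males = males, females = females)
}

#' Per-family and per-subfamily descriptive summary
#'
#' @param ped a `Pedigree`
#' @param subfamilies optional named list: subfamily label -> character
#'   vector of member ids
#' @param pop_prevalence population prevalence used for the binomial
#'   case-count expectation (default 0.013)
#' @return a `FamilySummary` data.frame with one row per unit (whole family
#'   first): n, cases, prevalence (%), expected cases and upper 95% bound,
#'   male/female case counts and the sex-ratio P value.
#' @export
family_summary <- function(ped, subfamilies = NULL, pop_prevalence = 0.013) {
  units <- c(list(ALL = ped$id), subfamilies)
  out <- do.call(rbind, lapply(names(units), function(u) {
    ids <- units[[u]]
    sub <- ped[ped$id %in% ids, , drop = FALSE]
    cases <- sum(sub$affection == "affected")
    m <- sum(sub$affection == "affected" & sub$sex == "male")
    f <- sum(sub$affection == "affected" & sub$sex == "female")
    exp <- expected_cases(nrow(sub), pop_prevalence)
    data.frame(unit = u, n = nrow(sub), cases = cases,
               prevalence = prevalence(cases, nrow(sub)),
               expected = exp$expectation, upper95 = exp$upper95,
               male_cases = m, female_cases = f,
               sex_p = if (m + f >= 1) sex_ratio_test(m, f)$p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("FamilySummary", "data.frame")
  out
}
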