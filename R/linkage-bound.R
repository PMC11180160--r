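#' Count informative chromosomes for the marker-trait cosegregation bound
#'
#' Under a fully recessive trait, a marker-trait recombination event is
#' phenotypically detectable only on chromosomes transmitted through a
#' heterozygous parent into progeny whose phenotype would flip: the wild-type
#' chromosome of heterozygous F2 progeny, either chromosome of homozygous
#' mutant F2 progeny, and the F1-derived chromosome of backcross-to-mutant
#' progeny. Backcross-to-wild-type progeny are all seeded regardless of
#' recombination and contribute nothing.
#'
#' Contribution rules per scored plant: F2 het 1, F2 hom_del 2, F2 hom_wt 0,
#' BC_Bs het 1, BC_Bs hom_del 1, BC_M anything 0. Plants with `no_call`
#' genotype or `unknown` phenotype are excluded. A recombinant is a
#' genotype-phenotype mismatch (a wild-type-allele carrier that is seedless,
#' or a deletion homozygote that is seeded) among plants contributing at
#' least one chromosome; each mismatched plant counts one observed
#' recombination event.
#'
#' @param records Data.frame with columns `plant_id`, `generation`
#'   (`F2`/`BC_Bs`/`BC_M`), `genotype` (`hom_wt`/`het`/`hom_del`/`no_call`),
#'   `phenotype` (`seeded`/`seedless`/`unknown`), e.g. from
#'   [simulate_cross()] or [read_progeny_records()].
#' @return An object of class `"informative_count"`: list with
#'   `n_chromosomes`, `n_recombinants_observed` and a per
#'   (generation, genotype) `breakdown` table.
#' @export
count_informative_chromosomes <- function(records) {
  req <- c("plant_id", "generation", "genotype", "phenotype")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  gen_ok <- c("F1", "F2", "BC_Bs", "BC_M") # F1 contributes no chromosomes
  gt_ok <- c("hom_wt", "het", "hom_del", "no_call")
  ph_ok <- c("seeded", "seedless", "unknown")
  if (nrow(records) > 0 &&
      (!all(records$generation %in% gen_ok) ||
       !all(records$genotype %in% gt_ok) ||
       !all(records$phenotype %in% ph_ok))) {
    stop("invalid generation/genotype/phenotype labels in records",
         call. = FALSE)
  }
  use <- records[records$genotype != "no_call" &
                 records$phenotype != "unknown", , drop = FALSE]
  contrib <- function(generation, genotype) {
    ifelse(generation == "F2" & genotype == "het", 1L,
    ifelse(generation == "F2" & genotype == "hom_del", 2L,
    ifelse(generation == "BC_Bs" & genotype %in% c("het", "hom_del"), 1L,
           0L)))
  }
  chrom <- if (nrow(use)) contrib(use$generation, use$genotype) else integer(0)
  mismatch <- if (nrow(use)) {
    (use$genotype %in% c("hom_wt", "het") & use$phenotype == "seedless") |
      (use$genotype == "hom_del" & use$phenotype == "seeded")
  } else logical(0)
  informative <- chrom > 0L
  breakdown <- if (nrow(use)) {
    stats::aggregate(list(n_plants = rep(1L, nrow(use)),
                          n_chromosomes = chrom),
                     by = list(generation = use$generation,
                               genotype = use$genotype), FUN = sum)
  } else {
    data.frame(generation = character(0), genotype = character(0),
               n_plants = integer(0), n_chromosomes = integer(0))
  }
  structure(
    list(n_chromosomes = sum(chrom),
         n_recombinants_observed = sum(mismatch & informative),
         breakdown = breakdown),
    class = "informative_count"
  )
}

#' @export
print.informative_count <- function(x, ...) {
  cat(sprintf("Informative chromosomes: %d (%d recombinant)\n",
              x$n_chromosomes, x$n_recombinants_observed))
  if (nrow(x$breakdown)) print(x$breakdown, row.names = FALSE)
  invisible(x)
}

new_informative_count <- function(n_chromosomes, n_recombinants = 0L) {
  stopifnot(n_recombinants <= n_chromosomes)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_recombinants_observed = as.integer(n_recombinants),
                 breakdown = NULL),
            class = "informative_count")
}

#' Chi-square rejection test for a candidate map distance
#'
#' Tests whether the observed number of recombinants among informative
#' chromosomes is compatible with a map distance of `distance_cM` between
#' marker and trait locus (1 cM = 1% recombination; no interference). The
#' default `"recombinant_class_term"` statistic is the single recombinant
#' class term (O - E)^2 / E with E = n * d/100, df 1 (with zero observed
#' recombinants it equals E exactly); `"two_class"` adds the
#' non-recombinant class term.
#'
#' @param count An `"informative_count"` object (or a plain list with
#'   `n_chromosomes` and `n_recombinants_observed`).
#' @param distance_cM Candidate distance in centimorgans, 0 < d < 50.
#' @param alpha Significance level.
#' @param variant `"recombinant_class_term"` (default) or `"two_class"`.
#' @return An object of class `"distance_bound"`: list with
#'   `tested_distance_cM`, `expected_recombinants`, `statistic`, `df`,
#'   `p_value`, `rejected`, `variant`, `n_chromosomes`, `observed`.
#' @examples
#' distance_rejection_test(list(n_chromosomes = 114,
#'                              n_recombinants_observed = 0), 3.5)
#' @export
distance_rejection_test <- function(count, distance_cM, alpha = 0.05,
                                    variant = c("recombinant_class_term",
                                                "two_class")) {
  variant <- match.arg(variant)
  n <- count$n_chromosomes
  o <- count$n_recombinants_observed
  if (is.null(n) || n <= 0) stop("no informative chromosomes", call. = FALSE)
  if (!is.numeric(distance_cM) || distance_cM <= 0 || distance_cM >= 50) {
    stop("'distance_cM' must lie in (0, 50)", call. = FALSE)
  }
  e <- n * distance_cM / 100
  if (e == 0) stop("expected recombinant count is zero", call. = FALSE)
  stat <- (o - e)^2 / e
  if (variant == "two_class") stat <- stat + (n - o - (n - e))^2 / (n - e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(
    list(tested_distance_cM = distance_cM, expected_recombinants = e,
         statistic = stat, df = 1L, p_value = p, rejected = p < alpha,
         alpha = alpha, variant = variant, n_chromosomes = n, observed = o),
    class = "distance_bound"
  )
}

#' @export
print.distance_bound <- function(x, ...) {
  cat(sprintf(
    "Map-distance test: d = %g cM over %d chromosomes (%d recombinant)\n",
    x$tested_distance_cM, x$n_chromosomes, x$observed))
  cat(sprintf("  expected recombinants = %.3f, X-squared = %.4g, p = %.4g: %s\n",
              x$expected_recombinants, x$statistic, x$p_value,
              if (x$rejected) sprintf("rejected at alpha = %g", x$alpha)
              else "not rejected"))
  invisible(x)
}

#' Minimal rejectable map distance
#'
#' The smallest map distance (cM) at or above the observed recombination
#' fraction that [distance_rejection_test()] rejects at `alpha` — an upper
#' bound on the marker-trait distance supported by the data. With zero
#' observed recombinants and the recombinant-class statistic the closed form
#' is d = 100 * qchisq(1 - alpha, 1) / n; otherwise the bound is found by
#' bisection on the rising flank of the statistic above the point estimate
#' 100 * O / n.
#'
#' @inheritParams distance_rejection_test
#' @return Distance in cM, or `NA_real_` when no distance below 50 cM can be
#'   rejected (too few chromosomes).
#' @examples
#' min_rejectable_distance(list(n_chromosomes = 114,
#'                              n_recombinants_observed = 0))
#' @export
min_rejectable_distance <- function(count, alpha = 0.05,
                                    variant = c("recombinant_class_term",
                                                "two_class")) {
  variant <- match.arg(variant)
  n <- count$n_chromosomes
  o <- count$n_recombinants_observed
  if (is.null(n) || n <= 0) stop("no informative chromosomes", call. = FALSE)
  upper <- 50 - 1e-9
  rej_at <- function(d) {
    distance_rejection_test(count, d, alpha = alpha, variant = variant)$rejected
  }
  if (o == 0 && variant == "recombinant_class_term") {
    d <- 100 * stats::qchisq(1 - alpha, df = 1) / n
    return(if (d < 50) d else NA_real_)
  }
  lo <- max(100 * o / n, 1e-9)
  if (lo >= upper || !rej_at(upper)) return(NA_real_)
  # statistic is monotone increasing in d above the point estimate
  for (i in 1:200) {
    mid <- (lo + upper) / 2
    if (rej_at(mid)) upper <- mid else lo <- mid
    if (upper - lo < 1e-10) break
  }
  upper
}

#' Monte Carlo check of the map-distance rejection test
#'
#' Simulates binomial recombinant counts at true rate `d_cM`/100 over `n`
#' chromosomes and applies [distance_rejection_test()] at test distance
#' `test_cM` (default: the true distance, giving the type-I error of the
#' bound). Reproducible given `seed`.
#'
#' @param n Number of informative chromosomes.
#' @param d_cM True simulation distance (cM); may be 0.
#' @param alpha Significance level.
#' @param reps Number of Monte Carlo replicates (>= 1000).
#' @param seed Integer RNG seed.
#' @param test_cM Distance handed to the test; defaults to `d_cM`.
#' @param variant Statistic variant, see [distance_rejection_test()].
#' @return Fraction of replicates rejected (a single number in \[0, 1\]).
#' @export
recombination_power_mc <- function(n, d_cM, alpha = 0.05, reps = 10000L,
                                   seed = 1L, test_cM = d_cM,
                                   variant = c("recombinant_class_term",
                                               "two_class")) {
  variant <- match.arg(variant)
  if (reps < 1000) stop("'reps' must be at least 1000", call. = FALSE)
  if (test_cM <= 0 || test_cM >= 50) {
    stop("'test_cM' must lie in (0, 50)", call. = FALSE)
  }
  set.seed(seed)
  o <- stats::rbinom(reps, size = n, prob = d_cM / 100)
  e <- n * test_cM / 100
  stat <- (o - e)^2 / e
  if (variant == "two_class") stat <- stat + (n - o - (n - e))^2 / (n - e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  mean(p < alpha)
}
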