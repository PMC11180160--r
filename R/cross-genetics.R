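#' Cross family observation
#'
#' Bundles the observed class counts for one cross family (an F1, F2 or
#' backcross progeny set) together with ordered class labels, ready for
#' segregation goodness-of-fit testing.
#'
#' @param family_id Single string identifying the family.
#' @param generation One of `"F1"`, `"F2"`, `"BC_M"`, `"BC_Bs"`.
#' @param observed Non-negative integer counts, one per phenotype or
#'   genotype class.
#' @param class_labels Character labels aligned with `observed`. Defaults to
#'   `"class1"`, `"class2"`, ...
#' @return An object of class `"cross_family"`.
#' @examples
#' cross_family("M2xBs_F2", "F2", c(48, 10), c("seeded", "seedless"))
#' @export
cross_family <- function(family_id, generation, observed,
                         class_labels = paste0("class", seq_along(observed))) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  generation <- match.arg(generation, c("F1", "F2", "BC_M", "BC_Bs"))
  observed <- as.numeric(observed)
  if (length(observed) < 1L || any(is.na(observed)) || any(observed < 0) ||
      any(observed != round(observed))) {
    stop("'observed' must be non-negative integer counts", call. = FALSE)
  }
  if (length(class_labels) != length(observed)) {
    stop("'class_labels' and 'observed' lengths differ", call. = FALSE)
  }
  structure(
    list(family_id = family_id, generation = generation,
         class_labels = as.character(class_labels), observed = observed),
    class = "cross_family"
  )
}

#' Segregation ratio hypothesis
#'
#' An expected Mendelian segregation ratio (e.g. 3:1 for one gene with
#' complete dominance, 1:2:1 for codominant genotype classes).
#'
#' @param ratio Positive numbers giving the expected ratio terms, e.g.
#'   `c(3, 1)`.
#' @param name Display name; defaults to `"3:1"`-style formatting.
#' @param gene_count Number of segregating genes the hypothesis assumes
#'   (1-3).
#' @param class_labels Optional labels aligned with `ratio`.
#' @return An object of class `"ratio_hypothesis"`.
#' @examples
#' ratio_hypothesis(c(3, 1))
#' ratio_hypothesis(c(1, 2, 1), gene_count = 1)
#' @export
ratio_hypothesis <- function(ratio, name = paste(ratio, collapse = ":"),
                             gene_count = 1L,
                             class_labels = paste0("class", seq_along(ratio))) {
  ratio <- as.numeric(ratio)
  if (length(ratio) < 1L || any(is.na(ratio)) || any(ratio <= 0)) {
    stop("all ratio terms must be positive (drop zero-expectation classes)",
         call. = FALSE)
  }
  if (!gene_count %in% 1:3) stop("'gene_count' must be 1, 2 or 3", call. = FALSE)
  if (length(class_labels) != length(ratio)) {
    stop("'class_labels' and 'ratio' lengths differ", call. = FALSE)
  }
  structure(
    list(name = name, gene_count = as.integer(gene_count), ratio = ratio,
         class_labels = as.character(class_labels)),
    class = "ratio_hypothesis"
  )
}

#' Default panel of Mendelian segregation hypotheses
#'
#' Two-class segregation ratios expected for one, two and three independent
#' genes acting on a dominant/recessive phenotype: 3:1; 9:7, 13:3, 15:1;
#' 37:27, 63:1. The panel is a conventional stand-in and fully
#' user-overridable in [test_hypothesis_panel()].
#'
#' @return A list of [ratio_hypothesis()] objects.
#' @export
mendelian_panel <- function() {
  list(
    ratio_hypothesis(c(3, 1), gene_count = 1L),
    ratio_hypothesis(c(9, 7), gene_count = 2L),
    ratio_hypothesis(c(13, 3), gene_count = 2L),
    ratio_hypothesis(c(15, 1), gene_count = 2L),
    ratio_hypothesis(c(37, 27), gene_count = 3L),
    ratio_hypothesis(c(63, 1), gene_count = 3L)
  )
}

#' Chi-square goodness-of-fit test for one segregation ratio
#'
#' Uncorrected Pearson chi-square test of observed class counts against a
#' Mendelian ratio hypothesis: statistic sum((O - E)^2 / E) with
#' E_i = total * ratio_i / sum(ratio), df = classes - 1, upper-tail p-value.
#' No Yates continuity correction is applied (the convention in plant
#' segregation tables). A p-value exactly equal to `alpha` is treated as
#' non-significant.
#'
#' @param family A [cross_family()] object (or a bare numeric count vector).
#' @param hypothesis A [ratio_hypothesis()] object (or a bare ratio vector).
#' @param alpha Significance level, default 0.05.
#' @return An object of class `"chisq_gof"`: list with `statistic`, `df`,
#'   `p_value`, `significant`, `alpha`, `observed`, `expected`,
#'   `hypothesis`, `family_id`.
#' @examples
#' chi_square_gof(cross_family("F2", "F2", c(48, 10)), ratio_hypothesis(c(3, 1)))
#' @export
chi_square_gof <- function(family, hypothesis, alpha = 0.05) {
  if (is.numeric(family)) family <- cross_family("family", "F2", family)
  if (is.numeric(hypothesis)) hypothesis <- ratio_hypothesis(hypothesis)
  stopifnot(inherits(family, "cross_family"),
            inherits(hypothesis, "ratio_hypothesis"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  obs <- family$observed
  ratio <- hypothesis$ratio
  if (length(obs) != length(ratio)) {
    stop(sprintf("family '%s' has %d classes but hypothesis '%s' has %d",
                 family$family_id, length(obs), hypothesis$name,
                 length(ratio)), call. = FALSE)
  }
  total <- sum(obs)
  if (total == 0) {
    stop("total observed count is zero; test undefined", call. = FALSE)
  }
  p <- ratio / sum(ratio)
  # expected counts are all positive because ratio terms are; chisq.test
  # warns when expected < 5, which these sparse field tables routinely are
  ct <- suppressWarnings(stats::chisq.test(obs, p = p, correct = FALSE))
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value),
         significant = unname(ct$p.value) < alpha, alpha = alpha,
         observed = obs, expected = unname(ct$expected),
         hypothesis = hypothesis$name, family_id = family$family_id),
    class = "chisq_gof"
  )
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("Segregation chi-square test: %s vs %s\n",
              x$family_id, x$hypothesis))
  cat(sprintf("  observed: %s   expected: %s\n",
              paste(x$observed, collapse = ":"),
              paste(sprintf("%.2f", x$expected), collapse = ":")))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g %s\n", x$statistic,
              x$df, x$p_value,
              if (x$significant) sprintf("(significant at %g)", x$alpha)
              else "(ns)"))
  invisible(x)
}

#' Test one family against a panel of ratio hypotheses
#'
#' Applies [chi_square_gof()] to each hypothesis and flags acceptance
#' (non-rejection) at `alpha`; output row order matches the input panel.
#'
#' @inheritParams chi_square_gof
#' @param hypotheses List of [ratio_hypothesis()] objects (default
#'   [mendelian_panel()]).
#' @return A data.frame with columns `hypothesis`, `gene_count`,
#'   `statistic`, `df`, `p_value`, `rejected`.
#' @export
test_hypothesis_panel <- function(family, hypotheses = mendelian_panel(),
                                  alpha = 0.05) {
  if (length(hypotheses) == 0L) {
    stop("empty hypothesis panel", call. = FALSE)
  }
  if (inherits(hypotheses, "ratio_hypothesis")) hypotheses <- list(hypotheses)
  rows <- lapply(hypotheses, function(h) {
    if (is.numeric(h)) h <- ratio_hypothesis(h)
    r <- chi_square_gof(family, h, alpha)
    data.frame(hypothesis = h$name, gene_count = h$gene_count,
               statistic = r$statistic, df = r$df, p_value = r$p_value,
               rejected = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled and heterogeneity chi-square partition across families
#'
#' Partitions the summed per-family goodness-of-fit chi-square into a pooled
#' component (the test applied to the element-wise sum of counts) and a
#' heterogeneity component (total minus pooled) testing whether families
#' share a common segregation ratio. Heterogeneity df =
#' (families - 1) * (classes - 1).
#'
#' @param families List of [cross_family()] objects (at least two), all with
#'   the same number of classes.
#' @inheritParams chi_square_gof
#' @return An object of class `"family_set_result"`: list with `per_family`
#'   (list of `"chisq_gof"`), `total_statistic`, `pooled` and
#'   `heterogeneity` (`"chisq_gof"` objects).
#' @examples
#' fams <- list(cross_family("a", "F2", c(99, 43)),
#'              cross_family("b", "F2", c(190, 71)),
#'              cross_family("c", "F2", c(69, 33)))
#' heterogeneity_partition(fams, ratio_hypothesis(c(3, 1)))
#' @export
heterogeneity_partition <- function(families, hypothesis, alpha = 0.05) {
  if (is.numeric(hypothesis)) hypothesis <- ratio_hypothesis(hypothesis)
  if (length(families) < 2L) {
    stop("heterogeneity partition needs at least two families", call. = FALSE)
  }
  per <- lapply(families, chi_square_gof, hypothesis = hypothesis,
                alpha = alpha)
  total_stat <- sum(vapply(per, `[[`, numeric(1), "statistic"))
  total_df <- sum(vapply(per, `[[`, numeric(1), "df"))
  pooled_counts <- Reduce(`+`, lapply(families, `[[`, "observed"))
  pooled_fam <- cross_family("pooled", families[[1L]]$generation,
                             pooled_counts, families[[1L]]$class_labels)
  pooled <- chi_square_gof(pooled_fam, hypothesis, alpha)
  het_stat <- total_stat - pooled$statistic
  het_df <- as.integer(total_df - pooled$df)
  het_p <- stats::pchisq(het_stat, het_df, lower.tail = FALSE)
  het <- structure(
    list(statistic = het_stat, df = het_df, p_value = het_p,
         significant = het_p < alpha, alpha = alpha,
         observed = NULL, expected = NULL, hypothesis = hypothesis$name,
         family_id = "heterogeneity"),
    class = "chisq_gof"
  )
  structure(
    list(per_family = per, total_statistic = total_stat, total_df = total_df,
         pooled = pooled, heterogeneity = het),
    class = "family_set_result"
  )
}

#' @export
print.family_set_result <- function(x, ...) {
  cat(sprintf("Heterogeneity partition over %d families (hypothesis %s)\n",
              length(x$per_family), x$pooled$hypothesis))
  for (r in x$per_family) {
    cat(sprintf("  %-14s X2 = %7.4f  df %d  p = %.3f\n", r$family_id,
                r$statistic, r$df, r$p_value))
  }
  cat(sprintf("  %-14s X2 = %7.4f  df %d\n", "total", x$total_statistic,
              x$total_df))
  cat(sprintf("  %-14s X2 = %7.4f  df %d  p = %.3f\n", "pooled",
              x$pooled$statistic, x$pooled$df, x$pooled$p_value))
  cat(sprintf("  %-14s X2 = %7.4f  df %d  p = %.3f\n", "heterogeneity",
              x$heterogeneity$statistic, x$heterogeneity$df,
              x$heterogeneity$p_value))
  invisible(x)
}
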