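#' Codominant genotype call from a two-band PCR pattern
#'
#' The codominant assay combines a wild-type-specific product (amplified
#' inside the intact locus, about 350 bp) and a deletion-junction-specific
#' product (about 456 bp, amplifiable only when the deletion brings the
#' primer sites within range). Band presence maps deterministically to
#' genotype: wild-type band only = `hom_wt`, both bands = `het`, junction
#' band only = `hom_del`, neither = `no_call` (failed assay).
#'
#' @param wt_band,del_band Logical vectors (recycled to common length):
#'   presence of the wild-type and deletion-junction products.
#' @return Character vector of genotype calls
#'   (`hom_wt`/`het`/`hom_del`/`no_call`).
#' @examples
#' call_codominant(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
#' @export
call_codominant <- function(wt_band, del_band) {
  n <- max(length(wt_band), length(del_band))
  wt_band <- rep_len(as.logical(wt_band), n)
  del_band <- rep_len(as.logical(del_band), n)
  if (anyNA(wt_band) || anyNA(del_band)) {
    stop("band presence must be TRUE/FALSE, not NA", call. = FALSE)
  }
  ifelse(wt_band & del_band, "het",
  ifelse(wt_band, "hom_wt",
  ifelse(del_band, "hom_del", "no_call")))
}

#' Dominant genotype call from a single wild-type-specific band
#'
#' A dominant marker amplifies only from chromosomes carrying the intact
#' locus, so band presence means at least one wild-type allele (genotype
#' unresolved between homozygote and heterozygote) and absence is an
#' absence-based inference of deletion homozygosity.
#'
#' @param has_band Logical vector: presence of the wild-type product.
#' @return Character vector: `"carries_INO"` or `"putative_hom_del"`.
#' @export
call_dominant <- function(has_band) {
  has_band <- as.logical(has_band)
  if (anyNA(has_band)) stop("band presence must be TRUE/FALSE", call. = FALSE)
  ifelse(has_band, "carries_INO", "putative_hom_del")
}

#' Cosegregation of locus genotype with the seedless phenotype
#'
#' Cross-tabulates codominant genotype calls against phenotypes and lists
#' discordant plants: carriers of a wild-type allele (`hom_wt`/`het`) scored
#' seedless, or deletion homozygotes scored seeded. Discordance under a
#' fully recessive causal model indicates marker-trait recombination (or a
#' scoring error); the summary feeds
#' [count_informative_chromosomes()] directly when a `generation` column is
#' supplied.
#'
#' @param genotypes Character vector of calls from [call_codominant()].
#' @param phenotypes Character vector (`seeded`/`seedless`/`unknown`).
#' @param plant_id Optional plant identifiers (default `plant1`, ...). When
#'   `genotypes` and `phenotypes` come from separate keyed tables, join them
#'   first; mismatched lengths are a join error.
#' @param generation Optional generation labels carried into the record
#'   table.
#' @return An object of class `"cosegregation"`: list with `counts` (a
#'   genotype x phenotype table), `n_scored`, `n_no_call`, `n_concordant`,
#'   `n_discordant`, `discordant_plants` and a `records` data.frame
#'   compatible with [count_informative_chromosomes()].
#' @export
cosegregation_analysis <- function(genotypes, phenotypes,
                                   plant_id = paste0("plant", seq_along(genotypes)),
                                   generation = "F2") {
  if (length(genotypes) != length(phenotypes)) {
    stop(sprintf("join error: %d genotypes vs %d phenotypes",
                 length(genotypes), length(phenotypes)), call. = FALSE)
  }
  if (length(plant_id) != length(genotypes)) {
    stop("join error: plant_id length mismatch", call. = FALSE)
  }
  gt_ok <- c("hom_wt", "het", "hom_del", "no_call")
  ph_ok <- c("seeded", "seedless", "unknown")
  if (!all(genotypes %in% gt_ok) || !all(phenotypes %in% ph_ok)) {
    stop("invalid genotype or phenotype labels", call. = FALSE)
  }
  generation <- rep_len(generation, length(genotypes))
  scored <- genotypes != "no_call" & phenotypes != "unknown"
  discord <- scored &
    ((genotypes %in% c("hom_wt", "het") & phenotypes == "seedless") |
     (genotypes == "hom_del" & phenotypes == "seeded"))
  counts <- table(genotype = factor(genotypes, levels = gt_ok),
                  phenotype = factor(phenotypes, levels = ph_ok))
  structure(
    list(counts = counts,
         n_scored = sum(scored),
         n_no_call = sum(!scored),
         n_concordant = sum(scored & !discord),
         n_discordant = sum(discord),
         discordant_plants = plant_id[discord],
         records = data.frame(plant_id = plant_id,
                              generation = generation,
                              genotype = genotypes,
                              phenotype = phenotypes,
                              stringsAsFactors = FALSE)),
    class = "cosegregation"
  )
}

#' @export
print.cosegregation <- function(x, ...) {
  cat(sprintf("Cosegregation: %d scored (%d excluded), %d concordant, %d discordant\n",
              x$n_scored, x$n_no_call, x$n_concordant, x$n_discordant))
  print(x$counts[rowSums(x$counts) > 0, colSums(x$counts) > 0, drop = FALSE])
  if (x$n_discordant > 0) {
    cat("discordant plants:", paste(x$discordant_plants, collapse = ", "),
        "\n")
  }
  invisible(x)
}
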