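#' Binary SSR band matrix
#'
#' A genotypes x bands presence/absence matrix (1 = band amplified,
#' 0 = absent). Although SSR markers are codominant, scoring here is
#' presence/absence of each amplified fragment; joint absences carry no
#' similarity information under the Jaccard coefficient.
#'
#' @param m Matrix (or data.frame) of 0/1 entries, genotypes in rows.
#' @param genotype_ids,band_ids Optional dimension names.
#' @return An integer matrix of class `"band_matrix"`.
#' @export
band_matrix <- function(m, genotype_ids = rownames(m), band_ids = colnames(m)) {
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L))) {
    stop("band matrix entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (is.null(genotype_ids)) genotype_ids <- paste0("g", seq_len(nrow(m)))
  if (is.null(band_ids)) band_ids <- paste0("band", seq_len(ncol(m)))
  dimnames(m) <- list(genotype_ids, band_ids)
  class(m) <- c("band_matrix", class(m))
  m
}

#' Jaccard distance matrix from SSR band presence/absence
#'
#' For each genotype pair the Jaccard similarity is a/(a+b+c), with a the
#' shared band presences and b, c the bands private to either genotype;
#' joint absences are excluded. The distance is 1 - similarity. Pairs with
#' no bands in either genotype (a+b+c = 0) have undefined similarity and are
#' returned as `NA` and flagged.
#'
#' @param m A [band_matrix()] (or plain 0/1 matrix), at least 2 genotypes.
#' @return Symmetric numeric matrix of distances with zero diagonal and an
#'   attribute `undefined_pairs` (two-column matrix of genotype ids, zero
#'   rows when all pairs are defined).
#' @examples
#' m <- band_matrix(rbind(a = c(1, 1, 0, 1), b = c(1, 0, 0, 1)))
#' jaccard_distance_matrix(m)
#' @export
jaccard_distance_matrix <- function(m) {
  m <- band_matrix(unclass(m))
  if (nrow(m) < 2L) stop("need at least two genotypes", call. = FALSE)
  d <- suppressWarnings(
    as.matrix(vegan::vegdist(unclass(m), method = "jaccard", binary = TRUE))
  )
  diag(d) <- 0
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  undefined <- cbind(genotype_a = rownames(m)[undef[, 1]],
                     genotype_b = rownames(m)[undef[, 2]])
  attr(d, "undefined_pairs") <- undefined
  d
}

#' Long-format genotype-pair distance list
#'
#' @param d Distance matrix from [jaccard_distance_matrix()].
#' @return Data.frame with columns `genotype_a`, `genotype_b`, `distance`,
#'   one row per unordered pair.
#' @export
jaccard_pair_list <- function(d) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(genotype_a = rownames(d)[idx[, 1]],
             genotype_b = colnames(d)[idx[, 2]],
             distance = d[idx], stringsAsFactors = FALSE)
}

#' Band polymorphism summary
#'
#' A band locus is monomorphic when present in every genotype or absent from
#' every genotype, polymorphic otherwise. All-absent bands (null
#' amplification) are additionally reported separately since they usually
#' reflect failed primers rather than shared alleles.
#'
#' @param m A [band_matrix()] (or plain 0/1 matrix).
#' @return List with `n_bands`, `n_monomorphic`, `n_polymorphic`, `n_null`
#'   and per-band `status` (character vector).
#' @export
polymorphism_summary <- function(m) {
  m <- band_matrix(unclass(m))
  cs <- colSums(m)
  status <- ifelse(cs == 0L, "null",
            ifelse(cs == nrow(m), "monomorphic", "polymorphic"))
  list(n_bands = ncol(m),
       n_monomorphic = sum(status %in% c("monomorphic", "null")),
       n_polymorphic = sum(status == "polymorphic"),
       n_null = sum(status == "null"),
       status = stats::setNames(status, colnames(m)))
}
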