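#' Simulate progeny of a one-locus cross with a linked marker
#'
#' Two loci on one chromosome: a fully recessive trait locus (wild-type
#' allele vs deletion allele) and a codominant molecular marker at
#' `distance_cM` centimorgans. Heterozygous parents emit recombinant gametes
#' with probability `distance_cM`/100 (single interval, no interference);
#' homozygous parents transmit their only haplotype. Phenotype is seedless
#' iff the trait genotype is homozygous for the deletion. F1 crosses a
#' wild-type homozygote to a deletion homozygote; F2 selfs/intercrosses F1;
#' `BC_to_wt` and `BC_to_mut` backcross F1 to the respective parent.
#'
#' @param generation `"F1"`, `"F2"`, `"BC_to_wt"` or `"BC_to_mut"`.
#' @param n_progeny Number of progeny (>= 1).
#' @param distance_cM Marker-trait map distance in cM (0 <= d < 50).
#' @param seed Integer RNG seed (the generator is a pure function of it).
#' @return Data.frame with columns `plant_id`, `generation` (labels
#'   compatible with [count_informative_chromosomes()]: F2, BC_M, BC_Bs),
#'   `trait_genotype` and `genotype` (marker genotype), both coded
#'   `hom_wt`/`het`/`hom_del`, and `phenotype` (`seeded`/`seedless`).
#' @examples
#' head(simulate_cross("F2", 10, distance_cM = 0, seed = 1))
#' @export
simulate_cross <- function(generation = c("F2", "F1", "BC_to_wt", "BC_to_mut"),
                           n_progeny, distance_cM = 0, seed = 1L) {
  generation <- match.arg(generation)
  stopifnot(n_progeny >= 1, distance_cM >= 0, distance_cM < 50)
  set.seed(seed)
  r <- distance_cM / 100
  n <- as.integer(n_progeny)
  # a gamete is (trait allele, marker allele); 1 = wild type, 0 = deletion.
  # F1 parents are coupling-phase double heterozygotes.
  het_gamete <- function(n) {
    trait <- stats::rbinom(n, 1L, 0.5)
    rec <- stats::rbinom(n, 1L, r) == 1L
    marker <- ifelse(rec, 1L - trait, trait)
    cbind(trait, marker)
  }
  const_gamete <- function(n, allele) cbind(trait = rep(allele, n),
                                            marker = rep(allele, n))
  g1 <- switch(generation,
               F1 = const_gamete(n, 1L),
               F2 = het_gamete(n),
               BC_to_wt = het_gamete(n),
               BC_to_mut = het_gamete(n))
  g2 <- switch(generation,
               F1 = const_gamete(n, 0L),
               F2 = het_gamete(n),
               BC_to_wt = const_gamete(n, 1L),
               BC_to_mut = const_gamete(n, 0L))
  code <- function(a, b) c("hom_del", "het", "hom_wt")[a + b + 1L]
  trait_gt <- code(g1[, 1], g2[, 1])
  marker_gt <- code(g1[, 2], g2[, 2])
  gen_label <- switch(generation, F1 = "F1", F2 = "F2",
                      BC_to_wt = "BC_M", BC_to_mut = "BC_Bs")
  data.frame(
    plant_id = sprintf("%s_%06d", generation, seq_len(n)),
    generation = gen_label,
    trait_genotype = trait_gt,
    genotype = marker_gt,
    phenotype = ifelse(trait_gt == "hom_del", "seedless", "seeded"),
    stringsAsFactors = FALSE
  )
}

#' Tabulate simulated progeny into a cross family
#'
#' @param progeny Data.frame from [simulate_cross()].
#' @param by `"phenotype"` (seeded/seedless classes) or `"genotype"`
#'   (marker genotype classes hom_wt/het/hom_del).
#' @param family_id Family label for the resulting [cross_family()].
#' @return A [cross_family()] object.
#' @export
tabulate_cross <- function(progeny, by = c("phenotype", "genotype"),
                           family_id = "simulated") {
  by <- match.arg(by)
  if (by == "phenotype") {
    labs <- c("seeded", "seedless")
    counts <- as.numeric(table(factor(progeny$phenotype, levels = labs)))
  } else {
    labs <- c("hom_wt", "het", "hom_del")
    counts <- as.numeric(table(factor(progeny$genotype, levels = labs)))
  }
  cross_family(family_id, progeny$generation[1], counts, labs)
}

#' Simulate a wild-type reference and a deletion allele
#'
#' Draws a random nucleotide sequence at the requested GC content and
#' removes `deletion_interval` to form the deletion allele; the truth call
#' is clean by construction.
#'
#' @param ref_length Reference length in bases.
#' @param deletion_interval 0-based half-open `c(start, end)`, strictly
#'   inside the reference with at least `margin` flanking bases.
#' @param gc_fraction Target GC content (default 0.5).
#' @param seed Integer RNG seed.
#' @param margin Minimum flank width (default 1000).
#' @param name Reference sequence name.
#' @return List of class `"genome_pair"`: `reference` ([reference_seq()]),
#'   `deletion_allele` (string), `truth` (list with `deleted_interval`,
#'   `length`).
#' @export
simulate_genome_pair <- function(ref_length, deletion_interval,
                                 gc_fraction = 0.5, seed = 1L,
                                 margin = 1000L, name = "synthetic_contig") {
  a <- deletion_interval[1]; b <- deletion_interval[2]
  if (!(a >= margin && b <= ref_length - margin && b > a)) {
    stop("deletion interval must lie strictly inside the reference ",
         "with at least 'margin' flanking bases", call. = FALSE)
  }
  stopifnot(gc_fraction > 0, gc_fraction < 1)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), ref_length, replace = TRUE, prob = p)
  ref <- paste(bases, collapse = "")
  allele <- paste0(substr(ref, 1L, a), substr(ref, b + 1L, ref_length))
  structure(
    list(reference = reference_seq(name, ref),
         deletion_allele = allele,
         truth = list(deleted_interval = c(a, b), length = b - a)),
    class = "genome_pair"
  )
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("<genome_pair> %s: %d bp reference, %d bp deleted at [%d, %d)\n",
              x$reference$name, x$reference$length, x$truth$length,
              x$truth$deleted_interval[1], x$truth$deleted_interval[2]))
  invisible(x)
}

#' Simulate reads from an allele and project them onto the reference
#'
#' Single-end reads of fixed length are drawn uniformly from the chosen
#' allele. Alignments are produced by coordinate projection rather than by
#' running a mapper: a read fully inside a retained segment aligns
#' end-to-end; a read spanning the deletion junction is split there and
#' aligned to its longer side, the remainder soft-clipped (ties go to the
#' left side). Substitution errors are injected uniformly at `error_rate`.
#'
#' @param pair A `"genome_pair"` from [simulate_genome_pair()].
#' @param which_allele `"deletion"` (default) or `"wildtype"`.
#' @param read_len Read length (default 150).
#' @param depth Mean coverage of the source allele (default 20).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer RNG seed.
#' @return An [aligned_reads()] table (against `pair$reference`).
#' @export
simulate_alignments <- function(pair, which_allele = c("deletion", "wildtype"),
                                read_len = 150L, depth = 20, error_rate = 0,
                                seed = 1L) {
  which_allele <- match.arg(which_allele)
  allele <- if (which_allele == "deletion") pair$deletion_allele
            else pair$reference$sequence
  alen <- nchar(allele)
  if (read_len >= alen) stop("read length exceeds allele length", call. = FALSE)
  set.seed(seed)
  n_reads <- as.integer(round(depth * alen / read_len))
  if (n_reads == 0L) {
    return(aligned_reads(character(0), integer(0), integer(0), integer(0),
                         integer(0), character(0)))
  }
  starts <- sample.int(alen - read_len + 1L, n_reads, replace = TRUE) - 1L
  seqs <- substring(allele, starts + 1L, starts + read_len)
  if (error_rate > 0) {
    n_err <- stats::rbinom(1L, n_reads * read_len, error_rate)
    if (n_err > 0) {
      pos <- sample.int(n_reads * read_len, n_err)
      ri <- (pos - 1L) %/% read_len + 1L
      pi <- (pos - 1L) %% read_len + 1L
      for (e in seq_len(n_err)) {
        old <- substr(seqs[ri[e]], pi[e], pi[e])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(seqs[ri[e]], pi[e], pi[e]) <- new
      }
    }
  }
  a <- pair$truth$deleted_interval[1]
  dlen <- pair$truth$length
  if (which_allele == "wildtype") {
    return(aligned_reads(sprintf("wt_%06d", seq_len(n_reads)), starts,
                         starts + read_len, 0L, 0L, seqs,
                         reference = pair$reference))
  }
  # allele coordinate u maps to reference u (u < a) or u + dlen (u >= a)
  ends <- starts + read_len
  spans <- starts < a & ends > a
  left_len <- pmin(pmax(a - starts, 0L), read_len)
  right_len <- read_len - left_len
  ref_start <- integer(n_reads); ref_end <- integer(n_reads)
  clip_p <- integer(n_reads); clip_s <- integer(n_reads)
  left_only <- ends <= a
  right_only <- starts >= a
  ref_start[left_only] <- starts[left_only]
  ref_end[left_only] <- ends[left_only]
  ref_start[right_only] <- starts[right_only] + dlen
  ref_end[right_only] <- ends[right_only] + dlen
  use_left <- spans & left_len >= right_len # tie -> left
  ref_start[spans & use_left] <- starts[spans & use_left]
  ref_end[spans & use_left] <- a
  clip_s[spans & use_left] <- right_len[spans & use_left]
  use_right <- spans & !use_left
  ref_start[use_right] <- a + dlen
  ref_end[use_right] <- a + dlen + right_len[use_right]
  clip_p[use_right] <- left_len[use_right]
  aligned_reads(sprintf("del_%06d", seq_len(n_reads)), ref_start, ref_end,
                clip_p, clip_s, seqs, reference = pair$reference)
}

#' Simulate a binary SSR band matrix
#'
#' Monomorphic bands are present in every genotype; polymorphic bands get a
#' random non-constant presence pattern.
#'
#' @param n_genotypes,n_monomorphic,n_polymorphic Non-negative counts
#'   (`n_genotypes` >= 2 when any band is polymorphic).
#' @param seed Integer RNG seed.
#' @return A [band_matrix()].
#' @export
simulate_band_matrix <- function(n_genotypes, n_monomorphic, n_polymorphic,
                                 seed = 1L) {
  stopifnot(n_genotypes >= 1, n_monomorphic >= 0, n_polymorphic >= 0)
  if (n_polymorphic > 0 && n_genotypes < 2) {
    stop("polymorphic bands require at least two genotypes", call. = FALSE)
  }
  set.seed(seed)
  mono <- matrix(1L, n_genotypes, n_monomorphic)
  poly <- matrix(0L, n_genotypes, n_polymorphic)
  for (j in seq_len(n_polymorphic)) {
    repeat {
      col <- stats::rbinom(n_genotypes, 1L, 0.5)
      if (length(unique(col)) > 1L) break
    }
    poly[, j] <- col
  }
  band_matrix(cbind(mono, poly),
              genotype_ids = paste0("g", seq_len(n_genotypes)),
              band_ids = c(sprintf("mono%03d", seq_len(n_monomorphic)),
                           sprintf("poly%03d", seq_len(n_polymorphic))))
}
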