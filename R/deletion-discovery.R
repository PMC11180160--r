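#' Reference sequence object
#'
#' A named nucleotide sequence; all coordinates in this package are 0-based,
#' half-open on the reference.
#'
#' @param name Sequence name.
#' @param sequence Nucleotide string over A, C, G, T, N (case-insensitive).
#' @return An object of class `"reference_seq"`.
#' @export
reference_seq <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty reference sequence", call. = FALSE)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence)),
            class = "reference_seq")
}

#' @export
print.reference_seq <- function(x, ...) {
  cat(sprintf("<reference_seq> %s (%d bp)\n", x$name, x$length))
  invisible(x)
}

#' Aligned-read table constructor
#'
#' Validates a table of single-end alignments against a reference. Each row
#' is one read: `ref_start`/`ref_end` give the 0-based half-open aligned
#' span on the reference; `clip_prefix`/`clip_suffix` are soft-clipped base
#' counts at the read's 5'/3' ends; `seq` is the full read sequence
#' (clipped bases included), so
#' `clip_prefix + (ref_end - ref_start) + clip_suffix == nchar(seq)`.
#'
#' @param read_id,ref_start,ref_end,clip_prefix,clip_suffix,seq Column
#'   vectors of equal length.
#' @param reference Optional [reference_seq()] for bounds checking.
#' @return A data.frame of class `"aligned_reads"`.
#' @export
aligned_reads <- function(read_id, ref_start, ref_end, clip_prefix,
                          clip_suffix, seq, reference = NULL) {
  df <- data.frame(read_id = as.character(read_id),
                   ref_start = as.integer(ref_start),
                   ref_end = as.integer(ref_end),
                   clip_prefix = as.integer(clip_prefix),
                   clip_suffix = as.integer(clip_suffix),
                   seq = as.character(seq), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$ref_end <= df$ref_start) || any(df$ref_start < 0)) {
      stop("invalid aligned spans", call. = FALSE)
    }
    if (any(df$clip_prefix < 0) || any(df$clip_suffix < 0)) {
      stop("negative clip lengths", call. = FALSE)
    }
    bad <- df$clip_prefix + (df$ref_end - df$ref_start) + df$clip_suffix !=
      nchar(df$seq)
    if (any(bad)) {
      stop("clip lengths + aligned length must equal read length (reads: ",
           paste(utils::head(df$read_id[bad], 5), collapse = ", "), ")",
           call. = FALSE)
    }
    if (!is.null(reference) && any(df$ref_end > reference$length)) {
      stop("alignment extends beyond the reference", call. = FALSE)
    }
  }
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Per-base read depth over a reference
#'
#' Depth at position i counts reads whose aligned span covers i; soft-clipped
#' bases do not contribute.
#'
#' @param alignments An [aligned_reads()] table.
#' @param reference A [reference_seq()] (its length sets the profile length).
#' @return Integer vector of length `reference$length`.
#' @export
depth_profile <- function(alignments, reference) {
  n <- reference$length
  if (nrow(alignments) == 0L) return(integer(n))
  if (any(alignments$ref_end > n) || any(alignments$ref_start < 0)) {
    stop("alignment outside reference bounds", call. = FALSE)
  }
  delta <- integer(n + 1L)
  inc <- tabulate(alignments$ref_start + 1L, nbins = n + 1L)
  dec <- tabulate(alignments$ref_end + 1L, nbins = n + 1L)
  cumsum(inc - dec)[seq_len(n)]
}

#' Detect coverage gaps consistent with a deletion
#'
#' Finds maximal runs of positions with depth at most `max_internal_depth`.
#' High-depth runs strictly shorter than `max_spike_len` that are flanked by
#' low runs are absorbed into the surrounding gap — these spikes arise from
#' reads mis-mapped to repeated sequence inside a deletion. Gaps strictly
#' shorter than `min_gap_len` are discarded.
#'
#' @param depth Integer depth vector (from [depth_profile()]).
#' @param max_internal_depth Maximum depth still counted as "gap" (default
#'   2, tolerating stray mis-mapped reads).
#' @param min_gap_len Minimum reported gap length (default 100).
#' @param max_spike_len Spikes shorter than this are merged through
#'   (default 500).
#' @return Data.frame of class `"coverage_gaps"`: columns `start`, `end`
#'   (0-based half-open), `length`, `mean_flanking_depth`,
#'   `internal_max_depth`.
#' @export
detect_gaps <- function(depth, max_internal_depth = 2L, min_gap_len = 100L,
                        max_spike_len = 500L) {
  if (length(depth) == 0L) stop("empty depth profile", call. = FALSE)
  low <- depth <= max_internal_depth
  r <- rle(low)
  # absorb short interior high runs flanked by low runs, repeating until
  # stable so adjacent merged runs coalesce
  repeat {
    k <- length(r$values)
    spike <- which(!r$values & r$lengths < max_spike_len)
    spike <- spike[spike > 1L & spike < k]
    if (!length(spike)) break
    r$values[spike] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based
  keep <- r$values & r$lengths >= min_gap_len
  gs <- starts[keep]; ge <- ends[keep]
  flank <- function(s, e, w = 500L) {
    vals <- c(if (s > 0L) depth[max(1L, s - w + 1L):s],
              if (e < length(depth)) depth[(e + 1L):min(length(depth), e + w)])
    if (length(vals)) mean(vals) else NA_real_
  }
  out <- data.frame(
    start = as.integer(gs), end = as.integer(ge),
    length = as.integer(ge - gs),
    mean_flanking_depth = vapply(seq_along(gs), function(i) {
      s <- gs[i]; e <- ge[i]
      if (s == 0L && e == length(depth)) return(0)
      flank(s, e)
    }, numeric(1)),
    internal_max_depth = vapply(seq_along(gs), function(i) {
      as.integer(max(depth[(gs[i] + 1L):ge[i]]))
    }, integer(1))
  )
  class(out) <- c("coverage_gaps", "data.frame")
  out
}

#' Collect reads soft-clipped at a coverage-gap boundary
#'
#' Returns reads whose aligned span ends within `window` bases of the gap
#' start with a soft-clipped suffix of at least `min_clip` bases (left side
#' of the junction), or begins within `window` of the gap end with a clipped
#' prefix of at least `min_clip` (right side). These clipped tails carry the
#' sequence across the deletion junction.
#'
#' @param alignments An [aligned_reads()] table.
#' @param gap One row of a [detect_gaps()] result (or a list with `start`
#'   and `end`).
#' @param min_clip Minimum soft-clip length (default 10).
#' @param window Tolerance around the gap boundary in bases (default 5;
#'   gap edges from thresholded depth can be off by a few bases).
#' @return The subset of `alignments` with an added `side` column
#'   (`"left"`/`"right"`).
#' @export
collect_junction_reads <- function(alignments, gap, min_clip = 10L,
                                   window = 5L) {
  gs <- gap$start[1]; ge <- gap$end[1]
  left <- abs(alignments$ref_end - gs) <= window &
    alignments$clip_suffix >= min_clip
  right <- abs(alignments$ref_start - ge) <= window &
    alignments$clip_prefix >= min_clip
  out <- alignments[left | right, , drop = FALSE]
  out$side <- ifelse(left[left | right], "left", "right")
  out
}

# longest suffix(a)/prefix(b) overlap with at most max_mismatch mismatches;
# returns 0 when none reaches min_overlap
overlap_len <- function(a, b, min_overlap, max_mismatch = 0L) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) < min_overlap) return(0L)
  for (len in seq(min(la, lb), min_overlap)) {
    sa <- substr(a, la - len + 1L, la)
    sb <- substr(b, 1L, len)
    if (max_mismatch == 0L) {
      if (sa == sb) return(len)
    } else {
      mm <- sum(utf8ToInt(sa) != utf8ToInt(sb))
      if (mm <= max_mismatch) return(len)
    }
  }
  0L
}

#' Greedy overlap assembly of junction reads
#'
#' Assembles clipped junction reads into a single contig by
#' overlap-layout-consensus: reads contained in another are removed, then the
#' pair with the longest suffix-prefix overlap (exact by default) of at
#' least `min_overlap` bases is merged repeatedly. Ties are broken
#' lexicographically by read id. If more than one sequence remains with no
#' admissible overlap, the assembly fails (a result, not an error).
#'
#' @param reads Character vector of read sequences, or an [aligned_reads()]
#'   table (its `seq` column is used, named by `read_id`).
#' @param min_overlap Minimum overlap length (default 20).
#' @param max_mismatch Maximum mismatches tolerated in an overlap
#'   (default 0; exact).
#' @return An object of class `"junction_assembly"`: list with `success`,
#'   `contig` (NA on failure), `support` (number of reads merged in) and
#'   `n_input`.
#' @examples
#' assemble_junction(c(a = "ACGTACGT", b = "ACGTTTTT"), min_overlap = 4)
#' @export
assemble_junction <- function(reads, min_overlap = 20L, max_mismatch = 0L) {
  if (is.data.frame(reads)) {
    seqs <- stats::setNames(reads$seq, reads$read_id)
  } else {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%04d", seq_along(seqs))
  }
  if (length(seqs) < 2L) {
    stop("assembly needs at least two reads", call. = FALSE)
  }
  seqs <- seqs[order(names(seqs))]
  # drop exact duplicates and contained reads (they add no junction span)
  seqs <- seqs[!duplicated(unname(seqs))]
  if (length(seqs) > 1L) {
    contained <- vapply(seq_along(seqs), function(i) {
      any(vapply(seq_along(seqs)[-i], function(j) {
        grepl(seqs[[i]], seqs[[j]], fixed = TRUE)
      }, logical(1)))
    }, logical(1))
    seqs <- seqs[!contained]
  }
  support <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  while (length(seqs) > 1L) {
    best <- NULL
    ids <- names(seqs)
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        if (i == j) next
        len <- overlap_len(seqs[[i]], seqs[[j]], min_overlap, max_mismatch)
        if (len >= min_overlap) {
          cand <- list(i = i, j = j, len = len)
          if (is.null(best) || len > best$len ||
              (len == best$len &&
               (ids[i] < ids[best$i] ||
                (ids[i] == ids[best$i] && ids[j] < ids[best$j])))) {
            best <- cand
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- paste0(seqs[[best$i]],
                     substr(seqs[[best$j]], best$len + 1L,
                            nchar(seqs[[best$j]])))
    new_id <- paste(ids[best$i], ids[best$j], sep = "+")
    new_support <- support[[best$i]] + support[[best$j]]
    keep <- setdiff(seq_along(seqs), c(best$i, best$j))
    seqs <- c(seqs[keep], stats::setNames(merged, new_id))
    support <- c(support[keep], stats::setNames(new_support, new_id))
    seqs <- seqs[order(names(seqs))]
    support <- support[names(seqs)]
  }
  if (length(seqs) == 1L) {
    structure(list(success = TRUE, contig = unname(seqs[[1L]]),
                   support = unname(support[[1L]]),
                   n_input = NA_integer_),
              class = "junction_assembly")
  } else {
    structure(list(success = FALSE, contig = NA_character_,
                   support = 0L, n_input = length(seqs)),
              class = "junction_assembly")
  }
}

#' @export
print.junction_assembly <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<junction_assembly> contig of %d bp from %d reads\n",
                nchar(x$contig), x$support))
  } else {
    cat("<junction_assembly> FAILED: no overlap path connects the reads\n")
  }
  invisible(x)
}

# seed the contig prefix on the reference and extend each seed match
# rightward; the placement with the longest exact extension wins and must be
# unique. Returns c(ls, k): 0-based match start and extension length.
anchor_prefix <- function(contig, ref, refdna, min_anchor) {
  seed <- substr(contig, 1L, min_anchor)
  hits <- Biostrings::matchPattern(seed, refdna)
  if (length(hits) == 0L) {
    stop("contig prefix does not anchor on the reference", call. = FALSE)
  }
  L <- nchar(contig); n <- nchar(ref)
  ext <- vapply(BiocGenerics::start(hits) - 1L, function(ls) {
    k <- min_anchor
    while (k < L && ls + k < n &&
           substr(contig, k + 1L, k + 1L) ==
           substr(ref, ls + k + 1L, ls + k + 1L)) {
      k <- k + 1L
    }
    k
  }, integer(1))
  best <- which(ext == max(ext))
  if (length(best) > 1L) {
    stop("contig prefix anchors ambiguously (multi-locus match)",
         call. = FALSE)
  }
  c(BiocGenerics::start(hits)[best] - 1L, max(ext))
}

# mirror image for the contig suffix; extends leftward. Returns c(re, s):
# 0-based exclusive end of the match and extension length.
anchor_suffix <- function(contig, ref, refdna, min_anchor) {
  L <- nchar(contig)
  seed <- substr(contig, L - min_anchor + 1L, L)
  hits <- Biostrings::matchPattern(seed, refdna)
  if (length(hits) == 0L) {
    stop("contig suffix does not anchor on the reference", call. = FALSE)
  }
  ext <- vapply(BiocGenerics::end(hits), function(re) { # re 0-based exclusive
    s <- min_anchor
    while (s < L && re - s > 0L &&
           substr(contig, L - s, L - s) == substr(ref, re - s, re - s)) {
      s <- s + 1L
    }
    s
  }, integer(1))
  best <- which(ext == max(ext))
  if (length(best) > 1L) {
    stop("contig suffix anchors ambiguously (multi-locus match)",
         call. = FALSE)
  }
  c(BiocGenerics::end(hits)[best], max(ext))
}

#' Characterise a deletion from an assembled junction contig
#'
#' Anchors the contig on the reference by its maximal exact prefix and
#' suffix matches (each seeded by a unique `min_anchor`-base exact match),
#' derives the deleted interval, any inserted bases between the anchors, and
#' the microhomology (the length of identical flank sequence over which the
#' breakpoint can slide). The reported interval is left-aligned: the
#' breakpoint is shifted maximally leftward through identical flanking
#' bases, on the contig evidence and then on the reference itself.
#'
#' @param contig Junction contig sequence (string) or a
#'   `"junction_assembly"` result.
#' @param reference A [reference_seq()].
#' @param min_anchor Minimum exact anchor length on each side (default 20).
#' @return An object of class `"deletion_call"`: list with
#'   `deleted_interval` (0-based half-open `c(start, end)`), `length`,
#'   `inserted_sequence`, `microhomology_len`, `classification`
#'   (`clean`/`with_insertion`/`with_duplication`), `contig`,
#'   `reference_name`, `support`.
#' @examples
#' ref <- reference_seq("r", "AAAACGTTTT")
#' call_deletion("AAAATTTT", ref, min_anchor = 3)
#' @export
call_deletion <- function(contig, reference, min_anchor = 20L) {
  support <- NA_integer_
  if (inherits(contig, "junction_assembly")) {
    if (!contig$success) stop("assembly failed; no contig to place",
                              call. = FALSE)
    support <- contig$support
    contig <- contig$contig
  }
  stopifnot(inherits(reference, "reference_seq"))
  min_anchor <- as.integer(min_anchor)
  L <- nchar(contig)
  if (L < 2L * min_anchor) {
    stop("contig shorter than twice 'min_anchor'", call. = FALSE)
  }
  ref <- reference$sequence
  refdna <- Biostrings::DNAString(ref)
  left <- anchor_prefix(contig, ref, refdna, min_anchor)
  ls <- left[1]; k <- left[2]
  right <- anchor_suffix(contig, ref, refdna, min_anchor)
  re <- right[1]; s <- right[2]
  m <- L - s # contig start of maximal suffix match (0-based)
  if (k >= m) {
    homology <- k - m
    inserted <- ""
    p <- m # leftmost junction placement on the contig
  } else {
    homology <- 0L
    inserted <- substr(contig, k + 1L, m)
    p <- k
  }
  del_start <- ls + p              # 0-based
  del_end <- re - (L - p) + nchar(inserted)
  if (del_end <= del_start) {
    # contig shows more reference sequence than the anchors allow: a
    # duplicated flank rather than a simple deletion
    return(structure(
      list(deleted_interval = c(NA_integer_, NA_integer_), length = NA_integer_,
           inserted_sequence = inserted, microhomology_len = homology,
           classification = "with_duplication", contig = contig,
           reference_name = reference$name, support = support),
      class = "deletion_call"))
  }
  # left-align through identical flanking bases on the reference, then
  # measure the total sliding freedom (microhomology) rightward from the
  # canonical placement: deleting [a+1, b+1) leaves the same allele as
  # [a, b) whenever ref[a] == ref[b] (0-based)
  if (inserted == "") {
    while (del_start > 0L &&
           substr(ref, del_start, del_start) ==
           substr(ref, del_end, del_end)) {
      del_start <- del_start - 1L
      del_end <- del_end - 1L
    }
    homology <- 0L
    while (del_end + homology < reference$length &&
           substr(ref, del_start + homology + 1L, del_start + homology + 1L) ==
           substr(ref, del_end + homology + 1L, del_end + homology + 1L)) {
      homology <- homology + 1L
    }
  }
  structure(
    list(deleted_interval = c(del_start, del_end),
         length = del_end - del_start,
         inserted_sequence = inserted,
         microhomology_len = as.integer(homology),
         classification = if (inserted == "") "clean" else "with_insertion",
         contig = contig, reference_name = reference$name, support = support),
    class = "deletion_call"
  )
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> %s: [%s, %s) on %s (%s bp), %s\n",
              x$classification,
              format(x$deleted_interval[1]), format(x$deleted_interval[2]),
              x$reference_name, format(x$length),
              if (nzchar(x$inserted_sequence))
                sprintf("inserted '%s'", x$inserted_sequence)
              else sprintf("microhomology %d bp", x$microhomology_len)))
  invisible(x)
}

#' Compare two deletion calls for identity
#'
#' Two calls are identical when they share the deleted interval, the
#' inserted sequence, and the junction-window sequence of the rearranged
#' allele (`window` bases on each side of the junction, reconstructed from
#' the reference and the call). Used to establish that independent mutant
#' accessions carry one and the same deletion event.
#'
#' @param call_a,call_b `"deletion_call"` objects on the same reference.
#' @param reference The shared [reference_seq()].
#' @param window Junction context half-width in bases (default 200).
#' @return List with `identical` (logical) and `mismatches` (character
#'   vector describing each disagreement, empty when identical).
#' @export
junctions_identical <- function(call_a, call_b, reference, window = 200L) {
  if (!identical(call_a$reference_name, call_b$reference_name)) {
    stop("calls are on different references; not comparable", call. = FALSE)
  }
  junction_context <- function(call) {
    a <- call$deleted_interval[1]; b <- call$deleted_interval[2]
    left <- substr(reference$sequence, max(1L, a - window + 1L), a)
    right <- substr(reference$sequence, b + 1L,
                    min(reference$length, b + window))
    paste0(left, call$inserted_sequence, right)
  }
  mism <- character(0)
  if (!identical(call_a$deleted_interval, call_b$deleted_interval)) {
    mism <- c(mism, sprintf("deleted interval [%d,%d) vs [%d,%d)",
                            call_a$deleted_interval[1], call_a$deleted_interval[2],
                            call_b$deleted_interval[1], call_b$deleted_interval[2]))
  }
  if (!identical(call_a$inserted_sequence, call_b$inserted_sequence)) {
    mism <- c(mism, "inserted sequences differ")
  }
  if (!length(mism)) {
    ca <- junction_context(call_a); cb <- junction_context(call_b)
    if (!identical(ca, cb)) {
      pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])[1]
      mism <- c(mism, sprintf("junction window differs at offset %d", pos))
    }
  }
  list(identical = length(mism) == 0L, mismatches = mism)
}

#' Difference two complete alleles of the same locus
#'
#' Convenience wrapper treating one whole allele sequence (e.g. a deposited
#' mutant haplotype) as the junction contig and calling [call_deletion()]
#' against the wild-type sequence.
#'
#' @param wildtype,mutant [reference_seq()] objects or plain sequences.
#' @param min_anchor Anchor length passed to [call_deletion()].
#' @return A `"deletion_call"`.
#' @export
diff_alleles <- function(wildtype, mutant, min_anchor = 20L) {
  if (!inherits(wildtype, "reference_seq")) {
    wildtype <- reference_seq("wildtype", wildtype)
  }
  if (inherits(mutant, "reference_seq")) mutant <- mutant$sequence
  call_deletion(mutant, wildtype, min_anchor = min_anchor)
}

#' In-silico PCR amplicon prediction
#'
#' Finds plus-strand matches of the forward primer and downstream matches of
#' the reverse complement of the reverse primer, and reports every amplicon
#' no longer than `max_amplicon`. Amplicon length includes both primer
#' footprints. Strand logic is plus-strand only; no thermodynamics.
#'
#' @param template Template sequence (string or [reference_seq()]).
#' @param forward_primer,reverse_primer Primer sequences, at least 15 bases.
#' @param max_amplicon Maximum reportable product length (default 3000,
#'   roughly the limit of standard PCR).
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return Data.frame with columns `start`, `end` (0-based half-open
#'   amplicon footprint) and `length`; zero rows when nothing amplifies.
#' @examples
#' insilico_pcr(paste0("GATTACAGATTACAGG", strrep("A", 100),
#'                     "CCTGTAATCTGTAATC"),
#'              "GATTACAGATTACAGG", "GATTACAGATTACAGG")
#' @export
insilico_pcr <- function(template, forward_primer, reverse_primer,
                         max_amplicon = 3000L, max_mismatch = 0L) {
  if (inherits(template, "reference_seq")) template <- template$sequence
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  if (nchar(forward_primer) < 15L || nchar(reverse_primer) < 15L) {
    stop("primers must be at least 15 bases", call. = FALSE)
  }
  tdna <- Biostrings::DNAString(toupper(template))
  fw <- Biostrings::matchPattern(forward_primer, tdna,
                                 max.mismatch = max_mismatch)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(reverse_primer)))
  rv <- Biostrings::matchPattern(rc, tdna, max.mismatch = max_mismatch)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (length(fw) == 0L || length(rv) == 0L) return(empty)
  fs <- BiocGenerics::start(fw) - 1L # 0-based amplicon starts
  re <- BiocGenerics::end(rv)        # 0-based exclusive ends
  out <- do.call(rbind, lapply(fs, function(f) {
    ok <- re - f >= nchar(forward_primer) + nchar(reverse_primer) &
      re - f <= max_amplicon &
      (re - nchar(rc)) >= f + nchar(forward_primer) # primers do not overlap
    if (!any(ok)) return(NULL)
    data.frame(start = f, end = re[ok], length = re[ok] - f)
  }))
  if (is.null(out)) empty else out[order(out$start, out$end), , drop = FALSE]
}

#' Run the full deletion-discovery pipeline
#'
#' Chains [depth_profile()], [detect_gaps()], [collect_junction_reads()],
#' [assemble_junction()] and [call_deletion()]. The largest detected gap is
#' pursued.
#'
#' @param alignments An [aligned_reads()] table.
#' @param reference A [reference_seq()].
#' @param max_internal_depth,min_gap_len,max_spike_len See [detect_gaps()].
#' @param min_clip,window See [collect_junction_reads()].
#' @param min_overlap,max_mismatch See [assemble_junction()].
#' @param min_anchor See [call_deletion()].
#' @return List with `depth`, `gaps`, `junction_reads`, `assembly` and
#'   `call` (`NULL` at the first stage that yields nothing).
#' @export
detect_deletion <- function(alignments, reference, max_internal_depth = 2L,
                            min_gap_len = 100L, max_spike_len = 500L,
                            min_clip = 10L, window = 5L, min_overlap = 20L,
                            max_mismatch = 0L, min_anchor = 20L) {
  depth <- depth_profile(alignments, reference)
  gaps <- detect_gaps(depth, max_internal_depth, min_gap_len, max_spike_len)
  out <- list(depth = depth, gaps = gaps, junction_reads = NULL,
              assembly = NULL, call = NULL)
  if (nrow(gaps) == 0L) return(out)
  gap <- gaps[which.max(gaps$length), , drop = FALSE]
  jr <- collect_junction_reads(alignments, gap, min_clip, window)
  out$junction_reads <- jr
  if (nrow(jr) < 2L) return(out)
  asm <- assemble_junction(jr, min_overlap, max_mismatch)
  out$assembly <- asm
  if (!asm$success) return(out)
  out$call <- call_deletion(asm, reference, min_anchor)
  out
}
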