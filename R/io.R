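#' Read a reference sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return A [reference_seq()].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path, call. = FALSE)
  reference_seq(sub("\\s.*$", "", names(x)[1]), as.character(x[[1]]))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a [reference_seq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "reference_seq")) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Emits a minimal single-reference SAM file: mandatory header, flag 0,
#' MAPQ 60, CIGAR of the form `[pS] nM [pS]` encoding the soft clips, and
#' placeholder qualities.
#'
#' @param alignments An [aligned_reads()] table.
#' @param reference A [reference_seq()] (for the `@SQ` header line).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", reference$name, reference$length))
  body <- character(0)
  if (nrow(alignments)) {
    aligned_len <- alignments$ref_end - alignments$ref_start
    cigar <- paste0(
      ifelse(alignments$clip_prefix > 0,
             paste0(alignments$clip_prefix, "S"), ""),
      aligned_len, "M",
      ifelse(alignments$clip_suffix > 0,
             paste0(alignments$clip_suffix, "S"), ""))
    body <- paste(alignments$read_id, 0L, reference$name,
                  alignments$ref_start + 1L, 60L, cigar, "*", 0L, 0L,
                  alignments$seq, strrep("I", nchar(alignments$seq)),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read single-end alignments from SAM (or BAM)
#'
#' SAM input is converted with [Rsamtools::asBam()] and scanned; soft-clip
#' lengths come from the CIGAR string and the aligned span from the
#' CIGAR reference width, so M/I/D/N operations are handled. Unmapped
#' records are dropped.
#'
#' @param path SAM or BAM file.
#' @param reference Optional [reference_seq()] for bounds validation.
#' @return An [aligned_reads()] table.
#' @export
read_sam_alignments <- function(path, reference = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "pos", "cigar", "seq")))[[1]]
  keep <- !is.na(res$pos) & !bitwAnd(res$flag, 4L)
  qname <- res$qname[keep]
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  seq <- as.character(res$seq[keep])
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  clip_of <- function(pattern) {
    m <- regexpr(pattern, cigar)
    out <- integer(length(cigar))
    out[m > 0] <- as.integer(sub("S", "", regmatches(cigar, m)))
    out
  }
  clip_p <- clip_of("^[0-9]+S")
  clip_s <- clip_of("[0-9]+S$")
  aligned_reads(qname, pos - 1L, pos - 1L + ref_width, clip_p, clip_s, seq,
                reference = reference)
}

#' Write a deletion call as a minimal VCF record
#'
#' One symbolic `<DEL>` record in VCF 4.2: POS is the 1-based base
#' preceding the deletion, INFO carries SVTYPE, END (1-based last deleted
#' base), SVLEN (negative), HOMLEN and, when present, INSSEQ.
#'
#' @param call A `"deletion_call"`.
#' @param reference The [reference_seq()] the call was made on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(call, reference, path) {
  if (is.na(call$deleted_interval[1])) {
    stop("cannot write a VCF record for a call without an interval",
         call. = FALSE)
  }
  a <- call$deleted_interval[1]; b <- call$deleted_interval[2]
  pos <- a # 1-based position of the base before the deletion (0-based a - 1)
  ref_base <- if (a > 0) substr(reference$sequence, a, a) else "N"
  info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=%d;HOMLEN=%d", b,
                  -(b - a), call$microhomology_len)
  if (nzchar(call$inserted_sequence)) {
    info <- paste0(info, ";INSSEQ=", call$inserted_sequence)
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$name, reference$length),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based end of the deleted interval\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length (negative)\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Breakpoint microhomology length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence at the junction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t<DEL>\t.\tPASS\t%s", reference$name,
            max(pos, 1L), ref_base, info)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read cross-family count tables
#'
#' Delimited text, one row per family, with columns `family_id`,
#' `generation`, `class_labels`, `observed`, `ratio`; `class_labels`,
#' `observed` and `ratio` are `;`-separated lists (e.g. `"48;10"` and
#' `"3;1"`). Extra columns are preserved as attributes on each family.
#'
#' @param path CSV file path.
#' @return List of lists, each with `family` ([cross_family()]) and
#'   `hypothesis` ([ratio_hypothesis()]).
#' @export
read_cross_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("family_id", "generation", "class_labels", "observed", "ratio")
  if (!all(req %in% names(df))) {
    stop("cross table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  split_num <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  split_chr <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]
  lapply(seq_len(nrow(df)), function(i) {
    labs <- split_chr(df$class_labels[i])
    list(family = cross_family(df$family_id[i], df$generation[i],
                               split_num(df$observed[i]), labs),
         hypothesis = ratio_hypothesis(split_num(df$ratio[i]),
                                       class_labels = labs),
         meta = df[i, setdiff(names(df), req), drop = FALSE])
  })
}

#' Segregation results table for a set of families
#'
#' Runs [chi_square_gof()] on every (family, hypothesis) pair from
#' [read_cross_table()] input and mirrors the layout of published
#' segregation tables: observed counts, expected ratio, chi-square, p-value
#' and a significance mark.
#'
#' @param entries Output of [read_cross_table()], or a list of lists with
#'   `family` and `hypothesis` elements.
#' @param alpha Significance level for the mark.
#' @return Data.frame with one row per family.
#' @export
segregation_table <- function(entries, alpha = 0.05) {
  rows <- lapply(entries, function(e) {
    r <- chi_square_gof(e$family, e$hypothesis, alpha)
    data.frame(family_id = e$family$family_id,
               generation = e$family$generation,
               observed = paste(e$family$observed, collapse = ":"),
               expected_ratio = e$hypothesis$name,
               chi_square = r$statistic, df = r$df, p_value = r$p_value,
               significance = if (r$significant) "*" else "ns",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bundled segregation counts for the seedless-trait crosses
#'
#' The observed class counts of the published cross families: phenotypic
#' seed presence/absence (assay `"phenotypic"`), dominant wild-type-specific
#' marker presence/absence (`"dominant"`), and codominant genotype classes
#' (`"codominant"`). For the codominant backcross rows only the two
#' segregating genotype classes are carried (the third class has expected
#' count zero and is not testable).
#'
#' @return The raw data.frame (see [read_cross_table()] for the layout).
#' @export
ino_segregation_counts <- function() {
  path <- system.file("extdata", "segregation_counts.csv", package = "inodel",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read progeny genotype/phenotype records
#'
#' Delimited text with columns `plant_id`, `generation`, `genotype`,
#' `phenotype` (see [count_informative_chromosomes()] for the level sets).
#'
#' @param path CSV file path.
#' @return Data.frame of progeny records.
#' @export
read_progeny_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plant_id", "generation", "genotype", "phenotype")
  if (!all(req %in% names(df))) {
    stop("progeny records must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a binary SSR band matrix
#'
#' Delimited text, genotypes in rows (first column = genotype id), bands in
#' columns, entries 0/1.
#'
#' @param path CSV file path.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  band_matrix(as.matrix(df))
}
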