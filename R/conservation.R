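# Per-column conservation of a multiple sequence alignment: residue
# frequencies, information content in bits, and a qualitative category for
# the reference residue at a mutated position.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an alignment object
#'
#' @param sequences character vector of equal-length aligned sequences
#'   (20 canonical residues plus gap; `.` is normalized to `-` and the
#'   ambiguity codes B/Z/X are treated as gaps).
#' @param ids sequence labels.
#' @param target_index which row is the reference (target) sequence.
#' @return An object of class `msa_alignment`.
#' @export
msa_alignment <- function(sequences, ids = NULL, target_index = 1) {
  if (length(sequences) < 1)
    stop_vuscope("alignment needs at least one sequence",
                 class = "vuscope_format_error")
  sequences <- toupper(sequences)
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  sequences <- gsub("[BZX]", "-", sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop_vuscope("ragged alignment: sequence lengths %s",
                 paste(unique(lens), collapse = ", "),
                 class = "vuscope_format_error")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  stopifnot(target_index >= 1, target_index <= length(sequences))
  structure(list(sequences = sequences, ids = ids,
                 target_index = target_index),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns (target: %s)\n",
              length(x$sequences), nchar(x$sequences[1]),
              x$ids[x$target_index]))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments (via seqinr) into an
#' [msa_alignment()]. The format is inferred from the file content unless
#' given.
#'
#' @param path alignment file.
#' @param format `"fasta"`, `"clustal"`, or `"auto"`.
#' @param target_index row index of the reference sequence (default 1).
#' @return An [msa_alignment()].
#' @export
parse_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                            target_index = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    if (length(first) == 0)
      stop_vuscope("empty alignment file: %s", path,
                   class = "vuscope_format_error")
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  if (aln$nb < 1)
    stop_vuscope("no sequences in %s", path, class = "vuscope_format_error")
  msa_alignment(unlist(aln$seq), ids = aln$nam, target_index = target_index)
}

#' Write an alignment as FASTA
#'
#' @param aln an [msa_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$sequences), names = aln$ids,
                      file.out = path, nbchar = 60)
  invisible(path)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequences, ""))
}

#' Per-column conservation profile
#'
#' Residue frequencies over the non-gap symbols of one alignment column,
#' with information content `info_bits = log2(20) - H`, where
#' `H = -sum(f * log2 f)` is the Shannon entropy of the frequencies. No
#' small-sample correction is applied unless requested.
#'
#' @param aln an [msa_alignment()].
#' @param column 0-based alignment column index.
#' @param small_sample_correction subtract the Miller-Madow correction
#'   `(20-1)/(2*ln(2)*n)` from the information content (floored at 0)?
#' @return An object of class `conservation_profile` with fields `column`,
#'   `frequencies`, `gap_fraction`, `info_bits`, `ref_residue`, `ref_rank`,
#'   `ref_frequency`, `unreliable` (gap fraction above 0.5).
#' @export
column_profile <- function(aln, column, small_sample_correction = FALSE) {
  m <- aln_matrix(aln)
  if (column < 0 || column >= ncol(m))
    stop_vuscope("column %d outside alignment of width %d", column, ncol(m),
                 class = "vuscope_index_error")
  col <- m[, column + 1]
  isgap <- !(col %in% AA20)
  gap_fraction <- mean(isgap)
  res <- col[!isgap]
  if (length(res) == 0)
    stop_vuscope("column %d is all-gap; profile undefined", column,
                 class = "vuscope_undefined_profile_error")
  f <- table(factor(res, levels = AA20)) / length(res)
  f <- as.numeric(f); names(f) <- AA20
  H <- -sum(ifelse(f > 0, f * log2(f), 0))
  info <- log2(20) - H
  if (small_sample_correction)
    info <- max(0, info - (length(AA20) - 1) / (2 * log(2) * length(res)))
  ref <- m[aln$target_index, column + 1]
  if (ref %in% AA20) {
    ref_freq <- f[[ref]]
    ref_rank <- sum(f > ref_freq) + 1L
  } else {
    ref_freq <- NA_real_; ref_rank <- NA_integer_
  }
  structure(list(column = column, frequencies = f,
                 gap_fraction = gap_fraction, info_bits = info,
                 ref_residue = ref, ref_rank = ref_rank,
                 ref_frequency = ref_freq,
                 unreliable = gap_fraction > 0.5),
            class = "conservation_profile")
}

#' Map a target residue number to its alignment column
#'
#' Residues are numbered 1-based along the ungapped target sequence;
#' alignment columns are 0-based. [column_to_residue()] is the inverse.
#'
#' @param aln an [msa_alignment()].
#' @param residue_number 1-based position in the ungapped target.
#' @return 0-based alignment column index.
#' @export
map_residue_to_column <- function(aln, residue_number) {
  tgt <- strsplit(aln$sequences[aln$target_index], "")[[1]]
  nongap <- which(tgt %in% AA20)
  if (residue_number < 1 || residue_number > length(nongap))
    stop_vuscope("residue %d outside ungapped target of length %d",
                 residue_number, length(nongap),
                 class = "vuscope_index_error")
  nongap[residue_number] - 1L
}

#' @rdname map_residue_to_column
#' @param column 0-based alignment column holding a target residue.
#' @export
column_to_residue <- function(aln, column) {
  tgt <- strsplit(aln$sequences[aln$target_index], "")[[1]]
  if (column < 0 || column >= length(tgt))
    stop_vuscope("column %d outside alignment of width %d", column,
                 length(tgt), class = "vuscope_index_error")
  if (!tgt[column + 1] %in% AA20)
    stop_vuscope("column %d is a gap in the target", column,
                 class = "vuscope_index_error")
  sum(tgt[seq_len(column + 1)] %in% AA20)
}

#' Qualitative conservation category of the reference residue
#'
#' `high` when the reference residue is modal (rank 1) with frequency at or
#' above `high_threshold`; `moderate` when it ranks within `moderate_rank`
#' with frequency at or above `moderate_threshold` (the pattern of a
#' position where another residue predominates but the reference is well
#' represented); otherwise `low`. Cutoffs are calibration choices and are
#' exposed as arguments.
#'
#' @param profile a [column_profile()].
#' @param high_threshold minimum modal frequency for `high` (default 0.80).
#' @param moderate_rank maximum rank for `moderate` (default 3).
#' @param moderate_threshold minimum frequency for `moderate` (default 0.05).
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
conservation_category <- function(profile, high_threshold = 0.80,
                                  moderate_rank = 3,
                                  moderate_threshold = 0.05) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (is.na(profile$ref_rank)) return("low")
  if (profile$ref_rank == 1 && profile$ref_frequency >= high_threshold)
    return("high")
  if (profile$ref_rank <= moderate_rank &&
      profile$ref_frequency >= moderate_threshold)
    return("moderate")
  "low"
}

#' Conservation report for a set of target positions
#'
#' @param aln an [msa_alignment()].
#' @param positions 1-based residue numbers in the ungapped target.
#' @param ... passed to [conservation_category()].
#' @return data.frame with column index, reference residue, top residue and
#'   frequency, reference frequency and rank, gap fraction, information
#'   content (bits) and category per position.
#' @export
conservation_report <- function(aln, positions, ...) {
  rows <- lapply(positions, function(p) {
    col <- map_residue_to_column(aln, p)
    pr <- column_profile(aln, col)
    top <- which.max(pr$frequencies)
    data.frame(residue_number = p, column = col,
               ref_residue = pr$ref_residue,
               ref_frequency = pr$ref_frequency, ref_rank = pr$ref_rank,
               top_residue = names(pr$frequencies)[top],
               top_frequency = pr$frequencies[[top]],
               gap_fraction = pr$gap_fraction,
               info_bits = pr$info_bits,
               category = conservation_category(pr, ...))
  })
  do.call(rbind, rows)
}
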