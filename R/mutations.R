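# Mutation filtering and flank-verified mapping onto protein sequences.
#
# Disease (ClinVar-like) records are kept when strictly labeled pathogenic
# only, supported by at least one review star, and free of conflicting
# interpretations. Non-disease (dbSNP-like) records are kept when validated,
# not withdrawn, free of disease assertions, and common (minor allele
# frequency strictly above 1%). A mutation is mapped onto its protein when
# the transcript flanking sequence (up to 10 residues on each side of the
# mutated position) occurs in the protein sequence at the same position as
# reported on the transcript.

DISEASE_ASSERTION_BLACKLIST <- c(
  "pathogenic", "likely pathogenic", "drug-response",
  "uncertain significance", "other"
)

split_labels <- function(x) {
  lab <- strsplit(tolower(x %||% ""), ";", fixed = TRUE)
  lapply(lab, function(v) trimws(v[nzchar(trimws(v))]))
}

is_missense <- function(records) {
  nzchar(records$wt_aa) & nzchar(records$mut_aa) & records$wt_aa != records$mut_aa
}

dedup_by_position <- function(records) {
  if (nrow(records) == 0) return(records)
  o <- order(records$mutation_id)
  records <- records[o, , drop = FALSE]
  key <- paste(records$protein_id, records$transcript_position, sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Filter disease (ClinVar-like) mutation records
#'
#' Keeps missense records whose clinical significance set is exactly
#' \{pathogenic\}, with at least one review star and no conflicting
#' interpretations. Multiple records at the same (protein, position) are
#' collapsed to the one with the smallest mutation id.
#'
#' @param records Data frame with columns `mutation_id`, `protein_id`,
#'   `transcript_sequence`, `transcript_position`, `wt_aa`, `mut_aa`,
#'   `significance` (`;`-separated labels), `review_stars`, `conflicting`.
#' @return Filtered data frame.
#' @export
filter_disease <- function(records) {
  if (nrow(records) == 0) return(records)
  sig <- split_labels(records$significance)
  strictly_pathogenic <- vapply(sig, function(v) {
    length(v) == 1 && v == "pathogenic"
  }, logical(1))
  keep <- is_missense(records) &
    strictly_pathogenic &
    records$review_stars >= 1 &
    !isTRUE_vec(records$conflicting)
  dedup_by_position(records[keep, , drop = FALSE])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Filter non-disease (dbSNP-like) mutation records
#'
#' Keeps missense records that are validated, not withdrawn, carry no
#' disease-assertion label, and have minor allele frequency strictly above
#' 1%. Records overlapping a disease mutation position are discarded, and
#' positions are de-duplicated.
#'
#' @param records Data frame as in [filter_disease()], plus `validated`,
#'   `withdrawn`, `assertions` (`;`-separated labels) and `maf`.
#' @param disease_positions Data frame with columns `protein_id`, `position`:
#'   the mapped disease mutation positions to exclude.
#' @param maf_threshold Minimum minor allele frequency (strict, default 0.01).
#' @param assertion_blacklist Disease-assertion labels that disqualify a
#'   record.
#' @return Filtered data frame.
#' @export
filter_nondisease <- function(records,
                              disease_positions = NULL,
                              maf_threshold = 0.01,
                              assertion_blacklist = DISEASE_ASSERTION_BLACKLIST) {
  if (nrow(records) == 0) return(records)
  asserts <- split_labels(records$assertions)
  clean <- vapply(asserts, function(v) !any(v %in% assertion_blacklist), logical(1))
  keep <- is_missense(records) &
    isTRUE_vec(records$validated) &
    !isTRUE_vec(records$withdrawn) &
    clean &
    !is.na(records$maf) & records$maf > maf_threshold
  out <- records[keep, , drop = FALSE]
  if (!is.null(disease_positions) && nrow(disease_positions) > 0) {
    dkey <- paste(disease_positions$protein_id, disease_positions$position, sep = "\r")
    okey <- paste(out$protein_id, out$transcript_position, sep = "\r")
    out <- out[!(okey %in% dkey), , drop = FALSE]
  }
  dedup_by_position(out)
}

#' Flanking sequence of a transcript position
#'
#' Returns the mutated position's wild-type residue together with up to 10
#' residues (or all available, whichever is shorter) on each side.
#'
#' @param transcript_sequence Amino-acid string.
#' @param position 1-based position of the mutation.
#' @param flank_len Residues taken on each side (default 10).
#' @return The flank string.
#' @export
flank_of <- function(transcript_sequence, position, flank_len = 10) {
  n <- nchar(transcript_sequence)
  assert_that(position >= 1 && position <= n,
              sprintf("position %d out of range 1..%d", position, n))
  left <- max(1, position - flank_len)
  right <- min(n, position + flank_len)
  substr(transcript_sequence, left, right)
}

#' Map one mutation onto a protein sequence
#'
#' The transcript flank is looked up in the protein sequence; the mutation is
#' mapped if and only if the flank occurs with the wild-type residue at the
#' same position on the protein as reported on the transcript. With
#' `same_position = FALSE` any unique occurrence is accepted and the mapped
#' position is derived from the match (a looser mode for real data with
#' transcript/protein coordinate offsets).
#'
#' @param record One-row data frame (or list) with `transcript_sequence`,
#'   `transcript_position`, `wt_aa`, `protein_id`.
#' @param protein_sequence The protein's amino-acid sequence.
#' @param flank_len Flank length per side (default 10).
#' @param same_position Require the protein position to equal the transcript
#'   position (default TRUE).
#' @return The 1-based protein position, or `NA` when the mutation does not
#'   map.
#' @export
map_mutation <- function(record, protein_sequence, flank_len = 10,
                         same_position = TRUE) {
  pos <- record$transcript_position
  flank <- flank_of(record$transcript_sequence, pos, flank_len)
  left_len <- pos - max(1, pos - flank_len)
  if (same_position) {
    start <- pos - left_len
    if (start < 1 || start + nchar(flank) - 1 > nchar(protein_sequence)) return(NA_integer_)
    hit <- substr(protein_sequence, start, start + nchar(flank) - 1) == flank
    if (!hit) return(NA_integer_)
    # defensive: the flank embeds the wild-type residue at offset left_len
    if (substr(protein_sequence, pos, pos) != record$wt_aa) return(NA_integer_)
    pos
  } else {
    occ <- gregexpr(flank, protein_sequence, fixed = TRUE)[[1]]
    if (occ[1] == -1 || length(occ) != 1) return(NA_integer_)
    as.integer(occ[1] + left_len)
  }
}

#' Map a mutation table onto protein sequences
#'
#' Applies [map_mutation()] to every record; unmappable mutations (missing
#' protein, flank mismatch, shifted position) are dropped and counted.
#'
#' @param records Filtered mutation data frame.
#' @param proteins Named character vector of protein sequences.
#' @param flank_len,same_position Passed to [map_mutation()].
#' @param quiet Suppress the summary message.
#' @return The mapped records with a `protein_position` column; attribute
#'   `n_unmapped` counts discarded records.
#' @export
map_mutations <- function(records, proteins, flank_len = 10,
                          same_position = TRUE, quiet = FALSE) {
  if (nrow(records) == 0) {
    records$protein_position <- integer(0)
    return(records)
  }
  pp <- rep(NA_integer_, nrow(records))
  prot <- unname(proteins[records$protein_id])
  known <- !is.na(prot)
  if (same_position) {
    # vectorised same-position check: the flank starts at the same index on
    # transcript and protein, so one aligned substring comparison suffices
    pos <- records$transcript_position
    tlen <- nchar(records$transcript_sequence)
    ok <- known & pos >= 1 & pos <= tlen
    left <- pmax(1, pos - flank_len)
    right <- pmin(tlen, pos + flank_len)
    flank <- substr(records$transcript_sequence, left, right)
    target <- substr(ifelse(ok, prot, ""), left, left + nchar(flank) - 1)
    hit <- ok & target == flank &
      substr(ifelse(ok, prot, ""), pos, pos) == records$wt_aa
    pp[hit] <- pos[hit]
  } else {
    for (i in seq_len(nrow(records))) {
      if (!known[i]) next
      pp[i] <- map_mutation(records[i, ], prot[i], flank_len, same_position)
    }
  }
  out <- records[!is.na(pp), , drop = FALSE]
  out$protein_position <- pp[!is.na(pp)]
  n_unmapped <- sum(is.na(pp))
  if (!quiet && n_unmapped > 0) {
    message(sprintf("discarded %d unmappable mutation(s)", n_unmapped))
  }
  attr(out, "n_unmapped") <- n_unmapped
  rownames(out) <- NULL
  out
}

#' Write mapped mutations as TSV
#'
#' Columns: `mutation_id`, `protein_id`, `protein_position`, `wt_aa`,
#' `mut_aa`, `mutation_class`.
#'
#' @param mapped Mapped mutation table from [map_mutations()].
#' @param path Output file.
#' @export
write_mapped_mutations <- function(mapped, path) {
  df <- mapped[, c("mutation_id", "protein_id", "protein_position",
                   "wt_aa", "mut_aa", "mutation_class")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
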