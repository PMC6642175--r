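# Serialization of synthetic worlds and pipeline tables.
#
# Structures are written as minimal PDB-dialect files (ATOM records only,
# 1-based residue numbers equal to the SEQRES index), sequences as FASTA,
# tabular inputs as TSV, and the ground truth as a JSON sidecar.

write_chain_pdbs <- function(chains, dir) {
  sids <- vapply(chains, function(ch) ch$structure_id, character(1))
  for (sid in unique(sids)) {
    grp <- chains[sids == sid]
    at <- do.call(rbind, lapply(grp, function(ch) {
      cbind(ch$atoms, chain = ch$chain_id, stringsAsFactors = FALSE)
    }))
    xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
    bio3d::write.pdb(file = file.path(dir, paste0(sid, ".pdb")),
                     xyz = round(xyz, 3),
                     resno = at$resno,
                     resid = bio3d::aa123(at$aa),
                     elety = at$elety,
                     chain = at$chain,
                     eleno = seq_len(nrow(at)))
  }
  invisible(dir)
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

pairs_to_token <- function(p) {
  paste(sprintf("%d:%d", p[, 1], p[, 2]), collapse = ",")
}

token_to_pairs <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) {
    return(cbind(protein_position = integer(0), chain_position = integer(0)))
  }
  parts <- strsplit(strsplit(tok, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("protein_position", "chain_position")
  m
}

#' Write alignment hits as TSV
#'
#' Columns: protein_id, structure_id, chain_id, evalue, pairs — the aligned
#' (protein, chain) position columns serialized as comma-separated `p:q`
#' tokens.
#'
#' @param hits Alignment hit table (with a `pairs` list-column).
#' @param path Output file.
#' @export
write_alignment_hits <- function(hits, path) {
  df <- hits[, c("protein_id", "structure_id", "chain_id", "evalue")]
  df$pairs <- vapply(hits$pairs, pairs_to_token, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignment hits written by [write_alignment_hits()]
#' @param path TSV file.
#' @return Alignment hit table with a `pairs` list-column.
#' @export
read_alignment_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pairs = "character"))
  pairs <- lapply(df$pairs, token_to_pairs)
  df$pairs <- NULL
  df$pairs <- pairs
  df
}

#' Write a synthetic world to a directory
#'
#' Layout: `structures/<id>.pdb`, `proteins.fasta`, `chain_seqres.fasta`
#' (names `<structure>_<chain>`), `interactome.tsv`, `alignments.tsv`,
#' `mutations.tsv`, `ddg.tsv`, `go_terms.tsv`, `go_annotations.tsv`,
#' `expression.tsv`, and `truth.json`.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  write_chain_pdbs(world$chains, file.path(dir, "structures"))
  write_fasta(world$proteins, file.path(dir, "proteins.fasta"))
  seqres <- vapply(world$chains, function(ch) ch$seqres, character(1))
  names(seqres) <- vapply(world$chains, function(ch) {
    paste0(ch$structure_id, "_", ch$chain_id)
  }, character(1))
  write_fasta(seqres, file.path(dir, "chain_seqres.fasta"))
  utils::write.table(cbind(world$edges,
                           structure_id = world$structures$structure_id),
                     file.path(dir, "interactome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_alignment_hits(world$alignments, file.path(dir, "alignments.tsv"))
  utils::write.table(world$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$ddg_table, file.path(dir, "ddg.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$go_terms, file.path(dir, "go_terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(world$go_annotations, file.path(dir, "go_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(protein_id = rownames(world$expression),
                                world$expression, check.names = FALSE),
                     file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a synthetic world directory back into memory
#'
#' Chains are re-parsed from the PDB-dialect files through [parse_chain()],
#' so a written-and-reread world exercises the same input path as any
#' externally supplied data.
#'
#' @param dir Directory written by [write_world()].
#' @return A list with the same tabular components as a `synthetic_world`
#'   (`proteins`, `edges`, `chains`, `alignments`, `mutations`, `ddg_table`,
#'   `go_terms`, `go_annotations`, `expression`, `truth`).
#' @export
read_world <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  seqres <- read_fasta(file.path(dir, "chain_seqres.fasta"))
  edges <- utils::read.delim(file.path(dir, "interactome.tsv"),
                             stringsAsFactors = FALSE)
  chains <- list()
  for (key in names(seqres)) {
    sid <- sub("_[^_]+$", "", key)
    cid <- sub("^.*_", "", key)
    chains[[key]] <- parse_chain(file.path(dir, "structures", paste0(sid, ".pdb")),
                                 sid, cid, seqres[[key]], quiet = TRUE)
  }
  expr_df <- utils::read.delim(file.path(dir, "expression.tsv"),
                               check.names = FALSE, stringsAsFactors = FALSE)
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$protein_id
  list(
    proteins = proteins,
    edges = edges[, c("ppi_id", "protein_a", "protein_b")],
    structures = edges[, c("ppi_id", "structure_id")],
    chains = chains,
    alignments = read_alignment_hits(file.path(dir, "alignments.tsv")),
    mutations = utils::read.delim(file.path(dir, "mutations.tsv"),
                                  stringsAsFactors = FALSE),
    ddg_table = utils::read.delim(file.path(dir, "ddg.tsv"),
                                  stringsAsFactors = FALSE),
    go_terms = utils::read.delim(file.path(dir, "go_terms.tsv"),
                                 stringsAsFactors = FALSE,
                                 na.strings = ""),
    go_annotations = utils::read.delim(file.path(dir, "go_annotations.tsv"),
                                       stringsAsFactors = FALSE),
    expression = expression,
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  )
}
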