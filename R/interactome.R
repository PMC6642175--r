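# Structural interactome construction.
#
# A reference interactome edge list plus protein-to-chain alignment hits is
# turned into a structural interactome: every retained PPI carries binding
# interface residues expressed in protein sequence coordinates, obtained by
# mapping chain-pair interfaces through the alignments.
#
# Filter chain (applied in this order):
#   1. alignment hits above the E-value cutoff (default 1e-10) are dropped;
#   2. per (protein, structure, chain) only the smallest-E-value hit is kept;
#   3. a candidate chain-pair annotation requires a nonempty chain-pair
#      interface and >= 50% of each chain's interface residues mapped onto
#      the corresponding protein;
#   4. at most 5 annotations per PPI, those with the smallest joint E-values
#      (product of the two hits' E-values), are retained; the PPI interface is
#      the union of their mapped residues. PPIs with no surviving annotation
#      are discarded.

#' Filter alignment hits
#'
#' Removes hits with E-value above the cutoff, then keeps exactly one hit per
#' (protein, structure, chain): the one with the smallest E-value, ties broken
#' by the longest alignment and then by input order.
#'
#' @param hits Data frame with columns `protein_id`, `structure_id`,
#'   `chain_id`, `evalue` and a list-column `pairs` of two-column integer
#'   matrices (protein position, chain SEQRES position), strictly increasing
#'   on both sides.
#' @param evalue_cutoff Maximum E-value retained (default `1e-10`).
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-10) {
  if (nrow(hits) == 0) return(hits)
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  len <- vapply(h$pairs, nrow, integer(1))
  o <- order(h$protein_id, h$structure_id, h$chain_id, h$evalue, -len)
  h <- h[o, , drop = FALSE]
  key <- paste(h$protein_id, h$structure_id, h$chain_id, sep = "\r")
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  h
}

map_chain_interface <- function(pairs, chain_interface) {
  mapped_chain <- intersect(chain_interface, pairs[, "chain_position"])
  list(
    coverage = if (length(chain_interface) == 0) 0
               else length(mapped_chain) / length(chain_interface),
    protein_positions = sort(pairs[match(mapped_chain, pairs[, "chain_position"]),
                                   "protein_position"])
  )
}

#' Annotate one PPI with chain-pair structural templates
#'
#' Enumerates candidate chain pairs (one chain aligned to each protein of the
#' PPI, both chains in the same structure, nonempty chain-pair interface),
#' requires at least half of each chain's interface residues to be mapped onto
#' the protein, keeps at most `max_annotations` candidates with the smallest
#' joint E-values, and returns the union of their mapped interfaces.
#'
#' For a self-interaction (`protein_a == protein_b`) both chains are evaluated
#' against the same protein and the interface is the union of both sides'
#' images.
#'
#' @param protein_a,protein_b Protein identifiers of the PPI.
#' @param hits Filtered alignment hits (see [filter_hits()]).
#' @param catalog Interface catalog from [interface_catalog()].
#' @param min_coverage Minimum fraction of chain interface residues mapped
#'   (default 0.5, applied as `>=`).
#' @param max_annotations Maximum chain-pair annotations retained (default 5).
#' @return A `structural_ppi` object, or `NULL` when no candidate survives.
#' @export
annotate_ppi <- function(protein_a, protein_b, hits, catalog,
                         min_coverage = 0.5, max_annotations = 5) {
  homodimer <- identical(protein_a, protein_b)
  ha <- hits[hits$protein_id == protein_a, , drop = FALSE]
  hb <- hits[hits$protein_id == protein_b, , drop = FALSE]
  if (nrow(ha) == 0 || nrow(hb) == 0) return(NULL)

  cand <- list()
  for (sid in intersect(unique(ha$structure_id), unique(hb$structure_id))) {
    sa <- ha[ha$structure_id == sid, , drop = FALSE]
    sb <- hb[hb$structure_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(sa))) {
      for (j in seq_len(nrow(sb))) {
        ca <- sa$chain_id[i]; cb <- sb$chain_id[j]
        if (identical(ca, cb)) next
        if (homodimer && ca > cb) next  # count each unordered pair once
        ip <- catalog_lookup(catalog, sid, ca, cb)
        if (is.null(ip)) {
          stop(sprintf("no interface record for chains %s:%s of structure %s",
                       ca, cb, sid), call. = FALSE)
        }
        if (length(ip$interface_a) == 0) next
        ma <- map_chain_interface(sa$pairs[[i]], ip$interface_a)
        mb <- map_chain_interface(sb$pairs[[j]], ip$interface_b)
        if (ma$coverage < min_coverage || mb$coverage < min_coverage) next
        cand[[length(cand) + 1]] <- list(
          structure_id = sid, chain_a = ca, chain_b = cb,
          joint_evalue = sa$evalue[i] * sb$evalue[j],
          coverage_a = ma$coverage, coverage_b = mb$coverage,
          mapped_a = ma$protein_positions, mapped_b = mb$protein_positions
        )
      }
    }
  }
  if (length(cand) == 0) return(NULL)

  ann <- data.frame(
    structure_id = vapply(cand, `[[`, character(1), "structure_id"),
    chain_a = vapply(cand, `[[`, character(1), "chain_a"),
    chain_b = vapply(cand, `[[`, character(1), "chain_b"),
    joint_evalue = vapply(cand, `[[`, numeric(1), "joint_evalue"),
    coverage_a = vapply(cand, `[[`, numeric(1), "coverage_a"),
    coverage_b = vapply(cand, `[[`, numeric(1), "coverage_b"),
    stringsAsFactors = FALSE
  )
  o <- order(ann$joint_evalue, ann$structure_id, ann$chain_a, ann$chain_b)
  keep <- o[seq_len(min(max_annotations, length(o)))]
  ann <- ann[keep, , drop = FALSE]
  rownames(ann) <- NULL
  iface_a <- sort(unique(unlist(lapply(cand[keep], `[[`, "mapped_a"))))
  iface_b <- sort(unique(unlist(lapply(cand[keep], `[[`, "mapped_b"))))
  if (homodimer) {
    iface_a <- iface_b <- sort(unique(c(iface_a, iface_b)))
  }
  structure(
    list(protein_a = protein_a, protein_b = protein_b,
         interface_a = iface_a, interface_b = iface_b,
         annotations = ann),
    class = "structural_ppi"
  )
}

#' @export
print.structural_ppi <- function(x, ...) {
  cat(sprintf("<structural_ppi> %s:%s — interfaces %d/%d residues, %d annotation(s)\n",
              x$protein_a, x$protein_b, length(x$interface_a),
              length(x$interface_b), nrow(x$annotations)))
  invisible(x)
}

#' Build a structural interactome
#'
#' Applies the full filter chain ([filter_hits()] then [annotate_ppi()]) to
#' every edge of a reference interactome; edges with no surviving chain-pair
#' annotation are discarded.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b` (optionally
#'   `ppi_id`; generated when absent).
#' @param hits Alignment hit table (unfiltered; the E-value filter is applied
#'   here).
#' @param catalog Interface catalog from [interface_catalog()].
#' @param evalue_cutoff,min_coverage,max_annotations Filter parameters.
#' @param quiet Suppress the summary message.
#' @return Object of class `structural_interactome`: a named list of
#'   `structural_ppi` (keyed by `ppi_id`) with attributes `n_edges_in` and
#'   `n_resolved`.
#' @export
build_structural_interactome <- function(edges, hits, catalog,
                                         evalue_cutoff = 1e-10,
                                         min_coverage = 0.5,
                                         max_annotations = 5,
                                         quiet = FALSE) {
  assert_that(is.data.frame(edges) && all(c("protein_a", "protein_b") %in% names(edges)),
              "edges must be a data.frame with columns protein_a, protein_b")
  if (is.null(edges$ppi_id)) edges$ppi_id <- sprintf("PPI%04d", seq_len(nrow(edges)))
  fh <- filter_hits(hits, evalue_cutoff)
  out <- list()
  for (i in seq_len(nrow(edges))) {
    sp <- annotate_ppi(edges$protein_a[i], edges$protein_b[i], fh, catalog,
                       min_coverage = min_coverage,
                       max_annotations = max_annotations)
    if (!is.null(sp)) {
      sp$ppi_id <- edges$ppi_id[i]
      out[[edges$ppi_id[i]]] <- sp
    }
  }
  if (!quiet) {
    message(sprintf("structural interactome: %d of %d edges structurally resolved",
                    length(out), nrow(edges)))
  }
  structure(out, class = "structural_interactome",
            n_edges_in = nrow(edges), n_resolved = length(out))
}

#' @export
print.structural_interactome <- function(x, ...) {
  cat(sprintf("<structural_interactome> %d structurally resolved PPIs (from %d edges)\n",
              length(x), attr(x, "n_edges_in") %||% NA))
  invisible(x)
}

#' Expand a structural interactome into a per-position index
#'
#' @param si A `structural_interactome`.
#' @return Data frame with one row per (protein, interface position, PPI):
#'   columns `ppi_id`, `protein_id`, `position`.
#' @export
si_position_index <- function(si) {
  rows <- lapply(si, function(sp) {
    a <- data.frame(ppi_id = sp$ppi_id, protein_id = sp$protein_a,
                    position = sp$interface_a, stringsAsFactors = FALSE)
    b <- data.frame(ppi_id = sp$ppi_id, protein_id = sp$protein_b,
                    position = sp$interface_b, stringsAsFactors = FALSE)
    df <- rbind(a, b)
    df[!duplicated(df), , drop = FALSE]  # self-interactions list each position once
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ppi_id = character(0), protein_id = character(0),
                      position = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Write a structural interactome as TSV
#'
#' Columns: `ppi_id`, `protein_a`, `protein_b`, comma-separated interface
#' positions per side, and the number of retained annotations.
#'
#' @param si A `structural_interactome`.
#' @param path Output file.
#' @export
write_structural_interactome <- function(si, path) {
  df <- data.frame(
    ppi_id = vapply(si, `[[`, character(1), "ppi_id"),
    protein_a = vapply(si, `[[`, character(1), "protein_a"),
    protein_b = vapply(si, `[[`, character(1), "protein_b"),
    interface_a = vapply(si, function(sp) paste(sp$interface_a, collapse = ","), character(1)),
    interface_b = vapply(si, function(sp) paste(sp$interface_b, collapse = ","), character(1)),
    n_annotations = vapply(si, function(sp) nrow(sp$annotations), integer(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structural interactome written by [write_structural_interactome()]
#'
#' @param path TSV file.
#' @return A `structural_interactome` (annotation detail is not round-tripped;
#'   only interface sets and counts are).
#' @export
read_structural_interactome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(interface_a = "character",
                                         interface_b = "character"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[df$ppi_id[i]]] <- structure(
      list(protein_a = df$protein_a[i], protein_b = df$protein_b[i],
           interface_a = as.integer(strsplit(df$interface_a[i], ",")[[1]]),
           interface_b = as.integer(strsplit(df$interface_b[i], ",")[[1]]),
           annotations = data.frame(n = df$n_annotations[i]),
           ppi_id = df$ppi_id[i]),
      class = "structural_ppi"
    )
  }
  structure(out, class = "structural_interactome",
            n_edges_in = NA_integer_, n_resolved = length(out))
}
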