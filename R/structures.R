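# Chain structures and binding-interface geometry.
#
# A binding interface is defined purely geometrically: a residue of one chain
# is an interface residue if the minimum distance between any of its atoms and
# any atom of the partner chain is within a cutoff (5 angstrom by default).

#' Construct a chain structure
#'
#' A `chain_structure` holds one chain's declared backbone sequence (SEQRES)
#' together with per-residue atomic coordinates. Residues whose amino acid
#' does not match the backbone sequence at their declared position are
#' discarded at construction time, mirroring coordinate-vs-SEQRES validation
#' of real structure files.
#'
#' @param structure_id Structure identifier (e.g. a PDB-style code).
#' @param chain_id Chain identifier within the structure.
#' @param seqres Backbone amino-acid sequence (one-letter codes) as a single
#'   string. Residue numbering throughout the package is the 1-based index
#'   into this string; insertion codes are not supported.
#' @param atoms `data.frame` with columns `resno` (1-based SEQRES position),
#'   `aa` (one-letter residue code), `elety` (atom name), `x`, `y`, `z`
#'   (angstrom).
#' @param quiet Suppress the message reporting discarded residues.
#'
#' @return An object of class `chain_structure`: a list with elements
#'   `structure_id`, `chain_id`, `seqres`, `atoms` and `n_discarded`.
#' @export
chain_structure <- function(structure_id, chain_id, seqres, atoms, quiet = FALSE) {
  assert_that(is.character(seqres) && length(seqres) == 1 && nzchar(seqres),
              "seqres must be a non-empty string")
  need <- c("resno", "aa", "elety", "x", "y", "z")
  assert_that(is.data.frame(atoms) && all(need %in% names(atoms)),
              sprintf("atoms must be a data.frame with columns %s",
                      paste(need, collapse = ", ")))
  atoms <- atoms[, need]
  n_res <- nchar(seqres)
  seqres_vec <- strsplit(seqres, "")[[1]]

  in_range <- atoms$resno >= 1 & atoms$resno <= n_res
  matches <- in_range & atoms$aa == seqres_vec[pmax(atoms$resno, 1L)]
  dropped <- unique(atoms$resno[!matches])
  if (length(dropped) > 0 && !quiet) {
    message(sprintf("%s chain %s: discarded %d residue(s) failing SEQRES validation",
                    structure_id, chain_id, length(dropped)))
  }
  atoms <- atoms[matches & !(atoms$resno %in% dropped), , drop = FALSE]
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(
    list(structure_id = structure_id, chain_id = chain_id,
         seqres = seqres, atoms = atoms, n_discarded = length(dropped)),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s chain %s: %d residues with coordinates / %d in SEQRES, %d atoms\n",
              x$structure_id, x$chain_id, length(unique(x$atoms$resno)),
              nchar(x$seqres), nrow(x$atoms)))
  invisible(x)
}

#' Parse one chain from a coordinate file
#'
#' Reads ATOM records from a minimal PDB-dialect file, keeps the first model
#' only, extracts the requested chain, and validates each residue against the
#' supplied backbone sequence; mismatching residues are discarded.
#'
#' @param coordinate_file Path to the coordinate file.
#' @inheritParams chain_structure
#' @param heavy_only Drop hydrogen atoms. By default all atoms present in the
#'   record are used, hydrogens included.
#'
#' @return A [chain_structure()].
#' @export
parse_chain <- function(coordinate_file, structure_id, chain_id, seqres,
                        heavy_only = FALSE, quiet = FALSE) {
  assert_that(file.exists(coordinate_file),
              sprintf("coordinate file not found: %s", coordinate_file))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(coordinate_file, multi = FALSE, verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse coordinate file %s: %s",
                                     coordinate_file, conditionMessage(e)), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) {
    stop(sprintf("chain %s not found in %s", chain_id, coordinate_file), call. = FALSE)
  }
  if (heavy_only) {
    at <- at[at$elesy != "H" & !grepl("^H", at$elety), , drop = FALSE]
  }
  atoms <- data.frame(
    resno = at$resno,
    aa = bio3d::aa321(at$resid),
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  chain_structure(structure_id, chain_id, seqres, atoms, quiet = quiet)
}

#' Minimum inter-atomic distance between two residues
#'
#' The distance between two residues is the minimum over all pairs of one
#' atom from each residue of the Euclidean distance.
#'
#' @param res_a,res_b Matrices (or data.frames) of atom coordinates with
#'   columns x, y, z; one row per atom.
#' @return Distance in angstrom.
#' @export
residue_min_distance <- function(res_a, res_b) {
  a <- as.matrix(as.data.frame(res_a)[, c("x", "y", "z")])
  b <- as.matrix(as.data.frame(res_b)[, c("x", "y", "z")])
  assert_that(nrow(a) >= 1 && nrow(b) >= 1, "both residues must have at least one atom")
  min(cross_dist(a, b))
}

#' Compute the binding interface between two chains
#'
#' A residue of one chain is an interface residue if its minimum atomic
#' distance to any residue of the other chain is within `cutoff` (inclusive).
#'
#' @param chain_a,chain_b [chain_structure()] objects.
#' @param cutoff Distance cutoff in angstrom (default 5).
#'
#' @return An object of class `interface_pair`: list with `structure_id`,
#'   `chain_a`, `chain_b`, and sorted integer vectors `interface_a`,
#'   `interface_b` of 1-based SEQRES positions.
#' @export
compute_interface <- function(chain_a, chain_b, cutoff = 5.0) {
  assert_that(inherits(chain_a, "chain_structure") && inherits(chain_b, "chain_structure"),
              "chain_a and chain_b must be chain_structure objects")
  if (!identical(chain_a$structure_id, chain_b$structure_id)) {
    warning("chains come from different structures; interface computed anyway")
  }
  out <- structure(
    list(structure_id = chain_a$structure_id,
         chain_a = chain_a$chain_id, chain_b = chain_b$chain_id,
         interface_a = integer(0), interface_b = integer(0)),
    class = "interface_pair"
  )
  if (nrow(chain_a$atoms) == 0 || nrow(chain_b$atoms) == 0) {
    warning("empty chain: returning empty interfaces")
    return(out)
  }
  a <- as.matrix(chain_a$atoms[, c("x", "y", "z")])
  b <- as.matrix(chain_b$atoms[, c("x", "y", "z")])
  close <- cross_dist(a, b) <= cutoff
  close_a <- rowSums(close) > 0
  close_b <- colSums(close) > 0
  out$interface_a <- sort(unique(chain_a$atoms$resno[close_a]))
  out$interface_b <- sort(unique(chain_b$atoms$resno[close_b]))
  out
}

#' @export
print.interface_pair <- function(x, ...) {
  cat(sprintf("<interface_pair> %s %s:%s — %d / %d interface residues\n",
              x$structure_id, x$chain_a, x$chain_b,
              length(x$interface_a), length(x$interface_b)))
  invisible(x)
}

#' Compute all chain-pair interfaces of a structure catalog
#'
#' Groups chains by structure and computes the interface for every unordered
#' chain pair within each structure.
#'
#' @param chains List of [chain_structure()] objects.
#' @param cutoff Distance cutoff in angstrom.
#' @return A named list of `interface_pair` objects, keyed
#'   `"<structure_id>|<chain_a>|<chain_b>"` with chain ids in sorted order.
#' @export
interface_catalog <- function(chains, cutoff = 5.0) {
  sids <- vapply(chains, function(ch) ch$structure_id, character(1))
  out <- list()
  for (sid in unique(sids)) {
    grp <- chains[sids == sid]
    cids <- vapply(grp, function(ch) ch$chain_id, character(1))
    grp <- grp[order(cids)]
    cids <- sort(cids)
    if (length(grp) < 2) next
    for (i in seq_len(length(grp) - 1)) {
      for (j in seq(i + 1, length(grp))) {
        ip <- compute_interface(grp[[i]], grp[[j]], cutoff = cutoff)
        out[[paste(sid, cids[i], cids[j], sep = "|")]] <- ip
      }
    }
  }
  out
}

#' Look up an oriented interface pair in a catalog
#'
#' @param catalog Result of [interface_catalog()].
#' @param structure_id,chain_a,chain_b Identify the chain pair; the returned
#'   interface is oriented so that `interface_a` belongs to `chain_a`.
#' @return An `interface_pair` or `NULL` when absent.
#' @export
catalog_lookup <- function(catalog, structure_id, chain_a, chain_b) {
  key <- paste(structure_id, min(chain_a, chain_b), max(chain_a, chain_b), sep = "|")
  ip <- catalog[[key]]
  if (is.null(ip)) return(NULL)
  if (!identical(ip$chain_a, chain_a)) {
    ip <- structure(
      list(structure_id = ip$structure_id, chain_a = ip$chain_b, chain_b = ip$chain_a,
           interface_a = ip$interface_b, interface_b = ip$interface_a),
      class = "interface_pair"
    )
  }
  ip
}

#' Write an interface catalog as TSV
#'
#' One row per interface residue: structure_id, chain_a, chain_b, side
#' (`a` or `b`), position.
#'
#' @param catalog Result of [interface_catalog()].
#' @param path Output file.
#' @export
write_interfaces <- function(catalog, path) {
  rows <- lapply(catalog, function(ip) {
    n_a <- length(ip$interface_a)
    n_b <- length(ip$interface_b)
    if (n_a + n_b == 0) return(NULL)
    data.frame(structure_id = ip$structure_id, chain_a = ip$chain_a,
               chain_b = ip$chain_b,
               side = c(rep("a", n_a), rep("b", n_b)),
               position = c(ip$interface_a, ip$interface_b),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(structure_id = character(0), chain_a = character(0),
                     chain_b = character(0), side = character(0),
                     position = integer(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interface catalog written by [write_interfaces()]
#'
#' @param path TSV file.
#' @return Named list of `interface_pair` objects.
#' @export
read_interfaces <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  key <- paste(df$structure_id, df$chain_a, df$chain_b, sep = "|")
  for (k in unique(key)) {
    sub <- df[key == k, ]
    out[[k]] <- structure(
      list(structure_id = sub$structure_id[1], chain_a = sub$chain_a[1],
           chain_b = sub$chain_b[1],
           interface_a = sort(sub$position[sub$side == "a"]),
           interface_b = sort(sub$position[sub$side == "b"])),
      class = "interface_pair"
    )
  }
  out
}
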