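# Quality-control metrics for a structural interactome: SimGIC functional
# similarity over GO annotations, and tissue co-expression of interacting
# protein pairs.

#' Build a GO annotation object
#'
#' @param terms Data frame with columns `term`, `parent` (`NA` for roots) and
#'   optionally `category` (e.g. BP/MF/CC). A term may have several parents
#'   (one row per parent).
#' @param annotations Data frame with columns `protein_id`, `term`: the
#'   directly annotated terms per protein.
#' @return Object of class `go_annotations` with precomputed ancestor-closed
#'   annotation sets and information content (IC) per term. The IC corpus is
#'   the annotated protein set supplied: IC(t) = -log(fraction of corpus
#'   proteins whose closure contains t); terms carried by every corpus
#'   protein (the roots) thus have IC 0.
#' @export
go_annotations <- function(terms, annotations) {
  assert_that(all(c("term", "parent") %in% names(terms)),
              "terms needs columns term, parent")
  assert_that(all(c("protein_id", "term") %in% names(annotations)),
              "annotations needs columns protein_id, term")
  known <- unique(terms$term)
  bad <- setdiff(unique(annotations$term), known)
  if (length(bad) > 0) {
    stop(sprintf("annotated term(s) absent from the DAG: %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  parents <- split(terms$parent[!is.na(terms$parent)],
                   terms$term[!is.na(terms$parent)])

  closure_env <- new.env(parent = emptyenv())
  closure_of <- function(t) {
    got <- closure_env[[t]]
    if (!is.null(got)) return(got)
    out <- t
    frontier <- parents[[t]]
    while (length(frontier) > 0) {
      if (t %in% frontier) {
        stop("cycle detected in the term DAG", call. = FALSE)
      }
      out <- c(out, frontier)
      nxt <- unique(unlist(parents[frontier], use.names = FALSE))
      if (t %in% nxt) {
        stop("cycle detected in the term DAG", call. = FALSE)
      }
      frontier <- setdiff(nxt, out)
    }
    out <- unique(out)
    closure_env[[t]] <- out
    out
  }
  term_closures <- lapply(stats::setNames(known, known), closure_of)

  prot_terms <- split(annotations$term, annotations$protein_id)
  prot_closures <- lapply(prot_terms, function(ts) {
    unique(unlist(term_closures[unique(ts)], use.names = FALSE))
  })
  n_prot <- length(prot_closures)
  counts <- table(unlist(prot_closures, use.names = FALSE))
  ic <- stats::setNames(rep(Inf, length(known)), known)
  ic[names(counts)] <- -log(as.numeric(counts) / n_prot)
  ic[ic < 0] <- 0

  categories <- if ("category" %in% names(terms)) {
    stats::setNames(terms$category, terms$term)[known]
  } else {
    stats::setNames(rep("all", length(known)), known)
  }
  structure(list(closures = prot_closures, ic = ic, categories = categories,
                 term_closures = term_closures),
            class = "go_annotations")
}

#' SimGIC semantic similarity between two proteins
#'
#' Information-content-weighted Jaccard index of the two proteins'
#' ancestor-closed GO annotation sets:
#' sum of IC over the intersection / sum of IC over the union. Root terms
#' (present in every corpus protein) have IC 0 and contribute nothing.
#'
#' @param protein_a,protein_b Protein identifiers.
#' @param annotations A [go_annotations()] object.
#' @param category Restrict to terms of one root category (default: all
#'   terms).
#' @return Similarity in [0, 1], or `NA` when either protein is unannotated
#'   or the IC union is zero.
#' @export
simgic <- function(protein_a, protein_b, annotations, category = NULL) {
  stopifnot(inherits(annotations, "go_annotations"))
  ca <- annotations$closures[[protein_a]]
  cb <- annotations$closures[[protein_b]]
  if (is.null(ca) || is.null(cb)) return(NA_real_)
  if (!is.null(category)) {
    keep <- names(annotations$categories)[annotations$categories == category]
    ca <- intersect(ca, keep)
    cb <- intersect(cb, keep)
  }
  ic <- annotations$ic
  denom <- sum(ic[union(ca, cb)])
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  sum(ic[intersect(ca, cb)]) / denom
}

#' Tissue co-expression of two proteins
#'
#' Pearson correlation of the two proteins' expression profiles over the
#' tissues in which both are defined (non-missing; a categorical value of 0,
#' "not detected", counts as defined). Pairs sharing fewer than
#' `min_shared_tissues` tissues, or with a zero-variance profile, yield `NA`.
#'
#' @param protein_a,protein_b Protein identifiers (rows of `expression`).
#' @param expression Numeric matrix, proteins x tissues.
#' @param min_shared_tissues Minimum number of jointly defined tissues
#'   (default 5).
#' @return Pearson correlation or `NA`.
#' @export
coexpression <- function(protein_a, protein_b, expression,
                         min_shared_tissues = 5) {
  if (!(protein_a %in% rownames(expression)) ||
      !(protein_b %in% rownames(expression))) {
    return(NA_real_)
  }
  xa <- expression[protein_a, ]
  xb <- expression[protein_b, ]
  shared <- !is.na(xa) & !is.na(xb)
  if (sum(shared) < min_shared_tissues) return(NA_real_)
  if (stats::sd(xa[shared]) == 0 || stats::sd(xb[shared]) == 0) return(NA_real_)
  stats::cor(xa[shared], xb[shared], method = "pearson")
}

#' Quality-control report for a structural interactome
#'
#' Compares functional similarity (SimGIC) and tissue co-expression between
#' interacting protein pairs and an equal-size seeded sample of random
#' non-interacting pairs, reporting medians and a rank-based (Wilcoxon)
#' comparison.
#'
#' @param si A `structural_interactome`.
#' @param annotations A [go_annotations()] object (or `NULL` to skip).
#' @param expression Protein x tissue matrix (or `NULL` to skip).
#' @param n_random_pairs Number of random non-interacting pairs.
#' @param seed Integer seed for the random pair sample.
#' @return List with per-metric interacting / random value vectors, medians,
#'   and Wilcoxon p-values.
#' @export
qc_report <- function(si, annotations = NULL, expression = NULL,
                      n_random_pairs = 100, seed = 1L) {
  pairs <- data.frame(
    a = vapply(si, `[[`, character(1), "protein_a"),
    b = vapply(si, `[[`, character(1), "protein_b"),
    stringsAsFactors = FALSE
  )
  prots <- sort(unique(c(pairs$a, pairs$b)))
  edge_keys <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "\r")
  rnd <- with_seed(seed, {
    out <- matrix(character(0), ncol = 2)
    guard <- 0
    while (nrow(out) < n_random_pairs && guard < 100 * n_random_pairs) {
      guard <- guard + 1
      ab <- sample(prots, 2)
      key <- paste(min(ab), max(ab), sep = "\r")
      if (!(key %in% edge_keys)) out <- rbind(out, sort(ab))
    }
    out
  })
  metric <- function(fun) {
    inter <- mapply(fun, pairs$a, pairs$b)
    random <- if (nrow(rnd) > 0) mapply(fun, rnd[, 1], rnd[, 2]) else numeric(0)
    p <- if (sum(!is.na(inter)) > 0 && sum(!is.na(random)) > 0) {
      suppressWarnings(stats::wilcox.test(inter, random)$p.value)
    } else NA_real_
    list(interacting = unname(inter), random = unname(random),
         median_interacting = stats::median(inter, na.rm = TRUE),
         median_random = stats::median(random, na.rm = TRUE),
         wilcox_p = p)
  }
  out <- list(n_ppis = length(si), n_random_pairs = nrow(rnd))
  if (!is.null(annotations)) {
    out$simgic <- metric(function(a, b) simgic(a, b, annotations))
  }
  if (!is.null(expression)) {
    out$coexpression <- metric(function(a, b) coexpression(a, b, expression))
  }
  out
}
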