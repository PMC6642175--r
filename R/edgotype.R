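# Mutation edgotyping.
#
# Geometry-based rule: a mutation edgetically disrupts a PPI if and only if
# it occurs on the interface mediating that PPI. Physics-based rule: among a
# mutation's interfacial PPIs, a PPI is disrupted if and only if the binding
# free energy change (ddG) exceeds 0.5 kcal/mol (strict); interfacial
# mutations with no ddG record for any of their PPIs are excluded from
# physics-based tallies.

new_edgotype_calls <- function(df, method) {
  df$method <- method
  df$label <- ifelse(is.na(df$n_disrupted), NA_character_,
                     ifelse(df$n_disrupted >= 1, "edgetic", "non_edgetic"))
  df$mono_edgetic <- df$n_disrupted == 1L
  df
}

#' Geometry-based edgotype calls
#'
#' For each mapped mutation, the disrupted PPIs are those of the mutated
#' protein whose interface (on that protein) contains the mutated position.
#'
#' @param mapped Mapped mutation table (see [map_mutations()]); must contain
#'   `mutation_id`, `protein_id`, `protein_position`, `mutation_class`.
#' @param si A `structural_interactome`.
#' @return Data frame with one row per mutation: `mutation_id`,
#'   `mutation_class`, `method`, `n_disrupted`, `label` (`edgetic` /
#'   `non_edgetic`), `mono_edgetic`, and a list-column `disrupted_ppis`.
#' @export
geometry_edgotypes <- function(mapped, si) {
  idx <- si_position_index(si)
  lut <- split(idx$ppi_id, paste(idx$protein_id, idx$position, sep = "\r"))
  key <- paste(mapped$protein_id, mapped$protein_position, sep = "\r")
  disrupted <- lut[key]
  names(disrupted) <- NULL
  disrupted <- lapply(disrupted, function(v) sort(unique(v %||% character(0))))
  out <- data.frame(mutation_id = mapped$mutation_id,
                    mutation_class = mapped$mutation_class,
                    n_disrupted = lengths(disrupted),
                    stringsAsFactors = FALSE)
  out$disrupted_ppis <- disrupted
  new_edgotype_calls(out, "geometry")
}

#' Physics-based (ddG-thresholded) edgotype calls
#'
#' Starts from the geometry-based interfacial PPIs of each mutation and keeps
#' as disrupted only those whose ddG exceeds the threshold. Mutations that
#' are interfacial but have no ddG record for any of their interfacial PPIs
#' receive an `NA` label and are excluded from downstream tallies (physics
#' denominators are therefore at most the geometry denominators).
#' Non-interfacial mutations are called `non_edgetic`.
#'
#' @param mapped Mapped mutation table.
#' @param si A `structural_interactome`.
#' @param ddg_table Data frame with columns `mutation_id`, `ppi_id` (or
#'   `protein_a`/`protein_b` resolvable against `si`), `ddg` in kcal/mol
#'   (positive destabilizes binding).
#' @param threshold Disruption threshold in kcal/mol (default 0.5, strict
#'   `>`).
#' @return Data frame as in [geometry_edgotypes()] with `method = "physics"`.
#' @export
physics_edgotypes <- function(mapped, si, ddg_table, threshold = 0.5) {
  ddg <- resolve_ddg_ppis(ddg_table, si)
  geo <- geometry_edgotypes(mapped, si)
  # consistency: every ddG record must be interfacial for its mutation
  geo_pairs <- paste(rep(geo$mutation_id, lengths(geo$disrupted_ppis)),
                     unlist(geo$disrupted_ppis), sep = "\r")
  ddg_known <- ddg[ddg$mutation_id %in% geo$mutation_id, , drop = FALSE]
  bad <- !(paste(ddg_known$mutation_id, ddg_known$ppi_id, sep = "\r") %in% geo_pairs)
  if (any(bad)) {
    stop(sprintf("ddG record(s) for non-interfacial (mutation, PPI) pair(s), e.g. %s / %s",
                 ddg_known$mutation_id[bad][1], ddg_known$ppi_id[bad][1]),
         call. = FALSE)
  }
  ddg_key <- paste(ddg$mutation_id, ddg$ppi_id, sep = "\r")
  out <- geo
  dis <- out$disrupted_ppis
  ndis <- out$n_disrupted
  for (i in seq_along(dis)) {
    ifaces <- dis[[i]]
    if (length(ifaces) == 0) next  # non-interfacial: stays non_edgetic
    have <- match(paste(out$mutation_id[i], ifaces, sep = "\r"), ddg_key)
    if (all(is.na(have))) {
      ndis[i] <- NA_integer_
      dis[[i]] <- NA_character_
      next
    }
    keep <- !is.na(have) & ddg$ddg[have] > threshold
    dis[[i]] <- ifaces[keep]
    ndis[i] <- sum(keep)
  }
  out$disrupted_ppis <- dis
  out$n_disrupted <- ndis
  new_edgotype_calls(out[, c("mutation_id", "mutation_class", "n_disrupted",
                             "disrupted_ppis")], "physics")
}

# Accept ddG tables keyed either by ppi_id or by the protein pair.
resolve_ddg_ppis <- function(ddg_table, si) {
  if (!is.null(ddg_table$ppi_id)) return(ddg_table)
  assert_that(all(c("protein_a", "protein_b") %in% names(ddg_table)),
              "ddg_table needs either a ppi_id or protein_a/protein_b columns")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  si_keys <- vapply(si, function(sp) pair_key(sp$protein_a, sp$protein_b), character(1))
  ids <- vapply(si, `[[`, character(1), "ppi_id")
  m <- match(pair_key(ddg_table$protein_a, ddg_table$protein_b), si_keys)
  if (anyNA(m)) {
    stop("ddg_table references a protein pair absent from the structural interactome",
         call. = FALSE)
  }
  ddg_table$ppi_id <- ids[m]
  ddg_table
}

#' Class-wise PPI disruption probability (gamma) from ddG records
#'
#' gamma is the fraction of interfacial (mutation, PPI) pairs of the given
#' mutation class whose ddG exceeds the threshold, with its binomial standard
#' error.
#'
#' @param ddg_table ddG table (`mutation_id`, `ppi_id` or protein pair,
#'   `ddg`).
#' @param mutations Mutation table carrying `mutation_id` and
#'   `mutation_class`.
#' @param class `"disease"` or `"non_disease"`.
#' @param threshold Disruption threshold in kcal/mol (default 0.5).
#' @return List with `gamma`, `se` and `n_pairs`.
#' @export
estimate_gamma <- function(ddg_table, mutations, class, threshold = 0.5) {
  cls <- mutations$mutation_class[match(ddg_table$mutation_id, mutations$mutation_id)]
  sub <- ddg_table$ddg[!is.na(cls) & cls == class]
  if (length(sub) == 0) {
    stop(sprintf("no ddG records for mutation class '%s'", class), call. = FALSE)
  }
  g <- mean(sub > threshold)
  list(gamma = g, se = sqrt(g * (1 - g) / length(sub)), n_pairs = length(sub))
}

#' Tally edgetic counts from edgotype calls
#'
#' @param calls Calls from [geometry_edgotypes()] or [physics_edgotypes()];
#'   `NA`-labelled mutations (no ddG data) are excluded from both numerator
#'   and denominator.
#' @param mono Count only mono-edgetic mutations (exactly one disrupted PPI)
#'   as edgetic.
#' @return An [edgetic_counts()] object.
#' @export
tally_edgetic_counts <- function(calls, mono = FALSE) {
  ok <- !is.na(calls$label)
  edge <- if (mono) isTRUE_vec(calls$mono_edgetic) else calls$label == "edgetic"
  n_cls <- function(cl) sum(ok & calls$mutation_class == cl)
  k_cls <- function(cl) sum(ok & edge & calls$mutation_class == cl)
  edgetic_counts(k_N = k_cls("non_disease"), n_N = n_cls("non_disease"),
                 k_M = k_cls("disease"), n_M = n_cls("disease"))
}

pam30_env <- new.env(parent = emptyenv())

pam30_matrix <- function() {
  if (is.null(pam30_env$m)) {
    path <- system.file("extdata", "PAM30.txt", package = "edgotype")
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
    m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
    rownames(m) <- vapply(rows, `[[`, character(1), 1)
    colnames(m) <- header
    pam30_env$m <- m
  }
  pam30_env$m
}

#' PAM30 substitution score
#'
#' Looks up the PAM30 substitution matrix (NCBI scale) shipped with the
#' package as a plain-text fixture. Ambiguity codes (B, Z, X, *) are rejected
#' unless `strict = FALSE`.
#'
#' @param wt_aa,mut_aa One-letter residue codes (vectorised).
#' @param strict Reject non-standard residue codes (default TRUE).
#' @return Integer score(s).
#' @export
pam30_score <- function(wt_aa, mut_aa, strict = TRUE) {
  m <- pam30_matrix()
  ok_codes <- if (strict) AA_ALPHABET_20 else rownames(m)
  bad <- c(setdiff(unique(wt_aa), ok_codes), setdiff(unique(mut_aa), ok_codes))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  }
  m[cbind(wt_aa, mut_aa)]
}

#' Two-sided bootstrap comparison of substitution score distributions
#'
#' Tests the difference in mean substitution score between two groups (e.g.
#' disease vs non-disease mutations) by a two-sided bootstrap test: both
#' groups are recentred to the pooled mean (the null), resampled with
#' replacement, and the p-value is the two-sided tail fraction of the
#' resampled mean differences beyond the observed one (with the +1 smallest-
#' p-value correction).
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param n_resamples Number of bootstrap resamples (default 1e6).
#' @param seed Integer seed.
#' @return List with `statistic` (mean difference a - b), `p_value`, and
#'   `n_resamples`.
#' @export
compare_substitution_scores <- function(scores_a, scores_b,
                                        n_resamples = 1e6, seed = 1L) {
  assert_that(length(scores_a) > 0 && length(scores_b) > 0,
              "both score vectors must be nonempty")
  obs <- mean(scores_a) - mean(scores_b)
  pooled <- mean(c(scores_a, scores_b))
  a0 <- scores_a - mean(scores_a) + pooled
  b0 <- scores_b - mean(scores_b) + pooled
  na <- length(a0); nb <- length(b0)
  extreme <- 0
  with_seed(seed, {
    done <- 0
    chunk <- max(1, floor(2e6 / (na + nb)))
    while (done < n_resamples) {
      k <- min(chunk, n_resamples - done)
      ma <- colMeans(matrix(sample(a0, na * k, replace = TRUE), na, k))
      mb <- colMeans(matrix(sample(b0, nb * k, replace = TRUE), nb, k))
      extreme <- extreme + sum(abs(ma - mb) >= abs(obs))
      done <- done + k
    }
  })
  list(statistic = obs,
       p_value = (1 + extreme) / (n_resamples + 1),
       n_resamples = n_resamples)
}

#' Fisher's exact test comparing edgetic fractions
#'
#' Two-sided Fisher's exact test on the 2x2 table of edgetic vs non-edgetic
#' counts for non-disease and disease mutations.
#'
#' @param counts An [edgetic_counts()] object.
#' @return Two-sided p-value.
#' @export
fisher_edgetic_comparison <- function(counts) {
  tab <- matrix(c(counts$k_N, counts$n_N - counts$k_N,
                  counts$k_M, counts$n_M - counts$k_M),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Write edgotype calls as TSV
#'
#' Columns: `mutation_id`, `mutation_class`, `method`, `label`,
#' `n_disrupted`, `mono_edgetic`.
#'
#' @param calls Edgotype call table.
#' @param path Output file.
#' @export
write_edgotype_calls <- function(calls, path) {
  df <- calls[, c("mutation_id", "mutation_class", "method", "label",
                  "n_disrupted", "mono_edgetic")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
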