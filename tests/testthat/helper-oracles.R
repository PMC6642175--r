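# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use plain nested loops and no package helpers, so
# they constitute an independent route to the same quantities.

# All-pairs Euclidean interface oracle: a residue is interfacial iff any of
# its atoms is within `cutoff` of any atom of the partner chain.
oracle_interface <- function(chain_a, chain_b, cutoff = 5.0) {
  res_a <- split(chain_a$atoms, chain_a$atoms$resno)
  res_b <- split(chain_b$atoms, chain_b$atoms$resno)
  min_dist <- function(ra, rb) {
    best <- Inf
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(rb))) {
        d <- sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 +
                    (ra$z[i] - rb$z[j])^2)
        if (d < best) best <- d
      }
    }
    best
  }
  ia <- integer(0); ib <- integer(0)
  for (pa in names(res_a)) {
    for (pb in names(res_b)) {
      if (min_dist(res_a[[pa]], res_b[[pb]]) <= cutoff) {
        ia <- c(ia, as.integer(pa))
        ib <- c(ib, as.integer(pb))
      }
    }
  }
  list(interface_a = sort(unique(ia)), interface_b = sort(unique(ib)))
}

# Brute-force minimum residue-residue distance (independent of cross_dist).
oracle_min_distance <- function(ra, rb) {
  best <- Inf
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(rb))) {
      d <- sqrt(sum((unlist(ra[i, c("x", "y", "z")]) -
                       unlist(rb[j, c("x", "y", "z")]))^2))
      best <- min(best, d)
    }
  }
  best
}

# Independent record-by-record reimplementation of the structural-interactome
# filter chain (E-value cutoff, best-hit-per-chain, coverage >= 0.5 per side,
# <= 5 smallest joint E-values, union of mapped interfaces).
oracle_structural_interactome <- function(edges, hits, catalog,
                                          evalue_cutoff = 1e-10,
                                          min_coverage = 0.5,
                                          max_annotations = 5) {
  # step 1+2: best hit per (protein, structure, chain)
  best <- list()
  for (i in seq_len(nrow(hits))) {
    if (hits$evalue[i] > evalue_cutoff) next
    key <- paste(hits$protein_id[i], hits$structure_id[i], hits$chain_id[i])
    cur <- best[[key]]
    cand <- list(evalue = hits$evalue[i], pairs = hits$pairs[[i]],
                 protein_id = hits$protein_id[i],
                 structure_id = hits$structure_id[i],
                 chain_id = hits$chain_id[i])
    if (is.null(cur) || cand$evalue < cur$evalue ||
        (cand$evalue == cur$evalue && nrow(cand$pairs) > nrow(cur$pairs))) {
      best[[key]] <- cand
    }
  }
  best <- unname(best)

  result <- list()
  for (e in seq_len(nrow(edges))) {
    pa <- edges$protein_a[e]; pb <- edges$protein_b[e]
    homodimer <- pa == pb
    cands <- list()
    for (ha in best) {
      if (ha$protein_id != pa) next
      for (hb in best) {
        if (hb$protein_id != pb) next
        if (ha$structure_id != hb$structure_id) next
        if (ha$chain_id == hb$chain_id) next
        if (homodimer && ha$chain_id > hb$chain_id) next
        key <- paste(ha$structure_id, min(ha$chain_id, hb$chain_id),
                     max(ha$chain_id, hb$chain_id), sep = "|")
        ip <- catalog[[key]]
        if (is.null(ip)) next
        iface <- if (ip$chain_a == ha$chain_id) {
          list(a = ip$interface_a, b = ip$interface_b)
        } else {
          list(a = ip$interface_b, b = ip$interface_a)
        }
        if (length(iface$a) == 0) next
        map_side <- function(hit, chain_iface) {
          mp <- integer(0)
          for (p in chain_iface) {
            row <- which(hit$pairs[, 2] == p)
            if (length(row) == 1) mp <- c(mp, hit$pairs[row, 1])
          }
          list(cov = length(mp) / length(chain_iface), img = sort(mp))
        }
        ma <- map_side(ha, iface$a); mb <- map_side(hb, iface$b)
        if (ma$cov < min_coverage || mb$cov < min_coverage) next
        cands[[length(cands) + 1]] <- list(
          joint = ha$evalue * hb$evalue,
          sid = ha$structure_id, ca = ha$chain_id, cb = hb$chain_id,
          img_a = ma$img, img_b = mb$img)
      }
    }
    if (length(cands) == 0) next
    ord <- order(vapply(cands, `[[`, numeric(1), "joint"),
                 vapply(cands, `[[`, character(1), "sid"),
                 vapply(cands, `[[`, character(1), "ca"),
                 vapply(cands, `[[`, character(1), "cb"))
    keep <- cands[ord[seq_len(min(max_annotations, length(ord)))]]
    ia <- sort(unique(unlist(lapply(keep, `[[`, "img_a"))))
    ib <- sort(unique(unlist(lapply(keep, `[[`, "img_b"))))
    if (homodimer) ia <- ib <- sort(unique(c(ia, ib)))
    ppi_id <- if (!is.null(edges$ppi_id)) edges$ppi_id[e] else as.character(e)
    result[[ppi_id]] <- list(protein_a = pa, protein_b = pb,
                             interface_a = ia, interface_b = ib,
                             n_annotations = length(keep))
  }
  result
}

# Exhaustive two-sided Fisher p-value over the hypergeometric support.
oracle_fisher <- function(k_N, n_N, k_M, n_M) {
  k_tot <- k_N + k_M
  support <- max(0, k_tot - n_M):min(n_N, k_tot)
  probs <- stats::dhyper(support, n_N, n_M, k_tot)
  p_obs <- stats::dhyper(k_N, n_N, n_M, k_tot)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small world used by several test files (memoised per session).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_world(synthetic_world_config(
        n_proteins = 25, n_ppis = 20, mean_protein_length = 100,
        interface_width = 6, n_disease_mut = 250, n_nondisease_mut = 250,
        true_pEgivenN = 0.10, true_pEgivenM = 0.30, seed = 42
      ))
    }
    cache
  }
})
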