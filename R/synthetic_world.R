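# Synthetic-world generator.
#
# Produces a complete, internally consistent set of pipeline inputs
# (chain coordinates, SEQRES sequences, alignment hits, an interactome edge
# list, mutation tables, ddG tables, GO annotations, tissue expression) with
# known ground truth, so every downstream stage can be validated without any
# external database.
#
# Geometry is intentionally minimal: residues are laid out as C-alpha plus one
# dummy side-chain atom on a jittered lattice. Only inter-atomic distances
# matter to the interface rule, so stereochemistry is irrelevant. Contact
# residues sit ~3.8 A from their partner; every non-contact inter-chain
# residue pair is kept beyond a 6 A guard band so the 5 A rule classifies
# positions unambiguously.

#' Configuration of a synthetic interactome world
#'
#' @param n_proteins Number of proteins.
#' @param n_ppis Number of protein-protein interactions (edges).
#' @param mean_protein_length Mean protein length in residues.
#' @param interface_width Interface width in residues per side of each PPI.
#' @param true_pEgivenN,true_pEgivenM Probability for a non-disease (resp.
#'   disease) mutation to be placed on a binding interface, i.e. the true
#'   P(E|N) and P(E|M) of the world.
#' @param gamma_N,gamma_M Probability that an interfacial non-disease (resp.
#'   disease) mutation disrupts the PPI mediated by that interface (the
#'   fraction of interfacial (mutation, PPI) pairs with ddG above the
#'   0.5 kcal/mol disruption threshold).
#' @param ddg_disrupt_mean,ddg_neutral_mean Means (kcal/mol) of the disrupting
#'   and non-disrupting ddG components; must straddle the 0.5 kcal/mol
#'   threshold.
#' @param ddg_sd Standard deviation (kcal/mol) of both ddG components.
#' @param n_disease_mut,n_nondisease_mut Number of disease / non-disease
#'   missense mutations.
#' @param seed Master integer seed; per-stage substreams are derived from it
#'   so that, e.g., adding mutations does not perturb structure generation.
#'
#' @return An object of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_proteins = 120,
                                   n_ppis = 150,
                                   mean_protein_length = 250,
                                   interface_width = 15,
                                   true_pEgivenN = 0.051,
                                   true_pEgivenM = 0.186,
                                   gamma_N = 0.60,
                                   gamma_M = 0.66,
                                   ddg_disrupt_mean = 2.0,
                                   ddg_neutral_mean = -0.5,
                                   ddg_sd = 1.0,
                                   n_disease_mut = 5000,
                                   n_nondisease_mut = 5000,
                                   seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_ppis = n_ppis,
              mean_protein_length = mean_protein_length,
              interface_width = interface_width,
              true_pEgivenN = true_pEgivenN, true_pEgivenM = true_pEgivenM,
              gamma_N = gamma_N, gamma_M = gamma_M,
              ddg_disrupt_mean = ddg_disrupt_mean,
              ddg_neutral_mean = ddg_neutral_mean, ddg_sd = ddg_sd,
              n_disease_mut = n_disease_mut, n_nondisease_mut = n_nondisease_mut,
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "synthetic_world_config")
}

validate_world_config <- function(cfg) {
  cfg_err <- function(field, msg) {
    stop(sprintf("invalid synthetic_world_config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  for (f in c("true_pEgivenN", "true_pEgivenM", "gamma_N", "gamma_M")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      cfg_err(f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("n_proteins", "n_ppis", "mean_protein_length",
              "n_disease_mut", "n_nondisease_mut")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      cfg_err(f, "must be a count >= 1")
    }
  }
  if (!is.numeric(cfg$interface_width) || cfg$interface_width < 1) {
    cfg_err("interface_width", "must be >= 1")
  }
  if (!(cfg$ddg_disrupt_mean > 0.5)) {
    cfg_err("ddg_disrupt_mean", "must exceed the 0.5 kcal/mol threshold")
  }
  if (!(cfg$ddg_neutral_mean < 0.5)) {
    cfg_err("ddg_neutral_mean", "must be below the 0.5 kcal/mol threshold")
  }
  if (!is.numeric(cfg$ddg_sd) || cfg$ddg_sd <= 0) {
    cfg_err("ddg_sd", "must be > 0")
  }
  if (cfg$n_ppis > choose(cfg$n_proteins, 2)) {
    cfg_err("n_ppis", "exceeds the number of distinct protein pairs")
  }
  invisible(cfg)
}

random_protein_sequences <- function(n, mean_len, min_len) {
  lens <- pmax(min_len, round(stats::rnorm(n, mean_len, mean_len / 10)))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET_20, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("P%04d", seq_len(n))
  seqs
}

# Coordinates for one dimer: chains laid out on two parallel lattice lines
# 40 A apart; each contact residue of chain B is re-placed ~3.8 A from its
# paired contact residue of chain A. Jitter amplitude (0.15 A per coordinate)
# is small enough to preserve both the 5 A contact guarantee and the 6 A
# guard band for all non-contact inter-chain residue pairs.
build_dimer_chains <- function(structure_id, seq_a, seq_b,
                               contacts_a, contacts_b,
                               chain_ids = c("A", "B")) {
  stopifnot(length(contacts_a) == length(contacts_b))
  jit <- function(n) stats::runif(n, -0.15, 0.15)
  la <- nchar(seq_a); lb <- nchar(seq_b)

  coords_for <- function(L, y0) {
    x <- 7 * seq_len(L) + jit(L)
    y <- y0 + jit(L)
    z <- jit(L)
    list(ca = cbind(x, y, z), cb = cbind(x + jit(L), y + jit(L), z + 1 + jit(L)))
  }
  A <- coords_for(la, 0)
  B <- coords_for(lb, 40)
  if (length(contacts_a) > 0) {
    # pair the k-th contact residue of B with the k-th contact residue of A
    bx <- 7 * contacts_a + jit(length(contacts_a))
    by <- 3.8 + jit(length(contacts_a))
    bz <- jit(length(contacts_a))
    B$ca[contacts_b, ] <- cbind(bx, by, bz)
    B$cb[contacts_b, ] <- cbind(bx + jit(length(contacts_a)),
                                by + jit(length(contacts_a)),
                                bz + 1 + jit(length(contacts_a)))
  }
  mk_atoms <- function(L, seq, crd) {
    aa <- strsplit(seq, "")[[1]]
    data.frame(
      resno = rep(seq_len(L), each = 2),
      aa = rep(aa, each = 2),
      elety = rep(c("CA", "CB"), L),
      x = as.vector(rbind(crd$ca[, 1], crd$cb[, 1])),
      y = as.vector(rbind(crd$ca[, 2], crd$cb[, 2])),
      z = as.vector(rbind(crd$ca[, 3], crd$cb[, 3])),
      stringsAsFactors = FALSE
    )
  }
  list(
    chain_structure(structure_id, chain_ids[1], seq_a, mk_atoms(la, seq_a, A), quiet = TRUE),
    chain_structure(structure_id, chain_ids[2], seq_b, mk_atoms(lb, seq_b, B), quiet = TRUE)
  )
}

#' Generate a toy dimer with an exact, known interface
#'
#' Builds a two-chain structure in which exactly `n_contact` residues of each
#' chain have at least one atom within 5 A of the partner chain, and every
#' other inter-chain residue pair is farther than 6 A (a guard band), so
#' interface detection has an unambiguous ground truth.
#'
#' @param n_res_a,n_res_b Chain lengths in residues.
#' @param n_contact Number of contact residues per chain.
#' @param seed Integer seed.
#' @return List with elements `chain_a`, `chain_b` ([chain_structure()]s),
#'   `contacts_a`, `contacts_b` (the ground-truth interface positions).
#' @export
generate_toy_dimer <- function(n_res_a, n_res_b, n_contact, seed = 1L) {
  if (n_contact > min(n_res_a, n_res_b)) {
    stop("infeasible geometry: n_contact exceeds a chain length", call. = FALSE)
  }
  with_seed(seed, {
    seq_a <- paste(sample(AA_ALPHABET_20, n_res_a, replace = TRUE), collapse = "")
    seq_b <- paste(sample(AA_ALPHABET_20, n_res_b, replace = TRUE), collapse = "")
    contacts_a <- sort(sample.int(n_res_a, n_contact))
    contacts_b <- sort(sample.int(n_res_b, n_contact))
    chains <- build_dimer_chains("TOY", seq_a, seq_b, contacts_a, contacts_b)
    list(chain_a = chains[[1]], chain_b = chains[[2]],
         contacts_a = contacts_a, contacts_b = contacts_b)
  })
}

# Place one interface window of `width` residues on each protein of each PPI.
# Windows on the same protein never overlap, so every interface position
# belongs to exactly one PPI and mutation ground truth is unambiguous.
assign_interface_windows <- function(edges, protein_lengths, width) {
  free <- lapply(protein_lengths, function(L) rep(TRUE, L))
  pick_window <- function(pid) {
    f <- free[[pid]]
    L <- length(f)
    if (L < width) stop(sprintf("interface capacity exceeded for protein %s", pid), call. = FALSE)
    cs <- cumsum(as.integer(f))
    starts <- seq_len(L - width + 1)
    winsum <- cs[starts + width - 1] - c(0, cs)[starts]
    ok <- starts[winsum == width]
    if (length(ok) == 0) {
      stop(sprintf("interface capacity exceeded for protein %s", pid), call. = FALSE)
    }
    s <- ok[sample.int(length(ok), 1)]
    f[s:(s + width - 1)] <- FALSE
    free[[pid]] <<- f
    s
  }
  rows <- vector("list", 2 * nrow(edges))
  for (i in seq_len(nrow(edges))) {
    sa <- pick_window(edges$protein_a[i])
    sb <- pick_window(edges$protein_b[i])
    rows[[2 * i - 1]] <- data.frame(ppi_id = edges$ppi_id[i], side = "a",
                                    protein_id = edges$protein_a[i],
                                    start = sa, width = width,
                                    stringsAsFactors = FALSE)
    rows[[2 * i]] <- data.frame(ppi_id = edges$ppi_id[i], side = "b",
                                protein_id = edges$protein_b[i],
                                start = sb, width = width,
                                stringsAsFactors = FALSE)
  }
  list(windows = do.call(rbind, rows), free = free)
}

window_positions <- function(windows) {
  data.frame(
    ppi_id = rep(windows$ppi_id, windows$width),
    side = rep(windows$side, windows$width),
    protein_id = rep(windows$protein_id, windows$width),
    position = unlist(Map(function(s, w) s:(s + w - 1), windows$start, windows$width)),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic world
#'
#' Creates proteins, an interactome edge list, one dimeric structure per PPI
#' realising the declared interfaces under the 5 A rule, identity alignment
#' hits, mutation tables with class-dependent interfacial placement rates,
#' ddG records whose exceedance probability at the 0.5 kcal/mol threshold
#' equals the configured class-wise gamma, GO annotations and a tissue
#' expression matrix, plus a ground-truth record of every choice made.
#'
#' @param config A [synthetic_world_config()].
#' @param alignment_noise Inject filter-exercising alignment records:
#'   duplicate hits with larger E-values, sub-threshold hits, and gapped
#'   alignments with reduced interface coverage.
#' @return An object of class `synthetic_world`.
#' @export
generate_world <- function(config = synthetic_world_config(),
                           alignment_noise = FALSE) {
  validate_world_config(config)
  seed <- config$seed
  w <- config$interface_width

  ## stage 1: proteins -------------------------------------------------------
  proteins <- with_seed(substream_seed(seed, 1L), {
    random_protein_sequences(config$n_proteins, config$mean_protein_length,
                             min_len = 4 * w + 20)
  })
  lens <- nchar(proteins)

  ## stage 2: interactome edges and interface windows ------------------------
  st2 <- with_seed(substream_seed(seed, 2L), {
    seen <- character(0)
    pairs <- matrix(character(0), ncol = 2)
    while (nrow(pairs) < config$n_ppis) {
      idx <- sample.int(config$n_proteins, 2)
      key <- paste(sort(names(proteins)[idx]), collapse = "|")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        pairs <- rbind(pairs, sort(names(proteins)[idx]))
      }
    }
    edges <- data.frame(ppi_id = sprintf("PPI%04d", seq_len(config$n_ppis)),
                        protein_a = pairs[, 1], protein_b = pairs[, 2],
                        stringsAsFactors = FALSE)
    c(list(edges = edges), assign_interface_windows(edges, lens, w))
  })
  edges <- st2$edges
  windows <- st2$windows
  free <- st2$free
  wpos <- window_positions(windows)

  ## stage 3: structures -----------------------------------------------------
  chains <- with_seed(substream_seed(seed, 3L), {
    out <- list()
    for (i in seq_len(nrow(edges))) {
      sid <- sprintf("S%04d", i)
      wa <- windows[windows$ppi_id == edges$ppi_id[i] & windows$side == "a", ]
      wb <- windows[windows$ppi_id == edges$ppi_id[i] & windows$side == "b", ]
      ch <- build_dimer_chains(sid,
                               proteins[[edges$protein_a[i]]],
                               proteins[[edges$protein_b[i]]],
                               contacts_a = wa$start:(wa$start + w - 1),
                               contacts_b = wb$start:(wb$start + w - 1))
      out[[paste0(sid, "_A")]] <- ch[[1]]
      out[[paste0(sid, "_B")]] <- ch[[2]]
    }
    out
  })
  structures <- data.frame(ppi_id = edges$ppi_id,
                           structure_id = sprintf("S%04d", seq_len(nrow(edges))),
                           stringsAsFactors = FALSE)

  ## stage 4: alignment hits -------------------------------------------------
  alignments <- with_seed(substream_seed(seed, 4L), {
    identity_pairs <- function(L) cbind(protein_position = seq_len(L),
                                        chain_position = seq_len(L))
    rows <- vector("list", 2 * nrow(edges))
    for (i in seq_len(nrow(edges))) {
      rows[[2 * i - 1]] <- list(protein_id = edges$protein_a[i],
                                structure_id = structures$structure_id[i],
                                chain_id = "A", evalue = 1e-50,
                                pairs = identity_pairs(lens[[edges$protein_a[i]]]))
      rows[[2 * i]] <- list(protein_id = edges$protein_b[i],
                            structure_id = structures$structure_id[i],
                            chain_id = "B", evalue = 1e-50,
                            pairs = identity_pairs(lens[[edges$protein_b[i]]]))
    }
    hits <- data.frame(
      protein_id = vapply(rows, `[[`, character(1), "protein_id"),
      structure_id = vapply(rows, `[[`, character(1), "structure_id"),
      chain_id = vapply(rows, `[[`, character(1), "chain_id"),
      evalue = vapply(rows, `[[`, numeric(1), "evalue"),
      stringsAsFactors = FALSE
    )
    hits$pairs <- lapply(rows, `[[`, "pairs")

    if (alignment_noise) {
      n <- nrow(hits)
      # duplicate hits with a worse (but still sub-cutoff) E-value
      dup <- hits[sample.int(n, max(1, round(0.3 * n))), , drop = FALSE]
      dup$evalue <- 1e-12
      # hits above the E-value cutoff; must be filtered out entirely
      weak <- hits[sample.int(n, max(1, round(0.2 * n))), , drop = FALSE]
      weak$evalue <- 1e-05
      # gapped alignments dropping 60% of the interface window columns on one
      # side of some PPIs: coverage 0.4 < 0.5, so the annotation is rejected
      gap_idx <- sample(seq_len(nrow(edges)), max(1, round(0.1 * nrow(edges))))
      for (i in gap_idx) {
        row_i <- 2 * i - 1  # side-a hit of PPI i
        wa <- windows[windows$ppi_id == edges$ppi_id[i] & windows$side == "a", ]
        win <- wa$start:(wa$start + w - 1)
        drop_cols <- sort(sample(win, ceiling(0.6 * w)))
        p <- hits$pairs[[row_i]]
        hits$pairs[[row_i]] <- p[!(p[, "chain_position"] %in% drop_cols), , drop = FALSE]
      }
      hits <- rbind(hits, dup, weak)
      rownames(hits) <- NULL
    }
    hits
  })

  ## stage 5: mutations ------------------------------------------------------
  interactome_proteins <- sort(unique(c(edges$protein_a, edges$protein_b)))
  muts <- with_seed(substream_seed(seed, 5L), {
    iface_pool <- wpos[wpos$protein_id %in% interactome_proteins, ]
    noniface_pool <- do.call(rbind, lapply(interactome_proteins, function(pid) {
      pos <- which(free[[pid]])
      data.frame(protein_id = pid, position = pos, stringsAsFactors = FALSE)
    }))
    n_d <- config$n_disease_mut
    n_n <- config$n_nondisease_mut
    iface_d <- stats::rbinom(n_d, 1, config$true_pEgivenM) == 1
    iface_n <- stats::rbinom(n_n, 1, config$true_pEgivenN) == 1
    n_iface <- sum(iface_d) + sum(iface_n)
    n_non <- n_d + n_n - n_iface
    if (n_iface > nrow(iface_pool)) {
      stop("interface position pool exhausted; increase n_ppis or interface_width",
           call. = FALSE)
    }
    if (n_non > nrow(noniface_pool)) {
      stop("non-interface position pool exhausted; increase n_proteins or mean_protein_length",
           call. = FALSE)
    }
    ipick <- iface_pool[sample.int(nrow(iface_pool), n_iface), ]
    npick <- noniface_pool[sample.int(nrow(noniface_pool), n_non), ]

    assemble <- function(class, n, iface_flags, ip, np) {
      pid <- character(n); pos <- integer(n); ppi <- rep(NA_character_, n)
      pid[iface_flags] <- ip$protein_id; pos[iface_flags] <- ip$position
      ppi[iface_flags] <- ip$ppi_id
      pid[!iface_flags] <- np$protein_id; pos[!iface_flags] <- np$position
      wt <- substr(proteins[pid], pos, pos)
      mut <- vapply(wt, function(a) sample(setdiff(AA_ALPHABET_20, a), 1), character(1),
                    USE.NAMES = FALSE)
      data.frame(protein_id = pid, position = pos, ppi_id = ppi,
                 interfacial = iface_flags, wt_aa = wt, mut_aa = mut,
                 mutation_class = class, stringsAsFactors = FALSE)
    }
    d <- assemble("disease", n_d, iface_d,
                  ipick[seq_len(sum(iface_d)), , drop = FALSE],
                  npick[seq_len(sum(!iface_d)), , drop = FALSE])
    nn <- assemble("non_disease", n_n, iface_n,
                   ipick[sum(iface_d) + seq_len(sum(iface_n)), , drop = FALSE],
                   npick[sum(!iface_d) + seq_len(sum(!iface_n)), , drop = FALSE])
    d$mutation_id <- sprintf("D%05d", seq_len(n_d))
    nn$mutation_id <- sprintf("N%05d", seq_len(n_n))
    all <- rbind(d, nn)
    data.frame(
      mutation_id = all$mutation_id,
      protein_id = all$protein_id,
      transcript_sequence = unname(proteins[all$protein_id]),
      transcript_position = all$position,
      wt_aa = all$wt_aa, mut_aa = all$mut_aa,
      mutation_class = all$mutation_class,
      significance = ifelse(all$mutation_class == "disease", "pathogenic", ""),
      review_stars = ifelse(all$mutation_class == "disease",
                            sample(1:4, nrow(all), replace = TRUE), 0L),
      conflicting = FALSE,
      validated = TRUE,
      withdrawn = FALSE,
      assertions = "",
      maf = ifelse(all$mutation_class == "disease", NA_real_,
                   stats::runif(nrow(all), 0.011, 0.5)),
      interfacial = all$interfacial,
      ppi_id = all$ppi_id,
      stringsAsFactors = FALSE
    )
  })
  mutations <- muts[, !(names(muts) %in% c("interfacial", "ppi_id"))]
  truth_mut <- muts[, c("mutation_id", "mutation_class", "protein_id",
                        "transcript_position", "interfacial", "ppi_id")]
  names(truth_mut)[names(truth_mut) == "transcript_position"] <- "position"

  ## stage 6: ddG records for interfacial (mutation, PPI) pairs --------------
  ddg <- with_seed(substream_seed(seed, 6L), {
    im <- truth_mut[truth_mut$interfacial, ]
    if (nrow(im) == 0) {
      data.frame(mutation_id = character(0), ppi_id = character(0),
                 protein_a = character(0), protein_b = character(0),
                 ddg = numeric(0), disrupts = logical(0))
    } else {
      gam <- ifelse(im$mutation_class == "disease", config$gamma_M, config$gamma_N)
      disrupts <- stats::rbinom(nrow(im), 1, gam) == 1
      vals <- numeric(nrow(im))
      vals[disrupts] <- rtnorm(sum(disrupts), config$ddg_disrupt_mean,
                               config$ddg_sd, lower = 0.5)
      vals[!disrupts] <- rtnorm(sum(!disrupts), config$ddg_neutral_mean,
                                config$ddg_sd, upper = 0.5)
      ed <- edges[match(im$ppi_id, edges$ppi_id), ]
      data.frame(mutation_id = im$mutation_id, ppi_id = im$ppi_id,
                 protein_a = ed$protein_a, protein_b = ed$protein_b,
                 ddg = vals, disrupts = disrupts, stringsAsFactors = FALSE)
    }
  })
  ddg_table <- ddg[, c("mutation_id", "ppi_id", "protein_a", "protein_b", "ddg")]

  ## stage 7: GO annotations -------------------------------------------------
  go <- with_seed(substream_seed(seed, 7L), {
    cats <- c("BP", "MF", "CC")
    terms <- do.call(rbind, lapply(cats, function(cat) {
      root <- sprintf("GO:%s:root", cat)
      mids <- sprintf("GO:%s:M%02d", cat, 1:5)
      leaves <- sprintf("GO:%s:L%02d", cat, 1:15)
      data.frame(term = c(root, mids, leaves),
                 parent = c(NA_character_, rep(root, 5), mids[sample.int(5, 15, replace = TRUE)]),
                 category = cat, stringsAsFactors = FALSE)
    }))
    leaves <- terms$term[grepl(":L", terms$term, fixed = TRUE)]
    ann <- list()
    for (i in seq_len(nrow(edges))) {
      shared <- sample(leaves, 1)  # interacting partners share a term
      ann[[edges$protein_a[i]]] <- c(ann[[edges$protein_a[i]]], shared)
      ann[[edges$protein_b[i]]] <- c(ann[[edges$protein_b[i]]], shared)
    }
    for (pid in names(proteins)) {
      ann[[pid]] <- unique(c(ann[[pid]], sample(leaves, 2)))
    }
    annotations <- data.frame(
      protein_id = rep(names(ann), lengths(ann)),
      term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
    list(terms = terms, annotations = annotations)
  })

  ## stage 8: tissue expression ----------------------------------------------
  expression <- with_seed(substream_seed(seed, 8L), {
    tissues <- sprintf("T%02d", 1:16)
    latent <- matrix(stats::rnorm(nrow(edges) * 16, 4, 2), nrow(edges), 16)
    m <- matrix(NA_real_, length(proteins), 16,
                dimnames = list(names(proteins), tissues))
    for (pid in names(proteins)) {
      rows <- which(edges$protein_a == pid | edges$protein_b == pid)
      base <- if (length(rows) > 0) colMeans(latent[rows, , drop = FALSE])
              else stats::rnorm(16, 4, 2)
      m[pid, ] <- base + stats::rnorm(16, 0, 0.5)
    }
    m
  })

  structure(
    list(config = config,
         proteins = proteins,
         edges = edges,
         structures = structures,
         windows = windows,
         chains = chains,
         alignments = alignments,
         mutations = mutations,
         ddg_table = ddg_table,
         go_terms = go$terms,
         go_annotations = go$annotations,
         expression = expression,
         truth = list(config = unclass(config),
                      mutations = truth_mut,
                      ddg_disrupts = ddg[, c("mutation_id", "ppi_id", "disrupts")])),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d proteins, %d PPIs, %d structures, ",
                     "%d mutations (%d disease / %d non-disease), %d ddG records\n"),
              length(x$proteins), nrow(x$edges), nrow(x$structures),
              nrow(x$mutations), sum(x$mutations$mutation_class == "disease"),
              sum(x$mutations$mutation_class == "non_disease"), nrow(x$ddg_table)))
  invisible(x)
}
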