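# Structural interactome construction: hit filtering, chain-pair annotation,
# coverage rule, annotation cap, and equivalence with an independent oracle.

mk_hit <- function(protein, sid, chain, evalue, pairs) {
  h <- data.frame(protein_id = protein, structure_id = sid, chain_id = chain,
                  evalue = evalue, stringsAsFactors = FALSE)
  h$pairs <- list(pairs)
  h
}

identity_pairs <- function(n) cbind(protein_position = 1:n, chain_position = 1:n)

test_that("filter_hits keeps the best hit per chain and applies the cutoff", {
  hits <- rbind(
    mk_hit("P1", "S1", "A", 1e-20, identity_pairs(10)),
    mk_hit("P1", "S1", "A", 1e-15, identity_pairs(10)),
    mk_hit("P2", "S1", "B", 1e-05, identity_pairs(10))   # above cutoff
  )
  out <- filter_hits(hits)
  expect_equal(nrow(out), 1L)
  expect_equal(out$evalue, 1e-20)

  # E-value ties break toward the longest alignment
  tie <- rbind(
    mk_hit("P1", "S1", "A", 1e-20, identity_pairs(5)),
    mk_hit("P1", "S1", "A", 1e-20, identity_pairs(9))
  )
  expect_equal(nrow(filter_hits(tie)$pairs[[1]]), 9L)
})

test_that("filter_hits equals a group-by-minimum oracle on random hits", {
  set.seed(21)
  hits <- do.call(rbind, lapply(1:10, function(i) {
    mk_hit(sample(c("P1", "P2"), 1), "S1", sample(c("A", "B", "C"), 1),
           10^-sample(11:30, 1), identity_pairs(sample(5:15, 1)))
  }))
  got <- filter_hits(hits)
  key <- paste(hits$protein_id, hits$chain_id)
  for (k in unique(key)) {
    sub <- hits[key == k, ]
    want_min <- min(sub$evalue)
    got_k <- got[paste(got$protein_id, got$chain_id) == k, ]
    expect_equal(nrow(got_k), 1L)
    expect_equal(got_k$evalue, want_min)
  }
})

test_that("annotate_ppi maps interfaces through identity alignments", {
  td <- generate_toy_dimer(20, 20, 3, seed = 5)
  catalog <- interface_catalog(list(td$chain_a, td$chain_b))
  hits <- rbind(mk_hit("P1", "TOY", "A", 1e-50, identity_pairs(20)),
                mk_hit("P2", "TOY", "B", 1e-50, identity_pairs(20)))
  sp <- annotate_ppi("P1", "P2", hits, catalog)
  expect_equal(sp$interface_a, td$contacts_a)
  expect_equal(sp$interface_b, td$contacts_b)
  expect_equal(sp$annotations$coverage_a, 1.0)
  expect_equal(sp$annotations$coverage_b, 1.0)
})

test_that("annotations with < 50% interface coverage are rejected", {
  td <- generate_toy_dimer(20, 20, 3, seed = 5)
  catalog <- interface_catalog(list(td$chain_a, td$chain_b))
  # alignment covering only 1 of the 3 interface residues on side a
  gap_pairs <- identity_pairs(20)
  gap_pairs <- gap_pairs[!(gap_pairs[, 2] %in% td$contacts_a[2:3]), ]
  hits <- rbind(mk_hit("P1", "TOY", "A", 1e-50, gap_pairs),
                mk_hit("P2", "TOY", "B", 1e-50, identity_pairs(20)))
  expect_null(annotate_ppi("P1", "P2", hits, catalog))

  # partial coverage at or above the threshold is kept: 2/3 >= 0.5
  gap2 <- identity_pairs(20)
  gap2 <- gap2[gap2[, 2] != td$contacts_a[1], ]
  sp <- annotate_ppi("P1", "P2", rbind(mk_hit("P1", "TOY", "A", 1e-50, gap2),
                                       mk_hit("P2", "TOY", "B", 1e-50, identity_pairs(20))),
                     catalog)
  expect_equal(sp$annotations$coverage_a, 2 / 3)
  expect_equal(sp$interface_a, td$contacts_a[2:3])
})

test_that("at most 5 annotations with smallest joint E-values are retained", {
  # 7 candidate structures with distinct joint E-values
  tds <- lapply(1:7, function(i) generate_toy_dimer(15, 15, 3, seed = i))
  chains <- list()
  hits <- NULL
  for (i in 1:7) {
    sid <- sprintf("X%d", i)
    tds[[i]]$chain_a$structure_id <- sid
    tds[[i]]$chain_b$structure_id <- sid
    chains <- c(chains, list(tds[[i]]$chain_a, tds[[i]]$chain_b))
    hits <- rbind(hits,
                  mk_hit("P1", sid, "A", 10^-(20 + i), identity_pairs(15)),
                  mk_hit("P2", sid, "B", 1e-20, identity_pairs(15)))
  }
  catalog <- interface_catalog(chains)
  sp <- annotate_ppi("P1", "P2", hits, catalog)
  expect_equal(nrow(sp$annotations), 5L)
  # the 5 smallest joint E-values correspond to structures X3..X7
  expect_setequal(sp$annotations$structure_id, sprintf("X%d", 3:7))
  # union oracle: enumerate and sort by joint E-value by hand
  want_a <- sort(unique(unlist(lapply(3:7, function(i) tds[[i]]$contacts_a))))
  expect_equal(sp$interface_a, want_a)

  # adding a candidate with a larger joint E-value changes nothing
  td8 <- generate_toy_dimer(15, 15, 3, seed = 8)
  td8$chain_a$structure_id <- "X8"; td8$chain_b$structure_id <- "X8"
  catalog8 <- interface_catalog(c(chains, list(td8$chain_a, td8$chain_b)))
  hits8 <- rbind(hits,
                 mk_hit("P1", "X8", "A", 1e-11, identity_pairs(15)),
                 mk_hit("P2", "X8", "B", 1e-11, identity_pairs(15)))
  sp8 <- annotate_ppi("P1", "P2", hits8, catalog8)
  expect_equal(sp8$interface_a, sp$interface_a)
  expect_equal(sp8$annotations$structure_id, sp$annotations$structure_id)
})

test_that("zero E-values sort before any positive joint E-value", {
  td1 <- generate_toy_dimer(15, 15, 2, seed = 31)
  td2 <- generate_toy_dimer(15, 15, 2, seed = 32)
  td1$chain_a$structure_id <- "Z1"; td1$chain_b$structure_id <- "Z1"
  td2$chain_a$structure_id <- "Z2"; td2$chain_b$structure_id <- "Z2"
  catalog <- interface_catalog(list(td1$chain_a, td1$chain_b,
                                    td2$chain_a, td2$chain_b))
  hits <- rbind(mk_hit("P1", "Z1", "A", 1e-50, identity_pairs(15)),
                mk_hit("P2", "Z1", "B", 1e-50, identity_pairs(15)),
                mk_hit("P1", "Z2", "A", 0.0, identity_pairs(15)),
                mk_hit("P2", "Z2", "B", 1e-30, identity_pairs(15)))
  sp <- annotate_ppi("P1", "P2", hits, catalog, max_annotations = 1)
  expect_equal(sp$annotations$structure_id, "Z2")
  expect_equal(sp$annotations$joint_evalue, 0)
})

test_that("homodimers use both chains of one protein", {
  td <- generate_toy_dimer(20, 20, 3, seed = 17)
  td$chain_b$seqres <- td$chain_a$seqres  # same protein on both chains
  td$chain_b$atoms$aa <- rep(strsplit(td$chain_a$seqres, "")[[1]],
                             each = 2)[seq_len(nrow(td$chain_b$atoms))]
  catalog <- interface_catalog(list(td$chain_a, td$chain_b))
  hits <- rbind(mk_hit("P1", "TOY", "A", 1e-50, identity_pairs(20)),
                mk_hit("P1", "TOY", "B", 1e-50, identity_pairs(20)))
  sp <- annotate_ppi("P1", "P1", hits, catalog)
  expect_false(is.null(sp))
  want <- sort(unique(c(td$contacts_a, td$contacts_b)))
  expect_equal(sp$interface_a, want)
  expect_equal(sp$interface_b, want)
  expect_equal(nrow(sp$annotations), 1L)  # unordered chain pair counted once
})

test_that("build_structural_interactome keeps exactly the annotatable edges", {
  w <- tiny_world()
  catalog <- interface_catalog(w$chains)
  si <- build_structural_interactome(w$edges, w$alignments, catalog, quiet = TRUE)
  expect_equal(length(si), nrow(w$edges))  # identity hits: full coverage

  # remove all hits for 5 PPIs: those edges disappear
  drop_ppis <- w$edges$ppi_id[1:5]
  drop_sids <- w$structures$structure_id[match(drop_ppis, w$structures$ppi_id)]
  hits2 <- w$alignments[!(w$alignments$structure_id %in% drop_sids), ]
  si2 <- build_structural_interactome(w$edges, hits2, catalog, quiet = TRUE)
  expect_equal(length(si2), nrow(w$edges) - 5L)
  expect_false(any(drop_ppis %in% names(si2)))
})

test_that("the filter chain equals an independent record-by-record oracle", {
  w <- generate_world(synthetic_world_config(
    n_proteins = 18, n_ppis = 14, mean_protein_length = 90, interface_width = 5,
    n_disease_mut = 30, n_nondisease_mut = 30, seed = 3
  ), alignment_noise = TRUE)
  catalog <- interface_catalog(w$chains)
  si <- build_structural_interactome(w$edges, w$alignments, catalog, quiet = TRUE)
  want <- oracle_structural_interactome(w$edges, w$alignments, catalog)
  expect_setequal(names(si), names(want))
  for (k in names(si)) {
    expect_equal(si[[k]]$interface_a, want[[k]]$interface_a)
    expect_equal(si[[k]]$interface_b, want[[k]]$interface_b)
    expect_equal(nrow(si[[k]]$annotations), want[[k]]$n_annotations)
  }
  # no surviving annotation has coverage below 0.5 on either side
  for (k in names(si)) {
    expect_true(all(si[[k]]$annotations$coverage_a >= 0.5))
    expect_true(all(si[[k]]$annotations$coverage_b >= 0.5))
  }
})

test_that("structural interactomes round-trip through TSV", {
  w <- tiny_world()
  catalog <- interface_catalog(w$chains)
  si <- build_structural_interactome(w$edges, w$alignments, catalog, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structural_interactome(si, path)
  back <- read_structural_interactome(path)
  expect_equal(names(back), names(si))
  k <- names(si)[4]
  expect_equal(back[[k]]$interface_a, si[[k]]$interface_a)
  expect_equal(back[[k]]$protein_b, si[[k]]$protein_b)
})
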