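# Mutation filtering rules and flank-verified mapping.

mk_records <- function(...) {
  rows <- list(...)
  defaults <- list(mutation_id = NA_character_, protein_id = "P1",
                   transcript_sequence = NA_character_, transcript_position = NA_integer_,
                   wt_aa = NA_character_, mut_aa = NA_character_,
                   mutation_class = "disease", significance = "pathogenic",
                   review_stars = 2L, conflicting = FALSE, validated = TRUE,
                   withdrawn = FALSE, assertions = "", maf = 0.05)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
}

seq30 <- paste(rep(c("A", "R", "N", "D", "C", "Q"), 5), collapse = "")

test_that("filter_disease keeps strictly-pathogenic supported records only", {
  recs <- mk_records(
    list(mutation_id = "m1", transcript_sequence = seq30, transcript_position = 5L,
         wt_aa = "C", mut_aa = "W"),
    list(mutation_id = "m2", transcript_sequence = seq30, transcript_position = 6L,
         wt_aa = "Q", mut_aa = "W", significance = "pathogenic;likely pathogenic"),
    list(mutation_id = "m3", transcript_sequence = seq30, transcript_position = 7L,
         wt_aa = "A", mut_aa = "W", review_stars = 0L),
    list(mutation_id = "m4", transcript_sequence = seq30, transcript_position = 8L,
         wt_aa = "R", mut_aa = "W", conflicting = TRUE),
    list(mutation_id = "m5", transcript_sequence = seq30, transcript_position = 9L,
         wt_aa = "N", mut_aa = "N")  # not missense
  )
  out <- filter_disease(recs)
  expect_equal(out$mutation_id, "m1")
})

test_that("filter_disease collapses duplicate positions to one record", {
  recs <- mk_records(
    list(mutation_id = "m1", transcript_sequence = seq30, transcript_position = 5L,
         wt_aa = "C", mut_aa = "W"),
    list(mutation_id = "m2", transcript_sequence = seq30, transcript_position = 5L,
         wt_aa = "C", mut_aa = "Y"),
    list(mutation_id = "m3", transcript_sequence = seq30, transcript_position = 11L,
         wt_aa = "N", mut_aa = "W"),
    list(mutation_id = "m4", transcript_sequence = seq30, transcript_position = 11L,
         wt_aa = "N", mut_aa = "K"),
    list(mutation_id = "m5", transcript_sequence = seq30, transcript_position = 12L,
         wt_aa = "D", mut_aa = "K"),
    list(mutation_id = "m6", transcript_sequence = seq30, transcript_position = 13L,
         wt_aa = "C", mut_aa = "K")
  )
  out <- filter_disease(recs)
  expect_equal(nrow(out), 4L)
  expect_equal(out$mutation_id[out$transcript_position == 5], "m1")  # smallest id
  # idempotence
  expect_equal(filter_disease(out), out)
})

test_that("filter_nondisease applies flag, MAF and overlap rules", {
  recs <- mk_records(
    list(mutation_id = "s01", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 3L, wt_aa = "N", mut_aa = "K"),
    list(mutation_id = "s02", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 4L, wt_aa = "D", mut_aa = "K", validated = FALSE),
    list(mutation_id = "s03", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 5L, wt_aa = "C", mut_aa = "K", withdrawn = TRUE),
    list(mutation_id = "s04", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 6L, wt_aa = "Q", mut_aa = "K",
         assertions = "uncertain significance"),
    list(mutation_id = "s05", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 7L, wt_aa = "A", mut_aa = "K", maf = 0.01),
    list(mutation_id = "s06", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 8L, wt_aa = "R", mut_aa = "K"),
    list(mutation_id = "s07", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 9L, wt_aa = "N", mut_aa = "K"),
    list(mutation_id = "s08", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 10L, wt_aa = "C", mut_aa = "K"),
    list(mutation_id = "s09", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 11L, wt_aa = "N", mut_aa = "K"),
    list(mutation_id = "s10", mutation_class = "non_disease", transcript_sequence = seq30,
         transcript_position = 12L, wt_aa = "D", mut_aa = "K")
  )
  disease_pos <- data.frame(protein_id = "P1", position = c(9L, 10L))
  out <- filter_nondisease(recs, disease_pos)
  # s02/s03/s04 fail flags, s05 fails the strict MAF rule, s07/s08 (positions
  # 9 and 10) overlap disease positions -> 4 survive
  expect_equal(out$mutation_id, c("s01", "s06", "s09", "s10"))
  expect_equal(filter_nondisease(out, disease_pos), out)
})

test_that("flank_of takes up to 10 residues on each side", {
  s <- paste(rep("A", 30), collapse = "")
  expect_equal(nchar(flank_of(s, 15)), 21L)
  expect_equal(nchar(flank_of(s, 3)), 13L)
  expect_equal(flank_of("ARNDC", 1), "ARNDC")  # both flanks truncated
  expect_error(flank_of(s, 31), "out of range")
})

test_that("map_mutation requires the flank at the same position", {
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"
  rec <- list(transcript_sequence = prot, transcript_position = 12L,
              wt_aa = substr(prot, 12, 12), protein_id = "P1")
  expect_equal(map_mutation(rec, prot), 12L)

  # a protein with a one-residue N-terminal extension shifts the flank
  shifted <- paste0("G", prot)
  expect_true(is.na(map_mutation(rec, shifted)))
  # the looser mode recovers the shifted position from the unique occurrence
  expect_equal(map_mutation(rec, shifted, same_position = FALSE), 13L)
})

test_that("map_mutations matches scalar mapping and counts discards", {
  w <- tiny_world()
  recs <- w$mutations[1:50, ]
  # corrupt 10 transcripts inside the flank window so they cannot map
  bad <- 6:15
  for (i in bad) {
    p <- recs$transcript_position[i]
    s <- recs$transcript_sequence[i]
    swap_at <- max(1, p - 3)
    old <- substr(s, swap_at, swap_at)
    new <- if (old == "G") "P" else "G"
    substr(s, swap_at, swap_at) <- new
    if (swap_at == p) recs$wt_aa[i] <- new
    recs$transcript_sequence[i] <- s
  }
  mapped <- map_mutations(recs, w$proteins, quiet = TRUE)
  expect_equal(nrow(mapped), 40L)
  expect_equal(attr(mapped, "n_unmapped"), 10L)
  # vectorised batch mapping agrees with the scalar operation
  for (i in c(1, 6, 20, 44)) {
    want <- map_mutation(recs[i, ], w$proteins[[recs$protein_id[i]]])
    got <- mapped$protein_position[match(recs$mutation_id[i], mapped$mutation_id)]
    if (is.na(want)) expect_false(recs$mutation_id[i] %in% mapped$mutation_id)
    else expect_equal(got, want)
  }
  # every mapped residue equals the wild type
  wt <- substr(w$proteins[mapped$protein_id], mapped$protein_position,
               mapped$protein_position)
  expect_equal(unname(wt), mapped$wt_aa)
})

test_that("disease and non-disease mapped sets are position-disjoint", {
  w <- tiny_world()
  res <- run_pipeline(w, physics = FALSE)
  m <- res$mapped
  kd <- paste(m$protein_id[m$mutation_class == "disease"],
              m$protein_position[m$mutation_class == "disease"])
  kn <- paste(m$protein_id[m$mutation_class == "non_disease"],
              m$protein_position[m$mutation_class == "non_disease"])
  expect_length(intersect(kd, kn), 0)
})
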