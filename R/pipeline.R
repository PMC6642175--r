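# End-to-end pipeline over a synthetic world (or any equivalently shaped set
# of inputs): interface detection, structural interactome construction,
# mutation filtering and mapping, geometry- and physics-based edgotyping,
# and the dispensability estimate.

#' Run the full edgotyping pipeline
#'
#' @param world A [generate_world()] result, or a [read_world()] list.
#' @param evalue_cutoff,min_coverage,max_annotations Structural-interactome
#'   filter parameters.
#' @param ddg_threshold PPI disruption threshold in kcal/mol.
#' @param interface_cutoff Interface distance cutoff in angstrom.
#' @param priors A [fitness_priors()] object.
#' @param physics Also run the ddG-based edgotyping (default TRUE).
#' @param quiet Suppress progress messages.
#' @return List with elements `si`, `mapped`, `calls_geometry`,
#'   `counts_geometry`, `estimate_geometry`, and (when `physics`)
#'   `calls_physics`, `counts_physics`, `estimate_physics`, `gamma_N`,
#'   `gamma_M`.
#' @export
run_pipeline <- function(world,
                         evalue_cutoff = 1e-10,
                         min_coverage = 0.5,
                         max_annotations = 5,
                         ddg_threshold = 0.5,
                         interface_cutoff = 5.0,
                         priors = fitness_priors(),
                         physics = TRUE,
                         quiet = TRUE) {
  catalog <- interface_catalog(world$chains, cutoff = interface_cutoff)
  si <- build_structural_interactome(world$edges, world$alignments, catalog,
                                     evalue_cutoff = evalue_cutoff,
                                     min_coverage = min_coverage,
                                     max_annotations = max_annotations,
                                     quiet = quiet)

  mut <- world$mutations
  disease <- filter_disease(mut[mut$mutation_class == "disease", , drop = FALSE])
  mapped_d <- map_mutations(disease, world$proteins, quiet = quiet)
  disease_positions <- data.frame(protein_id = mapped_d$protein_id,
                                  position = mapped_d$protein_position)
  nondis <- filter_nondisease(mut[mut$mutation_class == "non_disease", , drop = FALSE],
                              disease_positions)
  mapped_n <- map_mutations(nondis, world$proteins, quiet = quiet)
  mapped <- rbind(mapped_d, mapped_n)

  calls_geo <- geometry_edgotypes(mapped, si)
  counts_geo <- tally_edgetic_counts(calls_geo)
  out <- list(si = si, mapped = mapped,
              calls_geometry = calls_geo,
              counts_geometry = counts_geo,
              estimate_geometry = estimate_dispensability(counts_geo, priors))

  if (physics && nrow(world$ddg_table) > 0) {
    calls_phys <- physics_edgotypes(mapped, si, world$ddg_table,
                                    threshold = ddg_threshold)
    counts_phys <- tally_edgetic_counts(calls_phys)
    out$calls_physics <- calls_phys
    out$counts_physics <- counts_phys
    out$estimate_physics <- estimate_dispensability(counts_phys, priors)
    out$gamma_N <- estimate_gamma(world$ddg_table, mapped, "non_disease",
                                  threshold = ddg_threshold)
    out$gamma_M <- estimate_gamma(world$ddg_table, mapped, "disease",
                                  threshold = ddg_threshold)
  }
  out
}
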