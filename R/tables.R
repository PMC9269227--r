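# Recorded example screen: the published best affinities of the three
# hemp-leaf cannabinoids against their retained anti-inflammatory targets,
# in replay form.

#' Recorded hemp cannabinoid screen (replay example)
#'
#' The retained results of an inverse virtual screen of the three
#' hemp-leaf cannabinoids ([hemp_compounds()]) against a panel of acute
#' inflammatory response proteins: per-compound best affinities on their
#' top target (tumor necrosis factor alpha) and on the two consensus
#' targets shared by all three compounds (prothrombin/thrombin and
#' PPARgamma), with the PDB-to-UniProt mapping of the structures
#' involved. Decoy affinities were not published; the bundled decoy table
#' is synthetic (a flat -6.5 kcal/mol for ten decoys on every structure),
#' which leaves every recorded hit's retention status unchanged.
#'
#' @return List ready for [run_screen()] with a [replay_backend()]:
#'   `affinities`, `decoy_affinities` (synthetic), `decoy_map`, `panel`,
#'   `compounds`.
#' @export
#' @examples
#' ex <- hemp_screen_example()
#' backend <- replay_backend(dplyr::bind_rows(ex$affinities,
#'                                            ex$decoy_affinities))
hemp_screen_example <- function() {
  affinities <- tibble(
    compound_id = c("1", "1", "1", "2", "2", "2", "3", "3", "3"),
    pdb_id = c("6X83", "6ZUX", "2ZK6",
               "7KPA", "6ZV8", "4PRG",
               "7KPA", "1RD3", "4PRG"),
    affinity_kcal_mol = c(-9.2, -8.4, -8.6,
                          -9.7, -8.6, -9.2,
                          -10.1, -8.5, -9.4)
  )
  panel <- tibble(
    pdb_id = c("6X83", "7KPA", "6ZUX", "6ZV8", "1RD3", "2ZK6", "4PRG"),
    uniprot_id = c("P01375", "P01375", "P00734", "P00734", "P00734",
                   "P37231", "P37231"),
    molecule_name = c(
      "Tumor necrosis factor", "Tumor necrosis factor",
      "Prothrombin/Thrombin", "Prothrombin/Thrombin",
      "Prothrombin/Thrombin",
      "Peroxisome proliferator-activated receptor gamma",
      "Peroxisome proliferator-activated receptor gamma"
    )
  )
  decoy_ids <- sprintf("D%02d", 1:10)
  decoy_affinities <- tidyr::crossing(compound_id = decoy_ids,
                                      pdb_id = panel$pdb_id) |>
    mutate(affinity_kcal_mol = -6.5)
  list(
    affinities = affinities,
    decoy_affinities = decoy_affinities,
    decoy_map = tidyr::crossing(query_id = c("1", "2", "3"),
                                decoy_id = decoy_ids),
    panel = panel,
    compounds = hemp_compounds()
  )
}
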