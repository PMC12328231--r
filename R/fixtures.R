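#' Bundled worked-example cascade fixture
#'
#' A 38-gene receptor-candidate pool with disease categories (13 shared, 18
#' AML-only, 7 bcCML-only), the 16-gene surface-misannotation blacklist, a
#' matching ligand-receptor table and ligand enrichment calls. The blacklist
#' names, the seven ligand-excluded receptors and several well-known
#' receptors (SLC6A6, LDLR, KIT, CD47, PRKD2, CD33) carry their real gene
#' symbols; the remaining candidate names, the category assignment of
#' individual genes, and all ligand calls are synthetic placeholders (the
#' underlying cohort data are not redistributable), so only the printed
#' counts and printed gene lists should be read as real. Running the cascade
#' on this fixture reproduces the audit trail 38 candidates -> 22 after
#' blacklist removal -> 15 receptors with enriched ligands.
#'
#' @return List: `candidates` (tibble `gene`, `category`, `name_source`),
#'   `blacklist`, `atlas`, `lr` (tibble `ligand`, `receptor`), `calls`
#'   (tibble of enrichment calls).
#' @export
cascade_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "nichemapper",
                                  mustWork = TRUE)
  candidates <- tibble::as_tibble(utils::read.delim(path("cascade_candidates_synthetic.tsv")))
  blacklist <- readLines(path("surface_blacklist.tsv"))
  lr <- tibble::as_tibble(utils::read.delim(path("lr_pairs_synthetic.tsv")))
  calls <- tibble::as_tibble(utils::read.delim(path("ligand_calls_synthetic.tsv")))
  list(candidates = candidates, blacklist = blacklist,
       atlas = candidates$gene, lr = lr, calls = calls)
}

#' Run the filtering cascade on the bundled fixture
#'
#' Applies [surface_filter()] and [exclude_by_ligand()] to the bundled
#' 38-candidate pool and returns the audit counts.
#'
#' @return One-row tibble: `candidates`, `blacklist_size`, `post_blacklist`,
#'   `no_known_ligand`, `no_enriched_ligand`, `survivors`.
#' @export
cascade_fixture_counts <- function() {
  fx <- cascade_fixture()
  sf <- surface_filter(fx$candidates$gene, fx$atlas, fx$blacklist)
  lig <- exclude_by_ligand(sf$kept, fx$lr, fx$calls)
  tibble::tibble(
    candidates = nrow(fx$candidates),
    blacklist_size = length(fx$blacklist),
    post_blacklist = length(sf$kept),
    no_known_ligand = sum(lig$exclusion_reason == "no_known_ligand"),
    no_enriched_ligand = sum(lig$exclusion_reason == "no_enriched_ligand"),
    survivors = sum(lig$exclusion_reason == "none")
  )
}
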