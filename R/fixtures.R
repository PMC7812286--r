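#' Bundled synthetic fibrosis-pathway membership fixtures
#'
#' Two small GMT collections shipped with the package that encode, purely
#' as membership multiplicities, the published per-gene
#' fibrosis-associated pathway counts for the twelve key candidate driver
#' genes (KEGG-style: Mmp7 1, Tgfb3 4, Id1 2, Hsd17b6 1, Cyp1a1 1, Fst 1,
#' Cxcl1 2, Retsat 1, Il1r2 2, Itgb21 2; IPA-style: Mmp7 5, Tgfb3 5,
#' Cxcl1 2, Mmp13 5, Ces1d 1, Il1r2 6). The set contents are synthetic —
#' built so that each gene's membership count matches the printed number —
#' because the underlying pathway databases are licensed; only the counts
#' carry information.
#'
#' @return list with `kegg` and `ipa` ([gene_set_collection()]s) and
#'   `key_genes` (the union of the two gene lists).
#' @export
fibrosis_pathway_fixtures <- function() {
  kegg <- read_gmt(system.file("extdata", "kegg_fibrosis_synthetic.gmt",
                               package = "dnbtip", mustWork = TRUE))
  ipa <- read_gmt(system.file("extdata", "ipa_fibrosis_synthetic.gmt",
                              package = "dnbtip", mustWork = TRUE))
  list(kegg = kegg, ipa = ipa,
       key_genes = sort(unique(c(unlist(kegg), unlist(ipa)))))
}
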