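# Canonical S-phase and G2/M marker gene lists (mouse symbol case), used as
# the default phase sets for cell-cycle scoring and by the synthetic
# generator to plant phase structure.

#' S-phase marker genes (mouse symbols)
#'
#' The widely used 43-gene S-phase list from melanoma single-cell work,
#' title-cased to mouse symbol convention.
#' @format Character vector of gene symbols.
#' @export
s_phase_genes <- c(
  "Mcm5", "Pcna", "Tyms", "Fen1", "Mcm2", "Mcm4", "Rrm1", "Ung", "Gins2",
  "Mcm6", "Cdca7", "Dtl", "Prim1", "Uhrf1", "Cenpu", "Hells", "Rfc2",
  "Rpa2", "Nasp", "Rad51ap1", "Gmnn", "Wdr76", "Slbp", "Ccne2", "Ubr7",
  "Pold3", "Msh2", "Atad2", "Rad51", "Rrm2", "Cdc45", "Cdc6", "Exo1",
  "Tipin", "Dscc1", "Blm", "Casp8ap2", "Usp1", "Clspn", "Pola1", "Chaf1b",
  "Brip1", "E2f8")

#' G2/M-phase marker genes (mouse symbols)
#'
#' The companion 54-gene G2/M list.
#' @format Character vector of gene symbols.
#' @export
g2m_phase_genes <- c(
  "Hmgb2", "Cdk1", "Nusap1", "Ube2c", "Birc5", "Tpx2", "Top2a", "Ndc80",
  "Cks2", "Nuf2", "Cks1b", "Mki67", "Tmpo", "Cenpf", "Tacc3", "Pimreg",
  "Smc4", "Ccnb2", "Ckap2l", "Ckap2", "Aurkb", "Bub1", "Kif11", "Anp32e",
  "Tubb4b", "Gtse1", "Kif20b", "Hjurp", "Cdca3", "Jpt1", "Cdc20", "Ttk",
  "Cdc25c", "Kif2c", "Rangap1", "Ncapd2", "Dlgap5", "Cdca2", "Cdca8",
  "Ect2", "Kif23", "Hmmr", "Aurka", "Psrc1", "Anln", "Lbr", "Ckap5",
  "Cenpe", "Ctcf", "Nek2", "G2e3", "Gas2l3", "Cbx5", "Cenpa")

#' Default exhaustion signature (mouse symbols)
#'
#' Canonical T cell exhaustion markers used as the generator's planted
#' exhaustion program and as the default scoring signature in examples and
#' tests. Real analyses should supply their published signature via GMT.
#' @format Character vector of gene symbols.
#' @export
exhaustion_genes <- c(
  "Pdcd1", "Ctla4", "Lag3", "Havcr2", "Tigit", "Tox", "Entpd1", "Cd160",
  "Eomes", "Batf", "Nr4a1", "Nr4a2", "Nr4a3", "Cd244a", "Vsir", "Btla",
  "Cd38", "Tnfrsf9", "Prdm1", "Cd101")
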