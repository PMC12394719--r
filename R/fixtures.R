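#' Shipped low-complexity domain sequences
#'
#' `fus_lcd()` is residues 1-163 of human FUS (UniProt P35637): 163 aa, two
#' negatively charged residues (D5, D46), no positively charged ones, net -2e.
#' `tdp43_lcd()` is the TDP-43 C-terminal low-complexity domain in local
#' numbering (offset +260 to full-length UniProt Q13148 numbering), carrying
#' the four LARKS at local positions 27-32, 39-44, 55-60 and 60-70; following
#' the annotation this package mirrors, the 60-70 LARKS is the literal motif
#' SWGAAGALASQ (the wild-type 321-330 span reads SWGMMGMLASQ; the discrepancy
#' is deliberate and kept). Composition: 3R + 1K vs 1D + 1E, net +2e.
#'
#' @return A [sequence_record()].
#' @export
fus_lcd <- function() {
  sequence_record("FUS_LCD", paste0(
    "MASNDYTQQATQSYGAYPTQPGQGYSQQSSQPYGQQSYSGYSQSTDTSGY",
    "GQSSYSSYGQSQNTGYGTQSTPQGYGSTGGYGSSQSSQSSYGQQSSYPGY",
    "GQQPAPSSTSGSYGSSSQSSSYGQPQSGSYSQQPSYGGQQQSYGQQQSYN",
    "PPQGYGQQNQYNS"), kind = "protein")
}

#' @rdname fus_lcd
#' @export
tdp43_lcd <- function() {
  sequence_record("TDP43_LCD", paste0(
    "GRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGSNMGGGMNFGAFSINPAMM",
    "AAAQAALQSSWGAAGALASQQNQSGPSGNNQNQGNMQREPNQAFGSGNNS",
    "YSGSNSGAAIGWGSASNAGSGSGFNGGFGSSMDSKSSGWGM"), kind = "protein")
}

#' Shipped LARKS annotations
#'
#' FUS LCD: 37-42 (SYSGYS), 54-61 (SYSSYGQS), 77-82 (STGGYG), structured
#' target 30 kBT. TDP-43 LCD (local numbering): 27-32 (GNNQGS), 39-44
#' (NFGAFS), 55-60 (AALQSS), 60-70 (SWGAAGALASQ), structured target 40 kBT.
#' Disordered baselines default to the 3-6 kBT window midpoint.
#'
#' @return A [larks_annotation()] tibble.
#' @export
fus_larks <- function() {
  larks_annotation("FUS_LCD", start = c(37, 54, 77), end = c(42, 61, 82),
                   e_dis = 4.5, e_str = 30)
}

#' @rdname fus_larks
#' @export
tdp43_larks <- function() {
  larks_annotation("TDP43_LCD", start = c(27, 39, 55, 60),
                   end = c(32, 44, 60, 70), e_dis = 4.5, e_str = 40)
}

#' The designed 24-residue peptide library
#'
#' The 13 named modulator peptides, in repeat notation; each expands to
#' exactly 24 residues.
#'
#' @return Named character vector of repeat-notation specs.
#' @export
peptide_library <- function() {
  specs <- c("(WY)12", "R24", "E24", "(SYGSYYGS)3", "(PHSY)6",
             "(SYSYEEEE)3", "(SYGSYEGS)3", "(SYGESYGSYGEG)2",
             "(SYGSYGSYEGEG)2", "(SYSYKRKS)3", "(SYSYKRKK)3",
             "(SYGKSYGSYGKG)2", "(SYGYSYGSYGYG)2")
  setNames(specs, specs)
}

#' Fast toy ageing system: eight sticky mini-chains with one LARKS each
#'
#' A synthetic 8-chain system (30 residues per chain, one central SYSGYS
#' LARKS) built to undergo a complete cross-beta ageing run in minutes on a
#' single core. Aromatic-rich background drives condensation; short cutoffs
#' keep the box valid at toy sizes.
#'
#' @param n_chains Number of chains.
#' @param density Bulk mass density, g/L.
#' @param temperature K.
#' @param e_str Structured per-LARKS target, kBT.
#' @param seed Build seed.
#' @return A [cg_system()] ready for [ageing_run()].
#' @export
mini_larks_system <- function(n_chains = 8, density = 700, temperature = 300,
                              e_str = 40, seed = 1) {
  rec <- mini_larks_record()
  tab <- forcefield_table(cutoff_ah = 1.2, cutoff_dh = 1.2)
  ann <- larks_annotation("MINI_LARKS", 13, 18, e_dis = 4.5, e_str = e_str)
  topo <- build_topology(list(rec), n_chains, tab, ann)
  cfg <- build_bulk(topo, density, seed = seed)
  sys <- cg_system(topo, cfg, tab,
                   compute_debye_length(0.15, temperature, tab$dielectric))
  minimize_config(sys)
}

mini_larks_record <- function() {
  sequence_record("MINI_LARKS",
                  paste0("SGYGSYGGSYGS", "SYSGYS", "GSYGSYGGSYGS"),
                  kind = "protein")
}

#' Write a named fixture to disk
#'
#' Writes the FASTA sequence(s), the LARKS annotation TSV and a run
#' configuration YAML for one of the shipped systems:
#' `"mini-larks-8"`, `"fus-lcd"`, `"tdp43-lcd"` or `"peptide-library"`.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of file paths written.
#' @export
make_fixture <- function(name = c("mini-larks-8", "fus-lcd", "tdp43-lcd",
                                  "peptide-library"),
                         dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  files <- list()
  if (name == "peptide-library") {
    recs <- lapply(peptide_library(), expand_repeat_notation)
    files$fasta <- write_fasta(recs, p("peptide_library.fasta"))
  } else {
    rec <- switch(name,
                  "mini-larks-8" = mini_larks_record(),
                  "fus-lcd" = fus_lcd(),
                  "tdp43-lcd" = tdp43_lcd())
    ann <- switch(name,
                  "mini-larks-8" = larks_annotation("MINI_LARKS", 13, 18,
                                                    e_dis = 4.5, e_str = 40),
                  "fus-lcd" = fus_larks(),
                  "tdp43-lcd" = tdp43_larks())
    base <- gsub("-", "_", name)
    files$fasta <- write_fasta(rec, p(paste0(base, ".fasta")))
    files$larks <- write_larks_tsv(ann, p(paste0(base, "_larks.tsv")))
    cfgobj <- list(
      system = list(protein = rec$name, copies = if (name == "mini-larks-8") 8L else 40L),
      forcefield = if (name == "mini-larks-8")
        list(cutoff_ah = 1.2, cutoff_dh = 1.2) else
          list(cutoff_ah = 2.0, cutoff_dh = 4.0),
      conditions = list(ionic_strength = 0.15, temperature = 300,
                        density_gL = if (name == "mini-larks-8") 700 else 500),
      ageing = list(min_cluster = 4L, growth_min = 2L, check_interval = 5000L,
                    reduced_temperature = 0.95),
      replicates = list(n = 6L, seeds = 1:6),
      notes = if (name == "tdp43-lcd")
        paste("local numbering, offset +260 to full-length numbering;",
              "60-70 LARKS uses the literal annotated motif SWGAAGALASQ",
              "in place of wild-type SWGMMGMLASQ") else NULL)
    files$config <- p(paste0(base, "_config.yaml"))
    yaml::write_yaml(cfgobj, files$config)
  }
  invisible(files)
}
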