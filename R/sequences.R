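.canonical_codes <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Sequence record
#'
#' A named amino-acid sequence with a role: `protein` (the condensate-forming
#' low-complexity domain) or `peptide` (a short designed modulator).
#'
#' @param name Record name.
#' @param residues Character scalar (one-letter codes) or character vector.
#' @param kind `"protein"` or `"peptide"`.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(name, residues, kind = c("protein", "peptide")) {
  kind <- match.arg(kind)
  if (length(residues) == 1 && nchar(residues[1]) > 1)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  if (length(residues) < 1) stop("sequence must have length >= 1")
  bad <- setdiff(unique(residues), .canonical_codes)
  if (length(bad) > 0)
    stop("non-canonical residue code(s) in '", name, "': ", paste(bad, collapse = ", "))
  structure(list(name = name, residues = residues, kind = kind),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%s, %d aa)\n  %s\n", x$name, x$kind,
              length(x$residues), paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
length.sequence_record <- function(x) length(x$residues)

#' Expand peptide repeat notation
#'
#' Accepts `"(BLOCK)n"` (n copies of BLOCK), `"Xn"` (n copies of residue X) or
#' a plain sequence, e.g. `"(SYGSYEGS)3"`, `"R24"`, `"SYSGYS"`.
#'
#' @param spec Repeat-notation string.
#' @param name Record name; defaults to the spec itself.
#' @param kind Passed to [sequence_record()].
#' @return A [sequence_record()].
#' @export
#' @examples
#' length(expand_repeat_notation("(WY)12")) # 24
expand_repeat_notation <- function(spec, name = spec, kind = "peptide") {
  spec <- gsub("\\s", "", spec)
  if (grepl("^\\([A-Za-z]+\\)[0-9]+$", spec)) {
    block <- sub("^\\(([A-Za-z]+)\\).*$", "\\1", spec)
    n <- as.integer(sub("^\\([A-Za-z]+\\)([0-9]+)$", "\\1", spec))
    seqs <- strrep(block, n)
  } else if (grepl("^[A-Za-z][0-9]+$", spec)) {
    n <- as.integer(sub("^[A-Za-z]([0-9]+)$", "\\1", spec))
    seqs <- strrep(substr(spec, 1, 1), n)
  } else if (grepl("^[A-Za-z]+$", spec)) {
    seqs <- spec
  } else {
    stop("malformed repeat notation: '", spec, "'")
  }
  sequence_record(name, seqs, kind)
}

#' Net charge of a sequence
#'
#' Sum of per-residue charges under the charge scheme configured in the
#' force-field table (histidine protonation, optional terminal charges).
#'
#' @param seq A [sequence_record()].
#' @param table A [forcefield_table()].
#' @return Signed net charge in elementary charges.
#' @export
net_charge <- function(seq, table) {
  idx <- match(seq$residues, table$residues$code)
  if (anyNA(idx)) stop("residue(s) not in force-field table")
  # +1e N-terminus and -1e C-terminus cancel in the net, so the terminal-charge
  # switch affects per-bead charges only
  sum(table$residues$charge[idx])
}

#' Chain mass
#'
#' @inheritParams net_charge
#' @return Summed residue mass in Da.
#' @export
chain_mass <- function(seq, table) {
  idx <- match(seq$residues, table$residues$code)
  if (anyNA(idx)) stop("residue(s) not in force-field table")
  sum(table$residues$mass[idx])
}

#' Resolve a peptide/protein stoichiometry from a mass ratio
#'
#' Converts a target mass ratio (mg peptide per mg protein) and a protein copy
#' number into an integer peptide copy number,
#' `round(mass_ratio * protein_copies * M_protein / M_peptide)`, and reports
#' the realized (post-rounding) mass ratio.
#'
#' @param mass_ratio Target mg peptide per mg protein, >= 0.
#' @param protein,peptide [sequence_record()]s.
#' @param protein_copies Number of protein chains.
#' @param table A [forcefield_table()] supplying residue masses.
#' @return A list of class `stoichiometry` with `mass_ratio` (target),
#'   `realized_ratio`, `protein_copies`, `peptide_copies`.
#' @export
resolve_stoichiometry <- function(mass_ratio, protein, peptide, protein_copies,
                                  table = forcefield_table()) {
  if (mass_ratio < 0) stop("mass_ratio must be >= 0")
  mp <- chain_mass(protein, table)
  mq <- chain_mass(peptide, table)
  if (mq <= 0) stop("peptide mass must be positive")
  k <- round(mass_ratio * protein_copies * mp / mq)
  structure(list(mass_ratio = mass_ratio,
                 realized_ratio = k * mq / (protein_copies * mp),
                 protein_copies = as.integer(protein_copies),
                 peptide_copies = as.integer(k)),
            class = "stoichiometry")
}

#' Read sequences from a FASTA file
#'
#' Standard FASTA dialect (`>` headers); validates records against the
#' canonical amino-acid alphabet.
#'
#' @param path FASTA file.
#' @param kind Role given to every record.
#' @return List of [sequence_record()]s.
#' @export
read_fasta <- function(path, kind = "protein") {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no FASTA records in ", path)
  lapply(seq_along(recs), function(i) {
    nm <- attr(recs[[i]], "name")
    aa <- toupper(as.character(recs[[i]]))
    if (length(aa) == 0) stop("empty FASTA record '", nm, "' in ", path)
    bad <- setdiff(unique(aa), .canonical_codes)
    if (length(bad) > 0)
      stop("illegal residue code(s) in record '", nm, "': ", paste(bad, collapse = ", "))
    sequence_record(nm, aa, kind)
  })
}

#' Write sequences to a FASTA file
#'
#' @param records A [sequence_record()] or list of them.
#' @param path Output path. Lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqinr::write.fasta(lapply(records, function(r) r$residues),
                      names = vapply(records, function(r) r$name, character(1)),
                      file.out = path, nbchar = 60)
  invisible(path)
}
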