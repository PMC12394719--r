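#' LARKS annotation table
#'
#' Annotates low-complexity aromatic-rich kinked segments (LARKS) on a named
#' sequence: 1-based inclusive local residue indices plus the disordered and
#' structured inter-protein binding energies (kBT per LARKS) that parameterize
#' the ageing engine.
#'
#' @param seq_name Sequence the annotation refers to.
#' @param start,end 1-based inclusive residue indices.
#' @param e_dis Disordered per-LARKS binding energy (kBT); informational
#'   baseline window of the model is 3-6 kBT.
#' @param e_str Structured (cross-beta) per-LARKS binding target (kBT);
#'   model window 30-50 kBT.
#' @return A tibble with one row per LARKS.
#' @export
larks_annotation <- function(seq_name, start, end, e_dis = 4.5, e_str = 40) {
  out <- tibble::tibble(seq_name = seq_name, start = as.integer(start),
                        end = as.integer(end), e_dis = e_dis, e_str = e_str)
  if (any(out$start < 1) || any(out$end < out$start))
    stop("require 1 <= start <= end")
  if (any(out$e_str <= out$e_dis))
    stop("structured energy must exceed disordered energy")
  out
}

#' Read or write LARKS annotations as TSV
#'
#' Columns: `seq`, `start`, `end`, `E_dis_kT`, `E_str_kT`.
#' @param path File path.
#' @return `read_larks_tsv()` returns an annotation tibble;
#'   `write_larks_tsv()` returns `path` invisibly.
#' @export
read_larks_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("seq", "start", "end", "E_dis_kT", "E_str_kT")
  if (!all(need %in% names(df)))
    stop("LARKS TSV must have columns: ", paste(need, collapse = ", "))
  larks_annotation(df$seq, df$start, df$end, df$E_dis_kT, df$E_str_kT)
}

#' @rdname read_larks_tsv
#' @param larks Annotation tibble from [larks_annotation()].
#' @export
write_larks_tsv <- function(larks, path) {
  out <- data.frame(seq = larks$seq_name, start = larks$start, end = larks$end,
                    E_dis_kT = larks$e_dis, E_str_kT = larks$e_str)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a bead-spring topology from sequences
#'
#' Instantiates `copies[i]` chains of each sequence record, resolves per-bead
#' force-field parameters, consecutive-bead harmonic bonds, and per-copy LARKS
#' instances with global bead ranges.
#'
#' @param records List of [sequence_record()]s.
#' @param copies Integer vector, chains per record.
#' @param table A [forcefield_table()].
#' @param larks Optional LARKS annotation tibble ([larks_annotation()]);
#'   annotations are matched to records by `seq_name` and instantiated once per
#'   chain copy.
#' @return An object of class `cg_topology`: list with `beads` (tibble),
#'   `bonds` (matrix), `chains` (tibble), `larks` (tibble of instances),
#'   `n_beads`.
#' @export
build_topology <- function(records, copies, table = forcefield_table(), larks = NULL) {
  if (inherits(records, "sequence_record")) records <- list(records)
  copies <- as.integer(copies)
  stopifnot(length(copies) == length(records), all(copies >= 0))
  beads <- list(); chains <- list(); bonds <- list(); inst <- list()
  bead0 <- 0L; chain_id <- 0L; inst_id <- 0L
  res <- table$residues
  for (k in seq_along(records)) {
    rec <- records[[k]]
    idx <- match(rec$residues, res$code)
    if (anyNA(idx)) stop("residue(s) of '", rec$name, "' not in force-field table")
    L <- length(rec$residues)
    q <- res$charge[idx]
    if (isTRUE(table$terminal_charges)) { q[1] <- q[1] + 1; q[L] <- q[L] - 1 }
    ann <- if (is.null(larks)) NULL else larks[larks$seq_name == rec$name, , drop = FALSE]
    if (!is.null(ann) && nrow(ann) > 0 && any(ann$end > L))
      stop("LARKS annotation exceeds length of '", rec$name, "'")
    for (cp in seq_len(copies[k])) {
      chain_id <- chain_id + 1L
      beads[[chain_id]] <- tibble::tibble(
        bead = bead0 + seq_len(L), chain = chain_id, resid = seq_len(L),
        code = rec$residues, sigma = res$sigma[idx], lambda = res$lambda[idx],
        charge = q, mass = res$mass[idx], seq_name = rec$name, kind = rec$kind)
      if (L > 1)
        bonds[[chain_id]] <- cbind(bead0 + seq_len(L - 1), bead0 + 2:L)
      chains[[chain_id]] <- tibble::tibble(chain = chain_id, seq_name = rec$name,
                                           kind = rec$kind, length = L, copy = cp)
      if (!is.null(ann) && nrow(ann) > 0) {
        for (a in seq_len(nrow(ann))) {
          inst_id <- inst_id + 1L
          inst[[inst_id]] <- tibble::tibble(
            instance = inst_id, chain = chain_id, seq_name = rec$name,
            start = ann$start[a], end = ann$end[a],
            bead_start = bead0 + ann$start[a], bead_end = bead0 + ann$end[a],
            e_dis = ann$e_dis[a], e_str = ann$e_str[a],
            motif = paste(rec$residues[ann$start[a]:ann$end[a]], collapse = ""))
        }
      }
      bead0 <- bead0 + L
    }
  }
  beads <- dplyr::bind_rows(beads)
  larks_tb <- if (length(inst)) dplyr::bind_rows(inst) else
    tibble::tibble(instance = integer(), chain = integer(), seq_name = character(),
                   start = integer(), end = integer(), bead_start = integer(),
                   bead_end = integer(), e_dis = numeric(), e_str = numeric(),
                   motif = character())
  beads$larks_instance <- NA_integer_
  if (nrow(larks_tb) > 0) {
    for (a in seq_len(nrow(larks_tb)))
      beads$larks_instance[larks_tb$bead_start[a]:larks_tb$bead_end[a]] <- larks_tb$instance[a]
  }
  structure(list(beads = beads,
                 bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2),
                 chains = dplyr::bind_rows(chains),
                 larks = larks_tb, n_beads = nrow(beads)),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d beads, %d chains, %d bonds, %d LARKS instances\n",
              x$n_beads, nrow(x$chains), nrow(x$bonds), nrow(x$larks)))
  invisible(x)
}

#' Total mass of a topology
#' @param topology A `cg_topology`.
#' @return Mass in Da (g/mol).
#' @export
topology_mass <- function(topology) sum(topology$beads$mass)

# Da/nm^3 -> g/L
.dens_conv <- 1e24 / 6.02214076e23

#' Mass density of a configuration
#' @param config A `cg_config`.
#' @param topology A `cg_topology`.
#' @return Density in g/L.
#' @export
mass_density <- function(config, topology) {
  topology_mass(topology) * .dens_conv / prod(config$box)
}

# place chains as non-overlapping random walks; dmin excluded-volume threshold
place_random_walks <- function(topology, box, dmin, bond_length, z_range = NULL,
                               max_retry = 1e4) {
  n <- topology$n_beads
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  for (c_id in topology$chains$chain) {
    beads <- which(topology$beads$chain == c_id)
    ok <- FALSE
    for (attempt in seq_len(max_retry)) {
      p <- matrix(NA_real_, length(beads), 3)
      p[1, ] <- runif(3) * box
      if (!is.null(z_range)) p[1, 3] <- runif(1, z_range[1], z_range[2])
      good <- TRUE
      if (placed > 0 && min_image_mindist(p[1, , drop = FALSE],
                                          pos[seq_len(placed), , drop = FALSE], box) < dmin)
        good <- FALSE
      if (good && length(beads) > 1) {
        for (b in 2:length(beads)) {
          step_ok <- FALSE
          for (tries in 1:50) {
            dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
            cand <- p[b - 1, ] + bond_length * dir
            if (!is.null(z_range) && (cand[3] < z_range[1] || cand[3] > z_range[2])) next
            prev <- rbind(if (placed > 0) pos[seq_len(placed), , drop = FALSE],
                          p[seq_len(b - 2), , drop = FALSE])
            if (!is.null(prev) && nrow(prev) > 0 &&
                min_image_mindist(matrix(cand, 1), prev, box) < dmin) next
            p[b, ] <- cand; step_ok <- TRUE; break
          }
          if (!step_ok) { good <- FALSE; break }
        }
      }
      if (good) { ok <- TRUE; break }
    }
    if (!ok) stop("packing error: could not place chain ", c_id,
                  " after ", max_retry, " retries (density unreachable?)")
    pos[beads, ] <- p
    placed <- placed + length(beads)
  }
  # wrap into the box
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  pos
}

min_image_mindist <- function(a, b, box) {
  d <- Inf
  for (i in seq_len(nrow(a))) {
    dd <- sweep(b, 2, a[i, ])
    for (k in 1:3) dd[, k] <- dd[, k] - box[k] * round(dd[, k] / box[k])
    d <- min(d, sqrt(min(rowSums(dd^2))))
  }
  d
}

#' Build a bulk (cubic) initial configuration
#'
#' Chains are placed as non-overlapping random walks in a cubic periodic box
#' sized so the realized mass density matches `target_density`. Deterministic
#' for a fixed seed.
#'
#' @param topology A `cg_topology`.
#' @param target_density Target mass density, g/L.
#' @param seed Integer RNG seed.
#' @param bond_length Bond length used for the walk (nm).
#' @param dmin_factor Excluded-volume threshold as a fraction of the smallest
#'   residue diameter.
#' @return An object of class `cg_config`: list with `positions` (nm, n x 3),
#'   `box` (3 edge lengths, nm), `periodic`.
#' @export
build_bulk <- function(topology, target_density, seed = 1,
                       bond_length = 0.38, dmin_factor = 0.7) {
  if (target_density <= 0) stop("density must be > 0")
  V <- topology_mass(topology) * .dens_conv / target_density
  L <- V^(1 / 3)
  dmin <- dmin_factor * min(topology$beads$sigma)
  set.seed(seed)
  pos <- place_random_walks(topology, c(L, L, L), dmin, bond_length)
  structure(list(positions = pos, box = c(L, L, L), periodic = c(TRUE, TRUE, TRUE)),
            class = "cg_config")
}

#' Build an elongated slab initial configuration
#'
#' A dense region is placed in the central third of the long (z) axis, with
#' vacuum elsewhere, for direct-coexistence runs. The two short edges are sized
#' so the central-third slab has density `slab_density`; the long edge is
#' `elongation_factor` times the short edge.
#'
#' @inheritParams build_bulk
#' @param elongation_factor Long-axis multiple of the short edge (> 1).
#' @param slab_density Mass density of the initial central slab, g/L.
#' @return A `cg_config`.
#' @export
build_slab <- function(topology, elongation_factor = 3, slab_density = 600,
                       seed = 1, bond_length = 0.38, dmin_factor = 0.7) {
  if (elongation_factor <= 1) stop("elongation_factor must be > 1")
  # slab volume = Ls^2 * (Lz/3) = Ls^3 * elongation/3
  Vslab <- topology_mass(topology) * .dens_conv / slab_density
  Ls <- (3 * Vslab / elongation_factor)^(1 / 3)
  Lz <- elongation_factor * Ls
  dmin <- dmin_factor * min(topology$beads$sigma)
  set.seed(seed)
  pos <- place_random_walks(topology, c(Ls, Ls, Lz), dmin, bond_length,
                            z_range = c(Lz / 3, 2 * Lz / 3))
  structure(list(positions = pos, box = c(Ls, Ls, Lz), periodic = c(TRUE, TRUE, TRUE)),
            class = "cg_config")
}

#' @export
print.cg_config <- function(x, ...) {
  cat(sprintf("<cg_config> %d beads, box %.2f x %.2f x %.2f nm\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Bundle a simulation system
#'
#' Convenience container tying a topology, a configuration and the interaction
#' parameters together for the runners.
#'
#' @param topology A `cg_topology`.
#' @param config A `cg_config`.
#' @param table A [forcefield_table()].
#' @param dh [compute_debye_length()] output.
#' @param bonded [bonded_params()].
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(topology, config, table = forcefield_table(),
                      dh = compute_debye_length(0.15, 300, table$dielectric),
                      bonded = bonded_params()) {
  structure(list(topology = topology, config = config, table = table,
                 dh = dh, bonded = bonded),
            class = "cg_system")
}

#' Serialize a topology snapshot to JSON
#' @param topology A `cg_topology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(list(
    chains = topology$chains, beads = topology$beads,
    bonds = as.data.frame(topology$bonds), larks = topology$larks),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
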