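#' Order-parameter settings for cross-beta nucleation detection
#'
#' The ageing engine watches for local high-density fluctuations of LARKS: a
#' cross-beta nucleus forms when at least `min_cluster` disordered LARKS on
#' pairwise-distinct chains fall within `cutoff` of each other (connected
#' component of the centre-to-centre proximity graph). Once a nucleus exists,
#' a disordered LARKS touching at least `growth_min` structured members of one
#' assembly converts by templated growth.
#'
#' @param cutoff Centre-to-centre proximity cutoff, nm. `NULL` defers to a
#'   topology-calibrated default: 1.2x the mean LARKS bead diameter (the
#'   bead-level contact criterion, just outside the pair-potential minimum)
#'   plus the rod-estimate radius of gyration of the LARKS segment, so that
#'   two segments whose beads sit at the potential minimum register as
#'   proximal even though their centres are separated by the segment extent.
#' @param min_cluster Minimum number of distinct-chain LARKS in a nucleus
#'   (>= 2; the model default is 4).
#' @param growth_min Structured neighbours required for templated growth.
#' @param check_interval Steps between detection sweeps.
#' @return List of class `order_parameter_params`.
#' @export
order_parameter_params <- function(cutoff = NULL, min_cluster = 4,
                                   growth_min = 2, check_interval = 5000) {
  stopifnot(min_cluster >= 2, is.null(cutoff) || cutoff > 0, growth_min >= 1)
  structure(list(cutoff = cutoff, min_cluster = as.integer(min_cluster),
                 growth_min = as.integer(growth_min),
                 check_interval = as.integer(check_interval)),
            class = "order_parameter_params")
}

resolve_cutoff <- function(params, topology, bond_length = 0.38) {
  if (!is.null(params$cutoff)) return(params$cutoff)
  lb <- topology$beads[!is.na(topology$beads$larks_instance), , drop = FALSE]
  if (nrow(lb) == 0) stop("topology has no LARKS instances")
  L <- mean(topology$larks$end - topology$larks$start + 1)
  # bead contact criterion + rod-estimate segment Rg
  1.2 * mean(lb$sigma) + bond_length * sqrt((L^2 - 1) / 12)
}

#' Create a LARKS state ledger
#'
#' The ageing bookkeeping object: per-instance disordered/structured flags,
#' assembly membership, the inter-LARKS pair-strength scale matrix applied by
#' the force field, and the transition event log. Structured counts are
#' non-decreasing over time (transitions are irreversible).
#'
#' @param topology A `cg_topology` with LARKS instances.
#' @return Object of class `larks_ledger`.
#' @export
larks_ledger <- function(topology) {
  n <- nrow(topology$larks)
  structure(list(
    state = rep("disordered", n),
    assembly = rep(NA_integer_, n),
    pair_scale = matrix(1, max(n, 1), max(n, 1)),
    events = tibble::tibble(time_ps = numeric(), kind = character(),
                            instances = list(), chains = list(),
                            partners = list()),
    n_assemblies = 0L),
    class = "larks_ledger")
}

#' @export
print.larks_ledger <- function(x, ...) {
  cat(sprintf("<larks_ledger> %d LARKS: %d structured, %d events\n",
              length(x$state), sum(x$state == "structured"), nrow(x$events)))
  invisible(x)
}

#' Structured fraction of a ledger
#' @param ledger A `larks_ledger`.
#' @return Fraction of LARKS instances in the structured state.
#' @export
structured_fraction <- function(ledger) {
  if (length(ledger$state) == 0) return(0)
  mean(ledger$state == "structured")
}

#' Centres of geometry of all LARKS instances
#'
#' Each segment is unwrapped relative to its first bead (minimum image along
#' the chain) before averaging, then the centre is wrapped back into the box,
#' so centres are consistent for chains crossing the periodic boundary.
#'
#' @param config A `cg_config`.
#' @param topology A `cg_topology`.
#' @return `n_larks x 3` matrix of positions (nm).
#' @export
larks_centers <- function(config, topology) {
  la <- topology$larks
  out <- matrix(NA_real_, nrow(la), 3)
  pos <- config$positions; box <- config$box
  for (i in seq_len(nrow(la))) {
    beads <- la$bead_start[i]:la$bead_end[i]
    p <- pos[beads, , drop = FALSE]
    ref <- p[1, ]
    d <- sweep(p, 2, ref)
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    ctr <- ref + colMeans(d)
    out[i, ] <- ctr %% box
  }
  out
}

center_dist_matrix <- function(centers, box) {
  n <- nrow(centers)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (k in 1:3) {
    dk <- outer(centers[, k], centers[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d <- d + dk^2
  }
  sqrt(d)
}

#' Detect cross-beta nucleation clusters
#'
#' Candidate nuclei are connected components of the proximity graph over the
#' *disordered* LARKS centres (edges at distance <= cutoff). A component
#' qualifies when it spans at least `min_cluster` pairwise-distinct chains;
#' the event members are one LARKS per chain (the one closest to the component
#' centroid), so detection is invariant under chain relabelling.
#'
#' @param centers Matrix from [larks_centers()].
#' @param topology A `cg_topology`.
#' @param params [order_parameter_params()].
#' @param ledger Current [larks_ledger()].
#' @param box Box edge lengths (nm).
#' @return List of integer vectors of LARKS instance ids (possibly empty).
#' @export
detect_nucleation_clusters <- function(centers, topology, params, ledger, box) {
  cand <- which(ledger$state == "disordered")
  if (length(cand) < params$min_cluster) return(list())
  cutoff <- resolve_cutoff(params, topology)
  if (cutoff <= 0) return(list())
  d <- center_dist_matrix(centers[cand, , drop = FALSE], box)
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (cc in unique(comp)) {
    memb <- cand[comp == cc]
    ch <- topology$larks$chain[memb]
    if (length(unique(ch)) < params$min_cluster) next
    # one LARKS per chain: the member closest to the component centroid
    centroid <- colMeans(centers[memb, , drop = FALSE])
    dist_c <- sqrt(rowSums(sweep(centers[memb, , drop = FALSE], 2, centroid)^2))
    pick <- vapply(split(seq_along(memb), ch), function(ii) memb[ii[which.min(dist_c[ii])]],
                   integer(1))
    out[[length(out) + 1]] <- sort(unname(pick))
  }
  out
}

# per-LARKS binding energy (kBT) of instance `a` against partner instances,
# from summed aligned-pair potential minima at contact
larks_pair_binding <- function(topology, table, dh, a, partners, temperature) {
  la <- topology$larks
  kT <- .kB * temperature
  beads <- topology$beads
  total <- 0
  for (b in partners) {
    ia <- la$bead_start[a]:la$bead_end[a]
    ib <- la$bead_start[b]:la$bead_end[b]
    L <- min(length(ia), length(ib))
    for (k in seq_len(L)) {
      i <- ia[k]; j <- ib[k]
      pp <- list(sigma_ij = (beads$sigma[i] + beads$sigma[j]) / 2,
                 lam_ij = (beads$lambda[i] + beads$lambda[j]) / 2)
      rmin <- 2^(1 / 6) * pp$sigma_ij
      u <- ashbaugh_hatch_energy(rmin, pp, table$eps_ah, table$cutoff_ah) +
        debye_huckel_energy(rmin, beads$charge[i] * beads$charge[j], dh, table$cutoff_dh)
      total <- total - u
    }
  }
  total / kT
}

#' Apply an irreversible cross-beta transition
#'
#' Marks the cluster members structured, rescales the Ashbaugh-Hatch energy of
#' inter-chain bead pairs between member LARKS so each member's summed
#' aligned-pair binding minima reach its configured structured target (kBT),
#' activates the angle potential along the member segments (implicitly, via
#' the ledger), and appends a time-stamped event. Members must all be
#' disordered; re-transition attempts are a logic error.
#'
#' @param ledger A [larks_ledger()].
#' @param cluster Integer vector of instance ids (from
#'   [detect_nucleation_clusters()]), or a single id for templated growth.
#' @param topology,table,dh System description (for the energy solve).
#' @param temperature K (defines kBT for the binding targets).
#' @param time_ps Event timestamp.
#' @param partners For templated growth: the structured instances the new
#'   member binds to. Default `NULL` means a nucleation event where every
#'   member partners with every other member.
#' @param kind Event label.
#' @return The updated ledger.
#' @export
apply_transition <- function(ledger, cluster, topology, table, dh, temperature,
                             time_ps = NA_real_, partners = NULL,
                             kind = "nucleation") {
  if (any(ledger$state[cluster] != "disordered"))
    stop("logic error: re-transition of a structured LARKS attempted")
  la <- topology$larks
  kT <- .kB * temperature
  if (is.null(partners)) {
    partner_of <- lapply(cluster, function(a) setdiff(cluster, a))
    assembly <- ledger$n_assemblies + 1L
    ledger$n_assemblies <- assembly
  } else {
    partner_of <- rep(list(partners), length(cluster))
    assembly <- unique(ledger$assembly[partners])
    assembly <- assembly[!is.na(assembly)][1]
  }
  # per-member scale so summed aligned pair minima hit the structured target;
  # for a pair of freshly nucleating members the geometric mean of the two
  # member scales is used (identical for same-motif LARKS, where the target is
  # then met exactly)
  scale_of <- numeric(length(cluster))
  for (i in seq_along(cluster)) {
    a <- cluster[i]
    base <- larks_pair_binding(topology, table, dh, a, partner_of[[i]], temperature)
    if (base <= 0) stop("non-attractive disordered baseline for LARKS ", a)
    scale_of[i] <- la$e_str[a] / base
  }
  for (i in seq_along(cluster)) {
    a <- cluster[i]
    for (b in partner_of[[i]]) {
      s <- if (b %in% cluster) sqrt(scale_of[i] * scale_of[match(b, cluster)]) else scale_of[i]
      ledger$pair_scale[a, b] <- s
      ledger$pair_scale[b, a] <- s
    }
  }
  ledger$state[cluster] <- "structured"
  ledger$assembly[cluster] <- assembly
  ledger$events <- dplyr::bind_rows(ledger$events, tibble::tibble(
    time_ps = time_ps, kind = kind,
    instances = list(as.integer(cluster)),
    chains = list(as.integer(la$chain[cluster])),
    partners = list(as.integer(if (is.null(partners)) integer() else partners))))
  ledger
}

#' Templated-growth attachment candidates
#'
#' Disordered LARKS within the cutoff of at least `growth_min` structured
#' LARKS belonging to one assembly (on chains distinct from the candidate's)
#' are returned for conversion, mimicking elongation once a stable nucleus
#' exists.
#'
#' @inheritParams detect_nucleation_clusters
#' @return List of `list(instance =, partners =)` entries (possibly empty).
#' @export
growth_attachment <- function(centers, topology, params, ledger, box) {
  str_idx <- which(ledger$state == "structured")
  if (length(str_idx) == 0) return(list())
  dis_idx <- which(ledger$state == "disordered")
  if (length(dis_idx) == 0) return(list())
  cutoff <- resolve_cutoff(params, topology)
  out <- list()
  d <- center_dist_matrix(centers, box)
  for (a in dis_idx) {
    nb <- str_idx[d[a, str_idx] <= cutoff &
                    topology$larks$chain[str_idx] != topology$larks$chain[a]]
    if (length(nb) == 0) next
    by_asm <- split(nb, ledger$assembly[nb])
    counts <- vapply(by_asm, length, integer(1))
    if (max(counts) >= params$growth_min) {
      best <- by_asm[[which.max(counts)]]
      out[[length(out) + 1]] <- list(instance = a, partners = sort(best))
    }
  }
  out
}

#' Non-equilibrium ageing run
#'
#' Runs bulk NVT Langevin dynamics and, every `check_interval` steps, applies
#' the cross-beta state machine: nucleation detection over disordered LARKS,
#' then templated growth next to existing assemblies. Transitions are
#' irreversible, strengthen inter-member LARKS interactions to the structured
#' targets, and rigidify the member segments through the angle potential.
#'
#' @param system A [cg_system()] (bulk configuration at the pre-ageing
#'   condensate density).
#' @param params [integrator_params()].
#' @param op_params [order_parameter_params()].
#' @param n_steps Total steps.
#' @param thin Trajectory recording interval (steps).
#' @return List of class `ageing_result`: `curve` (tibble `time_ps`,
#'   `structured_count`, `structured_fraction`), `events` tibble, final
#'   `ledger`, and the concatenated `trajectory`.
#' @export
ageing_run <- function(system, params, op_params = order_parameter_params(),
                       n_steps = 1e5, thin = NULL) {
  topo <- system$topology
  ledger <- larks_ledger(topo)
  n_inst <- nrow(topo$larks)
  ci <- op_params$check_interval
  if (is.null(thin)) thin <- ci
  n_checks <- floor(n_steps / ci)
  curve <- tibble::tibble(time_ps = numeric(n_checks + 1),
                          structured_count = integer(n_checks + 1),
                          structured_fraction = numeric(n_checks + 1))
  curve$time_ps[1] <- 0
  curve$structured_count[1] <- 0L
  curve$structured_fraction[1] <- 0
  set.seed(params$seed)
  vel <- init_velocities(topo, params$temperature)
  pieces <- vector("list", n_checks)
  cfg <- system$config
  for (ch in seq_len(n_checks)) {
    tr <- run_engine(system, params, ci, thin, state = ledger,
                     velocities = vel, t_offset = (ch - 1) * ci * params$dt,
                     reseed = FALSE)
    cfg$positions <- tr$final$positions
    system$config <- cfg
    vel <- tr$final$velocities
    pieces[[ch]] <- tr
    t_now <- ch * ci * params$dt
    if (n_inst > 0 && any(ledger$state == "disordered")) {
      centers <- larks_centers(cfg, topo)
      clusters <- detect_nucleation_clusters(centers, topo, op_params, ledger, cfg$box)
      for (cl in clusters) {
        cl <- cl[ledger$state[cl] == "disordered"]
        if (length(cl) >= op_params$min_cluster)
          ledger <- apply_transition(ledger, cl, topo, system$table, system$dh,
                                     params$temperature, time_ps = t_now)
      }
      growth <- growth_attachment(centers, topo, op_params, ledger, cfg$box)
      for (g in growth) {
        if (ledger$state[g$instance] == "disordered")
          ledger <- apply_transition(ledger, g$instance, topo, system$table,
                                     system$dh, params$temperature,
                                     time_ps = t_now, partners = g$partners,
                                     kind = "growth")
      }
    }
    curve$time_ps[ch + 1] <- t_now
    curve$structured_count[ch + 1] <- sum(ledger$state == "structured")
    curve$structured_fraction[ch + 1] <- structured_fraction(ledger)
  }
  events <- ledger$events
  structure(list(curve = structure(curve, class = c("ageing_curve", class(curve))),
                 events = events, ledger = ledger,
                 trajectory = bind_trajectories(pieces)),
            class = "ageing_result")
}

#' @export
print.ageing_result <- function(x, ...) {
  cat(sprintf("<ageing_result> %d checks, final structured fraction %.2f, %d events\n",
              nrow(x$curve) - 1, tail(x$curve$structured_fraction, 1), nrow(x$events)))
  invisible(x)
}

#' Write a transition event log as JSONL
#'
#' One JSON object per line: time, LARKS instance ids, chain ids, event kind.
#'
#' @param events Events tibble from [ageing_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(list(time_ps = events$time_ps[i],
                                     kind = events$kind[i],
                                     larks = events$instances[[i]],
                                     chains = events$chains[[i]]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
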