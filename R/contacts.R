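# Salt-bridge detection, site assignment, contact timelines, and the two
# summary statistics: the per-glutamate interaction-rate matrix and the
# tail inaccessibility trace.

#' Salt-bridge geometric criterion
#'
#' A tail residue and a body residue form a salt bridge when any sidechain
#' donor nitrogen (Lys NZ; Arg NE/NH1/NH2) lies within `cutoff` of any
#' carboxylate oxygen (Glu OE1/OE2; Asp OD1/OD2; for a C-terminal residue,
#' OXT and the backbone carbonyl O).  The 4.0 Angstrom default is the
#' common salt-bridge convention; it is fully configurable and every
#' downstream statistic can be recomputed at other cutoffs.
#'
#' @param cutoff donor-acceptor distance cutoff in Angstrom (> 0).
#' @param donor_atoms named list mapping residue name to donor atom names.
#' @param acceptor_atoms named list mapping residue name to acceptor atom
#'   names.
#' @param cterm_acceptors acceptor atom names contributed by a C-terminal
#'   residue (one bearing an OXT).
#' @return an object of class `salt_bridge_criterion`.
#' @export
salt_bridge_criterion <- function(cutoff = 4.0,
                                  donor_atoms = list(
                                    LYS = "NZ",
                                    ARG = c("NE", "NH1", "NH2")),
                                  acceptor_atoms = list(
                                    GLU = c("OE1", "OE2"),
                                    ASP = c("OD1", "OD2")),
                                  cterm_acceptors = c("OXT", "O")) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, donor_atoms = donor_atoms,
                 acceptor_atoms = acceptor_atoms,
                 cterm_acceptors = cterm_acceptors),
            class = "salt_bridge_criterion")
}

# acceptor atoms among `sel` (atom indices): carboxylate oxygens, plus the
# terminal carboxylate of OXT-bearing residues when include_cterm; warns
# once and skips residues that lack their named atoms
acceptor_atoms_of <- function(topology, sel, criterion,
                              include_cterm = FALSE) {
  at <- topology$atoms
  out <- integer(0)
  key <- paste(at$chain[sel], at$resno[sel])
  for (res_key in unique(key)) {
    idx <- sel[key == res_key]
    resid <- at$resid[idx[1]]
    want <- criterion$acceptor_atoms[[resid]]
    has_oxt <- any(at$elety[idx] == "OXT")
    if (is.null(want) && !(include_cterm && has_oxt)) next
    got <- idx[at$elety[idx] %in% want]
    if (!is.null(want) && !length(got)) {
      warning("residue ", resid, " ", res_key,
              " lacks acceptor atoms (", paste(want, collapse = ","),
              "); skipped", call. = FALSE)
      next
    }
    if (include_cterm && has_oxt)
      got <- c(got, idx[at$elety[idx] %in% criterion$cterm_acceptors])
    out <- c(out, got)
  }
  sort(unique(out))
}

donor_atoms_of <- function(topology, sel, criterion) {
  at <- topology$atoms
  out <- integer(0)
  key <- paste(at$chain[sel], at$resno[sel])
  for (res_key in unique(key)) {
    idx <- sel[key == res_key]
    resid <- at$resid[idx[1]]
    want <- criterion$donor_atoms[[resid]]
    if (is.null(want)) next
    got <- idx[at$elety[idx] %in% want]
    if (!length(got)) {
      warning("residue ", resid, " ", res_key,
              " lacks donor atoms (", paste(want, collapse = ","),
              "); skipped", call. = FALSE)
      next
    }
    out <- c(out, got)
  }
  sort(unique(out))
}

# logical A x D matrix of donor-acceptor atom pairs within cutoff
contact_matrix_brute <- function(acc_xyz, don_xyz, cutoff, box = NULL) {
  A <- nrow(acc_xyz); D <- nrow(don_xyz)
  dx <- outer(acc_xyz[, 1], don_xyz[, 1], "-")
  dy <- outer(acc_xyz[, 2], don_xyz[, 2], "-")
  dz <- outer(acc_xyz[, 3], don_xyz[, 3], "-")
  if (!is.null(box) && box$mode == "axial_periodic") {
    # axis is +z by package convention after lattice building; general axis
    ax <- box$axis; L <- box$axial_length
    comp <- dx * ax[1] + dy * ax[2] + dz * ax[3]
    corr <- -L * round(comp / L)
    dx <- dx + corr * ax[1]; dy <- dy + corr * ax[2]; dz <- dz + corr * ax[3]
  }
  dx * dx + dy * dy + dz * dz <= cutoff^2
}

# same result via spatial hashing on a cutoff-sized grid; the z axis is
# wrapped into [0, L) and binned into an integer number of cells when the
# box is axially periodic (box axis must be +z for the cell path)
contact_matrix_cells <- function(acc_xyz, don_xyz, cutoff, box = NULL) {
  periodic <- !is.null(box) && box$mode == "axial_periodic"
  if (periodic && max(abs(box$axis - c(0, 0, 1))) > 1e-9)
    return(contact_matrix_brute(acc_xyz, don_xyz, cutoff, box))
  out <- matrix(FALSE, nrow(acc_xyz), nrow(don_xyz))
  if (periodic) {
    L <- box$axial_length
    nz <- max(1L, floor(L / cutoff))
    hz <- L / nz
    wrap_z <- function(z) z - L * floor(z / L)
    az <- wrap_z(acc_xyz[, 3]); dz <- wrap_z(don_xyz[, 3])
  } else {
    nz <- NA; hz <- cutoff
    az <- acc_xyz[, 3]; dz <- don_xyz[, 3]
  }
  cell_of <- function(x, y, z)
    cbind(floor(x / cutoff), floor(y / cutoff), floor(z / hz))
  dc <- cell_of(don_xyz[, 1], don_xyz[, 2], dz)
  don_key <- paste(dc[, 1], dc[, 2], dc[, 3])
  don_map <- split(seq_len(nrow(don_xyz)), don_key)
  ac <- cell_of(acc_xyz[, 1], acc_xyz[, 2], az)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (i in seq_len(nrow(acc_xyz))) {
    zz <- ac[i, 3] + offs[, 3]
    if (periodic) zz <- zz %% nz
    keys <- unique(paste(ac[i, 1] + offs[, 1], ac[i, 2] + offs[, 2], zz))
    cand <- unlist(don_map[keys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d <- sweep(don_xyz[cand, , drop = FALSE], 2, acc_xyz[i, ])
    if (periodic) {
      w <- d[, 3] - L * round(d[, 3] / L)
      d[, 3] <- w
    }
    hit <- rowSums(d * d) <= cut2
    out[i, cand[hit]] <- TRUE
  }
  out
}

#' Detect tail-body salt bridges in one frame
#'
#' Reports a (tail residue, body residue) contact iff any donor-acceptor
#' atom pair is within the criterion cutoff; multiple qualifying atom pairs
#' collapse to one residue-level contact.  Distances honor the minimum
#' image convention when the box is axially periodic.
#'
#' @param frame n x 3 coordinate matrix for all topology atoms, or NULL to
#'   use the topology's own coordinates.
#' @param topology a `lattice_model`.
#' @param criterion a [salt_bridge_criterion()].
#' @param tail_selection atom indices of candidate acceptor residues
#'   (acidic tail residues), e.g. from [select_atoms()].
#' @param body_selection atom indices of candidate donor residues (basic
#'   body residues).
#' @param box optional [box_geometry()] (defaults to the topology's box).
#' @param method `"brute"` (all pairs), `"cells"` (neighbor-list spatial
#'   hash; identical results) or `"auto"`.
#' @param include_cterm also treat OXT-bearing selected residues as
#'   acceptors through their terminal carboxylate.
#' @return data frame with columns `tail_chain`, `tail_resno`,
#'   `body_chain`, `body_resno`, one row per contact.
#' @export
detect_salt_bridges <- function(frame = NULL, topology,
                                criterion = salt_bridge_criterion(),
                                tail_selection, body_selection,
                                box = topology$box,
                                method = c("auto", "brute", "cells"),
                                include_cterm = FALSE) {
  method <- match.arg(method)
  if (!length(tail_selection) || !length(body_selection))
    stop("tail and body selections must be nonempty")
  acc <- acceptor_atoms_of(topology, tail_selection, criterion, include_cterm)
  don <- donor_atoms_of(topology, body_selection, criterion)
  if (!length(acc) || !length(don))
    return(data.frame(tail_chain = character(0), tail_resno = integer(0),
                      body_chain = character(0), body_resno = integer(0)))
  xyz <- if (is.null(frame)) coords(topology) else as.matrix(frame)
  if (method == "auto")
    method <- if (length(acc) * length(don) > 250000) "cells" else "brute"
  M <- if (method == "brute")
    contact_matrix_brute(xyz[acc, , drop = FALSE], xyz[don, , drop = FALSE],
                         criterion$cutoff, box)
  else
    contact_matrix_cells(xyz[acc, , drop = FALSE], xyz[don, , drop = FALSE],
                         criterion$cutoff, box)
  hits <- which(M, arr.ind = TRUE)
  at <- topology$atoms
  out <- unique(data.frame(
    tail_chain = at$chain[acc[hits[, 1]]],
    tail_resno = at$resno[acc[hits[, 1]]],
    body_chain = at$chain[don[hits[, 2]]],
    body_resno = at$resno[don[hits[, 2]]],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# number of rings present in a labeled model
ring_count <- function(topology) {
  r <- topology$chains$ring
  if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE) + 1L
}

#' Assign detected contacts to interaction sites
#'
#' A contact is labeled with site `s` only if its body residue belongs to
#' `s` in the registry *and* the body chain satisfies the site's host
#' relation for the tail's chain: `cis_alpha` requires the same alpha chain
#' that bears the tail; `trans_beta_minus` requires the beta chain of the
#' dimer one ring toward the minus end on the same protofilament (wrapping
#' across the boundary when the box is axially periodic).  Contacts with
#' basic residues outside all sites are labeled `"other"` and retained.
#'
#' @param contacts data frame from [detect_salt_bridges()].
#' @param registry a [site_registry()].
#' @param topology a labeled `lattice_model`.
#' @param box optional box (defaults to the topology's) controlling the
#'   minus-neighbor wrap.
#' @return `contacts` with an added `site` column
#'   (`"1","2","3","4","other"`).
#' @export
assign_sites <- function(contacts, registry, topology, box = topology$box) {
  ch <- topology$chains
  if (any(is.na(ch$pf[ch$role %in% c("alpha", "beta")])) ||
      any(is.na(ch$ring[ch$role %in% c("alpha", "beta")])))
    stop("topology lacks protofilament/ring labels; run the lattice ",
         "builder (or label chains) before site assignment")
  nr <- ring_count(topology)
  periodic <- !is.null(box) && box$mode == "axial_periodic"
  site <- rep("other", nrow(contacts))
  if (!nrow(contacts)) {
    contacts$site <- character(0)
    return(contacts)
  }
  tci <- match(contacts$tail_chain, ch$chain)
  bci <- match(contacts$body_chain, ch$chain)
  at <- topology$atoms
  body_resname <- at$resid[match(paste(contacts$body_chain,
                                       contacts$body_resno),
                                 paste(at$chain, at$resno))]
  for (s in unique(registry$site_id)) {
    rows <- registry[registry$site_id == s, ]
    host <- rows$host[1]
    in_site <- paste(contacts$body_resno, body_resname) %in%
      paste(rows$resno, rows$resname)
    ok <- if (host == "cis_alpha") {
      in_site & contacts$body_chain == contacts$tail_chain
    } else {
      minus_ring <- ch$ring[tci] - 1L
      if (periodic) minus_ring <- minus_ring %% nr
      in_site & ch$role[bci] == "beta" & ch$pf[bci] == ch$pf[tci] &
        ch$ring[bci] == minus_ring
    }
    if (any(ok & site != "other"))
      stop("contact matches more than one site; registry is ambiguous")
    site[ok] <- as.character(s)
  }
  contacts$site <- site
  contacts
}

# Precomputed plan for scanning a trajectory: acceptor atoms grouped by
# (tail, residue) and, per tail, the site label of every donor atom.
contact_plan <- function(topology, registry, criterion,
                         tail_role = "alpha", tail_resno = 441:451,
                         include_cterm = FALSE, box = topology$box) {
  ch <- topology$chains
  tails <- ch$chain[ch$role == tail_role]
  if (!length(tails)) stop("no chains with role '", tail_role, "'")
  if (any(is.na(ch$pf[ch$role %in% c("alpha", "beta")])))
    stop("topology lacks lattice labels")
  sel <- select_atoms(topology, chain = tails, resno = tail_resno)
  acc <- acceptor_atoms_of(topology, sel, criterion, include_cterm)
  if (!length(acc)) stop("no acceptor atoms among the tail residues")
  at <- topology$atoms
  body_sel <- select_atoms(topology, role = c("alpha", "beta"),
                           resid = c("LYS", "ARG"))
  don <- donor_atoms_of(topology, body_sel, criterion)

  acc_tail <- match(at$chain[acc], tails)
  residues <- sort(unique(at$resno[acc]))
  acc_res <- match(at$resno[acc], residues)

  nr <- ring_count(topology)
  periodic <- !is.null(box) && box$mode == "axial_periodic"
  don_chain_i <- match(at$chain[don], ch$chain)
  don_resno <- at$resno[don]
  don_resname <- at$resid[don]

  # site label of each donor atom as seen from each tail (0 = other)
  lab <- matrix(0L, length(tails), length(don))
  eligible <- matrix(TRUE, length(tails), 4L,
                     dimnames = list(tails, as.character(1:4)))
  for (ti in seq_along(tails)) {
    tci <- match(tails[ti], ch$chain)
    for (s in unique(registry$site_id)) {
      rows <- registry[registry$site_id == s, ]
      in_site <- paste(don_resno, don_resname) %in%
        paste(rows$resno, rows$resname)
      if (rows$host[1] == "cis_alpha") {
        ok <- in_site & at$chain[don] == tails[ti]
      } else {
        minus_ring <- ch$ring[tci] - 1L
        if (periodic) minus_ring <- minus_ring %% nr
        if (minus_ring < 0) {
          # minus-most ring of a non-periodic lattice: no trans partner
          eligible[ti, as.character(s)] <- FALSE
          next
        }
        ok <- in_site & ch$role[don_chain_i] == "beta" &
          ch$pf[don_chain_i] == ch$pf[tci] & ch$ring[don_chain_i] == minus_ring
      }
      lab[ti, ok] <- as.integer(s)
    }
  }
  list(topology = topology, criterion = criterion, box = box,
       tails = tails, residues = residues, acc = acc, don = don,
       acc_tail = acc_tail, acc_res = acc_res, lab = lab,
       eligible = eligible)
}

#' Build a contact timeline over a trajectory
#'
#' Runs per-frame salt-bridge detection and site assignment, producing the
#' boolean occupancy tensor over (tail, tail residue, site, frame) that the
#' interaction-rate matrix and inaccessibility trace are computed from.
#' The trajectory may be an in-memory [mt_trajectory()] or a path to a
#' multi-frame PDB file (streamed with constant memory per frame).
#'
#' @param traj an `mt_trajectory`, or a file path (then `topology` is
#'   required).
#' @param registry a [site_registry()].
#' @param criterion a [salt_bridge_criterion()].
#' @param tail_role role of the tail-bearing chains (default `"alpha"`;
#'   the analysis tracks alpha tails unless told otherwise).
#' @param tail_resno residue numbers scanned for acidic tail residues
#'   (default 441:451, the TubA1A alpha-tail numbering).
#' @param include_cterm include the C-terminal carboxylate (OXT-bearing
#'   residue) as an acceptor.
#' @param topology required when `traj` is a file path.
#' @param method contact-matrix method, see [detect_salt_bridges()].
#' @param frame_interval frame spacing in ns (file-path input only).
#' @return an object of class `contact_timeline`: a list with the logical
#'   `occupancy` array `[tail, residue, site(1:4 + other), frame]`, axis
#'   labels, per-tail site `eligible` matrix and `frame_interval`.
#' @export
build_timeline <- function(traj, registry = default_site_registry(),
                           criterion = salt_bridge_criterion(),
                           tail_role = "alpha", tail_resno = 441:451,
                           include_cterm = FALSE, topology = NULL,
                           method = c("auto", "brute", "cells"),
                           frame_interval = 1) {
  method <- match.arg(method)
  streaming <- is.character(traj)
  if (!streaming) {
    topology <- traj$topology
    frame_interval <- traj$frame_interval
  } else if (is.null(topology)) {
    stop("streaming from a file requires the topology")
  }
  plan <- contact_plan(topology, registry, criterion, tail_role,
                       tail_resno, include_cterm)
  nt <- length(plan$tails); nres <- length(plan$residues)
  sites <- c("1", "2", "3", "4", "other")
  grp_row <- plan$acc_tail + nt * (plan$acc_res - 1L)  # (tail, residue) id

  nf <- if (streaming) NA_integer_ else n_frames(traj)
  frames_occ <- list()
  scan_frame <- function(f, xyz) {
    A <- xyz[plan$acc, , drop = FALSE]
    D <- xyz[plan$don, , drop = FALSE]
    M <- if (method == "cells")
      contact_matrix_cells(A, D, plan$criterion$cutoff, plan$box)
    else
      contact_matrix_brute(A, D, plan$criterion$cutoff, plan$box)
    occ <- array(FALSE, c(nt, nres, 5L))
    for (ti in seq_len(nt)) {
      rows <- which(plan$acc_tail == ti)
      if (!length(rows)) next
      Mt <- M[rows, , drop = FALSE]
      labt <- plan$lab[ti, ]
      for (si in seq_len(5L)) {
        cols <- if (si <= 4L) labt == si else labt == 0L
        if (!any(cols)) next
        hit <- rowSums(Mt[, cols, drop = FALSE]) > 0
        if (any(hit)) {
          res_hit <- unique(plan$acc_res[rows[hit]])
          occ[ti, res_hit, si] <- TRUE
        }
      }
    }
    frames_occ[[f]] <<- occ
  }
  if (streaming) {
    nf <- stream_frames(traj, topology, scan_frame)
  } else {
    for (f in seq_len(nf)) scan_frame(f, frame_coords(traj, f))
  }
  if (!nf) stop("trajectory has zero frames")
  occupancy <- array(unlist(frames_occ, use.names = FALSE),
                     dim = c(nt, nres, 5L, nf),
                     dimnames = list(plan$tails,
                                     as.character(plan$residues),
                                     sites, NULL))
  structure(list(occupancy = occupancy, tail_ids = plan$tails,
                 tail_residues = plan$residues, site_ids = sites,
                 eligible = plan$eligible,
                 frame_interval = frame_interval),
            class = "contact_timeline")
}

#' @export
print.contact_timeline <- function(x, ...) {
  d <- dim(x$occupancy)
  cat("contact_timeline:", d[1], "tails x", d[2], "residues x", d[3],
      "sites x", d[4], "frames (", x$frame_interval, "ns/frame )\n")
  invisible(x)
}

#' Concatenate contact timelines along the frame axis
#' @param ... `contact_timeline` objects over the same tails/residues.
#' @return the concatenated `contact_timeline`.
#' @export
concat_timelines <- function(...) {
  tls <- list(...)
  stopifnot(length(tls) >= 1)
  t1 <- tls[[1]]
  for (tl in tls[-1]) {
    stopifnot(identical(tl$tail_ids, t1$tail_ids),
              identical(tl$tail_residues, t1$tail_residues),
              identical(tl$frame_interval, t1$frame_interval))
  }
  occ <- array(unlist(lapply(tls, `[[`, "occupancy"), use.names = FALSE),
               dim = c(dim(t1$occupancy)[1:3],
                       sum(vapply(tls, function(t) dim(t$occupancy)[4],
                                  numeric(1)))),
               dimnames = c(dimnames(t1$occupancy)[1:3], list(NULL)))
  t1$occupancy <- occ
  t1
}

#' Interaction-rate matrix
#'
#' For each (tail residue, site) cell, the fraction of (frame, tail)
#' observations in which at least one salt bridge is present -- the
#' fractional frame occupancy.  Tails with no trans partner (the
#' minus-most ring of a non-periodic lattice) are excluded from the
#' denominators of sites 1 and 2.  When several timelines (independent
#' trajectories) are given, their matrices are averaged with equal weight.
#' An events-per-ns variant (number of off-to-on binding events per
#' simulated time) is available via `units`.
#'
#' @param timeline a `contact_timeline`, or a list of them.
#' @param units `"occupancy"` (default) or `"events_per_ns"`.
#' @return an `interaction_rate_matrix`: residues x sites 1-4 numeric
#'   matrix, values in `[0, 1]` for occupancy units.
#' @export
interaction_rates <- function(timeline, units = c("occupancy",
                                                  "events_per_ns")) {
  units <- match.arg(units)
  if (inherits(timeline, "contact_timeline")) timeline <- list(timeline)
  mats <- lapply(timeline, function(tl) {
    occ <- tl$occupancy
    nf <- dim(occ)[4]
    if (!nf || is.na(nf)) stop("timeline has zero frames")
    m <- matrix(0, dim(occ)[2], 4,
                dimnames = list(dimnames(occ)[[2]], paste0("site_", 1:4)))
    for (s in 1:4) {
      el <- tl$eligible[, s]
      if (!any(el)) { m[, s] <- NA_real_; next }
      sub <- occ[el, , s, , drop = FALSE]
      if (units == "occupancy") {
        m[, s] <- apply(sub, 2, mean)
      } else {
        onsets <- sub[, , , -1, drop = FALSE] &
          !sub[, , , -dim(sub)[4], drop = FALSE]
        m[, s] <- apply(onsets, 2, sum) /
          (sum(el) * (dim(sub)[4] - 1) * tl$frame_interval)
      }
    }
    m
  })
  out <- Reduce(`+`, mats) / length(mats)
  class(out) <- c("interaction_rate_matrix", class(out))
  attr(out, "units") <- units
  out
}

#' Tail inaccessibility trace
#'
#' The fraction of tails (or tail residues) engaged in at least one salt
#' bridge with the body sites at each time point.  In `per_tail` mode a
#' tail is inaccessible in a frame when any of the chosen residues binds
#' any of sites 1-4; in `per_residue` mode the fraction of chosen residues
#' bound is averaged over tails.  An optional trailing moving average
#' smooths the curve.
#'
#' @param timeline a `contact_timeline`.
#' @param residues residue numbers entering the definition; default: the
#'   glutamates within 445-450 present in the timeline.
#' @param mode `"per_tail"` (default) or `"per_residue"`.
#' @param smoothing_window trailing moving-average window in frames
#'   (1 = none).
#' @param sites site labels that count as binding (default sites 1-4).
#' @return an `accessibility_trace` data frame with columns `time` (ns)
#'   and `fraction_inaccessible`.
#' @export
inaccessibility_trace <- function(timeline, residues = NULL,
                                  mode = c("per_tail", "per_residue"),
                                  smoothing_window = 1L,
                                  sites = as.character(1:4)) {
  mode <- match.arg(mode)
  stopifnot(inherits(timeline, "contact_timeline"))
  if (is.null(residues))
    residues <- intersect(445:450, timeline$tail_residues)
  residues <- intersect(residues, timeline$tail_residues)
  if (!length(residues)) stop("empty residue set for the trace")
  ri <- match(residues, timeline$tail_residues)
  si <- match(sites, timeline$site_ids)
  occ <- timeline$occupancy[, ri, si, , drop = FALSE]
  nf <- dim(occ)[4]
  if (mode == "per_tail") {
    bound <- apply(occ, c(1, 4), any)        # tail x frame
    val <- colMeans(bound)
  } else {
    bound <- apply(occ, c(1, 2, 4), any)     # tail x residue x frame
    val <- apply(bound, 3, mean)
  }
  w <- as.integer(smoothing_window)
  if (w > 1L) {
    cs <- cumsum(val)
    sm <- numeric(nf)
    for (f in seq_len(nf)) {
      lo <- max(1L, f - w + 1L)
      sm[f] <- (cs[f] - if (lo > 1L) cs[lo - 1L] else 0) / (f - lo + 1L)
    }
    val <- sm
  }
  out <- data.frame(time = seq_len(nf) * timeline$frame_interval,
                    fraction_inaccessible = val)
  class(out) <- c("accessibility_trace", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "smoothing_window") <- w
  out
}

#' Export the rate matrix and trace as TSV files
#'
#' Writes `<prefix>_rates.tsv` (rows = tail residues, columns = sites in
#' fixed order 1-4) and `<prefix>_trace.tsv` (time in ns, fraction
#' inaccessible), both deterministic in column order and readable back
#' with `read.delim`.
#'
#' @param rates an `interaction_rate_matrix` (or NULL to skip).
#' @param trace an `accessibility_trace` (or NULL to skip).
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
export_results <- function(rates = NULL, trace = NULL, prefix) {
  out <- character(0)
  if (!is.null(rates)) {
    p <- paste0(prefix, "_rates.tsv")
    df <- data.frame(residue = rownames(rates),
                     unclass(rates)[, paste0("site_", 1:4), drop = FALSE],
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p)
  }
  if (!is.null(trace)) {
    p <- paste0(prefix, "_trace.tsv")
    utils::write.table(
      data.frame(time_ns = trace$time,
                 fraction_inaccessible = trace$fraction_inaccessible),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}

#' @export
plot.interaction_rate_matrix <- function(x, ...) {
  m <- t(unclass(x))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "site", ylab = "tail residue", axes = FALSE,
                  main = "interaction rate (frame occupancy)", ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m))
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m))
  invisible(x)
}

#' @export
plot.accessibility_trace <- function(x, ...) {
  graphics::plot(x$time, x$fraction_inaccessible, type = "l",
                 xlab = "time (ns)", ylab = "fraction inaccessible",
                 ylim = c(0, 1), ...)
  invisible(x)
}
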