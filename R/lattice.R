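# Helical lattice construction: the 13-protofilament / 3-start ring, ring
# stacking by the dimer repeat distance, the axially periodic "infinite"
# microtubule, padded boxes, nucleotide conversion, and fitting a lattice
# onto a reference lattice.

#' Helical lattice specification
#'
#' Holds the helical parameters of a microtubule lattice: the lateral
#' protofilament-to-protofilament rigid transform, the axial dimer repeat,
#' and the protofilament/start counts.  For the canonical 13-protofilament,
#' 3-start lattice the seam-closure identity must hold: composing the
#' lateral transform 13 times is a pure axial translation by 3 monomer
#' repeats (1.5 dimer repeats), which is what lets protofilaments match
#' their periodic image in an "infinite" microtubule.
#'
#' @param pf_transform `rigid_transform` mapping the dimer at protofilament
#'   `j` onto the dimer at protofilament `j + 1` of the same ring.
#' @param dimer_repeat axial rise per dimer along one protofilament
#'   (Angstrom).
#' @param n_protofilaments number of protofilaments (default 13).
#' @param start_number helix start number (default 3).
#' @param n_rings number of stacked rings (default 3).
#' @param axis unit axis vector; the microtubule axis, plus end toward
#'   increasing axis coordinate.
#' @param monomer_repeat axial rise per monomer; defaults to
#'   `dimer_repeat / 2`.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(pf_transform, dimer_repeat, n_protofilaments = 13L,
                         start_number = 3L, n_rings = 3L, axis = c(0, 0, 1),
                         monomer_repeat = dimer_repeat / 2) {
  stopifnot(inherits(pf_transform, "rigid_transform"),
            n_protofilaments >= 1, n_rings >= 1, start_number >= 0)
  structure(list(pf_transform = pf_transform,
                 dimer_repeat = dimer_repeat,
                 monomer_repeat = monomer_repeat,
                 n_protofilaments = as.integer(n_protofilaments),
                 start_number = as.integer(start_number),
                 n_rings = as.integer(n_rings),
                 axis = axis / sqrt(sum(axis^2))),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("lattice_spec:", x$n_protofilaments, "protofilaments,",
      x$start_number, "start,", x$n_rings, "rings, dimer repeat",
      format(x$dimer_repeat, digits = 6), "A\n")
  invisible(x)
}

#' Check the seam-closure identity of a lattice spec
#'
#' Composes the lateral transform `n_protofilaments` times and compares the
#' result with a pure axial translation by `start_number * monomer_repeat`.
#' Real cryo-EM lattices close imperfectly, so the tolerances are
#' configurable; the defaults accept residuals up to 0.5 Angstrom and 0.5
#' degree.
#'
#' @param spec a `lattice_spec`.
#' @param tol_translation,tol_rotation_deg acceptance tolerances on the
#'   residual translation (Angstrom) and rotation (degrees).
#' @return list with `ok` (logical), `rotation_residual_deg`,
#'   `translation_residual` and the composed transform.
#' @export
seam_closure <- function(spec, tol_translation = 0.5, tol_rotation_deg = 0.5) {
  comp <- transform_power(spec$pf_transform, spec$n_protofilaments)
  rot_deg <- rotation_angle(comp$R) * 180 / pi
  expected_t <- spec$start_number * spec$monomer_repeat * spec$axis
  trans_res <- sqrt(sum((comp$t - expected_t)^2))
  list(ok = is.finite(spec$dimer_repeat) && spec$dimer_repeat > 0 &&
         rot_deg <= tol_rotation_deg && trans_res <= tol_translation,
       rotation_residual_deg = rot_deg,
       translation_residual = trans_res,
       composed = comp)
}

# chains belonging to one dimer: accepts a character vector of chain ids or
# a single dimer index
resolve_dimer_chains <- function(model, dimer) {
  if (is.numeric(dimer)) {
    ch <- model$chains$chain[!is.na(model$chains$dimer) &
                             model$chains$dimer == dimer]
    if (!length(ch)) stop("no chains carry dimer index ", dimer)
    ch
  } else as.character(dimer)
}

# paired backbone coordinate sets for two equally composed dimers; atoms are
# matched by (position of the chain within the pair, residue number, atom
# name).  Backbone atoms (N, CA, C, O) suffice and are robust to sidechain
# divergence between template entries.
matched_coords <- function(model, chains_a, chains_b,
                           backbone = c("N", "CA", "C", "O"),
                           coverage = 0.9) {
  if (length(chains_a) != length(chains_b))
    stop("dimer chain pairs have different lengths")
  key <- function(chs) {
    sel <- model$atoms$chain %in% chs & model$atoms$elety %in% backbone &
      !(model$atoms$resid %in% LIGAND_CODES)
    idx <- which(sel)
    ord <- match(model$atoms$chain[idx], chs)
    list(idx = idx,
         key = paste(ord, model$atoms$resno[idx], model$atoms$elety[idx]))
  }
  a <- key(chains_a); b <- key(chains_b)
  m <- match(a$key, b$key)
  frac <- mean(!is.na(m))
  if (frac < coverage) {
    missing <- utils::head(a$key[is.na(m)], 10)
    stop("atom sets of the two dimers match only ",
         format(100 * frac, digits = 3), "% (< ", 100 * coverage,
         "%); unmatched e.g.: ", paste(missing, collapse = "; "))
  }
  keep <- !is.na(m)
  list(a = coords_at(model, a$idx[keep]),
       b = coords_at(model, b$idx[keep]))
}

coords_at <- function(model, idx) {
  as.matrix(model$atoms[idx, c("x", "y", "z")])
}

#' Infer the helical lattice spec from a template lattice
#'
#' Recovers the lateral protofilament transform by least-squares rigid
#' superposition of a seed dimer onto its lateral neighbor, the dimer
#' repeat from the axial component of the seed-to-axial-neighbor transform,
#' and the helix axis from the screw axis of the lateral transform.  The
#' result is independent of any global rigid placement of the template.
#'
#' @param template a labeled `lattice_model`.
#' @param seed_dimer,neighbor_dimer_pf,neighbor_dimer_axial each either a
#'   character vector of chain identifiers (in corresponding order) or a
#'   dimer index.  `neighbor_dimer_pf` is the lateral (protofilament + 1)
#'   neighbor of the seed, `neighbor_dimer_axial` the next dimer along the
#'   seed's protofilament (toward the plus end).
#' @param n_protofilaments,start_number,n_rings lattice counts for the spec.
#' @param coverage minimum fraction of backbone atoms that must pair up.
#' @param rmsd_ceiling warn when either superposition RMSD exceeds this
#'   (Angstrom).
#' @return a `lattice_spec`.
#' @export
infer_lattice_spec <- function(template, seed_dimer, neighbor_dimer_pf,
                               neighbor_dimer_axial, n_protofilaments = 13L,
                               start_number = 3L, n_rings = 3L,
                               coverage = 0.9, rmsd_ceiling = 2.0) {
  seed <- resolve_dimer_chains(template, seed_dimer)
  latn <- resolve_dimer_chains(template, neighbor_dimer_pf)
  axn  <- resolve_dimer_chains(template, neighbor_dimer_axial)

  lat <- matched_coords(template, seed, latn, coverage = coverage)
  fit_lat <- superpose(lat$a, lat$b)
  if (fit_lat$rmsd > rmsd_ceiling)
    warning("lateral superposition RMSD ", format(fit_lat$rmsd, digits = 4),
            " A exceeds ceiling ", rmsd_ceiling, " A")

  ax <- matched_coords(template, seed, axn, coverage = coverage)
  fit_ax <- superpose(ax$a, ax$b)
  if (fit_ax$rmsd > rmsd_ceiling)
    warning("axial superposition RMSD ", format(fit_ax$rmsd, digits = 4),
            " A exceeds ceiling ", rmsd_ceiling, " A")

  axis <- rotation_axis(fit_lat$transform$R)
  disp <- apply_transform(fit_ax$transform, colMeans(lat$a)) - colMeans(lat$a)
  if (sum(disp * axis) < 0) axis <- -axis
  dimer_repeat <- abs(sum(disp * axis))

  lattice_spec(pf_transform = fit_lat$transform, dimer_repeat = dimer_repeat,
               n_protofilaments = n_protofilaments,
               start_number = start_number, n_rings = n_rings, axis = axis)
}

# replicate a model's atoms/chains under a transform with fresh labels
transformed_copy <- function(model, tr, suffix, pf = NA_integer_,
                             ring = NA_integer_, dimer = NA_integer_) {
  atoms <- model$atoms
  xyz <- apply_transform(tr, as.matrix(atoms[, c("x", "y", "z")]))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms$chain <- paste0(atoms$chain, suffix)
  chains <- model$chains
  chains$chain <- paste0(chains$chain, suffix)
  if (!is.na(pf)) chains$pf <- pf
  if (!is.na(ring)) chains$ring <- ring
  if (!is.na(dimer)) chains$dimer <- dimer
  list(atoms = atoms, chains = chains)
}

#' Build a complete microtubule ring from a single dimer
#'
#' Applies the lateral transform `j` times to place the dimer at
#' protofilament `j` (`j = 0 ... n_protofilaments - 1`), producing one
#' complete ring.  The seam-closure identity of the spec is checked first.
#'
#' @param dimer a `lattice_model` holding one alpha/beta dimer (plus its
#'   ligands).
#' @param spec a `lattice_spec`.
#' @param tol_translation,tol_rotation_deg seam-closure tolerances, passed
#'   to [seam_closure()].
#' @return a `lattice_model` with `n_protofilaments` dimers, protofilament
#'   indices `0 ... n - 1` and ring index 0.
#' @export
build_ring <- function(dimer, spec, tol_translation = 0.5,
                       tol_rotation_deg = 0.5) {
  stopifnot(inherits(dimer, "lattice_model"), inherits(spec, "lattice_spec"))
  sc <- seam_closure(spec, tol_translation, tol_rotation_deg)
  if (!sc$ok)
    stop("lattice spec fails seam closure: residual rotation ",
         format(sc$rotation_residual_deg, digits = 4), " deg, residual ",
         "translation ", format(sc$translation_residual, digits = 4),
         " A (dimer repeat ", format(spec$dimer_repeat, digits = 4), " A)")
  n <- spec$n_protofilaments
  if (n == 1L) {
    dimer$chains$pf <- 0L; dimer$chains$ring <- 0L; dimer$chains$dimer <- 0L
    return(dimer)
  }
  tr <- identity_transform()
  parts <- vector("list", n)
  for (j in seq_len(n) - 1L) {
    parts[[j + 1L]] <- transformed_copy(dimer, tr, sprintf(".p%02d", j),
                                        pf = j, ring = 0L, dimer = j)
    tr <- compose_transform(spec$pf_transform, tr)
  }
  lattice_model(do.call(rbind, lapply(parts, `[[`, "atoms")),
                do.call(rbind, lapply(parts, `[[`, "chains")),
                box = dimer$box, metadata = dimer$metadata)
}

#' Stack rings along the axis by the dimer repeat distance
#'
#' Translates the ring `n_rings` times by multiples of the dimer repeat
#' along the axis, with ring index increasing toward the plus end.
#'
#' @param ring a `lattice_model` with a uniform ring index (output of
#'   [build_ring()]).
#' @param spec a `lattice_spec`.
#' @return a `lattice_model` with `n_protofilaments * n_rings` dimers.
#' @export
stack_rings <- function(ring, spec) {
  stopifnot(inherits(ring, "lattice_model"), inherits(spec, "lattice_spec"))
  if (spec$n_rings < 1) stop("n_rings must be >= 1")
  r0 <- unique(ring$chains$ring[!is.na(ring$chains$ring)])
  if (length(r0) > 1) stop("input ring must have a uniform ring index")
  if (spec$n_rings == 1L) return(ring)
  npf <- max(0L, ring$chains$pf, na.rm = TRUE) + 1L
  parts <- vector("list", spec$n_rings)
  for (k in seq_len(spec$n_rings) - 1L) {
    tr <- rigid_transform(diag(3), k * spec$dimer_repeat * spec$axis)
    part <- transformed_copy(ring, tr, sprintf(".r%d", k), ring = k)
    part$chains$dimer <- k * npf + part$chains$dimer
    parts[[k + 1L]] <- part
  }
  lattice_model(do.call(rbind, lapply(parts, `[[`, "atoms")),
                do.call(rbind, lapply(parts, `[[`, "chains")),
                box = ring$box, metadata = ring$metadata)
}

#' Place a lattice in an axially periodic box ("infinite" microtubule)
#'
#' Sets an axially periodic box whose length equals `n_rings` dimer repeats,
#' so that protofilaments continue seamlessly across the boundary and the
#' fragment has no free ends.  This requires a seam-closed (untwisted)
#' lattice: a lattice whose lateral transform does not close cannot match
#' its own periodic image, in which case an error advises a padded box.
#'
#' @param lattice a `lattice_model` built with `spec`.
#' @param spec the `lattice_spec` used to build it.
#' @param tol_translation,tol_rotation_deg seam-closure tolerances.
#' @return the lattice with `box$mode == "axial_periodic"`; atoms unmoved.
#' @export
make_infinite <- function(lattice, spec, tol_translation = 0.5,
                          tol_rotation_deg = 0.5) {
  sc <- seam_closure(spec, tol_translation, tol_rotation_deg)
  if (!sc$ok)
    stop("lattice is twisted (seam-closure residual: rotation ",
         format(sc$rotation_residual_deg, digits = 4), " deg, translation ",
         format(sc$translation_residual, digits = 4), " A): protofilaments ",
         "would not match their periodic image; use make_padded_box() ",
         "instead")
  lattice$box <- box_geometry(mode = "axial_periodic",
                              axial_length = spec$n_rings * spec$dimer_repeat,
                              axis = spec$axis)
  lattice
}

#' Place a lattice in a padded orthorhombic box
#'
#' Each box face lies exactly `padding` Angstrom beyond the extreme atom
#' coordinate along that axis.
#'
#' @param lattice a `lattice_model`.
#' @param padding padding distance in Angstrom (>= 0).
#' @return the lattice with `box$mode == "padded"`; atoms unmoved.
#' @export
make_padded_box <- function(lattice, padding = 20) {
  if (padding < 0) stop("padding must be >= 0")
  xyz <- coords(lattice)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  lattice$box <- box_geometry(mode = "padded", lengths = hi - lo,
                              origin = lo, padding = padding)
  lattice
}

# canonical heavy-atom templates for the guanine nucleotides (PDB v3 atom
# names).  GMPCPP ("GCP"; the dialect "CPP" is normalized on read) replaces
# the alpha,beta-bridging oxygen O3A of GTP with the methylene carbon C3A.
GTP_HEAVY_ATOMS <- c("PG", "O1G", "O2G", "O3G", "O3B", "PB", "O1B", "O2B",
                     "O3A", "PA", "O1A", "O2A", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7",
                     "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
GCP_HEAVY_ATOMS <- replace(GTP_HEAVY_ATOMS, GTP_HEAVY_ATOMS == "O3A", "C3A")
GDP_HEAVY_ATOMS <- setdiff(GTP_HEAVY_ATOMS, c("PG", "O1G", "O2G", "O3G"))
GCP_BRIDGE_HYDROGENS <- c("H3A1", "H3A2")

#' Convert GMPCPP ligands to GTP
#'
#' Template-driven bookkeeping conversion: in every beta-subunit-associated
#' GMPCPP ligand, the alpha,beta-bridging methylene carbon (C3A) is replaced
#' by a bridging oxygen (O3A) placed at the carbon's position, its
#' hydrogens are dropped, and all other ligand atoms are preserved.  The
#' resulting atom-name set equals the canonical GTP template.  Ligands in
#' alpha subunits (the non-exchangeable site) are untouched.
#'
#' @param model a `lattice_model`.
#' @param from_state,to_state currently `"GMPCPP"` to `"GTP"`; requesting a
#'   conversion with `from_state == to_state` is the identity.
#' @return the converted `lattice_model`.
#' @export
convert_nucleotide <- function(model, from_state = "GMPCPP",
                               to_state = "GTP") {
  if (identical(from_state, to_state)) return(model)
  stopifnot(from_state == "GMPCPP", to_state == "GTP")
  lig_chains <- ligand_chains_by_assoc(model, "beta")
  targets <- lig_chains[vapply(lig_chains, function(ch) {
    any(model$atoms$resid[model$atoms$chain == ch] == "GCP")
  }, logical(1))]
  if (!length(targets))
    stop("no beta-associated GMPCPP (GCP) ligands found")
  for (ch in targets) {
    sel <- model$atoms$chain == ch
    names_heavy <- model$atoms$elety[sel & !grepl("^H", model$atoms$elety)]
    extra <- setdiff(names_heavy, GCP_HEAVY_ATOMS)
    miss <- setdiff(GCP_HEAVY_ATOMS, names_heavy)
    if (length(extra) || length(miss))
      stop("ligand in chain ", ch, " does not match the GMPCPP template",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
    drop <- sel & model$atoms$elety %in% GCP_BRIDGE_HYDROGENS
    model$atoms <- model$atoms[!drop, ]
    sel <- model$atoms$chain == ch
    bridge <- sel & model$atoms$elety == "C3A"
    model$atoms$elety[bridge] <- "O3A"
    model$atoms$elesy[bridge] <- "O"
    model$atoms$resid[sel] <- "GTP"
    got <- sort(model$atoms$elety[sel & !grepl("^H", model$atoms$elety)])
    if (!identical(got, sort(GTP_HEAVY_ATOMS)))
      stop("internal: converted ligand in chain ", ch,
           " does not match the GTP template")
  }
  rownames(model$atoms) <- NULL
  model
}

# ligand chains associated with a given subunit role; uses the chain table's
# assoc column when set, otherwise falls back to the nearest protein-chain
# centroid of the same dimer (or overall)
ligand_chains_by_assoc <- function(model, role) {
  lig <- model$chains$chain[model$chains$role == "ligand"]
  if (!length(lig)) return(character(0))
  assoc <- model$chains$assoc[match(lig, model$chains$chain)]
  unknown <- is.na(assoc)
  if (any(unknown)) {
    prot <- model$chains[model$chains$role %in% c("alpha", "beta"), ]
    cent <- t(vapply(prot$chain, function(ch) {
      colMeans(coords_at(model, which(model$atoms$chain == ch)))
    }, numeric(3)))
    for (i in which(unknown)) {
      lc <- colMeans(coords_at(model, which(model$atoms$chain == lig[i])))
      d <- sqrt(rowSums(sweep(cent, 2, lc)^2))
      assoc[i] <- prot$role[which.min(d)]
    }
  }
  lig[assoc == role]
}

#' Fit a lattice onto a reference lattice
#'
#' Rigid-body superposes each dimer of the mobile lattice (backbone least
#' squares) onto its partner in the reference lattice, so that the mobile
#' structure adopts the reference lattice geometry while the internal
#' geometry of every dimer is preserved exactly.  A global single-transform
#' fit is available but, unlike the per-dimer fit, does not guarantee the
#' same lattice structure when the two lattices differ in twist or repeat.
#'
#' @param mobile,reference labeled `lattice_model`s.
#' @param mapping data frame with columns `mobile` and `reference` pairing
#'   dimer indices; by default dimer `i` maps to dimer `i`.  Every mobile
#'   dimer must be mapped.
#' @param per_dimer if FALSE, apply one global superposition instead.
#' @param coverage minimum backbone pairing fraction per dimer.
#' @return the fitted mobile `lattice_model`.
#' @export
fit_to_reference <- function(mobile, reference, mapping = NULL,
                             per_dimer = TRUE, coverage = 0.9) {
  mob_dimers <- sort(unique(stats::na.omit(mobile$chains$dimer)))
  if (!length(mob_dimers)) stop("mobile lattice carries no dimer labels")
  if (is.null(mapping))
    mapping <- data.frame(mobile = mob_dimers, reference = mob_dimers)
  unmapped <- setdiff(mob_dimers, mapping$mobile)
  if (length(unmapped))
    stop("unmapped mobile dimer(s): ", paste(unmapped, collapse = ", "))

  pair_coords <- function(md, rd) {
    mch <- mobile$chains[!is.na(mobile$chains$dimer) &
                         mobile$chains$dimer == md, ]
    rch <- reference$chains[!is.na(reference$chains$dimer) &
                            reference$chains$dimer == rd, ]
    bb <- c("N", "CA", "C", "O")
    msel <- which(mobile$atoms$chain %in% mch$chain &
                  mobile$atoms$elety %in% bb)
    mrole <- mch$role[match(mobile$atoms$chain[msel], mch$chain)]
    mkey <- paste(mrole, mobile$atoms$resno[msel], mobile$atoms$elety[msel])
    rsel <- which(reference$atoms$chain %in% rch$chain &
                  reference$atoms$elety %in% bb)
    rrole <- rch$role[match(reference$atoms$chain[rsel], rch$chain)]
    rkey <- paste(rrole, reference$atoms$resno[rsel], reference$atoms$elety[rsel])
    m <- match(mkey, rkey)
    frac <- mean(!is.na(m))
    if (frac < coverage)
      stop("backbone atoms of mobile dimer ", md, " pair with reference ",
           "dimer ", rd, " at only ", format(100 * frac, digits = 3), "%")
    keep <- !is.na(m)
    list(m = coords_at(mobile, msel[keep]),
         r = coords_at(reference, rsel[keep]))
  }

  if (!per_dimer) {
    pairs <- lapply(seq_len(nrow(mapping)), function(i)
      pair_coords(mapping$mobile[i], mapping$reference[i]))
    fit <- superpose(do.call(rbind, lapply(pairs, `[[`, "m")),
                     do.call(rbind, lapply(pairs, `[[`, "r")))
    return(set_coords(mobile, apply_transform(fit$transform, coords(mobile))))
  }
  for (i in seq_len(nrow(mapping))) {
    md <- mapping$mobile[i]; rd <- mapping$reference[i]
    pc <- pair_coords(md, rd)
    fit <- superpose(pc$m, pc$r)
    dch <- mobile$chains$chain[!is.na(mobile$chains$dimer) &
                               mobile$chains$dimer == md]
    sel <- which(mobile$atoms$chain %in% dch)
    xyz <- apply_transform(fit$transform, coords_at(mobile, sel))
    mobile$atoms$x[sel] <- xyz[, 1]
    mobile$atoms$y[sel] <- xyz[, 2]
    mobile$atoms$z[sel] <- xyz[, 3]
  }
  mobile
}
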