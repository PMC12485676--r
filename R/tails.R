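# Disordered C-terminal tail construction.  Tails are grown residue by
# residue from the last resolved residue of each target chain, with
# backbone dihedrals drawn from the extended-coil region and a hard-sphere
# clash filter against all previously placed heavy atoms.  Conformations
# are randomized, not energy-minimized: downstream users equilibrate the
# structures themselves.

#' Tyrosinated alpha-tubulin (TubA1A) C-terminal tail sequences
#'
#' The human TubA1A tail, appended after the last resolved body residue so
#' that the genetically encoded C-terminal tyrosine is Y451.  The
#' tyrosinated tail contains seven glutamates (E441, E443, E445, E446,
#' E447, E449, E450); note G448, so the glutamates are not contiguous.
#'
#' @param form `"Y"` (tyrosinated), `"deY"` (detyrosinated) or `"delta2"`
#'   (lacking the last two residues).
#' @return one-letter amino-acid string.
#' @export
tuba1a_tail <- function(form = c("Y", "deY", "delta2")) {
  switch(match.arg(form),
         Y = "SVEGEGEEEGEEY",
         deY = "SVEGEGEEEGEE",
         delta2 = "SVEGEGEEEGE")
}

AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", I = "ILE", K = "LYS", L = "LEU", M = "MET",
            N = "ASN", Q = "GLN", R = "ARG", S = "SER", T = "THR",
            V = "VAL", Y = "TYR")

# Sidechain heavy atoms from internal coordinates.  Each row places one
# atom from three previously placed atoms of the same residue: position =
# place_atom(a, b, c, bond, angle, torsion).  Rotatable chi torsions use
# the common trans rotamer; ring geometry is idealized.
SIDECHAIN_ICS <- list(
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.808, 113.8, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.527, 110.7, 180),
             c("CG2", "N", "CA", "CB", 1.527, 110.4, 60)),
  LEU = list(c("CG", "N", "CA", "CB", 1.53, 116.3, 180),
             c("CD1", "CA", "CB", "CG", 1.524, 110.7, 180),
             c("CD2", "CA", "CB", "CG", 1.525, 110.7, 60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.53, 110.4, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  ASP = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  PHE = list(c("CG", "N", "CA", "CB", 1.51, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.39, 120.9, 90),
             c("CD2", "CA", "CB", "CG", 1.39, 120.9, -90),
             c("CE1", "CB", "CG", "CD1", 1.39, 121.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.39, 121.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.39, 119.6, 0)),
  TYR = list(c("CG", "N", "CA", "CB", 1.51, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.39, 120.9, 90),
             c("CD2", "CA", "CB", "CG", 1.39, 120.9, -90),
             c("CE1", "CB", "CG", "CD1", 1.39, 121.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.39, 121.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.39, 119.6, 0),
             c("OH", "CD1", "CE1", "CZ", 1.377, 119.9, 180)),
  GLY = list())

# improper torsion N-C-CA-CB giving the L configuration
CB_IC <- c(bond = 1.53, angle = 110.5, torsion = -122.5)

build_residue_atoms <- function(resname, prevN, prevCA, prevC, prevPsi,
                                phi) {
  # backbone
  N  <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, prevPsi)
  CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, 180)
  C  <- place_atom(prevC, N, CA, 1.525, 111.0, phi)
  pos <- list(N = N, CA = CA, C = C)
  if (resname != "GLY") {
    pos$CB <- place_atom(pos$N, pos$C, pos$CA, CB_IC["bond"], CB_IC["angle"],
                         CB_IC["torsion"])
    ics <- SIDECHAIN_ICS[[resname]]
    if (is.null(ics))
      stop("no sidechain template for residue ", resname)
    for (row in ics) {
      pos[[row[1]]] <- place_atom(pos[[row[2]]], pos[[row[3]]], pos[[row[4]]],
                                  as.numeric(row[5]), as.numeric(row[6]),
                                  as.numeric(row[7]))
    }
  }
  pos
}

#' Append disordered C-terminal tails to tubulin subunits
#'
#' Grows the given one-letter sequences onto every chain of the targeted
#' role(s), with author numbering continuing from each chain's last
#' resolved residue.  The backbone is built residue by residue with
#' extended-coil dihedrals (phi in (-160, -60), psi in (90, 180)) drawn
#' deterministically from `seed`; a residue placement is accepted only if
#' every new heavy atom lies at least `clash_cutoff` from all previously
#' placed heavy atoms (the covalently attached preceding residue is exempt,
#' since its bonded and 1-3 neighbors are necessarily closer).  An OXT
#' terminal-carboxylate oxygen is added to the final residue of each tail.
#'
#' The alpha tail defaults to the tyrosinated TubA1A sequence
#' ([tuba1a_tail()]); there is no default beta sequence (the beta isotype
#' is a user decision), so by default only alpha subunits gain tails.
#'
#' @param model a `lattice_model`.
#' @param alpha one-letter tail sequence for alpha subunits, `NULL` to skip
#'   alpha chains, or `""` for an explicit no-op.
#' @param beta one-letter tail sequence for beta subunits (no default).
#' @param alpha_start,beta_start first tail residue number; defaults to one
#'   past the chain's last resolved residue.  When supplied, every target
#'   chain must end exactly at `start - 1` (error otherwise).
#' @param clash_cutoff minimum heavy-atom distance for accepting a
#'   placement (Angstrom).
#' @param seed integer seed; identical seeds give bitwise-identical tails.
#' @param max_attempts dihedral redraws allowed per residue.
#' @param max_restarts whole-chain rebuilds allowed when a chain grows
#'   into a dead end; exhausting them fails with an error naming the
#'   chain and residue.
#' @return the model with tail residues appended to the target chains.
#' @export
append_tails <- function(model, alpha = tuba1a_tail("Y"), beta = NULL,
                         alpha_start = NULL, beta_start = NULL,
                         clash_cutoff = 2.5, seed = 1L,
                         max_attempts = 100L, max_restarts = 25L) {
  stopifnot(inherits(model, "lattice_model"))
  jobs <- list()
  if (!is.null(alpha) && nzchar(alpha))
    jobs$alpha <- list(seq = alpha, start = alpha_start)
  if (!is.null(beta) && nzchar(beta))
    jobs$beta <- list(seq = beta, start = beta_start)
  if (!length(jobs)) return(model)

  heavy <- !grepl("^H", model$atoms$elety)
  existing <- coords(model)[heavy, , drop = FALSE]
  # rows of `existing` contributed by each chain's current last residue are
  # exempted from the clash check of the first appended residue
  exist_chain <- model$atoms$chain[heavy]
  exist_resno <- model$atoms$resno[heavy]

  new_atoms <- list()
  with_seed(seed, {
    for (role in names(jobs)) {
      job <- jobs[[role]]
      seq1 <- strsplit(job$seq, "")[[1]]
      bad <- setdiff(seq1, names(AA1TO3))
      if (length(bad))
        stop("no residue template for one-letter code(s): ",
             paste(unique(bad), collapse = ", "))
      targets <- model$chains$chain[model$chains$role == role]
      for (ch in targets) {
        sel <- model$atoms$chain == ch
        last_resno <- max(model$atoms$resno[sel])
        if (!is.null(job$start) && job$start != last_resno + 1L)
          stop("chain ", ch, " ends at residue ", last_resno,
               ", not at requested start - 1 = ", job$start - 1L)
        start <- if (is.null(job$start)) last_resno + 1L else job$start
        anchor <- model$atoms[sel & model$atoms$resno == last_resno, ]
        need <- c("N", "CA", "C")
        if (!all(need %in% anchor$elety))
          stop("chain ", ch, " last residue ", last_resno,
               " lacks backbone atoms needed to anchor a tail")
        getp <- function(df, nm) as.numeric(df[df$elety == nm,
                                               c("x", "y", "z")])
        anchorN <- getp(anchor, "N"); anchorCA <- getp(anchor, "CA")
        anchorC <- getp(anchor, "C")
        # keep the anchor's existing carbonyl O consistent: the first new N
        # is placed trans to it when it is present
        anchorPsi <- if ("O" %in% anchor$elety)
          dihedral(anchorN, anchorCA, anchorC, getp(anchor, "O")) + 180
        else stats::runif(1, 90, 180)

        # grow the whole tail; if a residue cannot be placed (the chain
        # walked into a dead end) restart the chain with fresh dihedrals
        chain_atoms <- NULL
        for (restart in seq_len(max_restarts)) {
          prevN <- anchorN; prevCA <- anchorCA; prevC <- anchorC
          prevPsi <- anchorPsi
          prev_resno <- last_resno
          built <- list()
          add_xyz <- NULL; add_resno <- integer(0)
          dead_end <- FALSE
          for (k in seq_along(seq1)) {
            resname <- AA1TO3[[seq1[k]]]
            resno <- start + k - 1L
            placed <- FALSE
            for (attempt in seq_len(max_attempts)) {
              phi <- stats::runif(1, -160, -60)
              psi <- stats::runif(1, 90, 180)
              pos <- build_residue_atoms(resname, prevN, prevCA, prevC,
                                         prevPsi, phi)
              # carbonyl O (and OXT on the final residue) from psi
              pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.5,
                                  psi + 180)
              if (k == length(seq1))
                pos$OXT <- place_atom(pos$N, pos$CA, pos$C, 1.249, 117.0,
                                      psi)
              m <- do.call(rbind, pos)
              exempt <- exist_chain == ch & exist_resno == prev_resno
              dmin <- min(
                min_cross_dist(m, existing[!exempt, , drop = FALSE]),
                if (is.null(add_xyz)) Inf
                else min_cross_dist(m, add_xyz[add_resno != prev_resno, ,
                                               drop = FALSE]))
              if (dmin >= clash_cutoff) { placed <- TRUE; break }
            }
            if (!placed) { dead_end <- TRUE; break }
            built[[k]] <- data.frame(
              elety = rownames(m), resid = resname, chain = ch,
              resno = resno, x = m[, 1], y = m[, 2], z = m[, 3],
              elesy = guess_element(rownames(m)), stringsAsFactors = FALSE)
            add_xyz <- rbind(add_xyz, m)
            add_resno <- c(add_resno, rep(resno, nrow(m)))
            prevN <- pos$N; prevCA <- pos$CA; prevC <- pos$C
            prevPsi <- psi
            prev_resno <- resno
          }
          if (!dead_end) {
            chain_atoms <- do.call(rbind, built)
            existing <- rbind(existing, add_xyz)
            exist_chain <- c(exist_chain, rep(ch, nrow(add_xyz)))
            exist_resno <- c(exist_resno, add_resno)
            break
          }
          if (restart == max_restarts)
            stop("failed to place residue ", resname, " ", resno,
                 " on chain ", ch, " after ", max_restarts,
                 " chain restarts (clash cutoff ", clash_cutoff, " A)")
        }
        new_atoms[[length(new_atoms) + 1L]] <- chain_atoms
      }
    }
  })
  if (!length(new_atoms)) return(model)
  add <- do.call(rbind, new_atoms)
  # keep atoms of each chain contiguous and in residue order
  atoms <- rbind(model$atoms, add)
  atoms <- atoms[order(match(atoms$chain, model$chains$chain)), ]
  rownames(atoms) <- NULL
  lattice_model(atoms, model$chains, box = model$box,
                metadata = model$metadata)
}

# minimum distance between two coordinate sets (no periodicity: tails are
# built on the unwrapped lattice)
min_cross_dist <- function(a, b) {
  if (!nrow(b)) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
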