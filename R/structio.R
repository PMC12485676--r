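# Structure and trajectory containers and file I/O.
#
# The central container is the `lattice_model`: an atom table in file order
# plus a chain table carrying the lattice labels (subunit role, protofilament
# index, ring index, dimer index) that every downstream stage needs.  PDB and
# mmCIF parsing is delegated to bio3d; lattice labels that the PDB format
# cannot carry are serialized into `REMARK 299 MTCTT` header lines so that
# models written by this package round-trip losslessly.

LIGAND_CODES <- c("GTP", "GDP", "GCP", "CPP")

# GMPCPP appears under two residue-name dialects in the wild; both are
# normalized to the single internal code "GCP".
normalize_ligand_name <- function(resid) {
  ifelse(resid == "CPP", "GCP", resid)
}

CHAIN_CYCLE <- c(LETTERS, letters, as.character(0:9))

base36 <- function(i, width = 3) {
  digits <- c(0:9, LETTERS)
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- character(0)
    repeat {
      s <- c(digits[n %% 36 + 1], s)
      n <- n %/% 36
      if (n == 0) break
    }
    out[k] <- paste(c(rep("0", max(0, width - length(s))), s), collapse = "")
  }
  out
}

#' Construct a lattice model
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain` (chain identifier, any string),
#'   `resno` (author residue number), `x`, `y`, `z` (Angstrom) and
#'   optionally `elesy` (element symbol).
#' @param chains data frame with one row per chain: `chain`, `role`
#'   (one of `"alpha"`, `"beta"`, `"ligand"`, `"other"`), integer labels
#'   `pf`, `ring`, `dimer` (NA until assigned by the lattice builder) and
#'   `assoc` (for ligand chains, the subunit role the ligand sits in).
#' @param box optional [box_geometry()].
#' @param metadata optional [md_run_metadata()] record.
#' @return an object of class `lattice_model`.
#' @export
lattice_model <- function(atoms, chains = NULL, box = NULL, metadata = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stop("empty model: atom table has zero rows")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.null(atoms$elesy))
    atoms$elesy <- guess_element(atoms$elety)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name): ",
         key[anyDuplicated(key)])
  if (is.null(chains)) {
    chains <- data.frame(chain = unique(atoms$chain), stringsAsFactors = FALSE)
  }
  chains <- as.data.frame(chains)
  for (col in c("role", "assoc"))
    if (is.null(chains[[col]])) chains[[col]] <- NA_character_
  for (col in c("pf", "ring", "dimer"))
    if (is.null(chains[[col]])) chains[[col]] <- NA_integer_
  if (!setequal(chains$chain, unique(atoms$chain)))
    stop("chain table does not match the chains present in the atom table")
  chains <- chains[match(unique(atoms$chain), chains$chain),
                   c("chain", "role", "pf", "ring", "dimer", "assoc")]
  rownames(chains) <- NULL
  structure(list(atoms = atoms, chains = chains, box = box,
                 metadata = metadata),
            class = "lattice_model")
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1, 1)
}

#' @export
print.lattice_model <- function(x, ...) {
  cat("lattice_model:", nrow(x$atoms), "atoms,", nrow(x$chains), "chains")
  nd <- dimer_count(x)
  if (!is.na(nd)) cat(",", nd, "dimers")
  if (!is.null(x$box)) cat(", box:", x$box$mode)
  cat("\n")
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `lattice_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Number of distinct dimers in a model
#' @param model a `lattice_model`.
#' @return number of distinct dimer indices, or NA if labels are unset.
#' @export
dimer_count <- function(model) {
  d <- model$chains$dimer[model$chains$role %in% c("alpha", "beta")]
  if (all(is.na(d))) return(NA_integer_)
  length(unique(d[!is.na(d)]))
}

#' Extract the coordinate matrix of a model
#' @param model a `lattice_model`.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a model
#' @param model a `lattice_model`.
#' @param xyz n x 3 matrix (or length-3n vector, xyz interleaved).
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(nrow(xyz) == n_atoms(model))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# role/pf/ring/dimer of the chain each atom belongs to, as vectors over atoms
atom_chain_labels <- function(model) {
  idx <- match(model$atoms$chain, model$chains$chain)
  list(role  = model$chains$role[idx],
       pf    = model$chains$pf[idx],
       ring  = model$chains$ring[idx],
       dimer = model$chains$dimer[idx])
}

#' Box geometry of a model
#'
#' @param mode one of `"axial_periodic"` (periodic along the microtubule
#'   axis, used for the "infinite" microtubule), `"padded"` (orthorhombic
#'   box at a fixed distance from the extreme atoms) or `"none"`.
#' @param axial_length box length along `axis` (Angstrom); required and
#'   positive for `axial_periodic`.
#' @param lengths length-3 box edge lengths (Angstrom) for padded boxes.
#' @param origin length-3 position of the box corner (padded mode).
#' @param axis unit axis vector (default +z, the microtubule axis).
#' @param padding padding used to construct a padded box (Angstrom).
#' @return an object of class `box_geometry`.
#' @export
box_geometry <- function(mode = c("none", "axial_periodic", "padded"),
                         axial_length = NA_real_, lengths = rep(NA_real_, 3),
                         origin = rep(NA_real_, 3), axis = c(0, 0, 1),
                         padding = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "axial_periodic" &&
      (!is.finite(axial_length) || axial_length <= 0))
    stop("axial_periodic mode requires axial_length > 0")
  if (mode == "padded" && (!is.finite(padding) || padding < 0))
    stop("padded mode requires padding >= 0")
  structure(list(mode = mode, axial_length = axial_length,
                 lengths = as.numeric(lengths), origin = as.numeric(origin),
                 axis = axis / sqrt(sum(axis^2)), padding = padding),
            class = "box_geometry")
}

#' Minimum-image displacement under axial periodicity
#'
#' Wraps the component of each displacement along the box axis into
#' `[-L/2, L/2]` when the box is axially periodic; other modes return the
#' displacement unchanged.
#'
#' @param d n x 3 matrix (or length-3 vector) of displacements.
#' @param box a [box_geometry()] or NULL.
#' @return displacement(s) of the same shape, minimum-image corrected.
#' @export
min_image <- function(d, box = NULL) {
  vec <- is.null(dim(d))
  if (vec) d <- matrix(d, ncol = 3)
  if (!is.null(box) && box$mode == "axial_periodic") {
    L <- box$axial_length
    ax <- box$axis
    comp <- as.numeric(d %*% ax)
    wrapped <- comp - L * round(comp / L)
    d <- d + outer(wrapped - comp, ax)
  }
  if (vec) as.numeric(d) else d
}

#' Record molecular-dynamics run metadata
#'
#' A record-only container: no computation in the package depends on these
#' fields.  They travel with models and trajectories so that provenance of
#' externally produced trajectories is not lost.
#'
#' @param engine,force_field,water_model free-text descriptors.
#' @param ionic_strength_mM ionic strength in mM.
#' @param timestep_fs integration step in fs.
#' @param trajectory_lengths_ns numeric vector of run lengths in ns.
#' @param nucleotide_state one of `"GDP"`, `"GTP"`, `"GMPCPP"`.
#' @return an object of class `md_run_metadata`.
#' @export
md_run_metadata <- function(engine = NA_character_,
                            force_field = NA_character_,
                            water_model = NA_character_,
                            ionic_strength_mM = NA_real_,
                            timestep_fs = NA_real_,
                            trajectory_lengths_ns = numeric(0),
                            nucleotide_state = NA_character_) {
  if (!is.na(nucleotide_state))
    nucleotide_state <- match.arg(nucleotide_state, c("GDP", "GTP", "GMPCPP"))
  structure(list(engine = engine, force_field = force_field,
                 water_model = water_model,
                 ionic_strength_mM = ionic_strength_mM,
                 timestep_fs = timestep_fs,
                 trajectory_lengths_ns = trajectory_lengths_ns,
                 nucleotide_state = nucleotide_state),
            class = "md_run_metadata")
}

# --- structure reading -------------------------------------------------------

#' Read a structure file into a lattice model
#'
#' Reads PDB or mmCIF coordinates (via bio3d).  Chains written by
#' [write_structure()] carry their identity in the PDB segid field and their
#' lattice labels in `REMARK 299 MTCTT` header lines, both of which are
#' recovered here.  For foreign files, subunit roles are assigned from chain
#' composition: chains consisting solely of nucleotide ligand residues
#' (GTP/GDP/GMPCPP dialects) are classified `"ligand"`; protein chains are
#' assigned via `chain_roles` when given, otherwise alternately
#' `alpha, beta, alpha, ...` in file order (the usual deposition order of
#' tubulin dimers; override with `chain_roles` when it does not hold).
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param chain_roles optional named character vector mapping chain
#'   identifiers to roles, e.g. `c(A = "alpha", B = "beta")`; the loader
#'   never guesses which chains form the seed dimer when this is supplied.
#' @param multi if TRUE, all MODEL records of a multi-model PDB are read and
#'   returned as a trajectory; by default only the first model is read.
#' @return a `lattice_model`, or an `mt_trajectory` when `multi = TRUE`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chain_roles = NULL, multi = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path)
    else bio3d::read.pdb(path, multi = multi),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty model: no ATOM/HETATM records in ", path)
  segid <- at$segid
  if (is.null(segid)) segid <- rep("", nrow(at))
  segid[is.na(segid)] <- ""
  chain_col <- at$chain
  chain_col[is.na(chain_col)] <- " "
  use_segid <- all(segid != "") && length(unique(segid)) >= length(unique(chain_col))
  chain_id <- if (use_segid) segid else chain_col
  atoms <- data.frame(elety = at$elety,
                      resid = normalize_ligand_name(at$resid),
                      chain = chain_id,
                      resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      elesy = if (!is.null(at$elesy) && !all(is.na(at$elesy)))
                                at$elesy else guess_element(at$elety),
                      stringsAsFactors = FALSE)

  hdr <- read_mtctt_header(path, format)
  chains <- build_chain_table(atoms, hdr$chain_labels, chain_roles)
  if (!is.null(hdr$chain_labels)) {
    # restore original chain identifiers recorded at write time
    map <- hdr$chain_labels
    idx <- match(atoms$chain, map$seg)
    ok <- !is.na(idx)
    atoms$chain[ok] <- map$orig[idx[ok]]
    chains$chain <- map$orig[match(chains$chain, map$seg)]
  }
  model <- lattice_model(atoms, chains, box = hdr$box)
  if (multi && !is.null(pdb$xyz) && nrow(as.matrix(pdb$xyz)) > 1) {
    return(mt_trajectory(model, as.matrix(pdb$xyz)))
  }
  model
}

read_mtctt_header <- function(path, format) {
  if (format != "pdb") return(list(chain_labels = NULL, box = NULL))
  lines <- readLines(path, n = 5000L, warn = FALSE)
  lines <- lines[startsWith(lines, "REMARK 299 MTCTT")]
  if (!length(lines)) return(list(chain_labels = NULL, box = NULL))
  toks <- strsplit(trimws(sub("^REMARK 299 MTCTT ", "", lines)), "\\s+")
  chain_rows <- Filter(function(t) t[1] == "CHAIN", toks)
  box_rows <- Filter(function(t) t[1] == "BOX", toks)
  chain_labels <- NULL
  if (length(chain_rows)) {
    m <- do.call(rbind, chain_rows)
    na_dot <- function(x) ifelse(x == ".", NA, x)
    chain_labels <- data.frame(
      seg = m[, 2], orig = m[, 3], role = na_dot(m[, 4]),
      pf = as.integer(na_dot(m[, 5])), ring = as.integer(na_dot(m[, 6])),
      dimer = as.integer(na_dot(m[, 7])), assoc = na_dot(m[, 8]),
      stringsAsFactors = FALSE)
  }
  box <- NULL
  if (length(box_rows)) {
    b <- box_rows[[1]]
    num <- suppressWarnings(as.numeric(ifelse(b == ".", NA, b)))
    box <- box_geometry(mode = b[2], axial_length = num[3],
                        lengths = num[4:6], origin = num[7:9],
                        axis = ifelse(is.na(num[10:12]), c(0, 0, 1), num[10:12]),
                        padding = num[13])
  }
  list(chain_labels = chain_labels, box = box)
}

build_chain_table <- function(atoms, chain_labels, chain_roles) {
  ids <- unique(atoms$chain)
  chains <- data.frame(chain = ids, role = NA_character_, pf = NA_integer_,
                       ring = NA_integer_, dimer = NA_integer_,
                       assoc = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(chain_labels)) {
    idx <- match(ids, chain_labels$seg)
    ok <- !is.na(idx)
    for (col in c("role", "pf", "ring", "dimer", "assoc"))
      chains[[col]][ok] <- chain_labels[[col]][idx[ok]]
    return(chains)
  }
  is_lig <- vapply(ids, function(id) {
    all(atoms$resid[atoms$chain == id] %in% LIGAND_CODES)
  }, logical(1))
  chains$role[is_lig] <- "ligand"
  prot <- which(!is_lig)
  if (!is.null(chain_roles)) {
    idx <- match(ids, names(chain_roles))
    ok <- !is.na(idx)
    chains$role[ok] <- unname(chain_roles[idx[ok]])
    chains$role[!ok & !is_lig] <- "other"
  } else if (length(prot)) {
    chains$role[prot] <- rep(c("alpha", "beta"), length.out = length(prot))
  }
  chains
}

# --- structure writing -------------------------------------------------------

#' Write a lattice model to a PDB file
#'
#' Chain identifiers in the fixed-width PDB chain column are re-lettered
#' deterministically through the 62-character cycle `A-Z a-z 0-9` (wrapping
#' when a lattice has more chains than the column can distinguish); chain
#' identity is carried unambiguously in the segid field as
#' `<role letter><3-char base-36 chain ordinal>` (role letters: A = alpha,
#' B = beta, L = ligand, O = other).  Lattice labels and box geometry are
#' written as `REMARK 299 MTCTT` header lines, and an axially periodic box
#' additionally as a CRYST1 record.
#'
#' @param model a `lattice_model`.
#' @param path output file path.
#' @param format only `"pdb"` is supported.
#' @return the path, invisibly.
#' @export
write_structure <- function(model, path, format = "pdb") {
  stopifnot(inherits(model, "lattice_model"))
  format <- match.arg(format, "pdb")
  if (!n_atoms(model)) stop("refusing to write an empty model")
  xyz <- coords(model)
  if (any(xyz <= -1000) || any(xyz >= 10000))
    stop("coordinates exceed the fixed-width PDB coordinate fields ",
         "(must lie in (-1000, 10000) Angstrom); consider mmCIF for such ",
         "systems")
  ids <- model$chains$chain
  role <- model$chains$role
  role_letter <- c(alpha = "A", beta = "B", ligand = "L", other = "O")[role]
  role_letter[is.na(role_letter)] <- "O"
  seg <- paste0(role_letter, base36(seq_along(ids) - 1L, 3))
  pdb_chain <- CHAIN_CYCLE[(seq_along(ids) - 1L) %% length(CHAIN_CYCLE) + 1L]
  idx <- match(model$atoms$chain, ids)

  na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  hdr <- c(
    sprintf("REMARK 299 MTCTT CHAIN %s %s %s %s %s %s %s",
            seg, ids, na_dot(role), na_dot(model$chains$pf),
            na_dot(model$chains$ring), na_dot(model$chains$dimer),
            na_dot(model$chains$assoc)))
  if (!is.null(model$box)) {
    b <- model$box
    hdr <- c(hdr, sprintf(
      "REMARK 299 MTCTT BOX %s %s %s %s %s %s %s %s %s %s %s %s",
      b$mode, na_dot(b$axial_length),
      na_dot(b$lengths[1]), na_dot(b$lengths[2]), na_dot(b$lengths[3]),
      na_dot(b$origin[1]), na_dot(b$origin[2]), na_dot(b$origin[3]),
      na_dot(b$axis[1]), na_dot(b$axis[2]), na_dot(b$axis[3]),
      na_dot(b$padding)))
    if (b$mode == "axial_periodic") {
      span <- apply(xyz, 2, function(v) diff(range(v)))
      lat <- ifelse(is.finite(b$lengths), b$lengths, span + 100)
      hdr <- c(hdr, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        lat[1], lat[2], b$axial_length, 90, 90, 90))
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  het <- model$atoms$resid %in% LIGAND_CODES
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(xyz)),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = model$atoms$resno,
                   resid = model$atoms$resid,
                   eleno = seq_len(n_atoms(model)),
                   elety = model$atoms$elety,
                   chain = pdb_chain[idx],
                   segid = seg[idx],
                   elesy = model$atoms$elesy,
                   print.segid = TRUE)
  writeLines(c(hdr, readLines(tmp, warn = FALSE)), path)
  invisible(path)
}

# --- trajectories ------------------------------------------------------------

#' Construct an in-memory trajectory
#'
#' @param topology the `lattice_model` defining atom order and labels.
#' @param xyz frames-by-3N coordinate matrix (bio3d xyz convention: each row
#'   is one frame, columns interleave x,y,z per atom).
#' @param frame_interval time between frames in ns.
#' @param metadata optional [md_run_metadata()].
#' @return an object of class `mt_trajectory`.
#' @export
mt_trajectory <- function(topology, xyz, frame_interval = 1,
                          metadata = NULL) {
  stopifnot(inherits(topology, "lattice_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("frame width (", ncol(xyz), ") does not match 3 x topology atom ",
         "count (", 3L * n_atoms(topology), ")")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval = frame_interval, metadata = metadata),
            class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat("mt_trajectory:", nrow(x$xyz), "frames x", n_atoms(x$topology),
      "atoms, frame interval", x$frame_interval, "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mt_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param traj an `mt_trajectory`.
#' @param i frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Write a trajectory
#'
#' Two on-disk forms are supported: `"multipdb"`, a plain-text multi-frame
#' PDB dialect (one `MODEL n` / coordinate block / `ENDMDL` per frame, atoms
#' strictly in topology order, no per-frame headers), and `"dcd"`, the
#' CHARMM/NAMD binary DCD format.
#'
#' @param traj an `mt_trajectory`.
#' @param path output path.
#' @param format `"multipdb"`, `"dcd"` or `"auto"` (by extension).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "multipdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "multipdb"
  if (format == "dcd") return(write_dcd(traj, path))
  at <- traj$topology$atoms
  ids <- traj$topology$chains$chain
  pdb_chain <- CHAIN_CYCLE[(match(at$chain, ids) - 1L) %% length(CHAIN_CYCLE) + 1L]
  elety4 <- ifelse(nchar(at$elety) < 4, sprintf(" %-3s", at$elety),
                   sprintf("%-4s", at$elety))
  pre <- sprintf("ATOM  %5d %s %-3s %s%4d    ",
                 seq_len(nrow(at)) %% 100000L, elety4, at$resid,
                 pdb_chain, at$resno %% 10000L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(c(sprintf("MODEL     %4d", f),
                 sprintf("%s%8.3f%8.3f%8.3f", pre, m[, 1], m[, 2], m[, 3]),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory
#'
#' The text dialect is parsed frame by frame through [stream_frames()], so
#' memory use is constant in the number of frames until the frames are
#' collected; binary DCD files are read with `bio3d::read.dcd`.
#'
#' @param topology the `lattice_model` the frames belong to.
#' @param path trajectory file path.
#' @param format `"multipdb"`, `"dcd"` or `"auto"` (by extension).
#' @param frame_interval time between frames in ns.
#' @return an `mt_trajectory`.
#' @export
read_trajectory <- function(topology, path,
                            format = c("auto", "multipdb", "dcd"),
                            frame_interval = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "multipdb"
  if (format == "dcd") {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3L * n_atoms(topology))
      stop("DCD atom count (", ncol(xyz) / 3, ") does not match topology (",
           n_atoms(topology), ")")
    return(mt_trajectory(topology, xyz, frame_interval))
  }
  frames <- list()
  stream_frames(path, topology, function(i, m) {
    frames[[i]] <<- as.numeric(t(m))
  })
  if (!length(frames)) stop("no frames found in ", path)
  mt_trajectory(topology, do.call(rbind, frames), frame_interval)
}

#' Stream over the frames of a text trajectory
#'
#' Calls `fun(frame_index, coords)` for every frame of a multi-frame PDB
#' file, holding only one frame in memory at a time.  Statistics computed
#' this way are identical to those from an eagerly loaded trajectory.
#'
#' @param path multi-frame PDB file.
#' @param topology the `lattice_model` fixing the expected atom count/order.
#' @param fun function of `(frame_index, n x 3 coordinate matrix)`.
#' @return the number of frames processed, invisibly.
#' @export
stream_frames <- function(path, topology, fun) {
  want <- n_atoms(topology)
  con <- file(path, open = "rt")
  on.exit(close(con))
  frame <- 0L
  repeat {
    block <- character(0)
    in_model <- FALSE
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line)) {
        if (in_model)
          stop("truncated frame ", frame + 1L, " in ", path,
               ": file ended inside a MODEL block")
        return(invisible(frame))
      }
      if (startsWith(line, "MODEL")) { in_model <- TRUE; next }
      if (startsWith(line, "ENDMDL")) break
      if (startsWith(line, "END")) {
        if (in_model)
          stop("truncated frame ", frame + 1L, " in ", path)
        return(invisible(frame))
      }
      if (startsWith(line, "ATOM") || startsWith(line, "HETATM"))
        block <- c(block, line)
    }
    frame <- frame + 1L
    if (length(block) != want)
      stop("frame ", frame, " has ", length(block), " atoms; topology has ",
           want)
    m <- cbind(as.numeric(substr(block, 31, 38)),
               as.numeric(substr(block, 39, 46)),
               as.numeric(substr(block, 47, 54)))
    fun(frame, m)
  }
}

# CHARMM/NAMD-style DCD writer (32-bit Fortran record markers, native
# little-endian, no unit cell, no fixed atoms).  bio3d reads DCD but has no
# writer, so this is the package's counterpart; round-trip against
# bio3d::read.dcd is exercised in the test suite.
write_dcd <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nf <- n_frames(traj); nat <- n_atoms(traj$topology)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record: CORD + 20 control integers (icntrl); icntrl[10] holds the
  # timestep as a float, icntrl[20] the CHARMM version stamp
  wi(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wi(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(1.0, con, size = 4, endian = "little")   # delta, arbitrary
  wi(rep(0L, 9))
  wi(24L)
  wi(84L)
  # title record
  title <- sprintf("%-80s", "mtctt trajectory")
  wi(4L + 80L)
  wi(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wi(4L + 80L)
  # natom record
  wi(4L); wi(nat); wi(4L)
  nb <- 4L * nat
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    for (k in 1:3) {
      wi(nb)
      writeBin(as.numeric(m[, k]), con, size = 4, endian = "little")
      wi(nb)
    }
  }
  invisible(path)
}
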