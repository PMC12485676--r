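# minimal hand-built model: one alpha "tail" glutamate and ARG/LYS body
# residues on labeled chains, for exact-distance and host-relation tests
mini_model <- function(glu_pos = c(0, 0, 0), nh1 = c(3.2, 0, 0),
                       extra_chain = FALSE) {
  atoms <- rbind(
    data.frame(elety = c("CA", "OE1", "OE2"), resid = "GLU", chain = "T",
               resno = 441L,
               x = c(glu_pos[1] - 2, glu_pos[1], glu_pos[1] + 1),
               y = glu_pos[2], z = glu_pos[3] + c(0, 0, 2)),
    data.frame(elety = c("NE", "NH1", "NH2"), resid = "ARG", chain = "B",
               resno = 390L, x = c(nh1[1] + 1.2, nh1[1], nh1[1] + 0.8),
               y = nh1[2] + c(0.5, 0, -0.5), z = nh1[3]))
  chains <- data.frame(chain = c("T", "B"), role = c("alpha", "beta"),
                       pf = 0L, ring = c(1L, 0L), dimer = c(1L, 0L),
                       assoc = NA_character_)
  if (extra_chain) {
    atoms <- rbind(atoms,
      data.frame(elety = c("NE", "NH1", "NH2"), resid = "ARG", chain = "B2",
                 resno = 390L, x = c(1.2, 0, 0.8) - 3.0,
                 y = c(0.5, 0, -0.5), z = 0))
    chains <- rbind(chains,
      data.frame(chain = "B2", role = "beta", pf = 1L, ring = 0L,
                 dimer = 2L, assoc = NA_character_))
  }
  lattice_model(atoms, chains)
}

test_that("salt bridges respect the distance criterion exactly", {
  m <- mini_model(nh1 = c(3.2, 0, 0))
  contacts <- detect_salt_bridges(NULL, m, tail_selection = select_atoms(m, chain = "T"),
                                  body_selection = select_atoms(m, chain = "B"))
  expect_equal(nrow(contacts), 1)
  expect_equal(contacts$tail_resno, 441)
  expect_equal(contacts$body_resno, 390)
  # nearest donor-acceptor pair beyond the cutoff: empty set
  far <- mini_model(nh1 = c(6.0, 0, 0))
  expect_equal(nrow(detect_salt_bridges(NULL, far,
    tail_selection = select_atoms(far, chain = "T"),
    body_selection = select_atoms(far, chain = "B"))), 0)
  # multiple qualifying atom pairs deduplicate to one residue contact
  near <- mini_model(nh1 = c(2.8, 0, 0))
  expect_equal(nrow(detect_salt_bridges(NULL, near,
    tail_selection = select_atoms(near, chain = "T"),
    body_selection = select_atoms(near, chain = "B"))), 1)
})

test_that("enlarging the cutoff never removes a contact", {
  m <- tailed_lattice()$model
  set.seed(10)
  xyz <- coords(m) + matrix(rnorm(3 * n_atoms(m), 0, 3), ncol = 3)
  tail_sel <- select_query(m, "role=alpha and resno 441-451")
  body_sel <- select_query(m, "resname ARG,LYS")
  prev <- NULL
  for (cutoff in c(3, 4, 5, 7)) {
    got <- detect_salt_bridges(xyz, m, salt_bridge_criterion(cutoff),
                               tail_sel, body_sel)
    key <- paste(got$tail_chain, got$tail_resno, got$body_chain,
                 got$body_resno)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("residues lacking their named atoms warn once and are skipped", {
  m <- mini_model()
  m$atoms <- m$atoms[m$atoms$elety != "OE1" & m$atoms$elety != "OE2", ]
  expect_warning(
    out <- detect_salt_bridges(NULL, m,
      tail_selection = select_atoms(m, chain = "T"),
      body_selection = select_atoms(m, chain = "B")),
    "lacks acceptor")
  expect_equal(nrow(out), 0)
})

test_that("neighbor-list detection equals brute force on random frames", {
  set.seed(11)
  box <- box_geometry("axial_periodic", axial_length = 50)
  for (i in 1:10) {
    acc <- cbind(runif(250, -30, 30), runif(250, -30, 30), runif(250, 0, 50))
    don <- cbind(runif(250, -30, 30), runif(250, -30, 30), runif(250, 0, 50))
    expect_identical(
      mtctt:::contact_matrix_cells(acc, don, 4.0, box),
      mtctt:::contact_matrix_brute(acc, don, 4.0, box))
    expect_identical(
      mtctt:::contact_matrix_cells(acc, don, 4.0, NULL),
      mtctt:::contact_matrix_brute(acc, don, 4.0, NULL))
  }
})

test_that("site assignment enforces the host relation", {
  m <- mini_model(extra_chain = TRUE)
  contacts <- detect_salt_bridges(NULL, m,
    tail_selection = select_atoms(m, chain = "T"),
    body_selection = select_atoms(m, role = "beta"))
  expect_equal(nrow(contacts), 2)  # B (correct pf) and B2 (wrong pf)
  lab <- assign_sites(contacts, default_site_registry(), m)
  expect_setequal(lab$site, c("1", "other"))
  expect_equal(lab$site[lab$body_chain == "B"], "1")   # minus-neighbor beta
  expect_equal(lab$site[lab$body_chain == "B2"], "other")
  # every labeled contact has exactly one label from the partition
  expect_true(all(lab$site %in% c("1", "2", "3", "4", "other")))
  # missing lattice labels are an error
  m2 <- m
  m2$chains$pf <- NA_integer_
  expect_error(assign_sites(contacts, default_site_registry(), m2), "labels")
})

test_that("trans contacts wrap across the periodic boundary", {
  sim <- short_sim()
  tl <- sim$timeline
  # tails live on rings 0..2; the ring-0 tail's minus neighbor is the
  # ring-2 beta through the periodic image, and site-1 binding was planted
  # for every tail including ring 0
  ring0_tail <- grep("\\.r0$", tl$tail_ids)
  expect_gt(mean(tl$occupancy[ring0_tail, "441", "1", ]), 0)
  expect_true(all(tl$eligible))
})

test_that("timelines reflect planted frames and concatenate associatively", {
  sim <- short_sim()
  tl <- sim$timeline
  expect_identical(unname(tl$occupancy[, , 1:4, ]),
                   unname(sim$truth$bound))
  # concatenation = timeline of concatenated trajectories
  n <- dim(tl$occupancy)[4]
  half1 <- tl; half1$occupancy <- tl$occupancy[, , , 1:200, drop = FALSE]
  half2 <- tl; half2$occupancy <- tl$occupancy[, , , 201:n, drop = FALSE]
  cc <- concat_timelines(half1, half2)
  expect_identical(cc$occupancy, tl$occupancy, ignore_attr = TRUE)
})

test_that("streaming and in-memory timelines agree", {
  sim <- short_sim()
  sub <- sim$trajectory
  sub$xyz <- sub$xyz[1:40, , drop = FALSE]
  f <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(sub, f, "multipdb")
  tl_mem <- build_timeline(sub)
  tl_str <- build_timeline(f, topology = sub$topology,
                           frame_interval = sub$frame_interval)
  expect_equal(unname(tl_str$occupancy), unname(tl_mem$occupancy))
})

test_that("interaction rates are occupancy fractions with exact edge cases", {
  sim <- short_sim()
  tl <- sim$timeline
  r <- interaction_rates(tl)
  expect_true(all(r >= 0 & r <= 1, na.rm = TRUE))
  expect_equal(dim(r), c(7, 4))
  # all-false timeline
  tl0 <- tl; tl0$occupancy[] <- FALSE
  expect_true(all(interaction_rates(tl0) == 0))
  # a cell planted bound forever recovers exactly 1
  kin <- binding_kinetics(
    data.frame(resno = 441, site = 1, p_on = 1, p_off = 0), n_frames = 30)
  sim2 <- simulate_binding(kin, tailed_lattice()$model, seed = 3)
  r2 <- interaction_rates(build_timeline(sim2$trajectory))
  expect_equal(unname(r2["441", "site_1"]), 1.0)
  # p_on = 0 everywhere gives the zero matrix
  kin0 <- binding_kinetics(
    data.frame(resno = c(441, 445), site = c(1, 2), p_on = 0, p_off = 0.5),
    n_frames = 30)
  sim0 <- simulate_binding(kin0, tailed_lattice()$model, seed = 3)
  expect_true(all(interaction_rates(build_timeline(sim0$trajectory)) == 0))
  # averaging two timelines weights them equally
  ravg <- interaction_rates(list(tl, tl0))
  expect_equal(unname(unclass(ravg)), unname(unclass(r)) / 2)
  # zero frames are an error
  tlz <- tl
  tlz$occupancy <- tl$occupancy[, , , 0, drop = FALSE]
  expect_error(interaction_rates(tlz), "zero frames")
})

test_that("event-rate units count binding onsets per nanosecond", {
  sim <- short_sim()
  tl <- sim$timeline
  re <- interaction_rates(tl, units = "events_per_ns")
  occ <- tl$occupancy[, "441", "1", ]
  onsets <- sum(occ[, -1] & !occ[, -ncol(occ)])
  expect_equal(unname(re["441", "site_1"]),
               onsets / (3 * (ncol(occ) - 1) * tl$frame_interval))
})

test_that("inaccessibility traces have exact limits and consistency", {
  sim <- short_sim()
  tl <- sim$timeline
  tr <- inaccessibility_trace(tl)
  expect_true(all(tr$fraction_inaccessible >= 0 &
                  tr$fraction_inaccessible <= 1))
  expect_true(all(diff(tr$time) > 0))
  # all-false -> identically 0; all-true -> identically 1
  tl0 <- tl; tl0$occupancy[] <- FALSE
  expect_true(all(inaccessibility_trace(tl0)$fraction_inaccessible == 0))
  tl1 <- tl; tl1$occupancy[] <- TRUE
  expect_true(all(inaccessibility_trace(tl1)$fraction_inaccessible == 1))
  # per-tail trace dominates the per-residue trace frame-wise
  tr_res <- inaccessibility_trace(tl, mode = "per_residue")
  expect_true(all(tr$fraction_inaccessible >=
                  tr_res$fraction_inaccessible - 1e-12))
  # time-average lies within [max restricted rate cell, 1]
  r <- interaction_rates(tl)
  restricted <- r[rownames(r) %in% as.character(445:450), ]
  expect_gte(mean(tr$fraction_inaccessible), max(restricted))
  expect_lte(mean(tr$fraction_inaccessible), 1)
  # smoothing: a window equal to the run length gives the running mean
  trs <- inaccessibility_trace(tl, smoothing_window = 5)
  expect_equal(trs$fraction_inaccessible[5],
               mean(tr$fraction_inaccessible[1:5]))
  expect_error(inaccessibility_trace(tl, residues = integer(0)), "empty")
})

test_that("results export as TSV and round-trip numerically", {
  sim <- short_sim()
  r <- interaction_rates(sim$timeline)
  tr <- inaccessibility_trace(sim$timeline)
  pre <- withr::local_tempfile()
  files <- export_results(r, tr, pre)
  rt <- utils::read.delim(paste0(pre, "_rates.tsv"))
  expect_equal(dim(rt), c(7, 5))  # residue column + 4 site columns
  expect_equal(names(rt), c("residue", paste0("site_", 1:4)))
  expect_equal(as.matrix(rt[, -1]), unclass(r), ignore_attr = TRUE,
               tolerance = 1e-9)
  tt <- utils::read.delim(paste0(pre, "_trace.tsv"))
  expect_equal(tt$fraction_inaccessible, tr$fraction_inaccessible,
               tolerance = 1e-9)
  # the zero matrix round-trips too
  tl0 <- sim$timeline; tl0$occupancy[] <- FALSE
  export_results(interaction_rates(tl0), NULL, pre)
  expect_true(all(utils::read.delim(paste0(pre, "_rates.tsv"))[, -1] == 0))
})

test_that("site registry validates and round-trips through TSV", {
  reg <- default_site_registry()
  expect_equal(length(unique(reg$site_id)), 4)
  expect_equal(sum(reg$site_id == 2), 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_registry(reg, f)
  expect_identical(read_site_registry(f), reg)
  expect_error(site_registry(transform(reg, resname = "GLU")), "LYS or ARG")
  bad <- rbind(reg, data.frame(site_id = 1, host = "cis_alpha",
                               resno = 390, resname = "ARG"))
  expect_error(site_registry(bad), "single host")
})
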