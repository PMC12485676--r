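test_that("the toy dimer satisfies its fixture contract", {
  m <- toy_dimer()
  expect_setequal(m$chains$role, c("alpha", "beta", "ligand"))
  a <- m$atoms[m$atoms$chain == "A", ]
  expect_equal(max(a$resno), 438)  # tails anchor at S439
  # all interaction-site residues are present with their donor atoms
  reg <- default_site_registry()
  for (i in seq_len(nrow(reg))) {
    ch <- if (reg$host[i] == "cis_alpha") "A" else "B"
    res <- m$atoms[m$atoms$chain == ch & m$atoms$resno == reg$resno[i], ]
    expect_equal(res$resid[1], reg$resname[i])
    donors <- if (reg$resname[i] == "LYS") "NZ" else c("NE", "NH1", "NH2")
    expect_true(all(donors %in% res$elety))
  }
  # deterministic per seed; different seeds move atoms but keep topology
  expect_identical(make_toy_dimer(1)$atoms, m$atoms)
  m2 <- make_toy_dimer(2)
  expect_false(isTRUE(all.equal(coords(m2), coords(m))))
  expect_identical(m2$atoms$elety, m$atoms$elety)
})

test_that("the toy lattice generator is its own spec oracle", {
  lat <- make_toy_lattice()
  expect_equal(dimer_count(lat$model), 39)
  got <- infer_lattice_spec(lat$model, 0L, 1L, 13L)
  expect_lt(max(abs(got$pf_transform$R - lat$spec$pf_transform$R)), 1e-6)
  expect_lt(max(abs(got$pf_transform$t - lat$spec$pf_transform$t)), 1e-4)
  # single-protofilament stack
  one <- make_toy_lattice(n_pf = 1, n_rings = 3)
  expect_equal(dimer_count(one$model), 3)
  expect_true(all(one$model$chains$pf[one$model$chains$role == "alpha"] == 0))
})

test_that("kinetics validate their probabilities and geometry margins", {
  expect_error(binding_kinetics(
    data.frame(resno = 441, site = 1, p_on = 1.2, p_off = 0)), "\\[0, 1\\]")
  expect_error(binding_kinetics(
    data.frame(resno = 441, site = 5, p_on = 0.1, p_off = 0.1)), "site")
  expect_error(binding_kinetics(
    data.frame(resno = 441, site = 1, p_on = 0.1, p_off = 0.1),
    d_bound = 7, d_unbound = 7.2), "d_unbound")
  k <- binding_kinetics(
    data.frame(resno = 441, site = 1, p_on = 0.1, p_off = 0.3))
  expect_equal(k$cells$q, 0.25)
})

test_that("presets encode the lattice-state contrast and round-trip", {
  gdp <- kinetics_preset("gdp_like")
  gtp <- kinetics_preset("gtp_like")
  qof <- function(k, r, s) {
    row <- k$cells[k$cells$resno == r & k$cells$site == s, ]
    if (nrow(row)) row$q else 0
  }
  # C-terminal site-2 and site-4 occupancies depressed in the GTP-like state
  for (r in c(445, 446, 447, 449, 450))
    expect_lt(qof(gtp, r, 2), qof(gdp, r, 2))
  for (r in c(449, 450))
    expect_lt(qof(gtp, r, 4), qof(gdp, r, 4))
  # site-1 binding of the N-terminal glutamates is shared
  expect_equal(qof(gtp, 441, 1), qof(gdp, 441, 1))
  expect_equal(qof(gtp, 443, 1), qof(gdp, 443, 1))
  # config-file round trip
  f <- withr::local_tempfile(fileext = ".txt")
  write_kinetics(gdp, f)
  back <- read_kinetics(f)
  expect_equal(back$cells, gdp$cells)
  expect_equal(back[c("n_frames", "frame_interval", "d_bound", "d_unbound",
                      "jitter", "start")],
               gdp[c("n_frames", "frame_interval", "d_bound", "d_unbound",
                     "jitter", "start")])
})

test_that("emitted coordinates realize exactly the planted contacts", {
  sim <- short_sim()
  tl <- sim$timeline
  expect_identical(unname(tl$occupancy[, , 1:4, ]), unname(sim$truth$bound))
  # bound distances hug d_bound, unbound stay beyond d_unbound: check the
  # realized (441, site 1) pair geometry on a few frames of one tail
  topo <- sim$trajectory$topology
  tail1 <- tl$tail_ids[1]
  oe <- select_atoms(topo, chain = tail1, resno = 441, elety = c("OE1", "OE2"))
  don_res <- default_site_registry()
  don_res <- don_res[don_res$site_id == 1, ]
  plan <- mtctt:::contact_plan(topo, default_site_registry(),
                               salt_bridge_criterion())
  donors <- plan$don[plan$lab[1, ] == 1L]
  for (f in c(1, 50, 200)) {
    xyz <- frame_coords(sim$trajectory, f)
    d <- min(vapply(seq_along(donors), function(i) {
      min(sqrt(rowSums(min_image(
        sweep(xyz[oe, , drop = FALSE], 2, xyz[donors[i], ]),
        topo$box)^2)))
    }, numeric(1)))
    if (sim$truth$bound[1, "441", "1", f]) {
      expect_lt(abs(d - sim$truth$d_bound), 0.41)
    } else {
      expect_gte(d, sim$truth$d_unbound)
    }
  }
})

test_that("simulation is deterministic per seed, byte-for-byte in text form", {
  kin <- kinetics_preset("gdp_like", n_frames = 25)
  topo <- tailed_lattice()$model
  s1 <- simulate_binding(kin, topo, seed = 5)
  s2 <- simulate_binding(kin, topo, seed = 5)
  expect_identical(s1$trajectory$xyz, s2$trajectory$xyz)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectory(s1$trajectory, f1, "multipdb")
  write_trajectory(s2$trajectory, f2, "multipdb")
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  s3 <- simulate_binding(kin, topo, seed = 6)
  expect_false(identical(s1$trajectory$xyz, s3$trajectory$xyz))
})

test_that("an unbound start relaxes toward the stationary occupancy", {
  kin <- kinetics_preset("gdp_like", n_frames = 3000, start = "unbound")
  sim <- simulate_binding(kin, tailed_lattice()$model, seed = 8)
  tr <- inaccessibility_trace(build_timeline(sim$trajectory),
                              smoothing_window = 200)
  expect_equal(tr$fraction_inaccessible[1], 0)
  expect_gt(mean(tr$fraction_inaccessible[2500:3000]), 0.5)
})

test_that("more than two sites on one residue is a geometric infeasibility", {
  kin <- binding_kinetics(
    data.frame(resno = 445, site = 1:3, p_on = 0.1, p_off = 0.1),
    n_frames = 10)
  expect_error(simulate_binding(kin, tailed_lattice()$model, seed = 1),
               "infeasibility")
})

test_that("planting on a lattice without a minus-end partner is refused", {
  lat <- make_toy_lattice(n_pf = 1, n_rings = 2)
  topo <- append_tails(lat$model, seed = 2)  # no periodic box
  kin <- binding_kinetics(
    data.frame(resno = 441, site = 1, p_on = 0.1, p_off = 0.1),
    n_frames = 10)
  expect_error(simulate_binding(kin, topo, seed = 1), "minus-end partner")
})
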