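test_that("lattice spec is recovered exactly from a generated template", {
  lat <- make_toy_lattice()
  got <- infer_lattice_spec(lat$model, 0L, 1L, 13L)
  expect_lt(max(abs(got$pf_transform$R - lat$spec$pf_transform$R)), 1e-6)
  expect_lt(max(abs(got$pf_transform$t - lat$spec$pf_transform$t)), 1e-4)
  expect_equal(got$dimer_repeat, lat$spec$dimer_repeat, tolerance = 1e-6)
  expect_equal(as.numeric(got$axis), c(0, 0, 1), tolerance = 1e-8)
})

test_that("spec inference is invariant to a global rigid motion", {
  lat <- make_toy_lattice(n_pf = 5, n_rings = 2, start_number = 3)
  tr <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.9), c(10, -4, 7))
  moved <- set_coords(lat$model, apply_transform(tr, coords(lat$model)))
  a <- infer_lattice_spec(lat$model, 0L, 1L, 5L, n_protofilaments = 5)
  b <- infer_lattice_spec(moved, 0L, 1L, 5L, n_protofilaments = 5)
  expect_equal(b$dimer_repeat, a$dimer_repeat, tolerance = 1e-8)
  expect_equal(rotation_angle(b$pf_transform$R),
               rotation_angle(a$pf_transform$R), tolerance = 1e-9)
})

test_that("a degenerate seed-equals-neighbor inference fails spec validation", {
  lat <- make_toy_lattice(n_pf = 3, n_rings = 1)
  spec <- infer_lattice_spec(lat$model, 0L, 0L, 0L, n_protofilaments = 3)
  expect_equal(spec$dimer_repeat, 0)
  expect_lt(rotation_angle(spec$pf_transform$R), 1e-9)
  expect_false(seam_closure(spec)$ok)
  expect_error(build_ring(make_toy_dimer(1), spec), "seam")
})

test_that("ring building yields 13 dimers and stacking yields 39", {
  lat0 <- make_toy_lattice(n_rings = 1)
  ring <- lat0$model
  expect_equal(dimer_count(ring), 13)
  expect_setequal(ring$chains$pf[ring$chains$role == "alpha"], 0:12)
  full <- stack_rings(ring, make_toy_lattice()$spec)
  expect_equal(dimer_count(full), 39)
})

test_that("dimer-count law holds across small lattice parameters", {
  for (np in c(1, 4, 11, 15)) for (nr in c(1, 2, 4)) {
    lat <- make_toy_lattice(n_pf = np, n_rings = nr)
    expect_equal(dimer_count(lat$model), np * nr)
  }
})

test_that("builders are isometries of each dimer", {
  dimer <- toy_dimer()
  lat <- make_toy_lattice(n_pf = 6, n_rings = 2)
  ref <- as.matrix(dist(coords(dimer)[1:40, ]))
  for (d in c(0, 3, 11)) {
    chains <- lat$model$chains$chain[lat$model$chains$dimer %in% d]
    idx <- which(lat$model$atoms$chain %in% chains)[1:40]
    got <- as.matrix(dist(coords(lat$model)[idx, ]))
    expect_lt(max(abs(got - ref)), 1e-6)
  }
})

test_that("the 13-fold composed lateral transform is 3 monomer repeats", {
  spec <- make_toy_lattice()$spec
  comp <- transform_power(spec$pf_transform, 13)
  expect_lt(rotation_angle(comp$R), 1e-6)       # residual rotation, rad
  expect_equal(comp$t, c(0, 0, 3 * spec$monomer_repeat), tolerance = 1e-9)
})

test_that("ring stacking spaces consecutive ring centroids by the dimer repeat", {
  lat <- make_toy_lattice(n_pf = 4, n_rings = 3)
  m <- lat$model
  cz <- vapply(0:2, function(r) {
    chains <- m$chains$chain[m$chains$ring %in% r]
    mean(m$atoms$z[m$atoms$chain %in% chains])
  }, numeric(1))
  expect_equal(diff(cz), rep(lat$spec$dimer_repeat, 2), tolerance = 1e-6)
})

test_that("infinite box has axial length of n_rings dimer repeats", {
  lat <- make_toy_lattice(n_pf = 4, n_rings = 3)
  inf <- make_infinite(lat$model, lat$spec)
  expect_equal(inf$box$mode, "axial_periodic")
  expect_equal(inf$box$axial_length, 3 * lat$spec$dimer_repeat)
  expect_equal(coords(inf), coords(lat$model))  # atoms unmoved
})

test_that("a twisted lattice cannot be made infinite and advises padding", {
  lat <- make_toy_lattice(n_pf = 4, n_rings = 2)
  twisted <- lat$spec
  # perturb the lateral rotation so composition no longer closes
  twisted$pf_transform <- rigid_transform(
    rotation_about_axis(c(0, 0, 1), 2 * pi / 4 + 0.02),
    twisted$pf_transform$t)
  expect_error(make_infinite(lat$model, twisted), "padded")
})

test_that("atoms straddling the periodic face are within contact range", {
  tl <- tailed_lattice()
  box <- tl$model$box
  L <- box$axial_length
  a <- c(5, 5, L + 1)   # 1 A past the +z face
  b <- c(5, 5, 2)       # 2 A inside the -z face
  d_mi <- sqrt(sum(min_image(a - b, box)^2))
  # explicit-image brute force
  d_exp <- min(vapply(-1:1, function(k) sqrt(sum((a - (b + c(0, 0, k * L)))^2)),
                      numeric(1)))
  expect_equal(d_mi, d_exp)
  expect_equal(d_mi, 1)  # well inside salt-bridge range across the face
})

test_that("minimum-image distances equal explicit-image brute force", {
  box <- box_geometry("axial_periodic", axial_length = 120)
  set.seed(8)
  for (i in 1:1000) {
    a <- c(runif(2, -60, 60), runif(1, 0, 120))
    b <- c(runif(2, -60, 60), runif(1, 0, 120))
    d_exp <- min(vapply(-1:1, function(k)
      sqrt(sum((a - (b + c(0, 0, k * 120)))^2)), numeric(1)))
    expect_equal(sqrt(sum(min_image(a - b, box)^2)), d_exp)
  }
})

test_that("padded boxes sit exactly at the padding from extreme atoms", {
  lat <- make_toy_lattice(n_pf = 3, n_rings = 1)$model
  pb <- make_padded_box(lat, 20)
  xyz <- coords(pb)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  expect_equal(lo - pb$box$origin, rep(20, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pb$box$origin + pb$box$lengths - hi, rep(20, 3),
               tolerance = 1e-6, ignore_attr = TRUE)
  p0 <- make_padded_box(lat, 0)
  expect_equal(p0$box$lengths, hi - lo, ignore_attr = TRUE)
  # translation invariance
  moved <- set_coords(lat, sweep(xyz, 2, c(7, -3, 11), "+"))
  pm <- make_padded_box(moved, 20)
  expect_equal(pm$box$origin - pb$box$origin, c(7, -3, 11),
               ignore_attr = TRUE)
  expect_equal(pm$box$lengths, pb$box$lengths)
  expect_error(make_padded_box(lat, -1), ">= 0")
})

test_that("GMPCPP to GTP conversion is template-exact and scoped to beta", {
  m <- make_toy_dimer(1, beta_nucleotide = "GCP")
  conv <- convert_nucleotide(m)
  lb <- conv$atoms[conv$atoms$chain == "LB", ]
  expect_setequal(lb$elety, mtctt:::GTP_HEAVY_ATOMS)
  expect_true(all(lb$resid == "GTP"))
  # the bridging atom keeps the carbon's position
  old <- m$atoms[m$atoms$chain == "LB" & m$atoms$elety == "C3A", c("x", "y", "z")]
  new <- lb[lb$elety == "O3A", c("x", "y", "z")]
  expect_equal(as.numeric(new), as.numeric(old))
  # alpha-site ligand untouched
  expect_equal(conv$atoms[conv$atoms$chain == "LA", ],
               m$atoms[m$atoms$chain == "LA", ], ignore_attr = TRUE)
  # identity conversion and template mismatch
  expect_identical(convert_nucleotide(m, "GTP", "GTP"), m)
  broken <- m
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "LB" &
                                 broken$atoms$elety == "PG"), ]
  expect_error(convert_nucleotide(broken), "LB.*missing.*PG")
})

test_that("fitting to a reference undoes global and per-dimer motions", {
  ref <- make_toy_lattice(n_pf = 4, n_rings = 2)$model
  tr <- rigid_transform(rotation_about_axis(c(1, 2, 3), 0.7), c(5, -3, 2))
  mob <- set_coords(ref, apply_transform(tr, coords(ref)))
  fit <- fit_to_reference(mob, ref)
  expect_lt(max(abs(coords(fit) - coords(ref))), 1e-6)
  # identity fit
  fit0 <- fit_to_reference(ref, ref)
  expect_lt(max(abs(coords(fit0) - coords(ref))), 1e-9)
  # independent random per-dimer motions are recovered too
  set.seed(9)
  mob2 <- ref
  for (d in unique(na.omit(ref$chains$dimer))) {
    chains <- ref$chains$chain[ref$chains$dimer %in% d]
    idx <- which(ref$atoms$chain %in% chains)
    rt <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 0.5)),
                          rnorm(3, 0, 3))
    xyz <- apply_transform(rt, coords(ref)[idx, ])
    mob2$atoms$x[idx] <- xyz[, 1]; mob2$atoms$y[idx] <- xyz[, 2]
    mob2$atoms$z[idx] <- xyz[, 3]
  }
  fit2 <- fit_to_reference(mob2, ref)
  expect_lt(max(abs(coords(fit2) - coords(ref))), 1e-6)
  # intra-dimer geometry preserved by the fit
  d0 <- ref$chains$chain[ref$chains$dimer %in% 0]
  i0 <- which(ref$atoms$chain %in% d0)[1:30]
  expect_lt(max(abs(as.matrix(dist(coords(fit2)[i0, ])) -
                    as.matrix(dist(coords(mob2)[i0, ])))), 1e-6)
  # unmapped dimers are an error
  expect_error(fit_to_reference(mob2, ref,
                                mapping = data.frame(mobile = 0,
                                                     reference = 0)),
               "unmapped")
})
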