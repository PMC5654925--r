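test_that("noise-free sphere samples are fit exactly", {
  set.seed(1)
  s <- sample_sphere_points(c(1, 2, 3), 0.0725, 200)
  fit <- fit_sphere(s)
  expect_lt(max(abs(fit$center - c(1, 2, 3))), 1e-9)
  expect_lt(abs(fit$radius - 0.0725), 1e-9)
  expect_lte(fit$rms_residual, 1e-9)
  expect_equal(fit$n_points, 200)
  # order invariance
  perm <- s[sample.int(200), ]
  class(perm) <- class(s)
  fit2 <- fit_sphere(perm)
  expect_equal(fit2$center, fit$center, tolerance = 1e-12)
})

test_that("noisy sphere fit matches a grid-search minimizer of the same objective", {
  set.seed(11)
  sigma <- 0.00095
  s <- sample_sphere_points(c(1, 2, 3), 0.0725, 200, sigma = sigma)
  fit <- fit_sphere(s)
  expect_lt(sqrt(sum((fit$center - c(1, 2, 3))^2)), 3 * sigma / sqrt(200) * 3)
  grid <- oracle_sphere_grid(s, fit$center, halfwidth = 3e-4, step = 1e-4)
  expect_lt(sqrt(sum((grid$center - fit$center)^2)), 1e-4 * sqrt(3) + 1e-12)
  # the refined fit is at least as good as the best grid candidate
  rho <- sqrt(rowSums(sweep(xyz_matrix(s), 2, fit$center)^2))
  expect_lte(sum((rho - fit$radius)^2), grid$obj + 1e-15)
})

test_that("degenerate sphere geometries are rejected", {
  expect_error(fit_sphere(point_cloud(1:3, 1:3, 1:3)), "at least 4")
  planar <- point_cloud(runif(50), runif(50), rep(1, 50))
  expect_error(fit_sphere(planar), "coplanar")
})

test_that("rigid transform of identical center sets is the identity", {
  set.seed(2)
  ctrs <- matrix(rnorm(15), 5)
  tr <- estimate_rigid_transform(ctrs, ctrs)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(tr$translation)), 1e-12)
})

test_that("a known rotation + translation is recovered to machine precision", {
  set.seed(3)
  ctrs <- matrix(rnorm(15), 5)
  ang <- 5 * pi / 180
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  tr0 <- rigid_transform(Rz, c(0.01, 0.02, 0.005))
  moved <- apply_transform(tr0, ctrs)
  tr <- estimate_rigid_transform(ctrs, moved)
  expect_lt(max(abs(tr$rotation - Rz)), 1e-12)
  expect_lt(max(abs(tr$translation - tr0$translation)), 1e-12)
  expect_lt(registration_tension(tr, ctrs, moved), 1e-12)
})

test_that("too-few or collinear correspondences are rejected", {
  expect_error(estimate_rigid_transform(matrix(rnorm(6), 2),
                                        matrix(rnorm(6), 2)), "at least 3")
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(estimate_rigid_transform(line, line), "collinear")
})

test_that("tension equals the mean residual distance by definition", {
  set.seed(4)
  ctrs <- matrix(rnorm(12), 4)
  # constructed residual: rigid-invariant offset of +1 mm in z on all targets
  tgt <- ctrs; tgt[, 3] <- tgt[, 3] + 0.001
  ident <- rigid_transform()
  expect_equal(registration_tension(ident, ctrs, tgt), 0.001)
  expect_equal(registration_tension(ident, ctrs, ctrs), 0)
  # noisy pair: direct formula recomputation
  noisy <- ctrs + matrix(rnorm(12, sd = 1e-3), 4)
  tr <- estimate_rigid_transform(ctrs, noisy)
  moved <- apply_transform(tr, ctrs)
  expect_equal(registration_tension(tr, ctrs, noisy),
               mean(sqrt(rowSums((moved - noisy)^2))))
})

test_that("tension is invariant under a common rigid motion of both sets", {
  set.seed(5)
  for (rep in 1:10) {
    ctrs <- matrix(rnorm(15), 5)
    noisy <- ctrs + matrix(rnorm(15, sd = 1e-3), 5)
    tr <- estimate_rigid_transform(ctrs, noisy)
    t0 <- registration_tension(tr, ctrs, noisy)
    common <- rigid_transform(random_rotation(0.3), rnorm(3))
    a <- apply_transform(common, ctrs)
    b <- apply_transform(common, noisy)
    tr2 <- estimate_rigid_transform(a, b)
    expect_equal(registration_tension(tr2, a, b), t0, tolerance = 1e-9)
  }
})

test_that("random rigid transforms are recovered under target noise", {
  set.seed(6)
  for (rep in 1:20) {
    ctrs <- matrix(runif(12, -2, 2), 4)
    tr0 <- rigid_transform(random_rotation(10 * pi / 180), runif(3, -0.1, 0.1))
    moved <- apply_transform(tr0, ctrs)
    sigma <- 1e-3
    noisy <- moved + matrix(rnorm(12, sd = sigma), 4)
    tr <- estimate_rigid_transform(ctrs, noisy)
    resid <- sqrt(rowSums((apply_transform(tr, ctrs) - noisy)^2))
    expect_lt(max(resid), 3 * sigma * sqrt(3))
  }
})

make_offset_series <- function(n_scans = 5, seed = 10) {
  set.seed(seed)
  base <- generate_tree(tree_spec(point_count = 2000), seed = seed)
  spheres <- default_sphere_targets()
  sched <- default_scan_schedule()[seq_len(n_scans)]
  records <- list(); targets <- list(); trs <- list()
  for (i in seq_len(n_scans)) {
    tr <- if (i == 1) rigid_transform() else
      rigid_transform(random_rotation(0.001), runif(3, -0.005, 0.005))
    trs[[i]] <- tr
    cl <- apply_transform(tr, base)
    ctr <- apply_transform(tr, as.matrix(spheres[, c("x", "y", "z")]))
    id <- sprintf("scan%02d", i)
    records[[i]] <- scan_record(id, sched[i], cl)
    targets[[i]] <- data.frame(scan_id = id, label = spheres$label,
                               x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
  }
  list(series = scan_series(records), targets = do.call(rbind, targets),
       base = base, transforms = trs)
}

test_that("registering an already-aligned series changes nothing", {
  sim <- make_offset_series(n_scans = 3, seed = 20)
  # rebuild with identity offsets: all scans identical
  spheres <- default_sphere_targets()
  sched <- default_scan_schedule()[1:3]
  recs <- lapply(1:3, function(i)
    scan_record(sprintf("scan%02d", i), sched[i], sim$base))
  tg <- do.call(rbind, lapply(1:3, function(i)
    data.frame(scan_id = sprintf("scan%02d", i), label = spheres$label,
               x = spheres$x, y = spheres$y, z = spheres$z)))
  reg <- register_series(scan_series(recs), tg)
  expect_lt(reg$report$max_mean_tension, 1e-12)
  for (i in 1:3)
    expect_lt(max(abs(xyz_matrix(reg$series$records[[i]]$cloud) -
                      xyz_matrix(sim$base))), 1e-12)
})

test_that("synthetic rigid offsets are exactly undone with noiseless targets", {
  sim <- make_offset_series(n_scans = 5, seed = 21)
  reg <- register_series(sim$series, sim$targets)
  expect_lt(reg$report$max_mean_tension, 1e-10)
  for (i in 2:5) {
    recovered <- reg$transforms[[sprintf("scan%02d", i)]]
    inv <- invert_transform(sim$transforms[[i]])
    expect_lt(max(abs(recovered$rotation - inv$rotation)), 1e-9)
    expect_lt(max(abs(recovered$translation - inv$translation)), 1e-9)
    expect_lt(max(abs(xyz_matrix(reg$series$records[[i]]$cloud) -
                      xyz_matrix(sim$base))), 1e-9)
  }
  expect_equal(reg$report$max_mean_tension, max(reg$report$per_scan_tension))
})

test_that("three shared target labels suffice; two are an error", {
  sim <- make_offset_series(n_scans = 3, seed = 22)
  drop_one <- sim$targets[!(sim$targets$scan_id == "scan02" &
                            sim$targets$label == "S4"), ]
  reg <- register_series(sim$series, drop_one)
  expect_lt(reg$report$max_mean_tension, 1e-10)
  drop_two <- drop_one[!(drop_one$scan_id == "scan02" &
                         drop_one$label == "S3"), ]
  expect_error(register_series(sim$series, drop_two), "scan02")
})

test_that("registration reports serialize with tensions in mm", {
  sim <- make_offset_series(n_scans = 3, seed = 23)
  reg <- register_series(sim$series, sim$targets)
  f <- tempfile(fileext = ".json")
  write_registration_report(reg$report, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$max_mean_tension_mm, reg$report$max_mean_tension * 1000)
})
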