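test_that("order parameter hits its landmark values and symmetries", {
  expect_equal(order_parameter(0, 0.2, 0), 1)
  expect_equal(order_parameter(0, 0, 0.1), -1)
  expect_equal(order_parameter(0, 1, 1), 0, tolerance = 1e-12)
  # gauge and velocity-sign invariance, bounds, on random inputs
  set.seed(1)
  a <- runif(50, 0, pi); vx <- rnorm(50); vy <- rnorm(50)
  s <- order_parameter(a, vx, vy)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(order_parameter(a + pi, vx, vy), s)
  expect_equal(order_parameter(a, -vx, -vy), s)
  expect_warning(sz <- order_parameter(0.3, 0, 0), "zero-velocity")
  expect_true(is.na(sz))
})

test_that("image Pearson behaves on identity, inversion and noise", {
  set.seed(2)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(pearson_images(img, img), 1)
  expect_equal(pearson_images(img, max(img) - img), -1)
  n1 <- matrix(rnorm(64 * 64), 64, 64)
  n2 <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(abs(pearson_images(n1, n2, smooth_sd = 0, downsample_to = 64)),
            0.05)
  # symmetry and affine invariance
  expect_equal(pearson_images(n1, n2), pearson_images(n2, n1))
  expect_equal(pearson_images(3 * n1 + 2, n2), pearson_images(n1, n2),
               tolerance = 1e-9)
  expect_error(pearson_images(matrix(1, 64, 64), img), "zero-variance")
})

test_that("direction fraction reproduces the counting formula", {
  r <- direction_fraction(9, 1)
  expect_equal(r$fraction, 0.9)
  expect_lt(r$p_value, 0.05)
  expect_equal(direction_fraction(5, 5)$fraction, 0.5)
  r2 <- direction_fraction(14, 1)
  expect_equal(r2$fraction, 14 / 15, tolerance = 1e-12)
  expect_lt(r2$p_value, 0.001)
  expect_error(direction_fraction(0, 0), "no exits")
})

test_that("exit classification detects the skew-set direction bias", {
  run_exits <- function(skew, seed = 7) {
    f <- make_asymmetric_plus_half(skew, shape = c(81L, 81L), pixel_size = 0.5)
    det <- detect_defects(f)
    det <- det[which.min((det$x - 20.25)^2 + (det$y - 20.25)^2), ]
    p <- sim_params(speed = 0.1, align_rate = 0.1, persistence_length = 100,
                    dt = 0.25, n_steps = 1600, seed = seed)
    set.seed(seed)
    init <- data.frame(x = rep(30, 40), y = 20.25 + rnorm(40, 0, 1.5),
                       theta = pi)
    s <- simulate_gliders(f, 40, p, init = init)
    classify_exits(s, det, d = 2)
  }
  pos <- run_exits(0.4)
  neg <- run_exits(-0.4)
  sym <- run_exits(0)
  fp <- direction_fraction(pos$n1, pos$n2)
  fn <- direction_fraction(neg$n1, neg$n2)
  fs <- direction_fraction(sym$n1, sym$n2)
  expect_gt(fp$fraction, 0.75)
  expect_lt(fp$p_value, 0.01)
  expect_gt(fn$fraction, 0.75)
  expect_lt(fn$p_value, 0.01)
  # mirrored skew flips the preferred side
  expect_true((pos$n1 > pos$n2) != (neg$n1 > neg$n2))
  # symmetric defect: no significant bias
  expect_gt(fs$p_value, 0.05)
})

test_that("explicit circles are classified by chirality and open paths ignored", {
  f <- director_field(matrix(0, 64, 64), 1) # field only feeds the winding
  th <- seq(0, 2 * pi, length.out = 400)
  ccw <- cbind(32 + 10 * cos(th), 32 + 10 * sin(th))
  loops <- detect_loops(list(ccw), f, closure_tol = 0.5, edge_margin = 0)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$chirality, "CCW")
  expect_gt(loops$signed_area, 0)
  cw <- ccw[rev(seq_len(nrow(ccw))), ]
  loops2 <- detect_loops(list(cw), f, closure_tol = 0.5, edge_margin = 0)
  expect_equal(loops2$chirality, "CW")
  open_path <- cbind(seq(5, 60, by = 0.2), seq(5, 60, by = 0.2))
  expect_equal(nrow(detect_loops(list(open_path), f)), 0L)
})

test_that("loops in confined simulations enclose charge +1 with N+2 bookkeeping", {
  f <- make_confined_field(40, n_plus = 4, n_minus = 2, pixel_size = 1,
                           seed = 3)
  truth <- spec_defects(f)
  p <- sim_params(speed = 0.1, align_rate = 0.03, persistence_length = 100,
                  dt = 1, n_steps = 12000, seed = 5)
  s <- simulate_gliders(f, 30, p, record_every = 6)
  loops <- detect_loops(s, f, truth, closure_tol = 1, min_perimeter = 15,
                        edge_margin = 0)
  expect_gt(nrow(loops), 0)
  good <- !is.na(loops$enclosed_charge)
  expect_gt(mean(loops$enclosed_charge[good] == 1), 0.7)
  idx <- good & loops$enclosed_charge == 1
  # bookkeeping identity; defects sitting on the polygon edge can miscount
  expect_gt(mean(loops$n_plus[idx] - loops$n_minus[idx] == 2), 0.85)
})

test_that("mirror reflection flips every chirality", {
  f <- make_confined_field(30, n_plus = 2, n_minus = 0, pixel_size = 1,
                           rim_tilt = 0.26, seed = 1)
  # reflect the texture about the vertical midline: x -> W - x, angle -> pi - angle
  fm <- f
  fm$angle <- (pi - f$angle[, ncol(f$angle):1]) %% pi
  fm$mask <- f$mask[, ncol(f$mask):1]
  attr(fm, "spec") <- attr(f, "spec")
  p <- sim_params(speed = 0.1, align_rate = 0.03, persistence_length = 100,
                  dt = 1, n_steps = 9000, seed = 3)
  ctr <- (nrow(f$angle) - 1) / 2
  set.seed(2)
  ang <- runif(30, 0, 2 * pi)
  init <- data.frame(x = ctr + 27 * cos(ang), y = ctr + 27 * sin(ang),
                     theta = ang + pi / 2)
  init_m <- data.frame(x = 2 * ctr - init$x, y = init$y,
                       theta = pi - init$theta)
  s <- simulate_gliders(f, 30, p, init = init, record_every = 6)
  sm <- simulate_gliders(fm, 30, p, init = init_m, record_every = 6)
  es <- edge_stats(s, band = 0.15)
  esm <- edge_stats(sm, band = 0.15)
  late <- seq(round(0.7 * nrow(es$counts)), nrow(es$counts))
  bal <- sum(es$counts$cw_minus_ccw[late])
  balm <- sum(esm$counts$cw_minus_ccw[late])
  expect_true(abs(bal) > 0)
  expect_lt(bal * balm, 0) # opposite handedness
  expect_equal(abs(sum(es$counts$n_band[late]) - sum(esm$counts$n_band[late])) /
                 sum(es$counts$n_band[late]), 0, tolerance = 0.25)
})

test_that("edge statistics classify a deterministic edge orbit", {
  f <- make_confined_field(30, n_plus = 2, n_minus = 0, pixel_size = 1,
                           seed = 1)
  ctr <- (nrow(f$angle) - 1) / 2
  # hand-built CW orbit at the rim (y-down frame: CW has x vy - y vx > 0)
  th <- seq(0, 4 * pi, length.out = 200)
  sim <- structure(list(
    x = matrix(ctr + 28 * cos(th), 200, 3),
    y = matrix(ctr + 28 * sin(th), 200, 3),
    theta = matrix(0, 200, 3), t = seq_along(th),
    params = sim_params(), confine = list(cx = ctr, cy = ctr, R = 30),
    field_dim = dim(f$angle), pixel_size = 1), class = "glide_sim")
  es <- edge_stats(sim, band = 0.15)
  cc <- es$counts[-1, ]
  expect_true(all(cc$n_cw == 3))
  expect_true(all(cc$n_ccw == 0))
  expect_true(all(cc$cw_minus_ccw == 3))
  expect_error(edge_stats(structure(list(confine = NULL), class = "glide_sim")),
               "confined")
})

test_that("confined runs select a single edge handedness (spiral texture)", {
  f <- make_confined_field(30, n_plus = 2, n_minus = 0, pixel_size = 1,
                           rim_tilt = 0.26, seed = 1)
  ctr <- (nrow(f$angle) - 1) / 2
  n <- 40
  set.seed(1)
  ang <- runif(n, 0, 2 * pi)
  tang <- ang + pi / 2
  # start half the particles CW, half CCW, on the rim
  init <- data.frame(x = ctr + 0.93 * 30 * cos(ang),
                     y = ctr + 0.93 * 30 * sin(ang),
                     theta = ifelse(seq_len(n) %% 2 == 0, tang, tang + pi))
  p <- sim_params(speed = 0.1, align_rate = 0.03, persistence_length = 100,
                  dt = 1, n_steps = 12000, seed = 4)
  s <- simulate_gliders(f, n, p, init = init, record_every = 10)
  es <- edge_stats(s, band = 0.15, groups = 1L + seq_len(n) %% 2L)
  cc <- es$counts
  late <- seq(round(0.8 * nrow(cc)), nrow(cc))
  imbalance <- abs(mean(cc$cw_minus_ccw[late])) / mean(cc$n_band[late])
  expect_gt(mean(cc$n_band[late]), 5)
  expect_gt(imbalance, 0.9) # one handedness has died out
  # the expelled group sits at smaller mean radius than the survivors
  rad <- es$radius
  r_end <- sapply(split(rad, rad$group), function(g)
    mean(g$mean_r[g$t_s >= stats::quantile(g$t_s, 0.8)]))
  expect_gt(abs(diff(r_end)), 2)
})
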