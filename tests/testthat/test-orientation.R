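# Orientation angles and their 1-D / 2-D distributions.

test_that("constructed alignments give the canonical angle values", {
  # para axis pointing exactly along R (toward the center): alpha = 0
  Q_in <- cbind(c(0, 0, -1), c(1, 0, 0), c(0, -1, 0))
  fr <- rbind(anchor_oleic(), place_gallic(Q_in, com = c(0, 0, 31)))
  class(fr) <- c("droplet_frame", "data.frame")
  expect_equal(orientation_angles(fr, 1L)$alpha, 0, tolerance = 1e-9)

  # ring plane perpendicular to R (parallel to the droplet surface): gamma = 90
  fr2 <- rbind(anchor_oleic(), place_gallic(diag(3L), com = c(0, 0, 31)))
  class(fr2) <- c("droplet_frame", "data.frame")
  o <- orientation_angles(fr2, 1L)
  expect_equal(o$gamma, 90, tolerance = 1e-9)
  expect_equal(o$com_radius, 31, tolerance = 1e-9)

  # ring plane containing R: gamma = 0
  Q_edge <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  fr3 <- rbind(anchor_oleic(), place_gallic(Q_edge, com = c(0, 0, 31)))
  class(fr3) <- c("droplet_frame", "data.frame")
  expect_equal(orientation_angles(fr3, 1L)$gamma, 0, tolerance = 1e-9)
})

test_that("angles match an independent dot-product oracle over random rotations", {
  set.seed(97)
  for (i in 1:250) {
    Q <- euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                        runif(1, 0, 2 * pi))
    com <- runif(3, -20, 20)
    com <- com / sqrt(sum(com^2)) * runif(1, 15, 45)
    fr <- rbind(anchor_oleic(), place_gallic(Q, com = com))
    class(fr) <- c("droplet_frame", "data.frame")
    got <- orientation_angles(fr, 1L)
    want <- oracle_angles(fr, 1L)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-9)
    expect_equal(got$beta, want$beta, tolerance = 1e-9)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-9)
  }
})

test_that("gamma via the plane normal equals gamma via in-plane projection", {
  set.seed(53)
  for (i in 1:100) {
    Q <- euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                        runif(1, 0, 2 * pi))
    com <- c(rnorm(2), runif(1, 20, 40))
    fr <- rbind(anchor_oleic(), place_gallic(Q, com = com))
    class(fr) <- c("droplet_frame", "data.frame")
    got <- orientation_angles(fr, 1L)$gamma
    # oracle: angle between R and its projection onto the ring plane
    mol <- fr[fr$species == "GAL", ]
    xyz <- as.matrix(mol[, c("x", "y", "z")]); rownames(xyz) <- mol$atom
    mcom <- colSums(xyz * mol$mass) / sum(mol$mass)
    rvec <- -mcom
    n <- crossprod_oracle(xyz["C2", ] - xyz["C1", ],
                          xyz["C4", ] - xyz["C1", ])
    n <- n / sqrt(sum(n^2))
    proj <- rvec - sum(rvec * n) * n
    g2 <- acos(max(-1, min(1, sum(rvec * proj) /
                             sqrt(sum(rvec^2) * sum(proj^2))))) * 180 / pi
    expect_equal(got, g2, tolerance = 1e-9)
  }
})

test_that("angles and radii are invariant under global rotation and translation", {
  spec <- tiny_spec(seed = 61L)
  fr <- build_droplet(spec)
  ids <- unique(fr$molid[fr$species == "GAL"])
  before <- lapply(ids, function(id) orientation_angles(fr, id))
  Q <- euler_rotation(0.7, 1.1, -0.4)
  shift <- c(12, -7, 3)
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% t(Q)
  fr2 <- fr
  fr2$x <- xyz[, 1L] + shift[1L]
  fr2$y <- xyz[, 2L] + shift[2L]
  fr2$z <- xyz[, 3L] + shift[3L]
  for (j in seq_along(ids)) {
    after <- orientation_angles(fr2, ids[j])
    expect_equal(after$alpha, before[[j]]$alpha, tolerance = 1e-9)
    expect_equal(after$beta, before[[j]]$beta, tolerance = 1e-9)
    expect_equal(after$gamma, before[[j]]$gamma, tolerance = 1e-9)
    expect_equal(after$com_radius, before[[j]]$com_radius, tolerance = 1e-9)
  }
})

test_that("degenerate geometries raise errors", {
  fr <- rbind(anchor_oleic(), place_gallic(diag(3L), com = c(0, 0, 0)))
  class(fr) <- c("droplet_frame", "data.frame")
  expect_error(orientation_angles(fr, 1L), "degenerate")
  fr2 <- rbind(anchor_oleic(), place_gallic(diag(3L), com = c(0, 0, 31)))
  class(fr2) <- c("droplet_frame", "data.frame")
  fr2 <- fr2[!(fr2$species == "GAL" & fr2$atom == "O4"), ]
  expect_error(orientation_angles(fr2, 1L), "label set")
})

test_that("angle histograms normalize, localize deltas and find flat laws flat", {
  # delta-generated alpha at 80 degrees: one maximum in the bin holding 80
  spec <- tiny_spec(n_water = 0L, n_surfactant = 0L, n_antioxidant = 8L,
                    orientation_law = orient_joint(c(80, 100), sd = 0),
                    seed = 29L)
  tr <- sample_trajectory(spec, 20)
  d <- angle_distribution(tr, "alpha", bin_width = 3)
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-9)
  expect_length(d$maxima, 1L)
  expect_equal(d$maxima, 79.5)  # center of [78, 81), which contains 80

  # uniform gamma law: flat density of 1/90 per degree
  specu <- tiny_spec(n_water = 0L, n_surfactant = 0L, n_antioxidant = 8L,
                     orientation_law = orient_gamma(law_uniform(0, 90)),
                     seed = 43L)
  tru <- sample_trajectory(specu, 500)
  du <- angle_distribution(tru, "gamma", bin_width = 3)
  expect_equal(sum(du$density * diff(du$breaks)), 1, tolerance = 1e-9)
  expect_lt(max(abs(du$density - 1 / 90)), 0.0045)
})

test_that("angle histogram equals a brute-force tally of the records", {
  spec <- tiny_spec(seed = 71L)
  tr <- sample_trajectory(spec, 5)
  tab <- emulsiphase:::orientation_table(tr)
  d <- angle_distribution(tr, "beta", bin_width = 5)
  hand <- vapply(seq_along(d$density), function(b)
    sum(tab$beta >= d$breaks[b] & tab$beta < d$breaks[b + 1L]),
    numeric(1))
  # top edge is closed
  hand[length(hand)] <- hand[length(hand)] + sum(tab$beta == 180)
  expect_equal(d$density, hand / (sum(hand) * 5), tolerance = 1e-12)
})

test_that("joint distribution finds the two generating maxima, ranked", {
  centers <- rbind(c(55.5, 64.5), c(82.5, 154.5))
  spec <- tiny_spec(n_water = 0L, n_surfactant = 0L, n_antioxidant = 8L,
                    orientation_law = orient_joint(centers, sd = 0,
                                                   weights = c(0.4, 0.6)),
                    seed = 83L)
  tr <- sample_trajectory(spec, 50)
  jd <- joint_angle_distribution(tr, bin_width = 3)
  expect_equal(sum(jd$density) * 9, 1, tolerance = 1e-9)
  expect_equal(nrow(jd$maxima), 2L)
  # ranked by density: the 0.6-weight component first
  expect_equal(jd$maxima$alpha, c(82.5, 55.5))
  expect_equal(jd$maxima$beta, c(154.5, 64.5))

  single <- tiny_spec(n_water = 0L, n_surfactant = 0L, n_antioxidant = 8L,
                      orientation_law = orient_joint(c(82.5, 154.5), sd = 0),
                      seed = 89L)
  js <- joint_angle_distribution(sample_trajectory(single, 10), 3)
  expect_equal(nrow(js$maxima), 1L)
})

test_that("dispersed joint components still peak at the generating centers", {
  centers <- rbind(c(55.5, 64.5), c(82.5, 154.5))
  spec <- tiny_spec(n_water = 0L, n_surfactant = 0L, n_antioxidant = 8L,
                    orientation_law = orient_joint(centers, sd = 6),
                    seed = 101L)
  tr <- sample_trajectory(spec, 400)
  jd <- joint_angle_distribution(tr, bin_width = 3)
  top2 <- jd$maxima[1:2, ]
  for (k in 1:2) {
    hit <- which.min(abs(top2$alpha - centers[k, 1]) +
                       abs(top2$beta - centers[k, 2]))
    expect_lte(abs(top2$alpha[hit] - centers[k, 1]), 3)
    expect_lte(abs(top2$beta[hit] - centers[k, 2]), 3)
  }
})

test_that("joint histogram equals a naive double-loop binning", {
  spec <- tiny_spec(seed = 107L)
  tr <- sample_trajectory(spec, 4)
  tab <- emulsiphase:::orientation_table(tr)
  jd <- joint_angle_distribution(tr, bin_width = 10)
  nb <- length(jd$breaks) - 1L
  counts <- matrix(0, nb, nb)
  for (r in seq_len(nrow(tab))) {
    ia <- min(nb, 1L + floor(tab$alpha[r] / 10))
    ib <- min(nb, 1L + floor(tab$beta[r] / 10))
    counts[ia, ib] <- counts[ia, ib] + 1
  }
  expect_equal(jd$density, counts / (sum(counts) * 100), tolerance = 1e-12)
})
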