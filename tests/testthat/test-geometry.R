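test_that("hydrogen bonds are detected inside the heavy-atom window", {
  # two waters 2.8 A apart: one bond
  fr <- make_atoms(rbind(c(0, 0, 0), c(2.8, 0, 0)), "O", "HOH",
                   c(1L, 2L), "O", chain = "W")
  hb <- detect_hbonds(fr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8, tolerance = 1e-12)

  # 3.5 A with the default window: nothing
  fr2 <- make_atoms(rbind(c(0, 0, 0), c(3.5, 0, 0)), "O", "HOH",
                    c(1L, 2L), "O", chain = "W")
  expect_equal(nrow(detect_hbonds(fr2)), 0L)

  # three collinear waters at 2.8 A spacing: exactly the two adjacent pairs
  fr3 <- make_atoms(rbind(c(0, 0, 0), c(2.8, 0, 0), c(5.6, 0, 0)), "O",
                    "HOH", c(1L, 2L, 3L), "O", chain = "W")
  expect_equal(nrow(detect_hbonds(fr3)), 2L)

  # empty frame is an empty list, not an error
  expect_equal(nrow(detect_hbonds(fr[0, ])), 0L)
})

test_that("hydrogen-bond detection matches a brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:40, 1L)
    fr <- make_atoms(matrix(runif(3 * n, 0, 12), ncol = 3L), "O", "HOH",
                     1000L + seq_len(n), "O", chain = "W")
    got <- detect_hbonds(fr)
    want <- oracle_hbond_pairs(fr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(as.matrix(got[, c("i", "j")]),
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("widening the distance window never removes a reported bond", {
  set.seed(7)
  n <- 25L
  fr <- make_atoms(matrix(runif(3 * n, 0, 10), ncol = 3L), "O", "HOH",
                   1000L + seq_len(n), "O", chain = "W")
  narrow <- detect_hbonds(fr, window = c(2.4, 2.9))
  wide <- detect_hbonds(fr, window = c(2.2, 3.2))
  key <- function(h) paste(h$i, h$j)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("donor-H geometry gates bonds when hydrogens are present", {
  # water donor with H pointing at the acceptor: near-linear D-H...A
  don <- make_atoms(rbind(c(0, 0, 0), c(0.96, 0, 0)), c("O", "H1"),
                    "HOH", 1L, c("O", "H"), chain = "W")
  acc <- make_atoms(rbind(c(2.8, 0, 0)), "O", "HOH", 2L, "O", chain = "W",
                    eleno = 3L)
  hb <- detect_hbonds(rbind(don, acc))
  expect_equal(nrow(hb), 1L)
  expect_gt(hb$angle, 170)

  # H pointing away: angle at H collapses, bond rejected
  don2 <- make_atoms(rbind(c(0, 0, 0), c(-0.96, 0, 0)), c("O", "H1"),
                     "HOH", 1L, c("O", "H"), chain = "W")
  expect_equal(nrow(detect_hbonds(rbind(don2, acc))), 0L)
})

test_that("direct contact takes the minimum over the target set", {
  asp <- make_atoms(rbind(c(0, 0, 0), c(-1.1, 1.91, 0)), c("OD1", "OD2"),
                    "ASP", 114L, "O")
  probe <- function(p) rbind(asp, make_atoms(rbind(p), "O1", "LIG", 900L,
                                             "O", chain = "B", eleno = 3L))
  expect_true(contact_direct(probe(c(2.7, 0, 0)), 3L, c(1L, 2L)))
  expect_false(contact_direct(probe(c(4.0, -1, 0)), 3L, c(1L, 2L)))
  # within window of OD2 only
  expect_true(contact_direct(probe(c(-1.1, 1.91 + 2.9, 0)), 3L, c(1L, 2L)))
  expect_error(contact_direct(probe(c(2.7, 0, 0)), 99L, c(1L, 2L)),
               "not present")
})

test_that("ring centroid/normal obey the stated conventions", {
  hx <- hexagon_coords()
  cn <- ring_centroid_normal(hx)
  expect_equal(cn$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(cn$normal, c(0, 0, 1), tolerance = 1e-12)

  # translation equivariance
  cn2 <- ring_centroid_normal(sweep(hx, 2L, -c(1, 2, 3)))
  expect_equal(cn2$centroid, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(cn2$normal, cn$normal, tolerance = 1e-12)

  # rotation by 90 degrees about x: normal along -y/+y, sign convention
  # picks a deterministic representative
  Rx <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  cn3 <- ring_centroid_normal(hx %*% t(Rx))
  expect_equal(abs(cn3$normal), c(0, 1, 0), tolerance = 1e-12)

  expect_error(ring_centroid_normal(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("pi-pi stacking applies distance, angle and offset gates", {
  rid <- ring_ids(two_ring_frame())
  # parallel rings 3.8 A apart, no offset: one contact
  fr <- two_ring_frame(centerB = c(0, 0, 3.8))
  expect_equal(nrow(detect_pipi(fr, ring_ids(fr))), 1L)
  # 5.5 A apart: beyond the exclusion bound
  fr2 <- two_ring_frame(centerB = c(0, 0, 5.5))
  expect_equal(nrow(detect_pipi(fr2, ring_ids(fr2))), 0L)
  # perpendicular rings 4 A apart fail the face-to-face angle gate
  fr3 <- two_ring_frame(centerB = c(0, 0, 4.0), normalB = c(1, 0, 0))
  expect_equal(nrow(detect_pipi(fr3, ring_ids(fr3))), 0L)
  # slipped stack beyond the lateral offset gate
  fr4 <- two_ring_frame(centerB = c(2.5, 0, 3.5))
  expect_equal(nrow(detect_pipi(fr4, ring_ids(fr4))), 0L)
  # unresolvable ring atoms fail loudly
  expect_error(detect_pipi(fr, list(a = c(998L, 999L, 1000L))), "absent")
})

test_that("all detectors are invariant under rigid-body motion", {
  set.seed(11)
  fr_h <- make_atoms(matrix(runif(60, 0, 9), ncol = 3L), "O", "HOH",
                     1000L + 1:20, "O", chain = "W")
  fr_p <- two_ring_frame(centerB = c(1.2, 0.5, 3.6))
  for (k in 1:5) {
    rg <- random_rigid()
    hb0 <- detect_hbonds(fr_h); hb1 <- detect_hbonds(apply_rigid(fr_h, rg))
    expect_equal(hb0$i, hb1$i)
    expect_equal(hb0$distance, hb1$distance, tolerance = 1e-9)
    pp0 <- detect_pipi(fr_p, ring_ids(fr_p))
    pp1 <- detect_pipi(apply_rigid(fr_p, rg), ring_ids(fr_p))
    expect_equal(nrow(pp0), nrow(pp1))
    expect_equal(pp0$centroid_distance, pp1$centroid_distance,
                 tolerance = 1e-9)
    # acos is ill-conditioned at 0 degrees: compare on the cosine scale
    expect_equal(cos(pp0$interplanar_angle * pi / 180),
                 cos(pp1$interplanar_angle * pi / 180), tolerance = 1e-9)
    expect_equal(pp0$lateral_offset, pp1$lateral_offset, tolerance = 1e-8)
  }
})
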