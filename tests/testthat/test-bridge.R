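roles <- default_roles()

test_that("classification follows the exclusion hierarchy", {
  # direct contact present together with a valid one-water path: direct wins
  g <- gen_bridge_frames(frame_spec(rep("direct", 5L), 0, seed = 1L))
  cl <- classify_frames(g$frames)
  expect_true(all(cl$label == "direct"))
  # and the constructed direct frames really do contain a one-water path:
  # removing the direct endpoint options is simulated by pushing the
  # ligand O out of range of the carboxylate
  fr <- split_frames(g$frames)[[1]]
  fr$x[fr$resname == "LIG"] <- fr$x[fr$resname == "LIG"] + 10
  expect_equal(classify_frame(fr, roles)$label, "none")

  # designed one- and two-water bridges classify as designed
  g2 <- gen_bridge_frames(frame_spec(c("water1", "water2", "none"), 0, seed = 2L))
  expect_equal(classify_frames(g2$frames)$label, c("water1", "water2", "none"))

  # water2 path structure: 4 atoms, two distinct waters in the middle
  cl2 <- classify_frame(split_frames(g2$frames)[[2]], roles)
  expect_length(cl2$path, 4L)
  mids <- cl2$path[2:3]
  fr2 <- split_frames(g2$frames)[[2]]
  expect_true(all(fr2$resname[match(mids, fr2$eleno)] == "HOH"))
  expect_false(mids[1] == mids[2])

  # adding a direct contact flips any frame to direct
  fr3 <- split_frames(g2$frames)[[3]]
  fr3 <- rbind(fr3, make_atoms(rbind(c(2.7, 0, 0)), "O1", "LIG", 900L, "O",
                               chain = "B", eleno = 99L)[, names(fr3)])
  fr3 <- fr3[fr3$elety != "O1" | fr3$eleno == 99L, ]
  expect_equal(classify_frame(fr3, roles)$label, "direct")

  # removing all waters from a water1 frame yields none
  fr1 <- split_frames(g2$frames)[[1]]
  expect_equal(classify_frame(fr1[fr1$resname != "HOH", ], roles)$label,
               "none")
})

test_that("graph classification equals brute-force path enumeration", {
  set.seed(31)
  labs <- character(0)
  for (k in 1:120) {
    fr <- random_bridge_frame(n_waters = sample(1:30, 1L))
    got <- classify_frame(fr, roles)$label
    expect_equal(got, oracle_classify(fr, roles))
    labs <- c(labs, got)
  }
  # the random ensemble exercises more than one class
  expect_gt(length(unique(labs)), 2L)
})

test_that("classification is invariant under water reordering and rigid motion", {
  set.seed(17)
  for (k in 1:20) {
    fr <- random_bridge_frame(n_waters = 12L)
    base <- classify_frame(fr, roles)$label
    # shuffle water rows and reassign serials
    wi <- which(fr$resname == "HOH")
    perm <- sample(wi)
    fr2 <- fr
    fr2[wi, ] <- fr[perm, ]
    fr2$eleno <- seq_len(nrow(fr2))
    expect_equal(classify_frame(fr2, roles)$label, base)
    # rigid motion
    fr3 <- apply_rigid(fr, random_rigid())
    expect_equal(classify_frame(fr3, roles)$label, base)
  }
})

test_that("class frequencies count correctly and sum to one", {
  labs <- c(rep("direct", 4), rep("water1", 3), "water2", rep("none", 2))
  fq <- bridge_frequencies(labs, rep("r1", 10))
  expect_equal(unlist(fq$per_replicate[1, BRIDGE_CLASSES]),
               c(direct = 0.4, water1 = 0.3, water2 = 0.1, none = 0.2))

  # two identical replicates: SEM 0 everywhere
  fq2 <- bridge_frequencies(c(labs, labs), rep(c("r1", "r2"), each = 10))
  expect_equal(fq2$summary$sem, rep(0, 4))

  # replicate fractions {0.2, 0.4}: mean 0.3, SEM 0.1 (sample SD / sqrt 2)
  labs3 <- c(rep("water1", 2), rep("none", 8), rep("water1", 4), rep("none", 6))
  fq3 <- bridge_frequencies(labs3, rep(c("a", "b"), each = 10))
  w1 <- fq3$summary[fq3$summary$class == "water1", ]
  expect_equal(w1$mean, 0.3)
  expect_equal(w1$sem, 0.1)

  # fractions sum to exactly 1 per replicate, even on random inputs
  set.seed(5)
  labs4 <- sample(BRIDGE_CLASSES, 200, replace = TRUE)
  rep4 <- sample(c("a", "b", "c"), 200, replace = TRUE)
  fq4 <- bridge_frequencies(labs4, rep4)
  sums <- unname(rowSums(fq4$per_replicate[, BRIDGE_CLASSES]))
  expect_equal(sums, rep(1, 3), tolerance = 1e-12)

  expect_error(bridge_frequencies(labs, rep("r1", 9)))
})

test_that("Mann-Whitney comparison is exact for small samples", {
  # identical groups: p = 1
  expect_equal(compare_frequencies(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3))$p, 1)
  # fully separated 2 vs 2: U = 0, two-sided exact p = 1/3
  res <- compare_frequencies(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$method, "exact_enumeration")

  # matches the independent full-enumeration oracle, including ties
  set.seed(23)
  for (k in 1:25) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    x <- round(runif(n1), 1)           # rounding induces ties
    y <- round(runif(n2), 1)
    expect_equal(compare_frequencies(x, y)$p, oracle_mw_exact(x, y))
  }

  # large samples switch to the tie-corrected normal approximation
  set.seed(4)
  x12 <- runif(12); y12 <- runif(12) + 0.2
  big <- compare_frequencies(x12, y12)
  expect_equal(big$method, "normal_approx_tie_corrected")
  expect_equal(big$p,
               stats::wilcox.test(x12, y12, exact = FALSE)$p.value)
  expect_error(compare_frequencies(0.5, c(0.1, 0.2)), "2 replicates")
})

test_that("stacking and hydrogen-bond frequencies count qualifying frames", {
  stacked <- two_ring_frame(centerB = c(0, 0, 3.8), frame = 1L)
  apart <- two_ring_frame(centerB = c(0, 0, 6.0), frame = 2L)
  frames <- rbind(stacked, apart)
  rid <- ring_ids(stacked)
  sf <- stacking_frequency(frames, rid)
  expect_equal(sf$summary$mean, 0.5)
  sf2 <- stacking_frequency(stacked, rid)
  expect_equal(sf2$summary$mean, 1.0)
  sf3 <- stacking_frequency(apart, rid)
  expect_equal(sf3$summary$mean, 0.0)

  # Y-OH to Q-amide bond frequency: bonded frame + distant frame = 0.5
  mk <- function(d, frame) {
    rbind(make_atoms(rbind(c(0, 0, 0)), "OH", "TYR", 326L, "O", frame = frame),
          make_atoms(rbind(c(d, 0, 0)), "OE1", "GLN", 124L, "O",
                     frame = frame, eleno = 2L))
  }
  frames2 <- rbind(mk(2.8, 1L), mk(4.0, 2L))
  hf <- hbond_frequency(frames2, roles, "tyr_oh", "gln_amide")
  expect_equal(hf$summary$mean, 0.5)
  expect_equal(hbond_frequency(mk(2.8, 1L), roles, "tyr_oh", "gln_amide")$summary$mean, 1)
  expect_equal(hbond_frequency(mk(4.0, 1L), roles, "tyr_oh", "gln_amide")$summary$mean, 0)
  expect_error(hbond_frequency(frames2, roles, "tyr_oh", "nope"), "configured")
})

test_that("frames survive a multi-model PDB round trip", {
  g <- gen_bridge_frames(frame_spec(c("direct", "water1", "water2", "none"),
                                    jitter_sd = 0.04, seed = 9L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(g$frames, path)
  back <- read_frames_pdb(path)
  expect_equal(sort(unique(back$frame)), 1:4)
  # PDB fixed columns carry 3 decimals
  expect_equal(back$x, g$frames$x, tolerance = 1e-3)
  expect_equal(classify_frames(back)$label, g$truth$label)
})
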