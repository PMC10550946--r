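## small helpers to build toy trajectories in code
straightChain <- function(n, spacing = 3.5, nFramesOut = 1) {
  coords <- array(0, dim = c(n, 3, nFramesOut))
  for (f in seq_len(nFramesOut)) coords[, 1, f] <- (seq_len(n) - 1) * spacing
  polymerTrajectory(coords, data.frame(resid = seq_len(n), name = "CA",
                                       element = "C", mass = 12.011))
}

anchorTraj <- function(p1, p2, p3) {
  coords <- array(0, dim = c(3, 3, 1))
  coords[1, , 1] <- p1; coords[2, , 1] <- p2; coords[3, , 1] <- p3
  polymerTrajectory(coords, data.frame(resid = 1:3, name = "CA",
                                       element = "C", mass = 12.011))
}

rigidTransform <- function(traj, seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  shift <- stats::runif(3, -50, 50)
  coords <- traj@coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- coords[, , f] %*% t(R) +
      matrix(shift, nrow = dim(coords)[1], ncol = 3, byrow = TRUE)
  polymerTrajectory(coords, traj@atoms, traj@replicaId)
}

test_that("normalized end-to-end distance matches the collinear closed form", {
  traj <- straightChain(71)
  sel <- mucinSelection(c(1, 71), nMucinResidues = 71, nGlycans = 14)
  expect_equal(endToEndSeries(traj, sel), 70 * 3.5 / 71, tolerance = 1e-9)
  # identical anchors give zero
  sel0 <- mucinSelection(c(1, 71), endAnchors = c(5, 5), nGlycans = 14,
                         nMucinResidues = 71)
  expect_equal(endToEndSeries(traj, sel0), 0)
  # rigid translation/rotation leaves the value unchanged
  expect_equal(endToEndSeries(rigidTransform(traj, 3), sel),
               endToEndSeries(traj, sel), tolerance = 1e-9)
  expect_error(endToEndSeries(traj, mucinSelection(c(1, 71),
                                                   endAnchors = c(1, 99),
                                                   nGlycans = 1)),
               "residue 99")
})

test_that("bending angles match analytic cases and are rotation invariant", {
  sel <- mucinSelection(c(1, 3), bendingAnchors = 1:3, nGlycans = 1)
  straight <- anchorTraj(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(bendingAngleSeries(straight, sel)$angles, 180, tolerance = 1e-9)
  right <- anchorTraj(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(bendingAngleSeries(right, sel)$angles, 90, tolerance = 1e-9)
  equi <- anchorTraj(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(bendingAngleSeries(equi, sel)$angles, 60, tolerance = 1e-9)
  expect_equal(bendingAngleSeries(rigidTransform(right, 5), sel)$angles, 90,
               tolerance = 1e-9)
  # degenerate (zero-length) vector flags NA
  degen <- anchorTraj(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_true(is.na(bendingAngleSeries(degen, sel)$angles))
})

test_that("bond autocorrelation is exactly 1 at lag 0 and bounded", {
  traj <- makeWlcTrajectory(9, nMonomers = 60, lb = 3.8, lp = 50,
                            nFrames = 50)
  sel <- mucinSelection(c(1, 60), nGlycans = 10)
  ac <- bondAutocorrelation(traj, sel, frameWindow = 50)
  expect_identical(ac$C[1], 1)
  expect_true(all(ac$C >= -1 & ac$C <= 1))
  expect_equal(ac$lb, 3.8, tolerance = 1e-9)
})

test_that("a rigid straight rod has infinite persistence length", {
  traj <- straightChain(50, nFramesOut = 5)
  sel <- mucinSelection(c(1, 50), nGlycans = 1)
  pr <- persistenceLength(traj, sel, frameWindow = 5)
  expect_true(pr$infinite)
  expect_identical(pr$perReplica[[1]], Inf)
})

test_that("a freely jointed chain decorrelates within one bond", {
  # lp << lb makes the mean deflection cosine ~ 0 (uniform directions)
  traj <- makeWlcTrajectory(4, nMonomers = 100, lb = 3.8, lp = 0.1,
                            nFrames = 300)
  sel <- mucinSelection(c(1, 100), nGlycans = 1)
  ac <- bondAutocorrelation(traj, sel, frameWindow = 300)
  expect_lt(abs(ac$C[2]), 0.02)
  pr <- persistenceLength(traj, sel, frameWindow = 300)
  expect_lt(pr$lp, 3.8)   # below one bond length
})

test_that("persistence length recovers the planted value on worm-like chains", {
  sel <- mucinSelection(c(1, 150), nGlycans = 1)
  for (lpTrue in c(20, 100)) {
    traj <- makeWlcTrajectory(100 + lpTrue, nMonomers = 150, lb = 3.8,
                              lp = lpTrue, nFrames = 300)
    pr <- persistenceLength(traj, sel, frameWindow = 300)
    expect_lt(abs(pr$lp - lpTrue) / lpTrue, 0.15)
  }
  # replica averaging reports mean and SD
  trajs <- lapply(1:3, function(s)
    makeWlcTrajectory(s, nMonomers = 120, lb = 3.8, lp = 80, nFrames = 200,
                      replicaId = paste0("rep", s)))
  pr <- persistenceLength(trajs, mucinSelection(c(1, 120), nGlycans = 1),
                          frameWindow = 200)
  expect_identical(pr$nReplicas, 3L)
  expect_length(pr$perReplica, 3L)
  expect_gt(pr$sd, 0)
  expect_lt(abs(pr$lp - 80) / 80, 0.15)
})

test_that("persistence length is invariant under rigid transforms", {
  traj <- makeWlcTrajectory(12, nMonomers = 80, lb = 3.8, lp = 60,
                            nFrames = 100)
  sel <- mucinSelection(c(1, 80), nGlycans = 1)
  pr1 <- persistenceLength(traj, sel, frameWindow = 100)
  pr2 <- persistenceLength(rigidTransform(traj, 8), sel, frameWindow = 100)
  expect_equal(pr1$lp, pr2$lp, tolerance = 1e-6)
})

test_that("height per glycan divides the backbone end-to-end length by glycan count", {
  traj <- straightChain(61, spacing = 3)   # backbone length 180 A
  sel <- mucinSelection(c(1, 61), nGlycans = 20)
  out <- heightPerGlycan(traj, sel, mode = "outstretched")
  expect_equal(out$heightPerGlycan, 9.0, tolerance = 1e-9)
  sel1 <- mucinSelection(c(1, 61), nGlycans = 1)
  expect_equal(heightPerGlycan(traj, sel1, "outstretched")$heightPerGlycan,
               180, tolerance = 1e-9)
  # compressing the chain by half halves the value
  half <- straightChain(61, spacing = 1.5)
  expect_equal(heightPerGlycan(half, sel, "outstretched")$heightPerGlycan,
               4.5, tolerance = 1e-9)
  # equilibrated mode averages the final frame window
  coords <- array(0, dim = c(61, 3, 4))
  for (f in 1:4) coords[, 1, f] <- (0:60) * c(3, 3, 1, 1)[f]
  varying <- polymerTrajectory(coords, straightChain(61)@atoms)
  eq <- heightPerGlycan(varying, sel, "equilibrated", frameWindow = 2)
  expect_equal(eq$heightPerGlycan, 60 * 1 / 20, tolerance = 1e-9)
})

test_that("multi-model PDB files read back as trajectories", {
  path <- tempfile(fileext = ".pdb")
  lines <- character()
  for (f in 1:2) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (i in 1:4)
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, (i - 1) * 3.8 * f, 0, 0))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  traj <- readTrajectoryPDB(path)
  expect_identical(dim(traj@coords), c(4L, 3L, 2L))
  expect_equal(traj@coords[4, 1, 2], 3 * 3.8 * 2, tolerance = 1e-6)
  sel <- mucinSelection(c(1, 4), nGlycans = 1)
  expect_equal(endToEndSeries(traj, sel)[1], 3 * 3.8 / 4, tolerance = 1e-6)
})
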