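test_that("a single satisfiable AIR minimizes to its target", {
  mobile <- coarseModel("A", 1L, rbind(c(0, 0, 0)))
  receptor <- coarseModel("B", 1L, rbind(c(0, 0, 0)))
  air <- ambiguousRestraint("A:1:CA", "B:1:CA", target = 5)
  ens <- dockTrials(mobile, receptor, air, nTrials = 5, seed = 2)
  expect_equal(length(ens@poses), 5L)
  best <- which.min(energies(ens))
  expect_lt(energies(ens)[best], 1e-6)
  d <- soxdimer:::vecNorm(poseCoords(ens, best)[1, ] -
                          coords(receptor)[1, ])
  expect_lte(d, 5 + 1e-3)
  expect_error(dockTrials(mobile, receptor, air, nTrials = 0), ">= 1")
})

test_that("docking is seed-reproducible and rigid-motion invariant", {
  prob <- plantedDockingProblem(seed = 6)
  e1 <- dockTrials(prob$mobile, prob$receptor, prob$airs, nTrials = 25,
                   seed = 11)
  e2 <- dockTrials(prob$mobile, prob$receptor, prob$airs, nTrials = 25,
                   seed = 11)
  expect_identical(energies(e1), energies(e2))
  expect_identical(e1@poses, e2@poses)

  ## the reference energy is invariant under joint rigid motion
  cairs <- soxdimer:::compileDockingAirs(prob$airs, prob$mobile,
                                         prob$receptor)
  mob <- poseCoords(e1, 1)
  rec <- coords(prob$receptor)
  e0 <- soxdimer:::dockEnergy(mob, rec, cairs)
  set.seed(313)
  R <- soxdimer:::randomRotation(); t <- rnorm(3, 0, 30)
  expect_equal(soxdimer:::dockEnergy(
    soxdimer:::transformCoords(mob, R, t),
    soxdimer:::transformCoords(rec, R, t), cairs), e0,
    tolerance = 1e-9)

  ## compiled and reference energies agree
  expect_equal(soxdimer:::.dockEnergyCpp(mob, rec, cairs, 4.0), e0,
               tolerance = 1e-9)
})

test_that("minimization never increases energy and clash-only separates", {
  prob <- plantedDockingProblem(seed = 8)
  ref <- coords(prob$mobile)
  rec <- coords(prob$receptor)
  cairs <- soxdimer:::compileDockingAirs(prob$airs, prob$mobile,
                                         prob$receptor)
  set.seed(314)
  R0 <- soxdimer:::randomRotation()
  t0 <- colMeans(rec) + c(30, 0, 0)
  eStart <- soxdimer:::dockEnergy(
    soxdimer:::transformCoords(ref, R0, t0), rec, cairs)
  m <- soxdimer:::minimizePose(ref, rec, cairs, R0, t0)
  expect_lte(m$energy, eStart)

  ## with the AIRs removed the clash-only optimum separates the chains
  overlap <- soxdimer:::minimizePose(ref, rec, list(), diag(3),
                                     colMeans(rec))
  expect_lt(overlap$energy, 1e-9)
  sep <- min(soxdimer:::crossDist(
    soxdimer:::transformCoords(ref, overlap$R, overlap$t), rec))
  expect_gte(sep, 4.0 - 1e-6)
})

test_that("rank selection keeps the lowest energies with stable ties", {
  prob <- plantedDockingProblem(seed = 3)
  mk <- function(energies) new("DockEnsemble",
    poses = rep(list(list(R = diag(3), t = c(0, 0, 0))),
                length(energies)),
    energies = energies, trial = seq_along(energies), seed = 1,
    mobileRef = prob$mobile, receptor = prob$receptor)

  sel <- rankSelect(mk(c(3, 1, 2)), top = 2)
  expect_equal(energies(sel), c(1, 2))
  expect_equal(sel@trial, c(2L, 3L))

  ties <- rankSelect(mk(rep(7, 5)), top = 3)
  expect_equal(ties@trial, 1:3)

  expect_warning(all <- rankSelect(mk(c(3, 1)), top = 10), "returning all")
  expect_equal(length(all@poses), 2L)

  ens <- dockTrials(prob$mobile, prob$receptor, prob$airs, nTrials = 40,
                    seed = 4)
  top <- rankSelect(ens, 10)
  expect_lte(max(energies(top)), min(energies(ens)[-top@trial]))
})

test_that("orientation clustering reproduces a 17-vs-3 split", {
  ens <- makeOrientationFixture()
  bins <- clusterByOrientation(ens)
  expect_equal(vapply(bins, function(b) length(b$members), integer(1)),
               c(17L, 3L))
  ## bins partition the ensemble
  expect_setequal(unlist(lapply(bins, `[[`, "members")), 1:20)

  rep <- pickRepresentative(bins, ens)
  expect_true(rep$index %in% bins[[1]]$members)
  expect_equal(rep$energy, min(energies(ens)[bins[[1]]$members]))

  ## all-identical poses collapse to one bin
  same <- ens
  same@poses <- rep(ens@poses[1], 20)
  oneBin <- clusterByOrientation(same)
  expect_equal(length(oneBin), 1L)
  expect_equal(length(oneBin[[1]]$members), 20L)
  expect_equal(pickRepresentative(oneBin, same)$index,
               which.min(energies(same)))

  ## two poses 180 degrees apart (helix parallel vs antiparallel to
  ## alpha1) occupy two bins
  rec <- coords(ens@receptor)
  spans <- ens@receptor@meta$spans
  rres <- residueNumbers(ens@receptor)
  a1ax <- soxdimer:::principalAxis(
    rec[rres >= spans$a1[1] & rres <= spans$a1[2], ])
  rotTo <- soxdimer:::crossProd3(c(0, 0, 1), a1ax)
  Rpar <- soxdimer:::rotAxis(rotTo, acos(max(-1, min(1, a1ax[3]))))
  perp <- soxdimer:::unitVec(soxdimer:::crossProd3(a1ax, c(0, 1, 0)))
  flip <- ens
  flip@poses <- list(list(R = Rpar, t = ens@poses[[1]]$t),
                     list(R = soxdimer:::rotAxis(perp, pi) %*% Rpar,
                          t = ens@poses[[1]]$t))
  flip@energies <- c(1, 2); flip@trial <- 1:2
  expect_equal(length(clusterByOrientation(flip)), 2L)
})
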