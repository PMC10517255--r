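test_that("chain simulation matches closed forms and conserves mass", {
  # one-step: pure exponential decay into the dianion
  m <- kineticModel(1, 0, 0)
  tt <- c(0, 0.5, 1, 2, 5)
  p <- simulateChain(m, tt)
  expect_equal(p[, "UA"], 25 * exp(-tt), tolerance = 1e-10)
  expect_equal(p[, "UA2"], 25 * (1 - exp(-tt)), tolerance = 1e-10)

  # symmetric two-species equilibrium: both converge to half the input
  m2 <- kineticModel(1, 0, 0, km1 = 1)
  p2 <- simulateChain(m2, c(0, 50))
  expect_equal(unname(p2[2, c("UA", "UA2")]), c(12.5, 12.5),
               tolerance = 1e-9)

  expect_error(simulateChain(m, c(-1, 0)), "negative time")

  # mass conservation over random models (relative 1e-9)
  set.seed(21)
  for (i in 1:20) {
    mm <- kineticModel(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50),
                       km1 = runif(1, 0, 10), km2 = runif(1, 0, 10),
                       km3 = runif(1, 0, 10))
    pp <- simulateChain(mm, logTimes(1e-3, 50, 40))
    expect_true(all(abs(rowSums(pp) - 25) < 25 * 1e-9))
  }
})

test_that("irreversible cascade agrees with Bateman and an RK4 oracle", {
  m <- kineticModel(3, 1, 0.3)
  tt <- logTimes(1e-3, 20, 50)
  p <- simulateChain(m, tt)
  bate <- batemanCascade(3, 1, 0.3, 25, tt)
  expect_equal(unname(p), unname(bate), tolerance = 1e-8)
  rk <- rk4Chain(uoxkit:::rateMatrix(m), c(UA = 25, UA2 = 0, PIU = 0,
                                           HIU = 0), tt, dtMax = 5e-4)
  expect_equal(unname(p), unname(rk), tolerance = 1e-8)

  # repeated-rate degenerate case falls back to the integrator and still
  # matches RK4
  md <- kineticModel(2, 2, 2)
  pd <- simulateChain(md, tt)
  rkd <- rk4Chain(uoxkit:::rateMatrix(md), c(UA = 25, UA2 = 0, PIU = 0,
                                             HIU = 0), tt, dtMax = 5e-4)
  expect_equal(unname(pd), unname(rkd), tolerance = 1e-7)
})

test_that("reversible chain settles at detailed-balance ratios", {
  m <- kineticModel(4, 3, 2, km1 = 2, km2 = 1.5, km3 = 5)
  p <- simulateChain(m, c(0, 500))
  eq <- p[2, ]
  expect_equal(unname(eq["UA2"] / eq["UA"]), 4 / 2, tolerance = 1e-6)
  expect_equal(unname(eq["PIU"] / eq["UA2"]), 3 / 1.5, tolerance = 1e-6)
  expect_equal(unname(eq["HIU"] / eq["PIU"]), 2 / 5, tolerance = 1e-6)
})

test_that("back-biased final step caps HIU below the initial urate", {
  m <- ggUoxLikeModel()
  tt <- logTimes(1e-3, 100, 80)
  p <- simulateChain(m, tt)
  plateau <- p[nrow(p), "HIU"]
  expect_lt(plateau, 25)
  expect_lt(plateau / 25, 0.35)   # strongly sub-stoichiometric yield
  expect_gt(plateau / 25, 0.05)
  # raising k3 with everything else fixed raises the plateau monotonically
  plateaus <- vapply(c(1.5, 3, 6, 12), function(k3) {
    mi <- kineticModel(3000, 1500, k3, km1 = 100, km2 = 50, km3 = 6)
    simulateChain(mi, c(0, 200))[2, "HIU"]
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
})

test_that("hydrogen peroxide output is cumulative and not consumed", {
  tt <- logTimes(1e-3, 10, 40)
  # irreversible chain: cumulative H2O2 equals HIU formed
  m <- kineticModel(10, 5, 2)
  h <- h2o2Produced(m, tt)
  p <- simulateChain(m, tt)
  expect_equal(h, unname(p[, "HIU"]), tolerance = 1e-6)
  # reversible final step: H2O2 keeps accumulating beyond the HIU plateau
  mr <- kineticModel(10, 5, 2, km3 = 4)
  hr <- h2o2Produced(mr, c(1, 5, 20, 80))
  pr <- simulateChain(mr, c(1, 5, 20, 80))
  expect_true(all(diff(hr) > 0))
  expect_gt(hr[4], pr[4, "HIU"])
})

test_that("spectral synthesis follows Beer-Lambert", {
  wl <- c(280, 292, 310)
  sp <- speciesSpectra(wl, list(UA = c(0, 12650, 0), UA2 = c(0, 0, 0),
                                PIU = c(0, 0, 0), HIU = c(0, 0, 0)))
  prof <- matrix(c(1, 1, 1, rep(0, 9)), nrow = 3,
                 dimnames = list(NULL, c("UA", "UA2", "PIU", "HIU")))
  sm <- synthesizeSpectra(prof, c(0, 1, 2), sp)
  A <- absorbanceMatrix(sm)
  expect_equal(unname(A[, "292"]), rep(0.01265, 3), tolerance = 1e-12)
  expect_true(all(A[, c("280", "310")] == 0))

  zero <- synthesizeSpectra(prof * 0, c(0, 1, 2), sp)
  expect_true(all(zero@absorbance == 0))

  # noiseless full-chain matrix has rank at most the number of species
  sf <- genStoppedFlowDataset(sigma = 0, seed = 1)
  sv <- svd(sf$spectra@absorbance)
  expect_lt(sv$d[5] / sv$d[1], 1e-10)

  expect_error(synthesizeSpectra(prof[, 1:3], c(0, 1, 2), sp), "columns")
  expect_error(synthesizeSpectra(prof, c(0, 1, 2), sp, sigma = -1),
               "sigma")
})

test_that("SVD components are ordered, sign-fixed, and reconstruct the input", {
  # rank-1: one decaying species
  wl <- seq(260, 340, by = 4)
  eps <- 12650 * exp(-(wl - 292)^2 / 200)
  sp <- speciesSpectra(wl, list(UA = eps, UA2 = eps * 0, PIU = eps * 0,
                                HIU = eps * 0))
  tt <- logTimes(1e-3, 5, 30)
  prof <- simulateChain(kineticModel(1, 0, 0, conc0 = c(UA = 25, UA2 = 0,
                                                        PIU = 0, HIU = 0)),
                        tt)
  prof[, "UA2"] <- 0   # keep only the absorbing species
  sm <- synthesizeSpectra(prof, tt, sp)
  sv <- svdComponents(sm)
  expect_gte(sv$explained[1], 1 - 1e-12)
  # sign convention: largest-|loading| spectral entry is positive
  expect_gt(sv$v[which.max(abs(sv$v[, 1])), 1], 0)

  # time-row permutation leaves singular values unchanged
  sf <- genStoppedFlowDataset(seed = 3)
  M <- sf$spectra@absorbance
  sv1 <- svd(M)$d
  sv2 <- svd(M[sample(nrow(M)), ])$d
  expect_equal(sv1, sv2, tolerance = 1e-12)

  # full reconstruction to numerical precision; truncation error
  # non-increasing in k
  sv <- svdComponents(sf$spectra)
  rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(max(abs(rec - M)) / max(abs(M)), 1e-10)
  errs <- vapply(1:4, function(k) {
    recK <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sqrt(sum((recK - M)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))

  Mna <- sf$spectra
  Mna@absorbance[1, 1] <- NA
  expect_error(svdComponents(Mna), "NA")
})

test_that("the leading difference component shows the PIU-HIU landmarks", {
  # noiseless default dataset; final-spectrum subtraction isolates the
  # PIU <-> HIU interconversion, whose difference spectrum was engineered
  # with a negative extremum at 294 nm and a positive extremum at 314 nm
  sf <- genStoppedFlowDataset(sigma = 0, seed = 1)
  sv <- svdComponents(sf$spectra, center = TRUE)
  v1 <- sv$v[, 1]
  wl <- sv$wavelengths
  expect_equal(wl[which.max(v1)], 314)
  expect_equal(wl[which.min(v1)], 294)
  expect_gt(max(v1), abs(min(v1)) * 0)   # positive lobe survives sign fix
  expect_gt(sv$explained[1], 0.95)
})

test_that("isolated-wavelength selection maximizes component dominance", {
  mkSvd <- function(v, wl) structure(
    list(d = rep(1, ncol(v)), u = NULL, v = v,
         explained = rep(1 / ncol(v), ncol(v)),
         times = NULL, wavelengths = wl, center = FALSE),
    class = "SVDResult")

  # component 2 crosses zero at exactly 320 nm while component 1 is nonzero
  wl <- c(300, 310, 320, 330, 340)
  v <- cbind(c(0.5, 0.6, 0.7, 0.6, 0.5),
             c(0.4, 0.2, 0.0, -0.2, -0.4))
  expect_equal(selectIsolatedWavelength(mkSvd(v, wl), component = 1,
                                        retain = 2), 320)

  # single retained component: wavelength of maximal |loading|
  expect_equal(selectIsolatedWavelength(mkSvd(v[, 1, drop = FALSE], wl),
                                        component = 1, retain = 1), 320)

  # known dominance ratios on a 5-point grid, hand-computed winner
  v2 <- cbind(c(1, 2, 3, 2, 1), c(2, 1, 2, 0.5, 2))
  ratio <- abs(v2[, 1]) / abs(v2[, 2])
  expect_equal(selectIsolatedWavelength(mkSvd(v2, wl), component = 1,
                                        retain = 2), wl[which.max(ratio)])

  vz <- cbind(rep(0, 5), c(1, 2, 3, 2, 1))
  expect_error(selectIsolatedWavelength(mkSvd(vz, wl), component = 1,
                                        retain = 2), "degenerate")
})

test_that("chain fitting recovers planted rates from a progress curve", {
  sp <- defaultSpeciesSpectra()
  eps320 <- sp$epsilon[match(320, sp$wavelengths), ]
  tt <- logTimes(2e-3, 3, 100)
  m <- drUoxLikeModel()
  trace <- as.vector((simulateChain(m, tt) * 1e-6) %*% eps320)

  # noiseless: final-step rate recovered to within 0.01
  fit <- fitChainModel(tt, trace, eps320)
  expect_equal(unname(fit$rates["k3"]), 4.11, tolerance = 0.01 / 4.11)
  expect_true(fit$identifiable)

  # a constant trace at the initial-composition absorbance is explained by
  # a vanishing entry rate (the downstream rates are then unconstrained and
  # the fit flags the flat RSS directions)
  flatTrace <- rep(25 * 1e-6 * eps320[["UA"]], length(tt))
  fit0 <- fitChainModel(tt, flatTrace, eps320, nStarts = 4L)
  expect_lt(fit0$rss, 1e-16)
  expect_lt(fit0$rates[["k1"]], 1e-3)
  expect_false(fit0$identifiable)

  expect_error(fitChainModel(c(1, 1, 2), trace[1:3], eps320), "increasing")
})

test_that("final-step rate is recovered within 5% under 1% noise", {
  sp <- defaultSpeciesSpectra()
  eps320 <- sp$epsilon[match(320, sp$wavelengths), ]
  tt <- logTimes(2e-3, 3, 80)
  m <- drUoxLikeModel()
  clean <- as.vector((simulateChain(m, tt) * 1e-6) %*% eps320)
  amp <- max(abs(clean))
  relErr <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(length(clean), 0, 0.01 * amp)
    fit <- fitChainModel(tt, noisy, eps320, nStarts = 4L)
    abs(fit$rates["k3"] - 4.11) / 4.11
  }, numeric(1))
  expect_lt(median(relErr), 0.05)
})

test_that("reversible and irreversible fits agree on an irreversible truth", {
  sp <- defaultSpeciesSpectra()
  eps320 <- sp$epsilon[match(320, sp$wavelengths), ]
  tt <- logTimes(2e-3, 3, 60)
  clean <- as.vector((simulateChain(drUoxLikeModel(), tt) * 1e-6) %*% eps320)
  firr <- fitChainModel(tt, clean, eps320, reversible = FALSE,
                        nStarts = 4L)
  frev <- fitChainModel(tt, clean, eps320, reversible = TRUE)
  expect_equal(unname(frev$rates["k3"]), unname(firr$rates["k3"]),
               tolerance = 0.02)
})

test_that("Michaelis-Menten fitting is exact on clean data and matches a grid oracle", {
  S <- rep(c(2, 5, 10, 20, 40, 80, 140), each = 3)
  v <- 0.03 * 4.1 * S / (12.5 + S)
  fit <- fitMichaelisMenten(S, v, enzymeConc = 4.1)
  expect_equal(fit$Km, 12.5, tolerance = 1e-8)
  expect_equal(fit$kcat, 0.03, tolerance = 1e-8)
  # law identity: v at S = Km equals Vmax / 2
  expect_equal(fit$Vmax * fit$Km / (fit$Km + fit$Km), fit$Vmax / 2)

  set.seed(31)
  for (i in 1:20) {
    Km <- runif(1, 3, 60)
    Vmax <- runif(1, 0.05, 5)
    S0 <- c(2, 5, 10, 20, 40, 80, 140)
    v0 <- Vmax * S0 / (Km + S0)
    f <- fitMichaelisMenten(S0, v0, enzymeConc = 1)
    g <- gridMM(S0, v0, KmGrid = seq(0.5 * Km, 1.5 * Km, length.out = 201),
                VmaxGrid = seq(0.8 * Vmax, 1.2 * Vmax, length.out = 201))
    expect_equal(f$Km, unname(g["Km"]), tolerance = 0.01)
    expect_equal(f$Vmax, unname(g["Vmax"]), tolerance = 0.01)
  }

  expect_error(fitMichaelisMenten(rep(10, 5), rep(1, 5), 1), "equal")
  expect_error(fitMichaelisMenten(c(1, 2, 3, 1, 2, 3), rep(1, 6), 1),
               "distinct")
})

test_that("Michaelis-Menten estimates are unbiased with calibrated intervals", {
  Km <- 12.5
  kcat <- 0.03
  E <- 4.1
  hits <- 0L
  est <- numeric(50)
  for (s in 1:50) {
    d <- genMMDataset(Km, kcat, E, cv = 0.02, replicates = 3, seed = s)
    f <- fitMichaelisMenten(d$data$S, d$data$v, E)
    est[s] <- f$Km
    ci <- f$Km + c(-1.96, 1.96) * f$se["Km"]
    if (Km >= ci[1] && Km <= ci[2]) hits <- hits + 1L
  }
  expect_lt(abs(mean(est) - Km) / Km, 0.03)
  expect_gte(hits / 50, 0.9)
})

test_that("FOX standard curve inverts exactly and clips negatives", {
  std <- genFoxStandards(slope = 0.005, intercept = 0.04, sigma = 0)
  curve <- foxStandardCurve(std$conc, std$a595)
  expect_equal(curve$slope, 0.005, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.04, tolerance = 1e-12)
  expect_equal(curve$r, 1, tolerance = 1e-9)

  # absorbance equal to the intercept reads zero concentration
  expect_equal(as.numeric(quantifyH2O2(curve, 0.04)), 0)

  # round trip: quantify(synthesize(c)) = c
  cc <- c(3.7, 18.2, 64.9)
  a <- 0.04 + 0.005 * cc
  expect_equal(as.numeric(quantifyH2O2(curve, a)), cc, tolerance = 1e-10)

  # clipping flag below the blank
  q <- quantifyH2O2(curve, 0.01)
  expect_equal(unname(q[1]), 0)
  expect_true(attr(q, "clipped")[1])

  flat <- foxStandardCurve(c(10, 25, 50, 100), rep(0.2, 4))
  expect_error(quantifyH2O2(flat, 0.3), "slope")
  expect_error(foxStandardCurve(c(10, 10), c(0.1, 0.2)), "distinct")
})

test_that("spectra CSV round-trips through the documented layout", {
  sf <- genStoppedFlowDataset(seed = 5, times = logTimes(1e-3, 1, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(sf$spectra, path)
  back <- readSpectraCSV(path)
  expect_equal(back@times, sf$spectra@times)
  expect_equal(back@wavelengths, sf$spectra@wavelengths)
  expect_equal(back@absorbance, sf$spectra@absorbance, tolerance = 1e-12)
})
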