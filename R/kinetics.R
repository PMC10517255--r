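# Rate matrix A of the linear system dc/dt = A c for the chain
# UA = UA2- = PIU = HIU.
rateMatrix <- function(model) {
  kf <- model@kf
  kr <- model@kr
  matrix(c(
    -kf[1],            kr[1],                  0,                0,
     kf[1], -(kr[1] + kf[2]),              kr[2],                0,
         0,            kf[2],   -(kr[2] + kf[3]),            kr[3],
         0,                0,              kf[3],           -kr[3]),
    4L, 4L, byrow = TRUE, dimnames = list(SPECIES_NAMES, SPECIES_NAMES))
}

#' Simulate the uricase reaction chain
#'
#' Concentration profiles of UA, UA2-, PIU and HIU over time for a
#' [KineticModel-class]. The linear first-order system is solved in closed
#' form through the eigendecomposition of the 4 x 4 rate matrix; when the
#' eigensystem is degenerate (repeated eigenvalues or an ill-conditioned
#' eigenvector matrix) a stiff high-accuracy integrator
#' ([deSolve::lsoda()], tolerances 1e-12) is used instead. Total
#' concentration is conserved at every time point.
#'
#' @param model A [KineticModel-class].
#' @param times Non-negative time vector (s).
#' @return Numeric matrix, length(times) x 4, columns UA, UA2, PIU, HIU
#'   (uM).
#' @export
simulateChain <- function(model, times) {
  stopifnot(is(model, "KineticModel"))
  if (any(times < 0)) stop("negative time")
  A <- rateMatrix(model)
  sol <- tryCatch({
    eg <- eigen(A)
    if (max(abs(Im(eg$values))) > 1e-8 * max(abs(eg$values), 1))
      stop("complex eigenvalues")
    lam <- Re(eg$values)
    V <- Re(eg$vectors)
    gaps <- abs(outer(lam, lam, "-"))
    diag(gaps) <- Inf
    if (min(gaps) < 1e-8 * max(abs(lam), 1) ||
        rcond(V) < 1e-10)
      stop("degenerate eigensystem")
    w <- solve(V, model@conc0)
    E <- exp(outer(times, lam))        # |times| x 4
    t(V %*% (t(E) * w))
  }, error = function(e) NULL)
  if (is.null(sol)) {
    deriv <- function(t, y, parms) list(as.vector(A %*% y))
    tt <- sort(unique(c(0, times)))
    o <- lsoda(model@conc0, tt, deriv, NULL, rtol = 1e-12, atol = 1e-12)
    sol <- o[match(times, tt), -1, drop = FALSE]
  }
  sol <- as.matrix(sol)
  dimnames(sol) <- list(NULL, SPECIES_NAMES)
  sol
}

#' Cumulative hydrogen peroxide production
#'
#' H2O2 is released stoichiometrically at the PIU -> HIU step and is not
#' consumed by the reverse (HIU reduction) step, so its cumulative
#' concentration is the integral of `k3 * [PIU]`. Computed by augmenting the
#' chain with a production state and integrating with tight tolerances.
#'
#' @param model A [KineticModel-class].
#' @param times Non-negative time vector (s).
#' @param stoichiometry Molecules of H2O2 released per PIU -> HIU event;
#'   default 1.
#' @return Numeric vector of cumulative H2O2 (uM) at `times`.
#' @export
h2o2Produced <- function(model, times, stoichiometry = 1) {
  stopifnot(is(model, "KineticModel"))
  if (any(times < 0)) stop("negative time")
  A <- rateMatrix(model)
  k3 <- model@kf[3]
  deriv <- function(t, y, parms) {
    c4 <- y[1:4]
    list(c(as.vector(A %*% c4), stoichiometry * k3 * c4[3]))
  }
  tt <- sort(unique(c(0, times)))
  o <- lsoda(c(model@conc0, h2o2 = 0), tt, deriv, NULL,
             rtol = 1e-10, atol = 1e-10)
  unname(o[match(times, tt), "h2o2"])
}

#' Species molar absorptivity spectra
#'
#' Bundles a wavelength grid with molar absorptivities (1/M/cm) for the four
#' chain species and the optical path length. `defaultSpeciesSpectra()`
#' builds the synthetic default used throughout: Gaussian bands placed at
#' the literature landmarks of the uricase reaction -- urate peaking at
#' 292 nm with eps = 12650 1/M/cm, HIU near 301 nm, the urate dianion
#' slightly red-shifted from urate, and PIU shaped so that the PIU - HIU
#' difference spectrum has its negative extremum at 294 nm and positive
#' extremum at 314 nm. These are engineered landmark positions, not measured
#' curves.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param epsilon Named list of numeric vectors (UA, UA2, PIU, HIU), each on
#'   `wavelengths`, in 1/M/cm.
#' @param path Path length (cm); default 1.
#' @return A list of class `SpeciesSpectra`.
#' @export
speciesSpectra <- function(wavelengths, epsilon, path = 1) {
  stopifnot(identical(sort(names(epsilon)), sort(SPECIES_NAMES)))
  epsilon <- epsilon[SPECIES_NAMES]
  if (any(vapply(epsilon, length, 1L) != length(wavelengths)))
    stop("epsilon grids must match the wavelength grid")
  if (any(unlist(epsilon) < 0)) stop("molar absorptivity must be >= 0")
  structure(list(wavelengths = wavelengths,
                 epsilon = do.call(cbind, epsilon), path = path),
            class = "SpeciesSpectra")
}

#' @rdname speciesSpectra
#' @export
defaultSpeciesSpectra <- function(wavelengths = seq(250, 360, by = 2),
                                  path = 1) {
  gauss <- function(center, height, width)
    height * exp(-(wavelengths - center)^2 / (2 * width^2))
  hiu <- gauss(301, 11500, 11)
  # PIU = HIU + engineered difference with extrema at 294 nm (-) / 314 nm (+)
  d <- gauss(314, 6000, 8) - gauss(294, 4000, 8)
  speciesSpectra(
    wavelengths,
    list(UA = gauss(292, 12650, 14),
         UA2 = gauss(295, 11800, 15),
         PIU = pmax(hiu + d, 0),
         HIU = hiu),
    path = path)
}

#' Beer-Lambert forward model for time-resolved spectra
#'
#' `A(t, lambda) = sum_s eps_s(lambda) * c_s(t) * path`, with concentrations
#' in uM (absorptivities are scaled by 1e-6 accordingly). Optional additive
#' Gaussian noise.
#'
#' @param profiles Concentration matrix from [simulateChain()] (uM).
#' @param times Time vector matching `profiles` rows (s), strictly
#'   increasing.
#' @param spectra A [speciesSpectra()] bundle.
#' @param sigma Additive Gaussian noise s.d. (AU); 0 for noiseless.
#' @param seed Optional RNG seed for the noise.
#' @return A [SpectraMatrix-class].
#' @export
synthesizeSpectra <- function(profiles, times, spectra, sigma = 0,
                              seed = NULL) {
  stopifnot(inherits(spectra, "SpeciesSpectra"))
  if (nrow(profiles) != length(times))
    stop("profiles rows must match times")
  if (!identical(colnames(profiles), SPECIES_NAMES))
    stop("profiles must have columns UA, UA2, PIU, HIU")
  if (sigma < 0) stop("noise sigma must be >= 0")
  A <- (profiles * 1e-6) %*% t(spectra$epsilon) * spectra$path
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    A <- A + matrix(rnorm(length(A), 0, sigma), nrow(A))
  }
  new("SpectraMatrix", times = as.numeric(times),
      wavelengths = spectra$wavelengths, absorbance = unname(A),
      sigma = sigma)
}

#' SVD component analysis of time-resolved spectra
#'
#' Singular value decomposition of the absorbance matrix, optionally after
#' subtracting the final spectrum from every row (which isolates the
#' time-evolving difference components; the raw matrix is the default).
#' Components are ordered by singular value and the sign of each component
#' is fixed so that the spectral vector's largest-magnitude entry is
#' positive (with the temporal vector flipped accordingly).
#'
#' @param x A [SpectraMatrix-class].
#' @param center `FALSE` (raw matrix, default) or `TRUE` (subtract the last
#'   spectrum).
#' @return A list of class `SVDResult` with `d` (singular values), `u`
#'   (temporal vectors), `v` (spectral vectors), `explained`
#'   (per-component variance fraction), `times`, `wavelengths`, `center`.
#' @export
svdComponents <- function(x, center = FALSE) {
  stopifnot(is(x, "SpectraMatrix"))
  M <- x@absorbance
  if (anyNA(M)) stop("absorbance matrix contains NA")
  if (!all(is.finite(M))) stop("absorbance matrix must be finite")
  if (isTRUE(center))
    M <- sweep(M, 2L, M[nrow(M), ], "-")
  s <- svd(M)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  structure(list(d = s$d, u = s$u, v = s$v,
                 explained = s$d^2 / sum(s$d^2),
                 times = x@times, wavelengths = x@wavelengths,
                 center = isTRUE(center)),
            class = "SVDResult")
}

#' @export
print.SVDResult <- function(x, ...) {
  cat("SVDResult (", if (x$center) "final-spectrum subtracted" else "raw",
      "): ", length(x$d), " components; top-3 explained variance ",
      paste(signif(head(x$explained, 3), 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of SVD components to retain
#'
#' Default retention rule: the smaller of `kMax` and the number of leading
#' components needed to explain `varTarget` of the variance.
#'
#' @param svd An `SVDResult`.
#' @param kMax Maximum components; default 3.
#' @param varTarget Cumulative explained-variance target; default 0.999.
#' @return Integer count.
#' @export
retainedComponents <- function(svd, kMax = 3L, varTarget = 0.999) {
  k <- which(cumsum(svd$explained) >= varTarget)[1]
  if (is.na(k)) k <- length(svd$d)
  min(kMax, k)
}

#' Wavelength where one SVD component dominates
#'
#' Returns the wavelength maximizing the ratio of the chosen component's
#' absolute spectral loading to the summed absolute loadings of all other
#' retained components -- the "isolated" wavelength at which single-
#' wavelength kinetics report on that component alone. With a single
#' retained component, the wavelength of its maximal |loading| is returned.
#' Where all other loadings vanish the ratio is infinite; among such
#' wavelengths the one with the largest |loading| of the chosen component
#' wins.
#'
#' @param svd An `SVDResult`.
#' @param component Index of the component to isolate; default 1.
#' @param retain Number of retained components;
#'   default [retainedComponents()].
#' @return Wavelength (nm).
#' @export
selectIsolatedWavelength <- function(svd, component = 1L,
                                     retain = retainedComponents(svd)) {
  stopifnot(inherits(svd, "SVDResult"))
  retain <- max(retain, component)
  V <- abs(svd$v[, seq_len(retain), drop = FALSE])
  if (all(V[, component] < .Machine$double.eps))
    stop("degenerate component: all-zero spectral loadings")
  if (retain == 1L)
    return(svd$wavelengths[which.max(V[, 1L])])
  others <- rowSums(V[, -component, drop = FALSE])
  ratio <- V[, component] / others            # Inf allowed where others = 0
  best <- which(ratio == max(ratio))
  if (length(best) > 1L)
    best <- best[which.max(V[best, component])]
  svd$wavelengths[best]
}

# Model absorbance trace at one wavelength for a parameter vector.
chainTraceModel <- function(k, times, conc0, epsAtLambda, path,
                            reversible) {
  m <- if (reversible)
    kineticModel(k[1], k[2], k[3], k[4], k[5], k[6], conc0 = conc0)
  else
    kineticModel(k[1], k[2], k[3], conc0 = conc0)
  prof <- simulateChain(m, times)
  as.vector((prof * 1e-6) %*% epsAtLambda) * path
}

#' Fit the three-step chain to a single-wavelength trace
#'
#' Nonlinear least squares of an absorbance progress curve at one (isolated)
#' wavelength to the sequential chain model. Free parameters are the forward
#' rates k1, k2, k3 and, for the reversible variant, the reverse rates km1,
#' km2, km3; all constrained >= 0. The fit is multistarted from 8 log-spaced
#' rate seeds (spanning 0.05-500 1/s, with a fixed per-rate stagger) and the
#' best residual sum of squares wins. A near-singular curvature matrix
#' (flat RSS in some direction) sets the `identifiable` flag to `FALSE`.
#'
#' @param times Strictly increasing time vector (s).
#' @param trace Absorbance trace (AU) at the isolated wavelength.
#' @param epsAtLambda Named numeric length-4: per-species molar absorptivity
#'   at that wavelength (1/M/cm), order UA, UA2, PIU, HIU.
#' @param conc0 Initial concentrations (uM), order UA, UA2, PIU, HIU;
#'   default 25 uM urate (single-turnover stopped-flow conditions).
#' @param reversible Fit reverse rates too; `FALSE` fixes them at 0.
#' @param path Path length (cm); default 1.
#' @param nStarts Number of multistart seeds; default 8.
#' @return A list of class `ChainFit`: `rates` (named estimates, 1/s), `se`
#'   (approximate standard errors), `rss`, `fitted`, `identifiable`,
#'   `reversible`.
#' @export
fitChainModel <- function(times, trace, epsAtLambda,
                          conc0 = c(UA = 25, UA2 = 0, PIU = 0, HIU = 0),
                          reversible = FALSE, path = 1, nStarts = 8L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(length(trace) == length(times), length(epsAtLambda) == 4L)
  epsAtLambda <- as.numeric(epsAtLambda)
  conc0 <- setNames(as.numeric(conc0), SPECIES_NAMES)
  nPar <- if (reversible) 6L else 3L
  parNames <- if (reversible)
    c("k1", "k2", "k3", "km1", "km2", "km3") else c("k1", "k2", "k3")

  resid <- function(k) {
    chainTraceModel(pmax(k, 0), times, conc0, epsAtLambda, path,
                    reversible) - trace
  }
  # log-spaced multistart: base grid 0.05-500 1/s with a per-rate stagger
  base <- 10^seq(log10(0.05), log10(500), length.out = nStarts)
  best <- NULL
  for (j in seq_len(nStarts)) {
    start <- base[j] * 3^(seq_len(nPar) - 2L)
    fit <- tryCatch(
      nls.lm(par = start, fn = resid, lower = rep(0, nPar),
             control = nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("all multistart fits failed")
  fit <- best$fit
  k <- pmax(fit$par, 0)
  n <- length(trace)
  dof <- max(n - nPar, 1L)
  H <- fit$hessian
  identifiable <- is.finite(rcond(H)) && rcond(H) > 1e-12
  se <- rep(NA_real_, nPar)
  if (identifiable)
    se <- sqrt(pmax(diag(solve(H)), 0) * best$rss / dof)
  structure(list(rates = setNames(k, parNames),
                 se = setNames(se, parNames),
                 rss = best$rss,
                 fitted = chainTraceModel(k, times, conc0, epsAtLambda,
                                          path, reversible),
                 identifiable = identifiable,
                 reversible = reversible),
            class = "ChainFit")
}

#' @export
print.ChainFit <- function(x, ...) {
  cat(if (x$reversible) "Reversible" else "Irreversible",
      "chain fit (1/s):\n")
  print(signif(rbind(estimate = x$rates, se = x$se), 4))
  cat("RSS:", signif(x$rss, 4),
      if (!x$identifiable) " [non-identifiable: flat RSS direction]\n"
      else "\n")
  invisible(x)
}

#' Michaelis-Menten fit of initial rates
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` with non-negativity
#' bounds; `kcat = Vmax / [E]`. Requires at least four distinct substrate
#' concentrations. A fitted `Km` pinned at the lower bound sets the
#' `boundary` flag.
#'
#' @param S Substrate concentrations (uM).
#' @param v Initial rates (uM/s), same length as `S` (replicates allowed as
#'   repeated S values).
#' @param enzymeConc Enzyme concentration (uM) used to convert `Vmax` to
#'   `kcat`.
#' @return A list of class `MMFit`: `Km` (uM), `Vmax` (uM/s), `kcat` (1/s),
#'   `se` (named, for Km/Vmax/kcat), `rss`, `fitted`, `boundary`.
#' @examples
#' S <- c(2, 5, 10, 20, 40, 80, 140)
#' v <- 0.03 * 4.1 * S / (12.5 + S)
#' fitMichaelisMenten(S, v, enzymeConc = 4.1)
#' @export
fitMichaelisMenten <- function(S, v, enzymeConc) {
  stopifnot(length(S) == length(v), enzymeConc > 0)
  if (length(unique(S)) < 2L) stop("all substrate concentrations equal")
  if (length(unique(S)) < 4L)
    stop("need >= 4 distinct substrate concentrations")
  if (any(v < 0)) stop("negative rates")
  resid <- function(p) p[1] * S / (p[2] + S) - v
  start <- c(Vmax = max(v) * 1.2, Km = stats::median(S))
  fit <- nls.lm(par = start, fn = resid,
                lower = c(1e-12, 1e-9),
                control = nls.lm.control(maxiter = 200))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- max(length(v) - 2L, 1L)
  se <- rep(NA_real_, 2L)
  if (rcond(fit$hessian) > 1e-14)
    se <- unname(sqrt(pmax(diag(solve(fit$hessian)), 0) * rss / dof))
  boundary <- p[2] <= 2e-9
  structure(list(Km = unname(p[2]), Vmax = unname(p[1]),
                 kcat = unname(p[1]) / enzymeConc,
                 se = c(Vmax = se[1], Km = se[2],
                        kcat = se[1] / enzymeConc),
                 rss = rss,
                 fitted = unname(p[1]) * S / (unname(p[2]) + S),
                 enzymeConc = enzymeConc,
                 boundary = boundary),
            class = "MMFit")
}

#' @export
print.MMFit <- function(x, ...) {
  cat("Michaelis-Menten fit: Km =", signif(x$Km, 4), "uM, kcat =",
      signif(x$kcat, 4), "1/s (Vmax =", signif(x$Vmax, 4), "uM/s, [E] =",
      x$enzymeConc, "uM)\n")
  if (x$boundary) cat("  [Km at lower bound]\n")
  invisible(x)
}

#' FOX-assay standard curve and inverse prediction
#'
#' `foxStandardCurve()` fits an ordinary least-squares line to H2O2 standard
#' concentrations versus absorbance at 595 nm; `quantifyH2O2()` inverts it,
#' `conc = (A - intercept) / slope`, clipping negative predictions to zero
#' with a flag.
#'
#' @param conc Standard H2O2 concentrations (uM); at least two distinct.
#' @param a595 Absorbances at 595 nm, same length.
#' @return `foxStandardCurve()`: a list of class `FoxCurve` with `slope`
#'   (AU/uM), `intercept` (AU), `r` (correlation coefficient), and the
#'   standards. `quantifyH2O2()`: numeric concentrations (uM) with a logical
#'   attribute `"clipped"`.
#' @export
foxStandardCurve <- function(conc, a595) {
  stopifnot(length(conc) == length(a595))
  if (length(unique(conc)) < 2L)
    stop("need >= 2 distinct standard concentrations")
  fit <- lm(a595 ~ conc)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = if (sd(a595) > 0) stats::cor(conc, a595) else NA_real_,
                 conc = conc, a595 = a595),
            class = "FoxCurve")
}

#' @rdname foxStandardCurve
#' @param curve A `FoxCurve`.
#' @param absorbances A595 values to convert.
#' @export
quantifyH2O2 <- function(curve, absorbances) {
  stopifnot(inherits(curve, "FoxCurve"))
  if (abs(curve$slope) < 1e-12)
    stop("zero slope: curve is not invertible")
  if (curve$slope < 0) stop("positive slope required for quantification")
  out <- (absorbances - curve$intercept) / curve$slope
  clipped <- out < 0
  out[clipped] <- 0
  attr(out, "clipped") <- clipped
  out
}

#' Logarithmically spaced acquisition times
#'
#' Stopped-flow style time grid, log-spaced from `from` (default 1 ms,
#' just above typical instrument dead time) to `to`.
#'
#' @param from,to Positive time range (s).
#' @param n Number of points.
#' @return Strictly increasing numeric vector.
#' @export
logTimes <- function(from = 1e-3, to = 10, n = 200L) {
  stopifnot(from > 0, to > from, n >= 2L)
  exp(seq(log(from), log(to), length.out = n))
}

#' Read/write spectra matrices as CSV
#'
#' CSV layout: first column `time_s`, remaining columns one per wavelength
#' with the wavelength (nm) as header.
#'
#' @param x A [SpectraMatrix-class] (for writing).
#' @param path CSV path.
#' @return `readSpectraCSV()` returns a [SpectraMatrix-class];
#'   `writeSpectraCSV()` returns `path` invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectraMatrix"))
  df <- data.frame(time_s = x@times, x@absorbance, check.names = FALSE)
  colnames(df) <- c("time_s", format(x@wavelengths, trim = TRUE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "time_s")
    stop("first column must be time_s")
  new("SpectraMatrix",
      times = as.numeric(df[[1]]),
      wavelengths = as.numeric(colnames(df)[-1]),
      absorbance = unname(as.matrix(df[, -1, drop = FALSE])),
      sigma = NA_real_)
}
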