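# Seeded synthetic Raman reaction-monitoring data.
#
# Emulates batch monitoring of a sequential first-order hydrogenation
# A -> B -> C (reactant / intermediate / product, e.g. phenylacetylene ->
# styrene -> ethylbenzene): pure spectra are sums of Gaussian/Lorentzian
# peaks on a wavenumber grid, concentrations follow the closed-form
# sequential kinetics, and the observed spectra are Beer-Lambert mixtures
# perturbed — in this fixed order — by extra spectral components, baseline
# drift, per-sample wavelength shift, intensity nonlinearity, and i.i.d.
# Gaussian noise. Noise never touches the concentrations: reference values
# play the role of (trusted) chromatography measurements.

.peakProfile <- function(peak, axis) {
  if (peak$center < axis[1L] || peak$center > axis[length(axis)]) {
    stop("peak center ", peak$center, " lies outside the wavenumber axis")
  }
  if (peak$width <= 0) stop("peak width must be positive")
  if (peak$amplitude < 0) stop("peak amplitude must be non-negative")
  shape <- if (is.null(peak$shape)) "gaussian" else peak$shape
  switch(shape,
    gaussian = peak$amplitude * exp(-0.5 * ((axis - peak$center) / peak$width)^2),
    lorentzian = peak$amplitude * peak$width^2 /
      ((axis - peak$center)^2 + peak$width^2),
    stop("unknown peak shape: ", shape)
  )
}

#' Evaluate pure-component spectra from peak lists
#'
#' @param peaks list with one element per component; each element is a list
#'   of peaks `list(center=, width=, amplitude=, shape=)` (shape `"gaussian"`
#'   or `"lorentzian"`, default gaussian). An empty peak list gives a zero
#'   spectrum.
#' @param axis wavenumber grid (1/cm).
#' @return M x P matrix of pure spectra, one row per component.
#' @export
generatePureSpectra <- function(peaks, axis) {
  axis <- as.numeric(axis)
  K <- t(vapply(peaks, function(plist) {
    row <- numeric(length(axis))
    for (pk in plist) row <- row + .peakProfile(pk, axis)
    row
  }, numeric(length(axis))))
  rownames(K) <- names(peaks)
  K
}

#' Sequential first-order kinetic concentration profiles
#'
#' Closed-form A -> B -> C profiles: cA = c0 exp(-k1 t),
#' cB = c0 k1/(k2-k1) (exp(-k1 t) - exp(-k2 t)), cC = c0 - cA - cB. The
#' reactant decreases monotonically, the product increases monotonically, and
#' the intermediate is unimodal; the three sum to c0 at every time (mass
#' conservation).
#'
#' @param c0 initial reactant concentration (> 0).
#' @param k1,k2 rate constants (> 0, k1 != k2; the equal-rate limiting form
#'   is rejected).
#' @param times numeric vector of sampling times.
#' @return length(times) x 3 matrix with columns A, B, C.
#' @examples
#' kineticProfiles(1, 1, 0.5, c(0, 1))
#' @export
kineticProfiles <- function(c0, k1, k2, times) {
  if (c0 <= 0) stop("c0 must be positive")
  if (k1 <= 0 || k2 <= 0) stop("rate constants must be positive")
  if (k1 == k2) stop("k1 and k2 must differ; the equal-rate case is not supported")
  cA <- c0 * exp(-k1 * times)
  cB <- c0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  cC <- c0 - cA - cB
  cbind(A = cA, B = cB, C = cC)
}

#' Construct a synthetic scenario
#'
#' Low-level constructor for [SyntheticScenario]; most users start from
#' [benchmarkScenario()]. All arguments map one-to-one onto the class slots.
#'
#' @param name scenario label.
#' @param axisStart,axisStop,axisStep wavenumber grid (1/cm).
#' @param samplesPerBatch integer vector of per-batch sample counts.
#' @param analyteNames three analyte labels (reactant, intermediate, product).
#' @param peaks list of three peak lists (see [generatePureSpectra()]).
#' @param c0,k1,k2 kinetics (see [kineticProfiles()]).
#' @param batchKineticsSd lognormal sd of per-batch rate jitter.
#' @param batchC0Sd lognormal sd of per-batch initial-charge jitter.
#' @param tMax,timeExponent within-batch sampling grid
#'   `tMax * ((i-1)/(n-1))^timeExponent`.
#' @param interferents list of interferent specs (see
#'   [SyntheticScenario]).
#' @param noiseSd Gaussian spectral noise sd.
#' @param seed default random seed.
#' @return a [SyntheticScenario].
#' @export
syntheticScenario <- function(name, axisStart = 230, axisStop = 3500,
                              axisStep = 2, samplesPerBatch,
                              analyteNames = c("PA", "ST", "EB"),
                              peaks, c0 = 0.46, k1 = 2, k2 = 0.06,
                              batchKineticsSd = 0.05, batchC0Sd = 0.02,
                              tMax = 30,
                              timeExponent = 2.5, interferents = list(),
                              noiseSd = 0, seed = 1L) {
  methods::new("SyntheticScenario",
    name = name, axisStart = axisStart, axisStop = axisStop,
    axisStep = axisStep, samplesPerBatch = as.integer(samplesPerBatch),
    analyteNames = analyteNames, peaks = peaks, c0 = c0, k1 = k1, k2 = k2,
    batchKineticsSd = batchKineticsSd, batchC0Sd = batchC0Sd, tMax = tMax,
    timeExponent = timeExponent, interferents = interferents,
    noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "SyntheticScenario", function(object) {
  P <- length(seq(object@axisStart, object@axisStop, by = object@axisStep))
  cat("SyntheticScenario '", object@name, "': ",
      sum(object@samplesPerBatch), " samples / ",
      length(object@samplesPerBatch), " batches, ", P, " channels\n",
      sep = "")
  cat("  analytes:", paste(object@analyteNames, collapse = ", "),
      "| kinetics c0 =", object@c0, ", k1 =", object@k1, ", k2 =", object@k2,
      "\n")
  if (length(object@interferents)) {
    cat("  interferents:",
        paste(vapply(object@interferents, `[[`, character(1), "kind"),
              collapse = ", "), "\n")
  }
  cat("  noise sd:", object@noiseSd, "| seed:", object@seed, "\n")
  invisible(NULL)
})

# Concentration profile of a spectral interferent over scaled time u in
# [0, 1]; "increasing", "bell" and "oscillating" are deterministic shapes
# (an "oscillating" profile — sp$cycles full periods, default 1.5 — cannot be
# written as a combination of the smooth monotone/unimodal kinetic profiles,
# so it injects genuinely new concentration-space variance), "random" is a
# smoothed seeded random walk (independent across interferents).
.interferentProfile <- function(sp, u) {
  profile <- if (is.null(sp$profile)) "increasing" else sp$profile
  switch(profile,
    increasing = u,
    bell = 4 * u * (1 - u),
    oscillating = {
      cycles <- if (is.null(sp$cycles)) 1.5 else sp$cycles
      0.5 * (1 + sin(2 * pi * cycles * u))
    },
    random = {
      w <- cumsum(stats::rnorm(length(u)))
      w <- w - mean(w)
      as.numeric(stats::filter(w, rep(1 / 5, 5), circular = TRUE))
    },
    stop("unknown interferent profile: ", profile)
  )
}

#' Generate a synthetic Raman dataset from a scenario
#'
#' Deterministic given the scenario and seed: per-batch rate constants are
#' jittered, concentrations follow the sequential kinetics on the uneven time
#' grid, spectra are formed as concentration-weighted sums of the pure
#' spectra, and the configured perturbations are applied in the fixed order
#' spectral components -> baseline drift -> wavelength shift -> intensity
#' nonlinearity -> noise.
#'
#' @param scenario a [SyntheticScenario].
#' @param seed random seed; defaults to the scenario's own.
#' @return a [RamanExperiment] whose colData holds the known analyte
#'   concentrations and batch ids. `metadata()$groundTruth` carries the full
#'   component matrix `C` (analytes plus spectral-interferent columns), the
#'   full pure-spectra matrix `K`, and the sampling times; `metadata()$scenario`
#'   keeps the scenario.
#' @export
generateDataset <- function(scenario, seed = NULL) {
  stopifnot(methods::is(scenario, "SyntheticScenario"))
  methods::validObject(scenario)
  if (is.null(seed)) seed <- scenario@seed
  set.seed(as.integer(seed))

  axis <- seq(scenario@axisStart, scenario@axisStop, by = scenario@axisStep)
  Kan <- generatePureSpectra(stats::setNames(scenario@peaks,
                                             scenario@analyteNames), axis)
  nb <- length(scenario@samplesPerBatch)
  Clist <- vector("list", nb)
  tlist <- vector("list", nb)
  for (b in seq_len(nb)) {
    n <- scenario@samplesPerBatch[b]
    jit <- exp(stats::rnorm(2L, 0, scenario@batchKineticsSd))
    c0b <- scenario@c0 * exp(stats::rnorm(1L, 0, scenario@batchC0Sd))
    tt <- scenario@tMax * ((seq_len(n) - 1L) / (n - 1L))^scenario@timeExponent
    Clist[[b]] <- kineticProfiles(c0b, scenario@k1 * jit[1L],
                                  scenario@k2 * jit[2L], tt)
    tlist[[b]] <- tt
  }
  C <- do.call(rbind, Clist)
  colnames(C) <- scenario@analyteNames
  batch <- rep(seq_len(nb), scenario@samplesPerBatch)
  times <- unlist(tlist)
  u <- times / scenario@tMax
  L <- nrow(C)
  A <- C %*% Kan
  Cfull <- C
  Kfull <- Kan

  # 1. unmodeled spectral components
  for (sp in scenario@interferents) {
    if (sp$kind != "spectral-component" || sp$magnitude == 0) next
    conc <- sp$magnitude * .interferentProfile(sp, u)
    Ki <- generatePureSpectra(list(sp$peaks), axis)
    A <- A + conc %*% Ki
    Cfull <- cbind(Cfull, conc)
    colnames(Cfull)[ncol(Cfull)] <- if (is.null(sp$label)) "interferent"
                                    else sp$label
    Kfull <- rbind(Kfull, Ki)
    rownames(Kfull)[nrow(Kfull)] <- colnames(Cfull)[ncol(Cfull)]
  }
  # 2. baseline drift: per-sample quadratic in normalized wavenumber
  for (sp in scenario@interferents) {
    if (sp$kind != "baseline-drift" || sp$magnitude == 0) next
    uw <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
    basis <- cbind(1, uw, uw^2)
    coefs <- matrix(stats::runif(L * 3L, -1, 1), L, 3L) * sp$magnitude
    A <- A + coefs %*% t(basis)
  }
  # 3. per-sample wavelength shift via sub-channel linear interpolation
  for (sp in scenario@interferents) {
    if (sp$kind != "wavelength-shift" || sp$magnitude == 0) next
    shifts <- stats::rnorm(L, 0, sp$magnitude)
    for (i in seq_len(L)) {
      A[i, ] <- stats::approx(axis, A[i, ], xout = axis + shifts[i],
                              rule = 2)$y
    }
  }
  # 4. intensity nonlinearity (quadratic saturation): x -> x - beta x^2
  for (sp in scenario@interferents) {
    if (sp$kind != "intensity-nonlinearity" || sp$magnitude == 0) next
    A <- A - sp$magnitude * A^2
  }
  # 5. i.i.d. Gaussian spectral noise
  if (scenario@noiseSd > 0) {
    A <- A + matrix(stats::rnorm(length(A), 0, scenario@noiseSd), nrow(A))
  }

  re <- RamanExperiment(A, axis, C, batch = batch,
                        sampleIds = sprintf("b%02d_s%02d", batch,
                                            unlist(lapply(scenario@samplesPerBatch,
                                                          seq_len))))
  S4Vectors::metadata(re)$groundTruth <- list(C = Cfull, K = Kfull,
                                              times = times)
  S4Vectors::metadata(re)$scenario <- scenario
  S4Vectors::metadata(re)$seed <- as.integer(seed)
  re
}

# Peak tables of the three analytes in the registered benchmark scenarios.
# Aromatic reactant/intermediate/product sharing ring modes (strong spectral
# overlap) plus one distinctive band each: alkyne stretch for the reactant,
# vinyl stretch for the intermediate, aliphatic CH for the product.
.benchmarkPeaks <- function() {
  list(
    PA = list(
      list(center = 1000, width = 12, amplitude = 1.0),
      list(center = 1598, width = 14, amplitude = 0.7),
      list(center = 2110, width = 16, amplitude = 1.2),   # C#C stretch
      list(center = 3060, width = 22, amplitude = 0.5)
    ),
    ST = list(
      list(center = 1001, width = 12, amplitude = 0.9),
      list(center = 1602, width = 14, amplitude = 0.8),
      list(center = 1631, width = 12, amplitude = 1.0),   # vinyl C=C
      list(center = 3058, width = 22, amplitude = 0.45)
    ),
    EB = list(
      list(center = 1003, width = 12, amplitude = 0.95),
      list(center = 1606, width = 14, amplitude = 0.55),
      list(center = 2900, width = 30, amplitude = 0.9),   # aliphatic CH
      list(center = 3055, width = 22, amplitude = 0.4)
    )
  )
}

#' Registered benchmark scenarios
#'
#' * `"paperlike"` — 7 batches / 110 samples on the 230-3500 1/cm grid at
#'   2 1/cm (1636 channels); sequential kinetics tuned so the analyte ranges
#'   are about 0-0.46 / 0-0.41 / 0-0.38 and the target correlates moderately
#'   with the other two species; one mild unmodeled spectral interferent on
#'   an oscillating concentration profile, a weak quadratic intensity
#'   nonlinearity, and noise.
#' * `"clean"` — same layout with every perturbation off: spectra are exact
#'   Beer-Lambert mixtures.
#' * `"two_interferents"` — paperlike layout with two independent unmodeled
#'   spectral components and noise (no drift/shift/nonlinearity), the setting
#'   for studying the RMSECV-curve elbow.
#' * `"demo"` — a small fast variant (600-1700 1/cm at 10 1/cm, 3 batches /
#'   36 samples) for examples and quick checks.
#'
#' @param name scenario name.
#' @param seed random seed stored in the scenario (default 1).
#' @return a [SyntheticScenario].
#' @export
benchmarkScenario <- function(name = c("paperlike", "clean",
                                       "two_interferents", "demo"),
                              seed = 1L) {
  name <- match.arg(name)
  peaks <- .benchmarkPeaks()
  base <- function(...) {
    syntheticScenario(
      name = name, samplesPerBatch = c(16L, 16L, 16L, 16L, 16L, 15L, 15L),
      peaks = peaks, c0 = 0.46, k1 = 1.6, k2 = 0.055,
      batchKineticsSd = 0.08, tMax = 32, timeExponent = 2.2, seed = seed,
      ...)
  }
  switch(name,
    paperlike = base(
      interferents = list(
        list(kind = "spectral-component", magnitude = 0.05,
             profile = "oscillating", label = "interferent1",
             peaks = list(list(center = 520, width = 40, amplitude = 1.0),
                          list(center = 1450, width = 35, amplitude = 0.8),
                          list(center = 2550, width = 60, amplitude = 0.6))),
        list(kind = "intensity-nonlinearity", magnitude = 0.003)
      ),
      noiseSd = 0.002),
    clean = base(interferents = list(), noiseSd = 0),
    two_interferents = base(
      interferents = list(
        list(kind = "spectral-component", magnitude = 0.6,
             profile = "oscillating", cycles = 1, label = "interferent1",
             peaks = list(list(center = 520, width = 40, amplitude = 1.0),
                          list(center = 1450, width = 35, amplitude = 0.8),
                          list(center = 1590, width = 30, amplitude = 0.5))),
        list(kind = "spectral-component", magnitude = 0.6,
             profile = "oscillating", cycles = 2.5, label = "interferent2",
             peaks = list(list(center = 750, width = 45, amplitude = 0.9),
                          list(center = 2080, width = 45, amplitude = 1.0),
                          list(center = 2550, width = 60, amplitude = 0.7)))
      ),
      noiseSd = 0.002),
    demo = syntheticScenario(
      name = "demo", axisStart = 600, axisStop = 1700, axisStep = 10,
      samplesPerBatch = c(12L, 12L, 12L),
      peaks = lapply(peaks, function(pl) {
        Filter(function(pk) pk$center >= 600 && pk$center <= 1700, pl)
      }),
      c0 = 0.46, k1 = 1.6, k2 = 0.055, batchKineticsSd = 0.08, tMax = 32,
      timeExponent = 2.2, seed = seed,
      interferents = list(
        list(kind = "spectral-component", magnitude = 0.25,
             profile = "increasing", label = "interferent1",
             peaks = list(list(center = 800, width = 40, amplitude = 1.0),
                          list(center = 1450, width = 35, amplitude = 0.8)))
      ),
      noiseSd = 0.002)
  )
}
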