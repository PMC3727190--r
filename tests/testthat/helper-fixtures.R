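# Shared fixtures: small exact mixture problems and a fast synthetic
# experiment, all seeded.

# Random full-column-rank CLS problem A = C K (exact, no noise).
randomCLSProblem <- function(L = 20L, M = 3L, P = 30L) {
  C <- matrix(runif(L * M, 0.1, 1), L, M,
              dimnames = list(NULL, paste0("c", seq_len(M))))
  K <- matrix(rnorm(M * P), M, P)
  list(C = C, K = K, A = C %*% K)
}

# Wrap matrices in a RamanExperiment on an arbitrary increasing axis.
toyExperiment <- function(A, C, wavenumber = NULL) {
  if (is.null(wavenumber)) wavenumber <- seq(100, by = 10, length.out = ncol(A))
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  RamanExperiment(A, wavenumber, C)
}

# Small exact three-component mixture experiment with smooth positive pure
# spectra; optional extra unmodeled component and noise.
toyMixture <- function(L = 24L, P = 40L, seed = 7L, interferent = FALSE,
                       noiseSd = 0) {
  set.seed(seed)
  axis <- seq(200, by = 10, length.out = P)
  peak <- function(center, width, amp) amp * exp(-0.5 * ((axis - center) / width)^2)
  K <- rbind(peak(400, 40, 1.0) + peak(700, 30, 0.5),
             peak(420, 40, 0.8) + peak(520, 35, 0.9),
             peak(360, 50, 0.6) + peak(560, 25, 1.0))
  tt <- seq(0, 3, length.out = L)
  C <- kineticProfiles(1, 1.8, 0.4, tt)
  C <- C * exp(matrix(rnorm(length(C), 0, 0.03), nrow(C)))  # break collinearity
  colnames(C) <- c("A", "B", "C")
  A <- C %*% K
  extra <- NULL
  if (interferent) {
    u <- 0.5 * (1 + sin(2 * pi * 1.5 * tt / max(tt)))
    extra <- list(conc = 0.4 * u, spectrum = peak(470, 30, 1.0) + peak(640, 45, 0.8))
    A <- A + extra$conc %*% t(extra$spectrum)
  }
  if (noiseSd > 0) A <- A + matrix(rnorm(length(A), 0, noiseSd), L)
  list(re = RamanExperiment(A, axis, C), A = A, C = C, K = K,
       axis = axis, extra = extra)
}
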