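# Transform-based least-squares phase unwrapping (deterministic and
# path-independent): wrapped phase gradients are integrated by solving a
# discrete Poisson equation with Neumann boundaries via the DCT.

wrap_to_pi <- function(x) (x + pi) %% (2 * pi) - pi

# DCT-II along the first dimension of a matrix, via FFT of the even
# extension; unnormalised: C[k] = sum_j x[j] cos(pi k (2j+1) / (2m))
dct1 <- function(X) {
  m <- nrow(X)
  y <- rbind(X, X[m:1, , drop = FALSE])
  Y <- stats::mvfft(y)
  w <- exp(-1i * pi * (0:(m - 1)) / (2 * m))
  Re(Y[1:m, , drop = FALSE] * w) / 2
}

# inverse of dct1 (unnormalised DCT-II -> samples)
idct1 <- function(C) {
  m <- nrow(C)
  w <- exp(1i * pi * (0:(m - 1)) / (2 * m))
  Y <- matrix(0 + 0i, 2 * m, ncol(C))
  Y[1:m, ] <- 2 * C * w
  if (m > 1) Y[(m + 2):(2 * m), ] <- Conj(Y[m:2, , drop = FALSE])
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / (2 * m)
  y[1:m, , drop = FALSE]
}

dct2d <- function(X) t(dct1(t(dct1(X))))
idct2d <- function(X) t(idct1(t(idct1(X))))

#' Least-squares 2-D phase unwrapping
#'
#' Ghiglia-Romero weighted-free least-squares unwrapping: the wrapped phase
#' differences are integrated globally by solving the discrete Poisson
#' equation with Neumann boundary conditions through a cosine transform.
#' Deterministic and path-independent; exact (up to an additive constant)
#' for noiseless phase maps whose true gradients are below pi per pixel.
#'
#' @param phase Matrix of wrapped phases (radians).
#' @return Matrix of unwrapped phases.
#' @export
unwrap_phase <- function(phase) {
  m <- nrow(phase); n <- ncol(phase)
  dx <- wrap_to_pi(phase[-1, , drop = FALSE] - phase[-m, , drop = FALSE])
  dy <- wrap_to_pi(phase[, -1, drop = FALSE] - phase[, -n, drop = FALSE])
  rho <- matrix(0, m, n)
  rho[1:(m - 1), ] <- rho[1:(m - 1), ] + dx
  rho[2:m, ] <- rho[2:m, ] - dx
  rho[, 1:(n - 1)] <- rho[, 1:(n - 1)] + dy
  rho[, 2:n] <- rho[, 2:n] - dy
  R <- dct2d(rho)
  denom <- outer(2 * cos(pi * (0:(m - 1)) / m),
                 2 * cos(pi * (0:(n - 1)) / n), "+") - 4
  denom[1, 1] <- 1
  Phi <- R / denom
  Phi[1, 1] <- 0
  out <- idct2d(Phi)
  # restore the absolute offset lost by the Poisson solve ...
  out <- out + stats::median(wrap_to_pi(phase - out))
  # ... and anchor the 2*pi multiple so the first pixel (assumed close to
  # background) keeps its wrapped value
  out - 2 * pi * round((out[1, 1] - phase[1, 1]) / (2 * pi))
}
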