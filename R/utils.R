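# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulators are deterministic without clobbering
#' the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Wrap angles into [0, 2*pi).
wrap_angle <- function(theta) {
  theta <- theta %% (2 * pi)
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  theta
}

# Circular majority filter over a logical/ integer label vector.
# window must be odd; ties keep the original label.
circular_majority <- function(labels, window) {
  n <- length(labels)
  if (window <= 1L || n == 0L) return(labels)
  half <- (window - 1L) %/% 2L
  idx <- seq_len(n)
  votes <- matrix(0L, nrow = n, ncol = 2L)
  for (k in seq(-half, half)) {
    shifted <- labels[((idx - 1L + k) %% n) + 1L]
    votes[, 1L] <- votes[, 1L] + (shifted == 0L)
    votes[, 2L] <- votes[, 2L] + (shifted == 1L)
  }
  res <- labels
  res[votes[, 2L] > votes[, 1L]] <- 1L
  res[votes[, 2L] < votes[, 1L]] <- 0L
  res
}

# Sample a 2-D image (matrix, row = y, col = x, 0-based pixel-centre
# coordinates) at arbitrary points. Coordinates are clamped to the image.
# method "bilinear" or "cubic" (Catmull-Rom, separable).
sample_image <- function(m, x, y, method = c("bilinear", "cubic")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  if (method == "bilinear") {
    x0 <- floor(x); y0 <- floor(y)
    x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
    fx <- x - x0; fy <- y - y0
    i00 <- cbind(y0 + 1, x0 + 1)
    v00 <- m[i00]
    v01 <- m[cbind(y0 + 1, x0 + 2)]
    v10 <- m[cbind(y0 + 2, x0 + 1)]
    v11 <- m[cbind(y0 + 2, x0 + 2)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  } else {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    wx <- catmull_rom_weights(fx)
    wy <- catmull_rom_weights(fy)
    out <- numeric(length(x))
    for (j in 1:4) {
      yy <- pmin(pmax(y0 + (j - 2), 0), h - 1)
      row_acc <- numeric(length(x))
      for (i in 1:4) {
        xx <- pmin(pmax(x0 + (i - 2), 0), w - 1)
        row_acc <- row_acc + wx[, i] * m[cbind(yy + 1, xx + 1)]
      }
      out <- out + wy[, j] * row_acc
    }
    out
  }
}

# Catmull-Rom weights for fractional offsets t in [0,1); returns n x 4 matrix
# for samples at offsets -1, 0, 1, 2.
catmull_rom_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind(
    -0.5 * t3 + t2 - 0.5 * t,
    1.5 * t3 - 2.5 * t2 + 1,
    -1.5 * t3 + 2 * t2 + 0.5 * t,
    0.5 * t3 - 0.5 * t2
  )
}

# Banded Toeplitz Gaussian blur operator for one dimension (rows re-normalised
# at the borders). Used as K %*% X %*% t(K) for a separable 2-D blur.
gaussian_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kern[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

# Separable Gaussian blur of a matrix.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Ky <- gaussian_blur_matrix(nrow(m), sigma)
  Kx <- gaussian_blur_matrix(ncol(m), sigma)
  Ky %*% m %*% t(Kx)
}

stopf <- function(fmt, ..., class = "guvquant_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
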