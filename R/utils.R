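#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi  # boundary maps to +pi
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Derive a child seed from a root seed
#'
#' All stochastic operations in the package draw from generators seeded with
#' deterministic children of a single root seed, so that whole analyses are
#' reproducible from one integer. The derivation is a small string hash of the
#' root seed and a textual tag, kept below 2^31.
#'
#' @param seed integer root seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(paste0("#", tag))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# run code under a seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 is uniform
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
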