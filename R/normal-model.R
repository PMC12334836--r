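# Canonical joint normal model for the sequential z statistics, and the
# numerical kernels (Gauss-Legendre quadrature, vectorized monotone root
# finding) every interval method is built on.

#' Canonical two-stage normal model
#'
#' Bundles the observed Fisher information at the interim and final analyses
#' with the standardized efficacy boundaries.  Under the canonical joint
#' distribution the z statistics satisfy \eqn{Z_k \sim N(\theta\sqrt{I_k}, 1)}
#' with \eqn{Cov(Z_1, Z_2) = \sqrt{I_1/I_2}}; all interval procedures in the
#' package operate on this model with the observed information treated as
#' fixed.
#'
#' @param info1,info2 Fisher information (inverse variance of the effect
#'   estimate) at the interim and final analysis.  `info2` may be `NA` for a
#'   trial stopped at stage 1.
#' @param e1,e2 standardized efficacy boundaries.
#' @return An object of class `gs_model`: a list with elements `info1`,
#'   `info2`, `e1`, `e2`, `rho` (the between-stage correlation) and a
#'   `degenerate` flag which is `TRUE` when the information decreased between
#'   the analyses (`info2 < info1`), in which case the bivariate-normal based
#'   procedures are unavailable.
#' @export
canonical_model <- function(info1, info2, e1, e2) {
  stopifnot(is.numeric(info1), info1 > 0)
  degen <- is.finite(info2) && info2 < info1
  rho <- if (is.finite(info2) && !degen) sqrt(info1 / info2) else NA_real_
  structure(
    list(info1 = info1, info2 = info2, e1 = e1, e2 = e2,
         rho = rho, degenerate = degen),
    class = "gs_model"
  )
}

# ---- Gauss-Legendre nodes (Golub-Welsch), cached per node count ----

.gl_env <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_env[[key]])) return(.gl_env[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  .gl_env[[key]] <- out
  out
}

# integral of dnorm(u) * Phi-bar((b - rho u)/s1) over [lo_i, a_i],
# vectorized over problems, for rho > 0.  The inner CDF factor transitions
# from 0 to 1 on the band u in (b -/+ 8.5 s1)/rho; below the band the
# integrand vanishes, above it the factor is 1 to within 1e-17 and the
# contribution is an exact normal-CDF difference.  Composite Gauss-Legendre
# panels resolve the band itself, so the absolute error stays far below
# 1e-9 at any correlation.  The denominator Pr(lo < Z1 < a) is exact.
gl_tail_integral <- function(lo, a, b, rho, den_too = FALSE,
                             nodes = 16L, panels = 6L) {
  m <- length(a)
  g <- gauss_legendre(nodes)
  s1 <- sqrt(1 - rho^2)
  c_lo <- pmin(pmax((b - 8.5 * s1) / rho, lo), a)
  c_hi <- pmin(pmax((b + 8.5 * s1) / rho, lo), a)
  num <- pnorm(a) - pnorm(c_hi)     # region where the CDF factor is ~1
  edges <- seq(0, 1, length.out = panels + 1L)
  for (p in seq_len(panels)) {
    p_lo <- c_lo + (c_hi - c_lo) * edges[p]
    p_hi <- c_lo + (c_hi - c_lo) * edges[p + 1L]
    half <- (p_hi - p_lo) / 2
    u <- outer(g$x, half) + rep((p_lo + p_hi) / 2, each = nodes)
    w <- outer(g$w, half)
    z <- (rep(b, each = nodes) - rep(rho, each = nodes) * u) /
      rep(s1, each = nodes)
    num <- num + colSums(w * dnorm(u) * pnorm(z, lower.tail = FALSE))
  }
  den <- if (den_too) pnorm(a) - pnorm(lo) else numeric(m)
  list(num = num, den = den)
}

# Pr(Z1 < a, Z2 >= b) for standard bivariate normal with correlation rho,
# vectorized over a, b (rho recycled).  a beyond +/-8.3 falls back to the
# exact marginal limits.
pbvn_cont <- function(a, b, rho, chunk = 20000L) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  hi <- a >= 8.3
  out[hi] <- pnorm(b[hi], lower.tail = FALSE)
  lo0 <- a <= -37
  mid <- which(!hi & !lo0)
  for (start in chunk_starts(length(mid), chunk)) {
    idx <- mid[start:min(start + chunk - 1L, length(mid))]
    aa <- a[idx]
    lo <- pmax(pmin(aa, 0) - 13, -38)
    out[idx] <- gl_tail_integral(lo, aa, b[idx], rho[idx])$num
  }
  out
}

# Pr(Z2 >= b | Z1 < a): numerator and denominator share the same quadrature
# nodes so the ratio stays well conditioned even when Pr(Z1 < a) underflows
# towards zero.  For a below -37 the truncated Z1 is concentrated at a and
# the exact conditional limit Phi-bar((b - rho a)/sqrt(1-rho^2)) is used.
pcond_exceed <- function(a, b, rho, chunk = 20000L) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  s1 <- sqrt(1 - rho^2)
  hi <- a >= 8.3
  out[hi] <- pnorm(b[hi], lower.tail = FALSE)
  lo0 <- a <= -37
  out[lo0] <- pnorm((b[lo0] - rho[lo0] * a[lo0]) / s1[lo0], lower.tail = FALSE)
  mid <- which(!hi & !lo0)
  for (start in chunk_starts(length(mid), chunk)) {
    idx <- mid[start:min(start + chunk - 1L, length(mid))]
    aa <- a[idx]
    lo <- pmax(pmin(aa, 0) - 13, -38)
    gi <- gl_tail_integral(lo, aa, b[idx], rho[idx], den_too = TRUE)
    r <- gi$num / gi$den
    deg <- !is.finite(r)
    if (any(deg)) {
      j <- idx[deg]
      r[deg] <- pnorm((b[j] - rho[j] * a[j]) / s1[j], lower.tail = FALSE)
    }
    out[idx] <- r
  }
  pmin(pmax(out, 0), 1)
}

# Vectorized root finder for a family of strictly increasing functions.
# `f(theta, idx)` must return f evaluated at theta (vector over the subset
# idx of problems).  Brackets are expanded by doubling before bisection;
# problems whose root cannot be bracketed come back as NA with failed = TRUE.
vroot_increasing <- function(f, target, lo = -1.5, hi = 1.5,
                             max_double = 6L, iters = 60L) {
  n <- length(target)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  all_idx <- seq_len(n)
  flo <- f(lo, all_idx); fhi <- f(hi, all_idx)
  for (k in seq_len(max_double)) {
    need <- which(flo > target)
    if (length(need)) {
      lo[need] <- lo[need] * 2
      flo[need] <- f(lo[need], need)
    }
    need <- which(fhi < target)
    if (length(need)) {
      hi[need] <- hi[need] * 2
      fhi[need] <- f(hi[need], need)
    }
  }
  failed <- flo > target | fhi < target | !is.finite(flo) | !is.finite(fhi)
  live <- which(!failed)
  for (k in seq_len(iters)) {
    mid <- (lo[live] + hi[live]) / 2
    fm <- f(mid, live)
    up <- fm < target[live]
    lo[live[up]] <- mid[up]
    hi[live[!up]] <- mid[!up]
  }
  root <- (lo + hi) / 2
  root[failed] <- NA_real_
  list(root = root, failed = failed)
}

# scalar convenience wrapper
root1 <- function(f, target, ...) {
  r <- vroot_increasing(function(th, idx) f(th), target, ...)
  if (r$failed) stop("root not bracketed; function values at the expanded ",
                     "bracket do not straddle the target", call. = FALSE)
  r$root
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

chunk_starts <- function(n, chunk) {
  if (n == 0) integer(0) else seq.int(1L, n, by = chunk)
}
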