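# Independent brute-force oracles used to cross-check package primitives.
# These deliberately re-derive results from first principles and never call
# the functions they validate.

# linear-interpolation quantile: h = (n-1)q + 1 on the sorted sample
quantile_oracle <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# simple-regression coefficients from the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# great-circle distance by the haversine formula (radius cancels in argmin)
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * asin(pmin(1, sqrt(a)))
}

# exhaustive nearest-lattice-point scan with lexicographic (lat, lon) tie-break
nearest_oracle <- function(lat, lon, lattice) {
  d <- haversine_oracle(lat, lon, lattice$lat, lattice$lon)
  tied <- which(d <= min(d) + 1e-12)
  tied[order(lattice$lat[tied], lattice$lon[tied])][1]
}

# coefficients with a constant quadratic term A and linear term B
# (independent of SMT), convenient for hand-computed RR values
flat_coeffs <- function(A, B) {
  risk_coefficients(a_s = 0, a_i = A, b_s = 0, b_i = B,
                    provenance = "test fixture")
}
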