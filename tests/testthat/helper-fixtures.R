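# Shared fixtures: small hand-written tracks and the brute-force CTCRW
# likelihood oracle.

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_fixes <- function(timestamp, lat, lon, lc = "LC3", error_radius_m = NA_real_) {
  tibble::tibble(timestamp = utc(timestamp), lat = lat, lon = lon, lc = lc,
                 error_radius_m = error_radius_m)
}

# a stationary animal at (lat0, lon0) with fixes every dt_h hours
stationary_track <- function(n, lat0 = 50, lon0 = -60, dt_h = 2,
                             start = "2015-01-01 00:00:00", id = "a1") {
  track(id, make_fixes(utc(start) + (seq_len(n) - 1) * dt_h * 3600,
                       rep(lat0, n), rep(lon0, n)))
}

territory_hints_for <- function(schedule) {
  tibble::tibble(lat = c(schedule$breeding[["lat"]], schedule$winter[["lat"]]),
                 lon = c(schedule$breeding[["lon"]], schedule$winter[["lon"]]))
}

# Brute-force joint multivariate-normal log-likelihood of the integrated-OU
# observation model, built from the exact transition moments by covariance
# recursion and evaluated with a Cholesky factorization. Independent of the
# sequential Kalman filter it checks.
bruteforce_ctcrw_loglik <- function(times_h, xy, tau_km, beta, sigma) {
  n <- length(times_h)
  tau2 <- rep_len(tau_km, n)^2
  ll <- 0
  for (ax in 1:2) {
    y <- xy[, ax]
    P0 <- diag(c(100^2, sigma^2 / (2 * beta)))
    As <- vector("list", n); Qs <- vector("list", n)
    for (i in 2:n) {
      dt <- times_h[i] - times_h[i - 1]
      phi <- exp(-beta * dt)
      a <- (1 - phi) / beta
      As[[i]] <- matrix(c(1, 0, a, phi), 2, 2)
      qxx <- sigma^2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
      qxv <- sigma^2 * (1 - phi)^2 / (2 * beta^2)
      qvv <- sigma^2 * (1 - phi^2) / (2 * beta)
      Qs[[i]] <- matrix(c(qxx, qxv, qxv, qvv), 2, 2)
    }
    C <- array(0, c(n, n, 2, 2))
    C[1, 1, , ] <- P0
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        C[i, j, , ] <- As[[i]] %*% C[i - 1, j, , ]
        C[j, i, , ] <- t(C[i, j, , ])
      }
      C[i, i, , ] <- As[[i]] %*% C[i - 1, i - 1, , ] %*% t(As[[i]]) + Qs[[i]]
    }
    S <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) S[i, j] <- C[i, j, 1, 1]
    diag(S) <- diag(S) + tau2
    r <- y - rep(y[1], n)
    ch <- chol(S)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  ll
}
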