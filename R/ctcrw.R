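# Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
# velocity) for interpolating movement paths across transmitter duty-cycle
# gaps. The model, per planar axis, is
#
#   dx = v dt,   dv = -beta v dt + sigma dW
#
# observed as x plus location-class measurement noise. The exact discrete-time
# transition over a step of length dt (hours) is
#
#   x' = x + v (1 - phi)/beta + xi,   v' = phi v + zeta,   phi = exp(-beta dt)
#
# with Gaussian innovations whose covariance has the closed form coded in
# iou_step() below. Likelihood is evaluated by a Kalman filter; interpolation
# uses the fixed-interval (RTS) smoother. Units throughout: km, hours.

#' CTCRW parameters
#'
#' @param beta_per_h Velocity autocorrelation decay rate (1/h, > 0). The
#'   velocity autocorrelation at lag tau is exp(-beta * tau).
#' @param sigma Velocity stochasticity scale (km/h per sqrt(h), > 0).
#' @param obs_error_m_by_class Named per-location-class observation SD in
#'   metres. Fixed, not estimated.
#' @return A list of class `flyway_ctcrw_params`.
#' @export
ctcrw_params <- function(beta_per_h = 0.5, sigma = 5,
                         obs_error_m_by_class = c(LC3 = 100, LC2 = 250, LC1 = 700)) {
  stopifnot(beta_per_h > 0, sigma > 0, all(obs_error_m_by_class >= 0))
  structure(list(beta_per_h = beta_per_h, sigma = sigma,
                 obs_error_m_by_class = obs_error_m_by_class),
            class = "flyway_ctcrw_params")
}

# Exact transition quantities for one time step dt (hours).
iou_step <- function(beta, sigma, dt) {
  phi <- exp(-beta * dt)
  a <- (1 - phi) / beta
  s2 <- sigma^2
  list(
    phi = phi, a = a,
    qxx = s2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta)),
    qxv = s2 * (1 - phi)^2 / (2 * beta^2),
    qvv = s2 * (1 - phi^2) / (2 * beta)
  )
}

# Prior on the state at the first observation instant: position centred on the
# first observation with a weak 100-km SD, velocity at its stationary
# distribution N(0, sigma^2 / (2 beta)).
ctcrw_prior <- function(beta, sigma, x0) {
  list(mx = x0, mv = 0, pxx = 100^2, pxv = 0, pvv = sigma^2 / (2 * beta))
}

# Kalman-filter log-likelihood for one axis.
# times_h: observation times (hours, strictly increasing); y: coordinates (km);
# tau2: per-observation measurement variance (km^2).
kalman_loglik_1d <- function(times_h, y, tau2, beta, sigma) {
  n <- length(y)
  pr <- ctcrw_prior(beta, sigma, y[1])
  mx <- pr$mx; mv <- pr$mv; pxx <- pr$pxx; pxv <- pr$pxv; pvv <- pr$pvv
  ll <- 0
  for (i in seq_len(n)) {
    if (i > 1) {
      st <- iou_step(beta, sigma, times_h[i] - times_h[i - 1])
      mx_new <- mx + st$a * mv
      mv_new <- st$phi * mv
      pxx_new <- pxx + 2 * st$a * pxv + st$a^2 * pvv + st$qxx
      pxv_new <- st$phi * (pxv + st$a * pvv) + st$qxv
      pvv_new <- st$phi^2 * pvv + st$qvv
      mx <- mx_new; mv <- mv_new
      pxx <- pxx_new; pxv <- pxv_new; pvv <- pvv_new
    }
    s <- max(pxx + tau2[i], 1e-12)
    r <- y[i] - mx
    ll <- ll - 0.5 * (log(2 * pi * s) + r * r / s)
    k1 <- pxx / s; k2 <- pxv / s
    mx <- mx + k1 * r; mv <- mv + k2 * r
    # update written in its cancellation-free form: P' = P * tau2 / S for the
    # position block, Schur complement (clamped) for the velocity block
    pvv <- max(pvv - k2 * pxv, 0)
    pxv <- pxv * tau2[i] / s
    pxx <- pxx * tau2[i] / s
  }
  ll
}

#' CTCRW log-likelihood of planar observations
#'
#' Sum of the per-axis Kalman-filter log-likelihoods (the two axes are
#' independent given the parameters and share the isotropic error model).
#'
#' @param times_h Observation times in hours (strictly increasing).
#' @param xy Two-column matrix of planar coordinates (km).
#' @param tau_km Per-observation measurement SD (km), recycled if scalar.
#' @param params A [ctcrw_params()].
#' @return Log-likelihood (scalar).
#' @export
ctcrw_loglik <- function(times_h, xy, tau_km, params) {
  stopifnot(nrow(xy) == length(times_h), all(diff(times_h) > 0))
  tau2 <- rep_len(tau_km, length(times_h))^2
  kalman_loglik_1d(times_h, xy[, 1], tau2, params$beta_per_h, params$sigma) +
    kalman_loglik_1d(times_h, xy[, 2], tau2, params$beta_per_h, params$sigma)
}

# Project a track's fixes into the planar working frame: azimuthal-equidistant
# centred on the temporally middle fix. Returns times (h since first fix), xy
# (km), tau (km) and the centre.
track_to_plane <- function(trk, obs_error_m_by_class) {
  fx <- trk$fixes
  if (nrow(fx) < 2) stop("track has fewer than 2 fixes")
  mid <- ceiling(nrow(fx) / 2)
  ctr <- c(lat = fx$lat[mid], lon = fx$lon[mid])
  xy <- aeqd_project(fx$lat, fx$lon, ctr["lat"], ctr["lon"])
  tau_km <- obs_error_m_by_class[as.character(fx$lc)] / 1000
  if (anyNA(tau_km)) {
    stop("no observation-error SD configured for class(es): ",
         paste(setdiff(unique(as.character(fx$lc)), names(obs_error_m_by_class)),
               collapse = ", "))
  }
  t_h <- (as.numeric(fx$timestamp) - as.numeric(fx$timestamp[1])) / 3600
  keep <- c(TRUE, diff(t_h) > 0)
  list(times_h = t_h[keep], xy = xy[keep, , drop = FALSE],
       tau_km = unname(tau_km)[keep], center = ctr,
       t0 = fx$timestamp[1])
}

#' Fit the CTCRW by maximum likelihood
#'
#' Maximises the Kalman-filter likelihood over log(beta), log(sigma) with
#' `optim(method = "L-BFGS-B")` from a fixed documented init; observation
#' error SDs are fixed per location class. Deterministic given the init.
#'
#' @param trk A [track()] with at least 8 fixes.
#' @param init A [ctcrw_params()] giving the starting values and error model.
#' @param lower,upper Bounds for `c(beta_per_h, sigma)` on the natural scale.
#' @return A list with `params` (fitted [ctcrw_params()]), `loglik`, `se`
#'   (delta-method SEs for beta and sigma), `convergence`, and `degenerate`
#'   (TRUE when sigma is pinned at its lower bound).
#' @export
fit_ctcrw <- function(trk, init = ctcrw_params(),
                      lower = c(1e-4, 1e-4), upper = c(1e3, 1e3)) {
  if (nrow(trk$fixes) < 8) {
    stop("CTCRW estimation needs at least 8 fixes; got ", nrow(trk$fixes))
  }
  pl <- track_to_plane(trk, init$obs_error_m_by_class)
  if (diff(range(pl$times_h)) <= 0) stop("track has zero time span")
  nll <- function(par) {
    p <- ctcrw_params(exp(par[1]), exp(par[2]), init$obs_error_m_by_class)
    -ctcrw_loglik(pl$times_h, pl$xy, pl$tau_km, p)
  }
  opt <- stats::optim(log(c(init$beta_per_h, init$sigma)), nll,
                      method = "L-BFGS-B",
                      lower = log(lower), upper = log(upper),
                      control = list(maxit = 200))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop("CTCRW optimizer did not converge (code ", opt$convergence,
         "); last iterate beta = ", exp(opt$par[1]),
         ", sigma = ", exp(opt$par[2]))
  }
  hess <- try(stats::optimHess(opt$par, nll), silent = TRUE)
  se <- c(beta = NA_real_, sigma = NA_real_)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      # delta method from the log scale
      se <- sqrt(diag(vc)) * exp(opt$par)
      names(se) <- c("beta", "sigma")
    }
  }
  fitted <- ctcrw_params(exp(opt$par[1]), exp(opt$par[2]),
                         init$obs_error_m_by_class)
  list(params = fitted, loglik = -opt$value, se = se,
       convergence = opt$convergence,
       degenerate = fitted$sigma <= lower[2] * (1 + 1e-6))
}

# Forward filter + RTS smoother for one axis over an augmented time grid.
# obs_idx marks grid instants carrying an observation. Returns smoothed mean
# and position variance at every grid instant.
kalman_smooth_1d <- function(times_h, y, tau2, obs_idx, beta, sigma) {
  n <- length(times_h)
  # filtered and predicted moments
  fm <- matrix(0, n, 2); fP <- matrix(0, n, 3)  # (pxx, pxv, pvv)
  pm <- matrix(0, n, 2); pP <- matrix(0, n, 3)
  pr <- ctcrw_prior(beta, sigma, y[1])
  m <- c(pr$mx, pr$mv); P <- c(pr$pxx, pr$pxv, pr$pvv)
  yi <- 1
  for (i in seq_len(n)) {
    if (i > 1) {
      st <- iou_step(beta, sigma, times_h[i] - times_h[i - 1])
      m <- c(m[1] + st$a * m[2], st$phi * m[2])
      P <- c(P[1] + 2 * st$a * P[2] + st$a^2 * P[3] + st$qxx,
             st$phi * (P[2] + st$a * P[3]) + st$qxv,
             st$phi^2 * P[3] + st$qvv)
    }
    pm[i, ] <- m; pP[i, ] <- P
    if (obs_idx[i]) {
      s <- max(P[1] + tau2[yi], 1e-12)
      r <- y[yi] - m[1]
      k1 <- P[1] / s; k2 <- P[2] / s
      m <- c(m[1] + k1 * r, m[2] + k2 * r)
      P <- c(P[1] * tau2[yi] / s, P[2] * tau2[yi] / s, max(P[3] - k2 * P[2], 0))
      yi <- yi + 1
    }
    fm[i, ] <- m; fP[i, ] <- P
  }
  # backward pass
  sm <- fm; sP <- fP
  for (i in (n - 1):1) {
    if (i < 1) break
    st <- iou_step(beta, sigma, times_h[i + 1] - times_h[i])
    A <- matrix(c(1, 0, st$a, st$phi), 2, 2)  # column-major: [1 0; a phi]
    Pf <- matrix(c(fP[i, 1], fP[i, 2], fP[i, 2], fP[i, 3]), 2, 2)
    Pp <- matrix(c(pP[i + 1, 1], pP[i + 1, 2], pP[i + 1, 2], pP[i + 1, 3]), 2, 2)
    G <- Pf %*% t(A) %*% solve(Pp)
    msm <- fm[i, ] + as.numeric(G %*% (sm[i + 1, ] - pm[i + 1, ]))
    Psm_next <- matrix(c(sP[i + 1, 1], sP[i + 1, 2], sP[i + 1, 2], sP[i + 1, 3]), 2, 2)
    Psm <- Pf + G %*% (Psm_next - Pp) %*% t(G)
    sm[i, ] <- msm
    sP[i, ] <- c(Psm[1, 1], Psm[1, 2], Psm[2, 2])
  }
  list(mean = sm, pos_var = sP[, 1], filter_pos_var = fP[, 1])
}

#' Interpolate a pathway on a regular grid with the CTCRW smoother
#'
#' Runs the forward filter and fixed-interval smoother on the union of the
#' observation instants and a regular prediction grid spanning the track, and
#' returns the smoothed positions at the grid instants.
#'
#' @param trk A [track()].
#' @param params A fitted [ctcrw_params()].
#' @param dt_min Prediction interval in minutes (default 15).
#' @return A tibble of class `flyway_path` with columns `time`, `lat`, `lon`,
#'   `position_sd_km`; the animal id is attached as an attribute.
#' @export
predict_path <- function(trk, params, dt_min = 15) {
  if (dt_min <= 0) stop("dt_min must be positive")
  pl <- track_to_plane(trk, params$obs_error_m_by_class)
  t_obs <- pl$times_h
  grid <- seq(t_obs[1], t_obs[length(t_obs)], by = dt_min / 60)
  if (grid[length(grid)] < t_obs[length(t_obs)]) {
    grid <- c(grid, t_obs[length(t_obs)])
  }
  all_t <- sort(unique(round(c(grid, t_obs), 9)))
  obs_idx <- all_t %in% round(t_obs, 9)
  tau2 <- pl$tau_km^2
  sx <- kalman_smooth_1d(all_t, pl$xy[, 1], tau2, obs_idx,
                         params$beta_per_h, params$sigma)
  sy <- kalman_smooth_1d(all_t, pl$xy[, 2], tau2, obs_idx,
                         params$beta_per_h, params$sigma)
  on_grid <- all_t %in% round(grid, 9)
  ll <- aeqd_inverse(sx$mean[on_grid, 1], sy$mean[on_grid, 1],
                     pl$center["lat"], pl$center["lon"])
  out <- tibble::tibble(
    time = pl$t0 + all_t[on_grid] * 3600,
    lat = ll[, "lat"], lon = ll[, "lon"],
    position_sd_km = sqrt(pmax(0, sx$pos_var[on_grid]) +
                            pmax(0, sy$pos_var[on_grid]))
  )
  attr(out, "animal_id") <- trk$animal_id
  attr(out, "center") <- pl$center
  class(out) <- c("flyway_path", class(out))
  out
}

#' Simulate the integrated Ornstein-Uhlenbeck process
#'
#' Exact-discretization sampling on a regular grid; used as the simulation
#' oracle for [fit_ctcrw()] parameter recovery.
#'
#' @param params A [ctcrw_params()].
#' @param duration_h Total duration (hours).
#' @param dt_h Step (hours).
#' @param seed Integer seed.
#' @param x0,v0 Initial planar position (km) and velocity (km/h), each
#'   length 2.
#' @return A tibble with `t_h`, `x`, `y`, `vx`, `vy`.
#' @export
simulate_ctcrw <- function(params, duration_h, dt_h, seed,
                           x0 = c(0, 0), v0 = c(0, 0)) {
  beta <- params$beta_per_h; sigma <- params$sigma
  times <- seq(0, duration_h, by = dt_h)
  n <- length(times)
  st <- iou_step(beta, sigma, dt_h)
  # lower Cholesky of the innovation covariance [[qxx, qxv], [qxv, qvv]]
  c11 <- sqrt(st$qxx)
  c21 <- if (c11 > 0) st$qxv / c11 else 0
  c22 <- sqrt(max(0, st$qvv - c21^2))
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(2 * 2 * (n - 1)), ncol = 4)
    xs <- matrix(0, n, 2); vs <- matrix(0, n, 2)
    xs[1, ] <- x0; vs[1, ] <- v0
    for (i in seq_len(n - 1)) {
      for (ax in 1:2) {
        z1 <- z[i, 2 * ax - 1]; z2 <- z[i, 2 * ax]
        xi <- c11 * z1
        zeta <- c21 * z1 + c22 * z2
        xs[i + 1, ax] <- xs[i, ax] + st$a * vs[i, ax] + xi
        vs[i + 1, ax] <- st$phi * vs[i, ax] + zeta
      }
    }
    tibble::tibble(t_h = times, x = xs[, 1], y = xs[, 2],
                   vx = vs[, 1], vy = vs[, 2])
  })
}
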