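# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and a
# two-window diagonal mass-matrix estimate, in the style of the standard
# adaptive samplers. `lpg(theta)` must return list(lp = scalar, grad =
# vector); -Inf signals out-of-support.

hmc_chain <- function(lpg, init, warmup, samples, L = 8, target = 0.8,
                      mass0 = NULL, step0 = 0.1, max_dh = 50) {
  d <- length(init)
  mass <- mass0 %||% rep(1, d)  # precision scale: p ~ N(0, mass)
  cur <- init
  cl <- lpg(cur)
  if (!is.finite(cl$lp)) stop("non-finite log posterior at init",
                              call. = FALSE)
  eps <- step0
  # dual averaging state (reset at the mass-update window boundary)
  da_reset <- function(eps0) list(mu = log(10 * eps0), lbar = log(eps0),
                                  hbar = 0, m = 0)
  da <- da_reset(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  # window 1 adapts the step size under the initial metric and collects
  # draws in its second half; the metric is re-estimated at the window
  # boundary and the step size re-adapted under it in window 2
  phase1 <- max(10L, as.integer(round(warmup * 0.5)))
  collect_from <- max(1L, as.integer(round(phase1 * 0.5)))
  buf <- matrix(NA_real_, phase1, d)
  bi <- 0L
  out <- matrix(NA_real_, samples, d)
  lp_out <- numeric(samples)
  n_acc <- 0; n_div <- 0
  total <- warmup + samples
  L_lo <- max(1L, as.integer(round(L * 0.8)))
  L_hi <- max(L_lo, as.integer(round(L * 1.2)))

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d, 0, sqrt(mass))
    th <- cur; lg <- cl; p <- p0
    Ls <- if (L_hi > L_lo) sample(L_lo:L_hi, 1) else L_lo
    H0 <- -cl$lp + 0.5 * sum(p0^2 / mass)
    ok <- TRUE
    p <- p + 0.5 * eps * lg$grad
    for (s in seq_len(Ls)) {
      th <- th + eps * p / mass
      lg <- lpg(th)
      if (!is.finite(lg$lp) || any(!is.finite(lg$grad))) { ok <- FALSE; break }
      if (s < Ls) p <- p + eps * lg$grad
    }
    if (ok) {
      p <- p + 0.5 * eps * lg$grad
      dh <- (-lg$lp + 0.5 * sum(p^2 / mass)) - H0
      if (!is.finite(dh)) ok <- FALSE
    }
    a <- if (ok) min(1, exp(-dh)) else 0
    divergent <- !ok || (ok && dh > max_dh)
    if (divergent && it > warmup) n_div <- n_div + 1
    if (!divergent && stats::runif(1) < a) {
      cur <- th; cl <- lg
      if (it > warmup) n_acc <- n_acc + 1
    }
    if (it <= warmup) {
      da$m <- da$m + 1
      w <- 1 / (da$m + t0)
      da$hbar <- (1 - w) * da$hbar + w * (target - a)
      leps <- da$mu - sqrt(da$m) / gamma * da$hbar
      eta <- da$m^(-kappa)
      da$lbar <- eta * leps + (1 - eta) * da$lbar
      eps <- exp(leps)
      if (it <= phase1 && it >= collect_from) {
        bi <- bi + 1L; buf[bi, ] <- cur
      }
      if (it == phase1) {
        if (bi >= 10L) {
          vr <- apply(buf[seq_len(bi), , drop = FALSE], 2, stats::var)
          ok_v <- is.finite(vr) & vr > 0
          mass[ok_v] <- 1 / vr[ok_v]
        }
        da <- da_reset(max(eps, 1e-8))
      }
      if (it == warmup) eps <- exp(da$lbar)
    } else {
      out[it - warmup, ] <- cur
      lp_out[it - warmup] <- cl$lp
    }
  }
  list(draws = out, lp = lp_out, accept_rate = n_acc / samples,
       divergences = n_div, step_size = eps, mass = mass)
}

# Split-chain potential scale reduction factor; `mat` is iterations x chains.
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  B <- nn * stats::var(mu)
  W <- mean(apply(sub, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size across chains (Geyer initial-monotone truncation
# on the combined autocorrelation).
ess_mean <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4) return(NA_real_)
  ch_var <- apply(mat, 2, stats::var)
  W <- mean(ch_var)
  mu <- colMeans(mat)
  B_n <- if (m > 1) stats::var(mu) else 0
  var_plus <- (n - 1) / n * W + B_n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  lag_max <- min(n - 1L, 200L)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(mat[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- rowMeans(acov)  # lag 0..lag_max
  rho <- 1 - (W - acov[-1]) / var_plus
  # pair sums; truncate at first negative, enforce monotone decrease
  npair <- length(rho) %/% 2
  s <- numeric(npair)
  for (k in seq_len(npair)) s[k] <- rho[2 * k - 1] + rho[2 * k]
  tau <- 1
  run_min <- Inf
  for (k in seq_len(npair)) {
    if (s[k] < 0) break
    run_min <- min(run_min, s[k])
    tau <- tau + 2 * run_min
  }
  max(m * n / tau, 1)
}
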