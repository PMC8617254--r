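## Embedded Dormand-Prince 5(4) integrator.
##
## The environment ships no ODE package, so the driver lives here. The
## coupled mRNA/protein system is only mildly stiff (the fastest time scale
## is the shortest mRNA lifetime, minutes, against a ~100 min growth time),
## so an explicit adaptive pair with PI-free step control is adequate;
## grid-convergence and closed-form relaxation tests pin the accuracy.

.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

## One DP5(4) step from (t, y) with derivative k1 = f(t, y) (FSAL reuse).
## Returns y5, the embedded error estimate and k7 = f(t + h, y5).
dp_step <- function(f, t, y, h, k1) {
  k <- vector("list", 7)
  k[[1]] <- k1
  for (s in 2:6) {
    acc <- y
    a <- .dp_a[[s - 1]]
    for (j in seq_along(a)) if (a[j] != 0) acc <- acc + h * a[j] * k[[j]]
    k[[s]] <- f(t + .dp_c[s] * h, acc)
  }
  y5 <- y
  for (j in 1:6) if (.dp_b5[j] != 0) y5 <- y5 + h * .dp_b5[j] * k[[j]]
  k[[7]] <- f(t + h, y5)
  err <- numeric(length(y))
  for (j in 1:7) {
    d <- .dp_b5[j] - .dp_b4[j]
    if (d != 0) err <- err + h * d * k[[j]]
  }
  list(y = y5, err = err, k_end = k[[7]])
}

## Advance y from t to exactly t_target with adaptive steps.
## Returns the final state plus the last accepted step size (for reuse).
ode_advance <- function(f, t, y, t_target, rtol = 1e-8, atol = 1e-6,
                        h = NULL, max_steps = 1e6) {
  if (t_target <= t) return(list(t = t, y = y, h = h))
  h <- min(h %||% ((t_target - t) / 10), t_target - t)
  k1 <- f(t, y)
  steps <- 0L
  while (t < t_target) {
    h <- min(h, t_target - t)
    st <- dp_step(f, t, y, h, k1)
    sc <- atol + rtol * pmax(abs(y), abs(st$y))
    errnorm <- sqrt(mean((st$err / sc)^2))
    if (!is.finite(errnorm)) {
      h <- h / 2
    } else if (errnorm <= 1) {
      t <- t + h
      y <- st$y
      k1 <- st$k_end
      fac <- if (errnorm == 0) 5 else min(5, max(0.2, 0.9 * errnorm^(-0.2)))
      h <- h * fac
    } else {
      h <- h * max(0.1, 0.9 * errnorm^(-0.2))
    }
    steps <- steps + 1L
    if (steps > max_steps)
      stop("ODE integrator exceeded ", max_steps, " steps (t = ", t, ")")
    if (h < 1e-12 * max(1, abs(t)))
      stop("ODE integrator step size underflow at t = ", t)
  }
  list(t = t, y = y, h = h)
}

## Integrate over a uniform output grid; optionally stop early when
## stop_fn(t, y) turns TRUE (checked at grid points). Returns times and a
## row-per-time state matrix.
ode_solve_grid <- function(f, y0, t0, t_end, dt_out, rtol = 1e-8, atol = 1e-6,
                           stop_fn = NULL) {
  times <- seq(t0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1, ] <- y0
  y <- y0
  h <- NULL
  last <- length(times)
  for (i in seq_along(times)[-1]) {
    adv <- ode_advance(f, times[i - 1], y, times[i], rtol, atol, h)
    y <- adv$y
    h <- adv$h
    out[i, ] <- y
    if (!is.null(stop_fn) && isTRUE(stop_fn(times[i], y))) {
      last <- i
      break
    }
  }
  list(time = times[seq_len(last)], y = out[seq_len(last), , drop = FALSE])
}

## Locate the time in (t_a, t_b] at which event_fn(t, y) crosses zero from
## below, by bisection with fresh sub-integrations from (t_a, y_a).
## Returns the event time and state. event_fn(t_a, y_a) must be < 0.
ode_locate_event <- function(f, t_a, y_a, t_b, event_fn, rtol = 1e-8,
                             atol = 1e-6, tol_t = 1e-6) {
  lo <- t_a
  hi <- t_b
  y_lo <- y_a
  while (hi - lo > tol_t) {
    mid <- (lo + hi) / 2
    adv <- ode_advance(f, lo, y_lo, mid, rtol, atol)
    if (event_fn(mid, adv$y) >= 0) {
      hi <- mid
    } else {
      lo <- mid
      y_lo <- adv$y
    }
  }
  adv <- ode_advance(f, lo, y_lo, hi, rtol, atol)
  list(t = hi, y = adv$y)
}
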