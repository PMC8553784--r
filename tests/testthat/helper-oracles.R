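# Independent oracle implementations, deliberately naive and written
# directly from the governing difference equations / definitions. They are
# kept free of any package internals so they can arbitrate.

# one forward-Euler step of the parcel difference equations, spelled out
# term by term (no flux capping: oracle cases stay well away from depletion)
oracle_parcel_step <- function(s, p, dt) {
  mu <- p$mu0 * exp(p$T * p$T_growth)
  N_lim <- s$DIN / (s$DIN + p$K_DIN)
  N_up <- mu * p$L_lim * min(p$Fe_lim, N_lim) * s$PON
  N15_up <- N_up * (s$DI15N / s$DIN) * (1 - N_lim * p$eps_phy / 1000)
  resp <- p$P_resp * s$PON * s$PON / (s$PON + p$K_resp)
  mort <- p$P_mort * s$PON^2
  det <- resp + mort
  f_rec <- min(1, max(0, p$f_recmin + p$T_rec * exp(p$T * p$T_growth)))
  N_rec <- det * f_rec
  N_exp <- det * (1 - f_rec)
  r15p <- s$PO15N / s$PON
  list(DIN = s$DIN + dt * (-N_up + N_rec * 1),
       PON = s$PON + dt * (N_up - N_rec - N_exp),
       ExpN = s$ExpN + dt * N_exp,
       DI15N = s$DI15N + dt * (-N15_up + N_rec * r15p),
       PO15N = s$PO15N + dt * (N15_up - N_rec * r15p - N_exp * r15p),
       Exp15N = s$Exp15N + dt * N_exp * r15p)
}

# centered boxcar with symmetric shrinking edges, naive double loop
oracle_boxcar <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - hi):(i + hi)])
  }
  out
}

# first index from which the condition holds to the end, by enumeration
oracle_toe_index <- function(exceed) {
  for (i in seq_along(exceed)) {
    if (all(exceed[i:length(exceed)])) return(i)
  }
  NA_integer_
}

# per-mil signature of net biogeochemical flux, direct transcription
oracle_tendency <- function(n15, n14, w15, w14, d15, d14) {
  ((n15 - w15 - d15) / (n14 - w14 - d14) - 1) * 1000
}

# cheap parcel parameterization for tests that only need dynamics, not the
# calibrated anchors (coarser dt keeps loops fast; properties are dt-robust)
fast_params <- function(...) {
  parcel_params(dt = 0.05, ...)
}
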