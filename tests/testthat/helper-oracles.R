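# Independent oracles used across the suite. The reference right-hand side
# below is a separate hand transcription of the model equations; the RK4
# integrator is a brute-force fixed-step scheme. Neither shares code with the
# package's solver path.

# Reference derivative of the nine-state system (no extracellular clearance).
ref_rhs <- function(y, p, uptake) {
  ox_den <- p$Km + y[["endoF_GSH"]] + y[["exogF_GSH"]]
  ox_endo <- p$Vmax * y[["endoF_GSH"]] / ox_den
  ox_exog <- p$Vmax * y[["exogF_GSH"]] / ox_den
  c(
    endoF = p$kp - p$k21 * y[["endoF"]] -
      p$k23 * y[["endoF"]] * y[["GSH"]] + p$k32 * y[["endoF_GSH"]] -
      p$kDNA_DG * y[["endoF"]] - p$kDNA_DPX * y[["endoF"]],
    exogF = uptake - p$k21 * y[["exogF"]] -
      p$k23 * y[["exogF"]] * y[["GSH"]] + p$k32 * y[["exogF_GSH"]] -
      p$kDNA_DG * y[["exogF"]] - p$kDNA_DPX * y[["exogF"]],
    GSH = -p$k23 * (y[["endoF"]] + y[["exogF"]]) * y[["GSH"]] +
      p$k32 * (y[["endoF_GSH"]] + y[["exogF_GSH"]]) + ox_endo + ox_exog,
    endoF_GSH = p$k23 * y[["endoF"]] * y[["GSH"]] -
      p$k32 * y[["endoF_GSH"]] - ox_endo,
    exogF_GSH = p$k23 * y[["exogF"]] * y[["GSH"]] -
      p$k32 * y[["exogF_GSH"]] - ox_exog,
    endoDG = p$kDNA_DG * y[["endoF"]] - p$krep_DG * y[["endoDG"]],
    exogDG = p$kDNA_DG * y[["exogF"]] - p$krep_DG * y[["exogDG"]],
    endoDPX = p$kDNA_DPX * y[["endoF"]] - p$krep_DPX * y[["endoDPX"]],
    exogDPX = p$kDNA_DPX * y[["exogF"]] - p$krep_DPX * y[["exogDPX"]])
}

# Fixed-step classical RK4 over a single-exposure run: uptake is constant
# `uptake_on` for t in [0, t_off) and zero afterwards. Reports states at the
# requested output times (which must be multiples of h, as must t_off).
rk4_single_exposure <- function(p, y0, uptake_on, t_off, h, out_times) {
  state_names <- names(y0)
  kp <- p$kp; k21 <- p$k21; k23 <- p$k23; k32 <- p$k32
  kdg <- p$kDNA_DG; kdpx <- p$kDNA_DPX
  rdg <- p$krep_DG; rdpx <- p$krep_DPX
  Vmax <- p$Vmax; Km <- p$Km
  kloss <- k21 + kdg + kdpx
  f <- function(y, uptake) {
    den <- Km + y[4L] + y[5L]
    ox_e <- Vmax * y[4L] / den
    ox_x <- Vmax * y[5L] / den
    ae <- k23 * y[1L] * y[3L]
    ax <- k23 * y[2L] * y[3L]
    c(kp - kloss * y[1L] - ae + k32 * y[4L],
      uptake - kloss * y[2L] - ax + k32 * y[5L],
      -(ae + ax) + k32 * (y[4L] + y[5L]) + ox_e + ox_x,
      ae - k32 * y[4L] - ox_e,
      ax - k32 * y[5L] - ox_x,
      kdg * y[1L] - rdg * y[6L],
      kdg * y[2L] - rdg * y[7L],
      kdpx * y[1L] - rdpx * y[8L],
      kdpx * y[2L] - rdpx * y[9L])
  }
  t_end <- max(out_times)
  n_steps <- round(t_end / h)
  off_step <- round(t_off / h)
  out_steps <- round(out_times / h)
  stopifnot(all(abs(out_steps * h - out_times) < 1e-9),
            abs(off_step * h - t_off) < 1e-9)
  y <- as.numeric(y0)
  out <- matrix(NA_real_, length(out_times), 9L)
  hit <- match(0L, out_steps)
  if (!is.na(hit)) out[hit, ] <- y
  for (s in seq_len(n_steps)) {
    uptake <- if (s <= off_step) uptake_on else 0
    k1 <- f(y, uptake)
    k2 <- f(y + h / 2 * k1, uptake)
    k3 <- f(y + h / 2 * k2, uptake)
    k4 <- f(y + h * k3, uptake)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- match(s, out_steps)
    if (!is.na(hit)) out[hit, ] <- y
  }
  colnames(out) <- state_names
  out
}

# Algebraic endogenous fixed point by direct scalar root bracketing on a
# fine grid (no uniroot), independent of the package's construction.
grid_fixed_point <- function(p, n = 400000L) {
  gsh_total <- p$GSH_init + p$endoF_GSH_init
  kloss <- p$k21 + p$kDNA_DG + p$kDNA_DPX
  F <- seq(1e-6, p$kp / kloss * (1 - 1e-9), length.out = n)
  ox <- p$kp - kloss * F
  C <- p$Km * ox / (p$Vmax - ox)
  g <- p$k23 * F * (gsh_total - C) - p$k32 * C - ox
  i <- which(g[-1] * g[-n] <= 0)[1]
  # linear interpolation across the sign change
  w <- g[i] / (g[i] - g[i + 1L])
  Fstar <- F[i] + w * (F[i + 1L] - F[i])
  ox <- p$kp - kloss * Fstar
  C <- p$Km * ox / (p$Vmax - ox)
  c(endoF = Fstar, GSH = gsh_total - C, endoF_GSH = C,
    endoDG = p$kDNA_DG * Fstar / p$krep_DG,
    endoDPX = p$kDNA_DPX * Fstar / p$krep_DPX)
}

default_params <- function() kinetic_parameters()
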