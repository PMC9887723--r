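#' State variables of the mucosal dosimetry model
#'
#' The model tracks nine concentrations (pmol/mm^3) in a single well-mixed
#' mucosal tissue slab: free formaldehyde of endogenous (\code{endoF}) and
#' exogenous (\code{exogF}) origin, free glutathione (\code{GSH}), the
#' S-hydroxymethylglutathione complexes formed from each formaldehyde pool
#' (\code{endoF_GSH}, \code{exogF_GSH}), DG monoadducts (\code{endoDG},
#' \code{exogDG}) and DNA-protein crosslinks (\code{endoDPX},
#' \code{exogDPX}).
#'
#' @param endoF,exogF,GSH,endoF_GSH,exogF_GSH,endoDG,exogDG,endoDPX,exogDPX
#'   concentrations (pmol/mm^3), all non-negative.
#' @return a named numeric vector of length 9 in canonical order.
#' @export
mucosal_state <- function(endoF = 0, exogF = 0, GSH = 0, endoF_GSH = 0,
                          exogF_GSH = 0, endoDG = 0, exogDG = 0,
                          endoDPX = 0, exogDPX = 0) {
  s <- c(endoF = endoF, exogF = exogF, GSH = GSH, endoF_GSH = endoF_GSH,
         exogF_GSH = exogF_GSH, endoDG = endoDG, exogDG = exogDG,
         endoDPX = endoDPX, exogDPX = exogDPX)
  .check_state(s)
  s
}

.state_names <- c("endoF", "exogF", "GSH", "endoF_GSH", "exogF_GSH",
                  "endoDG", "exogDG", "endoDPX", "exogDPX")

.check_state <- function(s) {
  if (length(s) != 9L)
    stop("state must have 9 components", call. = FALSE)
  if (is.null(names(s))) names(s) <- .state_names
  s <- s[.state_names]
  if (anyNA(s)) stop("state contains missing values", call. = FALSE)
  neg <- .state_names[s < 0]
  if (length(neg))
    stop("negative state component(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  invisible(s)
}

# Initial state from the published approximate initial concentrations
# (exogenous pools zero).
published_initial_state <- function(params) {
  mucosal_state(endoF = params$endoF_init, GSH = params$GSH_init,
                endoF_GSH = params$endoF_GSH_init,
                endoDG = params$endoDG_init, endoDPX = params$endoDPX_init)
}

#' Volumetric uptake rate of inhaled formaldehyde
#'
#' Converts a CFD-predicted site-specific wall flux (pmol/mm^2/h at 1 ppm)
#' into the volumetric source term of the tissue model:
#' \code{uptake = flux_per_ppm * ppm / thick} (pmol/mm^3/h). Flux is assumed
#' linear in the inhaled concentration.
#'
#' @param site a [site_flux()] object, or \code{"DPX"}/\code{"DG"}.
#' @param thick mucosal thickness (mm), strictly positive.
#' @param ppm inhaled concentration (>= 0), may be a vector.
#' @return uptake rate(s), pmol/mm^3/h.
#' @examples
#' uptake_rate(site_flux("DG"), 0.1138, 1)  # 6824.25
#' @export
uptake_rate <- function(site, thick, ppm) {
  site <- .as_site(site)
  if (!is.numeric(thick) || length(thick) != 1L || !is.finite(thick) ||
      thick <= 0)
    stop("thick must be a single positive number (mm)", call. = FALSE)
  if (any(ppm < 0)) stop("ppm must be non-negative", call. = FALSE)
  site$flux_per_ppm * ppm / thick
}

# Build the fast right-hand side closure for a fixed parameter set.
# y: state vector in canonical order; uptake: pmol/mm^3/h (constant within
# an integration segment). Oxidation of the two complexes competes for one
# formaldehyde-dehydrogenase pool (total complex in the denominator), and
# oxidation regenerates free GSH, so the glutathione moiety
# GSH + endoF_GSH + exogF_GSH is conserved by construction.
make_rhs <- function(params) {
  kp <- params$kp; k21 <- params$k21; k23 <- params$k23; k32 <- params$k32
  kdg <- params$kDNA_DG; kdpx <- params$kDNA_DPX
  rdg <- params$krep_DG; rdpx <- params$krep_DPX
  Vmax <- params$Vmax; Km <- params$Km
  ec_mode <- params$ec_mode
  ec_rate <- params$ec_rate; ec_Vmax <- params$ec_Vmax; ec_Km <- params$ec_Km
  kloss <- k21 + kdg + kdpx
  function(y, uptake) {
    endoF <- y[1L]; exogF <- y[2L]; GSH <- y[3L]
    eC <- y[4L]; xC <- y[5L]
    den <- Km + eC + xC
    ox_e <- Vmax * eC / den
    ox_x <- Vmax * xC / den
    ec <- if (ec_mode == "off") 0
          else if (ec_mode == "zero_order")
            # smooth clip so the zero-order sink cannot drive exogF negative
            ec_rate * exogF / (exogF + 1e-6)
          else ec_Vmax * exogF / (ec_Km + exogF)
    assoc_e <- k23 * endoF * GSH
    assoc_x <- k23 * exogF * GSH
    c(kp - kloss * endoF - assoc_e + k32 * eC,
      uptake - ec - kloss * exogF - assoc_x + k32 * xC,
      -(assoc_e + assoc_x) + k32 * (eC + xC) + ox_e + ox_x,
      assoc_e - k32 * eC - ox_e,
      assoc_x - k32 * xC - ox_x,
      kdg * endoF - rdg * y[6L],
      kdg * exogF - rdg * y[7L],
      kdpx * endoF - rdpx * y[8L],
      kdpx * exogF - rdpx * y[9L])
  }
}

#' Time derivatives of the mucosal state
#'
#' Evaluates the right-hand side of the dosimetry ODE system at a given
#' state and instantaneous uptake rate. Endogenous and exogenous
#' formaldehyde follow identical kinetics and differ only in their source
#' term (endogenous production \code{kp} vs inhalation uptake); their GSH
#' complexes compete for a single formaldehyde-dehydrogenase pool, whose
#' oxidation step regenerates free GSH.
#'
#' @param state a named state vector (see [mucosal_state()]); all components
#'   must be non-negative.
#' @param params a [kinetic_parameters()] set.
#' @param uptake_now instantaneous volumetric uptake of inhaled formaldehyde
#'   (pmol/mm^3/h, >= 0); see [uptake_rate()].
#' @return named numeric vector of per-state rates (pmol/mm^3/h).
#' @examples
#' p <- kinetic_parameters()
#' derivatives(mucosal_state(), p, 0)["endoF"]  # kp
#' @export
derivatives <- function(state, params, uptake_now = 0) {
  params <- validate_parameters(params)
  state <- .check_state(state)
  if (!is.numeric(uptake_now) || length(uptake_now) != 1L || uptake_now < 0)
    stop("uptake_now must be a single non-negative number", call. = FALSE)
  d <- make_rhs(params)(as.numeric(state[.state_names]), uptake_now)
  stats::setNames(d, .state_names)
}

#' Integrate the dosimetry model over an exposure schedule
#'
#' Solves the nine-state ODE system with the instantaneous uptake rate
#' driven by the schedule's square-wave exposure concentration. Exposure
#' on/off edges are always integration restart points; within each segment
#' the uptake is constant and a stiff-capable adaptive solver
#' (\code{deSolve::ode}, lsoda) is used with tight tolerances (the rate
#' constants span nine orders of magnitude).
#'
#' @param params a [kinetic_parameters()] set.
#' @param site a [site_flux()] or \code{"DPX"}/\code{"DG"}.
#' @param schedule an [exposure_schedule()].
#' @param output_times times (h) at which states are reported; defaults to
#'   the schedule's sampling times. Must lie within \code{[0, horizon]}.
#' @param initial initial state: \code{NULL} (default) starts from the
#'   endogenous steady state (burn-in), \code{"published"} uses the
#'   approximate published initial concentrations, or a named 9-vector.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param method solver method passed to \code{deSolve::ode}.
#' @return a \code{mucosal_trajectory}: a data frame with column
#'   \code{time_h} and the nine state columns, with provenance attributes
#'   (parameter hash, schedule and site labels).
#' @examples
#' \donttest{
#' p <- kinetic_parameters()
#' tr <- integrate_model(p, "DG", single_exposure(2), output_times = 0:7)
#' tr$exogDG
#' }
#' @export
integrate_model <- function(params, site, schedule,
                            output_times = schedule$sampling_times,
                            initial = NULL, rtol = 1e-8, atol = 1e-12,
                            method = "lsoda") {
  params <- validate_parameters(params)
  site <- .as_site(site)
  stopifnot(inherits(schedule, "exposure_schedule"))
  output_times <- sort(unique(as.numeric(output_times)))
  if (!length(output_times))
    stop("no output times requested", call. = FALSE)
  if (any(output_times < 0 | output_times > schedule$horizon))
    stop("output_times must lie within [0, horizon]", call. = FALSE)
  y <- if (is.null(initial)) {
    endogenous_steady_state(params)
  } else if (identical(initial, "published")) {
    published_initial_state(params)
  } else {
    .check_state(initial)
    initial[.state_names]
  }
  y <- as.numeric(y[.state_names])

  rhs <- make_rhs(params)
  t_end <- max(output_times)
  ep <- schedule$episodes
  breaks <- sort(unique(c(0, ep$start_h, ep$end_h, t_end)))
  breaks <- breaks[breaks <= t_end]
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)

  out <- matrix(NA_real_, nrow = length(output_times), ncol = 9L)
  record <- function(times, states) {
    hit <- match(round(times, 9), round(output_times, 9))
    ok <- !is.na(hit)
    out[hit[ok], ] <<- states[ok, , drop = FALSE]
  }
  if (output_times[1L] == 0) out[1L, ] <- y

  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    uptake <- uptake_rate(site, params$thick,
                          ppm_at(schedule, (t0 + t1) / 2))
    inner <- output_times[output_times > t0 & output_times < t1]
    times <- unique(c(t0, inner, t1))
    # integrate in segment-local time: keeps the solver's step-size control
    # well scaled on long schedules (t up to ~2000 h)
    sol <- deSolve::ode(y = y, times = times - t0,
                        func = function(t, y, parms) list(rhs(y, uptake)),
                        parms = NULL, method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed to converge on segment [", t0, ", ", t1,
           "] h", call. = FALSE)
    states <- unname(sol[, -1L, drop = FALSE])
    if (min(states) < -1e2 * atol - 1e-9 * max(abs(states)))
      stop("integration produced a negative state beyond tolerance on ",
           "segment [", t0, ", ", t1, "] h", call. = FALSE)
    states[states < 0] <- 0
    record(times[-1L], states[-1L, , drop = FALSE])
    y <- states[nrow(states), ]
  }

  if (anyNA(out))
    stop("internal error: some output times were not recorded",
         call. = FALSE)
  df <- data.frame(time_h = output_times, out)
  names(df) <- c("time_h", .state_names)
  structure(df,
            class = c("mucosal_trajectory", "data.frame"),
            param_hash = param_hash(params),
            site_label = site$site_label,
            schedule_label = schedule$label)
}

#' Endogenous steady state of the mucosa
#'
#' The zero-exposure fixed point of the model: exogenous pools are zero and
#' endogenous production balances first-order loss, DNA binding and enzymatic
#' oxidation of the GSH complex. The published initial concentrations are
#' approximate; multi-day simulations relax to this fixed point regardless of
#' the starting adduct values, so simulations here start from it by default.
#'
#' The \code{"algebraic"} method reduces the fixed point to a scalar root in
#' free endogenous formaldehyde (with the glutathione moiety total fixed at
#' \code{GSH_init + endoF_GSH_init}) and solves it with
#' \code{stats::uniroot}; \code{"burnin"} integrates the model at zero
#' exposure until the rates vanish.
#'
#' @param params a [kinetic_parameters()] set.
#' @param method \code{"algebraic"} (default) or \code{"burnin"}.
#' @param burnin_h burn-in horizon (h) for the \code{"burnin"} method.
#' @param tol convergence tolerance on \code{|rates| / kp}.
#' @return a [mucosal_state()] at the fixed point.
#' @examples
#' ss <- endogenous_steady_state(kinetic_parameters())
#' ss["endoF"]  # about 47 pmol/mm^3
#' @export
endogenous_steady_state <- function(params,
                                    method = c("algebraic", "burnin"),
                                    burnin_h = 5000, tol = 1e-9) {
  params <- validate_parameters(params)
  method <- match.arg(method)
  gsh_total <- params$GSH_init + params$endoF_GSH_init
  if (method == "algebraic") {
    kloss <- params$k21 + params$kDNA_DG + params$kDNA_DPX
    # at the fixed point: oxidation flux = kp - kloss * endoF
    g <- function(F) {
      ox <- params$kp - kloss * F
      C <- params$Km * ox / (params$Vmax - ox)
      params$k23 * F * (gsh_total - C) - params$k32 * C - ox
    }
    hi <- params$kp / kloss * (1 - 1e-12)
    lo <- max(1e-12, (params$kp - 0.999999 * params$Vmax) / kloss)
    if (g(lo) * g(hi) > 0)
      stop("failed to bracket the endogenous fixed point; check parameters",
           call. = FALSE)
    F <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
    ox <- params$kp - kloss * F
    C <- params$Km * ox / (params$Vmax - ox)
    ss <- mucosal_state(
      endoF = F, GSH = gsh_total - C, endoF_GSH = C,
      endoDG = params$kDNA_DG * F / params$krep_DG,
      endoDPX = params$kDNA_DPX * F / params$krep_DPX)
  } else {
    null_sched <- exposure_schedule(NULL, horizon = burnin_h,
                                    label = "burnin")
    tr <- integrate_model(params, site_flux("DG"), null_sched,
                          output_times = burnin_h,
                          initial = published_initial_state(params))
    ss <- mucosal_state(
      endoF = tr$endoF, exogF = 0, GSH = tr$GSH, endoF_GSH = tr$endoF_GSH,
      exogF_GSH = 0, endoDG = tr$endoDG, exogDG = 0,
      endoDPX = tr$endoDPX, exogDPX = 0)
  }
  rates <- derivatives(ss, params, 0)
  if (max(abs(rates)) > tol * params$kp && method == "algebraic")
    stop("algebraic fixed point did not satisfy the rate tolerance",
         call. = FALSE)
  if (max(abs(rates)) > 1e-6 * params$kp)
    stop("burn-in did not converge to the endogenous steady state ",
         "(max |rate| = ", format(max(abs(rates))), " pmol/mm^3/h)",
         call. = FALSE)
  ss
}

#' Write a trajectory as tidy delimited text
#'
#' One row per (time, species): columns \code{time_h}, \code{species},
#' \code{value_pmol_mm3}, \code{site}, \code{schedule}, plus a parameter-hash
#' comment line for provenance.
#'
#' @param traj a \code{mucosal_trajectory} from [integrate_model()].
#' @param path output file path.
#' @param sep field separator, default tab.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path, sep = "\t") {
  stopifnot(inherits(traj, "mucosal_trajectory"))
  long <- tidy_trajectory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# param_hash: ", attr(traj, "param_hash")), con)
  utils::write.table(long, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tidy long-format view of a trajectory
#'
#' @param traj a \code{mucosal_trajectory}.
#' @return a data frame with columns \code{time_h}, \code{species},
#'   \code{value_pmol_mm3}, \code{site}, \code{schedule}.
#' @export
tidy_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mucosal_trajectory"))
  long <- data.frame(
    time_h = rep(traj$time_h, times = length(.state_names)),
    species = rep(.state_names, each = nrow(traj)),
    value_pmol_mm3 = unlist(lapply(.state_names, function(s) traj[[s]]),
                            use.names = FALSE),
    site = attr(traj, "site_label"),
    schedule = attr(traj, "schedule_label"))
  long[order(long$time_h, long$species), , drop = FALSE]
}
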