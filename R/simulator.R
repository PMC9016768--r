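#' Free sigma28 under anti-sigma28 titration at binding equilibrium
#'
#' Solves the 1:1 binding equilibrium between sigma28 and its anti-sigma
#' factor for the free sigma28 concentration: the unique non-negative root
#' of \eqn{f^2 + (K_d + A - T) f - K_d T = 0}, where \eqn{T} is total
#' sigma28, \eqn{A} total anti-sigma28 and \eqn{K_d} the dissociation
#' constant. Tight binding (\eqn{K_d} far below the working
#' concentrations) produces the molecular-titration regime: free sigma28
#' stays near zero until the total exceeds the inhibitor pool, then rises
#' with slope ~1. Vectorised over its arguments; uses the numerically
#' stable quadratic form.
#'
#' @param total_sigma28 total sigma28 (uM), >= 0.
#' @param total_anti total anti-sigma28 (uM), >= 0.
#' @param kd_anti dissociation constant (uM), > 0.
#' @return free sigma28 concentration (uM).
#' @export
free_sigma28 <- function(total_sigma28, total_anti, kd_anti) {
  if (any(total_sigma28 < 0) || any(total_anti < 0) || any(kd_anti <= 0)) {
    stop("requires total_sigma28 >= 0, total_anti >= 0, kd_anti > 0",
         call. = FALSE)
  }
  b <- kd_anti + total_anti - total_sigma28
  disc <- sqrt(b^2 + 4 * kd_anti * total_sigma28)
  # avoid cancellation: subtractive form only when b < 0
  f <- ifelse(b >= 0,
              2 * kd_anti * total_sigma28 / (disc + b),
              (disc - b) / 2)
  pmin(f, total_sigma28)
}

#' Fraction of core RNAP bound as sigma28 holoenzyme
#'
#' Solves the rapid-equilibrium competitive binding of sigma28 and sigma70
#' to a shared, depletable core RNA polymerase pool. Free RNAP `E` is the
#' root of
#' \deqn{E (1 + S/(K28 + E) + \sigma70/(K70 + E)) = E_{tot},}
#' with the two sigma ligands themselves depletable (bound sigma is not
#' available), and the returned value is the sigma28-holoenzyme fraction
#' of the total RNAP pool. Monotone increasing in `free_sigma28`, 0 at 0,
#' and saturating at 1 when sigma28 outcompetes sigma70.
#'
#' @param free_sigma28 sigma28 available for RNAP binding (uM).
#' @param params a `kinetic_params` (uses `rnap_total`, `sigma70`, `K28`,
#'   `K70`).
#' @return holoenzyme fraction in [0, 1].
#' @export
holoenzyme28_fraction <- function(free_sigma28, params) {
  stopifnot(inherits(params, "kinetic_params"))
  vapply(free_sigma28, .holo28_one, 0.0,
         e_tot = params$rnap_total, s70 = params$sigma70,
         k28 = params$K28, k70 = params$K70)
}

.holo28_one <- function(s28, e_tot, s70, k28, k70) {
  if (s28 < 0) stop("free_sigma28 must be >= 0", call. = FALSE)
  if (s28 == 0 || e_tot <= 0) return(0)
  g <- function(e) e * (1 + s28 / (k28 + e) + s70 / (k70 + e)) - e_tot
  e_free <- stats::uniroot(g, c(0, e_tot), tol = 1e-14)$root
  (e_free * s28 / (k28 + e_free)) / e_tot
}

# state-vector index layout shared by the RHS and the output extraction
.state_names <- function(mode) {
  nm <- c(paste0("Rt", 1:3), paste0("Rs", 1:3),
          paste0("C", as.vector(outer(1:3, 1:3, paste0))),  # C_ij, i varies fastest
          "P", "res_tx", "res_tl")
  if (mode == "coupled") nm <- c(nm, "M", "G", "Af", "AB")
  nm
}

#' Simulate one batch TXTL reaction
#'
#' Deterministic integration of the mechanistic mass-action model on the
#' spec's sampling grid. In direct mode the activated switch complexes
#' translate deGFP; in coupled mode they translate sigma28, whose free
#' fraction (after dynamic anti-sigma28 titration) competes with sigma70
#' for core RNAP and drives transcription of the deGFP reporter template.
#' Switch RNA is treated as continuously replenished and not significantly
#' depleted by hybridization (the trigger-limiting regime), so that with
#' resource consumption disabled (`mu_res = 0`) the output is exactly
#' additive over inputs — the regime the rudimentary weighted-sum model
#' assumes. Resource pools decay first-order and are consumed in proportion
#' to synthesis flux, producing batch expression cessation and multi-input
#' burden.
#'
#' @param spec a `reaction_spec`.
#' @param params a `kinetic_params`; defaults to `default_params(spec$mode)`.
#' @param rtol,atol integrator tolerances (lsoda); the titration regime is
#'   stiff, hence the tight defaults.
#' @return a `txtl_trajectory`: list with `times` (min), `states` (matrix,
#'   one row per time), `observed_deGFP` (uM), and the generating `spec`.
#' @export
simulate_txtl <- function(spec, params = default_params(spec$mode),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "reaction_spec"))
  validate_kinetic_params(params)
  mode <- spec$mode
  times <- seq(0, spec$duration, by = spec$sample_interval)

  p <- params
  inp <- spec$input_conc
  w <- spec$weight_conc
  rep_c <- spec$reporter_conc
  anti0 <- spec$inhibitor_conc
  k_off_anti <- p$k_on_anti * p$kd_anti
  theta_t <- t(p$theta)  # theta_t[j, i] = theta[i, j]

  y0 <- stats::setNames(numeric(length(.state_names(mode))),
                        .state_names(mode))
  y0["res_tx"] <- p$res_tx0
  y0["res_tl"] <- p$res_tl0
  if (mode == "coupled") y0["Af"] <- anti0

  rhs <- function(t, y, parms) {
    Rt <- y[1:3]; Rs <- y[4:6]
    C <- matrix(y[7:15], 3, 3)  # C[i, j]
    P <- y[16]; res_tx <- y[17]; res_tl <- y[18]
    res_tx <- max(res_tx, 0); res_tl <- max(res_tl, 0)

    act <- p$k_hyb * (p$theta * outer(pmax(Rt, 0), pmax(Rs, 0)))  # flux i->j
    dRt <- p$k_tx * inp * res_tx - p$delta_rna * Rt - rowSums(act)
    dRs <- p$k_tx * w * res_tx - p$delta_rna * Rs
    dC <- act - p$delta_rna * C

    transl_nm <- colSums(pmax(C, 0)) + p$k_leak * pmax(Rs, 0)  # per switch j
    v_tl <- p$k_tl * transl_nm * res_tl  # uM protein/min per switch
    dP <- sum(v_tl)

    flux_tx <- p$k_tx * (sum(inp) + sum(w)) * res_tx  # nM RNA/min
    flux_tl <- dP * 1000  # protein flux in nM/min

    if (mode == "direct") {
      dres_tx <- -p$lambda_res * res_tx - p$mu_res * flux_tx
      dres_tl <- -p$lambda_res * res_tl - p$mu_res * flux_tl
      return(list(c(dRt, dRs, as.vector(dC), dP, dres_tx, dres_tl)))
    }

    M <- y[19]; G <- y[20]; Af <- y[21]; AB <- y[22]
    S_free <- max(P - AB, 0)  # sigma28 not sequestered by anti
    v_bind <- p$k_on_anti * max(Af, 0) * S_free - k_off_anti * max(AB, 0)
    phi28 <- .holo28_one(S_free, p$rnap_total, p$sigma70, p$K28, p$K70)
    f_rep <- p$k_tx_rep * phi28 * rep_c * res_tx  # nM mRNA/min
    dM <- f_rep - p$delta_rna * M
    dG <- p$k_tl_rep * max(M, 0) * res_tl

    flux_tx <- flux_tx + f_rep
    flux_tl <- flux_tl + dG * 1000
    dres_tx <- -p$lambda_res * res_tx - p$mu_res * flux_tx
    dres_tl <- -p$lambda_res * res_tl - p$mu_res * flux_tl

    list(c(dRt, dRs, as.vector(dC), dP, dres_tx, dres_tl,
           dM, dG, -v_bind, v_bind))
  }

  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  states <- out[, -1, drop = FALSE]
  if (any(!is.finite(states))) {
    stop("integrator produced non-finite state; parameter regime too stiff ",
         "(check k_on_anti/kd_anti and resource rates)", call. = FALSE)
  }
  observed <- if (mode == "direct") states[, "P"] else states[, "G"]
  structure(list(times = times, states = states,
                 observed_deGFP = pmax(as.numeric(observed), 0),
                 spec = spec),
            class = "txtl_trajectory")
}

#' @export
print.txtl_trajectory <- function(x, ...) {
  cat("<txtl_trajectory>", x$spec$label, sprintf("[%s]", x$spec$mode),
      "-", length(x$times), "samples,", "endpoint",
      signif(endpoint(x), 4), "uM deGFP\n")
  invisible(x)
}

#' End-point expression level of a trajectory
#'
#' The readout of a batch expression experiment: observed deGFP at the
#' final sampled time point.
#'
#' @param traj a `txtl_trajectory`.
#' @return deGFP concentration (uM) at the last grid time.
#' @export
endpoint <- function(traj) {
  stopifnot(inherits(traj, "txtl_trajectory"))
  if (!length(traj$times)) stop("empty trajectory", call. = FALSE)
  traj$observed_deGFP[length(traj$observed_deGFP)]
}

#' Tidy export of a trajectory
#'
#' @param x a `txtl_trajectory`.
#' @param row.names,optional unused, for generic compatibility.
#' @param ... unused.
#' @return data.frame with columns `time_min`, `species`, `value`, `units`.
#' @export
as.data.frame.txtl_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  sp <- colnames(x$states)
  units <- ifelse(sp %in% c("P", "G", "Af", "AB"), "uM",
                  ifelse(sp %in% c("res_tx", "res_tl"), "fraction", "nM"))
  df <- data.frame(
    time_min = rep(x$times, times = length(sp)),
    species = rep(sp, each = length(x$times)),
    value = as.vector(x$states),
    units = rep(units, each = length(x$times)))
  rbind(df, data.frame(time_min = x$times, species = "observed_deGFP",
                       value = x$observed_deGFP, units = "uM"))
}
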