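# split-variable layout shared by fit_fluxes and substrate_atp_yield:
# v = f - b with f in [max(0,lb), max(0,ub)], b in [max(0,-ub), max(0,-lb)]
.split_bounds <- function(lb, ub) {
  list(flo = pmax(0, lb), fup = pmax(0, ub),
       blo = pmax(0, -ub), bup = pmax(0, -lb))
}

#' Fit a parsimonious flux distribution to measured exchange rates
#'
#' Solves the parsimonious flux-balance problem: find the steady-state flux
#' vector that reproduces every measured exchange rate while minimising the
#' total flux through the network,
#' \deqn{\min \sum_r |v_r| \quad s.t.\ S v = 0,\ lb \le v \le ub,\
#'       v_{ex(j)} = measured_j,}
#' with each flux split into non-negative forward and backward parts to
#' linearise the absolute values.  Uptake is a negative exchange rate,
#' secretion positive.
#'
#' @param model a [metabolic_model()].
#' @param profile named numeric vector of measured exchange rates keyed by
#'   metabolite identifier (or a one-row data.frame from
#'   [simulate_uptake_profiles()]); an optional `cell_line` attribute or
#'   column is carried through.
#' @return object of class `flux_distribution`: list with `reaction_ids`,
#'   `v` (named flux vector), `objective` (sum of |v|), `cell_line`.
#' @export
fit_fluxes <- function(model, profile) {
  pr <- .as_profile(profile)
  emap <- exchange_map(model)
  missing_ex <- setdiff(names(pr$rates), names(emap))
  if (length(missing_ex))
    stop("no exchange reaction for measured metabolite(s): ",
         paste(missing_ex, collapse = ", "))
  lb <- model$lb; ub <- model$ub
  for (m in names(pr$rates)) {
    id <- emap[[m]]
    lb[id] <- ub[id] <- pr$rates[[m]]
  }
  sb <- .split_bounds(lb, ub)
  nr <- length(model$rxns)
  Aeq <- cbind(model$S, -model$S)
  sol <- .solve_lp(obj = rep(1, 2 * nr), Aeq = Aeq,
                   beq = numeric(nrow(model$S)),
                   lb = c(sb$flo, sb$blo), ub = c(sb$fup, sb$bup),
                   maximise = FALSE)
  if (sol$status == "infeasible")
    stop("no steady-state flux satisfies the measured exchanges (",
         paste(sprintf("%s=%g", names(pr$rates), pr$rates), collapse = ", "),
         ")")
  if (sol$status == "unbounded")
    stop("flux fit unbounded: model defect (uncapped cycle)")
  if (sol$status != "optimal") stop("LP solver failed to converge")
  v <- sol$x[seq_len(nr)] - sol$x[nr + seq_len(nr)]
  names(v) <- model$rxns
  v[abs(v) < 1e-11] <- 0
  resid <- max(abs(model$S %*% v))
  if (resid > 1e-9)
    stop(sprintf("steady-state residual %.3g exceeds tolerance", resid))
  structure(list(reaction_ids = model$rxns, v = v,
                 objective = sum(abs(v)), cell_line = pr$cell_line),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution%s: %d reactions, total |v| = %.4f\n",
              if (is.na(x$cell_line)) "" else paste0(" (", x$cell_line, ")"),
              length(x$v), x$objective))
  invisible(x)
}

.as_profile <- function(profile) {
  cl <- NA_character_
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1)
      stop("profile data.frame must have exactly one row")
    if ("cell_line" %in% colnames(profile)) {
      cl <- as.character(profile$cell_line)
      profile <- profile[, setdiff(colnames(profile), "cell_line"),
                         drop = FALSE]
    }
    profile <- stats::setNames(as.numeric(profile[1, ]), colnames(profile))
  }
  if (!is.null(attr(profile, "cell_line"))) cl <- attr(profile, "cell_line")
  if (is.null(names(profile)) || any(!nzchar(names(profile))))
    stop("profile rates must be named by metabolite")
  if (!all(is.finite(profile))) stop("profile rates must be finite")
  list(rates = profile, cell_line = cl)
}

#' Total ATP production of a flux distribution
#'
#' Sum over reactions of the positive part of (ATP stoichiometry x flux) —
#' the total ATP synthesis rate.  Under the pseudo-steady-state assumption
#' this equals total ATP consumption.
#'
#' @param model a [metabolic_model()].
#' @param flux a `flux_distribution` from [fit_fluxes()].
#' @return non-negative scalar.
#' @export
total_atp <- function(model, flux) {
  arow <- model$S[model$atp, ]
  sum(pmax(0, arow * flux$v[model$rxns]))
}

#' Maximal ATP yield per unit uptake of a substrate
#'
#' Fixes the uptake of the given metabolite at one unit, closes the uptake
#' of every other organic metabolite (exchanges of the model's `inorganic`
#' species stay open), and maximises total ATP production at steady state.
#' The result is the ATP gained from full degradation and oxidation of one
#' unit of the substrate; an infeasible problem (no consuming pathway)
#' yields 0.
#'
#' @param model a [metabolic_model()].
#' @param metabolite metabolite identifier with an exchange reaction.
#' @return ATP yield per unit uptake (>= 0).
#' @export
substrate_atp_yield <- function(model, metabolite) {
  emap <- exchange_map(model)
  if (!metabolite %in% names(emap))
    stop("metabolite '", metabolite, "' has no exchange reaction")
  lb <- model$lb; ub <- model$ub
  for (m in names(emap)) {
    if (m %in% model$inorganic || m == metabolite) next
    id <- emap[[m]]
    lb[id] <- max(lb[id], 0)        # close uptake, keep secretion open
    ub[id] <- max(ub[id], 0)
  }
  tid <- emap[[metabolite]]
  lb[tid] <- ub[tid] <- -1
  sb <- .split_bounds(lb, ub)
  nr <- length(model$rxns)
  arow <- model$S[model$atp, ]
  # ATP production is linear in the split variables: forward flux produces
  # max(0, s) per unit, backward flux produces max(0, -s)
  obj <- c(pmax(0, arow), pmax(0, -arow))
  sol <- .solve_lp(obj = obj, Aeq = cbind(model$S, -model$S),
                   beq = numeric(nrow(model$S)),
                   lb = c(sb$flo, sb$blo), ub = c(sb$fup, sb$bup),
                   maximise = TRUE)
  if (sol$status == "infeasible") return(0)
  if (sol$status == "unbounded")
    stop("ATP yield unbounded: model defect (energy-generating cycle)")
  if (sol$status != "optimal") stop("LP solver failed to converge")
  max(0, sol$value)
}

#' Attribute ATP production to lactate fermentation and BCAA degradation
#'
#' From a fitted flux distribution and the measured exchange profile,
#' credits ATP to each source: the lactate secretion rate times the
#' glycolytic substrate-level yield (1 ATP per lactate, i.e. 2 ATP per
#' glucose fermented to 2 lactate; configurable), and each branched-chain
#' amino acid's uptake rate times its model-derived maximal ATP yield
#' ([substrate_atp_yield()]).  The remainder of total ATP production is
#' `frac_other`.
#'
#' @param model a [metabolic_model()].
#' @param flux `flux_distribution` fitted from `profile` with
#'   [fit_fluxes()].
#' @param profile the same measured exchange profile.
#' @param lactate,bcaa metabolite identifiers of lactate and of the three
#'   branched-chain amino acids (named `leu`, `ile`, `val`).
#' @param atp_per_lactate ATP credited per secreted lactate.
#' @return object of class `atp_breakdown`: list with `cell_line`,
#'   `total_atp`, per-source ATP rates, and fractions `frac_lactate`,
#'   `frac_leu`, `frac_ile`, `frac_val`, `frac_other` summing to 1.
#' @export
atp_breakdown <- function(model, flux, profile, lactate = "lac",
                          bcaa = c(leu = "leu", ile = "ile", val = "val"),
                          atp_per_lactate = 1) {
  pr <- .as_profile(profile)
  need <- c(lactate, bcaa)
  miss <- setdiff(need, names(pr$rates))
  if (length(miss))
    stop("profile lacks required metabolite(s): ", paste(miss, collapse = ", "))
  lac_rate <- pr$rates[[lactate]]
  if (lac_rate < 0)
    stop("lactate exchange is negative (uptake); attribution assumes secretion")
  atp_lac <- lac_rate * atp_per_lactate
  atp_aa <- vapply(bcaa, function(m) {
    upt <- max(0, -pr$rates[[m]])
    if (upt == 0) 0 else upt * substrate_atp_yield(model, m)
  }, numeric(1))
  total <- total_atp(model, flux)
  src <- c(lactate = atp_lac, atp_aa)
  if (total == 0) {
    if (any(src > 0))
      stop("total ATP production is zero but sources are nonzero")
    frac <- c(lactate = 0, leu = 0, ile = 0, val = 0)
    other <- 0
  } else {
    frac <- src / total
    other <- 1 - sum(frac)
    if (other < -1e-6)
      stop(sprintf("source ATP exceeds total production (residual %.3g)",
                   other))
    other <- max(0, other)
  }
  structure(list(cell_line = pr$cell_line, total_atp = total,
                 atp_lactate = atp_lac,
                 atp_leu = unname(atp_aa["leu"]),
                 atp_ile = unname(atp_aa["ile"]),
                 atp_val = unname(atp_aa["val"]),
                 frac_lactate = unname(frac["lactate"]),
                 frac_leu = unname(frac["leu"]),
                 frac_ile = unname(frac["ile"]),
                 frac_val = unname(frac["val"]),
                 frac_other = other),
            class = "atp_breakdown")
}

#' @export
print.atp_breakdown <- function(x, ...) {
  cat(sprintf("ATP breakdown%s: total %.3f\n",
              if (is.na(x$cell_line)) "" else paste0(" (", x$cell_line, ")"),
              x$total_atp))
  cat(sprintf("  lactate %.1f%%  Leu %.1f%%  Ile %.1f%%  Val %.1f%%  other %.1f%%\n",
              100 * x$frac_lactate, 100 * x$frac_leu, 100 * x$frac_ile,
              100 * x$frac_val, 100 * x$frac_other))
  invisible(x)
}

#' ATP source accounting for a table of uptake profiles
#'
#' Convenience wrapper running [fit_fluxes()] and [atp_breakdown()] for each
#' row of an uptake-rate table.
#'
#' @param model a [metabolic_model()].
#' @param profiles data.frame with a `cell_line` column and one signed-rate
#'   column per measured metabolite.
#' @param ... passed to [atp_breakdown()].
#' @return data.frame, one row per cell line, with total ATP and the five
#'   source fractions.
#' @export
atp_accounting <- function(model, profiles, ...) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, , drop = FALSE]
    fx <- fit_fluxes(model, pr)
    bd <- atp_breakdown(model, fx, pr, ...)
    data.frame(cell_line = bd$cell_line, total_atp = bd$total_atp,
               frac_lactate = bd$frac_lactate, frac_leu = bd$frac_leu,
               frac_ile = bd$frac_ile, frac_val = bd$frac_val,
               frac_other = bd$frac_other, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
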