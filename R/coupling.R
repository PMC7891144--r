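#' Parameter overrides for dopamine-model coupling
#'
#' When the clock's TH/MAO expression profiles are used to drive an
#' external dopamine synthesis/release/reuptake model, four dopaminergic
#' parameters are adjusted (regional variation between brain areas is
#' expected): `alpha_th = 3.7`, `b_th = 0`, `epsilon_th = 0.3`,
#' `d_m = 0.02`. These overrides apply only to the coupling computation,
#' not to the stand-alone clock simulations.
#'
#' @return Named list of the four overrides.
#' @export
da_coupling_overrides <- function() {
  list(alpha_th = 3.7, b_th = 0, epsilon_th = 0.3, d_m = 0.02)
}

#' Clock-driven expression profiles for an external dopamine model
#'
#' Applies the coupling overrides to the parameter set, entrains the model
#' under 12:12 light-dark, and returns the scaled TH and MAO expression
#' profiles `ETH(t)` and `EMAO(t)` over one Zeitgeber day
#' ([expression_profiles()]).
#'
#' The coupling contract for any plug-in dopamine model is multiplicative:
#' at time `t`, multiply the dopamine model's TH maximal rate (Vmax) by
#' `ETH(t)` and its MAO Vmax by `EMAO(t)`, either from the tabulated
#' profile (interpolate in ZT) or from a callable wrapping it. Both curves
#' have maximum 1, so the overrides never increase the plugin's nominal
#' maximal rates. The dopamine model itself is deliberately not
#' implemented here.
#'
#' @param params base [clock_params()].
#' @param overrides named parameter overrides applied before entrainment
#'   (default [da_coupling_overrides()]).
#' @param schedule a [light_schedule()].
#' @param ... passed to [entrain_clock()].
#' @return An `expression_profile` data frame (`ZT_hr`, `ETH`, `EMAO`).
#' @examples
#' \donttest{
#' prof <- coupling_profiles()
#' range(prof$ETH)
#' }
#' @export
coupling_profiles <- function(params = clock_params(),
                              overrides = da_coupling_overrides(),
                              schedule = light_schedule("LD"), ...) {
  if (length(overrides)) {
    params <- do.call(
      clock_params,
      utils::modifyList(as.list(unclass(params)), overrides)
    )
  }
  ent <- entrain_clock(params, schedule, ...)
  expression_profiles(ent)
}
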