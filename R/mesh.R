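# MeSH (mean shift plus homeostasis) policy learning and the perturbation
# variants used to model SPE-timed optogenetic inactivation.
#
# Per trial i the agent samples a speed gain a[i] ~ N(A[i], sigma_a) and a
# heading offset omega[i] ~ N(Omega[i], sigma_omega), executes the resulting
# trajectory and then updates the policy means:
#   A[i+1]     = A[i]     + alpha * (a[i]     - A[i])     * upsilon[i]
#                         - beta  * (a[i]     - A[0])
#   Omega[i+1] = Omega[i] + alpha * (omega[i] - Omega[i]) * upsilon[i]
#                         - beta  * (omega[i] - Omega[0])
# where upsilon[i] is an exponentially smoothed local reward rate that
# includes trial i's outcome.  The reward-gated mean shift drags the policy
# toward executed values that coincide with reward; the homeostatic term
# relaxes it toward the default (A[0], Omega[0]).

#' Policy state of the trajectory-learning agent
#'
#' @param A speed-gain mean (peak speed, units/s); sets trajectory amplitude
#'   through the linear gain-to-amplitude map.
#' @param Omega heading-offset mean, radians in `(-pi, pi]`.
#' @param A0,Omega0 homeostatic defaults (initial policy).
#' @param sigma_a,sigma_omega per-trial sampling standard deviations.
#' @return object of class `fl_policy_state`.
#' @export
policy_state <- function(A, Omega = pi, A0 = A, Omega0 = Omega,
                         sigma_a = 0.25 * A0, sigma_omega = 0.15) {
  check_number(A, "A", lower = 1e-12)
  check_number(A0, "A0", lower = 1e-12)
  check_number(Omega, "Omega", lower = -pi, upper = pi)
  check_number(Omega0, "Omega0", lower = -pi, upper = pi)
  check_number(sigma_a, "sigma_a", lower = 0)
  check_number(sigma_omega, "sigma_omega", lower = 0)
  structure(list(A = A, Omega = Omega, A0 = A0, Omega0 = Omega0,
                 sigma_a = sigma_a, sigma_omega = sigma_omega),
            class = "fl_policy_state")
}

#' Default STF policy for an arena
#'
#' The default policy is the behavior the agent reverts to: an out-and-back
#' loop whose amplitude matches the familiar (near) target distance, 34 cm
#' from the port, oriented into the arena.  The speed gain achieving that
#' amplitude is computed from the noiseless gain-to-amplitude map of `shape`.
#'
#' @param shape a [trajectory_shape()]; default [stf_shape()].
#' @param target_distance_cm amplitude of the default loop, cm.
#' @param cv_a per-trial speed-gain coefficient of variation.
#' @param sigma_omega per-trial heading sampling s.d., radians.
#' @return an `fl_policy_state`.
#' @export
default_stf_policy <- function(shape = stf_shape(), target_distance_cm = 34,
                               cv_a = 0.25, sigma_omega = 0.15) {
  a0 <- target_distance_cm / amplitude_gain(shape)
  policy_state(A = a0, Omega = pi, A0 = a0, Omega0 = pi,
               sigma_a = cv_a * a0, sigma_omega = sigma_omega)
}

#' Default NTF policy for a joystick task
#'
#' Push amplitude defaults to the middle of the first target band; the push
#' direction is chosen so the speed peak is directed along +y, and heading is
#' frozen during NTF learning (amplitude-only adaptation).
#'
#' @param shape a [trajectory_shape()]; default [ntf_shape()].
#' @param spec a [joystick_spec()].
#' @param cv_a per-trial gain coefficient of variation.
#' @param sigma_omega per-trial heading sampling s.d., radians.
#' @return an `fl_policy_state`.
#' @export
default_ntf_policy <- function(shape = ntf_shape(), spec = joystick_spec(),
                               cv_a = 0.25, sigma_omega = 0.05) {
  band1 <- spec$target_bands[[1]]
  a0 <- mean(band1) / amplitude_gain(shape)
  omega0 <- wrap_angle(pi / 2 - (-pi + 2 * pi * shape$tau[1] / shape$duration))
  policy_state(A = a0, Omega = omega0, A0 = a0, Omega0 = omega0,
               sigma_a = cv_a * a0, sigma_omega = sigma_omega)
}

#' MeSH learning-rate parameters
#'
#' @param alpha forward (reward-gated mean shift) learning rate per trial.
#' @param beta homeostatic relaxation rate per trial.
#' @param lambda exponential smoothing constant of the local reward rate.
#' @return object of class `fl_mesh_params`.
#' @export
mesh_params <- function(alpha = 0.4, beta = 0.01, lambda = 0.3) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(beta, "beta", lower = 0, upper = 1)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda > 1) {
    fl_stop("`lambda` must lie in (0, 1]", "invalid_input")
  }
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "fl_mesh_params")
}

#' Update the smoothed local reward rate
#'
#' `upsilon' = (1 - lambda) * upsilon_prev + lambda * rewarded`, which stays
#' in `[0, 1]`.
#'
#' @param upsilon_prev previous reward-rate estimate in `[0, 1]`.
#' @param rewarded logical outcome of the current trial.
#' @param lam smoothing constant in `(0, 1]`.
#' @return updated reward rate.
#' @export
update_reward_rate <- function(upsilon_prev, rewarded, lam) {
  check_number(upsilon_prev, "upsilon_prev", lower = 0, upper = 1)
  check_flag(rewarded, "rewarded")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam <= 0 || lam > 1) {
    fl_stop("`lam` must lie in (0, 1]", "invalid_input")
  }
  (1 - lam) * upsilon_prev + lam * as.numeric(rewarded)
}

#' Apply one MeSH update to the policy
#'
#' Applies the mean-shift-plus-homeostasis recursions to the speed-gain mean
#' and (circularly) to the heading-offset mean; all other fields are carried
#' over unchanged.  The heading update uses the signed circular difference so
#' that offsets near the +/-pi seam behave continuously, and the updated
#' `Omega` is wrapped back into `(-pi, pi]`.
#'
#' @param policy an `fl_policy_state`.
#' @param a_i executed speed gain for the trial.
#' @param omega_i executed heading offset for the trial, radians.
#' @param upsilon smoothed local reward rate for the trial.
#' @param params an [mesh_params()].
#' @return the updated `fl_policy_state`.
#' @export
mesh_update <- function(policy, a_i, omega_i, upsilon, params) {
  if (!inherits(policy, "fl_policy_state")) {
    fl_stop("`policy` must be a policy_state()", "invalid_input")
  }
  if (!inherits(params, "fl_mesh_params")) {
    fl_stop("`params` must be mesh_params()", "invalid_input")
  }
  check_number(a_i, "a_i", lower = 0)
  check_number(omega_i, "omega_i")
  check_number(upsilon, "upsilon", lower = 0, upper = 1)
  out <- policy
  out$A <- policy$A + params$alpha * (a_i - policy$A) * upsilon -
    params$beta * (a_i - policy$A0)
  out$Omega <- wrap_angle(
    policy$Omega + params$alpha * circ_diff(omega_i, policy$Omega) * upsilon -
      params$beta * circ_diff(omega_i, policy$Omega0)
  )
  out
}

#' Perturbation variant specification
#'
#' Models of what SPE-timed dCA1 inactivation does to the policy update on
#' perturbed (catch) trials:
#' \describe{
#'   \item{none}{no perturbation.}
#'   \item{default_policy}{the policy reverts to its default `(A0, Omega0)`.}
#'   \item{reward_not_detected}{the update is recomputed as if the trial were
#'     unrewarded (the agent fails to register the reward).}
#'   \item{learning_bias}{the MeSH increment is exaggerated 10-fold.}
#'   \item{reduced_learning}{the MeSH increment is scaled by a small gain in
#'     `[0, 0.1]` (default 0.05).}
#' }
#'
#' @param variant one of the variant names above.
#' @param gain increment multiplier; only used by `learning_bias` (10) and
#'   `reduced_learning` (in `[0, 0.1]`).
#' @param trial_mask integer trial indices on which the perturbation acts.
#' @return object of class `fl_perturbation_spec`.
#' @export
perturbation_spec <- function(variant = c("none", "default_policy",
                                          "reward_not_detected",
                                          "learning_bias", "reduced_learning"),
                              gain = NULL, trial_mask = integer(0)) {
  variant <- tryCatch(match.arg(variant),
                      error = function(e) fl_stop("unknown perturbation variant",
                                                  "configuration_error"))
  if (is.null(gain)) {
    gain <- switch(variant, learning_bias = 10, reduced_learning = 0.05, 1)
  }
  check_number(gain, "gain", lower = 0, class = "configuration_error")
  if (variant == "reduced_learning" && gain > 0.1) {
    fl_stop("reduced_learning gain must lie in [0, 0.1]", "configuration_error")
  }
  structure(list(variant = variant, gain = gain,
                 trial_mask = as.integer(trial_mask)),
            class = "fl_perturbation_spec")
}

#' Apply a perturbation variant to a base MeSH update
#'
#' Given the policy before and after the unperturbed MeSH update, returns the
#' policy that results when the trial is perturbed.  Trials not in the spec's
#' `trial_mask` pass through unchanged.  `reward_not_detected` recomputes the
#' update with the reward forced absent and therefore needs `context`: a list
#' with `a_i`, `omega_i`, `upsilon_prev` and `mesh` (the [mesh_params()]).
#'
#' @param before policy before the update.
#' @param after policy after the unperturbed update.
#' @param spec an [perturbation_spec()].
#' @param trial_index current trial index.
#' @param context extra state for `reward_not_detected` (see above).
#' @return the (possibly perturbed) `fl_policy_state`.
#' @export
apply_perturbation <- function(before, after, spec, trial_index,
                               context = NULL) {
  if (!inherits(spec, "fl_perturbation_spec")) {
    fl_stop("`spec` must be perturbation_spec()", "configuration_error")
  }
  if (spec$variant == "none" || !(trial_index %in% spec$trial_mask)) {
    return(after)
  }
  out <- after
  switch(spec$variant,
    default_policy = {
      out$A <- before$A0
      out$Omega <- before$Omega0
    },
    reward_not_detected = {
      if (is.null(context)) {
        fl_stop("reward_not_detected needs `context`", "configuration_error")
      }
      ups <- update_reward_rate(context$upsilon_prev, FALSE,
                                context$mesh$lambda)
      out <- mesh_update(before, context$a_i, context$omega_i, ups,
                         context$mesh)
    },
    learning_bias = ,
    reduced_learning = {
      out$A <- before$A + spec$gain * (after$A - before$A)
      out$Omega <- wrap_angle(
        before$Omega + spec$gain * circ_diff(after$Omega, before$Omega))
    }
  )
  out
}
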