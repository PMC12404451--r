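#' Advance a feedback controller by one step
#'
#' Generic single-step interface shared by every controller the closed-loop
#' simulator accepts. Implementations receive the current flow error
#' (setpoint minus measured flow, L/min) and the sample time, and return the
#' new valve command in `[0, 1]` together with the updated controller (all
#' controllers are immutable values; state is carried functionally).
#'
#' @param controller A controller object.
#' @param error Flow error, L/min.
#' @param dt Sample time, s.
#' @return A list with elements `command` (in `[0, 1]`) and `controller`.
#' @seealso [pid_controller()], [flc_controller()]
#' @export
control_step <- function(controller, error, dt) {
  UseMethod("control_step")
}

#' Constant-command controller
#'
#' Ignores the error and always outputs the same command. Useful for open-loop
#' excitation and as a degenerate reference in tests.
#'
#' @param command Fixed valve command in `[0, 1]`.
#' @return A controller usable with [run_closed_loop()].
#' @export
constant_controller <- function(command) {
  stopifnot(command >= 0, command <= 1)
  structure(list(command = command), class = c("constant_controller", "controller"))
}

#' @export
control_step.constant_controller <- function(controller, error, dt) {
  list(command = controller$command, controller = controller)
}
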