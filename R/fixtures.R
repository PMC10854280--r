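#' Bundled example networks
#'
#' Small worked networks shipped with the package:
#'
#' * `"toy3"` -- three variables, two steady states and one 2-cycle;
#'   used throughout to illustrate trajectories and attractors.
#' * `"modular4"` -- four variables in two strongly connected modules
#'   `{x1,x2} -> {x3,x4}`; the standard decomposition example.
#' * `"twoloop4"` -- two coupled two-variable feedback loops; the standard
#'   control example.
#' * `"disc"` -- the one-node DISC (death-inducing signalling complex)
#'   fragment of the published T-LGL leukemia model, with Ceramide, Fas
#'   and FLIP as external parameters; illustrates canalizing layers and
#'   module decoupling.
#' * `"tlgl"` -- placeholder for the full 16-node T-LGL leukemia model.
#'   Its update rules are not bundled; supply the published rule file via
#'   `path` to load it.
#'
#' @param name one of the fixture names above.
#' @param path optional user-supplied rule file, required for `"tlgl"`.
#' @return a `BooleanNetwork`.
#' @export
#' @examples
#' attractors(bn_example("toy3"))
bn_example <- function(name = c("toy3", "modular4", "twoloop4", "disc", "tlgl"),
                       path = NULL) {
  name <- match.arg(name)
  if (name == "tlgl") {
    if (is.null(path)) {
      stop(paste("the 16-node T-LGL leukemia model's update rules are not",
                 "bundled; download the published rule file and pass it via",
                 "'path' (rule format: one 'target, expression' line per",
                 "variable)"), call. = FALSE)
    }
    return(read_bnet(path))
  }
  file <- system.file("extdata", paste0(name, ".bnet"),
                      package = "bncontrol", mustWork = TRUE)
  read_bnet(file)
}
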