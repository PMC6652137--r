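# Classed conditions so callers (and the CLI) can map failures to categories.

v2g_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "v2g_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# category -> CLI exit code
v2g_exit_codes <- c(
  ok                    = 0L,
  v2g_usage_error       = 2L,
  v2g_missing_file      = 3L,
  v2g_parameter_error   = 4L,
  v2g_input_error       = 5L,
  v2g_version_error     = 6L,
  v2g_empty_panel_error = 7L,
  v2g_error             = 1L   # uncategorised package error
)

err_usage       <- function(msg) v2g_error("v2g_usage_error", msg)
err_missing     <- function(msg) v2g_error("v2g_missing_file", msg)
err_parameter   <- function(msg) v2g_error("v2g_parameter_error", msg)
err_input       <- function(msg) v2g_error("v2g_input_error", msg)
err_version     <- function(msg) v2g_error("v2g_version_error", msg)
err_empty_panel <- function(msg) v2g_error("v2g_empty_panel_error", msg)
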