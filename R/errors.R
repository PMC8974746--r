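# Classed conditions so callers (and the CLI exit-code mapping) can tell
# configuration/validation problems apart from I/O and parse problems.

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("allerscreen_parse_error", "allerscreen_error")))
}

stop_args <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("allerscreen_argument_error", "allerscreen_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("allerscreen_config_error", "allerscreen_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("allerscreen_schema_error", "allerscreen_parse_error",
                                "allerscreen_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("allerscreen_io_error", "allerscreen_error")))
}
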