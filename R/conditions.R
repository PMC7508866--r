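#' @keywords internal
oat_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "oatopo_error", "error")))
}

oat_check <- function(ok, msg, class = "oatopo_validation") {
  if (!isTRUE(ok)) oat_stop(msg, class)
  invisible(TRUE)
}
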