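# internal validation helpers --------------------------------------------

cea_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(paste0("crswnp_", subclass), "crswnp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 0 || all(is.na(x)))) {
    return(invisible(x))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    cea_stop("validation", "`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    cea_stop("validation", "`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
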