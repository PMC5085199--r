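## internal helpers shared across modules

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) & !is.na(x) & x == floor(x) & x >= 0

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

## back-transform from an analysis scale to the reporting scale
report_transform <- function(measure) {
  switch(measure,
    log_rom = exp, log_or = exp,
    logit_sens = expit, logit_spec = expit,
    log_plr = exp, log_nlr = exp,
    stopf("unknown measure '%s'", measure)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
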