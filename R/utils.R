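# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## round half away from zero (round() is half-to-even); used by the
## tolerant off-ladder policy so that e.g. 1.5 repeat units -> 2
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## per-allele Bruvo contribution under the stepwise mutation model
bruvoStep <- function(x) 1 - 2^(-x)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
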