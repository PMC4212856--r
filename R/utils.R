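# internal helpers shared across modules

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "aflpsgs_error")))
}

.assert <- function(cond, msg, class = "aflpsgs_invalid") {
  if (!isTRUE(cond)) .err(msg, class)
  invisible(TRUE)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

.is_prop <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# set the RNG state locally when a seed is supplied; NULL leaves the
# caller's stream untouched
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    .assert(.is_count(abs(seed)) || (is.numeric(seed) && seed == round(seed)),
            "seed must be a whole number", "aflpsgs_invalid")
    set.seed(as.integer(seed))
  }
  expr
}

.logit <- function(x) log(x / (1 - x))
.ilogit <- function(x) 1 / (1 + exp(-x))
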