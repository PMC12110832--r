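# Internal helpers shared across modules.

# Smallest p-value carried through log transforms; avoids -Inf in RS scores.
.P_FLOOR <- 1e-300

.stop_icplnc <- function(..., class) {
  stop(structure(
    class = c(class, "icplnc_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

.assert <- function(ok, ..., class = "icplnc_contract_error") {
  if (!isTRUE(ok)) .stop_icplnc(..., class = class)
  invisible(TRUE)
}

# Two-sided p-value from a t statistic, floored so downstream logs are finite.
.t_pvalue <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df = df)
  pmin(pmax(p, .P_FLOOR), 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code does not clobber user seeds.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.msg <- function(...) message("[icplnc] ", ...)
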